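#' Build a simulation configuration for a synthetic treatment-response cohort
#'
#' The generator emulates a naturalistic psychiatric cohort: panel and
#' background genotypes with optional LD blocks and population structure,
#' demographics, longitudinal CGI-S/CGI-I observations and treatment events,
#' and a latent logistic response model with known ground truth. Defaults
#' describe a 460-subject cohort with responder fraction ~0.54 and a
#' per-PRS-unit odds ratio of 1.14.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param panel Score panel data frame (see [read_score_file()]) with an
#'   additional `eaf` column of effect-allele frequencies in (0,1). Defaults to
#'   the packaged 11-SNP response panel with [response_panel_eaf()].
#' @param ld_blocks Optional list of LD blocks, each `list(ids = <character>,
#'   r2 = <target squared correlation in [0,1]>)`. Members of a block must
#'   share the same effect-allele frequency; the first id is the anchor.
#' @param n_background_variants Number of additional independent variants (for
#'   PCA and QC exercises), with frequencies drawn uniformly in (0.05, 0.5).
#' @param n_subpopulations Number of subpopulations; allele frequencies drift
#'   between them under a Balding-Nichols model.
#' @param fst Drift parameter in \[0, 0.2\]; 0 disables structure.
#' @param true_log_or Per-PRS-unit log odds ratio of response (ground truth).
#' @param age_log_or Per-year log odds ratio of response.
#' @param subpop_log_or Additive log-odds shift for subjects outside the first
#'   subpopulation (induces an ancestry effect recoverable through PCs).
#' @param intercept Log-odds intercept; with covariates centered it controls
#'   the responder fraction (`plogis(intercept)` approximately).
#' @param missing_rate Per-entry genotype missingness probability in \[0, 0.1\].
#' @param observation_window_days Clinical observation window (days).
#' @param label_fidelity Fraction of subjects whose CGI/event trajectory is
#'   constructed to agree with their latent responder status (default 1).
#' @param age_range Two-element vector of uniform age bounds in years.
#' @param seed Integer seed; identical configs and seeds give byte-identical
#'   cohorts.
#' @return A validated object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 460,
                       panel = NULL,
                       ld_blocks = NULL,
                       n_background_variants = 200,
                       n_subpopulations = 2,
                       fst = 0.02,
                       true_log_or = log(1.14),
                       age_log_or = -0.02,
                       subpop_log_or = 0,
                       intercept = stats::qlogis(249 / 460),
                       missing_rate = 0.002,
                       observation_window_days = 365L,
                       label_fidelity = 1.0,
                       age_range = c(18, 80),
                       seed = 1L) {
  if (is.null(panel)) {
    panel <- response_panel()
    panel$eaf <- unname(response_panel_eaf()[panel$snp_id])
  }
  cfg <- structure(list(
    n_subjects = as.integer(n_subjects), panel = panel, ld_blocks = ld_blocks,
    n_background_variants = as.integer(n_background_variants),
    n_subpopulations = as.integer(n_subpopulations), fst = fst,
    true_log_or = true_log_or, age_log_or = age_log_or,
    subpop_log_or = subpop_log_or, intercept = intercept,
    missing_rate = missing_rate,
    observation_window_days = as.integer(observation_window_days),
    label_fidelity = label_fidelity, age_range = age_range,
    seed = as.integer(seed)), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#' @param cfg A `sim_config`.
#' @return `cfg`, invisibly; errors describe the first violated invariant.
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.na(cfg$n_subjects) || cfg$n_subjects < 2) stop("n_subjects must be >= 2")
  validate_score_panel(cfg$panel)
  if (!"eaf" %in% names(cfg$panel)) stop("simulation panel needs an 'eaf' column")
  eaf <- cfg$panel$eaf
  maf <- pmin(eaf, 1 - eaf)
  if (any(!is.finite(eaf)) || any(maf <= 0) || any(maf > 0.5)) {
    stop("panel minor allele frequencies must lie in (0, 0.5]")
  }
  if (cfg$missing_rate < 0 || cfg$missing_rate > 0.1) {
    stop("missing_rate must lie in [0, 0.1]")
  }
  if (cfg$fst < 0 || cfg$fst > 0.2) stop("fst must lie in [0, 0.2]")
  if (cfg$n_subpopulations < 1) stop("n_subpopulations must be >= 1")
  if (!is.finite(cfg$intercept)) {
    stop("intercept must be finite (implied responder fraction strictly in (0,1))")
  }
  if (cfg$label_fidelity < 0 || cfg$label_fidelity > 1) {
    stop("label_fidelity must lie in [0, 1]")
  }
  if (!is.null(cfg$ld_blocks)) {
    for (b in cfg$ld_blocks) {
      if (is.null(b$ids) || length(b$ids) < 2) stop("an LD block needs >= 2 variant ids")
      if (!all(b$ids %in% cfg$panel$snp_id)) {
        stop("LD block references unknown panel variant(s)")
      }
      if (is.null(b$r2) || b$r2 < 0 || b$r2 > 1) stop("LD block target r2 must lie in [0,1]")
      f <- cfg$panel$eaf[match(b$ids, cfg$panel$snp_id)]
      if (length(unique(round(f, 12))) > 1) {
        stop("target r2 incompatible with unequal allele frequencies in LD block (",
             paste(b$ids, collapse = ", "), "): block members must share one frequency")
      }
    }
  }
  invisible(cfg)
}

## internal: Balding-Nichols subpopulation frequencies for one ancestral p
bn_freq <- function(p, k, fst) {
  if (fst <= 0 || k == 1) return(rep(p, k))
  a <- p * (1 - fst) / fst
  b <- (1 - p) * (1 - fst) / fst
  pmin(pmax(stats::rbeta(k, a, b), 1e-4), 1 - 1e-4)
}

#' Simulate genotypes for a synthetic cohort
#'
#' Draws hard-call genotypes (0/1/2 effect-allele counts) for the panel plus
#' independent background variants. Subjects are split evenly across
#' subpopulations whose allele frequencies drift from the configured values
#' under a Balding-Nichols model. LD blocks are induced by copy-with-resample:
#' a member matches its anchor with probability `sqrt(r2)`, giving pairwise
#' dosage correlation `sqrt(r2)` and hence squared correlation `r2`.
#' Missingness is applied entrywise at `missing_rate`; the complete matrix is
#' kept in the `complete_dosage` attribute for ground-truth scoring.
#'
#' @param config A [sim_config()].
#' @return A [genotype_matrix()] with attributes `complete_dosage` (matrix
#'   before missingness) and `subpop` (integer subpopulation per subject).
#' @export
simulate_genotypes <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_subjects
  k <- config$n_subpopulations
  subpop <- sort(rep_len(seq_len(k), n))

  pv <- config$panel
  n_bg <- config$n_background_variants
  bg_eaf <- if (n_bg > 0) stats::runif(n_bg, 0.05, 0.5) else numeric(0)
  variants <- data.frame(
    id = c(pv$snp_id, if (n_bg > 0) sprintf("bg%04d", seq_len(n_bg))),
    chrom = c(pv$chr, rep("20", n_bg)),
    pos = c(pv$pos, if (n_bg > 0) 1000000L * seq_len(n_bg) else integer(0)),
    ref = c(pv$other_allele, rep("A", n_bg)),
    alt = c(pv$effect_allele, rep("G", n_bg)),
    stringsAsFactors = FALSE)
  eaf <- c(pv$eaf, bg_eaf)
  m <- length(eaf)

  # subpopulation-specific frequencies, one draw per variant
  freq <- matrix(vapply(eaf, bn_freq, numeric(k), k = k, fst = config$fst),
                 nrow = k)  # k x m
  dosage <- matrix(0, n, m)
  for (j in seq_len(m)) {
    dosage[, j] <- stats::rbinom(n, 2L, freq[subpop, j])
  }
  colnames(dosage) <- variants$id

  # LD blocks: members copy the anchor with probability sqrt(r2)
  if (!is.null(config$ld_blocks)) {
    for (b in config$ld_blocks) {
      anchor <- dosage[, b$ids[1]]
      q <- sqrt(b$r2)
      for (id in b$ids[-1]) {
        copy <- stats::runif(n) < q
        dosage[copy, id] <- anchor[copy]
      }
    }
  }

  complete <- dosage
  if (config$missing_rate > 0) {
    mask <- matrix(stats::runif(n * m) < config$missing_rate, n, m)
    dosage[mask] <- NA_real_
  }
  gm <- genotype_matrix(dosage, variants,
                        subjects = sprintf("S%04d", seq_len(n)))
  attr(gm, "complete_dosage") <- complete
  attr(gm, "subpop") <- subpop
  gm
}

## prescribing mix of a naturalistic cohort: drug, median daily dose (mg), weight
antipsychotic_mix <- function() {
  data.frame(
    drug = c("amisulpride", "aripiprazole", "clozapine", "haloperidol",
             "lurasidone", "levomepromazine", "olanzapine", "paliperidone",
             "quetiapine", "risperidone", "tiapride", "zuclopenthixol"),
    dose = c(400, 10, 200, 5, 40, 25, 10, 6, 400, 4, 400, 30),
    weight = c(38, 93, 32, 10, 13, 1, 55, 6, 116, 92, 1, 3),
    stringsAsFactors = FALSE)
}

## diagnosis mix: ICD-10 code and sampling weight
diagnosis_mix <- function() {
  data.frame(
    code = c("F20.0", "F25.0", "F31.0", "F23.9", "F32.9", "F03.9", "F19.9", "F99"),
    weight = c(149, 27, 59, 129, 42, 17, 9, 28),
    stringsAsFactors = FALSE)
}

#' Simulate phenotypes, clinical trajectories and ground truth
#'
#' Draws responder status from a logistic model on the true (complete-genotype)
#' PRS and age, then constructs CGI-S/CGI-I observations and treatment events
#' so that the response rule engine recovers the latent status for a
#' `label_fidelity` fraction of subjects. Responder trajectories carry one of
#' the response signals (a >= 2-point CGI-S drop across visits >= 30 days
#' apart, a CGI-S of 1, or a CGI-I <= 2) and none of the disqualifiers;
#' non-responder trajectories carry an add-on, switch, post-90-day dose
#' increase, discontinuation for inefficacy, or a flat CGI course.
#'
#' @param genotypes Output of [simulate_genotypes()] for the same config.
#' @param config The same [sim_config()].
#' @param include_clinical If `FALSE`, skip CGI/event construction (fast path
#'   for statistical calibration studies); the bundle then contains empty
#'   clinical tables.
#' @return An object of class `cohort_bundle`: list with `genotypes`,
#'   `subjects`, `cgi`, `events`, `truth`, `config`, and a `degenerate` flag
#'   set when the drawn outcome is single-class.
#' @export
simulate_phenotypes <- function(genotypes, config, include_clinical = TRUE) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  validate_sim_config(config)
  set.seed(config$seed + 1000003L)
  n <- config$n_subjects
  complete <- attr(genotypes, "complete_dosage")
  if (is.null(complete)) {
    complete <- genotypes$dosage
    complete[is.na(complete)] <- 0
  }
  w <- config$panel$weight
  idx <- match(config$panel$snp_id, genotypes$variants$id)
  if (anyNA(idx)) stop("genotypes do not contain the config panel variants")
  true_prs <- as.numeric(complete[, idx, drop = FALSE] %*% w)

  age <- stats::runif(n, config$age_range[1], config$age_range[2])
  sex <- sample(c("F", "M"), n, replace = TRUE)
  dx <- diagnosis_mix()
  diagnosis <- sample(dx$code, n, replace = TRUE, prob = dx$weight)
  admissions <- stats::rpois(n, 2)
  substance <- stats::runif(n) < 0.16
  ses <- round(stats::runif(n, 14, 81), 1)

  subpop <- attr(genotypes, "subpop")
  if (is.null(subpop)) subpop <- rep(1L, n)
  pop_shift <- ifelse(subpop > 1, config$subpop_log_or, 0)
  eta <- config$intercept +
    config$true_log_or * (true_prs - mean(true_prs)) +
    config$age_log_or * (age - mean(age)) +
    (pop_shift - mean(pop_shift))
  p_resp <- stats::plogis(eta)
  responder <- stats::rbinom(n, 1L, p_resp) == 1L
  degenerate <- length(unique(responder)) < 2
  if (degenerate) {
    warning("degenerate configuration: simulated outcome is single-class")
  }

  subjects <- data.frame(
    subject_id = genotypes$subjects, age = round(age, 1), sex = sex,
    diagnosis = diagnosis, admissions = admissions,
    substance_abuse = substance, ses = ses, stringsAsFactors = FALSE)
  truth <- data.frame(
    subject_id = genotypes$subjects, true_prs = true_prs,
    liability = p_resp, true_responder = responder, stringsAsFactors = FALSE)

  cgi <- events <- NULL
  if (include_clinical) {
    if (config$observation_window_days < 240) {
      stop("clinical trajectory construction needs observation_window_days >= 240; ",
           "use include_clinical = FALSE for shorter windows")
    }
    faithful <- stats::runif(n) < config$label_fidelity
    shown <- ifelse(faithful, responder, !responder)
    start <- as.Date("2015-01-01") + sample(0:1499, n, replace = TRUE)
    traj <- vector("list", n)
    ev <- vector("list", n)
    mix <- antipsychotic_mix()
    drug_row <- sample(nrow(mix), n, replace = TRUE, prob = mix$weight)
    win <- config$observation_window_days
    for (i in seq_len(n)) {
      sid <- genotypes$subjects[i]
      t0 <- start[i]
      ev_i <- data.frame(subject_id = sid, date = t0, kind = "start",
                         drug = mix$drug[drug_row[i]], dose = mix$dose[drug_row[i]],
                         reason = NA_character_, stringsAsFactors = FALSE)
      if (shown[i]) {
        mech <- sample(c("cgi_drop", "cgi_one", "cgi_i"), 1)
        base <- sample(4:6, 1)
        d1 <- sample(45:min(200, win - 30), 1)
        d2 <- min(d1 + sample(60:120, 1), win)
        cgi_i <- switch(mech,
          cgi_drop = data.frame(
            subject_id = sid, date = t0 + c(0, d1, d2), scale = "CGI-S",
            value = c(base, base - 2, max(base - 2 - sample(0:1, 1), 1)),
            stringsAsFactors = FALSE),
          cgi_one = data.frame(
            subject_id = sid, date = t0 + c(0, d1), scale = "CGI-S",
            value = c(base, 1L), stringsAsFactors = FALSE),
          cgi_i = rbind(
            data.frame(subject_id = sid, date = t0 + 0, scale = "CGI-S",
                       value = base, stringsAsFactors = FALSE),
            data.frame(subject_id = sid, date = t0 + d1, scale = "CGI-I",
                       value = sample(1:2, 1), stringsAsFactors = FALSE)))
        # an early dose increase (before day 90) does not disqualify response
        if (stats::runif(1) < 0.2) {
          ev_i <- rbind(ev_i, data.frame(
            subject_id = sid, date = t0 + sample(10:80, 1),
            kind = "dose_increase", drug = mix$drug[drug_row[i]],
            dose = mix$dose[drug_row[i]] * 1.5, reason = NA_character_,
            stringsAsFactors = FALSE))
        }
      } else {
        mech <- sample(c("addon", "late_increase", "switch", "stop_inefficacy", "flat"), 1)
        base <- sample(4:6, 1)
        # CGI never improves by >= 2 from any earlier visit and never hits 1
        days <- c(0, sample(30:160, 1), sample(190:min(340, win), 1))
        v2 <- base + sample(-1:1, 1)
        v3 <- base + sample(seq(max(-1, v2 - base - 1), 1), 1)
        vals <- pmin(pmax(c(base, v2, v3), 2), 7)
        cgi_i <- data.frame(subject_id = sid, date = t0 + days, scale = "CGI-S",
                            value = vals, stringsAsFactors = FALSE)
        extra <- switch(mech,
          addon = data.frame(
            subject_id = sid, date = t0 + sample(30:300, 1),
            kind = sample(c("addon_antipsychotic", "addon_mood_stabilizer"), 1),
            drug = "adjunct", dose = NA_real_, reason = NA_character_,
            stringsAsFactors = FALSE),
          late_increase = data.frame(
            subject_id = sid, date = t0 + sample(95:300, 1),
            kind = "dose_increase", drug = mix$drug[drug_row[i]],
            dose = mix$dose[drug_row[i]] * 2, reason = NA_character_,
            stringsAsFactors = FALSE),
          switch = data.frame(
            subject_id = sid, date = t0 + sample(95:300, 1), kind = "switch",
            drug = "alternative", dose = NA_real_, reason = NA_character_,
            stringsAsFactors = FALSE),
          stop_inefficacy = data.frame(
            subject_id = sid, date = t0 + sample(100:300, 1),
            kind = "discontinuation", drug = mix$drug[drug_row[i]],
            dose = NA_real_, reason = "inefficacy", stringsAsFactors = FALSE),
          flat = NULL)
        if (!is.null(extra)) ev_i <- rbind(ev_i, extra)
      }
      traj[[i]] <- cgi_i
      ev[[i]] <- ev_i
    }
    cgi <- do.call(rbind, traj)
    events <- do.call(rbind, ev)
    rownames(cgi) <- rownames(events) <- NULL
  } else {
    cgi <- data.frame(subject_id = character(0), date = as.Date(character(0)),
                      scale = character(0), value = integer(0))
    events <- data.frame(subject_id = character(0), date = as.Date(character(0)),
                         kind = character(0), drug = character(0),
                         dose = numeric(0), reason = character(0))
  }

  structure(list(genotypes = genotypes, subjects = subjects, cgi = cgi,
                 events = events, truth = truth, config = config,
                 degenerate = degenerate),
            class = "cohort_bundle")
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper running [simulate_genotypes()] then
#' [simulate_phenotypes()].
#'
#' @inheritParams simulate_phenotypes
#' @param config A [sim_config()].
#' @return A `cohort_bundle` (see [simulate_phenotypes()]).
#' @export
simulate_cohort <- function(config, include_clinical = TRUE) {
  gm <- simulate_genotypes(config)
  simulate_phenotypes(gm, config, include_clinical = include_clinical)
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat("cohort_bundle:", nrow(x$subjects), "subjects,",
      nrow(x$genotypes$variants), "variants;",
      sum(x$truth$true_responder), "latent responders\n")
  invisible(x)
}

#' Write a cohort bundle to disk
#'
#' Writes genotypes as gzipped VCF (`genotypes.vcf.gz`), subject/CGI/event and
#' ground-truth tables as UTF-8 TSV with ISO-8601 dates, and the configuration
#' as YAML.
#'
#' @param bundle A `cohort_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(bundle, dir) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genotypes_vcf(bundle$genotypes, file.path(dir, "genotypes.vcf.gz"))
  wt <- function(df, f) utils::write.table(
    df, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE,
    fileEncoding = "UTF-8")
  wt(bundle$subjects, "subjects.tsv")
  cgi <- bundle$cgi; cgi$date <- format(cgi$date, "%Y-%m-%d")
  wt(cgi, "cgi.tsv")
  ev <- bundle$events; ev$date <- format(ev$date, "%Y-%m-%d")
  wt(ev, "events.tsv")
  wt(bundle$truth, "ground_truth.tsv")
  cfg <- bundle$config
  cfg_list <- unclass(cfg)
  cfg_list$panel <- NULL  # panel travels as the score file
  yaml::write_yaml(cfg_list, file.path(dir, "config.yaml"))
  write_score_file(bundle$config$panel[, c("snp_id", "chr", "pos", "effect_allele",
                                           "other_allele", "weight", "p")],
                   file.path(dir, "score_panel.tsv"))
  invisible(dir)
}
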