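#' Genotype-by-response contingency table
#'
#' Cross-tabulates hard-call genotypes (0/1/2 copies of the counted allele)
#' against a binary responder indicator.
#'
#' @param dosages Numeric dosages for one variant (NA = missing; rounded to
#'   hard calls).
#' @param responder Logical (or 0/1) vector, same length.
#' @return 3x2 integer matrix, rows genotype 0/1/2, columns
#'   responder/non-responder.
#' @export
genotype_contingency <- function(dosages, responder) {
  if (length(dosages) != length(responder)) stop("length mismatch")
  responder <- as.logical(responder)
  ok <- !is.na(dosages) & !is.na(responder)
  g <- factor(round(dosages[ok]), levels = 0:2)
  r <- factor(ifelse(responder[ok], "responder", "non_responder"),
              levels = c("responder", "non_responder"))
  tab <- table(g, r)
  m <- matrix(as.integer(tab), 3, 2,
              dimnames = list(genotype = 0:2,
                              group = c("responder", "non_responder")))
  m
}

#' Cochran-Armitage trend test
#'
#' Chi-square test for trend in responder proportions across genotype scores
#' 0/1/2 (one degree of freedom, two-sided).
#'
#' @param table 3x2 matrix of counts, rows genotype 0/1/2, columns
#'   responder/non-responder (as from [genotype_contingency()]).
#' @param scores Genotype scores (default 0:2).
#' @return List with `statistic`, `p`, `df = 1`.
#' @export
trend_test <- function(table, scores = 0:2) {
  table <- as.matrix(table)
  if (nrow(table) != 3 || ncol(table) != 2) stop("need a 3x2 table")
  if (any(colSums(table) < 1)) stop("both group totals must be >= 1")
  totals <- rowSums(table)
  if (all(totals == 0)) stop("empty table")
  keep <- totals > 0
  # prop.trend.test warns via its internal anova() on saturated tables; the
  # chi-square statistic itself is unaffected
  tt <- suppressWarnings(
    stats::prop.trend.test(table[keep, 1], totals[keep], score = scores[keep]))
  list(statistic = unname(tt$statistic), p = tt$p.value, df = 1L)
}

#' Genotypic Fisher exact test
#'
#' Exact test of independence on the 3x2 genotype-by-response table
#' (conditional on the margins). For large tables an explicit limit guards
#' runtime; beyond it a Monte-Carlo p-value can be requested.
#'
#' @param table 3x2 matrix of counts.
#' @param enumeration_limit Maximum total count for the exact computation.
#' @param monte_carlo If `TRUE`, use a simulated p-value (with `B` replicates)
#'   regardless of size.
#' @param B Monte-Carlo replicates.
#' @return Exact (or simulated) p-value in (0,1].
#' @export
fisher_exact_genotypic <- function(table, enumeration_limit = 10000,
                                   monte_carlo = FALSE, B = 10000) {
  table <- as.matrix(table)
  if (monte_carlo) {
    return(stats::fisher.test(table, simulate.p.value = TRUE, B = B)$p.value)
  }
  if (sum(table) > enumeration_limit) {
    stop("table total exceeds enumeration_limit (", enumeration_limit,
         "); use monte_carlo = TRUE")
  }
  stats::fisher.test(table)$p.value
}

#' Allelic odds ratio from a genotype contingency table
#'
#' Collapses genotypes to allele counts (2 x hom + het per group) and reports
#' the odds ratio of carrying the counted allele in responders versus
#' non-responders, with a Woolf (log-OR +/- 1.96 SE) confidence interval. When
#' any allele cell is zero the Haldane-Anscombe 0.5 correction is applied and
#' flagged.
#'
#' @param table 3x2 matrix, rows genotype 0/1/2 copies of the counted allele,
#'   columns responder/non-responder.
#' @return Data frame of class `association_result` with `beta` (log OR), `se`,
#'   `or`, `ci_low`, `ci_high`, `p`, `n`; attribute `haldane` flags the
#'   correction.
#' @export
allelic_odds_ratio <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) != 3 || ncol(table) != 2) stop("need a 3x2 table")
  eff <- 2 * table[3, ] + table[2, ]   # counted-allele count per group
  oth <- 2 * table[1, ] + table[2, ]
  if (any(eff + oth == 0)) stop("a group has no observed alleles")
  cells <- c(eff[1], oth[1], eff[2], oth[2])
  haldane <- any(cells == 0)
  if (haldane) cells <- cells + 0.5
  beta <- log(cells[1] / cells[2]) - log(cells[3] / cells[4])
  se <- sqrt(sum(1 / cells))
  z <- beta / se
  out <- data.frame(predictor = "allele", beta = beta, se = se,
                    or = exp(beta), ci_low = exp(beta - 1.96 * se),
                    ci_high = exp(beta + 1.96 * se),
                    p = 2 * stats::pnorm(-abs(z)), n = sum(table),
                    stringsAsFactors = FALSE)
  attr(out, "haldane") <- haldane
  class(out) <- c("association_result", "data.frame")
  out
}

#' Covariate-adjusted logistic association model
#'
#' Maximum-likelihood logistic regression of a binary response on a score and
#' covariates, with Wald standard errors, odds ratios and 95 percent Wald
#' confidence intervals per predictor. Perfect separation and non-convergence
#' raise errors rather than returning misleading estimates.
#'
#' @param outcome Logical or 0/1 response vector (both classes present, no NA).
#' @param design Data frame of numeric predictors (no missing values). The
#'   canonical design is the PRS plus age and the first five ancestry PCs.
#' @return Data frame of class `association_result`, one row per predictor
#'   (intercept excluded): `predictor`, `beta`, `se`, `or`, `ci_low`,
#'   `ci_high`, `p`, `n`; attribute `converged`.
#' @export
fit_logistic <- function(outcome, design) {
  outcome <- as.numeric(as.logical(outcome))
  if (anyNA(outcome) || anyNA(design)) stop("missing values in outcome or design")
  if (length(unique(outcome)) < 2) stop("outcome must contain both classes")
  design <- as.data.frame(design)
  dat <- cbind(.y = outcome, design)
  fit <- suppressWarnings(
    stats::glm(.y ~ ., data = dat, family = stats::binomial()))
  mu <- fit$fitted.values
  eps <- 1e-7
  sep <- all(mu[outcome == 1] > 1 - eps) && all(mu[outcome == 0] < eps)
  if (sep) {
    stop("perfect separation detected: a linear combination of the design ",
         "predicts the outcome exactly; coefficients diverge")
  }
  if (!fit$converged) stop("logistic model did not converge")
  sm <- summary(fit)$coefficients
  sm <- sm[rownames(sm) != "(Intercept)", , drop = FALSE]
  out <- data.frame(predictor = rownames(sm), beta = sm[, 1], se = sm[, 2],
                    or = exp(sm[, 1]),
                    ci_low = exp(sm[, 1] - 1.96 * sm[, 2]),
                    ci_high = exp(sm[, 1] + 1.96 * sm[, 2]),
                    p = sm[, 4], n = length(outcome),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "converged") <- fit$converged
  class(out) <- c("association_result", "data.frame")
  out
}

#' Univariate confounder screen
#'
#' For each candidate covariate, fits a univariate linear-probability model and
#' a univariate logistic model against the response and flags candidates with
#' linear-model p <= `alpha` for inclusion in the multivariate model. Constant
#' covariates are skipped with a flag.
#'
#' @param candidates Data frame of numeric or binary candidate covariates.
#' @param outcome Logical or 0/1 response vector.
#' @param alpha Inclusion threshold (default 0.05).
#' @return Data frame with `covariate`, `beta_linear`, `p_linear`,
#'   `beta_logistic`, `p_logistic`, `flagged`, `skipped`.
#' @export
univariate_screen <- function(candidates, outcome, alpha = 0.05) {
  outcome <- as.numeric(as.logical(outcome))
  rows <- lapply(names(candidates), function(nm) {
    x <- candidates[[nm]]
    if (is.logical(x) || is.character(x)) x <- as.numeric(as.factor(x))
    ok <- !is.na(x) & !is.na(outcome)
    if (length(unique(x[ok])) < 2) {
      return(data.frame(covariate = nm, beta_linear = NA_real_,
                        p_linear = NA_real_, beta_logistic = NA_real_,
                        p_logistic = NA_real_, flagged = FALSE, skipped = TRUE,
                        stringsAsFactors = FALSE))
    }
    lf <- stats::lm(outcome[ok] ~ x[ok])
    ls <- summary(lf)$coefficients
    gf <- suppressWarnings(stats::glm(outcome[ok] ~ x[ok], family = stats::binomial()))
    gs <- summary(gf)$coefficients
    data.frame(covariate = nm, beta_linear = ls[2, 1], p_linear = ls[2, 4],
               beta_logistic = gs[2, 1], p_logistic = gs[2, 4],
               flagged = ls[2, 4] <= alpha, skipped = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-variant association table
#'
#' Builds the per-SNP report: genotype counts by response group, a trend or
#' Fisher exact p-value, and the allelic odds ratio with its Woolf interval.
#' The exact test is used when any genotype cell count is below
#' `fisher_cell_min` (default 5), the trend test otherwise; a Bonferroni
#' column over the tested variants is included for transparency although the
#' primary report is nominal.
#'
#' @param gm A [genotype_matrix()] (counted allele = effect allele).
#' @param responder Logical responder indicator aligned with `gm$subjects`.
#' @param fisher_cell_min Switch-over threshold for the exact test.
#' @return Data frame, one row per variant: counts, `test`, `p`, `p_bonferroni`,
#'   `or`, `ci_low`, `ci_high`.
#' @export
per_snp_association <- function(gm, responder, fisher_cell_min = 5) {
  stopifnot(inherits(gm, "genotype_matrix"))
  rows <- lapply(seq_len(nrow(gm$variants)), function(j) {
    tab <- genotype_contingency(gm$dosage[, j], responder)
    use_fisher <- any(tab < fisher_cell_min)
    p <- if (use_fisher) fisher_exact_genotypic(tab) else trend_test(tab)$p
    or <- tryCatch(allelic_odds_ratio(tab),
                   error = function(e) data.frame(or = NA_real_,
                                                  ci_low = NA_real_,
                                                  ci_high = NA_real_))
    data.frame(id = gm$variants$id[j],
               resp_00 = tab[1, 1], resp_01 = tab[2, 1], resp_02 = tab[3, 1],
               non_00 = tab[1, 2], non_01 = tab[2, 2], non_02 = tab[3, 2],
               test = if (use_fisher) "fisher" else "trend",
               p = p, or = or$or, ci_low = or$ci_low, ci_high = or$ci_high,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(out$p * nrow(out), 1)
  rownames(out) <- NULL
  out
}

#' Stratified score-response association with diagnostic evaluation
#'
#' For each stratum (a set of ICD-10 code prefixes, or the complement of one),
#' fits the covariate-adjusted logistic model of response on the score and
#' reports group sizes, score mean/SD/range per response group, the score OR
#' with Wald CI and p, and the Youden-optimal ROC summary.
#'
#' @param scores Data frame with `subject_id`, `score`.
#' @param labels Data frame with `subject_id`, `label` (unknowns must already
#'   be excluded).
#' @param covariates Data frame with `subject_id`, `age`, `PC1`..`PCk`.
#' @param subjects Data frame with `subject_id`, `diagnosis` (ICD-10 code).
#' @param strata Named list; each element is `list(prefixes = <character>,
#'   complement = <logical>)` or `NULL` for all subjects.
#' @return Data frame, one row per stratum, with columns `stratum`, `n`,
#'   `n_responder`, `n_non_responder`, `mean_resp`, `sd_resp`, `min_resp`,
#'   `max_resp`, `mean_non`, `sd_non`, `min_non`, `max_non`, `or`, `ci_low`,
#'   `ci_high`, `p`, `auc`, `cutoff`, `sensitivity`, `specificity`, `ppv`,
#'   `npv`, `youden_j`, `fit_ok`.
#' @export
associate_by_stratum <- function(scores, labels, covariates, subjects, strata) {
  df <- merge(merge(merge(scores, labels, by = "subject_id"),
                    covariates, by = "subject_id"),
              subjects[, c("subject_id", "diagnosis")], by = "subject_id")
  df$responder <- df$label == "responder"
  pc_cols <- grep("^PC[0-9]+$", names(df), value = TRUE)
  rows <- lapply(names(strata), function(nm) {
    spec <- strata[[nm]]
    keep <- if (is.null(spec)) rep(TRUE, nrow(df)) else {
      hit <- Reduce(`|`, lapply(spec$prefixes, function(p) startsWith(df$diagnosis, p)))
      if (isTRUE(spec$complement)) !hit else hit
    }
    d <- df[keep, , drop = FALSE]
    base <- data.frame(stratum = nm, n = nrow(d),
                       n_responder = sum(d$responder),
                       n_non_responder = sum(!d$responder),
                       stringsAsFactors = FALSE)
    grp <- function(r, f) if (any(d$responder == r)) f(d$score[d$responder == r]) else NA_real_
    base$mean_resp <- grp(TRUE, mean);  base$sd_resp <- grp(TRUE, stats::sd)
    base$min_resp <- grp(TRUE, min);    base$max_resp <- grp(TRUE, max)
    base$mean_non <- grp(FALSE, mean);  base$sd_non <- grp(FALSE, stats::sd)
    base$min_non <- grp(FALSE, min);    base$max_non <- grp(FALSE, max)
    fit <- tryCatch({
      design <- d[, c("score", "age", pc_cols), drop = FALSE]
      res <- fit_logistic(d$responder, design)
      res[res$predictor == "score", ]
    }, error = function(e) NULL)
    if (!is.null(fit)) {
      base$or <- fit$or; base$ci_low <- fit$ci_low; base$ci_high <- fit$ci_high
      base$p <- fit$p; base$fit_ok <- TRUE
    } else {
      base$or <- base$ci_low <- base$ci_high <- base$p <- NA_real_
      base$fit_ok <- FALSE
    }
    roc <- tryCatch(roc_curve(d$score, d$responder), error = function(e) NULL)
    if (!is.null(roc)) {
      opt <- youden_cutoff(roc)
      base$auc <- roc$auc; base$cutoff <- opt$cutoff
      base$sensitivity <- opt$sensitivity; base$specificity <- opt$specificity
      base$ppv <- opt$ppv; base$npv <- opt$npv; base$youden_j <- opt$youden
    } else {
      base$auc <- base$cutoff <- base$sensitivity <- base$specificity <-
        base$ppv <- base$npv <- base$youden_j <- NA_real_
    }
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
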