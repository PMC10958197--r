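#' Default pipeline configuration
#'
#' The demonstration configuration: a 460-subject synthetic cohort genotyped
#' on the packaged 11-SNP response panel plus 200 background variants, QC at
#' call rate 0.99 / HWE p 1e-6 / MAF 0.05, clumping at r2 0.1 within 250 kb at
#' clump-p 1, five ancestry PCs, and the diagnostic strata used for subgroup
#' reporting. All thresholds are configuration values, never constants.
#'
#' @param n_subjects Cohort size.
#' @param seed Integer seed.
#' @param ... Overrides passed to [sim_config()].
#' @return A list of class `pipeline_config` with elements `sim` (a
#'   [sim_config()]), `qc`, `clump`, `pca`, `prs`, `classify`, `strata`.
#' @export
default_config <- function(n_subjects = 460, seed = 1L, ...) {
  structure(list(
    sim = sim_config(n_subjects = n_subjects, seed = seed, ...),
    qc = list(min_call_rate = 0.99, max_hwe_p = 1e-6, min_maf = 0.05),
    clump = list(r2_threshold = 0.1, window_kb = 250, p_threshold = 1),
    pca = list(k = 5),
    prs = list(missing_policy = "mean", allow_palindromic = TRUE),
    classify = list(window_days = 365),
    strata = list(
      all_patients = NULL,
      scz_sa_bd = list(prefixes = c("F20", "F25", "F30", "F31"), complement = FALSE),
      scz_sa = list(prefixes = c("F20", "F25"), complement = FALSE),
      scz = list(prefixes = "F20", complement = FALSE),
      sa = list(prefixes = "F25", complement = FALSE),
      bd = list(prefixes = c("F30", "F31"), complement = FALSE),
      others = list(prefixes = c("F20", "F21", "F22", "F23", "F24", "F25",
                                 "F28", "F29", "F30", "F31"),
                    complement = TRUE))),
    class = "pipeline_config")
}

#' Run the full score-to-association pipeline on a synthetic cohort
#'
#' Orchestrates simulate -> QC -> PCA -> clump -> score -> classify ->
#' per-SNP and stratified association -> ROC under a single seeded
#' configuration. Subjects labeled `unknown` are excluded from association
#' and ROC stages and the exclusion count is reported. All record counts are
#' conserved across stages (variants in = retained + removed; subjects =
#' labeled + unknown).
#'
#' @param config A `pipeline_config` (see [default_config()]).
#' @param out_dir Optional directory; when given, all stage artifacts are
#'   written beneath it.
#' @return An object of class `prs_run_report`: list with `seed`, `counts`,
#'   `qc_report`, `clump`, `scores`, `labels`, `per_snp`, `association`,
#'   `screen`, `pca`, `version`, `elapsed_s`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- proc.time()[["elapsed"]]

  bundle <- simulate_cohort(config$sim)
  gm <- bundle$genotypes

  qc <- apply_qc_filters(gm, min_call_rate = config$qc$min_call_rate,
                         max_hwe_p = config$qc$max_hwe_p,
                         min_maf = config$qc$min_maf)
  gm_qc <- qc$genotypes

  pca <- genotype_pca(gm_qc, k = config$pca$k)

  panel <- config$sim$panel
  panel_in <- panel[panel$snp_id %in% gm_qc$variants$id, , drop = FALSE]
  cl_variants <- data.frame(id = panel_in$snp_id, chrom = panel_in$chr,
                            pos = panel_in$pos, p = panel_in$p,
                            stringsAsFactors = FALSE)
  cl <- clump(cl_variants,
              gm_qc$dosage[, panel_in$snp_id, drop = FALSE],
              r2_threshold = config$clump$r2_threshold,
              window_kb = config$clump$window_kb,
              p_threshold = config$clump$p_threshold)
  panel_used <- panel_in[panel_in$snp_id %in% cl$retained, , drop = FALSE]

  scores <- compute_prs(gm_qc, panel_used,
                        missing_policy = config$prs$missing_policy,
                        allow_palindromic = config$prs$allow_palindromic)

  labels <- classify_cohort(bundle$cgi, bundle$events,
                            window_days = config$classify$window_days)
  n_unknown <- sum(labels$label == "unknown")
  known <- labels[labels$label != "unknown", , drop = FALSE]

  covariates <- data.frame(subject_id = bundle$subjects$subject_id,
                           age = bundle$subjects$age, stringsAsFactors = FALSE)
  covariates <- merge(covariates, pca, by = "subject_id")

  keep_ids <- known$subject_id
  gm_known <- subset_genotypes(gm_qc,
                               variants = intersect(gm_qc$variants$id,
                                                    panel_used$snp_id),
                               subjects = keep_ids)
  responder_known <- known$label[match(gm_known$subjects, known$subject_id)] == "responder"
  per_snp <- per_snp_association(gm_known, responder_known)

  screen_df <- merge(bundle$subjects, known, by = "subject_id")
  screen <- univariate_screen(
    screen_df[, c("age", "sex", "admissions", "substance_abuse", "ses")],
    screen_df$label == "responder")

  association <- associate_by_stratum(
    scores[scores$subject_id %in% keep_ids, c("subject_id", "score")],
    known, covariates[covariates$subject_id %in% keep_ids, , drop = FALSE],
    bundle$subjects, config$strata)

  counts <- list(
    variants_in = nrow(gm$variants),
    variants_qc_pass = sum(qc$report$pass),
    variants_qc_fail = sum(!qc$report$pass),
    panel_in_clump = nrow(panel_in),
    panel_retained = length(intersect(cl$retained, panel_in$snp_id)),
    panel_removed = nrow(cl$removed),
    subjects = nrow(bundle$subjects),
    responders = sum(labels$label == "responder"),
    non_responders = sum(labels$label == "non_responder"),
    unknown_excluded = n_unknown)

  report <- structure(list(
    seed = config$sim$seed, config = config, counts = counts,
    qc_report = qc$report, clump = cl, scores = scores, labels = labels,
    per_snp = per_snp, association = association, screen = screen, pca = pca,
    truth = bundle$truth,
    version = as.character(utils::packageVersion("prsresponse")),
    elapsed_s = proc.time()[["elapsed"]] - t0),
    class = "prs_run_report")

  if (!is.null(out_dir)) write_run_report(report, out_dir, bundle = bundle)
  report
}

#' @export
print.prs_run_report <- function(x, ...) {
  ct <- x$counts
  cat("prs_run_report (seed ", x$seed, ")\n", sep = "")
  cat("  variants: ", ct$variants_in, " in -> ", ct$variants_qc_pass,
      " after QC; panel ", ct$panel_in_clump, " -> ", ct$panel_retained,
      " after clumping\n", sep = "")
  cat("  subjects: ", ct$subjects, " (", ct$responders, " responders, ",
      ct$non_responders, " non-responders, ", ct$unknown_excluded,
      " unknown excluded)\n", sep = "")
  a <- x$association[x$association$stratum == "all_patients", ]
  if (nrow(a) == 1 && isTRUE(a$fit_ok)) {
    cat(sprintf("  PRS ~ response (all patients): OR %.3f (%.3f-%.3f), p = %.4g\n",
                a$or, a$ci_low, a$ci_high, a$p))
    cat(sprintf("  Youden cutoff %.3f: sens %.0f%%, spec %.0f%%, PPV %.0f%%, NPV %.0f%%, AUC %.3f\n",
                a$cutoff, 100 * a$sensitivity, 100 * a$specificity,
                100 * a$ppv, 100 * a$npv, a$auc))
  }
  invisible(x)
}

#' Write all artifacts of a pipeline run
#'
#' Emits, under one directory: the QC report (TSV + JSON), clump result,
#' per-subject scores, response labels, per-SNP association table, stratified
#' association/ROC table, covariate screen, principal components, a JSON run
#' summary, and (when the cohort bundle is supplied) the cohort itself.
#'
#' @param report A `prs_run_report`.
#' @param dir Output directory (created if needed).
#' @param bundle Optional `cohort_bundle` to write alongside.
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(report, dir, bundle = NULL) {
  stopifnot(inherits(report, "prs_run_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, f) utils::write.table(
    as.data.frame(df), file.path(dir, f), sep = "\t", quote = FALSE,
    row.names = FALSE, fileEncoding = "UTF-8")
  write_qc_report(report$qc_report, file.path(dir, "qc_report.tsv"),
                  file.path(dir, "qc_report.json"))
  write_clump_result(report$clump, file.path(dir, "clump.tsv"))
  write_prs_result(report$scores, file.path(dir, "scores.tsv"))
  write_labels_tsv(report$labels, file.path(dir, "labels.tsv"))
  wt(report$per_snp, "per_snp.tsv")
  wt(report$association, "association.tsv")
  wt(report$screen, "covariate_screen.tsv")
  wt(report$pca, "principal_components.tsv")
  jsonlite::write_json(list(seed = report$seed, counts = report$counts,
                            version = report$version,
                            elapsed_s = report$elapsed_s),
                       file.path(dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(bundle)) write_cohort(bundle, file.path(dir, "cohort"))
  invisible(dir)
}
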