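#' Read a PRS score file
#'
#' A score file defines a polygenic score panel: one row per variant with the
#' effect (risk) allele, the other allele, and the per-allele weight. The
#' expected tab-separated header is
#' `snp_id chr pos effect_allele other_allele weight p`, where `weight` is the
#' per-effect-allele contribution (1 for a plain allele-count score, `ln(OR)`
#' for an odds-ratio-weighted score) and `p` is the source association p-value.
#'
#' @param path Path to a tab-separated score file.
#' @return A `data.frame` with columns `snp_id`, `chr`, `pos`, `effect_allele`,
#'   `other_allele`, `weight`, `p`, validated for uniqueness and allele sanity.
#' @export
#' @examples
#' panel <- response_panel()
#' nrow(panel)  # 11
read_score_file <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  required <- c("snp_id", "chr", "pos", "effect_allele", "other_allele",
                "weight", "p")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("score file is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- df[, required]
  df$snp_id <- as.character(df$snp_id)
  df$chr <- as.character(df$chr)
  df$pos <- as.integer(df$pos)
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  df$weight <- as.numeric(df$weight)
  df$p <- as.numeric(df$p)
  validate_score_panel(df)
  df
}

#' Validate a score panel data frame
#'
#' @param panel A data frame in the score-file layout (see [read_score_file()]).
#' @return The panel, invisibly, if valid; otherwise an error is raised.
#' @export
validate_score_panel <- function(panel) {
  if (nrow(panel) == 0) stop("score panel has no variants")
  if (anyDuplicated(panel$snp_id)) {
    stop("duplicate variant ids in score panel: ",
         paste(unique(panel$snp_id[duplicated(panel$snp_id)]), collapse = ", "))
  }
  if (any(panel$effect_allele == panel$other_allele)) {
    stop("effect allele equals other allele for: ",
         paste(panel$snp_id[panel$effect_allele == panel$other_allele],
               collapse = ", "))
  }
  if (any(!is.finite(panel$weight))) stop("non-finite weights in score panel")
  if (any(is.na(panel$p) | panel$p < 0 | panel$p > 1)) {
    stop("source p-values must lie in [0,1]")
  }
  if (any(is.na(panel$pos) | panel$pos < 0)) stop("positions must be non-negative integers")
  invisible(panel)
}

#' Write a score panel to a tab-separated score file
#'
#' @param panel A validated score panel data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_score_file <- function(panel, path) {
  validate_score_panel(panel)
  utils::write.table(panel, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' The packaged antipsychotic-response score panel
#'
#' Eleven SNPs previously associated with response to antipsychotic treatment
#' at genome-wide significance, scored with unit ("dummy beta") weights so the
#' score is a plain count of risk alleles in 0..22. Chromosomes follow the host
#' genes of the variants; base-pair positions are synthetic placeholders (they
#' matter only for clumping windows and are spaced far beyond any default
#' window).
#'
#' @return A score panel `data.frame` with 11 rows (see [read_score_file()]).
#' @export
response_panel <- function() {
  path <- system.file("extdata", "prs_response_panel.tsv",
                      package = "prsresponse", mustWork = TRUE)
  read_score_file(path)
}

#' Default effect-allele frequencies for the packaged response panel
#'
#' European-ancestry-scale effect-allele frequencies used by the synthetic
#' cohort generator for the packaged 11-SNP panel. Frequencies are on the
#' effect-allele scale and may exceed 0.5 (one panel variant's risk allele is
#' the major allele); the minor-allele frequency is `pmin(eaf, 1 - eaf)`.
#'
#' @return A named numeric vector of effect-allele frequencies.
#' @export
response_panel_eaf <- function() {
  c(rs6688363  = 184 / 922,
    rs10170310 = 144 / 922,
    rs7395555  = 173 / 922,
    rs711355   = 354 / 922,
    rs17382202 = 183 / 922,
    rs2980976  = 146 / 922,
    rs1875705  = 509 / 922,
    rs2133450  = 447 / 922,
    rs10023464 = 71 / 922,
    rs7668556  = 385 / 922,
    rs12767583 = 147 / 922)
}
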