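COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

## internal: reverse-complement for single bases; NA for non-ACGT
comp_allele <- function(x) {
  out <- COMPLEMENT[x]
  unname(out)
}

#' Align a score-file entry to a genotype-file variant
#'
#' Determines how the effect-allele dosage is obtained from the ALT-allele
#' dosage of a genotype file whose REF/ALT ordering is arbitrary:
#' \describe{
#'   \item{`use`}{effect = ALT, other = REF: ALT dosage counts the effect allele.}
#'   \item{`swap`}{effect = REF, other = ALT: use `2 - dosage`.}
#'   \item{`flip_use` / `flip_swap`}{alleles match only after A<->T / C<->G
#'     strand complementation, then as above.}
#'   \item{`drop`}{strand-ambiguous palindromic variants (A/T or C/G pairs,
#'     unless `allow_palindromic`) or irreconcilable allele sets; the reason is
#'     reported, never raised.}
#' }
#'
#' @param effect,other Effect and other allele of the score entry.
#' @param ref,alt REF and ALT allele of the genotype variant.
#' @param allow_palindromic Trust strand for palindromic variants and align by
#'   direct match (use when score file and genotypes share provenance).
#' @return List with `action` (one of use/swap/flip_use/flip_swap/drop) and
#'   `reason` (NA unless dropped).
#' @export
align_alleles <- function(effect, other, ref, alt, allow_palindromic = FALSE) {
  effect <- toupper(effect); other <- toupper(other)
  ref <- toupper(ref); alt <- toupper(alt)
  if (effect == other) return(list(action = "drop", reason = "degenerate entry"))
  single <- all(nchar(c(effect, other, ref, alt)) == 1) &&
    all(c(effect, other, ref, alt) %in% names(COMPLEMENT))
  palindromic <- single && comp_allele(effect) == other
  if (palindromic && !allow_palindromic) {
    return(list(action = "drop", reason = "ambiguous strand"))
  }
  if (effect == alt && other == ref) return(list(action = "use", reason = NA_character_))
  if (effect == ref && other == alt) return(list(action = "swap", reason = NA_character_))
  if (single && !palindromic) {
    fe <- comp_allele(effect); fo <- comp_allele(other)
    if (fe == alt && fo == ref) return(list(action = "flip_use", reason = NA_character_))
    if (fe == ref && fo == alt) return(list(action = "flip_swap", reason = NA_character_))
  }
  list(action = "drop", reason = "allele mismatch")
}

#' Compute polygenic scores by the weighted allele-count method
#'
#' For each subject the score is the sum over aligned panel variants of
#' `weight * effect-allele dosage`. Alignment of the score file to the
#' genotype alleles (including strand flips and palindromic drops) is handled
#' by [align_alleles()]; panel variants absent from the genotypes are dropped
#' with reason `absent`. Missing dosages follow `missing_policy`:
#' \describe{
#'   \item{`mean`}{impute `2 * f`, the in-sample effect-allele frequency (default).}
#'   \item{`omit`}{drop the variant for that subject (score over the rest).}
#'   \item{`fail`}{error on any missing dosage.}
#' }
#'
#' @param gm A [genotype_matrix()].
#' @param panel Score panel data frame (see [read_score_file()]).
#' @param missing_policy One of `"mean"`, `"omit"`, `"fail"`.
#' @param allow_palindromic Passed to [align_alleles()].
#' @return An object of class `prs_result`: data.frame with `subject_id`,
#'   `score`, `n_used`, `n_imputed`; attributes `dropped` (data.frame of
#'   dropped panel variants with reasons), `missing_policy`, `n_panel`,
#'   `n_aligned`.
#' @export
compute_prs <- function(gm, panel, missing_policy = c("mean", "omit", "fail"),
                        allow_palindromic = FALSE) {
  stopifnot(inherits(gm, "genotype_matrix"))
  validate_score_panel(panel)
  missing_policy <- match.arg(missing_policy)

  vmatch <- match(panel$snp_id, gm$variants$id)
  dropped <- list()
  eff_dosage <- matrix(NA_real_, length(gm$subjects), 0)
  weights <- numeric(0)
  used_ids <- character(0)
  for (j in seq_len(nrow(panel))) {
    vi <- vmatch[j]
    if (is.na(vi)) {
      dropped[[length(dropped) + 1]] <- data.frame(
        snp_id = panel$snp_id[j], reason = "absent", stringsAsFactors = FALSE)
      next
    }
    al <- align_alleles(panel$effect_allele[j], panel$other_allele[j],
                        gm$variants$ref[vi], gm$variants$alt[vi],
                        allow_palindromic = allow_palindromic)
    if (al$action == "drop") {
      dropped[[length(dropped) + 1]] <- data.frame(
        snp_id = panel$snp_id[j], reason = al$reason, stringsAsFactors = FALSE)
      next
    }
    d <- gm$dosage[, vi]
    if (al$action %in% c("swap", "flip_swap")) d <- 2 - d
    eff_dosage <- cbind(eff_dosage, d)
    weights <- c(weights, panel$weight[j])
    used_ids <- c(used_ids, panel$snp_id[j])
  }
  if (length(weights) == 0) stop("no panel variants could be aligned to the genotypes")

  miss <- is.na(eff_dosage)
  if (missing_policy == "fail" && any(miss)) {
    stop("missing genotypes present and missing_policy = 'fail'")
  }
  filled <- eff_dosage
  if (missing_policy == "mean") {
    eafs <- colMeans(eff_dosage, na.rm = TRUE) / 2
    for (j in which(colSums(miss) > 0)) {
      filled[miss[, j], j] <- 2 * eafs[j]
    }
    score <- as.numeric(filled %*% weights)
    n_used <- rep(length(weights), nrow(filled))
  } else {  # omit (also covers fail, which has no missing left)
    filled[miss] <- 0
    score <- as.numeric(filled %*% weights)
    n_used <- length(weights) - rowSums(miss)
    if (missing_policy == "fail") n_used <- rep(length(weights), nrow(filled))
  }
  out <- data.frame(subject_id = gm$subjects, score = score,
                    n_used = as.integer(n_used),
                    n_imputed = if (missing_policy == "mean")
                      as.integer(rowSums(miss)) else 0L,
                    stringsAsFactors = FALSE)
  attr(out, "dropped") <- if (length(dropped)) do.call(rbind, dropped) else
    data.frame(snp_id = character(0), reason = character(0))
  attr(out, "missing_policy") <- missing_policy
  attr(out, "n_panel") <- nrow(panel)
  attr(out, "n_aligned") <- length(weights)
  attr(out, "aligned_ids") <- used_ids
  class(out) <- c("prs_result", "data.frame")
  out
}

#' Write per-subject scores to TSV
#'
#' @param scores A `prs_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_prs_result <- function(scores, path) {
  utils::write.table(as.data.frame(scores), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
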