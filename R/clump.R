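#' Squared dosage correlation between two variants
#'
#' Pairwise-complete squared Pearson correlation of two dosage vectors, the
#' in-sample r-squared used by LD clumping. If either vector is constant over
#' the complete pairs, 0 is returned with a `constant` attribute set.
#'
#' @param a,b Numeric dosage vectors of equal length (NA = missing).
#' @return r-squared in \[0,1\].
#' @export
pairwise_r2 <- function(a, b) {
  if (length(a) != length(b)) stop("dosage vectors must have equal length")
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2) stop("fewer than 2 complete pairs")
  a <- a[ok]; b <- b[ok]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    return(structure(0, constant = TRUE))
  }
  stats::cor(a, b)^2
}

#' Greedy LD clumping
#'
#' PLINK/PRSice-style clumping: variants are sorted by ascending p-value (ties
#' broken by chromosome, position, then id); the best unassigned variant with
#' p <= `p_threshold` becomes an index and removes all unassigned variants on
#' the same chromosome within `window_kb` kilobases of it whose in-sample
#' r-squared with the index is >= `r2_threshold`. `p_threshold = 1` makes every
#' variant index-eligible. A `window_kb` of 0 disables all comparisons (every
#' variant is retained), as does `r2_threshold > 1`.
#'
#' @param variants Data frame with columns `id`, `chrom`, `pos`, `p` (p-values
#'   in \[0,1\]; ids unique).
#' @param dosages Numeric matrix, subjects x variants, with columns matching
#'   `variants$id` (by name or order).
#' @param r2_threshold Removal threshold on r-squared (default 0.1; variants
#'   with r2 strictly below it are kept as independent).
#' @param window_kb Window half-width in kb around the index (default 250).
#' @param p_threshold Index-eligibility p-value threshold (default 1).
#' @return An object of class `clump_result`: list with `retained` (ordered
#'   ids), `removed` (data.frame id / index_id / r2), `params`.
#' @export
clump <- function(variants, dosages, r2_threshold = 0.1, window_kb = 250,
                  p_threshold = 1) {
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  need <- c("id", "chrom", "pos", "p")
  if (!all(need %in% names(variants))) {
    stop("variants needs columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(variants$id)) stop("duplicate variant ids")
  if (any(is.na(variants$p) | variants$p < 0 | variants$p > 1)) {
    stop("p-values must lie in [0,1]")
  }
  dosages <- as.matrix(dosages)
  if (ncol(dosages) != nrow(variants)) stop("dosage columns must match variants")
  if (!is.null(colnames(dosages))) {
    idx <- match(variants$id, colnames(dosages))
    if (anyNA(idx)) stop("dosage columns must be named by variant id")
    dosages <- dosages[, idx, drop = FALSE]
  }

  ord <- order(variants$p, variants$chrom, variants$pos, variants$id)
  assigned <- rep(FALSE, nrow(variants))
  retained <- character(0)
  removed <- list()
  for (i in ord) {
    if (assigned[i]) next
    if (variants$p[i] > p_threshold) next  # not index-eligible
    assigned[i] <- TRUE
    retained <- c(retained, variants$id[i])
    if (window_kb <= 0 || r2_threshold > 1) next
    cand <- which(!assigned &
                    variants$chrom == variants$chrom[i] &
                    abs(variants$pos - variants$pos[i]) <= window_kb * 1000)
    for (j in cand) {
      r2 <- pairwise_r2(dosages[, i], dosages[, j])
      if (r2 >= r2_threshold) {
        assigned[j] <- TRUE
        removed[[length(removed) + 1]] <- data.frame(
          id = variants$id[j], index_id = variants$id[i], r2 = as.numeric(r2),
          stringsAsFactors = FALSE)
      }
    }
  }
  # index-ineligible variants never assigned stay in the retained set
  leftover <- variants$id[!assigned]
  retained <- c(retained, leftover)
  removed <- if (length(removed)) do.call(rbind, removed) else
    data.frame(id = character(0), index_id = character(0), r2 = numeric(0))
  structure(list(retained = retained, removed = removed,
                 params = list(r2_threshold = r2_threshold,
                               window_kb = window_kb,
                               p_threshold = p_threshold)),
            class = "clump_result")
}

#' @export
print.clump_result <- function(x, ...) {
  cat("clump_result:", length(x$retained), "retained,", nrow(x$removed),
      "removed (r2 >=", x$params$r2_threshold, "within",
      x$params$window_kb, "kb)\n")
  invisible(x)
}

#' Write a clump result as a two-section TSV
#'
#' Section lines start with `#`; the retained section lists index ids, the
#' removed section maps each removed variant to its index and r-squared.
#'
#' @param result A `clump_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clump_result <- function(result, path) {
  stopifnot(inherits(result, "clump_result"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("# retained", con)
  writeLines(result$retained, con)
  writeLines("# removed\tindex\tr2", con)
  if (nrow(result$removed) > 0) {
    writeLines(sprintf("%s\t%s\t%.6g", result$removed$id,
                       result$removed$index_id, result$removed$r2), con)
  }
  invisible(path)
}
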