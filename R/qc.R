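#' Per-variant call rate
#'
#' Fraction of non-missing dosages for one variant.
#'
#' @param dosages Numeric vector of dosages (NA = missing).
#' @return Call rate in \[0,1\].
#' @export
call_rate <- function(dosages) {
  if (length(dosages) == 0) stop("empty dosage vector")
  mean(!is.na(dosages))
}

#' Minor allele frequency from dosages
#'
#' `min(f, 1 - f)` where `f` is the counted-allele frequency
#' `sum(dosage) / (2 * n_nonmissing)`.
#'
#' @param dosages Numeric vector of dosages in \[0,2\] (NA = missing).
#' @return MAF in \[0, 0.5\].
#' @export
minor_allele_frequency <- function(dosages) {
  d <- dosages[!is.na(dosages)]
  if (length(d) == 0) stop("all dosages missing")
  f <- sum(d) / (2 * length(d))
  min(f, 1 - f)
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom Pearson chi-square of observed genotype counts
#' against Hardy-Weinberg expectations at the sample allele frequency, without
#' continuity correction. Monomorphic variants return a statistic of 0 with a
#' `monomorphic` flag.
#'
#' @param counts Integer vector of length 3: genotype counts for 0, 1 and 2
#'   copies of the counted allele.
#' @return List with `chi2`, `p` (upper tail, 1 df), `monomorphic` flag.
#' @export
hwe_chi2 <- function(counts) {
  if (length(counts) != 3 || any(is.na(counts)) || any(counts < 0)) {
    stop("counts must be 3 non-negative genotype counts")
  }
  n <- sum(counts)
  if (n < 1) stop("total genotype count must be >= 1")
  q <- (counts[2] + 2 * counts[3]) / (2 * n)  # counted-allele frequency
  if (q <= 0 || q >= 1) {
    return(list(chi2 = 0, p = 1, monomorphic = TRUE))
  }
  p <- 1 - q
  expected <- n * c(p^2, 2 * p * q, q^2)
  chi2 <- sum((counts - expected)^2 / expected)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       monomorphic = FALSE)
}

## internal: genotype counts (0/1/2 copies) from rounded dosages
genotype_counts <- function(dosages) {
  hard <- round(dosages[!is.na(dosages)])
  c(sum(hard == 0), sum(hard == 1), sum(hard == 2))
}

#' Apply variant-level QC filters
#'
#' Excludes variants with call rate below `min_call_rate`, Hardy-Weinberg
#' p-value below `max_hwe_p`, or minor allele frequency below `min_maf`
#' (defaults: 0.99, 1e-6, 0.05). A variant is retained iff it fails no filter;
#' subjects are never removed. The HWE test uses rounded hard calls.
#'
#' @param gm A [genotype_matrix()].
#' @param min_call_rate Retain iff call rate >= this value.
#' @param max_hwe_p Exclude iff HWE p < this value.
#' @param min_maf Exclude iff MAF < this value.
#' @return List with `genotypes` (the filtered matrix, original variant order
#'   preserved) and `report` (per-variant statistics and pass/fail flags).
#'   An empty retained set is allowed and flagged with a warning.
#' @export
apply_qc_filters <- function(gm, min_call_rate = 0.99, max_hwe_p = 1e-6,
                             min_maf = 0.05) {
  stopifnot(inherits(gm, "genotype_matrix"))
  d <- gm$dosage
  cr <- apply(d, 2, call_rate)
  maf <- apply(d, 2, function(x) {
    if (all(is.na(x))) NA_real_ else minor_allele_frequency(x)
  })
  hwe <- apply(d, 2, function(x) {
    if (all(is.na(x))) return(c(NA_real_, NA_real_))
    h <- hwe_chi2(genotype_counts(x))
    c(h$chi2, h$p)
  })
  fail_cr <- cr < min_call_rate
  fail_maf <- is.na(maf) | maf < min_maf
  fail_hwe <- is.na(hwe[2, ]) | hwe[2, ] < max_hwe_p
  pass <- !(fail_cr | fail_maf | fail_hwe)
  report <- data.frame(
    id = gm$variants$id, call_rate = cr, maf = maf,
    hwe_chi2 = hwe[1, ], hwe_p = hwe[2, ],
    fail_call_rate = fail_cr, fail_maf = fail_maf, fail_hwe = fail_hwe,
    pass = pass, stringsAsFactors = FALSE, row.names = NULL)
  attr(report, "thresholds") <- list(min_call_rate = min_call_rate,
                                     max_hwe_p = max_hwe_p, min_maf = min_maf)
  if (!any(pass)) warning("no variants pass QC")
  filtered <- subset_genotypes(gm, variants = gm$variants$id[pass])
  # carry simulation attributes through for downstream ground-truth use
  cd <- attr(gm, "complete_dosage")
  if (!is.null(cd)) attr(filtered, "complete_dosage") <- cd[, pass, drop = FALSE]
  attr(filtered, "subpop") <- attr(gm, "subpop")
  list(genotypes = filtered, report = report)
}

#' Ancestry principal components from genotypes
#'
#' EIGENSTRAT-style PCA: missing dosages are mean-imputed per variant, each
#' column is centered by `2f` and scaled by `sqrt(2f(1-f))` with `f` the sample
#' counted-allele frequency, and the top-`k` left singular vectors of the
#' standardized matrix are returned as unit-norm subject coordinates.
#' Monomorphic variants are dropped before the decomposition. The sign of each
#' component is fixed so its largest-magnitude entry is positive.
#'
#' @param gm A [genotype_matrix()].
#' @param k Number of components requested (default 5). If `k` exceeds the
#'   rank, fewer columns are returned and the result is flagged.
#' @return A data.frame with `subject_id` and `PC1..PCk` columns; attributes
#'   `eigenvalues` (squared singular values / (n-1)) and `degenerate` flag.
#' @export
genotype_pca <- function(gm, k = 5) {
  stopifnot(inherits(gm, "genotype_matrix"))
  n <- length(gm$subjects)
  if (n < k + 1) stop("need at least k + 1 subjects for ", k, " components")
  X <- gm$dosage
  for (j in seq_len(ncol(X))) {
    miss <- is.na(X[, j])
    if (any(miss)) X[miss, j] <- mean(X[, j], na.rm = TRUE)
  }
  f <- colMeans(X) / 2
  keep <- f > 0 & f < 1 & apply(X, 2, stats::var) > 0
  degenerate <- !any(keep)
  if (degenerate) {
    pcs <- matrix(0, n, k)
  } else {
    Z <- sweep(X[, keep, drop = FALSE], 2, 2 * f[keep], "-")
    Z <- sweep(Z, 2, sqrt(2 * f[keep] * (1 - f[keep])), "/")
    sv <- svd(Z, nu = min(k, min(dim(Z))), nv = 0)
    tol <- max(dim(Z)) * .Machine$double.eps * sv$d[1]
    rank <- sum(sv$d > tol)
    k_eff <- min(k, rank, ncol(sv$u))
    pcs <- matrix(0, n, k)
    if (k_eff > 0) {
      u <- sv$u[, seq_len(k_eff), drop = FALSE]
      for (j in seq_len(k_eff)) {  # sign convention
        imax <- which.max(abs(u[, j]))
        if (u[imax, j] < 0) u[, j] <- -u[, j]
      }
      pcs[, seq_len(k_eff)] <- u
    }
    if (k_eff < k) degenerate <- TRUE
    attr(pcs, "eigenvalues") <- (sv$d^2) / (n - 1)
  }
  out <- data.frame(subject_id = gm$subjects, pcs, stringsAsFactors = FALSE)
  names(out) <- c("subject_id", paste0("PC", seq_len(k)))
  attr(out, "eigenvalues") <- attr(pcs, "eigenvalues")
  attr(out, "degenerate") <- degenerate
  out
}

#' Subset subjects by principal-component thresholds
#'
#' Ancestry subsetting in the EIGENSTRAT tradition: keep subjects whose PC
#' coordinates satisfy configurable inequalities, e.g. keep the cluster with
#' `PC1 < a` and `PC2 > b`. Thresholds are cohort-specific and must be chosen
#' by inspection; none are hard-coded.
#'
#' @param pca Output of [genotype_pca()].
#' @param ... Named bounds of the form `PC1_max = 0.0025`, `PC2_min = -0.0125`
#'   (any `PCk_min` / `PCk_max` pair may be given).
#' @return Character vector of retained subject ids.
#' @export
pc_subset <- function(pca, ...) {
  bounds <- list(...)
  keep <- rep(TRUE, nrow(pca))
  for (nm in names(bounds)) {
    m <- regmatches(nm, regexec("^(PC[0-9]+)_(min|max)$", nm))[[1]]
    if (length(m) == 0) stop("bound names must look like PC1_max / PC2_min; got ", nm)
    col <- m[2]
    if (!col %in% names(pca)) stop("no column ", col, " in PCA result")
    keep <- keep & if (m[3] == "min") pca[[col]] > bounds[[nm]] else pca[[col]] < bounds[[nm]]
  }
  pca$subject_id[keep]
}

#' Write a QC report as TSV and JSON
#'
#' @param report The `report` element of [apply_qc_filters()].
#' @param path_tsv,path_json Output paths (either may be `NULL` to skip).
#' @return Invisibly, the report.
#' @export
write_qc_report <- function(report, path_tsv = NULL, path_json = NULL) {
  if (!is.null(path_tsv)) {
    utils::write.table(report, path_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  }
  if (!is.null(path_json)) {
    jsonlite::write_json(list(thresholds = attr(report, "thresholds"),
                              variants = report),
                         path_json, auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}
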