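#' Construct a genotype matrix
#'
#' The central genotype container: an effect-allele dosage matrix (subjects in
#' rows, variants in columns, values in \[0,2\] or `NA` for missing) together
#' with a variant table. By convention the ALT allele of the variant table is
#' the counted (dosage) allele.
#'
#' @param dosage Numeric matrix, subjects x variants; entries in \[0,2\] or `NA`.
#' @param variants Data frame with columns `id`, `chrom`, `pos`, `ref`, `alt`;
#'   one row per dosage column, ids unique.
#' @param subjects Character vector of subject ids (defaults to dosage
#'   rownames, or `S0001`-style ids).
#' @return An object of class `genotype_matrix` with elements `dosage`,
#'   `variants`, `subjects`.
#' @export
genotype_matrix <- function(dosage, variants, subjects = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  if (is.null(subjects)) {
    subjects <- rownames(dosage)
    if (is.null(subjects)) subjects <- sprintf("S%04d", seq_len(nrow(dosage)))
  }
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  need <- c("id", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(variants))) {
    stop("variant table must have columns: ", paste(need, collapse = ", "))
  }
  variants$id <- as.character(variants$id)
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  if (ncol(dosage) != nrow(variants)) {
    stop("dosage has ", ncol(dosage), " columns but variant table has ",
         nrow(variants), " rows")
  }
  if (length(subjects) != nrow(dosage)) stop("subject ids do not match dosage rows")
  if (anyDuplicated(variants$id)) stop("variant ids must be unique")
  if (any(is.na(variants$pos) | variants$pos < 0)) stop("positions must be non-negative")
  rng <- range(dosage, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2)) {
    stop("dosages must lie in [0,2] (or be NA)")
  }
  rownames(dosage) <- subjects
  colnames(dosage) <- variants$id
  structure(list(dosage = dosage, variants = variants,
                 subjects = as.character(subjects)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$subjects), "subjects x",
      nrow(x$variants), "variants;",
      sum(is.na(x$dosage)), "missing entries\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix by variant ids and/or subject ids
#'
#' @param gm A `genotype_matrix`.
#' @param variants Character vector of variant ids to keep (default all).
#' @param subjects Character vector of subject ids to keep (default all).
#' @return A `genotype_matrix` restricted to the requested rows/columns,
#'   preserving input order of the requested ids.
#' @export
subset_genotypes <- function(gm, variants = NULL, subjects = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  vi <- if (is.null(variants)) seq_len(nrow(gm$variants)) else {
    idx <- match(variants, gm$variants$id)
    if (anyNA(idx)) stop("unknown variant id(s): ",
                         paste(variants[is.na(idx)], collapse = ", "))
    idx
  }
  si <- if (is.null(subjects)) seq_along(gm$subjects) else {
    idx <- match(subjects, gm$subjects)
    if (anyNA(idx)) stop("unknown subject id(s): ",
                         paste(subjects[is.na(idx)], collapse = ", "))
    idx
  }
  genotype_matrix(gm$dosage[si, vi, drop = FALSE],
                  gm$variants[vi, , drop = FALSE],
                  gm$subjects[si])
}

#' Read genotypes from a VCF file
#'
#' Reads GT hard calls or DS dosages (DS preferred when present) into a
#' [genotype_matrix()]. Dosages count copies of the ALT allele; missing calls
#' become `NA`.
#'
#' @param path Path to a VCF (plain or bgzip/gzip compressed).
#' @return A `genotype_matrix`.
#' @export
read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, ":", fix$POS)[is.na(ids) | ids == "."]
  variants <- data.frame(id = ids, chrom = fix$CHROM, pos = as.integer(fix$POS),
                         ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  fmt <- vcf@gt[, 1]
  has_ds <- all(grepl("(^|:)DS(:|$)", fmt))
  if (has_ds) {
    ds <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
    dosage <- t(ds)
  } else {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    count_alt <- function(g) {
      if (is.na(g)) return(NA_real_)
      alleles <- strsplit(g, "[/|]")[[1]]
      if (any(alleles == ".")) return(NA_real_)
      sum(alleles == "1")
    }
    dosage <- t(apply(gt, c(1, 2), count_alt))
  }
  genotype_matrix(dosage, variants, subjects = rownames(dosage))
}

#' Write genotypes to a VCF file
#'
#' Writes a VCF v4.2 with per-sample `GT:DS` fields: GT is the rounded hard
#' call, DS the (possibly fractional) ALT-allele dosage. Output is
#' gzip-compressed; use a `.vcf.gz` path.
#'
#' @param gm A `genotype_matrix`.
#' @param path Output path (conventionally ending in `.vcf.gz`).
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  meta <- c("##fileformat=VCFv4.2",
            "##source=prsresponse",
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
            "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Alternate allele dosage\">")
  v <- gm$variants
  fix <- cbind(CHROM = v$chrom, POS = as.character(v$pos), ID = v$id,
               REF = v$ref, ALT = v$alt, QUAL = ".", FILTER = "PASS", INFO = ".")
  d <- t(gm$dosage)  # variants x subjects
  hard <- round(d)
  gt_str <- matrix("./.:.", nrow = nrow(d), ncol = ncol(d))
  ok <- !is.na(d)
  gt_code <- c("0/0", "0/1", "1/1")[hard[ok] + 1]
  gt_str[ok] <- paste0(gt_code, ":", formatC(d[ok], format = "g", digits = 6))
  gt <- cbind(FORMAT = "GT:DS", gt_str)
  colnames(gt) <- c("FORMAT", gm$subjects)
  vcf <- methods::new("vcfR", meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(vcf, file = path)
  invisible(path)
}
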