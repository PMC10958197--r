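#' ROC curve and AUC for a score against binary response labels
#'
#' Candidate cutoffs are the midpoints between consecutive distinct scores
#' plus -Inf/+Inf sentinels; a subject is predicted positive when
#' `score >= cutoff` (or `<=` with `direction = "le"`). The AUC is the
#' Mann-Whitney probability that a random positive outscores a random
#' negative, ties counted one half — identical to the trapezoidal area under
#' the empirical curve.
#'
#' @param scores Numeric score per subject.
#' @param labels Logical (or 0/1) responder indicator; both classes required.
#' @param direction `"ge"` (default; higher score predicts response) or `"le"`.
#' @return Object of class `roc_analysis`: list with `points` (data.frame
#'   `cutoff`, `sensitivity`, `specificity`), `auc`, `direction`, `n_pos`,
#'   `n_neg`, and the input `scores`/`labels` for downstream cutoff selection.
#' @export
roc_curve <- function(scores, labels, direction = c("ge", "le")) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  s <- if (direction == "ge") scores else -scores

  us <- sort(unique(s))
  cutoffs <- c(-Inf, if (length(us) > 1) (us[-1] + us[-length(us)]) / 2, Inf)
  sens <- spec <- numeric(length(cutoffs))
  for (i in seq_along(cutoffs)) {
    pred <- s >= cutoffs[i]
    sens[i] <- sum(pred & labels) / n_pos
    spec[i] <- sum(!pred & !labels) / n_neg
  }
  # Mann-Whitney AUC with ties counted half
  r <- rank(s)
  auc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  out_cut <- if (direction == "ge") cutoffs else -cutoffs
  structure(list(points = data.frame(cutoff = out_cut, sensitivity = sens,
                                     specificity = spec),
                 auc = auc, direction = direction, n_pos = n_pos,
                 n_neg = n_neg, scores = scores, labels = labels),
            class = "roc_analysis")
}

#' @export
print.roc_analysis <- function(x, ...) {
  cat("roc_analysis:", x$n_pos, "positives /", x$n_neg, "negatives; AUC =",
      round(x$auc, 4), "\n")
  invisible(x)
}

#' Youden-optimal cutoff with diagnostic summary
#'
#' Exhaustively evaluates every candidate cutoff of a [roc_curve()] and
#' reports the one maximizing the Youden index J = sensitivity +
#' specificity - 1. Ties are broken toward the smallest cutoff (in the
#' internal orientation). PPV/NPV are computed at the cohort prevalence; when
#' no subject is predicted positive (or negative) the corresponding value is
#' `NA` with a defined-flag set to `FALSE`.
#'
#' @param roc A `roc_analysis`.
#' @return List with `cutoff`, `sensitivity`, `specificity`, `ppv`, `npv`,
#'   `youden`, `ppv_defined`, `npv_defined`.
#' @export
youden_cutoff <- function(roc) {
  stopifnot(inherits(roc, "roc_analysis"))
  pts <- roc$points
  j <- pts$sensitivity + pts$specificity - 1
  internal_cut <- if (roc$direction == "ge") pts$cutoff else -pts$cutoff
  best <- which(j == max(j))
  best <- best[which.min(internal_cut[best])]
  cut <- internal_cut[best]
  s <- if (roc$direction == "ge") roc$scores else -roc$scores
  pred <- s >= cut
  tp <- sum(pred & roc$labels); fp <- sum(pred & !roc$labels)
  tn <- sum(!pred & !roc$labels); fn <- sum(!pred & roc$labels)
  ppv_defined <- (tp + fp) > 0
  npv_defined <- (tn + fn) > 0
  list(cutoff = pts$cutoff[best],
       sensitivity = pts$sensitivity[best],
       specificity = pts$specificity[best],
       ppv = if (ppv_defined) tp / (tp + fp) else NA_real_,
       npv = if (npv_defined) tn / (tn + fn) else NA_real_,
       youden = j[best],
       ppv_defined = ppv_defined, npv_defined = npv_defined)
}

#' Write ROC points and diagnostic summary
#'
#' @param roc A `roc_analysis`.
#' @param points_tsv Path for the cutoff/sensitivity/specificity table
#'   (`NULL` to skip).
#' @param summary_json Path for the JSON summary (cutoff, sens, spec, PPV,
#'   NPV, J, AUC; `NULL` to skip).
#' @return Invisibly, the Youden summary list.
#' @export
write_roc <- function(roc, points_tsv = NULL, summary_json = NULL) {
  opt <- youden_cutoff(roc)
  if (!is.null(points_tsv)) {
    utils::write.table(roc$points, points_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  }
  if (!is.null(summary_json)) {
    jsonlite::write_json(c(opt[c("cutoff", "sensitivity", "specificity",
                                 "ppv", "npv", "youden")],
                           list(auc = roc$auc)),
                         summary_json, auto_unbox = TRUE, digits = NA)
  }
  invisible(opt)
}
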