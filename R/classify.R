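#' Classify treatment response from CGI observations and treatment events
#'
#' Implements the study's response rules over a 1-year (configurable)
#' observation window starting at the primary treatment course start:
#'
#' Response signals (any one suffices):
#' \describe{
#'   \item{R1}{a CGI-S improvement (numeric decrease) of >= 2 points between two
#'     observations at least `min_pair_gap` (30) days apart;}
#'   \item{R2}{any CGI-S of 1;}
#'   \item{R3}{any CGI-I of <= 2.}
#' }
#' Necessary stability conditions:
#' \describe{
#'   \item{R4}{treatment duration >= 90 days;}
#'   \item{R5}{no antipsychotic or mood-stabilizer add-on in the window;}
#'   \item{R6}{no dose increase after day 90 of treatment.}
#' }
#' A subject is a responder iff (R1 or R2 or R3) and R4 and R5 and R6.
#' Otherwise, non-response rules apply:
#' \describe{
#'   \item{N1}{an add-on, a switch, or a post-90-day dose increase in the window;}
#'   \item{N2}{discontinuation attributed to inefficacy;}
#'   \item{N3}{>= `nonresponse_min_span` (180) days of CGI-S observation with
#'     >= 2 CGI-S values, duration >= 90 days, and no response signal.}
#' }
#' All remaining cases are `unknown` (discontinuation for side effects, sparse
#' records, improvement pairs closer than 30 days with no other signal, ...).
#' Records dated after the window never influence the label.
#'
#' @param cgi Data frame for one subject: `date` (Date), `scale` ("CGI-S" or
#'   "CGI-I"), `value` (integer 1..7).
#' @param events Data frame for one subject: `date` (Date), `kind` (one of
#'   start, dose_increase, addon_antipsychotic, addon_mood_stabilizer, switch,
#'   discontinuation), `reason` (for discontinuation: inefficacy, side_effects,
#'   other, unknown).
#' @param window_days Observation window length in days (default 365).
#' @param baseline_only If `TRUE`, R1 compares only against the first CGI-S
#'   observation rather than any earlier one.
#' @param min_pair_gap Minimum day gap for the R1 pair (default 30).
#' @param nonresponse_min_span Minimum CGI-S observation span for N3 (default 180).
#' @return List with `label` ("responder", "non_responder" or "unknown"),
#'   `criteria` (character vector of satisfied rule ids), `window_days`.
#' @export
classify_response <- function(cgi, events, window_days = 365,
                              baseline_only = FALSE, min_pair_gap = 30,
                              nonresponse_min_span = 180) {
  starts <- events$date[events$kind == "start"]
  if (length(starts) != 1) {
    stop("each subject needs exactly one course start event; found ", length(starts))
  }
  start <- as.Date(starts)
  if (any(as.Date(events$date) < start)) stop("event dates before course start")
  window_end <- start + window_days

  ev <- events[as.Date(events$date) >= start & as.Date(events$date) <= window_end, ,
               drop = FALSE]
  cg <- cgi[as.Date(cgi$date) >= start & as.Date(cgi$date) <= window_end, ,
            drop = FALSE]
  if (nrow(cg) > 0 && any(cg$value < 1 | cg$value > 7)) {
    stop("CGI values must be integers in 1..7")
  }
  day <- as.numeric(as.Date(cg$date) - start)
  ev_day <- as.numeric(as.Date(ev$date) - start)

  s_idx <- which(cg$scale == "CGI-S")
  i_idx <- which(cg$scale == "CGI-I")
  s_day <- day[s_idx]; s_val <- cg$value[s_idx]
  o <- order(s_day); s_day <- s_day[o]; s_val <- s_val[o]

  r1 <- FALSE
  if (length(s_val) >= 2) {
    earlier <- if (baseline_only) 1L else seq_along(s_val)
    for (a in earlier) {
      later <- which(s_day >= s_day[a] + min_pair_gap)
      if (any(s_val[later] <= s_val[a] - 2)) { r1 <- TRUE; break }
    }
  }
  r2 <- any(s_val == 1)
  r3 <- length(i_idx) > 0 && any(cg$value[i_idx] <= 2)

  disc <- which(ev$kind == "discontinuation")
  duration <- if (length(disc) > 0) min(ev_day[disc]) else window_days
  r4 <- duration >= 90
  addons <- ev$kind %in% c("addon_antipsychotic", "addon_mood_stabilizer")
  r5 <- !any(addons)
  late_increase <- ev$kind == "dose_increase" & ev_day > 90
  r6 <- !any(late_increase)

  n1 <- any(addons) || any(ev$kind == "switch") || any(late_increase)
  n2 <- length(disc) > 0 && any(!is.na(ev$reason[disc]) & ev$reason[disc] == "inefficacy")
  signal <- r1 || r2 || r3
  span <- if (length(s_day) >= 2) max(s_day) else 0
  n3 <- !signal && length(s_day) >= 2 && span >= nonresponse_min_span && duration >= 90

  sat <- c("R1", "R2", "R3", "R4", "R5", "R6", "N1", "N2", "N3")[
    c(r1, r2, r3, r4, r5, r6, n1, n2, n3)]
  label <- if (signal && r4 && r5 && r6) "responder"
           else if (n1 || n2 || n3) "non_responder"
           else "unknown"
  list(label = label, criteria = sat, window_days = window_days)
}

#' Classify every subject in a cohort
#'
#' Applies [classify_response()] per subject over long-format CGI and event
#' tables. Record order never affects labels.
#'
#' @param cgi Data frame with `subject_id`, `date`, `scale`, `value`.
#' @param events Data frame with `subject_id`, `date`, `kind`, `drug`, `dose`,
#'   `reason`.
#' @param ... Passed to [classify_response()].
#' @return Data frame with `subject_id`, `label`, `criteria`
#'   (comma-collapsed satisfied rules), `window_days`.
#' @export
classify_cohort <- function(cgi, events, ...) {
  ids <- unique(events$subject_id)
  res <- lapply(ids, function(sid) {
    r <- classify_response(cgi[cgi$subject_id == sid, , drop = FALSE],
                           events[events$subject_id == sid, , drop = FALSE], ...)
    data.frame(subject_id = sid, label = r$label,
               criteria = paste(r$criteria, collapse = ","),
               window_days = r$window_days, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Read CGI observations from TSV
#' @param path TSV with header `subject_id date scale value`, ISO-8601 dates.
#' @return Data frame with parsed `Date` column.
#' @export
read_cgi_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  df$date <- as.Date(df$date)
  df$value <- as.integer(df$value)
  df
}

#' Read treatment events from TSV
#' @param path TSV with header `subject_id date kind drug dose reason`.
#' @return Data frame with parsed `Date` column.
#' @export
read_events_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "", na.strings = c("NA", ""))
  df$date <- as.Date(df$date)
  df
}

#' Write response labels to TSV
#' @param labels Output of [classify_cohort()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels_tsv <- function(labels, path) {
  utils::write.table(labels, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
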