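# Independent reference implementations used as oracles. These deliberately
# share no code with the package: straightforward, O(n^2)-or-worse versions of
# each definition.

# quick genotype_matrix from a dosage matrix
make_gm <- function(dosage, chrom = NULL, pos = NULL, ref = "A", alt = "G") {
  m <- ncol(dosage)
  ids <- colnames(dosage)
  if (is.null(ids)) ids <- paste0("v", seq_len(m))
  genotype_matrix(dosage,
                  data.frame(id = ids,
                             chrom = if (is.null(chrom)) rep("1", m) else chrom,
                             pos = if (is.null(pos)) seq_len(m) * 10L else pos,
                             ref = rep_len(ref, m), alt = rep_len(alt, m),
                             stringsAsFactors = FALSE))
}

# exhaustive greedy clumping oracle: same definition, independent code path
oracle_clump <- function(variants, dosages, r2_threshold, window_kb, p_threshold = 1) {
  v <- variants[order(variants$p, variants$chrom, variants$pos, variants$id), ]
  done <- character(0)
  retained <- character(0)
  removed <- list()
  r2_of <- function(i1, i2) {
    a <- dosages[, i1]; b <- dosages[, i2]
    ok <- !is.na(a) & !is.na(b)
    a <- a[ok]; b <- b[ok]
    if (length(a) < 2 || sd(a) == 0 || sd(b) == 0) return(0)
    cor(a, b)^2
  }
  for (r in seq_len(nrow(v))) {
    id <- v$id[r]
    if (id %in% done) next
    if (v$p[r] > p_threshold) next
    done <- c(done, id)
    retained <- c(retained, id)
    if (window_kb <= 0 || r2_threshold > 1) next
    for (r2i in seq_len(nrow(v))) {
      oid <- v$id[r2i]
      if (oid %in% done) next
      if (v$chrom[r2i] != v$chrom[r]) next
      if (abs(v$pos[r2i] - v$pos[r]) > window_kb * 1000) next
      if (r2_of(id, oid) >= r2_threshold) {
        done <- c(done, oid)
        removed[[oid]] <- id
      }
    }
  }
  leftover <- setdiff(v$id, done)
  list(retained = c(retained, leftover), removed = removed)
}

# brute-force Youden optimum: every observed score (and -Inf) as cutoff
oracle_youden <- function(scores, labels) {
  labels <- as.logical(labels)
  cands <- sort(unique(c(-Inf, scores, Inf)))
  best <- NULL
  for (cut in cands) {
    pred <- scores >= cut
    sens <- sum(pred & labels) / sum(labels)
    spec <- sum(!pred & !labels) / sum(!labels)
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12) {
      best <- list(cut = cut, sens = sens, spec = spec, j = j)
    }
  }
  best
}

# textbook Cochran-Armitage trend statistic on a 3x2 table, scores 0/1/2
oracle_trend <- function(tab, w = 0:2) {
  n <- sum(tab)
  R <- sum(tab[, 1])              # responders
  ni <- rowSums(tab)
  num <- sum(w * (tab[, 1] - ni * R / n))
  pbar <- R / n
  den <- pbar * (1 - pbar) * (sum(w^2 * ni) - sum(w * ni)^2 / n)
  z2 <- num^2 / den
  list(statistic = z2, p = pchisq(z2, 1, lower.tail = FALSE))
}

# complete enumeration Fisher exact p for a 3x2 table with fixed margins
oracle_fisher_3x2 <- function(tab) {
  r <- rowSums(tab); c1 <- sum(tab[, 1]); n <- sum(tab)
  logp_table <- function(x) {
    sum(lchoose(r, x)) - lchoose(n, c1)
  }
  p_obs <- logp_table(tab[, 1])
  total <- 0
  for (x1 in 0:min(r[1], c1)) {
    for (x2 in 0:min(r[2], c1 - x1)) {
      x3 <- c1 - x1 - x2
      if (x3 < 0 || x3 > r[3]) next
      lp <- logp_table(c(x1, x2, x3))
      if (lp <= p_obs + 1e-7) total <- total + exp(lp)
    }
  }
  total
}

# build one subject's CGI/event fixture from day offsets
traj_case <- function(sid = "X1", start = as.Date("2016-01-01"),
                      cgi_s = NULL, cgi_i = NULL, events = NULL) {
  cgi <- data.frame(subject_id = character(0), date = as.Date(character(0)),
                    scale = character(0), value = integer(0))
  if (!is.null(cgi_s)) {
    cgi <- rbind(cgi, data.frame(subject_id = sid, date = start + cgi_s$day,
                                 scale = "CGI-S", value = cgi_s$value,
                                 stringsAsFactors = FALSE))
  }
  if (!is.null(cgi_i)) {
    cgi <- rbind(cgi, data.frame(subject_id = sid, date = start + cgi_i$day,
                                 scale = "CGI-I", value = cgi_i$value,
                                 stringsAsFactors = FALSE))
  }
  ev <- data.frame(subject_id = sid, date = start, kind = "start",
                   drug = "quetiapine", dose = 400, reason = NA_character_,
                   stringsAsFactors = FALSE)
  if (!is.null(events)) {
    ev <- rbind(ev, data.frame(subject_id = sid, date = start + events$day,
                               kind = events$kind, drug = "quetiapine",
                               dose = NA_real_,
                               reason = if (!is.null(events$reason)) events$reason
                                        else NA_character_,
                               stringsAsFactors = FALSE))
  }
  list(cgi = cgi, events = ev)
}

# the >= 20 hand-designed trajectory cases spanning R1-R6, N1-N3 and unknown;
# each entry: fixture + the label the rules should assign
classifier_cases <- function() {
  list(
    r1_basic = list(traj_case(cgi_s = list(day = c(0, 45), value = c(5, 3))),
                    "responder"),
    r1_late_pair = list(traj_case(cgi_s = list(day = c(0, 100, 200),
                                               value = c(6, 5, 4))),
                        "responder"),  # 6 -> 4 across >= 30 days
    r1_gap_too_short = list(traj_case(cgi_s = list(day = c(0, 20), value = c(5, 3))),
                            "unknown"),
    r2_cgi_one = list(traj_case(cgi_s = list(day = c(0, 60), value = c(3, 1))),
                      "responder"),
    r3_cgi_i = list(traj_case(cgi_s = list(day = 0, value = 5),
                              cgi_i = list(day = 100, value = 2)),
                    "responder"),
    r3_cgi_i_1 = list(traj_case(cgi_i = list(day = 40, value = 1)), "responder"),
    r4_short_duration = list(traj_case(
      cgi_s = list(day = c(0, 45), value = c(5, 3)),
      events = list(day = 60, kind = "discontinuation", reason = "other")),
      "unknown"),  # improved but stopped before day 90, not for inefficacy
    r5_addon_mood = list(traj_case(
      cgi_s = list(day = c(0, 45), value = c(5, 3)),
      events = list(day = 60, kind = "addon_mood_stabilizer")),
      "non_responder"),  # N1
    r5_addon_ap = list(traj_case(
      cgi_s = list(day = c(0, 45), value = c(5, 3)),
      events = list(day = 30, kind = "addon_antipsychotic")),
      "non_responder"),
    r6_late_increase = list(traj_case(
      cgi_s = list(day = c(0, 45), value = c(5, 3)),
      events = list(day = 150, kind = "dose_increase")),
      "non_responder"),  # N1 via post-90-day increase
    r6_early_increase_ok = list(traj_case(
      cgi_s = list(day = c(0, 45), value = c(5, 3)),
      events = list(day = 50, kind = "dose_increase")),
      "responder"),  # increases before day 90 do not disqualify
    n1_dose_increase_no_improvement = list(traj_case(
      cgi_s = list(day = 0, value = 5),
      events = list(day = 150, kind = "dose_increase")),
      "non_responder"),
    n1_switch = list(traj_case(
      cgi_s = list(day = c(0, 40), value = c(5, 5)),
      events = list(day = 120, kind = "switch")),
      "non_responder"),
    n2_stop_inefficacy = list(traj_case(
      cgi_s = list(day = 0, value = 5),
      events = list(day = 200, kind = "discontinuation", reason = "inefficacy")),
      "non_responder"),
    n2_stop_inefficacy_early = list(traj_case(
      cgi_s = list(day = 0, value = 5),
      events = list(day = 40, kind = "discontinuation", reason = "inefficacy")),
      "non_responder"),
    n3_flat = list(traj_case(cgi_s = list(day = c(0, 100, 365),
                                          value = c(4, 4, 4))),
                   "non_responder"),
    n3_mild_improvement = list(traj_case(
      cgi_s = list(day = c(0, 90, 200), value = c(5, 4, 4))),
      "non_responder"),  # 1-point improvement is not a response signal
    unknown_stop_side_effects = list(traj_case(
      cgi_s = list(day = 0, value = 5),
      events = list(day = 120, kind = "discontinuation", reason = "side_effects")),
      "unknown"),
    unknown_single_obs = list(traj_case(cgi_s = list(day = 0, value = 5)),
                              "unknown"),
    unknown_short_span = list(traj_case(
      cgi_s = list(day = c(0, 100), value = c(4, 4))),
      "unknown"),  # flat but only 100 days of observation
    unknown_no_cgi = list(traj_case(), "unknown"),
    window_outside_signal = list(traj_case(
      cgi_s = list(day = c(0, 400), value = c(5, 3))),
      "unknown"),  # the improvement falls outside the 1-year window
    window_outside_disqualifier = list(traj_case(
      cgi_s = list(day = c(0, 45), value = c(5, 3)),
      events = list(day = 400, kind = "addon_antipsychotic")),
      "responder")  # add-on after the window never influences the label
  )
}
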