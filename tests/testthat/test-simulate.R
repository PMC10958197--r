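test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_subjects = 1), "n_subjects")
  expect_error(sim_config(missing_rate = 0.5), "missing_rate")
  expect_error(sim_config(fst = 0.5), "fst")
  panel <- response_panel(); panel$eaf <- response_panel_eaf()[panel$snp_id]
  panel$eaf[1] <- 0
  expect_error(sim_config(panel = panel), "minor allele frequencies")
  panel$eaf[1] <- 1.2
  expect_error(sim_config(panel = panel), "minor allele frequencies")
  expect_error(
    sim_config(ld_blocks = list(list(ids = c("rs6688363", "rs10170310"), r2 = 1))),
    "incompatible")
})

test_that("same seed gives byte-identical cohorts", {
  cfg <- sim_config(n_subjects = 60, n_background_variants = 10, seed = 7)
  b1 <- simulate_cohort(cfg)
  b2 <- simulate_cohort(cfg)
  expect_identical(serialize(b1, NULL), serialize(b2, NULL))
})

test_that("empirical allele frequency converges to the configured value", {
  panel <- data.frame(snp_id = "v1", chr = "1", pos = 100L,
                      effect_allele = "G", other_allele = "A",
                      weight = 1, p = 1, eaf = 0.5, stringsAsFactors = FALSE)
  cfg <- sim_config(n_subjects = 10000, panel = panel,
                    n_background_variants = 0, n_subpopulations = 1, fst = 0,
                    missing_rate = 0, seed = 11)
  gm <- simulate_genotypes(cfg)
  f_hat <- mean(gm$dosage[, 1]) / 2
  tol <- 3 * sqrt(0.5 * 0.5 / (2 * 10000))   # binomial sampling error
  expect_lt(abs(f_hat - 0.5), tol)
})

test_that("missingness behaves: zero rate gives complete data, positive rate hits target", {
  cfg0 <- sim_config(n_subjects = 300, missing_rate = 0, seed = 3)
  expect_equal(sum(is.na(simulate_genotypes(cfg0)$dosage)), 0)
  cfg1 <- sim_config(n_subjects = 500, missing_rate = 0.05, seed = 3)
  gm <- simulate_genotypes(cfg1)
  rate <- mean(is.na(gm$dosage))
  n_entries <- length(gm$dosage)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / n_entries))
})

test_that("LD blocks reach their target r2", {
  panel <- response_panel()
  panel$eaf <- unname(response_panel_eaf()[panel$snp_id])
  # give two panel variants one shared frequency and wire them into a block
  panel$eaf[panel$snp_id %in% c("rs6688363", "rs10170310")] <- 0.3
  blocks <- list(list(ids = c("rs6688363", "rs10170310"), r2 = 1.0))
  cfg <- sim_config(n_subjects = 2000, panel = panel, ld_blocks = blocks,
                    n_background_variants = 0, n_subpopulations = 1, fst = 0,
                    missing_rate = 0, seed = 5)
  gm <- simulate_genotypes(cfg)
  expect_equal(unname(pairwise_r2(gm$dosage[, "rs6688363"],
                                  gm$dosage[, "rs10170310"])), 1.0)

  blocks <- list(list(ids = c("rs6688363", "rs10170310"), r2 = 0.5))
  cfg <- sim_config(n_subjects = 20000, panel = panel, ld_blocks = blocks,
                    n_background_variants = 0, n_subpopulations = 1, fst = 0,
                    missing_rate = 0, seed = 5)
  gm <- simulate_genotypes(cfg)
  r2 <- pairwise_r2(gm$dosage[, "rs6688363"], gm$dosage[, "rs10170310"])
  expect_lt(abs(r2 - 0.5), 0.05)
})

test_that("responder fraction is calibrated to the logistic model", {
  # across replicates the empirical responder fraction matches the implied mean
  R <- 200
  fracs <- p_implied <- numeric(R)
  for (r in seq_len(R)) {
    cfg <- sim_config(n_subjects = 1000, n_background_variants = 0, seed = 5000 + r)
    b <- simulate_cohort(cfg, include_clinical = FALSE)
    fracs[r] <- mean(b$truth$true_responder)
    p_implied[r] <- mean(b$truth$liability)
  }
  mc_se <- sd(fracs - p_implied) / sqrt(R)
  expect_lt(abs(mean(fracs) - mean(p_implied)), 3 * mc_se)
})

test_that("null effects leave the true PRS uninformative (AUC centred at 0.5)", {
  R <- 60
  aucs <- numeric(R)
  for (r in seq_len(R)) {
    cfg <- sim_config(n_subjects = 400, n_background_variants = 0,
                      true_log_or = 0, age_log_or = 0, subpop_log_or = 0,
                      seed = 9000 + r)
    b <- simulate_cohort(cfg, include_clinical = FALSE)
    aucs[r] <- roc_curve(b$truth$true_prs, b$truth$true_responder)$auc
  }
  expect_lt(abs(mean(aucs) - 0.5), 3 * sd(aucs) / sqrt(R))
})

test_that("trajectories at fidelity 1 are recoverable and degenerate configs warn", {
  cfg <- sim_config(n_subjects = 150, n_background_variants = 0, seed = 21)
  b <- simulate_cohort(cfg)
  labels <- classify_cohort(b$cgi, b$events)
  m <- merge(labels, b$truth, by = "subject_id")
  expect_true(all(m$label != "unknown"))
  expect_equal((m$label == "responder"), m$true_responder)

  cfg_deg <- sim_config(n_subjects = 50, n_background_variants = 0,
                        intercept = 30, true_log_or = 0, age_log_or = 0,
                        seed = 2)
  expect_warning(simulate_cohort(cfg_deg, include_clinical = FALSE), "degenerate")
})

test_that("a written cohort can be read back consistently", {
  cfg <- sim_config(n_subjects = 40, n_background_variants = 5, seed = 17)
  b <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(b, dir)
  gm <- read_genotypes_vcf(file.path(dir, "genotypes.vcf.gz"))
  expect_equal(gm$dosage, b$genotypes$dosage, tolerance = 1e-6,
               ignore_attr = TRUE)
  cgi <- read_cgi_tsv(file.path(dir, "cgi.tsv"))
  ev <- read_events_tsv(file.path(dir, "events.tsv"))
  labels_disk <- classify_cohort(cgi, ev)
  labels_mem <- classify_cohort(b$cgi, b$events)
  expect_equal(labels_disk[order(labels_disk$subject_id), ],
               labels_mem[order(labels_mem$subject_id), ],
               ignore_attr = TRUE)
  panel <- read_score_file(file.path(dir, "score_panel.tsv"))
  expect_equal(nrow(panel), 11)
})
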