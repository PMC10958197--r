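test_that("allele alignment covers match, swap, strand flip and drops", {
  expect_equal(align_alleles("T", "C", ref = "C", alt = "T")$action, "use")
  expect_equal(align_alleles("T", "C", ref = "T", alt = "C")$action, "swap")
  # complement pair: effect A/other G vs ref C/alt T matches after flip
  expect_equal(align_alleles("A", "G", ref = "C", alt = "T")$action, "flip_use")
  expect_equal(align_alleles("A", "G", ref = "T", alt = "C")$action, "flip_swap")
  pal <- align_alleles("A", "T", ref = "A", alt = "T")
  expect_equal(pal$action, "drop")
  expect_equal(pal$reason, "ambiguous strand")
  expect_equal(align_alleles("A", "T", ref = "A", alt = "T",
                             allow_palindromic = TRUE)$action, "swap")
  mis <- align_alleles("A", "G", ref = "A", alt = "C")
  expect_equal(mis$action, "drop")
  expect_equal(mis$reason, "allele mismatch")
})

test_that("dummy-weight scores equal plain allele counts with closed-form extremes", {
  panel <- response_panel()
  n_var <- nrow(panel)
  variants <- data.frame(id = panel$snp_id, chrom = panel$chr, pos = panel$pos,
                         ref = panel$other_allele, alt = panel$effect_allele,
                         stringsAsFactors = FALSE)
  d <- rbind(rep(2, n_var), rep(0, n_var), rep(1, n_var))
  gm <- genotype_matrix(d, variants, subjects = c("hom_eff", "hom_oth", "het"))
  res <- compute_prs(gm, panel, allow_palindromic = TRUE)
  expect_equal(res$score, c(22, 0, 11))
  expect_equal(res$n_used, rep(11L, 3))
  # with complete data the dummy-weight score is an integer allele count
  expect_true(all(res$score == round(res$score)))
})

test_that("weighted scores match hand arithmetic and policies handle missingness", {
  panel <- data.frame(snp_id = c("v1", "v2", "v3"), chr = "1",
                      pos = c(100L, 200L, 300L),
                      effect_allele = c("G", "G", "G"),
                      other_allele = c("A", "A", "A"),
                      weight = c(log(1.2), log(0.8), log(1.5)),
                      p = c(1e-8, 1e-8, 1e-8), stringsAsFactors = FALSE)
  d <- matrix(c(2, 1, 0), nrow = 1, dimnames = list("s1", panel$snp_id))
  gm <- make_gm(d)
  res <- compute_prs(gm, panel)
  expect_equal(res$score, 2 * log(1.2) + log(0.8))
  expect_equal(res$score, 0.14149, tolerance = 1e-4)

  # mean imputation: a missing genotype contributes 2 * in-sample frequency
  d2 <- matrix(c(0, 1, 2, NA,
                 0, 1, 2, 0), ncol = 2,
               dimnames = list(paste0("s", 1:4), c("v1", "v2")))
  panel2 <- data.frame(snp_id = c("v1", "v2"), chr = "1", pos = c(1L, 2L),
                       effect_allele = "G", other_allele = "A",
                       weight = 1, p = 0.5, stringsAsFactors = FALSE)
  gm2 <- make_gm(d2)
  res_mean <- compute_prs(gm2, panel2, missing_policy = "mean")
  f <- mean(c(0, 1, 2)) / 2   # in-sample effect-allele frequency 0.5
  expect_equal(res_mean$score[4], 2 * f + 0)
  expect_equal(res_mean$n_imputed, c(0L, 0L, 0L, 1L))

  res_omit <- compute_prs(gm2, panel2, missing_policy = "omit")
  expect_equal(res_omit$score[4], 0)
  expect_equal(res_omit$n_used[4], 1L)
  expect_error(compute_prs(gm2, panel2, missing_policy = "fail"), "missing")
  expect_error(compute_prs(gm2, panel2, missing_policy = "nonsense"))
})

test_that("scores are linear, scale with weights, and increase with dosage", {
  set.seed(10)
  n <- 30
  panel <- response_panel()
  panel_a <- panel[1:5, ]; panel_b <- panel[6:11, ]
  variants <- data.frame(id = panel$snp_id, chrom = panel$chr, pos = panel$pos,
                         ref = panel$other_allele, alt = panel$effect_allele,
                         stringsAsFactors = FALSE)
  d <- matrix(rbinom(n * 11, 2, 0.3), n, 11, dimnames = list(NULL, panel$snp_id))
  gm <- genotype_matrix(d, variants)
  s_all <- compute_prs(gm, panel, allow_palindromic = TRUE)$score
  s_a <- compute_prs(gm, panel_a, allow_palindromic = TRUE)$score
  s_b <- compute_prs(gm, panel_b, allow_palindromic = TRUE)$score
  expect_equal(s_all, s_a + s_b)   # linearity over disjoint panels

  panel_c <- panel; panel_c$weight <- panel$weight * 2.5
  expect_equal(compute_prs(gm, panel_c, allow_palindromic = TRUE)$score,
               2.5 * s_all)        # weight scaling

  d2 <- d; d2[3, 4] <- min(d2[3, 4] + 1, 2)
  gm2 <- genotype_matrix(d2, variants)
  s2 <- compute_prs(gm2, panel, allow_palindromic = TRUE)$score
  expect_true(all(s2 >= s_all))    # monotone in effect-allele dosage
})

test_that("palindromic and mismatched panel entries are dropped with reasons", {
  panel <- data.frame(snp_id = c("pal", "mis", "ok"), chr = "1",
                      pos = c(1L, 2L, 3L),
                      effect_allele = c("A", "A", "G"),
                      other_allele = c("T", "G", "A"),
                      weight = 1, p = 0.5, stringsAsFactors = FALSE)
  d <- matrix(c(1, 1, 1), nrow = 1, dimnames = list("s1", panel$snp_id))
  gm <- genotype_matrix(d, data.frame(id = panel$snp_id, chrom = "1",
                                      pos = 1:3, ref = c("A", "A", "A"),
                                      alt = c("T", "C", "G")))
  res <- compute_prs(gm, panel)
  dropped <- attr(res, "dropped")
  expect_setequal(dropped$snp_id, c("pal", "mis"))
  expect_equal(dropped$reason[dropped$snp_id == "pal"], "ambiguous strand")
  expect_equal(dropped$reason[dropped$snp_id == "mis"], "allele mismatch")
  expect_equal(attr(res, "n_aligned"), 1L)
  # zero aligned variants errors
  expect_error(compute_prs(gm, panel[1:2, ]), "aligned")
})
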