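# Joined fold-change inference: quadrants, nested ANOVA, enrichment,
# correlations.

fc_frame <- function(ids, fc_t, fc_a, call = NULL) {
  build_fc_table(
    data.frame(protein_id = ids, fc = fc_t),
    data.frame(protein_id = ids, fc = fc_a,
               call = if (is.null(call)) NA_character_ else call))
}

test_that("fold-change tables join on protein id with duplicate rejection", {
  tu <- data.frame(protein_id = c("A", "B", "C"), fc = c(1.2, 0.8, 1))
  ab <- data.frame(protein_id = c("B", "C", "D"), fc = c(2, 0.5, 3))
  j <- build_fc_table(tu, ab)
  expect_equal(j$protein_id, c("B", "C"))
  expect_equal(attr(j, "n_joined"), 2L)
  expect_equal(nrow(build_fc_table(tu, data.frame(protein_id = "Z", fc = 1))), 0)
  expect_error(build_fc_table(rbind(tu, tu[1, ]), ab), "duplicate")
})

test_that("quadrant labels follow the threshold rules and tie convention", {
  expect_equal(quadrant_classify(1.5, 1.2), "slower/increased")
  expect_equal(quadrant_classify(0.8, 1.3), "faster/increased")
  expect_equal(quadrant_classify(1.0, 1.0), "faster/decreased")  # tie rule
  expect_equal(quadrant_classify(c(2, 0.5), c(0.7, 0.9)),
               c("slower/decreased", "faster/decreased"))
  # significance mode reads the abundance call, not the fold change
  expect_equal(
    quadrant_classify(1.5, 1.4, abundance_call = "unchanged",
                      mode = "significance"),
    "slower/decreased")
})

test_that("quadrant percentages conserve counts and report the composite", {
  j <- fc_frame(sprintf("P%d", 1:8),
                fc_t = c(1.5, 1.5, 0.5, 0.5, 2, 2, 2, 0.9),
                fc_a = c(1.5, 0.5, 1.5, 0.5, 2, 2, 0.4, 1.1),
                call = c("increased", "decreased", "increased", "decreased",
                         "increased", "unchanged", "decreased", "unchanged"))
  q <- quadrant_percentages(j)
  expect_equal(sum(q$counts), q$n)
  expect_equal(sum(q$percentages), 100)
  expect_equal(unname(q$counts), c(3L, 2L, 2L, 1L))
  # composite: slower & not decreased = P1, P5, P6 of the 5 slower proteins
  expect_equal(q$pct_slower_incr_or_unch_sig, 100 * 3 / 8)
  # members at (1.5, 1.5) only
  q2 <- quadrant_percentages(j, members = c("P1", "P5"))
  expect_equal(unname(q2$percentages["slower/increased"]), 100)
  # empty intersection gives an explicit empty summary
  q0 <- quadrant_percentages(j, members = "NOPE")
  expect_equal(q0$n, 0L)
})

test_that("nested ANOVA sums of squares match the linear-model oracle on a toy", {
  # 4 proteins (2 per genotype), 3 replicates each, hand-sized numbers
  d <- data.frame(
    protein_id = rep(c("a", "b", "c", "d"), each = 3),
    genotype = rep(c("mutant", "mutant", "control", "control"), each = 3),
    t_half = c(10, 12, 14, 20, 22, 24, 9, 10, 11, 15, 16, 17))
  got <- group_mean_fc_test(d, "mutant", "control")
  want <- oracle_nested_anova(d)
  expect_equal(unname(got$ss["genotype"]), want$ss_genotype)
  expect_equal(unname(got$ss["protein_within_genotype"]), want$ss_protein)
  expect_equal(unname(got$ss["residual"]), want$ss_residual)
  expect_equal(got$F, want$F)
  expect_equal(got$p, want$p)
  expect_equal(got$df1, 1L)
  expect_equal(got$df2, 2L)
  # unbalanced case (drop one observation) still matches sequential SS
  d2 <- d[-5, ]
  got2 <- group_mean_fc_test(d2, "mutant", "control")
  want2 <- oracle_nested_anova(d2)
  expect_equal(unname(got2$ss["genotype"]), want2$ss_genotype)
  expect_equal(got2$p, want2$p)
})

test_that("nested ANOVA flags degenerate variance instead of failing", {
  d <- data.frame(protein_id = rep(c("a", "b", "c", "d"), each = 2),
                  genotype = rep(c("m", "m", "c", "c"), each = 2),
                  t_half = rep(50, 8))
  got <- group_mean_fc_test(d, "m", "c")
  expect_equal(got$p, 1)
  expect_equal(got$flag, "degenerate_variance")
})

test_that("nested ANOVA null rejection rate is calibrated at alpha 0.05", {
  set.seed(77)
  rej <- 0
  n_data <- 200
  for (i in seq_len(n_data)) {
    n <- 40
    th <- rlnorm(2 * n, log(48), 1)
    d <- data.frame(
      protein_id = rep(sprintf("p%03d", seq_len(2 * n)), each = 3),
      genotype = rep(rep(c("mutant", "control"), each = n), each = 3),
      t_half = rep(th, each = 3) * exp(rnorm(6 * n, 0, 0.1)))
    if (group_mean_fc_test(d, "mutant", "control")$p < 0.05) rej <- rej + 1
  }
  expect_gte(rej / n_data, 0.02)
  expect_lte(rej / n_data, 0.08)
})

test_that("a strong group slowing is detected by the nested ANOVA", {
  for (seed in 1:3) {
    cfg <- sim_config(
      n_proteins_per_class = c(mito = 150, other = 50),
      class_labels = c("mito", "other"),
      genotype_effects = list(control = numeric(0), mutant = c(mito = 1.45)),
      seed = seed)
    truth <- simulate_proteome(cfg)
    fit <- turnover_fit(simulate_labeling(truth, cfg))
    tfc <- turnover_fold_change(fit, "mutant", "control")
    mito <- truth$proteins$protein_id[truth$proteins$class_label == "mito"]
    gt <- group_mean_fc_test(replicate_halflives(fit), "mutant", "control",
                             members = intersect(mito, tfc$protein_id))
    expect_lt(gt$p, 0.01)
    expect_equal(gt$mean_fc, 1.45, tolerance = 0.15)
  }
})

test_that("Fisher p-values match exhaustive hypergeometric enumeration", {
  enr <- function(a, b, c_, d)
    prevalence_enrichment(rep(c(TRUE, FALSE), c(a, b)),
                          rep(c(TRUE, FALSE), c(c_, d)))
  r1 <- enr(3, 1, 1, 3)
  expect_equal(r1$p, 34 / 70, tolerance = 1e-10)   # 0.4857
  expect_equal(r1$test_used, "fisher")
  r2 <- enr(5, 0, 0, 5)
  expect_equal(r2$p, 2 / 252, tolerance = 1e-10)   # 0.00794
  r3 <- enr(0, 10, 0, 20)   # zero outcome margin
  expect_equal(r3$p, 1)
  expect_equal(r3$flag, "zero_margin")
  # random small tables against the enumeration oracle
  set.seed(12)
  for (i in 1:50) {
    cnt <- as.vector(rmultinom(1, sample(6:40, 1), rep(0.25, 4)))
    a <- cnt[1]; b <- cnt[2]; c_ <- cnt[3]; d <- cnt[4]
    if ((a + b) == 0 || (c_ + d) == 0) next
    r <- enr(a, b, c_, d)
    expect_equal(r$p, oracle_fisher_p(a, b, c_, d), tolerance = 1e-8)
  }
})

test_that("the test switches to chi-squared for large well-filled tables", {
  big <- prevalence_enrichment(rep(c(TRUE, FALSE), c(300, 400)),
                               rep(c(TRUE, FALSE), c(200, 600)))
  expect_equal(big$test_used, "chi2")
  expect_equal(big$p,
               chisq.test(matrix(c(300, 400, 200, 600), 2, byrow = TRUE),
                          correct = FALSE)$p.value)
  # sparse but large: expected cell < 5 forces the exact test
  sparse <- prevalence_enrichment(rep(c(TRUE, FALSE), c(2, 700)),
                                  rep(c(TRUE, FALSE), c(1, 800)))
  expect_equal(sparse$test_used, "fisher")
  # odds ratio with Haldane correction when a cell is zero
  z <- prevalence_enrichment(rep(TRUE, 5), rep(c(TRUE, FALSE), c(3, 7)))
  expect_equal(z$odds_ratio, (5.5 * 7.5) / (0.5 * 3.5))
})

test_that("label swap inverts fold changes and reflects quadrants", {
  set.seed(31)
  ids <- sprintf("P%02d", 1:30)
  fc_t <- 2^rnorm(30, 0, 0.5); fc_a <- 2^rnorm(30, 0, 0.5)
  q1 <- quadrant_classify(fc_t, fc_a)
  q2 <- quadrant_classify(1 / fc_t, 1 / fc_a)
  swap <- c(`slower/increased` = "faster/decreased",
            `slower/decreased` = "faster/increased",
            `faster/increased` = "slower/decreased",
            `faster/decreased` = "slower/increased")
  expect_equal(unname(swap[q1]), q2)
})

test_that("cross-dataset correlations behave at the identity, null and signal", {
  set.seed(9)
  ids <- sprintf("P%03d", 1:150)
  fc <- data.frame(protein_id = ids, fc = 2^rnorm(150, 0, 0.4))
  self <- cross_mutant_correlation(fc, fc)
  expect_equal(self$r, 1, tolerance = 1e-12)
  expect_equal(self$n, 150)

  # independent effects: near-zero correlation
  null_r <- vapply(1:10, function(i) {
    a <- data.frame(protein_id = ids, fc = 2^rnorm(150, 0, 0.4))
    b <- data.frame(protein_id = ids, fc = 2^rnorm(150, 0, 0.4))
    r <- cross_mutant_correlation(a, b)
    abs(r$r) < 0.2 && r$p > 0.05
  }, TRUE)
  expect_gte(mean(null_r), 0.9)

  # shared protein-level effects are recovered
  shared <- rnorm(150, 0, 0.6)
  a <- data.frame(protein_id = ids, fc = 2^(shared + rnorm(150, 0, 0.2)))
  b <- data.frame(protein_id = ids, fc = 2^(shared + rnorm(150, 0, 0.2)))
  expect_gt(cross_mutant_correlation(a, b)$r, 0.7)

  # too few common proteins
  small <- cross_mutant_correlation(fc[1:2, ], fc)
  expect_false(small$testable)
  expect_true(is.na(small$r))
})
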