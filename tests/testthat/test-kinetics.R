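# Half-life estimation, CV filtering, fold changes, per-protein tests.

make_meas <- function(f_by_time, genotype = "g", protein = "P1",
                      reps = paste0("r", 1:3)) {
  do.call(rbind, lapply(reps, function(r)
    data.frame(protein_id = protein, genotype = genotype, replicate = r,
               time_h = as.numeric(names(f_by_time)),
               fraction_new = unname(f_by_time), stringsAsFactors = FALSE)))
}

test_that("single-time-point fits equal the closed-form inversion", {
  # f = 0.5 at t = 100 h with plateau 1 is the definition of a 100 h half-life
  m <- data.frame(protein_id = "P1", genotype = "g",
                  replicate = paste0("r", 1:6), time_h = 100,
                  fraction_new = 0.5)
  fit <- turnover_fit(m)
  expect_equal(fit$estimates$t_half, 100)
  # random single-point datasets against t*ln2 / (-ln(1 - f/p))
  set.seed(1)
  for (i in 1:20) {
    t0 <- runif(1, 50, 400); f0 <- runif(1, 0.05, 0.95); p0 <- runif(1, 0.7, 1)
    m <- data.frame(protein_id = "P", genotype = "g",
                    replicate = paste0("r", 1:6), time_h = t0,
                    fraction_new = min(f0 * p0, p0 * 0.999))
    fit <- turnover_fit(m, plateau = p0)
    expect_equal(fit$estimates$t_half,
                 t0 * log(2) / (-log(1 - m$fraction_new[1] / p0)),
                 tolerance = 1e-8)
  }
})

test_that("two consistent noise-free time points recover the half-life exactly", {
  m <- make_meas(c(`120` = 0.5, `240` = 0.75))
  fit <- turnover_fit(m)
  expect_equal(fit$estimates$t_half, 120, tolerance = 1e-9)
  expect_equal(fit$estimates$k * fit$estimates$t_half, log(2))
  expect_equal(unname(fit$replicate_t_half[["P1|g"]]), rep(120, 3),
               tolerance = 1e-9)
  expect_equal(fit$estimates$cv, 0)
  expect_true(fit$estimates$passed_qc)
})

test_that("noise-free synthetic data is recovered to relative 1e-6 at any seed", {
  for (seed in c(1, 23)) {
    cfg <- noisefree_config(seed = seed, n = 25)
    truth <- simulate_proteome(cfg)
    fit <- turnover_fit(simulate_labeling(truth, cfg))
    mrg <- merge(fit$estimates, truth$half_life,
                 by = c("protein_id", "genotype"))
    expect_equal(nrow(mrg), nrow(truth$half_life))
    expect_lt(max(abs(mrg$t_half - mrg$t_half_h) / mrg$t_half_h), 1e-6)
  }
})

test_that("degenerate inputs are flagged, not thrown", {
  m0 <- make_meas(c(`120` = 0, `264` = 0))
  fit <- turnover_fit(m0)
  expect_equal(fit$estimates$k, 0)
  expect_equal(fit$estimates$t_half, Inf)
  expect_false(fit$estimates$passed_qc)
  expect_equal(fit$estimates$flag, "all_zero")

  msat <- make_meas(c(`120` = 1, `264` = 1))
  fsat <- turnover_fit(msat)
  expect_equal(fsat$estimates$flag, "saturated")
  expect_equal(fsat$estimates$k, log(2) / 0.1)

  mfew <- make_meas(c(`120` = 0.5), reps = c("r1", "r2"))
  ffew <- turnover_fit(mfew)
  expect_equal(ffew$estimates$flag, "too_few_measurements")
  expect_false(ffew$estimates$passed_qc)
  expect_true(is.na(ffew$estimates$t_half))
})

test_that("increasing every label fraction strictly decreases the fitted half-life", {
  set.seed(4)
  base <- make_meas(c(`120` = 0.4, `264` = 0.62))
  th <- numeric(0)
  for (bump in c(0, 0.05, 0.1, 0.15)) {
    m <- base; m$fraction_new <- m$fraction_new + bump
    th <- c(th, turnover_fit(m)$estimates$t_half)
  }
  expect_true(all(diff(th) < 0))
})

test_that("replicate CV matches hand computation and is scale invariant", {
  # [40, 60, 80]: mean 60, sd 20 -> cv = 1/3
  mk <- function(th_by_rep, genotype = "g") do.call(rbind, lapply(
    seq_along(th_by_rep), function(i)
      data.frame(protein_id = "P1", genotype = genotype,
                 replicate = paste0("r", i), time_h = c(120, 264),
                 fraction_new = 1 - exp(-log(2) * c(120, 264) / th_by_rep[i]),
                 stringsAsFactors = FALSE)))
  fit <- turnover_fit(mk(c(40, 60, 80)))
  expect_equal(fit$estimates$cv, sd(c(40, 60, 80)) / 60, tolerance = 1e-6)
  expect_false(fit$estimates$passed_qc)   # 0.333 >= 0.25
  for (c_ in c(0.5, 3, 10)) {
    fitc <- turnover_fit(mk(c_ * c(40, 60, 80)))
    expect_equal(fitc$estimates$cv, fit$estimates$cv, tolerance = 1e-6)
  }
})

test_that("a CV of exactly 0.25 is excluded and both genotypes must pass", {
  mk2 <- function(th_by_rep, genotype) do.call(rbind, lapply(
    seq_along(th_by_rep), function(i)
      data.frame(protein_id = "P1", genotype = genotype,
                 replicate = paste0("r", i), time_h = c(120, 264),
                 fraction_new = 1 - exp(-log(2) * c(120, 264) / th_by_rep[i]),
                 stringsAsFactors = FALSE)))
  # replicate half-lives with sd/mean exactly 0.25: mean 60, sd 15
  th <- c(45, 60, 75)
  expect_equal(sd(th) / mean(th), 0.25)
  fit <- turnover_fit(rbind(mk2(th, "mutant"), mk2(c(60, 60, 60), "control")))
  e <- fit$estimates
  expect_equal(e$cv[e$genotype == "mutant"], 0.25, tolerance = 1e-9)
  expect_false(e$passed_qc[e$genotype == "mutant"])
  expect_true(e$passed_qc[e$genotype == "control"])
  res <- apply_cv_filter(fit, "mutant", "control")
  expect_length(res$retained, 0)
  expect_equal(res$ledger$reason, "cv_failed_mutant")
})

test_that("turnover fold change is mutant over control with degenerate exclusion", {
  mk2 <- function(th, genotype, protein = "P1")
    data.frame(protein_id = protein, genotype = genotype,
               replicate = rep(paste0("r", 1:3), each = 2),
               time_h = rep(c(120, 264), 3),
               fraction_new = rep(1 - exp(-log(2) * c(120, 264) / th), 3),
               stringsAsFactors = FALSE)
  fit <- turnover_fit(rbind(mk2(174, "mutant"), mk2(120, "control")))
  fc <- turnover_fold_change(fit, "mutant", "control")
  expect_equal(fc$fc, 1.45, tolerance = 1e-8)
  # identical estimates -> FC 1
  fit1 <- turnover_fit(rbind(mk2(96, "mutant"), mk2(96, "control")))
  expect_equal(turnover_fold_change(fit1, "mutant", "control")$fc, 1)
  # all-zero control -> excluded with reason, not an FC
  m <- rbind(mk2(174, "mutant"),
             data.frame(protein_id = "P1", genotype = "control",
                        replicate = rep(paste0("r", 1:3), each = 2),
                        time_h = rep(c(120, 264), 3), fraction_new = 0))
  fit0 <- turnover_fit(m)
  fc0 <- turnover_fold_change(fit0, "mutant", "control")
  expect_equal(nrow(fc0), 0)
})

test_that("noise-free simulation recovers the configured factor as every FC", {
  cfg <- noisefree_config(seed = 11, n = 20)
  truth <- simulate_proteome(cfg)
  fit <- turnover_fit(simulate_labeling(truth, cfg))
  fc <- turnover_fold_change(fit, "mutant", "control")
  cls <- truth$proteins$class_label[match(fc$protein_id,
                                          truth$proteins$protein_id)]
  expect_equal(fc$fc[cls == "mito"], rep(1.45, sum(cls == "mito")),
               tolerance = 1e-6)
  expect_equal(fc$fc[cls == "other"], rep(1, sum(cls == "other")),
               tolerance = 1e-6)
})

test_that("per-protein t tests handle identical, separated and sparse inputs", {
  mkrep <- function(th_by_rep, genotype) do.call(rbind, lapply(
    seq_along(th_by_rep), function(i)
      data.frame(protein_id = "P1", genotype = genotype,
                 replicate = paste0("r", i), time_h = c(120, 264),
                 fraction_new = 1 - exp(-log(2) * c(120, 264) / th_by_rep[i]),
                 stringsAsFactors = FALSE)))
  fit_id <- turnover_fit(rbind(mkrep(c(80, 80, 80), "mutant"),
                               mkrep(c(80, 80, 80), "control")))
  t_id <- per_protein_turnover_test(fit_id, "mutant", "control")
  expect_equal(t_id$p, 1)
  expect_equal(t_id$direction, "none")

  fit_sep <- turnover_fit(rbind(mkrep(c(200, 200, 200), "mutant"),
                                mkrep(c(100, 100, 100), "control")))
  t_sep <- per_protein_turnover_test(fit_sep, "mutant", "control")
  expect_lt(t_sep$p, 1e-6)
  expect_equal(t_sep$direction, "slower")

  fit_sparse <- turnover_fit(rbind(mkrep(c(90, 100), "mutant"),
                                   mkrep(c(100, 100, 100), "control")),
                             min_measurements = 4)
  t_sp <- per_protein_turnover_test(fit_sparse, "mutant", "control")
  expect_false(t_sp$testable)
  expect_true(is.na(t_sp$p))
})

test_that("shared-peptide filtering removes exactly the ambiguous rows", {
  m <- data.frame(protein_id = rep(c("A", "B"), each = 6),
                  genotype = "g", replicate = rep(paste0("r", 1:3), 4),
                  time_h = rep(c(120, 264), 6),
                  fraction_new = 0.5,
                  peptide = rep(c("pep_a", "pep_shared", "pep_b", "pep_shared"),
                                each = 3), stringsAsFactors = FALSE)
  map <- data.frame(peptide = c("pep_a", "pep_b", "pep_shared", "pep_shared"),
                    protein_id = c("A", "B", "A", "B"))
  out <- suppressMessages(filter_shared_peptides(m, map))
  expect_equal(nrow(out), 6)
  expect_false(any(out$peptide == "pep_shared"))
  # all-unique map leaves input untouched
  map_u <- data.frame(peptide = unique(m$peptide),
                      protein_id = c("A", "AB1", "B"))
  out_u <- suppressMessages(filter_shared_peptides(m, map_u))
  expect_equal(nrow(out_u), nrow(m))
  # unmapped peptide is an error naming it
  expect_error(
    suppressMessages(filter_shared_peptides(m, map[map$peptide != "pep_a", ])),
    "pep_a")
})

test_that("model-object accessors are coherent", {
  cfg <- noisefree_config(seed = 3, n = 5)
  truth <- simulate_proteome(cfg)
  lab <- simulate_labeling(truth, cfg)
  fit <- turnover_fit(lab)
  cf <- coef(fit)
  expect_equal(dim(cf), c(10L, 2L))
  expect_equal(sort(colnames(cf)), c("control", "mutant"))
  expect_equal(residuals(fit), rep(0, nrow(lab)), tolerance = 1e-7)
  pred <- predict(fit, data.frame(protein_id = "P00001",
                                  genotype = "control", time_h = 120))
  th <- cf["P00001", "control"]
  expect_equal(pred, 1 - 2^(-120 / th), tolerance = 1e-7)
  expect_output(print(fit), "turnover fit")
  expect_output(print(summary(fit)), "genotype")
})
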