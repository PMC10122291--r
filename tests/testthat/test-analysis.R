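test_that("single-study meta-analysis returns the study unchanged", {
  m <- meta_fixed(1.5, 1.2, 1.875)
  expect_equal(m$hr, 1.5, tolerance = 1e-12)
  expect_equal(m$ci, c(1.2, 1.875), tolerance = 1e-9)
})

test_that("two identical studies halve the variance", {
  m1 <- meta_fixed(1.5, 1.1, 2.045)
  m2 <- meta_fixed(c(1.5, 1.5), c(1.1, 1.1), c(2.045, 2.045))
  expect_equal(m2$hr, 1.5, tolerance = 1e-12)
  expect_equal(m2$se, m1$se / sqrt(2), tolerance = 1e-12)
})

test_that("meta-analysis agrees with an independent fixed-effect fit", {
  set.seed(14)
  hr <- exp(rnorm(4, 0.2, 0.3))
  se <- runif(4, 0.05, 0.3)
  lo <- exp(log(hr) - qnorm(0.975) * se)
  hi <- exp(log(hr) + qnorm(0.975) * se)
  m <- meta_fixed(hr, lo, hi)
  ref <- metafor::rma(yi = log(hr), sei = se, method = "FE")
  expect_equal(m$log_hr, as.numeric(ref$beta), tolerance = 1e-10)
  expect_equal(m$se, ref$se, tolerance = 1e-10)
  expect_equal(m$p, ref$pval, tolerance = 1e-10)
  # pooled log-HR lies between the study log-HRs, pooled SE below each
  expect_gte(m$log_hr, min(log(hr)))
  expect_lte(m$log_hr, max(log(hr)))
  expect_lte(m$se, min(se) + 1e-12)
})

test_that("meta-analysis validates its inputs", {
  expect_error(meta_fixed(1.5, 1.6, 2.0), "lo <= hr")
  expect_error(meta_fixed(1.5, 1.5, 1.5), "degenerate")
  expect_error(meta_fixed(1.5, -1, 2), "lo <= hr")
})

test_that("data-frame input and study labels are honored", {
  df <- data.frame(study = c("A", "B"), hr = c(1.65, 1.81),
                   lo = c(1.36, 1.46), hi = c(2.01, 2.25))
  m <- meta_fixed(df)
  expect_equal(m$studies$study, c("A", "B"))
  expect_equal(round(m$hr, 2), 1.72)
})

test_that("recurrence fit covariates and exclusions are as documented", {
  sim <- quick_sim(800, seed = 17)
  dos <- sim$dosages
  # force an unresolvable dosage vector for one subject
  dos$rs8176743_T[1] <- dos$rs8176743_T[1] + 1L
  expect_message(
    fit <- fit_recurrence(sim$records, "ambispective", dosages = dos),
    "unresolved")
  expect_equal(attr(fit, "n_excluded_abo"), 1L)
  expect_named(fit$coefficients,
               c("abo_A1", "abo_A2", "abo_B", "abo_O2", "sex",
                 "provoked_first_vt", "age10", "dvt_first_vt",
                 "pc1", "pc2", "pc3", "pc4"))
  expect_equal(fit$n, nrow(sim$records) - 1L)
})

test_that("prospective design requires post-inclusion follow-up", {
  rec <- classify_case(toy_cohort()[3:4, ])   # CASE3 and CASE4 only
  expect_error(fit_recurrence(rec, "prospective", covariates = "sex"),
               "CASE1/CASE2")
})

test_that("immediate inclusion with full response equates the designs", {
  sim <- quick_sim(600, seed = 19, gomp_rate = 0, p_respond = 1,
                   incl_mean = 1e-9)
  fp <- fit_recurrence(sim$records, "prospective", dosages = sim$dosages)
  fa <- fit_recurrence(sim$records, "ambispective", dosages = sim$dosages)
  expect_equal(fp$coefficients, fa$coefficients, tolerance = 1e-9)
  expect_equal(fp$nevent, fa$nevent)
})

test_that("weighted fits carry finite non-negative robust SEs", {
  sim <- quick_sim(700, seed = 23, gomp_rate = 1e-4)
  ws <- compute_weights(suppressMessages(fit_death_model(sim$records)),
                        sim$records)
  fit <- fit_recurrence(sim$records, "ambispective", dosages = sim$dosages,
                        weights = ws)
  expect_true(fit$converged)
  rse <- sqrt(diag(fit$var_robust))
  expect_true(all(is.finite(rse) & rse >= 0))
})

test_that("weight-sensitivity replicates collapse when the covariance is zero", {
  sim <- quick_sim(500, seed = 27, gomp_rate = 1e-4)
  dfit <- suppressMessages(fit_death_model(sim$records))
  dfit0 <- dfit
  dfit0$var <- dfit$var * 0
  sens <- mc_weight_sensitivity(sim$records, dfit0, B = 3, seed = 5,
                                covariates = "sex")
  expect_equal(sens$n_failed, 0L)
  for (b in 1:3)
    expect_equal(unname(sens$estimates[b, ]), unname(sens$point),
                 tolerance = 1e-12)
})

test_that("weight-sensitivity is seed-deterministic and spreads with noise", {
  sim <- quick_sim(500, seed = 27, gomp_rate = 1e-4)
  dfit <- suppressMessages(fit_death_model(sim$records))
  s1 <- mc_weight_sensitivity(sim$records, dfit, B = 8, seed = 9,
                              covariates = "sex")
  s2 <- mc_weight_sensitivity(sim$records, dfit, B = 8, seed = 9,
                              covariates = "sex")
  expect_identical(s1$estimates, s2$estimates)
  expect_true(all(s1$summary$q2.5 <= s1$summary$q97.5))
  dfit4 <- dfit
  dfit4$var <- dfit$var * 4
  s4 <- mc_weight_sensitivity(sim$records, dfit4, B = 8, seed = 9,
                              covariates = "sex")
  expect_gt(mean(s4$summary$sd), mean(s1$summary$sd))
})

test_that("non-PSD death covariance falls back with a warning", {
  sim <- quick_sim(500, seed = 27, gomp_rate = 1e-4)
  dfit <- suppressMessages(fit_death_model(sim$records))
  bad <- dfit
  bad$var[1, 2] <- bad$var[2, 1] <- 10   # breaks positive definiteness
  expect_warning(
    mc_weight_sensitivity(sim$records, bad, B = 2, seed = 3,
                          covariates = "sex"),
    "positive definite")
})
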