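test_that("three-subject fit matches the closed-form stationary point", {
  d <- data.frame(time = c(1, 2, 3), event = c(1, 1, 0), z = c(1, 0, 1))
  fit <- wcoxph(survival::Surv(time, event) ~ z, d)
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)), -log(2) / 2, tolerance = 1e-6)
  # independent grid-search oracle over the same partial likelihood
  expect_equal(grid_search_beta(rep(0, 3), d$time, d$event, d$z),
               -log(2) / 2, tolerance = 1e-3)
})

test_that("small fits agree with exhaustive grid search", {
  cases <- list(
    list(entry = c(0, 0, 0.5, 0, 1), exit = c(1, 2, 2.5, 3, 4),
         status = c(1, 1, 0, 1, 1), x = c(1, 0, 1, -1, 0)),
    list(entry = rep(0, 4), exit = c(2, 2, 3, 5),   # tied event times
         status = c(1, 1, 1, 0), x = c(1, 0, 0, 1)),
    list(entry = c(0, 1, 0), exit = c(2, 3, 4), status = c(1, 1, 1),
         x = c(0.5, -0.5, 1), w = c(1, 2, 1)))
  for (cs in cases) {
    fit <- wcox_fit(cs$entry, cs$exit, cs$status, matrix(cs$x), cs$w)
    expect_equal(unname(fit$coefficients),
                 grid_search_beta(cs$entry, cs$exit, cs$status, cs$x, cs$w),
                 tolerance = 1e-3)
  }
})

test_that("all-censored data raise the no-events error", {
  expect_error(wcox_fit(c(0, 0), c(1, 2), c(0, 0), matrix(c(1, 0)), NULL),
               "no events")
})

test_that("non-positive weights are rejected", {
  expect_error(wcox_fit(c(0, 0), c(1, 2), c(1, 0), matrix(c(1, 0)),
                        w = c(1, 0)), "positive")
})

test_that("integer weights reproduce duplicated records bit-identically", {
  set.seed(5)
  n <- 30
  x <- matrix(rnorm(n), dimnames = list(NULL, "z"))
  exit <- rexp(n, 0.3 * exp(0.4 * x))
  status <- rbinom(n, 1, 0.7)
  w <- rep(1, n); w[7] <- 2
  f1 <- wcox_fit(rep(0, n), exit, status, x, w)
  dup <- c(1:7, 7:n)
  f2 <- wcox_fit(rep(0, n + 1), exit[dup], status[dup],
                 x[dup, , drop = FALSE], NULL)
  expect_identical(f1$coefficients, f2$coefficients)
  expect_identical(unname(f1$loglik), unname(f2$loglik))
  expect_identical(f1$baseline$cumhaz, f2$baseline$cumhaz)
})

test_that("engine matches an independent weighted Cox implementation", {
  set.seed(42)
  n <- 300
  x <- cbind(z1 = rbinom(n, 1, 0.4), z2 = rnorm(n))
  entry <- runif(n, 0, 2)
  exit <- entry + rexp(n, 0.2 * exp(x %*% c(0.5, -0.3)))
  status <- as.integer(exit < entry + 5)
  exit <- pmin(exit, entry + 5)
  w <- runif(n, 0.5, 2)
  mine <- wcox_fit(entry, exit, status, x, w)
  ref <- survival::coxph(survival::Surv(entry, exit, status) ~ x,
                         weights = w, ties = "breslow", robust = TRUE,
                         id = seq_len(n))
  expect_equal(unname(mine$coefficients), unname(coef(ref)),
               tolerance = 1e-8)
  expect_equal(unname(mine$var), unname(ref$naive.var), tolerance = 1e-8)
  expect_equal(unname(mine$var_robust), unname(ref$var), tolerance = 1e-8)
  bh <- survival::basehaz(ref, centered = FALSE)
  expect_equal(mine$baseline$cumhaz,
               bh$hazard[match(mine$baseline$time, bh$time)],
               tolerance = 1e-8)
})

test_that("baseline at beta = 0 is the Nelson-Aalen estimator", {
  set.seed(6)
  n <- 60
  entry <- runif(n, 0, 1)
  exit <- entry + rexp(n, 0.5)
  status <- rbinom(n, 1, 0.6)
  status[1] <- 1
  bl <- wcox_breslow(entry, exit, status, matrix(rnorm(n)), rep(1, n), 0)
  na <- nelson_aalen(entry, exit, status)
  expect_equal(bl$time, na$time)
  expect_equal(bl$cumhaz, na$cumhaz, tolerance = 1e-12)
  # doubling all weights leaves the increments unchanged
  bl2 <- wcox_breslow(entry, exit, status, matrix(rnorm(n)), rep(2, n), 0)
  expect_equal(bl2$cumhaz, bl$cumhaz, tolerance = 1e-12)
})

test_that("risk sets honor the half-open left-truncation convention", {
  # B's event at t = 1 must not see A, whose entry is exactly 1
  entry <- c(1, 0)
  exit <- c(2, 1)
  status <- c(0, 1)
  bl <- wcox_breslow(entry, exit, status, matrix(c(0, 0)), c(1, 1), 0)
  expect_equal(bl$cumhaz, 1)   # risk set of size 1: B alone
})

test_that("interval survival follows the step-function formula", {
  fit <- list(coefficients = c(z = log(2)),
              baseline = data.frame(time = 50, hazard = 0.1, cumhaz = 0.1))
  expect_equal(interval_survival(fit, 1, 40, 60), exp(-0.2))
  expect_equal(interval_survival(fit, 1, 55, 55), 1)     # empty interval
  expect_equal(interval_survival(fit, 1, 10, 49), 1)     # before support
  expect_equal(interval_survival(fit, 1, 51, 90), 1)     # after the step
  expect_error(interval_survival(fit, 1, 60, 40), "t_start")
})

test_that("monotone likelihood is reported as non-convergence", {
  # perfect separation: the z = 1 subjects fail first, in order
  d <- data.frame(time = c(1, 2, 3, 4), event = c(1, 1, 0, 0),
                  z = c(1, 1, 0, 0))
  fit <- wcoxph(survival::Surv(time, event) ~ z, d)
  expect_false(fit$converged)
  expect_match(fit$diagnostic, "monotone")
})

test_that("sandwich variance approximates the delete-one jackknife", {
  set.seed(7)
  m <- 150
  z <- rbinom(m, 1, 0.5)
  tt <- rexp(m, 0.2 * exp(0.5 * z))
  st <- rbinom(m, 1, 0.8)
  f <- wcox_fit(rep(0, m), tt, st, matrix(z), NULL, robust = TRUE)
  th <- vapply(seq_len(m), function(i)
    wcox_fit(rep(0, m - 1), tt[-i], st[-i], matrix(z[-i]), NULL)$coefficients,
    numeric(1L))
  vjk <- (m - 1) / m * sum((th - mean(th))^2)
  expect_equal(unname(f$var_robust[1, 1]) / vjk, 1, tolerance = 0.1)
})

test_that("robust and model variances agree on unweighted iid data", {
  set.seed(8)
  m <- 2000
  z <- cbind(a = rbinom(m, 1, 0.5), b = rnorm(m))
  tt <- rexp(m, 0.1 * exp(z %*% c(0.4, -0.2)))
  st <- rbinom(m, 1, 0.85)
  f <- wcox_fit(rep(0, m), tt, st, z, NULL, robust = TRUE)
  expect_equal(diag(f$var_robust) / diag(f$var), c(a = 1, b = 1),
               tolerance = 0.1)
})

test_that("rescaling weights changes neither estimate nor sandwich", {
  set.seed(9)
  m <- 80
  z <- rnorm(m)
  tt <- rexp(m, 0.3 * exp(0.3 * z))
  st <- rbinom(m, 1, 0.8)
  st[1] <- 1
  w <- runif(m, 0.5, 2)
  w <- m * w / sum(w)         # standardized to sum N
  f1 <- wcox_fit(rep(0, m), tt, st, matrix(z), w)
  f2 <- wcox_fit(rep(0, m), tt, st, matrix(z), 3 * w)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-12)
  expect_equal(f1$var_robust, f2$var_robust, tolerance = 1e-10)
})

test_that("log partial likelihood never falls below the null value", {
  set.seed(10)
  for (k in 1:5) {
    m <- 40
    z <- rnorm(m)
    tt <- rexp(m, 0.3 * exp(0.5 * z))
    st <- rbinom(m, 1, 0.7)
    if (!any(st == 1)) st[1] <- 1
    f <- wcox_fit(rep(0, m), tt, st, matrix(z), NULL)
    expect_gte(f$loglik[["final"]], f$loglik[["null"]])
  }
})

test_that("formula interface, methods and JSON serialization work", {
  set.seed(12)
  d <- data.frame(start = runif(50, 0, 1))
  d$stop <- d$start + rexp(50, 0.5)
  d$ev <- rbinom(50, 1, 0.6)
  d$z <- rnorm(50)
  d$grp <- rbinom(50, 1, 0.5)
  d$w <- runif(50, 0.5, 2)
  fit <- wcoxph(survival::Surv(start, stop, ev) ~ z + grp, d, weights = w)
  expect_s3_class(fit, "wcoxph")
  expect_named(coef(fit), c("z", "grp"))
  expect_equal(dim(vcov(fit, "robust")), c(2, 2))
  expect_equal(dim(vcov(fit, "model")), c(2, 2))
  expect_equal(unname(predict(fit, type = "risk")),
               unname(exp(predict(fit, type = "lp"))))
  expect_equal(predict(fit, newdata = d[1:3, ], type = "lp"),
               predict(fit, type = "lp")[1:3])
  expect_equal(dim(residuals(fit, "score")), c(50, 2))
  expect_equal(residuals(fit, "dfbeta"), residuals(fit, "score") %*% fit$var)
  s <- summary(fit)
  expect_true(s$robust)
  expect_equal(s$coefficients[, "hr"], exp(coef(fit)))
  expect_output(print(fit), "events")

  path <- withr::local_tempfile(fileext = ".json")
  write_fit_json(fit, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(unlist(back$coefficients), coef(fit))
  expect_equal(back$baseline$cumhaz, fit$baseline$cumhaz)
  expect_true(back$converged)
})
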