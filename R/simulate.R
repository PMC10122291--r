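#' Configuration of the synthetic ambispective cohort
#'
#' Defaults emulate a middle-aged venous-thrombosis recurrence cohort:
#' haplotype frequencies, sex ratio, age at first VT, provoked/DVT
#' proportions and response rate match the descriptive statistics of such
#' cohorts; the recurrence baseline gives roughly a 30% recurrence
#' fraction within 10 years; mortality is Gompertz on the age scale with
#' hazard ratios of 1.44 (male), 0.42 (provoked) and 0.98 per year of age
#' at first VT; inclusion occurs on average 6 years after the first VT and
#' 76% of contacted subjects respond at recontact.
#'
#' Linear predictors are computed on covariates centred at their
#' theoretical means, so the baseline hazards refer to a
#' population-average covariate profile and the marginal event rates stay
#' interpretable when effect sizes change.
#'
#' @param n_subjects number of subjects drawn (before pre-inclusion death
#'   exclusions).
#' @param seed master RNG seed; per-purpose sub-streams (covariates,
#'   recurrence, death, inclusion, response, vital status) are derived
#'   from it so changing one knob perturbs only its own draws.
#' @param hap_freq named haplotype frequencies (sum to 1).
#' @param p_male,p_provoked,p_dvt,p_respond,p_vital_known Bernoulli rates.
#' @param age_mean,age_sd,age_range age at first VT: Normal truncated to
#'   `age_range`.
#' @param recur_base_rate exponential baseline recurrence hazard per year.
#' @param recur_loghr named true recurrence log-HRs (names among `abo_A1`,
#'   `abo_A2`, `abo_B`, `abo_O2`, `sex`, `provoked_first_vt`, `age10`,
#'   `dvt_first_vt`, `pc1`..`pc4`).
#' @param gomp_rate,gomp_shape Gompertz death hazard
#'   \eqn{b e^{\theta a}} at age a (per year).
#' @param death_loghr named true death log-HRs (names among `sex`,
#'   `provoked_first_vt`, `age_first_vt`, `pc1`..`pc4`).
#' @param post_recur_death_hr multiplier on the death hazard after a
#'   recurrence; 1 (default) keeps death independent of recurrence, values
#'   above 1 create the informative selection the weighting targets.
#' @param incl_mean mean of the exponential delay from first VT to
#'   inclusion (years).
#' @param recontact_mean,recontact_sd recontact offset from inclusion:
#'   Normal truncated below at 0.5 years.
#' @param vital_extra_mean mean extra exponential follow-up for vital
#'   status beyond the recontact date (years).
#' @param admin_end administrative end of follow-up (years since first
#'   VT); censors the recontact date.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 1500L, seed = 1L,
                       hap_freq = c(O1 = 0.498, A1 = 0.335, A2 = 0.059,
                                    B = 0.093, O2 = 0.015),
                       p_male = 0.34,
                       age_mean = 41, age_sd = 15.7, age_range = c(18, 85),
                       p_provoked = 0.66, p_dvt = 0.79,
                       recur_base_rate = 0.04,
                       recur_loghr = c(abo_A1 = log(1.15), abo_A2 = log(1.27),
                                       abo_B = log(1.02), abo_O2 = log(1.19),
                                       sex = log(1.65),
                                       provoked_first_vt = 0,
                                       age10 = log(1.08),
                                       dvt_first_vt = log(1.17)),
                       gomp_rate = 2e-5, gomp_shape = 0.085,
                       death_loghr = c(sex = log(1.44),
                                       provoked_first_vt = log(0.42),
                                       age_first_vt = log(0.98)),
                       post_recur_death_hr = 1,
                       incl_mean = 6,
                       recontact_mean = 9, recontact_sd = 3,
                       p_respond = 0.76,
                       p_vital_known = 0.91, vital_extra_mean = 3,
                       admin_end = Inf) {
  cfg <- list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
              hap_freq = hap_freq, p_male = p_male, age_mean = age_mean,
              age_sd = age_sd, age_range = age_range,
              p_provoked = p_provoked, p_dvt = p_dvt,
              recur_base_rate = recur_base_rate, recur_loghr = recur_loghr,
              gomp_rate = gomp_rate, gomp_shape = gomp_shape,
              death_loghr = death_loghr,
              post_recur_death_hr = post_recur_death_hr,
              incl_mean = incl_mean, recontact_mean = recontact_mean,
              recontact_sd = recontact_sd, p_respond = p_respond,
              p_vital_known = p_vital_known,
              vital_extra_mean = vital_extra_mean, admin_end = admin_end)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_subjects >= 1L)
  if (abs(sum(cfg$hap_freq) - 1) > 1e-8)
    stop("haplotype frequencies must sum to 1")
  if (!setequal(names(cfg$hap_freq), c("O1", "O2", "A1", "A2", "B")))
    stop("hap_freq must name O1, O2, A1, A2, B")
  probs <- c(cfg$p_male, cfg$p_provoked, cfg$p_dvt, cfg$p_respond,
             cfg$p_vital_known)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$recur_base_rate <= 0 || cfg$gomp_rate < 0 || cfg$gomp_shape <= 0 ||
      cfg$incl_mean <= 0)
    stop("hazard and delay parameters must be positive")
  if (cfg$post_recur_death_hr <= 0) stop("post_recur_death_hr must be > 0")
  invisible(cfg)
}

# deterministic per-purpose sub-seeds below 2^31
sub_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + k * 1000003) %% 2147483647)
}

rtruncnorm1 <- function(n, mean, sd, lower, upper) {
  u <- runif(n, pnorm(lower, mean, sd), pnorm(upper, mean, sd))
  qnorm(u, mean, sd)
}

# Gompertz death age from age a0 with proportional multiplier m and a
# hazard jump (x rho) at age a_jump; inverse cumulative-hazard transform.
rgompertz_death <- function(a0, m, b, theta, rho = 1, a_jump = Inf) {
  n <- length(a0)
  e <- rexp(n)
  if (b == 0) return(rep(Inf, n))
  cum <- function(a_from, a_to, mi) (b * mi / theta) *
    (exp(theta * a_to) - exp(theta * a_from))
  inv <- function(a_from, mi, ee) log(exp(theta * a_from) +
                                        theta * ee / (b * mi)) / theta
  out <- numeric(n)
  before <- e <= cum(a0, pmin(a_jump, Inf), m) | !is.finite(a_jump)
  # death before the jump (or no jump)
  out[before] <- inv(a0[before], m[before], e[before])
  if (any(!before)) {
    rest <- (e[!before] - cum(a0[!before], a_jump[!before], m[!before])) / rho
    out[!before] <- inv(a_jump[!before], m[!before], rest)
  }
  out
}

#' Generate a synthetic ambispective cohort
#'
#' Draws covariates and ABO haplotype pairs, latent recurrence times from
#' an exponential proportional-hazards model on the time-since-first-VT
#' scale, and latent death ages from a Gompertz proportional-hazards model
#' on the age scale (optionally with an elevated hazard after recurrence).
#' Subjects dead before their inclusion date are excluded - the
#' survivorship selection the weighting corrects - and survivors are
#' classified into the four case types through the response draw and
#' recontact timing. Recurrences can only be observed while the subject is
#' alive, and post-inclusion recurrences only for responders alive at
#' recontact.
#'
#' @param cfg a [sim_config()].
#' @return a list with elements `records` (observed cohort data frame,
#'   classified), `dosages` (tag dosages consistent with the drawn
#'   diplotypes, rsID columns), `truth` (latent times and linear
#'   predictors for all drawn subjects, including the pre-inclusion
#'   deaths, with `included` and `case` columns) and `config`.
#' @export
generate_cohort <- function(cfg) {
  validate_sim_config(cfg)
  n <- cfg$n_subjects

  # --- covariates -----------------------------------------------------
  set.seed(sub_seed(cfg$seed, 1L))
  sex <- rbinom(n, 1L, cfg$p_male)
  age <- rtruncnorm1(n, cfg$age_mean, cfg$age_sd,
                     cfg$age_range[1], cfg$age_range[2])
  provoked <- rbinom(n, 1L, cfg$p_provoked)
  dvt <- rbinom(n, 1L, cfg$p_dvt)
  pcs <- matrix(rnorm(4L * n), n, 4L, dimnames = list(NULL, paste0("pc", 1:4)))
  haps <- names(cfg$hap_freq)
  h1 <- sample(haps, n, replace = TRUE, prob = cfg$hap_freq)
  h2 <- sample(haps, n, replace = TRUE, prob = cfg$hap_freq)
  hapcount <- sapply(haps, function(h) (h1 == h) + (h2 == h))
  colnames(hapcount) <- haps

  covar <- data.frame(sex = sex, age_first_vt = age, age10 = age / 10,
                      provoked_first_vt = provoked, dvt_first_vt = dvt,
                      abo_A1 = hapcount[, "A1"], abo_A2 = hapcount[, "A2"],
                      abo_B = hapcount[, "B"], abo_O2 = hapcount[, "O2"])
  covar <- cbind(covar, pcs)
  # theoretical covariate means, for centring the linear predictors
  mu <- c(sex = cfg$p_male, age_first_vt = cfg$age_mean,
          age10 = cfg$age_mean / 10, provoked_first_vt = cfg$p_provoked,
          dvt_first_vt = cfg$p_dvt,
          abo_A1 = 2 * cfg$hap_freq[["A1"]], abo_A2 = 2 * cfg$hap_freq[["A2"]],
          abo_B = 2 * cfg$hap_freq[["B"]], abo_O2 = 2 * cfg$hap_freq[["O2"]],
          pc1 = 0, pc2 = 0, pc3 = 0, pc4 = 0)
  lp_of <- function(loghr) {
    if (length(loghr) == 0L) return(rep(0, n))
    bad <- setdiff(names(loghr), names(mu))
    if (length(bad)) stop("unknown covariate(s) in log-HR vector: ",
                          paste(bad, collapse = ", "))
    zc <- sweep(as.matrix(covar[, names(loghr), drop = FALSE]), 2L,
                mu[names(loghr)])
    drop(zc %*% loghr)
  }

  # --- latent recurrence ---------------------------------------------
  set.seed(sub_seed(cfg$seed, 2L))
  lp_r <- lp_of(cfg$recur_loghr)
  t_recur_latent <- rexp(n, rate = cfg$recur_base_rate * exp(lp_r))

  # --- latent death ---------------------------------------------------
  set.seed(sub_seed(cfg$seed, 3L))
  lp_d <- lp_of(cfg$death_loghr)
  a_jump <- if (cfg$post_recur_death_hr != 1) age + t_recur_latent else
    rep(Inf, n)
  a_death <- rgompertz_death(age, exp(lp_d), cfg$gomp_rate, cfg$gomp_shape,
                             rho = cfg$post_recur_death_hr, a_jump = a_jump)
  t_death <- a_death - age   # years since first VT

  # --- inclusion ------------------------------------------------------
  set.seed(sub_seed(cfg$seed, 4L))
  t_incl <- rexp(n, rate = 1 / cfg$incl_mean)
  included <- t_death > t_incl

  # --- recontact & response ------------------------------------------
  set.seed(sub_seed(cfg$seed, 5L))
  offset <- rtruncnorm1(n, cfg$recontact_mean, cfg$recontact_sd, 0.5, Inf)
  t_recontact <- pmin(t_incl + offset, cfg$admin_end)
  respond_draw <- rbinom(n, 1L, cfg$p_respond)
  alive_at_recontact <- t_death > t_recontact

  # --- vital status ---------------------------------------------------
  set.seed(sub_seed(cfg$seed, 6L))
  vital_known <- rbinom(n, 1L, cfg$p_vital_known) == 1L
  t_vs_end <- t_recontact + rexp(n, rate = 1 / cfg$vital_extra_mean)

  # recurrence can only happen in life
  recurred <- t_recur_latent < t_death
  pre_incl_rec <- recurred & t_recur_latent < t_incl
  responded <- respond_draw == 1L & alive_at_recontact
  post_rec_obs <- !pre_incl_rec & responded & recurred &
    t_recur_latent <= t_recontact

  case <- rep(NA_character_, n)
  case[included & pre_incl_rec] <- "CASE4"
  case[included & !pre_incl_rec & !responded] <- "CASE3"
  case[included & post_rec_obs] <- "CASE2"
  case[included & !pre_incl_rec & responded & !post_rec_obs] <- "CASE1"

  rec_obs <- case %in% c("CASE2", "CASE4")
  t_collection <- ifelse(case %in% c("CASE1", "CASE2"), t_recontact, t_incl)
  died <- t_death <= t_vs_end
  vital_status <- ifelse(!vital_known, "unknown",
                         ifelse(died, "dead", "alive"))
  t_last_vital <- ifelse(vital_known, pmin(t_death, t_vs_end), NA_real_)

  records <- data.frame(
    subject_id = paste0("S", formatC(seq_len(n), width = nchar(n), flag = "0")),
    sex = sex, age_first_vt = age, provoked_first_vt = provoked,
    dvt_first_vt = dvt, pcs,
    t_inclusion = t_incl,
    recurrence_observed = as.integer(rec_obs),
    t_recurrence = ifelse(rec_obs, t_recur_latent, NA_real_),
    t_collection = t_collection,
    responded_recontact = as.integer(responded),
    vital_status = vital_status,
    t_last_vital = t_last_vital,
    stringsAsFactors = FALSE)

  dosages <- data.frame(subject_id = records$subject_id,
                        stringsAsFactors = FALSE)
  for (h in c("O1", "O2", "A1", "A2", "B"))
    dosages[[abo_tags()[[h]]]] <- as.integer(hapcount[, h])

  truth <- data.frame(
    subject_id = records$subject_id,
    t_recurrence_latent = t_recur_latent,
    age_death_latent = a_death,
    lp_recurrence = lp_r, lp_death = lp_d,
    included = included, case = case,
    stringsAsFactors = FALSE)

  obs <- included
  records <- classify_case(records[obs, , drop = FALSE])
  stopifnot(identical(as.character(records$case), case[obs]))
  list(records = records, dosages = dosages[obs, , drop = FALSE],
       truth = truth, config = cfg)
}

#' Bias experiment: naive versus weighted estimators
#'
#' Replicated simulation comparing three estimators of the recurrence
#' log-HRs: the naive prospective fit (post-inclusion events only, delayed
#' entry), the naive ambispective fit (all events, unweighted) and the
#' weighted ambispective fit (inverse-survival-probability weights from
#' the fitted death model, robust variance). For each estimator and
#' coefficient the mean bias, empirical SE, mean reported SE and 95% CI
#' coverage are tabulated.
#'
#' @param cfg a [sim_config()]; its true log-HRs are the estimands.
#' @param n_reps number of replicates (>= 2).
#' @param seed seed governing the per-replicate sub-seeds.
#' @param use_abo include the ABO additive coding in the fitted models?
#' @param file optional path: when given, the summary table is also
#'   written as CSV.
#' @return an object of class `bias_experiment`: `summary` (data frame
#'   `estimator`, `term`, `true`, `mean_est`, `bias`, `emp_se`, `mean_se`,
#'   `coverage`, `n_ok`), `convergence_rate`, `n_reps`, `seed`.
#' @export
bias_experiment <- function(cfg, n_reps = 50L, seed = 1L, use_abo = TRUE,
                            file = NULL) {
  stopifnot(n_reps >= 2L)
  estimators <- c("naive_prospective", "naive_ambispective",
                  "weighted_ambispective")
  res <- list()
  n_fail <- 0L
  for (rr in seq_len(n_reps)) {
    cfg_r <- cfg
    cfg_r$seed <- sub_seed(seed, 100L + rr)
    sim <- generate_cohort(cfg_r)
    dos <- if (use_abo) sim$dosages else NULL
    fits <- tryCatch({
      w <- suppressWarnings(compute_weights(
        suppressMessages(fit_death_model(sim$records)), sim$records))
      list(
        naive_prospective =
          fit_recurrence(sim$records, "prospective", dosages = dos),
        naive_ambispective =
          fit_recurrence(sim$records, "ambispective", dosages = dos),
        weighted_ambispective =
          fit_recurrence(sim$records, "ambispective", dosages = dos,
                         weights = w))
    }, error = function(e) NULL)
    if (is.null(fits) || !all(vapply(fits, function(f) f$converged,
                                     logical(1L)))) {
      n_fail <- n_fail + 1L
      next
    }
    for (est in estimators) {
      f <- fits[[est]]
      se <- sqrt(diag(if (!is.null(f$var_robust)) f$var_robust else f$var))
      res[[length(res) + 1L]] <- data.frame(
        rep = rr, estimator = est, term = names(f$coefficients),
        est = unname(f$coefficients), se = unname(se),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) stop("all replicates failed")
  raw <- do.call(rbind, res)

  true_of <- function(term) {
    lh <- cfg$recur_loghr
    if (term %in% names(lh)) lh[[term]] else 0
  }
  raw$true <- vapply(raw$term, true_of, numeric(1L))
  raw$cover <- abs(raw$est - raw$true) <= qnorm(0.975) * raw$se

  agg <- do.call(rbind, lapply(split(raw, list(raw$estimator, raw$term),
                                     drop = TRUE), function(g) {
    data.frame(estimator = g$estimator[1L], term = g$term[1L],
               true = g$true[1L], mean_est = mean(g$est),
               bias = mean(g$est) - g$true[1L],
               emp_se = sd(g$est), mean_se = mean(g$se),
               coverage = mean(g$cover), n_ok = nrow(g),
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  agg <- agg[order(agg$term, agg$estimator), ]
  out <- structure(list(summary = agg,
                        convergence_rate = 1 - n_fail / n_reps,
                        n_reps = as.integer(n_reps), seed = as.integer(seed),
                        raw = raw),
                   class = "bias_experiment")
  if (!is.null(file)) write.csv(agg, file, row.names = FALSE)
  out
}

#' @export
print.bias_experiment <- function(x, digits = 4L, ...) {
  cat("Bias experiment over", x$n_reps, "replicates (seed", x$seed, "),",
      sprintf("convergence rate %.2f", x$convergence_rate), "\n\n")
  tab <- x$summary
  num <- vapply(tab, is.numeric, logical(1L))
  tab[num] <- round(tab[num], digits)
  print(tab, row.names = FALSE)
  invisible(x)
}
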