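# Clinical adjustment set of the recurrence model; age is reported per
# 10-year increase.
recurrence_clinical <- function() {
  c("sex", "provoked_first_vt", "age10", "dvt_first_vt",
    "pc1", "pc2", "pc3", "pc4")
}

#' Fit the recurrence model on a prospective or ambispective sample
#'
#' Builds the at-risk intervals for the requested design (time-scale: years
#' since the first VT; the prospective design uses delayed entry at
#' inclusion) and fits a Cox model of first recurrence. Covariates are the
#' additive ABO haplotype counts (A1, A2, B, O2; O1 reference) when dosage
#' data are supplied, plus sex, provoked character of the first VT, age at
#' first VT (per 10 years), type of the first VT (DVT vs PE) and the first
#' four principal components. When a [compute_weights()] weight set is
#' supplied the fit is weighted and the robust sandwich covariance is
#' attached.
#'
#' @param records validated, classified cohort data frame.
#' @param design `"ambispective"` or `"prospective"`.
#' @param dosages optional dosage data frame from [read_dosages()] (or with
#'   haplotype-labelled columns); subjects whose diplotype cannot be
#'   resolved are excluded with a message.
#' @param weights optional `weight_set`; matched to subjects by
#'   `subject_id`.
#' @param covariates character vector of clinical covariate names; the
#'   default is the standard adjustment set.
#' @return a `wcoxph` fit with attributes `design` and `n_excluded_abo`.
#' @export
fit_recurrence <- function(records,
                           design = c("ambispective", "prospective"),
                           dosages = NULL, weights = NULL,
                           covariates = recurrence_clinical()) {
  design <- match.arg(design)
  if (is.null(records$case)) records <- classify_case(records)

  n_excluded_abo <- 0L
  if (!is.null(dosages)) {
    dip <- infer_diplotype(dosages[, setdiff(names(dosages), "subject_id"),
                                   drop = FALSE])
    unresolved <- dosages$subject_id[is.na(dip)]
    n_excluded_abo <- length(unresolved)
    if (n_excluded_abo > 0L)
      message(n_excluded_abo,
              " subject(s) with unresolved ABO diplotype excluded")
    resolved <- !is.na(dip)
    coding <- as.data.frame(abo_additive(dip[resolved]))
    names(coding) <- c("abo_A1", "abo_A2", "abo_B", "abo_O2")
    coding$subject_id <- dosages$subject_id[resolved]
    records <- merge(records, coding, by = "subject_id")
    if (nrow(records) == 0L) stop("no subjects with resolved ABO diplotypes")
  }

  records$age10 <- records$age_first_vt / 10
  if (design == "prospective" &&
      !any(records$case %in% c("CASE1", "CASE2")))
    stop("prospective design requires CASE1/CASE2 subjects")
  iv <- make_intervals(records, design)
  idx <- match(iv$subject_id, records$subject_id)
  xcols <- c(if (!is.null(dosages)) c("abo_A1", "abo_A2", "abo_B", "abo_O2"),
             covariates)
  x <- as.matrix(records[idx, xcols, drop = FALSE])

  w <- NULL
  weighted <- !is.null(weights)
  if (weighted) {
    w <- weights$w[match(iv$subject_id, weights$subject_id)]
    if (anyNA(w)) stop("weights missing for some subjects in the design")
  }
  fit <- wcox_fit(iv$entry, iv$exit, iv$event, x, w, robust = weighted)
  fit$call <- match.call()
  fit$weighted <- weighted
  class(fit) <- "wcoxph"
  attr(fit, "design") <- design
  attr(fit, "n_excluded_abo") <- n_excluded_abo
  fit
}

#' Fixed-effect meta-analysis of hazard ratios
#'
#' Combines study-level hazard ratios on the log scale with
#' inverse-variance fixed-effect weights. Each study's standard error is
#' recovered from its 95% confidence interval as
#' \eqn{SE = (\ln \mathrm{hi} - \ln \mathrm{lo}) / (2 \times 1.959964)};
#' the combined log-HR is the weight-averaged log-HR, its SE is
#' \eqn{(\sum w)^{-1/2}}, and the p-value is two-sided normal.
#'
#' @param hr vector of study hazard ratios (or a data frame with columns
#'   `hr`, `lo`, `hi` and optionally `study`).
#' @param lo,hi 95% confidence bounds, `0 < lo <= hr <= hi`.
#' @param studies optional study labels.
#' @return an object of class `meta_fixed`: combined `log_hr`, `se`, `hr`,
#'   `ci` (length 2), `z`, `p`, plus the per-study input table.
#' @export
meta_fixed <- function(hr, lo = NULL, hi = NULL, studies = NULL) {
  if (is.data.frame(hr)) {
    df <- hr
    studies <- if (!is.null(df$study)) df$study
    hr <- df$hr; lo <- df$lo; hi <- df$hi
  }
  stopifnot(length(hr) >= 1L, length(lo) == length(hr),
            length(hi) == length(hr))
  if (any(lo <= 0) || any(lo > hr) || any(hr > hi))
    stop("confidence bounds must satisfy 0 < lo <= hr <= hi")
  if (any(lo == hi)) stop("degenerate confidence interval (lo == hi)")
  if (is.null(studies)) studies <- paste0("study", seq_along(hr))
  q <- qnorm(0.975)
  yi <- log(hr)
  sei <- (log(hi) - log(lo)) / (2 * q)
  wi <- 1 / sei^2
  log_hr <- sum(wi * yi) / sum(wi)
  se <- 1 / sqrt(sum(wi))
  z <- log_hr / se
  structure(list(
    studies = data.frame(study = studies, hr = hr, lo = lo, hi = hi,
                         log_hr = yi, se = sei, stringsAsFactors = FALSE),
    log_hr = log_hr, se = se, hr = exp(log_hr),
    ci = exp(log_hr + c(-1, 1) * q * se),
    z = z, p = 2 * pnorm(-abs(z))), class = "meta_fixed")
}

#' @export
print.meta_fixed <- function(x, digits = 3L, ...) {
  cat("Fixed-effect (inverse-variance) meta-analysis of",
      nrow(x$studies), "studies\n\n")
  tab <- x$studies
  tab$hr <- round(tab$hr, digits); tab$lo <- round(tab$lo, digits)
  tab$hi <- round(tab$hi, digits)
  print(tab[, c("study", "hr", "lo", "hi")], row.names = FALSE)
  cat(sprintf("\nCombined HR %.2f (95%% CI %.2f-%.2f), z = %.2f, p = %.2g\n",
              x$hr, x$ci[1], x$ci[2], x$z, x$p))
  invisible(x)
}

# multivariate normal draw with nearest-PSD fallback for the covariance
rmvn_psd <- function(n, mu, sigma) {
  p <- length(mu)
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) {
    # semi-definite (e.g. zero) covariances are fine; warn only when
    # genuinely indefinite before projecting to the nearest PSD matrix
    eg <- eigen(sigma, symmetric = TRUE)
    tol <- 1e-12 * max(abs(eg$values), 1e-300)
    if (min(eg$values) < -tol)
      warning("covariance not positive definite; projecting to nearest PSD")
    ev <- pmax(eg$values, 0)
    ch <- t(eg$vectors %*% (t(eg$vectors) * sqrt(ev)))
  }
  matrix(rnorm(n * p), n, p) %*% ch + matrix(mu, n, p, byrow = TRUE)
}

#' Monte-Carlo sensitivity of the weighted fit to weight uncertainty
#'
#' The weights are estimated, not known: they inherit the sampling
#' uncertainty of the death model. For each of B replicates, a coefficient
#' vector is drawn from a multivariate normal centred at the death-model
#' estimate with its model-based covariance, the Breslow baseline is
#' recomputed at the drawn coefficients, survival probabilities and
#' weights are recomputed, and the recurrence model is refitted. The
#' spread of the replicate estimates measures how much the conclusions
#' depend on the precision of the weights.
#'
#' @param records validated, classified cohort data frame.
#' @param death_fit converged `wcoxph` from [fit_death_model()].
#' @param B number of replicates (>= 1).
#' @param seed RNG seed (integer).
#' @param dosages,design,covariates passed to [fit_recurrence()].
#' @return an object of class `wc_sensitivity`: `B`, `seed`, `estimates`
#'   (B x p matrix of replicate log-HRs), `summary` (per-coefficient mean,
#'   SD, 2.5/97.5 percentiles), `point` (the point-fit coefficients) and
#'   `n_failed`.
#' @export
mc_weight_sensitivity <- function(records, death_fit, B = 100L, seed = 1L,
                                  dosages = NULL,
                                  design = "ambispective",
                                  covariates = recurrence_clinical()) {
  stopifnot(B >= 1L)
  if (!isTRUE(death_fit$converged)) stop("death model did not converge")
  if (is.null(records$case)) records <- classify_case(records)
  dd <- death_fit$data
  set.seed(as.integer(seed))
  draws <- rmvn_psd(B, death_fit$coefficients, death_fit$var)

  point <- fit_recurrence(records, design = design, dosages = dosages,
                          weights = compute_weights(death_fit, records),
                          covariates = covariates)
  p <- length(point$coefficients)
  est <- matrix(NA_real_, B, p, dimnames = list(NULL, names(point$coefficients)))
  n_failed <- 0L
  for (bidx in seq_len(B)) {
    beta_b <- draws[bidx, ]
    rep_fit <- tryCatch({
      pseudo <- list(coefficients = setNames(beta_b,
                                             names(death_fit$coefficients)),
                     baseline = wcox_breslow(dd$entry, dd$exit, dd$status,
                                             dd$x, dd$w, beta_b),
                     converged = TRUE)
      ws <- suppressWarnings(compute_weights(pseudo, records))
      fit_recurrence(records, design = design, dosages = dosages,
                     weights = ws, covariates = covariates)
    }, error = function(e) NULL)
    if (is.null(rep_fit) || !rep_fit$converged) n_failed <- n_failed + 1L
    else est[bidx, ] <- rep_fit$coefficients
  }
  ok <- stats::complete.cases(est)
  summ <- data.frame(
    term = colnames(est),
    mean = colMeans(est[ok, , drop = FALSE]),
    sd = apply(est[ok, , drop = FALSE], 2L, sd),
    q2.5 = apply(est[ok, , drop = FALSE], 2L, quantile, probs = 0.025),
    q97.5 = apply(est[ok, , drop = FALSE], 2L, quantile, probs = 0.975),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(B = as.integer(B), seed = as.integer(seed),
                 estimates = est, summary = summ,
                 point = point$coefficients, n_failed = n_failed),
            class = "wc_sensitivity")
}

#' @export
print.wc_sensitivity <- function(x, digits = 4L, ...) {
  cat("Monte-Carlo weight-sensitivity analysis, B =", x$B,
      "replicates (seed", x$seed, ")\n")
  if (x$n_failed) cat(x$n_failed, "replicate(s) failed\n")
  tab <- x$summary
  tab$point <- x$point[tab$term]
  tab[-1] <- round(tab[-1], digits)
  print(tab, row.names = FALSE)
  invisible(x)
}
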