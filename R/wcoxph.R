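#' Control parameters for the weighted Cox fitter
#'
#' @param eps relative log-partial-likelihood convergence tolerance.
#' @param beta_tol max-norm coefficient-change tolerance.
#' @param max_iter maximum Newton-Raphson iterations.
#' @param max_halving maximum step-halvings per iteration.
#' @param beta_max divergence guard: any |beta_j| beyond this during
#'   iteration is reported as non-convergence (monotone likelihood).
#' @return a list of class `wcox_control`.
#' @export
wcox_control <- function(eps = 1e-9, beta_tol = 1e-8, max_iter = 50L,
                         max_halving = 10L, beta_max = 20) {
  stopifnot(eps > 0, beta_tol > 0, max_iter >= 1, max_halving >= 0, beta_max > 0)
  structure(list(eps = eps, beta_tol = beta_tol, max_iter = as.integer(max_iter),
                 max_halving = as.integer(max_halving), beta_max = beta_max),
            class = "wcox_control")
}

# Windowed risk-set sums by the difference-array trick.
# Subject i covers event-time indices (a_i, b_i]; returns K x m matrix whose
# k-th row is the sum of v over subjects at risk at event time k.
windowed_sums <- function(v, a, b, K) {
  v <- as.matrix(v)
  m <- ncol(v)
  acc <- matrix(0, K, m)
  use <- b > a
  if (any(use)) {
    ra <- rowsum(v[use, , drop = FALSE], a[use] + 1L)
    ia <- as.integer(rownames(ra))
    acc[ia, ] <- acc[ia, ] + ra
    sub <- use & (b + 1L <= K)
    if (any(sub)) {
      rb <- rowsum(v[sub, , drop = FALSE], b[sub] + 1L)
      ib <- as.integer(rownames(rb))
      acc[ib, ] <- acc[ib, ] - rb
    }
  }
  if (K == 1L) acc else apply(acc, 2L, cumsum)
}

# flattened symmetric index pairs for p columns -> p(p+1)/2 products
sym_pairs <- function(p) {
  idx <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  idx[order(idx[, 2L], idx[, 1L]), , drop = FALSE]
}

unflatten_sym <- function(v, p, pairs) {
  m <- matrix(0, p, p)
  m[pairs] <- v
  m[pairs[, c(2L, 1L), drop = FALSE]] <- v
  m
}

# Core weighted Cox fitter on counting-process data.
# Risk-set convention is half-open (entry, exit]: a subject is at risk for an
# event at time t iff entry < t <= exit. Breslow tie handling throughout.
wcox_fit <- function(entry, exit, status, x, w = NULL,
                     control = wcox_control(), robust = TRUE) {
  x <- as.matrix(x)
  n <- nrow(x)
  p <- ncol(x)
  if (is.null(w)) w <- rep(1, n)
  stopifnot(length(entry) == n, length(exit) == n, length(status) == n,
            length(w) == n)
  if (any(!is.finite(entry)) || any(!is.finite(exit)) || any(!is.finite(x)))
    stop("non-finite values in survival data")
  if (any(w <= 0)) stop("weights must be strictly positive")
  if (any(exit <= entry)) stop("all intervals must satisfy entry < exit")
  status <- as.integer(status != 0)
  if (sum(status) == 0L) stop("no events: cannot fit a Cox model")

  tau <- sort(unique(exit[status == 1L]))
  K <- length(tau)
  a <- findInterval(entry, tau)   # event times <= entry are excluded
  b <- findInterval(exit, tau)    # event times <= exit are included
  evt <- status == 1L
  ki <- match(exit[evt], tau)     # event-time index of each event row

  d <- numeric(K)                 # weighted number of events at each tau
  dtab <- rowsum(w[evt], ki)
  d[as.integer(rownames(dtab))] <- dtab
  ev_x_sum <- colSums(w[evt] * x[evt, , drop = FALSE])
  pairs <- sym_pairs(p)
  xx <- x[, pairs[, 1L], drop = FALSE] * x[, pairs[, 2L], drop = FALSE]

  risk_quantities <- function(beta) {
    eta <- drop(x %*% beta)
    r <- w * exp(eta)
    S0 <- drop(windowed_sums(r, a, b, K))
    S1 <- windowed_sums(r * x, a, b, K)
    # overflow/underflow of exp(eta) along a wild trial step makes S0
    # unusable; flagged rather than fatal so step-halving can recover
    list(eta = eta, r = r, S0 = S0, S1 = S1,
         ok = all(is.finite(S0)) && all(S0 > 0) && all(is.finite(S1)))
  }
  loglik_of <- function(beta, rq) {
    if (!rq$ok) return(-Inf)
    sum(w[evt] * rq$eta[evt]) - sum(d * log(rq$S0))
  }

  beta <- rep(0, p)
  rq <- risk_quantities(beta)
  if (!rq$ok) stop("empty risk set at an event time: corrupted input")
  ll <- loglik_of(beta, rq)
  ll0 <- ll
  converged <- FALSE
  diagnostic <- NULL
  iter <- 0L

  for (iter in seq_len(control$max_iter)) {
    xbar <- rq$S1 / rq$S0
    grad <- ev_x_sum - colSums(d * xbar)
    S2 <- windowed_sums(rq$r * xx, a, b, K)
    info_fl <- colSums(d * (S2 / rq$S0 -
                              xbar[, pairs[, 1L], drop = FALSE] *
                              xbar[, pairs[, 2L], drop = FALSE]))
    info <- unflatten_sym(info_fl, p, pairs)
    step <- tryCatch(solve(info, grad),
                     error = function(e) stop("singular information matrix"))
    fac <- 1
    repeat {
      beta_new <- beta + fac * step
      rq_new <- risk_quantities(beta_new)
      ll_new <- loglik_of(beta_new, rq_new)
      if (ll_new >= ll - 1e-12 || fac <= 2^(-control$max_halving)) break
      fac <- fac / 2
    }
    if (!rq_new$ok || !is.finite(ll_new)) {
      diagnostic <- "numerical overflow in the linear predictor"
      break
    }
    delta <- beta_new - beta
    beta <- beta_new
    rq <- rq_new
    if (any(abs(beta) > control$beta_max)) {
      diagnostic <- paste0("coefficient exceeded ", control$beta_max,
                           " in absolute value: likely monotone likelihood")
      ll <- ll_new
      break
    }
    if (abs(ll_new - ll) < control$eps * (abs(ll) + control$eps) ||
        max(abs(delta)) < control$beta_tol) {
      converged <- TRUE
      ll <- ll_new
      break
    }
    ll <- ll_new
  }
  if (!converged && is.null(diagnostic))
    diagnostic <- "maximum number of iterations reached"

  # final quantities at beta-hat
  xbar <- rq$S1 / rq$S0
  S2 <- windowed_sums(rq$r * xx, a, b, K)
  info_fl <- colSums(d * (S2 / rq$S0 -
                            xbar[, pairs[, 1L], drop = FALSE] *
                            xbar[, pairs[, 2L], drop = FALSE]))
  info <- unflatten_sym(info_fl, p, pairs)
  var_model <- solve(info)

  dL <- d / rq$S0                 # Breslow baseline hazard increments
  baseline <- data.frame(time = tau, hazard = dL, cumhaz = cumsum(dL))

  var_robust <- NULL
  resid_score <- NULL
  if (robust) {
    g0 <- c(0, cumsum(dL))
    g1 <- rbind(0, apply(dL * xbar, 2L, cumsum))
    if (K == 1L) g1 <- rbind(0, matrix(dL * xbar, 1L))
    dG0 <- g0[b + 1L] - g0[a + 1L]
    dG1 <- g1[b + 1L, , drop = FALSE] - g1[a + 1L, , drop = FALSE]
    U <- -(exp(rq$eta) * (dG0 * x - dG1))
    U[evt, ] <- U[evt, ] + (x[evt, , drop = FALSE] - xbar[ki, , drop = FALSE])
    U <- U * w
    var_robust <- var_model %*% crossprod(U) %*% var_model
    resid_score <- U
  }

  dimnames(var_model) <- list(colnames(x), colnames(x))
  if (!is.null(var_robust)) dimnames(var_robust) <- dimnames(var_model)
  names(beta) <- colnames(x)

  list(coefficients = beta,
       var = var_model,
       var_robust = var_robust,
       info = info,
       baseline = baseline,
       loglik = c(null = ll0, final = ll),
       iter = iter,
       converged = converged,
       diagnostic = diagnostic,
       n = n,
       nevent = sum(status),
       resid_score = resid_score,
       data = list(entry = entry, exit = exit, status = status,
                   x = x, w = w))
}

# Breslow baseline hazard at an arbitrary coefficient vector (no refit);
# used by the Monte-Carlo weight-sensitivity analysis.
wcox_breslow <- function(entry, exit, status, x, w, beta) {
  x <- as.matrix(x)
  status <- as.integer(status != 0)
  tau <- sort(unique(exit[status == 1L]))
  K <- length(tau)
  a <- findInterval(entry, tau)
  b <- findInterval(exit, tau)
  evt <- status == 1L
  ki <- match(exit[evt], tau)
  d <- numeric(K)
  dtab <- rowsum(w[evt], ki)
  d[as.integer(rownames(dtab))] <- dtab
  r <- w * exp(drop(x %*% beta))
  S0 <- drop(windowed_sums(r, a, b, K))
  dL <- d / S0
  data.frame(time = tau, hazard = dL, cumhaz = cumsum(dL))
}

#' Weighted Cox proportional-hazards model with left truncation
#'
#' Fits the Cox model \eqn{\lambda(t, Z) = \lambda_0(t) \exp(\beta^\top Z)} by
#' maximising the weighted Breslow partial likelihood with Newton-Raphson.
#' Counting-process responses `Surv(entry, exit, event)` give delayed entry
#' (left truncation); the risk-set convention is half-open `(entry, exit]`.
#' When weights are supplied, a robust sandwich covariance built from
#' per-subject weighted score residuals is attached, accounting for the
#' correlation the weights induce.
#'
#' @param formula a formula with a [survival::Surv()] response, either
#'   `Surv(time, event)` or counting-process `Surv(entry, exit, event)`.
#' @param data a data frame holding the variables.
#' @param weights optional strictly positive case weights (evaluated in
#'   `data`, as in [stats::lm()]).
#' @param robust compute the sandwich covariance? Defaults to `TRUE` when
#'   weights are supplied, `FALSE` otherwise.
#' @param control a [wcox_control()] list.
#' @return an object of class `wcoxph` with components `coefficients`,
#'   `var` (inverse observed information), `var_robust` (sandwich, or `NULL`),
#'   `baseline` (Breslow baseline hazard step function as a data frame with
#'   columns `time`, `hazard`, `cumhaz`), `loglik`, `n`, `nevent`,
#'   `converged`, `iter`.
#' @examples
#' d <- data.frame(time = c(1, 2, 3), event = c(1, 1, 0), z = c(1, 0, 1))
#' fit <- wcoxph(survival::Surv(time, event) ~ z, d)
#' coef(fit)  # -log(2)/2: closed-form stationary point for this toy data
#' @seealso [interval_survival()], [baseline_cumhaz()], [fit_recurrence()]
#' @export
wcoxph <- function(formula, data, weights = NULL, robust = NULL,
                   control = wcox_control()) {
  cl <- match.call()
  mf <- match.call(expand.dots = FALSE)
  m <- match(c("formula", "data", "weights"), names(mf), 0L)
  mf <- mf[c(1L, m)]
  mf$drop.unused.levels <- TRUE
  mf[[1L]] <- quote(stats::model.frame)
  mf <- eval(mf, parent.frame())
  y <- stats::model.response(mf)
  if (!inherits(y, "Surv"))
    stop("the response must be a survival::Surv object")
  w <- stats::model.weights(mf)
  has_weights <- !is.null(w)
  if (is.null(robust)) robust <- has_weights
  mt <- attr(mf, "terms")
  X <- stats::model.matrix(mt, mf)
  icpt <- match("(Intercept)", colnames(X), 0L)
  if (icpt > 0L) X <- X[, -icpt, drop = FALSE]
  if (ncol(X) == 0L) stop("at least one covariate is required")

  type <- attr(y, "type")
  if (type == "right") {
    entry <- rep(0, nrow(X))
    exit <- y[, "time"]
    status <- y[, "status"]
  } else if (type == "counting") {
    entry <- y[, "start"]
    exit <- y[, "stop"]
    status <- y[, "status"]
  } else stop("unsupported Surv type: ", type)

  fit <- wcox_fit(entry, exit, status, X, w, control = control, robust = robust)
  fit$call <- cl
  fit$terms <- mt
  fit$weighted <- has_weights
  class(fit) <- "wcoxph"
  fit
}

#' @export
print.wcoxph <- function(x, digits = max(3L, getOption("digits") - 3L), ...) {
  if (!is.null(x$call)) {
    cat("Call:\n")
    print(x$call)
    cat("\n")
  }
  se <- sqrt(diag(if (!is.null(x$var_robust)) x$var_robust else x$var))
  tab <- cbind(coef = x$coefficients, `exp(coef)` = exp(x$coefficients),
               se = se)
  print(round(tab, digits))
  cat("\nn =", x$n, ", events =", x$nevent,
      if (!is.null(x$var_robust)) "(robust se)" else "(model-based se)", "\n")
  if (!x$converged)
    cat("WARNING: fit did not converge:", x$diagnostic, "\n")
  invisible(x)
}

#' @export
coef.wcoxph <- function(object, ...) object$coefficients

#' Covariance matrix of a weighted Cox fit
#'
#' @param object a `wcoxph` fit.
#' @param type `"robust"` for the sandwich estimator (default when
#'   available), `"model"` for the inverse observed information.
#' @param ... unused.
#' @export
vcov.wcoxph <- function(object,
                        type = c(if (!is.null(object$var_robust)) "robust",
                                 "model"), ...) {
  type <- match.arg(type, c("robust", "model"))
  if (type == "robust") {
    if (is.null(object$var_robust))
      stop("no robust covariance stored; refit with robust = TRUE")
    object$var_robust
  } else object$var
}

#' @export
logLik.wcoxph <- function(object, ...) {
  structure(object$loglik[["final"]], df = length(object$coefficients),
            class = "logLik")
}

#' @export
residuals.wcoxph <- function(object, type = c("score", "dfbeta"), ...) {
  type <- match.arg(type)
  U <- object$resid_score
  if (is.null(U))
    stop("score residuals not stored; refit with robust = TRUE")
  switch(type, score = U, dfbeta = U %*% object$var)
}

#' @export
summary.wcoxph <- function(object, conf.level = 0.95, ...) {
  beta <- object$coefficients
  robust <- !is.null(object$var_robust)
  se <- sqrt(diag(if (robust) object$var_robust else object$var))
  z <- beta / se
  q <- stats::qnorm(1 - (1 - conf.level) / 2)
  tab <- cbind(coef = beta, hr = exp(beta), se = se,
               lower = exp(beta - q * se), upper = exp(beta + q * se),
               z = z, p = 2 * stats::pnorm(-abs(z)))
  structure(list(coefficients = tab, robust = robust, n = object$n,
                 nevent = object$nevent, converged = object$converged,
                 conf.level = conf.level, call = object$call),
            class = "summary.wcoxph")
}

#' @export
print.summary.wcoxph <- function(x, digits = 4L, ...) {
  if (!is.null(x$call)) {
    cat("Call:\n"); print(x$call); cat("\n")
  }
  cat("n =", x$n, ", events =", x$nevent, "\n")
  cat(if (x$robust) "Robust (sandwich)" else "Model-based",
      "standard errors;", format(100 * x$conf.level), "% CI\n\n")
  print(round(x$coefficients, digits))
  if (!x$converged) cat("\nWARNING: fit did not converge\n")
  invisible(x)
}

#' Breslow baseline cumulative hazard of a fit
#'
#' Step-function estimate of \eqn{\int_0^t \lambda_0(u) du} evaluated at the
#' fitted coefficients: at each distinct event time the increment is the
#' weighted number of events divided by the weighted risk-set sum of
#' \eqn{\exp(\beta^\top z)}.
#'
#' @param fit a `wcoxph` object.
#' @return a data frame with columns `time`, `hazard` (increment), `cumhaz`.
#' @export
baseline_cumhaz <- function(fit) {
  stopifnot(inherits(fit, "wcoxph") || is.list(fit))
  fit$baseline
}

#' Survival probability over a time interval
#'
#' Computes \eqn{s = \exp\{-[H_0(t_1) - H_0(t_0)] \exp(\beta^\top z)\}} from
#' the Breslow baseline cumulative hazard \eqn{H_0} of a fit. Times outside
#' the observed event-time support contribute no hazard mass, so intervals
#' lying before the first (or after the last) event time have survival 1
#' beyond the observed steps.
#'
#' @param fit a `wcoxph` fit (or any list with `coefficients` and `baseline`).
#' @param z covariate matrix (or vector for a single subject) in the order of
#'   the fitted coefficients.
#' @param t_start,t_end interval bounds, `t_start <= t_end`; vectors recycle
#'   against the rows of `z`.
#' @return a numeric vector of survival probabilities in (0, 1].
#' @export
interval_survival <- function(fit, z, t_start, t_end) {
  z <- if (is.null(dim(z))) matrix(z, nrow = 1L) else as.matrix(z)
  nr <- max(nrow(z), length(t_start), length(t_end))
  t_start <- rep_len(t_start, nr)
  t_end <- rep_len(t_end, nr)
  if (nrow(z) != nr) z <- z[rep_len(seq_len(nrow(z)), nr), , drop = FALSE]
  if (any(t_start > t_end)) stop("t_start must be <= t_end")
  bh <- fit$baseline
  H <- function(t) c(0, bh$cumhaz)[findInterval(t, bh$time) + 1L]
  dH <- H(t_end) - H(t_start)
  exp(-dH * exp(drop(z %*% fit$coefficients)))
}

#' Predictions from a weighted Cox fit
#'
#' @param object a `wcoxph` fit.
#' @param newdata optional data frame; defaults to the training covariates.
#' @param type `"lp"` (linear predictor) or `"risk"` (`exp(lp)`).
#' @param ... unused.
#' @export
predict.wcoxph <- function(object, newdata = NULL, type = c("lp", "risk"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    X <- object$data$x
  } else {
    tt <- stats::delete.response(object$terms)
    mf <- stats::model.frame(tt, newdata)
    X <- stats::model.matrix(tt, mf)
    icpt <- match("(Intercept)", colnames(X), 0L)
    if (icpt > 0L) X <- X[, -icpt, drop = FALSE]
  }
  lp <- drop(X %*% object$coefficients)
  if (type == "risk") exp(lp) else lp
}

#' Serialize a fit to JSON
#'
#' Writes coefficients, both covariance matrices, the Breslow baseline as
#' (time, cumhaz) pairs, and convergence metadata.
#'
#' @param fit a `wcoxph` fit.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  obj <- list(
    coefficients = as.list(fit$coefficients),
    covariance_model = unname(fit$var),
    covariance_robust = if (!is.null(fit$var_robust)) unname(fit$var_robust),
    baseline = list(time = fit$baseline$time, cumhaz = fit$baseline$cumhaz),
    n_subjects = fit$n, n_events = fit$nevent,
    converged = fit$converged, iterations = fit$iter,
    log_partial_likelihood = unname(fit$loglik[["final"]]))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
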