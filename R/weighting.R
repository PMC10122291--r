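# Covariates of the death model: sex, provoked first VT, age at first VT,
# and the first four genetic principal components.
death_covariates <- function() {
  c("sex", "provoked_first_vt", "age_first_vt", "pc1", "pc2", "pc3", "pc4")
}

#' Delayed-entry Cox model for the risk of death
#'
#' Fits a Cox model of death on the age time-scale among subjects with
#' known vital status. Each subject enters the risk set at their age at
#' inclusion (they had to be alive then to be included, so earlier ages are
#' left-truncated) and exits at the age of death or last vital information.
#' Using age as the time-scale leaves the age effect non-parametric in the
#' baseline hazard; covariates are sex, the provoked character of the first
#' VT, age at the first VT, and the first four principal components.
#'
#' @param records validated cohort data frame.
#' @return a `wcoxph` fit (unweighted, model-based covariance). Subjects
#'   with unknown vital status are excluded with a message; their count is
#'   stored as attribute `n_excluded_unknown_vital`.
#' @seealso [compute_weights()]
#' @export
fit_death_model <- function(records) {
  known <- records$vital_status %in% c("alive", "dead")
  n_unknown <- sum(!known)
  if (n_unknown > 0L)
    message(n_unknown,
            " subject(s) with unknown vital status excluded from death model")
  r <- records[known, , drop = FALSE]
  if (nrow(r) == 0L) stop("no subjects with known vital status")
  entry <- r$age_first_vt + r$t_inclusion
  exit <- r$age_first_vt + r$t_last_vital
  if (any(exit <= entry))
    stop("age at last vital information must exceed age at inclusion")
  status <- as.integer(r$vital_status == "dead")
  if (sum(status) == 0L) stop("no deaths: cannot fit the death model")
  x <- as.matrix(r[, death_covariates()])
  fit <- wcox_fit(entry, exit, status, x, w = NULL, robust = FALSE)
  fit$call <- match.call()
  class(fit) <- "wcoxph"
  attr(fit, "n_excluded_unknown_vital") <- n_unknown
  fit
}

#' Age at which recurrence information was collected
#'
#' The age up to which a subject had to survive for their recurrence
#' information to be observed: the recontact age for CASE1/CASE2 (their
#' post-inclusion follow-up was collected at recontact), the inclusion age
#' for CASE3/CASE4 (their pre-inclusion history was collected at the
#' inclusion visit).
#'
#' @param records classified cohort data frame.
#' @return numeric vector of ages in years.
#' @export
collection_age <- function(records) {
  if (is.null(records$case)) records <- classify_case(records)
  ifelse(records$case %in% c("CASE1", "CASE2"),
         records$age_first_vt + records$t_collection,
         records$age_first_vt + records$t_inclusion)
}

#' Inverse-survival-probability selection weights
#'
#' For each subject, the probability \eqn{s_i} of surviving from their age
#' at first VT to their own collection age is predicted from the
#' delayed-entry death model (the baseline cumulative hazard is zero
#' outside the observed entry-age support, so ages before the support
#' contribute no mass). Weights are the standardized inverses
#' \deqn{w_i = N \frac{1/s_i}{\sum_j 1/s_j},}
#' so that they sum to the studied sample size N. All subjects are
#' weighted, including those whose vital status was unavailable for
#' fitting: prediction needs only covariates.
#'
#' @param death_fit a converged `wcoxph` fit from [fit_death_model()].
#' @param records classified cohort data frame (N = its row count).
#' @return an object of class `weight_set`: a data frame `subject_id`, `s`
#'   (survival probability), `w` (standardized weight), with attributes
#'   `N`, `ess` (effective sample size \eqn{(\sum w)^2/\sum w^2}) and
#'   `range`.
#' @export
compute_weights <- function(death_fit, records) {
  if (!is.null(death_fit$converged) && !isTRUE(death_fit$converged))
    stop("death model did not converge; weights would be unreliable")
  if (is.null(records$case)) records <- classify_case(records)
  z <- as.matrix(records[, names(death_fit$coefficients)])
  s <- interval_survival(death_fit, z,
                         t_start = records$age_first_vt,
                         t_end = collection_age(records))
  if (any(s <= 0)) stop("zero survival probability encountered")
  N <- nrow(records)
  inv <- 1 / s
  w <- N * inv / sum(inv)
  if (max(w) > 10)
    warning("maximum weight exceeds 10; weighting may be unstable")
  out <- data.frame(subject_id = records$subject_id, s = s, w = w,
                    stringsAsFactors = FALSE)
  attr(out, "N") <- N
  attr(out, "ess") <- sum(w)^2 / sum(w^2)
  attr(out, "range") <- range(w)
  class(out) <- c("weight_set", "data.frame")
  out
}

#' @export
print.weight_set <- function(x, ...) {
  rg <- attr(x, "range")
  cat("Selection weights for", attr(x, "N"), "subjects\n")
  cat(sprintf("  sum = %.6f, range = [%.3f, %.3f], ESS = %.1f\n",
              sum(x$w), rg[1], rg[2], attr(x, "ess")))
  invisible(x)
}

#' Export weights as CSV
#'
#' @param ws a `weight_set`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_weights <- function(ws, path) {
  write.csv(as.data.frame(ws), path, row.names = FALSE)
  invisible(path)
}
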