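# Hand-built four-case cohort used across the cohort/weighting tests.
# Times are years since the first VT.
toy_cohort <- function() {
  data.frame(
    subject_id = c("P1", "P2", "P3", "P4"),
    sex = c(1, 0, 1, 0),
    age_first_vt = c(40, 50, 35, 60),
    provoked_first_vt = c(1, 0, 1, 0),
    dvt_first_vt = c(1, 1, 0, 1),
    pc1 = 0, pc2 = 0, pc3 = 0, pc4 = 0,
    t_inclusion = c(5, 5, 5, 5),
    recurrence_observed = c(0, 1, 0, 1),
    t_recurrence = c(NA, 8, NA, 2),
    t_collection = c(12, 12, 5, 5),
    responded_recontact = c(1, 1, 0, 0),
    vital_status = c("alive", "alive", "dead", "unknown"),
    t_last_vital = c(15, 15, 9, NA),
    stringsAsFactors = FALSE)
}

# small simulated cohort for property checks
quick_sim <- function(n = 600, seed = 42, ...) {
  generate_cohort(sim_config(n_subjects = n, seed = seed, ...))
}

# grid-search oracle for the one-covariate partial likelihood (Breslow
# ties, half-open risk sets), independent of the Newton path
grid_search_beta <- function(entry, exit, status, x, w = NULL,
                             lim = 3, step = 1e-4) {
  if (is.null(w)) w <- rep(1, length(exit))
  bs <- seq(-lim, lim, step)
  ll <- vapply(bs, function(b) {
    r <- w * exp(b * x)
    s <- 0
    for (i in which(status == 1)) {
      rs <- entry < exit[i] & exit >= exit[i]
      s <- s + w[i] * (b * x[i] - log(sum(r[rs])))
    }
    s
  }, numeric(1L))
  bs[which.max(ll)]
}

# Nelson-Aalen oracle on left-truncated data by direct risk-set counting
nelson_aalen <- function(entry, exit, status, w = NULL) {
  if (is.null(w)) w <- rep(1, length(exit))
  tau <- sort(unique(exit[status == 1]))
  inc <- vapply(tau, function(t)
    sum(w[exit == t & status == 1]) / sum(w[entry < t & exit >= t]),
    numeric(1L))
  data.frame(time = tau, cumhaz = cumsum(inc))
}

# unit weight set (the weights under a null death model)
unit_weights <- function(records) {
  out <- data.frame(subject_id = records$subject_id, s = 1, w = 1,
                    stringsAsFactors = FALSE)
  attr(out, "N") <- nrow(records)
  class(out) <- c("weight_set", "data.frame")
  out
}
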