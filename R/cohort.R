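#' @importFrom stats pnorm qnorm rbinom rexp rnorm runif sd quantile setNames
#' @importFrom utils read.csv write.csv
NULL

# Canonical cohort columns (one row per patient; all times are offsets in
# years from the first venous-thrombosis event).
cohort_columns <- function() {
  c("subject_id", "sex", "age_first_vt", "provoked_first_vt", "dvt_first_vt",
    "pc1", "pc2", "pc3", "pc4",
    "t_inclusion", "recurrence_observed", "t_recurrence", "t_collection",
    "responded_recontact", "vital_status", "t_last_vital")
}

#' Read an ambispective cohort file
#'
#' Expects a CSV with one header row and the canonical subject columns:
#' `subject_id`, `sex` (1 = male), `age_first_vt`, `provoked_first_vt`,
#' `dvt_first_vt` (1 = DVT, 0 = PE), `pc1`..`pc4`, `t_inclusion`,
#' `recurrence_observed`, `t_recurrence`, `t_collection`,
#' `responded_recontact`, `vital_status` (alive/dead/unknown),
#' `t_last_vital`. Missing values are empty cells; lines starting with `#`
#' (e.g. a schema-version comment) are skipped.
#'
#' @param path CSV file path.
#' @return a data frame of subject records (not yet validated).
#' @seealso [validate_cohort()]
#' @export
read_cohort <- function(path) {
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing_cols <- setdiff(cohort_columns(), names(df))
  if (length(missing_cols))
    stop("cohort file lacks columns: ", paste(missing_cols, collapse = ", "))
  df$vital_status[is.na(df$vital_status) | df$vital_status == ""] <- "unknown"
  df[, cohort_columns()]
}

#' Write an ambispective cohort file
#'
#' @param records a cohort data frame.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_cohort <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# ambicox cohort schema v1", con)
  write.csv(records[, intersect(cohort_columns(), names(records))],
            con, row.names = FALSE, na = "")
  invisible(path)
}

#' Validate subject timelines
#'
#' Checks every record against the timeline invariants (non-negative
#' offsets, recurrence not after its collection, inclusion not after
#' collection, vital follow-up not before inclusion, a recurrence time
#' present whenever a recurrence is flagged, and no post-inclusion
#' recurrence for recontact non-responders, which is not an observable
#' configuration in this design). Nothing is dropped silently: the return
#' value carries both the passing records and a structured report of the
#' rejected rows with reason codes.
#'
#' @param records a cohort data frame as from [read_cohort()].
#' @return a list of class `cohort_validation` with elements `records`
#'   (valid rows), `rejected` (data frame `subject_id`, `reason`), `n_input`.
#' @export
validate_cohort <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("empty cohort")
  if (anyDuplicated(records$subject_id))
    stop("duplicated subject_id: ",
         paste(unique(records$subject_id[duplicated(records$subject_id)]),
               collapse = ", "))
  num_req <- c("sex", "age_first_vt", "provoked_first_vt", "dvt_first_vt",
               "pc1", "pc2", "pc3", "pc4", "t_inclusion",
               "recurrence_observed", "t_collection", "responded_recontact")
  reasons <- vector("list", nrow(records))
  add <- function(bad, code) {
    bad[is.na(bad)] <- FALSE
    for (i in which(bad)) reasons[[i]] <<- c(reasons[[i]], code)
  }
  for (cc in num_req) add(is.na(records[[cc]]), paste0("missing_", cc))
  add(records$t_inclusion < 0 | records$t_collection < 0,
      "negative_time_offset")
  add(records$recurrence_observed == 1 & is.na(records$t_recurrence),
      "recurrence_without_time")
  add(records$recurrence_observed == 0 & !is.na(records$t_recurrence),
      "recurrence_time_without_flag")
  add(records$recurrence_observed == 1 & records$t_recurrence < 0,
      "negative_time_offset")
  add(records$recurrence_observed == 1 &
        records$t_recurrence > records$t_collection,
      "recurrence_after_collection")
  add(records$t_inclusion > records$t_collection,
      "inclusion_after_collection")
  add(!records$vital_status %in% c("alive", "dead", "unknown"),
      "bad_vital_status")
  known <- records$vital_status %in% c("alive", "dead")
  add(known & is.na(records$t_last_vital), "missing_t_last_vital")
  add(known & !is.na(records$t_last_vital) &
        records$t_last_vital < records$t_inclusion,
      "vital_before_inclusion")
  add(records$responded_recontact == 0 & records$recurrence_observed == 1 &
        records$t_recurrence >= records$t_inclusion,
      "post_inclusion_recurrence_without_response")

  bad <- !vapply(reasons, is.null, logical(1L))
  rejected <- data.frame(
    subject_id = records$subject_id[bad],
    reason = vapply(reasons[bad], paste, character(1L), collapse = ";"),
    stringsAsFactors = FALSE)
  accepted <- records[!bad, , drop = FALSE]
  rownames(accepted) <- NULL
  structure(list(records = accepted,
                 rejected = rejected,
                 n_input = nrow(records)),
            class = "cohort_validation")
}

#' @export
print.cohort_validation <- function(x, ...) {
  cat("Cohort validation:", nrow(x$records), "of", x$n_input,
      "records accepted\n")
  if (nrow(x$rejected)) {
    cat("Rejected rows:\n")
    print(x$rejected, row.names = FALSE)
  }
  invisible(x)
}

#' Classify subjects into the four ambispective case types
#'
#' * `CASE4` — recurrence before inclusion (`t_recurrence < t_inclusion`);
#' * `CASE3` — no pre-inclusion recurrence and no recontact response
#'   (lost to follow-up);
#' * `CASE2` — responded, recurrence observed between inclusion and the
#'   recontact collection time (a recurrence exactly at inclusion counts as
#'   post-inclusion: it is what the inclusion visit would record);
#' * `CASE1` — responded, no recurrence.
#'
#' @param records validated cohort data frame.
#' @return the data frame with a `case` column
#'   (factor `CASE1`..`CASE4`) appended.
#' @export
classify_case <- function(records) {
  if (any(records$recurrence_observed == 1 & is.na(records$t_recurrence)))
    stop("recurrence_observed without t_recurrence; validate first")
  rec <- records$recurrence_observed == 1
  pre <- rec & records$t_recurrence < records$t_inclusion
  case <- ifelse(pre, "CASE4",
          ifelse(records$responded_recontact == 0, "CASE3",
          ifelse(rec, "CASE2", "CASE1")))
  records$case <- factor(case, levels = paste0("CASE", 1:4))
  records
}

#' Derive at-risk intervals for a design
#'
#' Encodes the grey at-risk periods of the four case types as half-open
#' `(entry, exit]` intervals on the time-since-first-VT scale.
#'
#' Ambispective: every case contributes from the first VT (`entry = 0`);
#' exit is the recurrence time (event) for CASE2/CASE4, the recontact
#' collection time (censored) for CASE1, and the inclusion time (censored)
#' for CASE3. Prospective: only CASE1/CASE2 contribute, with delayed entry
#' at inclusion; CASE3/CASE4 are dropped.
#'
#' @param records classified cohort data frame (see [classify_case()]).
#' @param design `"ambispective"` or `"prospective"`.
#' @return a data frame `subject_id`, `entry`, `exit`, `event` with one row
#'   per contributing subject.
#' @export
make_intervals <- function(records, design = c("ambispective", "prospective")) {
  design <- match.arg(design)
  if (is.null(records$case)) records <- classify_case(records)
  if (design == "ambispective") {
    exit <- ifelse(records$case %in% c("CASE2", "CASE4"), records$t_recurrence,
            ifelse(records$case == "CASE1", records$t_collection,
                   records$t_inclusion))
    out <- data.frame(subject_id = records$subject_id, entry = 0,
                      exit = exit,
                      event = as.integer(records$case %in% c("CASE2", "CASE4")),
                      stringsAsFactors = FALSE)
  } else {
    keep <- records$case %in% c("CASE1", "CASE2")
    r <- records[keep, , drop = FALSE]
    exit <- ifelse(r$case == "CASE2", r$t_recurrence, r$t_collection)
    out <- data.frame(subject_id = r$subject_id, entry = r$t_inclusion,
                      exit = exit, event = as.integer(r$case == "CASE2"),
                      stringsAsFactors = FALSE)
  }
  if (any(out$exit <= out$entry))
    stop("degenerate at-risk interval (exit <= entry) for subject(s): ",
         paste(utils::head(out$subject_id[out$exit <= out$entry], 5L),
               collapse = ", "),
         " - timeline inconsistency")
  out
}
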