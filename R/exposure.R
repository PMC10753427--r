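## exposure container ---------------------------------------------------------

new_exposure <- function(X, set_id, y, subject_id, index_date) {
  stopifnot(nrow(X) == length(set_id), length(set_id) == length(y))
  structure(list(X = X, set_id = as.integer(set_id), y = as.integer(y),
                 subject_id = subject_id, index_date = index_date),
            class = "medscreen_exposure")
}

#' @exportS3Method base::print
print.medscreen_exposure <- function(x, ...) {
  cat("<medscreen_exposure> ", nrow(x$X), " members (",
      sum(x$y), " cases) x ", ncol(x$X), " medication classes\n", sep = "")
  invisible(x)
}

#' @exportS3Method base::dim
dim.medscreen_exposure <- function(x) dim(x$X)

#' Build the lagged binary exposure matrix
#'
#' One row per matched-set member, one column per ATC level-5 class; a cell
#' is 1 iff the member has at least one dispensing strictly before
#' `index_date - lag_days` (the set's shared index date). Dispensings inside
#' the lag window are ignored, which guards against reverse causation from
#' prodromal prescribing.
#'
#' @param matched_sets Output of [density_match()] (`set_id`, `subject_id`,
#'   `role`, `index_date`).
#' @param dispensing `data.table` with `subject_id`, `atc5`, `dispense_date`.
#' @param lag_days Exposure lag in days (default 730, i.e. 2 years).
#' @param classes Optional character vector fixing the column set (classes
#'   with no qualifying events appear as zero columns); default: classes
#'   observed in `dispensing`.
#' @param subjects Optional subject table; when given, dispensing rows whose
#'   `subject_id` is absent from it raise a data-integrity error.
#' @return A `medscreen_exposure`: sparse 0/1 matrix `X` (rows ordered by
#'   `set_id`, case first) plus `set_id`, `y` (case indicator),
#'   `subject_id`, `index_date`.
#' @export
build_exposure_matrix <- function(matched_sets, dispensing, lag_days = 730L,
                                  classes = NULL, subjects = NULL) {
  ms <- data.table::as.data.table(matched_sets)
  dispensing <- data.table::as.data.table(dispensing)
  if (!is.null(subjects)) {
    unknown <- setdiff(dispensing$subject_id,
                       data.table::as.data.table(subjects)$subject_id)
    if (length(unknown))
      stop("dispensing references unknown subject(s): ",
           paste(head(unknown, 5L), collapse = ", "), call. = FALSE)
  }
  data.table::setorder(ms, set_id, role)   # "case" sorts before "control"
  ms[, row := .I]
  if (is.null(classes)) classes <- sort(unique(dispensing$atc5))

  ev <- dispensing[atc5 %in% classes][ms, on = "subject_id",
                                      allow.cartesian = TRUE, nomatch = NULL]
  ev <- ev[dispense_date < index_date - lag_days,
           .(row = row[1L]), by = .(set_id, subject_id, atc5)]
  X <- Matrix::sparseMatrix(
    i = ev$row, j = match(ev$atc5, classes), x = 1,
    dims = c(nrow(ms), length(classes)),
    dimnames = list(NULL, classes))
  new_exposure(X = X, set_id = ms$set_id, y = as.integer(ms$role == "case"),
               subject_id = ms$subject_id, index_date = ms$index_date)
}

#' Drop rarely used medication classes
#'
#' Removes every class dispensed (within the lagged window) to fewer than
#' `ceiling(min_frac * N)` cohort members, where `N` is the total number of
#' matched-set members. The dropped classes and the count threshold are
#' recorded in the `"rare_filter"` attribute and reported via `message()`.
#'
#' @param exposure A `medscreen_exposure`.
#' @param min_frac Minimum fraction of cohort members using the class
#'   (default 0.001, i.e. 0.1%).
#' @param quiet Suppress the message.
#' @return The filtered `medscreen_exposure`.
#' @export
filter_rare_drugs <- function(exposure, min_frac = 0.001, quiet = FALSE) {
  stopifnot(inherits(exposure, "medscreen_exposure"), min_frac >= 0)
  n <- nrow(exposure$X)
  threshold <- ceiling(min_frac * n)
  users <- Matrix::colSums(exposure$X > 0)
  keep <- users >= threshold
  dropped <- colnames(exposure$X)[!keep]
  if (!quiet)
    message("rare-drug filter: threshold ", threshold, " of ", n,
            " members; dropped ", length(dropped), " of ", length(keep),
            " classes")
  out <- exposure
  out$X <- exposure$X[, keep, drop = FALSE]
  attr(out, "rare_filter") <- list(threshold = threshold, n = n,
                                   min_frac = min_frac, dropped = dropped)
  out
}

#' Build adjustment covariates for matched-set members
#'
#' Comorbidity indicators (`diabetes`, `hypertension`, `cardiovascular`,
#' `excess_weight`) are 1 iff the condition's onset is strictly before the
#' member's index date. The physician-visit rate — a surveillance-bias proxy —
#' counts visits strictly before `index_date - lag_days` divided by follow-up
#' months from enrollment start to that lagged cutoff. Members with
#' non-positive lagged follow-up get `visit_rate = NA` and a warning; the
#' regression stage drops such rows explicitly.
#'
#' @param matched_sets Output of [density_match()].
#' @param comorbidities `data.table` (`subject_id`, `condition`,
#'   `onset_date`).
#' @param visits `data.table` (`subject_id`, `visit_date`).
#' @param enrollment Table with `subject_id`, `enrollment_start`.
#' @param lag_days Lag applied to the visit window (default 730). Comorbidity
#'   indicators use the unlagged index date.
#' @param conditions Conditions to emit as columns.
#' @return `data.table` keyed like `matched_sets` (one row per member):
#'   `set_id`, `subject_id`, condition indicators, `visit_rate`.
#' @export
build_covariates <- function(matched_sets, comorbidities, visits, enrollment,
                             lag_days = 730L,
                             conditions = c("diabetes", "hypertension",
                                            "cardiovascular",
                                            "excess_weight")) {
  ms <- data.table::as.data.table(matched_sets)
  comorbidities <- data.table::as.data.table(comorbidities)
  visits <- data.table::as.data.table(visits)
  enrollment <- data.table::as.data.table(enrollment)
  data.table::setorder(ms, set_id, role)

  out <- ms[, .(set_id, subject_id, role, index_date)]
  for (cond in conditions) {
    onsets <- comorbidities[condition == cond,
                            .(subject_id, onset_date)]
    mm <- onsets[out, on = "subject_id"]
    out[, (cond) := as.integer(!is.na(mm$onset_date) &
                                 mm$onset_date < mm$index_date)]
  }

  out[, cutoff := index_date - lag_days]
  vc <- visits[out[, .(subject_id, set_id, cutoff)], on = "subject_id",
               allow.cartesian = TRUE, nomatch = NULL][
    visit_date < cutoff, .(n_visits = .N), by = .(set_id, subject_id)]
  out <- vc[out, on = c("set_id", "subject_id")]
  out[is.na(n_visits), n_visits := 0L]
  out <- enrollment[, .(subject_id, enrollment_start)][out, on = "subject_id"]
  out[, followup_months := as.numeric(cutoff - enrollment_start) /
        DAYS_PER_MONTH]
  out[, visit_rate := ifelse(followup_months > 0,
                             n_visits / followup_months, NA_real_)]
  if (anyNA(out$visit_rate))
    warning(sum(is.na(out$visit_rate)),
            " member(s) with non-positive lagged follow-up; visit_rate set ",
            "to NA", call. = FALSE)
  data.table::setorder(out, set_id, role)
  out[, c("cutoff", "enrollment_start") := NULL]
  out[]
}
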