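#' Ascertain eligible cases from the diagnosis registry
#'
#' Returns the first colorectal-cancer diagnosis per subject falling inside
#' the half-open study window with index age at most `max_age`. Age is
#' computed as index year minus birth year (matching is on birth year, not
#' birth date).
#'
#' @param diagnoses `data.table` with `subject_id`, `condition`,
#'   `diagnosis_date`; rows with `condition == "crc"` are used.
#' @param subjects Subject table with `subject_id`, `birth_year`.
#' @param window Half-open date pair `[start, end)`.
#' @param max_age Maximum index age in years (default 50).
#' @return `data.table` of `CaseRecord`s: `subject_id`, `index_date`,
#'   `age_at_index`, keyed by `subject_id`.
#' @export
ascertain_cases <- function(diagnoses, subjects,
                            window = c("2001-01-01", "2020-01-01"),
                            max_age = 50L) {
  diagnoses <- data.table::as.data.table(diagnoses)
  subjects <- data.table::as.data.table(subjects)
  win <- as_date(window)
  crc <- diagnoses[condition == "crc"]
  missing_subj <- setdiff(crc$subject_id, subjects$subject_id)
  if (length(missing_subj))
    stop("diagnosis references unknown subject(s): ",
         paste(head(missing_subj, 5L), collapse = ", "), call. = FALSE)
  first <- crc[, .(index_date = min(diagnosis_date)), by = subject_id]
  first <- first[subjects[, .(subject_id, birth_year)], on = "subject_id",
                 nomatch = NULL]
  first[, age_at_index := as.integer(format(index_date, "%Y")) - birth_year]
  out <- first[index_date >= win[1] & index_date < win[2] &
                 age_at_index <= max_age,
               .(subject_id, index_date, age_at_index)]
  data.table::setorder(out, index_date, subject_id)
  out[]
}

#' Apply enrollment and diagnosis-history exclusions
#'
#' Two rules in order: (1) drop cases with less than `min_years` of
#' continuous enrollment before the index date; (2) drop cases carrying an
#' IBD or hereditary-cancer-syndrome flag anywhere in their record (personal
#' or family history style flags, regardless of date). Returns the survivors
#' and a per-rule count ledger.
#'
#' @param cases Output of [ascertain_cases()].
#' @param diagnoses Diagnosis table (for `"ibd"` / `"hereditary"` flags).
#' @param enrollment Table with `subject_id`, `enrollment_start`,
#'   `enrollment_end` (the subject table works directly).
#' @param min_years Required continuous pre-index enrollment (default 3).
#' @return List with `cases` (surviving `CaseRecord`s) and `exclusions`, a
#'   `data.table` with columns `rule`, `n_dropped`, `n_remaining`.
#' @export
apply_exclusions <- function(cases, diagnoses, enrollment, min_years = 3L) {
  cases <- data.table::as.data.table(cases)
  enrollment <- data.table::as.data.table(enrollment)
  diagnoses <- data.table::as.data.table(diagnoses)
  min_days <- as.integer(round(min_years * 365.25))

  n0 <- nrow(cases)
  cs <- enrollment[, .(subject_id, enrollment_start, enrollment_end)][
    cases, on = "subject_id"]
  keep1 <- cs[!is.na(enrollment_start) &
                enrollment_start <= index_date - min_days]
  n1 <- nrow(keep1)

  flagged <- unique(diagnoses[condition %in% c("ibd", "hereditary"),
                              subject_id])
  keep2 <- keep1[!subject_id %in% flagged]
  n2 <- nrow(keep2)

  ledger <- data.table::data.table(
    rule = c("enrollment_lt_min_years", "ibd_or_hereditary_flag"),
    n_dropped = c(n0 - n1, n1 - n2),
    n_remaining = c(n1, n2))
  out <- keep2[, .(subject_id, index_date, age_at_index)]
  data.table::setorder(out, index_date, subject_id)
  list(cases = out[], exclusions = ledger)
}

## risk set of a single case: exact key match, birth year within tolerance,
## >= min_days pre-index enrollment, still enrolled and cancer-free at index.
## Exported indirectly through density_match; also used by tests as the
## exhaustive enumeration oracle via list_risk_set().

#' Enumerate the matching risk set of one case
#'
#' Returns every subject eligible to serve as a control for `case_row` at its
#' index date: exact match on sex, district, subpopulation, SES band and
#' periphery; birth year within `birth_tol`; enrolled at least `min_years`
#' before the index date and still enrolled at it; no colorectal-cancer
#' diagnosis on or before the index date; and not the case itself. Risk-set
#' semantics: a subject who becomes a case later is eligible before their own
#' diagnosis.
#'
#' @param case_row One-row `data.table` with `subject_id` and `index_date`.
#' @param subjects Subject table.
#' @param crc_dates `data.table` (`subject_id`, `crc_date`) of first CRC
#'   diagnosis dates, as built internally by [density_match()]; may be
#'   omitted when `diagnoses` is given instead.
#' @param diagnoses Optional diagnosis table used to derive `crc_dates`.
#' @param birth_tol Birth-year tolerance (default 2).
#' @param min_years Required pre-index enrollment (default 3).
#' @return Integer vector of eligible `subject_id`s.
#' @export
list_risk_set <- function(case_row, subjects, crc_dates = NULL,
                          diagnoses = NULL, birth_tol = 2L, min_years = 3L) {
  subjects <- data.table::as.data.table(subjects)
  if (is.null(crc_dates)) {
    diagnoses <- data.table::as.data.table(diagnoses)
    crc_dates <- diagnoses[condition == "crc",
                           .(crc_date = min(diagnosis_date)), by = subject_id]
  }
  min_days <- as.integer(round(min_years * 365.25))
  cs <- subjects[subject_id == case_row$subject_id]
  idx <- case_row$index_date
  cand <- subjects[sex == cs$sex & district == cs$district &
                     subpopulation == cs$subpopulation & ses == cs$ses &
                     periphery == cs$periphery &
                     abs(birth_year - cs$birth_year) <= birth_tol &
                     enrollment_start <= idx - min_days &
                     enrollment_end > idx &
                     subject_id != cs$subject_id]
  cand <- crc_dates[cand, on = "subject_id"]
  cand[is.na(crc_date) | crc_date > idx, subject_id]
}

#' Density (risk-set) matching of controls to cases
#'
#' For each case, in index-date order, samples `ratio` controls uniformly
#' without replacement from the case's risk set at its index date (see
#' [list_risk_set()] for eligibility). Controls share the case's index date.
#' Each subject serves as a control in at most one set; a future case may
#' serve as a control before its own diagnosis. Reproducible from `seed`.
#'
#' @param cases Eligible cases (output of [apply_exclusions()]`$cases`).
#' @param subjects Subject table.
#' @param enrollment Ignored if enrollment columns are already on `subjects`;
#'   otherwise a table with `subject_id`, `enrollment_start`,
#'   `enrollment_end` merged in.
#' @param diagnoses Diagnosis table (for CRC-free-at-index checks).
#' @param ratio Controls per case (default 10).
#' @param birth_tol Birth-year tolerance (default 2).
#' @param min_years Pre-index enrollment requirement (default 3).
#' @param seed Integer seed for control sampling.
#' @param allow_short_sets If `FALSE` (default), a risk set smaller than
#'   `ratio` is an error; if `TRUE`, a warning is issued and the short set is
#'   kept.
#' @return `data.table` of matched-set members: `set_id`, `subject_id`,
#'   `role` (`"case"`/`"control"`), `index_date`.
#' @export
density_match <- function(cases, subjects, enrollment = NULL, diagnoses,
                          ratio = 10L, birth_tol = 2L, min_years = 3L,
                          seed = 1L, allow_short_sets = FALSE) {
  cases <- data.table::as.data.table(cases)
  subjects <- data.table::as.data.table(subjects)
  if (!is.null(enrollment) &&
      !all(c("enrollment_start", "enrollment_end") %in% names(subjects))) {
    subjects <- data.table::as.data.table(enrollment)[
      , .(subject_id, enrollment_start, enrollment_end)][
        subjects, on = "subject_id"]
  }
  diagnoses <- data.table::as.data.table(diagnoses)
  crc_dates <- diagnoses[condition == "crc",
                         .(crc_date = min(diagnosis_date)), by = subject_id]
  min_days <- as.integer(round(min_years * 365.25))

  pool <- data.table::copy(subjects)
  pool <- crc_dates[pool, on = "subject_id"]
  pool[is.na(crc_date), crc_date := as.Date("9999-12-31")]
  data.table::setkey(pool, sex, district, subpopulation, ses, periphery)

  ord <- subjects[, .(subject_id, sex, district, subpopulation, ses,
                      periphery, birth_year)][
    data.table::as.data.table(cases), on = "subject_id", nomatch = NULL]
  data.table::setorder(ord, index_date, subject_id)
  used <- new.env(parent = emptyenv())   # subject_id -> TRUE once used

  out <- vector("list", nrow(ord))
  with_seed(seed, {
    for (i in seq_len(nrow(ord))) {
      cs_id <- ord$subject_id[i]
      idx <- ord$index_date[i]
      grp <- pool[.(ord$sex[i], ord$district[i], ord$subpopulation[i],
                    ord$ses[i], ord$periphery[i]), nomatch = NULL]
      elig <- grp[abs(birth_year - ord$birth_year[i]) <= birth_tol &
                    enrollment_start <= idx - min_days &
                    enrollment_end > idx &
                    crc_date > idx &
                    subject_id != cs_id, subject_id]
      elig <- elig[!vapply(as.character(elig), exists, logical(1L),
                           envir = used, inherits = FALSE)]
      if (length(elig) < ratio) {
        msg <- sprintf(
          "case %s (index %s): risk set has %d eligible controls (< %d)",
          cs_id, format(idx), length(elig), ratio)
        if (!allow_short_sets) stop(msg, call. = FALSE)
        warning(msg, call. = FALSE)
      }
      ctrl <- if (length(elig) <= ratio) elig else
        elig[sample.int(length(elig), ratio)]
      for (id in ctrl) assign(as.character(id), TRUE, envir = used)
      out[[i]] <- data.table::data.table(
        set_id = i,
        subject_id = c(cs_id, ctrl),
        role = c("case", rep("control", length(ctrl))),
        index_date = idx)
    }
  })
  data.table::rbindlist(out)[]
}
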