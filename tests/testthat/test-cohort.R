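## hand-built micro-population: one matching cell unless stated otherwise
mk_subjects <- function(n, birth_year = 1970L,
                        start = as.Date("1996-01-01"),
                        end = as.Date("2020-01-01")) {
  data.table::data.table(
    subject_id = seq_len(n), sex = "male", district = "north",
    subpopulation = "secular_jewish", ses = 5L, periphery = "core",
    birth_year = birth_year, enrollment_start = start, enrollment_end = end,
    visit_rate = 0.6)
}

test_that("case ascertainment applies the age and window boundaries", {
  subj <- mk_subjects(4, birth_year = c(1960L, 1959L, 1970L, 1970L))
  diag <- data.table::data.table(
    subject_id = c(1L, 2L, 3L, 4L, 3L),
    condition = "crc",
    diagnosis_date = as.Date(c("2010-06-01",  # age 50 -> kept
                               "2010-06-01",  # age 51 -> excluded
                               "2020-06-01",  # outside window -> excluded
                               "2019-12-31",  # kept
                               "2021-01-01"))) # later record, not first
  cases <- ascertain_cases(diag, subj, window = c("2001-01-01", "2020-01-01"))
  expect_identical(sort(cases$subject_id), c(1L, 4L))
  expect_identical(cases[cases$subject_id == 1L, ]$age_at_index, 50L)
  ## first diagnosis wins even when a later one is in-window
  diag2 <- data.table::data.table(subject_id = 3L, condition = "crc",
                                  diagnosis_date = as.Date(c("2000-06-01",
                                                             "2010-06-01")))
  expect_identical(nrow(ascertain_cases(diag2, subj)), 0L)
  ## unknown subject is a data-integrity error
  expect_error(ascertain_cases(
    data.table::data.table(subject_id = 99L, condition = "crc",
                           diagnosis_date = as.Date("2010-01-01")), subj),
    "unknown subject")
})

test_that("exclusions drop short enrollment then flagged cases, in order", {
  subj <- mk_subjects(3)
  subj$enrollment_start <- as.Date(c("1996-01-01", "2009-06-01", "1996-01-01"))
  diag <- data.table::data.table(
    subject_id = c(1L, 2L, 3L, 3L),
    condition = c("crc", "crc", "crc", "ibd"),
    diagnosis_date = as.Date(c("2010-01-01", "2010-01-01", "2010-01-01",
                               "2005-01-01")))
  cases <- ascertain_cases(diag, subj)
  res <- apply_exclusions(cases, diag, subj)
  expect_identical(res$cases$subject_id, 1L)
  expect_identical(res$exclusions$n_dropped, c(1L, 1L))
  expect_identical(res$exclusions$n_remaining, c(2L, 1L))
  ## identity when nothing is excludable
  res2 <- apply_exclusions(cases[cases$subject_id == 1L, ],
                           diag[diag$condition == "crc", ], subj)
  expect_identical(res2$cases$subject_id, 1L)
  expect_identical(sum(res2$exclusions$n_dropped), 0L)
})

test_that("matching keys are enforced exactly and birth year within tolerance", {
  subj <- mk_subjects(30)
  subj$sex[2L] <- "female"          # key violation
  subj$birth_year[3L] <- 1973L      # outside +-2
  subj$birth_year[4L] <- 1972L      # inside +-2
  diag <- data.table::data.table(subject_id = 1L, condition = "crc",
                                 diagnosis_date = as.Date("2010-01-01"))
  cases <- ascertain_cases(diag, subj)
  ms <- density_match(cases, subj, diagnoses = diag, ratio = 10, seed = 1)
  ctrl <- ms[ms$role == "control", ]$subject_id
  expect_false(2L %in% ctrl)
  expect_false(3L %in% ctrl)
  expect_identical(length(ctrl), 10L)
  ## repeated over seeds: the sex-discordant candidate is never selected
  for (s in 2:6) {
    ms_s <- density_match(cases, subj, diagnoses = diag, ratio = 10, seed = s)
    expect_false(2L %in% ms_s[ms_s$role == "control", ]$subject_id)
  }
})

test_that("a risk set of exactly `ratio` candidates is selected in full, any seed", {
  subj <- mk_subjects(11)
  diag <- data.table::data.table(subject_id = 1L, condition = "crc",
                                 diagnosis_date = as.Date("2010-01-01"))
  cases <- ascertain_cases(diag, subj)
  for (s in c(1L, 77L, 1234L)) {
    ms <- density_match(cases, subj, diagnoses = diag, ratio = 10, seed = s)
    expect_setequal(ms[ms$role == "control", ]$subject_id, 2:11)
  }
  ## one candidate fewer: error by default, warning + short set when allowed
  subj9 <- mk_subjects(10)
  expect_error(density_match(cases, subj9, diagnoses = diag, ratio = 10,
                             seed = 1),
               "risk set")
  expect_warning(
    ms_short <- density_match(cases, subj9, diagnoses = diag, ratio = 10,
                              seed = 1, allow_short_sets = TRUE),
    "risk set")
  expect_identical(sum(ms_short$role == "control"), 9L)
})

test_that("risk-set semantics: future cases may serve as controls before diagnosis", {
  subj <- mk_subjects(14)
  diag <- data.table::data.table(
    subject_id = c(1L, 2L, 3L),
    condition = "crc",
    diagnosis_date = as.Date(c("2010-01-01", "2015-06-01", "2009-06-01")))
  cases <- ascertain_cases(diag, subj)
  ms <- suppressWarnings(density_match(cases, subj, diagnoses = diag,
                                       ratio = 10, seed = 4,
                                       allow_short_sets = TRUE))
  ms <- data.table::as.data.table(ms)
  ## subject 2 (case in 2015) is eligible as control for the 2010 case;
  ## subject 3 (case in 2009) is not eligible on/after its diagnosis
  idx1 <- unique(ms[set_id == ms[subject_id == 1L & role == "case", set_id],
                    index_date])
  ctrl_rows <- ms[role == "control"]
  if (2L %in% ctrl_rows$subject_id)
    expect_lt(ctrl_rows[subject_id == 2L, index_date],
              diag[subject_id == 2L, diagnosis_date])
  expect_false(3L %in% ms[index_date >= as.Date("2009-06-01") &
                            role == "control", subject_id])
  ## control non-reuse across sets
  expect_false(any(duplicated(ctrl_rows$subject_id)))
})

test_that("density matching agrees with the exhaustive risk-set enumerator", {
  ## <=200-subject fixture with heterogeneous keys
  set.seed(42)
  n <- 180L
  subj <- data.table::data.table(
    subject_id = seq_len(n),
    sex = sample(c("male", "female"), n, TRUE),
    district = sample(c("north", "south"), n, TRUE),
    subpopulation = "secular_jewish",
    ses = sample(4:6, n, TRUE),
    periphery = "core",
    birth_year = sample(1965:1975, n, TRUE),
    enrollment_start = as.Date("1996-01-01") + sample(0:3000, n, TRUE),
    enrollment_end = as.Date("2020-01-01"),
    visit_rate = 0.6)
  diag <- data.table::data.table(
    subject_id = sample(n, 8L), condition = "crc",
    diagnosis_date = as.Date("2008-01-01") + sample(0:2000, 8L, TRUE))
  cases <- ascertain_cases(diag, subj)
  ms <- suppressWarnings(density_match(cases, subj, diagnoses = diag,
                                       ratio = 2, seed = 9,
                                       allow_short_sets = TRUE))
  ms <- data.table::as.data.table(ms)
  used <- character(0)
  for (sid in sort(unique(ms$set_id))) {
    case_row <- ms[set_id == sid & role == "case"]
    pool <- list_risk_set(case_row, subj, diagnoses = diag)
    picked <- ms[set_id == sid & role == "control", subject_id]
    ## every sampled control lies in the independently enumerated risk set
    expect_true(all(picked %in% pool))
  }
})
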