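mk_sets <- function(n_members, index = as.Date("2010-01-01")) {
  data.table::data.table(
    set_id = 1L, subject_id = seq_len(n_members),
    role = c("case", rep("control", n_members - 1L)),
    index_date = index)
}

test_that("the 2-year lag boundary is strict", {
  ms <- mk_sets(2)
  idx <- as.Date("2010-01-01")
  disp <- data.table::data.table(
    subject_id = c(1L, 1L, 2L, 2L),
    atc5 = c("c07aa05", "n05cm09", "c07aa05", "n05cm09"),
    dispense_date = c(idx - 100L,   # inside lag -> 0
                      idx - 800L,   # before lag -> 1
                      idx - 730L,   # exactly at the cutoff -> 0 (strict <)
                      idx - 731L))  # one day earlier -> 1
  em <- build_exposure_matrix(ms, disp, lag_days = 730L)
  ## columns (c07aa05, n05cm09), rows (subject 1, subject 2)
  expect_identical(as.vector(as.matrix(em$X)), c(0, 0, 1, 1))
  ## events inside the lag window never change the matrix (lag idempotence)
  more <- rbind(disp, data.table::data.table(
    subject_id = 1:2, atc5 = "c07aa05", dispense_date = idx - 10L))
  em2 <- build_exposure_matrix(ms, more, lag_days = 730L)
  expect_identical(as.matrix(em$X), as.matrix(em2$X))
})

test_that("a hand-written 5-subject, 3-class fixture reproduces its matrix", {
  idx <- as.Date("2015-06-15")
  ms <- mk_sets(5, index = idx)
  disp <- data.table::data.table(
    subject_id = c(1L, 1L, 2L, 3L, 3L, 4L, 5L, 5L),
    atc5 = c("aaa", "bbb", "aaa", "bbb", "ccc", "ccc", "aaa", "aaa"),
    dispense_date = idx - c(1000L, 3000L, 200L, 731L, 729L, 5000L, 800L,
                            2000L))
  em <- build_exposure_matrix(ms, disp, lag_days = 730L)
  expected <- matrix(c(1, 1, 0,   # s1: aaa@1000 yes, bbb@3000 yes
                       0, 0, 0,   # s2: aaa inside lag
                       0, 1, 0,   # s3: bbb@731 yes, ccc@729 no
                       0, 0, 1,   # s4: ccc@5000 yes
                       1, 0, 0),  # s5: two aaa events -> still 1
                     nrow = 5, byrow = TRUE,
                     dimnames = list(NULL, c("aaa", "bbb", "ccc")))
  expect_identical(as.matrix(em$X), expected)
  expect_identical(em$y, c(1L, 0L, 0L, 0L, 0L))
  ## unknown dispensing subject triggers the integrity check
  expect_error(build_exposure_matrix(
    ms, rbind(disp, data.table::data.table(subject_id = 42L, atc5 = "aaa",
                                           dispense_date = idx - 1000L)),
    subjects = data.table::data.table(subject_id = 1:5)),
    "unknown subject")
})

test_that("rare-drug filtering uses the ceiling count threshold", {
  ## N = 10,351 members: threshold ceil(0.001 * 10351) = 11 users
  n <- 10351L
  X <- Matrix::sparseMatrix(
    i = c(seq_len(10L), seq_len(11L)),
    j = c(rep(1L, 10L), rep(2L, 11L)),
    x = 1, dims = c(n, 2L), dimnames = list(NULL, c("ten", "eleven")))
  em <- medscreen:::new_exposure(X, set_id = rep(seq_len(n), 1L),
                                 y = rep(c(1L, rep(0L, 10L)), 941L),
                                 subject_id = seq_len(n),
                                 index_date = rep(as.Date("2010-01-01"), n))
  filt <- filter_rare_drugs(em, min_frac = 0.001, quiet = TRUE)
  expect_identical(colnames(filt$X), "eleven")
  expect_identical(attr(filt, "rare_filter")$threshold, 11)
  expect_identical(attr(filt, "rare_filter")$dropped, "ten")
  ## min_frac = 0 is the identity
  id <- filter_rare_drugs(em, min_frac = 0, quiet = TRUE)
  expect_identical(colnames(id$X), c("ten", "eleven"))
  ## monotonicity: raising min_frac never adds columns
  prev_cols <- ncol(em$X)
  for (f in c(0, 5e-4, 1e-3, 5e-3, 0.05)) {
    k <- ncol(filter_rare_drugs(em, min_frac = f, quiet = TRUE)$X)
    expect_lte(k, prev_cols)
    prev_cols <- k
  }
})

test_that("covariates use strict onset and lagged visit windows", {
  idx <- as.Date("2010-01-01")
  ms <- mk_sets(3, index = idx)
  enroll <- data.table::data.table(
    subject_id = 1:3,
    enrollment_start = c(idx - 730L - 3653L,  # 120.03 months of lagged f/u
                         idx - 3000L,
                         idx - 600L))         # follow-up ends before cutoff
  com <- data.table::data.table(
    subject_id = c(1L, 2L),
    condition = "diabetes",
    onset_date = c(idx - 1L,   # strictly before index -> 1
                   idx + 1L))  # one day after index -> 0
  ## 72 visits before the lagged cutoff for subject 1 (plus some inside lag)
  vis <- data.table::data.table(
    subject_id = c(rep(1L, 80L), 2L),
    visit_date = c(idx - 731L - seq_len(72L) * 10L,  # countable
                   idx - seq_len(8L) * 10L,          # inside lag, ignored
                   idx - 1000L))
  expect_warning(
    cov <- build_covariates(ms, com, vis, enroll, lag_days = 730L),
    "non-positive")
  cov <- data.table::as.data.table(cov)
  expect_identical(cov[subject_id == 1L, diabetes], 1L)
  expect_identical(cov[subject_id == 2L, diabetes], 0L)
  expect_identical(cov[subject_id == 3L, diabetes], 0L)
  ## 72 visits over ~120 months -> ~0.6 per month
  expect_lt(abs(cov[subject_id == 1L, visit_rate] - 0.6), 1e-3)
  expect_identical(cov[subject_id == 2L, visit_rate], 1 /
                     (as.numeric(2270) * 12 / 365.25))
  expect_true(is.na(cov[subject_id == 3L, visit_rate]))
})

test_that("prevalence columns equal exposure-matrix column means by group", {
  emr <- tiny_emr(seed = 19, n = 3000, classes = 10)
  reg <- plant_case_registry(emr, n_cases = 40, seed = 2)
  cases <- ascertain_cases(reg, emr$subjects)
  ms <- suppressWarnings(density_match(cases, emr$subjects, diagnoses = reg,
                                       ratio = 5, seed = 3,
                                       allow_short_sets = TRUE))
  em <- build_exposure_matrix(ms, emr$dispensing)
  is_case <- em$y == 1L
  for (j in seq_len(ncol(em$X))) {
    expect_identical(mean(em$X[is_case, j]),
                     sum(em$X[is_case, j]) / sum(is_case))
  }
  ## table 2 analogue consistency: recompute counts from the matrix
  shap <- matrix(1, 2, ncol(em$X), dimnames = list(NULL, colnames(em$X)))
  cons <- consensus_select(shap)
  t2 <- make_table2(em, cons)
  j <- match(t2$atc5[1], colnames(em$X))
  n_case <- sum(em$X[is_case, j] > 0)
  expect_match(t2$cases[1], paste0("^", n_case, " \\("))
})
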