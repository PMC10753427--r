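test_that("configuration invariants are enforced", {
  expect_error(sim_config(study_window = c("2020-01-01", "2001-01-01")),
               "end > start")
  expect_error(sim_config(baseline_annual_hazard = 0), "hazard")
  expect_error(sim_config(
    demographic_margins = modifyList(default_demographics(),
                                     list(sex = c(male = 0.7, female = 0.7)))),
    "sum to 1")
  expect_error(sim_config(n_drug_classes = 3,
                          planted_effects = data.frame(atc5 = "zzzzz99",
                                                       odds_ratio = 2)),
               "not in catalog")
  expect_error(sim_config(planted_effects = data.frame(atc5 = "c07aa05",
                                                       odds_ratio = -1)),
               "odds ratios")
  expect_error(
    sim_config(confounder_effects = list(gout = list(
      exposure_log_odds = 1, outcome_log_odds = 0.5, classes = "c07aa05"))),
    "comorbidity_prevalence")
})

test_that("an empty population generates empty tables without error", {
  cfg <- sim_config(n_population = 0)
  pop <- generate_population(cfg)
  expect_identical(nrow(pop$subjects), 0L)
  expect_identical(nrow(pop$visits), 0L)
  ev <- generate_dispensing(pop, cfg)
  expect_identical(nrow(ev), 0L)
  expect_identical(nrow(assign_outcomes(pop, ev, cfg)), 0L)
})

test_that("generation is a pure function of the seed", {
  cfg <- sim_config(seed = 31, n_population = 1500, n_drug_classes = 8)
  a <- simulate_emr(cfg)
  b <- simulate_emr(cfg)
  for (tab in c("subjects", "visits", "comorbidities", "dispensing",
                "diagnoses"))
    expect_identical(a[[tab]], b[[tab]])
  ## and the generator does not disturb the caller's RNG stream
  set.seed(99); x1 <- runif(1)
  set.seed(99); invisible(simulate_emr(cfg)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("demographic margins are recovered at the population scale", {
  cfg <- sim_config(seed = 5, n_population = 120000, n_drug_classes = 0)
  pop <- generate_population(cfg)
  expect_lt(abs(mean(pop$subjects$sex == "male") - 0.488), 0.01)
  expect_lt(abs(mean(pop$subjects$subpopulation == "secular_jewish") - 0.881),
            0.01)
  expect_true(all(pop$subjects$enrollment_start < pop$subjects$enrollment_end))
  ## comorbidity onsets inside enrollment
  cm <- merge(pop$comorbidities, pop$subjects, by = "subject_id")
  expect_true(all(cm$onset_date >= cm$enrollment_start &
                    cm$onset_date < cm$enrollment_end))
})

test_that("dispensing prevalence matches its logistic expectation", {
  ## 3.1% baseline, no confounding, n = 120,000: binomial tolerance +-0.005
  cfg <- sim_config(seed = 13, n_population = 120000, n_drug_classes = 3,
                    class_prevalence = c(0.031, 0, 0.2))
  pop <- generate_population(cfg)
  ev <- generate_dispensing(pop, cfg)
  prev <- sapply(cfg$catalog, function(cl)
    length(unique(ev[ev$atc5 == cl, ]$subject_id)) / cfg$n_population)
  expect_lt(abs(prev[[1]] - 0.031), 0.005)
  expect_identical(prev[[2]], 0)            # zero prevalence -> zero events
  ## all dispensing dates inside the subject's enrollment
  j <- merge(ev, pop$subjects, by = "subject_id")
  expect_true(all(j$dispense_date >= j$enrollment_start &
                    j$dispense_date < j$enrollment_end))
})

test_that("confounding by indication shifts exposure by the logistic closed form", {
  cfg <- sim_config(
    seed = 17, n_population = 60000, n_drug_classes = 2,
    class_prevalence = c(0.05, 0.02),
    comorbidity_prevalence = c(diabetes = 0.3),
    confounder_effects = list(diabetes = list(
      exposure_log_odds = 1.0, outcome_log_odds = 0,
      classes = "c07aa05")))
  pop <- generate_population(cfg)
  ev <- generate_dispensing(pop, cfg)
  diab <- unique(pop$comorbidities$subject_id)
  users <- unique(ev[ev$atc5 == "c07aa05", ]$subject_id)
  p_comorb <- mean(diab %in% users)
  expected <- plogis(qlogis(0.05) + 1.0)
  n_comorb <- length(diab)
  tol <- 3 * sqrt(expected * (1 - expected) / n_comorb)
  expect_lt(abs(p_comorb - expected), tol)
  ## unaffected class stays at baseline among the comorbid
  users2 <- unique(ev[ev$atc5 == "n05cm09", ]$subject_id)
  p2 <- mean(diab %in% users2)
  expect_lt(abs(p2 - 0.02), 3 * sqrt(0.02 * 0.98 / n_comorb))
})

test_that("the null outcome model carries no exposure signal", {
  cfg <- sim_config(seed = 23, n_population = 120000, n_drug_classes = 1,
                    class_prevalence = 0.1,
                    baseline_annual_hazard = 1e-3,
                    planted_effects = data.frame(atc5 = "c07aa05",
                                                 odds_ratio = 1))
  pop <- generate_population(cfg)
  ev <- generate_dispensing(pop, cfg)
  dg <- assign_outcomes(pop, ev, cfg)
  cases <- dg[dg$condition == "crc", ]$subject_id
  users <- unique(ev$subject_id)
  p_case <- mean(cases %in% users)
  p_pop <- length(users) / cfg$n_population
  z <- (p_case - p_pop) /
    sqrt(p_pop * (1 - p_pop) * (1 / length(cases) + 1 / cfg$n_population))
  expect_lt(abs(z), qnorm(0.995))
})

test_that("doubling the baseline hazard doubles case counts within Poisson tolerance", {
  base <- sim_config(seed = 29, n_population = 50000, n_drug_classes = 0,
                     baseline_annual_hazard = 2e-4)
  doubled <- sim_config(seed = 29, n_population = 50000, n_drug_classes = 0,
                        baseline_annual_hazard = 4e-4)
  n1 <- sum(simulate_emr(base)$diagnoses$condition == "crc")
  n2 <- sum(simulate_emr(doubled)$diagnoses$condition == "crc")
  ## ratio test: n2 ~ 2 * n1, tolerance 4 combined Poisson SDs
  expect_lt(abs(n2 - 2 * n1), 4 * sqrt(n2 + 4 * n1))
  expect_error(
    simulate_emr(sim_config(seed = 1, n_population = 100,
                            n_drug_classes = 1, class_prevalence = 0.5,
                            baseline_annual_hazard = 0.9,
                            planted_effects = data.frame(
                              atc5 = "c07aa05", odds_ratio = 10))),
    "probability >= 1")
})

test_that("matched-set simulator plants the exact conditional odds ratio", {
  prev <- c(drugA = 0.2, drugB = 0.05)
  em <- simulate_matched_sets(500, 10, prev,
                              planted = data.frame(atc5 = "drugA",
                                                   odds_ratio = 3),
                              seed = 3)
  expect_s3_class(em, "medscreen_exposure")
  expect_identical(dim(em$X), c(500L * 11L, 2L))
  expect_identical(sum(em$y), 500L)
  ## control exposure at control prevalence; case exposure at the shifted one
  p_ctrl <- mean(em$X[em$y == 0, "drugA"])
  p_case <- mean(em$X[em$y == 1, "drugA"])
  expect_lt(abs(p_ctrl - 0.2), 3 * sqrt(0.2 * 0.8 / 5000))
  p1 <- plogis(qlogis(0.2) + log(3))
  expect_lt(abs(p_case - p1), 3 * sqrt(p1 * (1 - p1) / 500))
  ## identical seeds reproduce, unknown classes refused
  em2 <- simulate_matched_sets(500, 10, prev,
                               planted = data.frame(atc5 = "drugA",
                                                    odds_ratio = 3),
                               seed = 3)
  expect_identical(as.matrix(em$X), as.matrix(em2$X))
  expect_error(simulate_matched_sets(10, 2, prev,
                                     planted = data.frame(atc5 = "nope",
                                                          odds_ratio = 2)),
               "not in prevalence")
})

test_that("EMR tables round-trip through CSV", {
  emr <- tiny_emr(seed = 3, n = 800, classes = 5)
  dir <- withr::local_tempdir()
  write_emr_tables(emr, dir)
  back <- read_emr_tables(dir)
  expect_equal(as.data.frame(back$subjects), as.data.frame(emr$subjects))
  expect_equal(as.data.frame(back$dispensing), as.data.frame(emr$dispensing))
  expect_equal(as.data.frame(back$diagnoses), as.data.frame(emr$diagnoses))
})
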