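#' Generate the synthetic subject population
#'
#' Draws `cfg$n_population` subjects with demographics sampled independently
#' from `cfg$demographic_margins`, enrollment spans anchored a few years
#' before the study window (so long pre-index follow-up is common, as in a
#' mature EMR system), per-subject physician-visit rates from a Gamma
#' distribution, visit dates as a homogeneous Poisson stream over enrollment,
#' and chronic-condition onsets as independent Bernoulli draws with onset
#' dates uniform inside enrollment. Fully reproducible from `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return List with `data.table`s `subjects` (`subject_id`, matching keys,
#'   `birth_year`, `enrollment_start`, `enrollment_end`, `visit_rate`),
#'   `visits` (`subject_id`, `visit_date`) and `comorbidities`
#'   (`subject_id`, `condition`, `onset_date`).
#' @export
generate_population <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_population
  m <- cfg$demographic_margins
  empty <- function() list(
    subjects = data.table::data.table(
      subject_id = integer(0), sex = character(0), district = character(0),
      subpopulation = character(0), ses = integer(0), periphery = character(0),
      birth_year = integer(0), enrollment_start = as.Date(character(0)),
      enrollment_end = as.Date(character(0)), visit_rate = numeric(0)),
    visits = data.table::data.table(subject_id = integer(0),
                                    visit_date = as.Date(character(0))),
    comorbidities = data.table::data.table(
      subject_id = integer(0), condition = character(0),
      onset_date = as.Date(character(0))))
  if (n == 0L) return(empty())

  with_seed(cfg$seed, {
    win <- cfg$study_window
    subjects <- data.table::data.table(
      subject_id = seq_len(n),
      sex = sample_margin(n, m$sex),
      district = sample_margin(n, m$district),
      subpopulation = sample_margin(n, m$subpopulation),
      ses = as.integer(sample_margin(n, m$ses)),
      periphery = sample_margin(n, m$periphery),
      birth_year = as.integer(sample_margin(n, m$birth_year)))
    ## enrollment: start up to 6y before the window opens, small dropout rate
    start <- win[1] - 2190L + as.integer(floor(runif(n, 0, 2190 + 1095)))
    dropout <- runif(n) < 0.12
    end <- rep(win[2], n)
    gap <- as.numeric(win[2] - (start + 730L))
    end[dropout] <- start[dropout] + 730L +
      as.integer(floor(runif(sum(dropout)) * pmax(gap[dropout], 1)))
    subjects[, enrollment_start := start]
    subjects[, enrollment_end := pmin(end, win[2])]
    subjects[, visit_rate := rgamma(n, shape = cfg$visit_rate_shape,
                                    rate = cfg$visit_rate_shape /
                                      cfg$visit_rate_mean)]

    months <- as.numeric(subjects$enrollment_end -
                           subjects$enrollment_start) / DAYS_PER_MONTH
    n_vis <- rpois(n, subjects$visit_rate * months)
    vid <- rep(subjects$subject_id, n_vis)
    vstart <- rep(subjects$enrollment_start, n_vis)
    vspan <- rep(as.numeric(subjects$enrollment_end -
                              subjects$enrollment_start), n_vis)
    visits <- data.table::data.table(
      subject_id = vid,
      visit_date = vstart + as.integer(floor(runif(length(vid)) * vspan)))
    ## rows arrive grouped by subject; kept in generation order (sorting
    ## tens of millions of rows buys nothing downstream)

    com <- lapply(names(cfg$comorbidity_prevalence), function(cond) {
      hit <- runif(n) < cfg$comorbidity_prevalence[[cond]]
      idx <- which(hit)
      span <- as.numeric(subjects$enrollment_end[idx] -
                           subjects$enrollment_start[idx])
      data.table::data.table(
        subject_id = subjects$subject_id[idx],
        condition = cond,
        onset_date = subjects$enrollment_start[idx] +
          as.integer(floor(runif(length(idx)) * span)))
    })
    comorbidities <- data.table::rbindlist(com)
    data.table::setorder(comorbidities, subject_id, condition)
    list(subjects = subjects, visits = visits, comorbidities = comorbidities)
  })
}

#' Generate ATC level-5 dispensing events
#'
#' For every subject and drug class, ever-exposure is Bernoulli with
#' `logit(p) = logit(baseline prevalence) + sum of exposure log-odds` over the
#' comorbid conditions for which the class is indicated (confounding by
#' indication). Ever-exposed subjects receive one dispensing at a date uniform
#' over their enrollment and, with probability `cfg$recent_event_prob`, an
#' additional dispensing inside the final two years of enrollment so that
#' downstream lag filtering is exercised.
#'
#' @param population Result of [generate_population()].
#' @param cfg The same [sim_config()].
#' @return `data.table` with `subject_id`, `atc5`, `dispense_date`.
#' @export
generate_dispensing <- function(population, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  subjects <- population$subjects
  n <- nrow(subjects)
  if (n == 0L || cfg$n_drug_classes == 0L)
    return(data.table::data.table(subject_id = integer(0),
                                  atc5 = character(0),
                                  dispense_date = as.Date(character(0))))

  ## per-condition comorbidity indicator vectors (any onset during enrollment)
  has_cond <- lapply(names(cfg$confounder_effects), function(cond) {
    ids <- population$comorbidities[condition == cond, subject_id]
    subjects$subject_id %in% ids
  })
  names(has_cond) <- names(cfg$confounder_effects)

  ## map: class -> total exposure log-odds shift vector (lazily built)
  shift_for_class <- function(code) {
    shift <- NULL
    for (cond in names(cfg$confounder_effects)) {
      ce <- cfg$confounder_effects[[cond]]
      if (code %in% ce$classes) {
        if (is.null(shift)) shift <- numeric(n)
        shift <- shift + ce$exposure_log_odds * has_cond[[cond]]
      }
    }
    shift
  }

  span <- as.numeric(subjects$enrollment_end - subjects$enrollment_start)
  with_seed(cfg$seed + 1L, {
    out <- vector("list", cfg$n_drug_classes)
    for (j in seq_len(cfg$n_drug_classes)) {
      code <- cfg$catalog[j]
      p0 <- cfg$class_prevalence[[j]]
      shift <- shift_for_class(code)
      p <- if (is.null(shift)) rep(p0, n) else plogis(qlogis(p0) + shift)
      exposed <- which(runif(n) < p)
      if (!length(exposed)) next
      d1 <- subjects$enrollment_start[exposed] +
        as.integer(floor(runif(length(exposed)) * span[exposed]))
      extra <- runif(length(exposed)) < cfg$recent_event_prob
      idx2 <- exposed[extra]
      lo <- pmax(as.numeric(subjects$enrollment_end[idx2] - 730L),
                 as.numeric(subjects$enrollment_start[idx2]))
      d2 <- as.Date(lo + floor(runif(length(idx2)) *
                                 (as.numeric(subjects$enrollment_end[idx2]) - lo)),
                    origin = "1970-01-01")
      out[[j]] <- data.table::data.table(
        subject_id = c(subjects$subject_id[exposed], subjects$subject_id[idx2]),
        atc5 = code,
        dispense_date = c(d1, d2))
    }
    events <- data.table::rbindlist(out)
    if (nrow(events)) data.table::setorder(events, subject_id, atc5,
                                           dispense_date)
    events[]
  })
}

#' Assign outcomes under a discrete annual-hazard model
#'
#' Walks the study window year by year. For each subject at risk (enrolled,
#' not yet diagnosed) the probability of a first colorectal-cancer diagnosis
#' in year `t` is
#' `baseline_annual_hazard * exp(sum planted log-OR * exposed_before(t - 2y)
#'  + sum outcome log-odds over comorbidities with onset before t)`,
#' where `exposed_before` means a dispensing of the planted class strictly
#' before the start of year `t` minus the 2-year lag. In the rare-disease
#' regime (default hazard 1e-4/year) the conditional odds ratios recovered
#' downstream approximate the planted hazard ratios. IBD and
#' hereditary-syndrome flags are assigned independently at the configured
#' rates to exercise exclusion rules.
#'
#' @param population Result of [generate_population()].
#' @param events Result of [generate_dispensing()].
#' @param cfg The same [sim_config()].
#' @param lag_days Exposure lag used by the hazard model (default 730).
#' @return `data.table` with `subject_id`, `condition`
#'   (`"crc"`, `"ibd"`, `"hereditary"`), `diagnosis_date`.
#' @export
assign_outcomes <- function(population, events, cfg, lag_days = 730L) {
  stopifnot(inherits(cfg, "sim_config"))
  subjects <- population$subjects
  n <- nrow(subjects)
  empty <- data.table::data.table(subject_id = integer(0),
                                  condition = character(0),
                                  diagnosis_date = as.Date(character(0)))
  if (n == 0L) return(empty)

  planted <- cfg$planted_effects
  ## first dispensing date per (subject, planted class)
  first_ev <- list()
  if (nrow(planted) && nrow(events)) {
    fe <- events[atc5 %in% planted$atc5,
                 .(first_date = min(dispense_date)), by = .(subject_id, atc5)]
    for (code in planted$atc5) {
      v <- rep(as.Date(NA), n)
      sub <- fe[atc5 == code]
      v[match(sub$subject_id, subjects$subject_id)] <- sub$first_date
      first_ev[[code]] <- v
    }
  }
  onset <- list()
  for (cond in names(cfg$confounder_effects)) {
    v <- rep(as.Date(NA), n)
    sub <- population$comorbidities[condition == cond]
    v[match(sub$subject_id, subjects$subject_id)] <- sub$onset_date
    onset[[cond]] <- v
  }

  win <- cfg$study_window
  years <- seq(as.integer(format(win[1], "%Y")),
               as.integer(format(win[2], "%Y")) - 1L)
  log_h0 <- log(cfg$baseline_annual_hazard)

  with_seed(cfg$seed + 2L, {
    diagnosed <- rep(FALSE, n)
    diag_date <- rep(as.Date(NA), n)
    for (yy in years) {
      ys <- as.Date(sprintf("%d-01-01", yy))
      ye <- as.Date(sprintf("%d-01-01", yy + 1L))
      at_risk <- which(!diagnosed &
                         subjects$enrollment_start <= ys &
                         subjects$enrollment_end > ys)
      if (!length(at_risk)) next
      lp <- rep(log_h0, length(at_risk))
      cutoff <- ys - lag_days
      for (k in seq_len(nrow(planted))) {
        code <- planted$atc5[k]
        fd <- first_ev[[code]][at_risk]
        lp <- lp + log(planted$odds_ratio[k]) *
          (!is.na(fd) & fd < cutoff)
      }
      for (cond in names(cfg$confounder_effects)) {
        od <- onset[[cond]][at_risk]
        lp <- lp + cfg$confounder_effects[[cond]]$outcome_log_odds *
          (!is.na(od) & od < ys)
      }
      haz <- exp(lp)
      if (any(haz >= 1))
        stop("annual outcome probability >= 1; reduce baseline hazard or ",
             "planted effects", call. = FALSE)
      hit <- at_risk[runif(length(at_risk)) < haz]
      if (length(hit)) {
        lim <- pmin(as.numeric(ye), as.numeric(subjects$enrollment_end[hit]))
        dd <- as.Date(as.numeric(ys) +
                        floor(runif(length(hit)) * pmax(lim - as.numeric(ys), 1)),
                      origin = "1970-01-01")
        diagnosed[hit] <- TRUE
        diag_date[hit] <- dd
      }
    }
    crc <- data.table::data.table(
      subject_id = subjects$subject_id[diagnosed],
      condition = "crc",
      diagnosis_date = diag_date[diagnosed])

    flag_tab <- function(rate, condname) {
      idx <- which(runif(n) < rate)
      span <- as.numeric(subjects$enrollment_end[idx] -
                           subjects$enrollment_start[idx])
      data.table::data.table(
        subject_id = subjects$subject_id[idx],
        condition = condname,
        diagnosis_date = subjects$enrollment_start[idx] +
          as.integer(floor(runif(length(idx)) * span)))
    }
    out <- data.table::rbindlist(list(crc,
                                      flag_tab(cfg$ibd_rate, "ibd"),
                                      flag_tab(cfg$hereditary_rate,
                                               "hereditary")))
    data.table::setorder(out, subject_id, condition)
    out[]
  })
}

#' Plant a case registry with known counts
#'
#' Constructs a diagnosis table containing exactly `n_cases` first
#' colorectal-cancer diagnoses inside the study window at index age
#' `<= max_age`, of which `n_short_enrollment` are deliberately given an index
#' date less than `min_years` after enrollment start (so the enrollment filter
#' removes exactly that many), and `n_flagged` of the fully enrolled cases
#' carry an IBD flag. Used to exercise ascertainment, exclusion and matching
#' with known ground truth; `min_risk_set` restricts planted cases to subjects
#' whose exact matching cell contains at least that many eligible control
#' candidates at the index date, guaranteeing the risk-set support that 1:M
#' matching assumes.
#'
#' @param population Result of [generate_population()].
#' @param n_cases Total planted cases.
#' @param window Study window (half-open date pair).
#' @param max_age Maximum index age in years (index year minus birth year).
#' @param n_short_enrollment How many cases get `< min_years` pre-index
#'   enrollment.
#' @param n_flagged How many fully enrolled cases get an IBD flag.
#' @param min_years Enrollment requirement the "short" cases must violate.
#' @param min_risk_set Minimum number of exact-key eligible control
#'   candidates required at the case's index date (0 = no check).
#' @param birth_tol Birth-year tolerance used in the risk-set count.
#' @param seed Integer seed.
#' @return `data.table` in the shape of [assign_outcomes()] output.
#' @export
plant_case_registry <- function(population, n_cases,
                                window = c("2001-01-01", "2020-01-01"),
                                max_age = 50L,
                                n_short_enrollment = 0L,
                                n_flagged = 0L,
                                min_years = 3L,
                                min_risk_set = 0L,
                                birth_tol = 2L,
                                seed = 1L) {
  subjects <- population$subjects
  win <- as_date(window)
  min_days <- as.integer(round(min_years * 365.25))
  stopifnot(n_short_enrollment <= n_cases, n_flagged <= n_cases -
              n_short_enrollment)

  ## feasible index interval per subject, [lo, hi)
  age_cap <- as.Date(sprintf("%d-01-01", subjects$birth_year + max_age + 1L))
  hi <- pmin(win[2], subjects$enrollment_end, age_cap)
  lo_long <- pmax(win[1], subjects$enrollment_start + min_days)
  lo_short <- pmax(win[1], subjects$enrollment_start)
  hi_short <- pmin(hi, subjects$enrollment_start + min_days)

  draw_group <- function(cand, lo, hi, n_needed, check_pool) {
    ok <- cand[as.numeric(hi[cand] - lo[cand]) > 0]
    if (length(ok) < n_needed)
      stop("population cannot support ", n_needed, " planted cases",
           call. = FALSE)
    pick <- ok[sample.int(length(ok),
                          min(length(ok), max(n_needed * 3L, n_needed + 20L)))]
    idx <- lo[pick] + as.integer(floor(runif(length(pick)) *
                                         as.numeric(hi[pick] - lo[pick])))
    if (check_pool && min_risk_set > 0L) {
      cand_dt <- data.table::data.table(
        row = pick, index_date = idx,
        sex = subjects$sex[pick], district = subjects$district[pick],
        subpopulation = subjects$subpopulation[pick],
        ses = subjects$ses[pick], periphery = subjects$periphery[pick],
        birth_year = subjects$birth_year[pick])
      pool <- subjects[, .(subject_id, sex, district, subpopulation, ses,
                           periphery, birth_year, enrollment_start,
                           enrollment_end)]
      joined <- pool[cand_dt, on = .(sex, district, subpopulation, ses,
                                     periphery),
                     allow.cartesian = TRUE, nomatch = NULL]
      joined <- joined[abs(birth_year - i.birth_year) <= birth_tol &
                         enrollment_start <= index_date - min_days &
                         enrollment_end > index_date &
                         subject_id != subjects$subject_id[row]]
      cnt <- joined[, .N, by = row]
      keep <- cnt[N >= min_risk_set, row]
      sel <- which(pick %in% keep)
    } else sel <- seq_along(pick)
    if (length(sel) < n_needed)
      stop("fewer than ", n_needed, " planted cases satisfy the risk-set ",
           "guard; enlarge the population or lower min_risk_set",
           call. = FALSE)
    sel <- sel[seq_len(n_needed)]
    list(row = pick[sel], index_date = idx[sel])
  }

  with_seed(seed, {
    all_rows <- seq_len(nrow(subjects))
    long <- draw_group(all_rows, lo_long, hi, n_cases - n_short_enrollment,
                       check_pool = TRUE)
    short_cand <- setdiff(all_rows, long$row)
    if (n_short_enrollment > 0L) {
      short <- draw_group(short_cand, lo_short, hi_short, n_short_enrollment,
                          check_pool = FALSE)
    } else short <- list(row = integer(0), index_date = as.Date(character(0)))

    crc <- data.table::data.table(
      subject_id = subjects$subject_id[c(long$row, short$row)],
      condition = "crc",
      diagnosis_date = c(long$index_date, short$index_date))
    flagged <- if (n_flagged > 0L) {
      rows <- long$row[sample.int(length(long$row), n_flagged)]
      data.table::data.table(
        subject_id = subjects$subject_id[rows],
        condition = "ibd",
        diagnosis_date = subjects$enrollment_start[rows] + 30L)
    } else NULL
    out <- data.table::rbindlist(c(list(crc), list(flagged)),
                                 use.names = TRUE, fill = TRUE)
    data.table::setorder(out, subject_id, condition)
    out[]
  })
}

#' Simulate a complete synthetic EMR
#'
#' Convenience wrapper running [generate_population()],
#' [generate_dispensing()] and [assign_outcomes()] under one configuration.
#'
#' @param cfg A [sim_config()].
#' @return List with `subjects`, `visits`, `comorbidities`, `dispensing`,
#'   `diagnoses` and the `config` used.
#' @export
simulate_emr <- function(cfg) {
  population <- generate_population(cfg)
  dispensing <- generate_dispensing(population, cfg)
  diagnoses <- assign_outcomes(population, dispensing, cfg)
  c(population, list(dispensing = dispensing, diagnoses = diagnoses,
                     config = cfg))
}

#' Write / read the synthetic EMR tables as CSV
#'
#' Schema: `subjects.csv` (demographics, enrollment span, visit rate),
#' `visits.csv` (`subject_id`, `visit_date`), `comorbidities.csv`
#' (`subject_id`, `condition`, `onset_date`), `dispensing.csv`
#' (`subject_id`, `atc5`, `dispense_date`), `diagnoses.csv`
#' (`subject_id`, `condition`, `diagnosis_date`). Dates are ISO-8601.
#'
#' @param emr Result of [simulate_emr()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly (for `write_emr_tables`); the table list (for
#'   `read_emr_tables`).
#' @export
write_emr_tables <- function(emr, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  data.table::fwrite(emr$subjects, file.path(dir, "subjects.csv"))
  data.table::fwrite(emr$visits, file.path(dir, "visits.csv"))
  data.table::fwrite(emr$comorbidities, file.path(dir, "comorbidities.csv"))
  data.table::fwrite(emr$dispensing, file.path(dir, "dispensing.csv"))
  data.table::fwrite(emr$diagnoses, file.path(dir, "diagnoses.csv"))
  invisible(dir)
}

#' @rdname write_emr_tables
#' @export
read_emr_tables <- function(dir) {
  rd <- function(f, datecols) {
    dt <- data.table::fread(file.path(dir, f))
    for (cc in intersect(datecols, names(dt)))
      data.table::set(dt, j = cc, value = as_date(dt[[cc]]))
    dt
  }
  list(
    subjects = rd("subjects.csv", c("enrollment_start", "enrollment_end")),
    visits = rd("visits.csv", "visit_date"),
    comorbidities = rd("comorbidities.csv", "onset_date"),
    dispensing = rd("dispensing.csv", "dispense_date"),
    diagnoses = rd("diagnoses.csv", "diagnosis_date"))
}
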