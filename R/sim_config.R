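#' Default demographic margins for the synthetic population
#'
#' Categorical distributions used by [generate_population()]. The sex,
#' residential-district and subpopulation margins follow the composition of a
#' large Israeli health-provider membership (roughly 49% male; five districts;
#' 88% secular Jewish, 7% Ultra-Orthodox, 5% Israeli Arab). Socioeconomic
#' status (SES) is a 10-band score centred at 6.5 (SD 1.9); the periphery
#' index (proximity to a large urban centre) uses three bands; birth years are
#' approximately normal around 1967 so that index ages concentrate near 44.
#'
#' @return Named list of named probability vectors (`sex`, `district`,
#'   `subpopulation`, `ses`, `periphery`, `birth_year`).
#' @export
default_demographics <- function() {
  ses_p <- stats::dnorm(1:10, mean = 6.5, sd = 1.9)
  yrs <- 1945:1995
  by_p <- stats::dnorm(yrs, mean = 1967, sd = 8)
  list(
    sex = c(male = 0.488, female = 0.512),
    district = c(north = 0.187, center = 0.194, jerusalem = 0.224,
                 sharon = 0.225, south = 0.170),
    subpopulation = c(secular_jewish = 0.881, ultra_orthodox = 0.068,
                      israeli_arab = 0.051),
    ses = setNames(ses_p / sum(ses_p), as.character(1:10)),
    periphery = c(core = 0.45, intermediate = 0.35, peripheral = 0.20),
    birth_year = setNames(by_p / sum(by_p), as.character(yrs))
  )
}

#' Generate an ATC level-5 drug-class catalog
#'
#' Produces `n` distinct 7-character lower-case codes in the ATC level-5
#' dialect (`letter, 2 digits, 2 letters, 2 digits`, e.g. `"c07aa05"`). The
#' catalog opens with a fixed panel of real level-5 codes commonly seen in
#' primary-care dispensing data (propranolol `c07aa05`, valerian `n05cm09`,
#' paroxetine `n06ab05`, enalapril `c09aa02`, simvastatin `c10aa01`, ...) so
#' that planted effects can use recognisable identifiers; the remainder are
#' synthetic codes drawn reproducibly from `seed`.
#'
#' @param n Number of classes.
#' @param seed Integer seed for the synthetic tail of the catalog.
#' @return Character vector of `n` distinct codes.
#' @export
make_atc_catalog <- function(n, seed = 1L) {
  known <- c("c07aa05", "n05cm09", "n06ab05", "c09aa02", "c10aa01",
             "a10ba02", "d04aa13", "s01ca01", "d07ac13", "d11ax18",
             "a02ba03", "s01aa01", "j01ce02", "r01ba52", "b03ad01",
             "g01aa10", "r03ac03")
  if (n <= length(known)) return(known[seq_len(n)])
  with_seed(seed, {
    codes <- known
    anat <- c("a", "b", "c", "d", "g", "h", "j", "l", "m", "n",
              "p", "r", "s", "v")
    while (length(codes) < n) {
      need <- n - length(codes)
      new <- paste0(
        sample(anat, need, TRUE),
        sprintf("%02d", sample.int(16L, need, TRUE)),
        sample(letters[1:24], need, TRUE),
        sample(letters[1:24], need, TRUE),
        sprintf("%02d", sample.int(60L, need, TRUE)))
      codes <- unique(c(codes, new))
    }
    codes[seq_len(n)]
  })
}

#' Configuration for the synthetic EMR generator
#'
#' Bundles every parameter of the generative model behind the synthetic
#' dispensing data: population size, study window, drug-class catalog with
#' per-class baseline ever-exposure prevalence, planted conditional odds
#' ratios, confounding-by-indication effects, the annual outcome hazard, and
#' demographic margins. All randomness downstream is a pure function of
#' `seed`.
#'
#' @param seed Integer master seed.
#' @param n_population Number of subjects (default 120,000).
#' @param study_window Character/Date length-2; half-open `[start, end)`
#'   calendar window for case ascertainment (default 2001-01-01 to
#'   2020-01-01).
#' @param n_drug_classes Number of ATC level-5 classes (default 800).
#' @param prevalence_range Range of the log-uniform baseline per-class
#'   ever-exposure probability (default `c(5e-4, 0.35)`), emulating the heavy
#'   right skew of real dispensing prevalence.
#' @param class_prevalence Optional explicit numeric vector (length
#'   `n_drug_classes`) of baseline prevalences; overrides `prevalence_range`.
#' @param planted_effects `data.frame`/`data.table` with columns `atc5` and
#'   `odds_ratio`: classes whose ever-exposure multiplies the outcome hazard
#'   (conditional odds ratio in the rare-disease regime). Default: none.
#' @param confounder_effects Named list, one element per comorbid condition,
#'   each a list with `exposure_log_odds` (added to the exposure logit of the
#'   classes in `classes` for comorbid subjects), `outcome_log_odds` (added to
#'   the log hazard), and `classes` (character vector of ATC codes treated as
#'   indicated for the condition). Default: empty (no confounding).
#' @param baseline_annual_hazard Outcome probability per person-year for an
#'   unexposed subject without comorbidities (default `1e-4`; the rare-disease
#'   regime in which conditional odds ratios approximate hazard ratios).
#' @param comorbidity_prevalence Named lifetime-prevalence vector for the
#'   chronic conditions carried by the generator (defaults: diabetes 4%,
#'   hypertension 8%, cardiovascular 3%, excess_weight 12%).
#' @param ibd_rate,hereditary_rate Rates of IBD / suspected hereditary cancer
#'   syndrome flags, assigned independently to exercise exclusion rules.
#' @param visit_rate_mean,visit_rate_shape Gamma distribution of per-subject
#'   expected physician visits per month (mean 0.6/month, i.e. 7.2/year).
#' @param recent_event_prob Probability that an ever-exposed subject receives
#'   an additional dispensing inside the final two years of enrollment, so
#'   that lag filtering has events to remove (default 0.3).
#' @param demographic_margins As returned by [default_demographics()].
#' @return Object of class `sim_config`.
#' @seealso [generate_population()], [generate_dispensing()],
#'   [assign_outcomes()], [simulate_emr()]
#' @export
sim_config <- function(seed = 1L,
                       n_population = 120000L,
                       study_window = c("2001-01-01", "2020-01-01"),
                       n_drug_classes = 800L,
                       prevalence_range = c(5e-4, 0.35),
                       class_prevalence = NULL,
                       planted_effects = NULL,
                       confounder_effects = list(),
                       baseline_annual_hazard = 1e-4,
                       comorbidity_prevalence = c(diabetes = 0.04,
                                                  hypertension = 0.08,
                                                  cardiovascular = 0.03,
                                                  excess_weight = 0.12),
                       ibd_rate = 0.01,
                       hereditary_rate = 0.005,
                       visit_rate_mean = 0.6,
                       visit_rate_shape = 1.44,
                       recent_event_prob = 0.3,
                       demographic_margins = default_demographics()) {
  seed <- as.integer(seed)
  n_population <- as.integer(n_population)
  n_drug_classes <- as.integer(n_drug_classes)
  stopifnot(length(seed) == 1L, !is.na(seed),
            n_population >= 0L, n_drug_classes >= 0L)
  window <- as_date(study_window)
  if (length(window) != 2L || !(window[2] > window[1]))
    stop("study_window must be two dates with end > start", call. = FALSE)
  if (baseline_annual_hazard <= 0 || baseline_annual_hazard >= 1)
    stop("baseline_annual_hazard must lie in (0, 1)", call. = FALSE)
  for (nm in names(demographic_margins))
    check_margin(demographic_margins[[nm]], nm, tol = 0.01)
  if (any(comorbidity_prevalence < 0 | comorbidity_prevalence >= 1))
    stop("comorbidity prevalences must lie in [0, 1)", call. = FALSE)

  catalog <- make_atc_catalog(n_drug_classes, seed)
  if (is.null(class_prevalence)) {
    class_prevalence <- with_seed(seed + 104729L, {
      exp(runif(n_drug_classes, log(prevalence_range[1]),
                log(prevalence_range[2])))
    })
  }
  if (length(class_prevalence) != n_drug_classes)
    stop("class_prevalence must have length n_drug_classes", call. = FALSE)
  if (any(class_prevalence < 0 | class_prevalence >= 1))
    stop("class prevalences must lie in [0, 1)", call. = FALSE)
  names(class_prevalence) <- catalog

  if (is.null(planted_effects)) {
    planted_effects <- data.table::data.table(atc5 = character(0),
                                              odds_ratio = numeric(0))
  } else {
    planted_effects <- data.table::as.data.table(planted_effects)
    if (!all(c("atc5", "odds_ratio") %in% names(planted_effects)))
      stop("planted_effects needs columns atc5 and odds_ratio", call. = FALSE)
    if (any(planted_effects$odds_ratio <= 0))
      stop("planted odds ratios must be > 0", call. = FALSE)
    bad <- setdiff(planted_effects$atc5, catalog)
    if (length(bad))
      stop("planted class not in catalog: ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  if (nrow(planted_effects) > n_drug_classes)
    stop("more planted effects than drug classes", call. = FALSE)

  for (nm in names(confounder_effects)) {
    ce <- confounder_effects[[nm]]
    if (!all(c("exposure_log_odds", "outcome_log_odds", "classes") %in%
             names(ce)))
      stop("confounder_effects[['", nm, "']] needs exposure_log_odds, ",
           "outcome_log_odds, classes", call. = FALSE)
    bad <- setdiff(ce$classes, catalog)
    if (length(bad))
      stop("confounder class not in catalog: ", paste(bad, collapse = ", "),
           call. = FALSE)
    if (!nm %in% names(comorbidity_prevalence))
      stop("confounder '", nm, "' has no entry in comorbidity_prevalence",
           call. = FALSE)
  }

  structure(list(
    seed = seed,
    n_population = n_population,
    study_window = window,
    n_drug_classes = n_drug_classes,
    catalog = catalog,
    class_prevalence = class_prevalence,
    planted_effects = planted_effects,
    confounder_effects = confounder_effects,
    baseline_annual_hazard = baseline_annual_hazard,
    comorbidity_prevalence = comorbidity_prevalence,
    ibd_rate = ibd_rate,
    hereditary_rate = hereditary_rate,
    visit_rate_mean = visit_rate_mean,
    visit_rate_shape = visit_rate_shape,
    recent_event_prob = recent_event_prob,
    demographic_margins = demographic_margins
  ), class = "sim_config")
}

#' @exportS3Method base::print
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  seed:", x$seed, " population:", x$n_population,
      " classes:", x$n_drug_classes, "\n")
  cat("  window: [", format(x$study_window[1]), ",",
      format(x$study_window[2]), ")\n")
  cat("  baseline annual hazard:", format(x$baseline_annual_hazard), "\n")
  cat("  planted effects:", nrow(x$planted_effects),
      " confounders:", length(x$confounder_effects), "\n")
  invisible(x)
}
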