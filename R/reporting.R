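fmt_pct <- function(n, total) sprintf("%d (%.1f)", n, 100 * n / total)
fmt_mean_sd <- function(x, digits = 1)
  sprintf(paste0("%.", digits, "f (%.", digits, "f)"),
          mean(x, na.rm = TRUE), sd(x, na.rm = TRUE))

#' Demographic table for the matched cohort
#'
#' Case and control columns for the matched keys (counts and percentages for
#' sex, subpopulation and district; mean (SD) for the SES band) plus index
#' age, pre-index follow-up in weeks and, when visits are supplied, the
#' yearly physician-visit rate. Matched keys are balanced by construction, so
#' their case and control percentage columns coincide.
#'
#' @param matched_sets Output of [density_match()].
#' @param subjects Subject table.
#' @param visits Optional visit table for the yearly visit-rate row.
#' @return `data.table` with `variable`, `level`, `cases`, `controls`
#'   (formatted strings).
#' @export
make_table1 <- function(matched_sets, subjects, visits = NULL) {
  ms <- data.table::as.data.table(matched_sets)
  dt <- data.table::as.data.table(subjects)[ms, on = "subject_id"]
  dt[, age_at_index := as.integer(format(index_date, "%Y")) - birth_year]
  dt[, followup_weeks := as.numeric(index_date - enrollment_start) / 7]
  if (!is.null(visits)) {
    vv <- data.table::as.data.table(visits)[
      dt[, .(subject_id, set_id, index_date)], on = "subject_id",
      allow.cartesian = TRUE, nomatch = NULL][
        visit_date < index_date, .(n_visits = .N), by = .(set_id, subject_id)]
    dt <- vv[dt, on = c("set_id", "subject_id")]
    dt[is.na(n_visits), n_visits := 0L]
    dt[, yearly_visits := n_visits / (followup_weeks / 52.18)]
  }
  rows <- list()
  n_by_role <- dt[, .N, by = role]
  ntot <- setNames(n_by_role$N, n_by_role$role)
  cat_row <- function(var) {
    tab <- dt[, .N, by = c("role", var)]
    data.table::setnames(tab, var, "level")
    wide <- data.table::dcast(tab, level ~ role, value.var = "N", fill = 0L)
    if (!"case" %in% names(wide)) wide[, case := 0L]
    if (!"control" %in% names(wide)) wide[, control := 0L]
    wide[, .(variable = var, level = as.character(level),
             cases = fmt_pct(case, ntot[["case"]]),
             controls = fmt_pct(control, ntot[["control"]]))]
  }
  rows$n <- data.table::data.table(
    variable = "n", level = "",
    cases = as.character(ntot[["case"]]),
    controls = as.character(ntot[["control"]]))
  for (v in c("sex", "subpopulation", "district")) rows[[v]] <- cat_row(v)
  num_row <- function(var, label, digits = 1) data.table::data.table(
    variable = label, level = "mean (SD)",
    cases = fmt_mean_sd(dt[role == "case"][[var]], digits),
    controls = fmt_mean_sd(dt[role == "control"][[var]], digits))
  rows$ses <- num_row("ses", "ses_band")
  rows$fu <- num_row("followup_weeks", "followup_weeks", 0)
  rows$age <- num_row("age_at_index", "age_at_index")
  if (!is.null(visits)) rows$visits <- num_row("yearly_visits",
                                               "yearly_physician_visits")
  data.table::rbindlist(rows)[]
}

#' Prevalence-and-consensus table for screened medications
#'
#' For the consensus-selected classes: user counts and percentages among
#' cases and controls (column means of the lagged exposure matrix split by
#' case status), the percentage of runs in which the class had positive
#' global Shapley importance, and the percentage of runs in which it reached
#' the top 2.5% of the run's importance distribution.
#'
#' @param exposure The (filtered) `medscreen_exposure`.
#' @param consensus Output of [consensus_select()] carrying `top_q_rate`
#'   (present when built from a `screen_result`).
#' @param selected_only Keep only selected classes (default `TRUE`).
#' @return `data.table` sorted by descending association rate.
#' @export
make_table2 <- function(exposure, consensus, selected_only = TRUE) {
  cs <- data.table::as.data.table(consensus)
  if (selected_only) cs <- cs[selected == TRUE]
  if (!nrow(cs))
    return(data.table::data.table(
      atc5 = character(0), cases = character(0), controls = character(0),
      pct_runs_associated = numeric(0), pct_runs_top = numeric(0)))
  is_case <- exposure$y == 1L
  keep <- match(cs$feature, colnames(exposure$X))
  n_case <- Matrix::colSums(exposure$X[is_case, keep, drop = FALSE] > 0)
  n_ctrl <- Matrix::colSums(exposure$X[!is_case, keep, drop = FALSE] > 0)
  out <- data.table::data.table(
    atc5 = cs$feature,
    cases = fmt_pct(as.integer(n_case), sum(is_case)),
    controls = fmt_pct(as.integer(n_ctrl), sum(!is_case)),
    pct_runs_associated = round(100 * cs$association_rate, 1))
  if ("top_q_rate" %in% names(cs))
    out[, pct_runs_top := round(100 * cs$top_q_rate, 1)]
  data.table::setorder(out, -pct_runs_associated, atc5)
  out[]
}

#' Odds-ratio table
#'
#' The effect estimates formatted as in an epidemiologic report: OR and 95%
#' CI to two decimals, sorted by descending OR.
#'
#' @param effects A `medscreen_effects` table from
#'   [fit_conditional_logistic()] / [estimate_effects()].
#' @param drop_covariates Drop adjustment covariates from the display
#'   (default `TRUE`).
#' @return Formatted `data.table` (`atc5`, `odds_ratio`, `ci95`, `p`).
#' @export
make_table3 <- function(effects,
                        drop_covariates = TRUE) {
  if (is.null(effects) || !nrow(effects))
    return(data.table::data.table(atc5 = character(0),
                                  odds_ratio = character(0),
                                  ci95 = character(0), p = character(0)))
  eff <- data.table::as.data.table(effects)
  if (drop_covariates)
    eff <- eff[!feature %in% c("visit_rate", "diabetes", "hypertension",
                               "cardiovascular", "excess_weight")]
  data.table::setorder(eff, -or)
  eff[, .(atc5 = feature,
          odds_ratio = sprintf("%.2f", or),
          ci95 = sprintf("%.2f-%.2f", ci_low, ci_high),
          p = ifelse(p < 0.001, "<.001", sub("^0", "", sprintf("%.2f", p))))]
}

#' Assemble the three report tables
#'
#' @param matched_sets,subjects,visits See [make_table1()].
#' @param exposure,consensus See [make_table2()].
#' @param effects See [make_table3()].
#' @return List `table1`, `table2`, `table3`.
#' @export
make_tables <- function(matched_sets, subjects, exposure, consensus,
                        effects, visits = NULL) {
  list(table1 = make_table1(matched_sets, subjects, visits),
       table2 = make_table2(exposure, consensus),
       table3 = make_table3(effects))
}

#' Pipeline configuration
#'
#' Every stage parameter defaults to the study protocol value: 2-year
#' exposure lag, 1:10 matching with birth-year tolerance 2 and 3-year
#' enrollment, 0.1% rare-drug threshold, 50 screening runs with a 20%
#' holdout and 5-fold cross-validated Bayesian hyperparameter search, and
#' joint conditional-logistic adjustment for visit rate, diabetes,
#' cardiovascular disease and excess weight.
#'
#' @param sim A [sim_config()] used when no `data_dir` is given.
#' @param data_dir Optional directory of EMR tables
#'   (see [read_emr_tables()]).
#' @param out_dir Output directory.
#' @param lag_days,ratio,birth_tol,min_years,min_frac Stage parameters.
#' @param screening A [screening_config()].
#' @param adjust_for Covariates entering the regression.
#' @param allow_short_sets Tolerate risk sets smaller than `ratio` (logged
#'   warning, smaller set) instead of erroring.
#' @param seed Master seed for matching.
#' @param verbose Log stage progress.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), data_dir = NULL,
                            out_dir = tempfile("medscreen_out_"),
                            lag_days = 730L, ratio = 10L, birth_tol = 2L,
                            min_years = 3L, min_frac = 0.001,
                            screening = screening_config(),
                            adjust_for = c("visit_rate", "diabetes",
                                           "cardiovascular", "excess_weight"),
                            allow_short_sets = FALSE,
                            seed = 1L, verbose = TRUE) {
  structure(list(sim = sim, data_dir = data_dir, out_dir = out_dir,
                 lag_days = as.integer(lag_days), ratio = as.integer(ratio),
                 birth_tol = as.integer(birth_tol),
                 min_years = as.integer(min_years), min_frac = min_frac,
                 screening = screening, adjust_for = adjust_for,
                 allow_short_sets = allow_short_sets,
                 seed = as.integer(seed), verbose = verbose),
            class = "pipeline_config")
}

#' Run the full screening pipeline
#'
#' simulate (or load) → ascertain and exclude cases → density-match →
#' build lagged exposures and covariates → repeated-model consensus screen →
#' interaction assessment → conditional logistic regression → report tables.
#' Every stage's row counts and parameters are logged and recorded in a JSON
#' manifest that suffices to reproduce the outputs exactly; all output files
#' are CSV.
#'
#' @param cfg A [pipeline_config()].
#' @return List with the matched sets, exposure container, covariates,
#'   screen result, consensus, interaction report, effects, report tables
#'   and the manifest (also written to `out_dir`).
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  stage <- function(name, expr) {
    ms_log(cfg$verbose, "stage: ", name)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  emr <- stage("simulate",
               if (is.null(cfg$data_dir)) simulate_emr(cfg$sim)
               else read_emr_tables(cfg$data_dir))
  cases <- stage("ascertain", ascertain_cases(
    emr$diagnoses, emr$subjects,
    window = if (is.null(cfg$data_dir)) cfg$sim$study_window else
      c("2001-01-01", "2020-01-01")))
  excl <- stage("exclusions", apply_exclusions(
    cases, emr$diagnoses, emr$subjects, min_years = cfg$min_years))
  matched <- stage("density-match", density_match(
    excl$cases, emr$subjects, diagnoses = emr$diagnoses, ratio = cfg$ratio,
    birth_tol = cfg$birth_tol, min_years = cfg$min_years, seed = cfg$seed,
    allow_short_sets = cfg$allow_short_sets))
  exposure <- stage("exposure", {
    em <- build_exposure_matrix(matched, emr$dispensing,
                                lag_days = cfg$lag_days)
    filter_rare_drugs(em, min_frac = cfg$min_frac, quiet = !cfg$verbose)
  })
  covariates <- stage("covariates", build_covariates(
    matched, emr$comorbidities, emr$visits, emr$subjects,
    lag_days = cfg$lag_days))
  screen <- stage("screen", run_screening(exposure, cfg = cfg$screening))
  consensus <- stage("consensus", consensus_select(screen))
  sel <- consensus[selected == TRUE, feature]
  interactions <- stage("interactions",
                        if (length(sel)) assess_interactions(
                          exposure$X[, sel, drop = FALSE], exposure$y,
                          cfg = cfg$screening) else NULL)
  effects <- stage("estimate",
                   if (length(sel)) estimate_effects(
                     exposure, covariates, features = sel,
                     adjust_for = cfg$adjust_for) else NULL)
  tables <- stage("report", make_tables(matched, emr$subjects, exposure,
                                        consensus, effects,
                                        visits = emr$visits))

  manifest <- list(
    package_version = as.character(utils::packageVersion("medscreen")),
    r_version = R.version.string,
    seed = cfg$seed,
    sim_seed = if (is.null(cfg$data_dir)) cfg$sim$seed else NA,
    parameters = list(lag_days = cfg$lag_days, ratio = cfg$ratio,
                      birth_tol = cfg$birth_tol, min_years = cfg$min_years,
                      min_frac = cfg$min_frac,
                      screening = cfg$screening[
                        c("n_runs", "holdout_frac", "cv_folds", "bo_budget",
                          "base_seed", "nrounds_max", "early_stopping")]),
    counts = list(cases_ascertained = nrow(cases),
                  exclusions = as.list(setNames(excl$exclusions$n_dropped,
                                                excl$exclusions$rule)),
                  matched_sets = length(unique(matched$set_id)),
                  members = nrow(matched),
                  classes_retained = ncol(exposure$X),
                  selected = length(sel)))

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    data.table::fwrite(matched, file.path(cfg$out_dir, "matched_sets.csv"))
    data.table::fwrite(consensus, file.path(cfg$out_dir, "consensus.csv"))
    if (!is.null(effects))
      data.table::fwrite(effects, file.path(cfg$out_dir, "effects.csv"))
    data.table::fwrite(tables$table1, file.path(cfg$out_dir, "table1.csv"))
    data.table::fwrite(tables$table2, file.path(cfg$out_dir, "table2.csv"))
    data.table::fwrite(tables$table3, file.path(cfg$out_dir, "table3.csv"))
    shap_long <- data.table::as.data.table(as.table(screen$shap))
    data.table::setnames(shap_long, c("run", "feature", "global_shap"))
    data.table::fwrite(shap_long, file.path(cfg$out_dir, "run_results.csv"))
    if (!is.null(interactions))
      jsonlite::write_json(
        list(informative = interactions$informative,
             best_depth = interactions$best_depth,
             curve = interactions$curve),
        file.path(cfg$out_dir, "interaction_report.json"),
        auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(matched_sets = matched, exposure = exposure, covariates = covariates,
       screen = screen, consensus = consensus, interactions = interactions,
       effects = effects, tables = tables, manifest = manifest)
}
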