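#' Default hyperparameter search space for the boosted-tree screen
#'
#' Learning rate and the L1/L2 penalties are searched on a log scale; tree
#' depth, subsampling fractions and minimum child weight linearly. Boosting
#' rounds are not searched: each configuration trains with early stopping
#' against the cross-validation loss.
#'
#' The minimum-child-weight cap is deliberately low (5). xgboost measures
#' child weight in hessian units, roughly 0.08 per row at the case rates of
#' a 1:10 design, so a cap of 5 already requires ~60 exposed rows in a
#' child; much larger values make medication classes near the 0.1% rarity
#' floor unsplittable — the search space would exclude exactly the rare
#' exposures the screen exists to find.
#'
#' @return Named list of parameter specs for [smbo_optimize()].
#' @export
default_hyperparameter_space <- function() {
  list(
    eta = list(type = "log", range = c(0.01, 0.3)),
    max_depth = list(type = "int", range = c(1, 8)),
    subsample = list(type = "num", range = c(0.5, 1)),
    colsample_bytree = list(type = "num", range = c(0.5, 1)),
    min_child_weight = list(type = "num", range = c(1, 5)),
    alpha = list(type = "log", range = c(1e-3, 10)),
    lambda = list(type = "log", range = c(1e-3, 10))
  )
}

#' Configuration of the repeated-model consensus screen
#'
#' @param n_runs Number of independent repetitions (study protocol: 50).
#' @param holdout_frac Fraction of rows set aside per run; the global Shapley
#'   importances are evaluated on these out-of-sample rows (study protocol:
#'   0.2).
#' @param cv_folds Cross-validation folds inside the hyperparameter search
#'   (study protocol: 5).
#' @param bo_budget Objective evaluations for the Bayesian hyperparameter
#'   search per run (default 30).
#' @param space Hyperparameter space, see [default_hyperparameter_space()].
#' @param base_seed Run `r` uses seed `base_seed + r`.
#' @param nrounds_max Maximum boosting rounds (default 500).
#' @param early_stopping Early-stopping patience in rounds (default 30).
#' @param nthread Threads handed to xgboost (default 1, fully deterministic).
#' @return Object of class `screening_config`.
#' @export
screening_config <- function(n_runs = 50L, holdout_frac = 0.2,
                             cv_folds = 5L, bo_budget = 30L,
                             space = default_hyperparameter_space(),
                             base_seed = 1L, nrounds_max = 500L,
                             early_stopping = 30L, nthread = 1L) {
  stopifnot(n_runs >= 1L, holdout_frac > 0, holdout_frac < 1,
            cv_folds >= 2L, bo_budget >= 1L)
  for (sp in space)
    if (!(length(sp$range) == 2L && sp$range[1] <= sp$range[2]))
      stop("hyperparameter ranges must be ordered pairs", call. = FALSE)
  structure(list(n_runs = as.integer(n_runs), holdout_frac = holdout_frac,
                 cv_folds = as.integer(cv_folds),
                 bo_budget = as.integer(bo_budget), space = space,
                 base_seed = as.integer(base_seed),
                 nrounds_max = as.integer(nrounds_max),
                 early_stopping = as.integer(early_stopping),
                 nthread = as.integer(nthread)),
            class = "screening_config")
}

xgb_params <- function(hp, cfg, seed) {
  c(list(objective = "binary:logistic", eval_metric = "logloss",
         tree_method = "hist", nthread = cfg$nthread, seed = seed), hp)
}

binary_logloss <- function(y, phat, eps = 1e-15) {
  phat <- pmin(pmax(phat, eps), 1 - eps)
  -mean(y * log(phat) + (1 - y) * log(1 - phat))
}

#' Bayesian hyperparameter optimisation for the boosted screen
#'
#' Minimises the mean `cv_folds`-fold cross-validated binary log-loss over
#' the hyperparameter space with [smbo_optimize()]; each candidate trains
#' with early stopping, and its best round count is retained so the final
#' model can be refit without a validation split.
#'
#' @param X Feature matrix (sparse `dgCMatrix` or dense) of 0/1 exposures.
#' @param y Binary outcome vector.
#' @param space Hyperparameter space (default
#'   [default_hyperparameter_space()]).
#' @param cv_folds,bo_budget,seed,nrounds_max,early_stopping,nthread See
#'   [screening_config()].
#' @return List with `params` (named list for xgboost), `nrounds`, `loss`
#'   (the cross-validated log-loss), and the search `history`.
#' @export
optimize_hyperparameters <- function(X, y,
                                     space = default_hyperparameter_space(),
                                     cv_folds = 5L, bo_budget = 30L,
                                     seed = 1L, nrounds_max = 500L,
                                     early_stopping = 30L, nthread = 1L) {
  if (length(unique(y)) < 2L)
    stop("outcome is degenerate (single class); cannot optimize",
         call. = FALSE)
  cfg <- list(nthread = nthread)
  dtrain <- xgboost::xgb.DMatrix(X, label = y)
  cache <- new.env(parent = emptyenv())
  objective <- function(hp) {
    key <- paste(format(unlist(hp), digits = 15), collapse = "|")
    set.seed(seed)  # fixed fold assignment across candidates
    cv <- xgboost::xgb.cv(params = xgb_params(hp, cfg, seed), data = dtrain,
                          nrounds = nrounds_max, nfold = cv_folds,
                          early_stopping_rounds = early_stopping,
                          verbose = 0)
    assign(key, cv$early_stop$best_iteration, envir = cache)
    as.numeric(cv$early_stop$best_score)
  }
  res <- smbo_optimize(objective, space, budget = bo_budget, seed = seed)
  key <- paste(format(unlist(res$best_params), digits = 15), collapse = "|")
  list(params = res$best_params,
       nrounds = get(key, envir = cache),
       loss = res$best_loss,
       history = res$history)
}

#' Run the repeated gradient-boosted screening protocol
#'
#' For run `r = 1..n_runs` (seed `base_seed + r`): set aside a random
#' `holdout_frac` of the rows; run the Bayesian hyperparameter search with
#' `cv_folds`-fold cross-validation on the remaining rows; fit the boosted
#' tree model at the selected configuration; and record the global Shapley
#' importance of every feature — the mean absolute TreeSHAP contribution over
#' the set-aside rows — together with the holdout log-loss. A feature never
#' used by any tree of a run has global importance exactly 0 in that run.
#' Runs whose training labels are degenerate are aborted and logged, never
#' silently skipped.
#'
#' @param X A `medscreen_exposure` (its medication matrix and case indicator
#'   are used), or a feature matrix.
#' @param y Binary outcome; ignored when `X` is a `medscreen_exposure`.
#' @param cfg A [screening_config()].
#' @return Object of class `screen_result`: `shap` (`n_runs x p` matrix of
#'   global Shapley importances), `eval_loss`, `params` (per-run selected
#'   hyperparameters), `features`, `failed` (character log of aborted runs),
#'   `config`.
#' @export
run_screening <- function(X, y = NULL, cfg = screening_config()) {
  stopifnot(inherits(cfg, "screening_config"))
  if (inherits(X, "medscreen_exposure")) {
    y <- X$y
    X <- X$X
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- nrow(X)
  p <- ncol(X)
  shap <- matrix(NA_real_, cfg$n_runs, p,
                 dimnames = list(paste0("run", seq_len(cfg$n_runs)),
                                 colnames(X)))
  eval_loss <- rep(NA_real_, cfg$n_runs)
  params <- vector("list", cfg$n_runs)
  failed <- character(0)

  for (r in seq_len(cfg$n_runs)) {
    rs <- cfg$base_seed + r
    hold <- with_seed(rs, sample.int(n, max(1L, round(cfg$holdout_frac * n))))
    tr <- setdiff(seq_len(n), hold)
    if (length(unique(y[tr])) < 2L || length(unique(y[hold])) < 1L) {
      msg <- sprintf("run %d aborted: degenerate training labels", r)
      warning(msg, call. = FALSE)
      failed <- c(failed, msg)
      next
    }
    opt <- optimize_hyperparameters(
      X[tr, , drop = FALSE], y[tr], space = cfg$space,
      cv_folds = cfg$cv_folds, bo_budget = cfg$bo_budget, seed = rs,
      nrounds_max = cfg$nrounds_max, early_stopping = cfg$early_stopping,
      nthread = cfg$nthread)
    dtrain <- xgboost::xgb.DMatrix(X[tr, , drop = FALSE], label = y[tr])
    set.seed(rs)
    bst <- xgboost::xgb.train(params = xgb_params(opt$params, cfg, rs),
                              data = dtrain, nrounds = opt$nrounds,
                              verbose = 0)
    Xh <- X[hold, , drop = FALSE]
    contrib <- predict(bst, xgboost::xgb.DMatrix(Xh), predcontrib = TRUE)
    shap[r, ] <- colMeans(abs(contrib[, seq_len(p), drop = FALSE]))
    eval_loss[r] <- binary_logloss(y[hold],
                                   predict(bst, xgboost::xgb.DMatrix(Xh)))
    params[[r]] <- opt$params
  }
  structure(list(shap = shap, eval_loss = eval_loss, params = params,
                 features = colnames(X), failed = failed, config = cfg),
            class = "screen_result")
}

#' @exportS3Method base::print
print.screen_result <- function(x, ...) {
  ok <- sum(!is.na(x$eval_loss))
  cat("<screen_result> ", ok, " completed runs x ", length(x$features),
      " features; mean holdout log-loss ",
      format(mean(x$eval_loss, na.rm = TRUE), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Consensus feature selection over repeated runs
#'
#' Applies the two-clause consensus rule to the per-run global Shapley
#' importances: a feature is selected iff (a) its importance is positive in
#' at least `min_rate` of the completed runs, or (b) in at least one run its
#' importance reaches the `q`-quantile (linear interpolation) of that run's
#' importance distribution over all features. Clause (b) additionally
#' requires a strictly positive importance, so an all-zero run selects
#' nothing.
#'
#' @param results A `screen_result` from [run_screening()], or a
#'   runs-by-features importance matrix.
#' @param min_rate Minimum fraction of runs with positive importance
#'   (default 0.5).
#' @param q Within-run quantile for the top-importance clause
#'   (default 0.975, i.e. the top 2.5%).
#' @return `data.table` with `feature`, `association_rate`, `top_q_hit`,
#'   `selected`, ordered by descending `association_rate`.
#' @export
consensus_select <- function(results, min_rate = 0.5, q = 0.975) {
  shap <- if (inherits(results, "screen_result")) results$shap else
    as.matrix(results)
  if (is.null(colnames(shap)))
    colnames(shap) <- paste0("x", seq_len(ncol(shap)))
  shap <- shap[stats::complete.cases(shap), , drop = FALSE]
  if (!nrow(shap)) stop("no completed runs", call. = FALSE)
  rate <- colMeans(shap > 0)
  thr <- apply(shap, 1L, quantile, probs = q, type = 7, names = FALSE)
  hit_mat <- sweep(shap, 1L, thr, ">=") & shap > 0
  hits <- apply(hit_mat, 2L, any)
  out <- data.table::data.table(
    feature = colnames(shap),
    association_rate = rate,
    top_q_hit = hits,
    top_q_rate = colMeans(hit_mat),
    selected = rate >= min_rate | hits)
  data.table::setorder(out, -association_rate, feature)
  out[]
}

#' Assess medication interactions through the tree-depth hyperparameter
#'
#' Refits the boosted model on the full data restricted to the selected
#' features, first optimising the non-depth hyperparameters, then scanning
#' tree depth over `depths` at the selected configuration. Interactions are
#' reported informative iff the cross-validated log-loss at the best depth
#' greater than 1 beats the depth-1 (additive, stump) model by more than one
#' standard error of the depth-1 fold losses. Depth-1 trees cannot express
#' any interaction, so a pure interaction effect (e.g. risk only under
#' co-exposure) flips the verdict.
#'
#' @param X A `medscreen_exposure` restricted to selected features, or a
#'   feature matrix.
#' @param y Binary outcome; ignored when `X` is a `medscreen_exposure`.
#' @param cfg A [screening_config()] (its `cv_folds`, `bo_budget`, seeds and
#'   round limits are reused).
#' @param depths Depths to scan (default `1:6`).
#' @return List with `informative` (logical verdict), `best_depth`, `curve`
#'   (`data.table`: `depth`, `logloss`, `se`, `nrounds`), and the non-depth
#'   `params` used.
#' @export
assess_interactions <- function(X, y = NULL, cfg = screening_config(),
                                depths = 1:6) {
  if (inherits(X, "medscreen_exposure")) {
    y <- X$y
    X <- X$X
  }
  if (ncol(X) == 0L)
    stop("empty feature selection; nothing to assess", call. = FALSE)
  ## depth is the quantity under test, so it leaves the search space; column
  ## subsampling is pinned to 1 because trees that cannot see two features
  ## at once cannot express their interaction at any depth
  space <- cfg$space
  space$max_depth <- NULL
  space$colsample_bytree <- NULL
  opt <- optimize_hyperparameters(X, y, space = space,
                                  cv_folds = cfg$cv_folds,
                                  bo_budget = cfg$bo_budget,
                                  seed = cfg$base_seed,
                                  nrounds_max = cfg$nrounds_max,
                                  early_stopping = cfg$early_stopping,
                                  nthread = cfg$nthread)
  dtrain <- xgboost::xgb.DMatrix(X, label = y)
  rows <- lapply(depths, function(d) {
    hp <- opt$params
    hp$max_depth <- as.integer(d)
    hp$colsample_bytree <- 1
    set.seed(cfg$base_seed)
    cv <- xgboost::xgb.cv(params = xgb_params(hp, cfg, cfg$base_seed),
                          data = dtrain, nrounds = cfg$nrounds_max,
                          nfold = cfg$cv_folds,
                          early_stopping_rounds = cfg$early_stopping,
                          verbose = 0)
    best <- cv$early_stop$best_iteration
    log <- cv$evaluation_log[best]
    data.table::data.table(
      depth = d, logloss = log$test_logloss_mean,
      se = log$test_logloss_std / sqrt(cfg$cv_folds), nrounds = best)
  })
  curve <- data.table::rbindlist(rows)
  best_depth <- curve$depth[which.min(curve$logloss)]
  d1 <- curve[depth == 1L]
  informative <- best_depth > 1L &&
    curve[depth == best_depth, logloss] < d1$logloss - d1$se
  list(informative = informative, best_depth = best_depth, curve = curve,
       params = opt$params)
}
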