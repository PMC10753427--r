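#' Construct a matched design matrix
#'
#' Validates the invariants the conditional likelihood requires: exactly one
#' case per set, at least two members per set, and no missing values in the
#' design. Rows with missing covariates are dropped (with a message) before
#' validation; a set whose case is dropped, or that shrinks below two
#' members, is removed entirely.
#'
#' @param X Numeric matrix (or sparse `Matrix`) of features, one row per
#'   matched-set member; column names are the feature names.
#' @param y Binary case indicator (exactly one `1` per set).
#' @param set_id Integer/character set identifier per row.
#' @return Object of class `matched_design` with elements `X` (dense
#'   matrix), `y`, `set_id` (rows sorted by set), and `dropped` (row count
#'   removed for missingness).
#' @export
matched_design <- function(X, y, set_id) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  stopifnot(nrow(X) == length(y), length(y) == length(set_id))
  y <- as.integer(y)

  complete <- stats::complete.cases(X)
  n_drop <- sum(!complete)
  if (n_drop) {
    message("matched_design: dropping ", n_drop,
            " row(s) with missing covariates")
    X <- X[complete, , drop = FALSE]
    y <- y[complete]
    set_id <- set_id[complete]
  }
  ## drop sets that lost their case or fell below 2 members
  dt <- data.table::data.table(set = set_id, y = y)
  info <- dt[, .(ncase = sum(y), n = .N), by = set]
  bad_case <- info[ncase != 1L, set]
  bad_size <- info[n < 2L, set]
  if (length(bad_case)) {
    still_there <- intersect(bad_case, unique(set_id))
    multi <- info[ncase > 1L, set]
    if (length(multi))
      stop("set(s) with more than one case: ",
           paste(head(multi, 5L), collapse = ", "), call. = FALSE)
  }
  drop_sets <- union(info[ncase == 0L, set], bad_size)
  if (length(drop_sets)) {
    message("matched_design: dropping ", length(drop_sets),
            " incomplete set(s)")
    keep <- !set_id %in% drop_sets
    X <- X[keep, , drop = FALSE]
    y <- y[keep]
    set_id <- set_id[keep]
  }
  if (!length(y)) stop("no usable matched sets remain", call. = FALSE)
  ord <- order(set_id)
  structure(list(X = X[ord, , drop = FALSE], y = y[ord],
                 set_id = set_id[ord], dropped = n_drop),
            class = "matched_design")
}

## internal: everything is computed on rows grouped by set; `g` is an integer
## group index 1..S aligned with rows, `case_rows` the row of each set's case.
clogit_core <- function(beta, X, g, case_rows, S) {
  eta <- drop(X %*% beta)
  mx <- vapply(split(eta, g), max, numeric(1L))
  w <- exp(eta - mx[g])
  denom <- rowsum(w, g)[, 1L]
  p <- w / denom[g]
  ll <- sum(eta[case_rows] - (log(denom) + mx))
  mu <- rowsum(X * p, g)                       # S x p, per-set mean of x
  score <- colSums(X[case_rows, , drop = FALSE] - mu)
  H <- crossprod(X, X * p) - crossprod(mu)     # observed information
  list(ll = ll, score = score, info = H, p = p)
}

#' Conditional logistic regression for matched sets
#'
#' Maximises the conditional likelihood
#' \deqn{L(\beta) = \prod_s \frac{\exp(x_{case,s}\beta)}
#'       {\sum_{j \in s} \exp(x_j\beta)}}
#' by Newton–Raphson with analytic gradient and Hessian, step-halving on a
#' likelihood decrease, convergence when the largest absolute score component
#' falls below `tol`. Standard errors come from the inverse observed
#' information; inference is Wald. Sets in which a feature is constant
#' contribute nothing to that feature's score, which the likelihood handles
#' naturally. For 1:1 binary designs the estimate equals the classical
#' discordant-pair odds ratio.
#'
#' @param design A [matched_design()], or anything [estimate_effects()] can
#'   assemble one from.
#' @param tol Convergence tolerance on the score (default `1e-8`).
#' @param max_iter Maximum Newton iterations (default 100).
#' @return `data.table` of class `medscreen_effects`: `feature`, `beta`,
#'   `se`, `or`, `ci_low`, `ci_high`, `p`, sorted by descending `or`; the
#'   log-likelihood and iteration count are attached as attributes.
#' @export
fit_conditional_logistic <- function(design, tol = 1e-8, max_iter = 100L) {
  stopifnot(inherits(design, "matched_design"))
  X <- design$X
  g <- match(design$set_id, unique(design$set_id))
  S <- max(g)
  case_rows <- which(design$y == 1L)
  stopifnot(length(case_rows) == S)

  ## a column constant within every set carries no conditional information
  ## (the likelihood absorbs set-level terms); drop it rather than inverting
  ## a singular information matrix
  ns <- tabulate(g)
  sums <- rowsum(X, g)
  sumsq <- rowsum(X^2, g)
  const_all <- colSums(abs(sumsq * ns - sums^2) > 1e-10) == 0L
  if (any(const_all)) {
    message("dropping set-constant feature(s) with no conditional ",
            "information: ", paste(colnames(X)[const_all], collapse = ", "))
    X <- X[, !const_all, drop = FALSE]
    if (!ncol(X))
      stop("all features are constant within sets", call. = FALSE)
  }
  pnames <- colnames(X)
  np <- ncol(X)

  beta <- numeric(np)
  cur <- clogit_core(beta, X, g, case_rows, S)
  for (it in seq_len(max_iter)) {
    if (max(abs(cur$score)) < tol) break
    step <- tryCatch(solve(cur$info, cur$score), error = function(e)
      stop("singular information matrix; feature(s) may be constant within ",
           "all sets: ",
           paste(pnames[diag(cur$info) < 1e-10], collapse = ", "),
           call. = FALSE))
    lambda <- 1
    repeat {
      cand <- beta + lambda * step
      nxt <- clogit_core(cand, X, g, case_rows, S)
      if (nxt$ll >= cur$ll - 1e-12) break
      lambda <- lambda / 2
      if (lambda < 1e-10)
        stop("step-halving failed to improve the conditional likelihood",
             call. = FALSE)
    }
    beta <- beta + lambda * step
    improving <- nxt$ll > cur$ll + 1e-12
    cur <- nxt
    if (any(abs(beta) > 15) && improving)
      stop("apparent complete separation (|beta| > 15 while the likelihood ",
           "still improves) for feature(s): ",
           paste(pnames[abs(beta) > 15], collapse = ", "),
           "; remove the feature or collapse categories", call. = FALSE)
    if (it == max_iter && max(abs(cur$score)) >= tol)
      stop("conditional logistic regression did not converge in ", max_iter,
           " iterations; worst score component: ",
           pnames[which.max(abs(cur$score))], call. = FALSE)
  }

  vcov <- solve(cur$info)
  se <- sqrt(diag(vcov))
  z <- beta / se
  out <- data.table::data.table(
    feature = pnames, beta = beta, se = se, or = exp(beta),
    ci_low = exp(beta - 1.96 * se), ci_high = exp(beta + 1.96 * se),
    p = 2 * pnorm(-abs(z)))
  data.table::setorder(out, -or)
  data.table::setattr(out, "loglik", cur$ll)
  data.table::setattr(out, "iterations", it)
  data.table::setattr(out, "vcov", vcov)
  data.table::setattr(out, "class", c("medscreen_effects", class(out)))
  out[]
}

#' Discordant-pair odds ratio (1:1 matched pairs)
#'
#' The classical closed-form conditional estimator for 1:1 matched pairs and
#' a single binary exposure: `n10 / n01`, the number of pairs in which only
#' the case is exposed over the number in which only the control is exposed.
#' Serves as the exact oracle that [fit_conditional_logistic()] must
#' reproduce on such designs.
#'
#' @param design A [matched_design()] with two members per set and a single
#'   binary feature.
#' @return The odds ratio (`Inf` with a warning when `n01 = 0`).
#' @export
discordant_pair_or <- function(design) {
  stopifnot(inherits(design, "matched_design"), ncol(design$X) == 1L)
  dt <- data.table::data.table(set = design$set_id, y = design$y,
                               x = design$X[, 1L])
  if (any(dt[, .N, by = set]$N != 2L))
    stop("discordant_pair_or requires 1:1 matched pairs", call. = FALSE)
  wide <- dt[, .(case_x = x[y == 1L], ctrl_x = x[y == 0L]), by = set]
  n10 <- wide[case_x == 1 & ctrl_x == 0, .N]
  n01 <- wide[case_x == 0 & ctrl_x == 1, .N]
  if (n10 == 0L && n01 == 0L)
    stop("no discordant pairs; odds ratio undefined", call. = FALSE)
  if (n01 == 0L) {
    warning("no control-only-exposed pairs; odds ratio is infinite",
            call. = FALSE)
    return(Inf)
  }
  n10 / n01
}

#' Estimate adjusted odds ratios for selected medications
#'
#' Assembles the matched design matrix from the exposure container and the
#' covariate table and fits the conditional logistic model. By default all
#' selected medications and the adjustment covariates (visit rate, diabetes,
#' cardiovascular disease, excess weight — hypertension is computed upstream
#' but not adjusted for) enter one joint model; `joint = FALSE` fits one
#' model per medication (each with the covariates).
#'
#' @param exposure A `medscreen_exposure` (post rare-drug filtering).
#' @param covariates Output of [build_covariates()] aligned to the same
#'   matched sets, or `NULL` for an unadjusted model.
#' @param features Medication columns to include (default: all columns of
#'   the exposure matrix).
#' @param adjust_for Covariate columns to adjust for.
#' @param joint Single joint model (default) or per-medication models.
#' @param ... Passed to [fit_conditional_logistic()].
#' @return A `medscreen_effects` table (joint), or the row-bound
#'   per-medication estimates for the medication terms only (`joint = FALSE`).
#' @export
estimate_effects <- function(exposure, covariates = NULL, features = NULL,
                             adjust_for = c("visit_rate", "diabetes",
                                            "cardiovascular",
                                            "excess_weight"),
                             joint = TRUE, ...) {
  stopifnot(inherits(exposure, "medscreen_exposure"))
  if (is.null(features)) features <- colnames(exposure$X)
  Xmed <- as.matrix(exposure$X[, features, drop = FALSE])
  Z <- NULL
  if (!is.null(covariates)) {
    cov_dt <- data.table::as.data.table(covariates)
    key <- data.table::data.table(set_id = exposure$set_id,
                                  subject_id = exposure$subject_id)
    cov_dt <- cov_dt[key, on = c("set_id", "subject_id")]
    adjust_for <- intersect(adjust_for, names(cov_dt))
    Z <- as.matrix(cov_dt[, adjust_for, with = FALSE])
  }
  if (joint) {
    des <- matched_design(cbind(Xmed, Z), exposure$y, exposure$set_id)
    fit_conditional_logistic(des, ...)
  } else {
    res <- lapply(features, function(f) {
      des <- matched_design(cbind(Xmed[, f, drop = FALSE], Z),
                            exposure$y, exposure$set_id)
      est <- fit_conditional_logistic(des, ...)
      est[feature == f]
    })
    out <- data.table::rbindlist(res)
    data.table::setorder(out, -or)
    out[]
  }
}
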