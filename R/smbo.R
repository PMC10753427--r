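## Compact sequential model-based (Bayesian) optimisation.
##
## Minimises a black-box objective over a box-constrained space: a Latin
## hypercube initial design on the unit cube, then a Gaussian-process
## surrogate (squared-exponential kernel, nugget-regularised) whose expected
## improvement is maximised over a random candidate cloud. Small budgets
## (10-30 evaluations) over <=10 dimensions are the intended regime.

## parameter space: named list, each element list(type = "num"|"log"|"int",
## range = c(lo, hi)). Unit-cube point -> native value.
space_decode <- function(u, space) {
  out <- vector("list", length(space))
  names(out) <- names(space)
  for (k in seq_along(space)) {
    sp <- space[[k]]
    r <- sp$range
    v <- switch(sp$type,
                num = r[1] + u[k] * (r[2] - r[1]),
                log = exp(log(r[1]) + u[k] * (log(r[2]) - log(r[1]))),
                int = as.integer(round(r[1] + u[k] * (r[2] - r[1]))),
                stop("unknown space type: ", sp$type))
    out[[k]] <- v
  }
  out
}

gp_kernel <- function(A, B, lengthscale) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  exp(-pmax(d2, 0) / (2 * lengthscale^2))
}

## fit GP on standardized losses, return EI scorer (minimisation)
gp_ei <- function(U, yv, lengthscale = 0.35, nugget = 1e-6) {
  mu <- mean(yv); sdv <- sd(yv)
  if (!is.finite(sdv) || sdv < 1e-12) sdv <- 1
  ys <- (yv - mu) / sdv
  K <- gp_kernel(U, U, lengthscale) + diag(nugget + 1e-8, nrow(U))
  L <- tryCatch(chol(K), error = function(e)
    chol(K + diag(1e-4, nrow(U))))
  alpha <- backsolve(L, forwardsolve(t(L), ys))
  best <- min(ys)
  function(Ucand) {
    Kc <- gp_kernel(Ucand, U, lengthscale)
    pred <- drop(Kc %*% alpha)
    v <- forwardsolve(t(L), t(Kc))
    var <- pmax(1 - colSums(v^2), 1e-12)
    s <- sqrt(var)
    imp <- best - pred
    z <- imp / s
    imp * pnorm(z) + s * dnorm(z)
  }
}

#' Sequential model-based optimisation of a black-box objective
#'
#' Minimises `objective(params)` over a typed box space using a Latin
#' hypercube initial design followed by Gaussian-process expected-improvement
#' proposals. Deterministic given `seed`. With `budget = 1` the single
#' (seed-determined) sampled configuration is evaluated and returned.
#'
#' @param objective Function taking a named list of parameter values and
#'   returning a scalar loss to minimise.
#' @param space Named list of parameter specs, each
#'   `list(type = "num"|"log"|"int", range = c(lo, hi))`.
#' @param budget Total number of objective evaluations.
#' @param seed Integer seed.
#' @param n_init Size of the initial design (default: half the budget,
#'   at least 4, at most `budget`).
#' @param n_cand Size of the random candidate cloud scored by expected
#'   improvement at each sequential step.
#' @return List with `best_params`, `best_loss`, and `history`
#'   (`data.table` of unit-cube coordinates and losses).
#' @export
smbo_optimize <- function(objective, space, budget, seed = 1L,
                          n_init = NULL, n_cand = 256L) {
  stopifnot(budget >= 1L, length(space) >= 1L)
  d <- length(space)
  n_init <- n_init %||% min(budget, max(4L, ceiling(budget / 2)))
  n_init <- min(n_init, budget)
  with_seed(seed, {
    U <- as.matrix(lhs::randomLHS(n_init, d))
    losses <- numeric(0)
    for (i in seq_len(n_init))
      losses[i] <- objective(space_decode(U[i, ], space))
    while (length(losses) < budget) {
      ei <- gp_ei(U, losses)
      Ucand <- matrix(runif(n_cand * d), n_cand, d)
      ## include jittered copies of the incumbent for local refinement
      inc <- U[which.min(losses), ]
      jit <- matrix(pmin(pmax(rep(inc, each = 16L) +
                                rnorm(16L * d, 0, 0.05), 0), 1), 16L, d)
      Ucand <- rbind(Ucand, jit)
      pick <- Ucand[which.max(ei(Ucand)), , drop = FALSE]
      U <- rbind(U, pick)
      losses <- c(losses, objective(space_decode(pick[1, ], space)))
    }
    best <- which.min(losses)
    hist <- data.table::as.data.table(U)
    data.table::setnames(hist, names(space))
    hist[, loss := losses]
    list(best_params = space_decode(U[best, ], space),
         best_loss = losses[best],
         history = hist[])
  })
}
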