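## internal helpers shared across modules

DAYS_PER_MONTH <- 365.25 / 12

`%||%` <- function(a, b) if (is.null(a)) b else a

as_date <- function(x) {
  if (inherits(x, "Date")) return(x)
  as.Date(x)
}

## run code under a temporary RNG state; restores .Random.seed afterwards so
## generators are pure functions of their own seed argument
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## categorical sampler from a named probability vector
sample_margin <- function(n, margin) {
  if (n == 0L) return(character(0))
  sample(names(margin), n, replace = TRUE, prob = margin)
}

check_margin <- function(margin, name, tol = 1e-6) {
  if (is.null(names(margin)) || any(!nzchar(names(margin))))
    stop("demographic margin '", name, "' must be a named probability vector",
         call. = FALSE)
  if (any(margin <= 0) || any(margin >= 1))
    stop("demographic margin '", name, "' must have probabilities in (0, 1)",
         call. = FALSE)
  if (abs(sum(margin) - 1) > tol)
    stop("demographic margin '", name, "' does not sum to 1 (got ",
         format(sum(margin)), ")", call. = FALSE)
  invisible(margin)
}

## message-level logging used by the pipeline; quiet unless verbose
ms_log <- function(verbose, ...) {
  if (isTRUE(verbose)) message("[medscreen] ", ...)
  invisible(NULL)
}
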