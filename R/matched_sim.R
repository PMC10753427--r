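#' Simulate matched case-control sets with exact conditional effects
#'
#' Generates `n_sets` matched sets of one case and `ratio` controls and a
#' binary exposure matrix in which, within every set, each control is exposed
#' to class `j` with its control prevalence `p0_j` while the case is exposed
#' with probability `p1_j` where `logit(p1_j) = logit(p0_j) + log(OR_j)`.
#' Under this mechanism the within-set (conditional) odds ratio of exposure
#' equals `OR_j` exactly, so the generator provides planted ground truth for
#' the conditional-logistic estimator and for the screening stage without
#' running the full population model. Classes not mentioned in `planted`
#' are null (`OR = 1`).
#'
#' @param n_sets Number of matched sets (study design: 941).
#' @param ratio Controls per case (study design: 10).
#' @param prevalence Named numeric vector of control ever-exposure
#'   prevalences, one per class (names are ATC codes / feature names).
#' @param planted Optional `data.frame` with columns `atc5`, `odds_ratio`;
#'   rows must name classes present in `prevalence`.
#' @param seed Integer seed.
#' @return A `medscreen_exposure` object (see [build_exposure_matrix()]):
#'   sparse binary matrix `X` plus `set_id`, `y`, `subject_id`.
#' @export
simulate_matched_sets <- function(n_sets, ratio, prevalence, planted = NULL,
                                  seed = 1L) {
  stopifnot(n_sets >= 1L, ratio >= 1L, all(prevalence >= 0),
            all(prevalence < 1))
  p <- length(prevalence)
  if (is.null(names(prevalence)))
    names(prevalence) <- sprintf("x%03d", seq_len(p))
  logor <- setNames(numeric(p), names(prevalence))
  if (!is.null(planted) && nrow(planted)) {
    planted <- data.table::as.data.table(planted)
    bad <- setdiff(planted$atc5, names(prevalence))
    if (length(bad))
      stop("planted class not in prevalence vector: ",
           paste(bad, collapse = ", "), call. = FALSE)
    if (any(planted$odds_ratio <= 0))
      stop("planted odds ratios must be > 0", call. = FALSE)
    logor[planted$atc5] <- log(planted$odds_ratio)
  }
  n <- n_sets * (ratio + 1L)
  set_id <- rep(seq_len(n_sets), each = ratio + 1L)
  y <- rep(c(1L, rep(0L, ratio)), n_sets)
  p_case <- plogis(qlogis(prevalence) + logor)   # qlogis(0) = -Inf -> 0

  with_seed(seed, {
    ii <- vector("list", p); jj <- vector("list", p)
    is_case <- y == 1L
    for (j in seq_len(p)) {
      pr <- ifelse(is_case, p_case[j], prevalence[j])
      rows <- which(runif(n) < pr)
      ii[[j]] <- rows
      jj[[j]] <- rep.int(j, length(rows))
    }
    X <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = 1,
                              dims = c(n, p),
                              dimnames = list(NULL, names(prevalence)))
    new_exposure(X = X, set_id = set_id, y = y,
                 subject_id = seq_len(n),
                 index_date = rep(as.Date(NA), n))
  })
}
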