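## fixtures built in code, shared across test files

## 1:1 matched pairs with prescribed discordance counts, single binary drug
mk_pair_design <- function(n10, n01, n11 = 5L, n00 = 5L) {
  sets <- n10 + n01 + n11 + n00
  x_case <- c(rep(1, n10), rep(0, n01), rep(1, n11), rep(0, n00))
  x_ctrl <- c(rep(0, n10), rep(1, n01), rep(1, n11), rep(0, n00))
  matched_design(
    matrix(c(rbind(x_case, x_ctrl)), ncol = 1,
           dimnames = list(NULL, "drug")),
    y = rep(c(1L, 0L), sets),
    set_id = rep(seq_len(sets), each = 2L))
}

## random 1:ratio matched design with one binary and one continuous feature
mk_random_design <- function(n_sets, ratio = 10L, seed = 1L,
                             p_base = 0.1, case_shift = 0) {
  set.seed(seed)
  n <- n_sets * (ratio + 1L)
  y <- rep(c(1L, rep(0L, ratio)), n_sets)
  X <- cbind(a = rbinom(n, 1, p_base + case_shift * y),
             b = rnorm(n))
  matched_design(X, y, rep(seq_len(n_sets), each = ratio + 1L))
}

## small synthetic EMR reused by cohort/exposure tests
tiny_emr <- function(seed = 7L, n = 4000L, classes = 12L) {
  cfg <- sim_config(seed = seed, n_population = n, n_drug_classes = classes)
  simulate_emr(cfg)
}

## brute-force conditional log-likelihood for a single-feature design
clogit_loglik_brute <- function(beta, design) {
  eta <- drop(design$X %*% beta)
  sum(vapply(split(seq_along(eta), design$set_id), function(i) {
    eta[i][design$y[i] == 1L] - log(sum(exp(eta[i])))
  }, numeric(1L)))
}
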