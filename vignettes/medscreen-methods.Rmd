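---
title: "Methods: medication-wide screening in a density-matched case-control design"
author: "medscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: medication-wide screening in a density-matched case-control design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Early-onset colorectal cancer (EOCRC, diagnosis at age 50 or younger) has
risen sharply since the 1990s, and the large majority of cases carry neither
a hereditary cancer syndrome nor inflammatory bowel disease. One candidate
class of environmental exposures is prior medication use. Testing that idea
against electronic medical records means screening on the order of 800 ATC
level-5 medication classes in a matched case-control design with roughly a
thousand cases — far too many correlated exposures for one-at-a-time
regression, and far too few cases for naive multivariable modelling.

`medscreen` implements the full analysis pattern for this setting:

1. a **synthetic EMR generator** with planted ground truth, so every stage is
   testable without access to proprietary records;
2. **case ascertainment, exclusions, and 1:10 density (risk-set) matching**;
3. a **lagged ever/never exposure matrix** with rare-class filtering;
4. a **consensus screen**: repeated gradient-boosted tree models, each with a
   Bayesian hyperparameter search, scored by global Shapley importances;
5. **conditional logistic regression** (written from scratch) for adjusted
   odds ratios on the matched sets.

## The matched design

Cases are subjects whose first colorectal-cancer diagnosis falls in the 2001–
2019 window at index age ≤ 50 (index age is index year minus birth year).
Cases need ≥ 3 years of continuous enrollment before the index date; cases
flagged for IBD or a suspected hereditary syndrome are excluded, in that
order, with a per-rule count ledger.

Controls are drawn by *density (risk-set) sampling*: for each case, in
index-date order, 10 controls are sampled uniformly without replacement from
the subjects who, at that case's index date, match exactly on sex,
residential district, subpopulation, SES band (1–10) and periphery band, have
birth year within ±2 years, have ≥ 3 years of pre-index enrollment, are still
enrolled, and have no colorectal-cancer diagnosis on or before that date. A
subject who becomes a case later is a valid control earlier (that is what
makes the sampling density sampling, and it is why the matched odds ratio
estimates a rate ratio); a subject serves as a control in at most one set,
which matches a design that reports 10 distinct controls per case. By
construction the matched keys are exactly balanced between cases and
controls, so they are excluded from all downstream models.

## Exposure and covariates

Exposure is *ever/never* per ATC level-5 class: a member is exposed iff they
have at least one dispensing **strictly before index date − 730 days**. The
2-year lag guards against reverse causation (prodromal prescribing); events
inside the lag window are ignored entirely, so adding lag-window events never
changes the matrix (a tested invariant). Classes used by fewer than
`ceiling(0.001 × N)` of the N cohort members are dropped, with the count
threshold and dropped classes logged.

Comorbidity indicators (diabetes, hypertension, cardiovascular disease,
excess weight) use onset strictly before the *unlagged* index date, because
chronic-condition history is a baseline fact rather than a prescribing
signal; the physician-visit rate — the surveillance-bias proxy — counts
visits before the lagged cutoff divided by follow-up months to that cutoff,
because contact frequency inside the lag window is exactly the kind of
diagnosis-adjacent signal the lag is meant to remove. Members with
non-positive lagged follow-up get a missing visit rate and are dropped (with
a log message) at the regression stage.

## The consensus screen

For run *r* = 1…R (protocol default R = 50), with seed `base_seed + r`:

* set aside a random 20% of the rows;
* on the remaining 80%, select hyperparameters by minimising 5-fold
  cross-validated binary log-loss under a sequential model-based (Bayesian)
  search;
* fit the gradient-boosted tree model (XGBoost) at the selected
  configuration;
* record each feature's **global Shapley importance**: the mean absolute
  TreeSHAP contribution over the held-out 20%.

A feature is *associated* in a run iff its global importance is strictly
positive — TreeSHAP gives exactly zero to features no tree splits on. The
consensus rule selects a feature iff it is associated in ≥ 50% of runs, or
its importance reaches the 97.5th percentile (linear-interpolation quantile,
ties included) of at least one run's importance distribution; the quantile
clause additionally requires a positive score so an all-zero run selects
nothing. Importances are scored out-of-sample because the only purpose of
the per-run holdout is reproducibility of the importances, and out-of-sample
scoring resists overfit artifacts. Only medication indicators enter the
screen; comorbidities and the visit rate are adjustment covariates for the
regression stage, not screening features, and the matched keys are balanced
by design.

Interactions are assessed through the tree-depth hyperparameter: after
optimising the non-depth hyperparameters on the full data restricted to the
selected features, depth is scanned over 1–6 with column subsampling pinned
to 1 — a tree that cannot see two features at once could not express their
interaction at any depth, so leaving `colsample_bytree` free would bias the
verdict toward "not informative" whenever few features are selected. Depth-1 trees (stumps) can
express only additive effects, so the verdict is *informative* iff the best
depth above 1 improves cross-validated log-loss over depth 1 by more than
one standard error (across-fold SD divided by √folds) of the depth-1 loss.
The one-standard-error rule is this package's operationalisation of an
otherwise qualitative judgement.

### Hyperparameter space and the optimizer

The searched space (all configurable): learning rate 0.01–0.3 (log scale),
depth 1–8, row and column subsampling 0.5–1, minimum child weight 1–5, L1
and L2 penalties 10⁻³–10 (log scale). The minimum-child-weight cap is
deliberately low: xgboost measures child weight in hessian units (about
0.08 per row at a 1:10 design's case rate), so a cap of 5 already demands
roughly 60 exposed rows per child, and much larger caps silently forbid
splits on the rare classes — down to 0.1% prevalence — that the screen
exists to find. Boosting rounds are not searched;
every configuration trains with early stopping (default: up to 500 rounds,
patience 30) against the cross-validation loss. Binary ever/never exposure
matrices saturate their cross-validated log-loss long before 500 rounds, so
a larger cap would only add compute.

No Bayesian-optimisation dependency is used; the optimiser is a compact
sequential model-based search: a Latin hypercube initial design over the
unit cube (half the budget, at least 4 points), then a Gaussian-process
surrogate (squared-exponential kernel, length-scale 0.35 on the unit cube,
nugget-regularised Cholesky) whose expected improvement is maximised over a
random candidate cloud plus jittered copies of the incumbent. In the
intended regime — budgets of 10–30 evaluations over 7 dimensions — this is
the standard textbook construction, and it is deterministic given the seed.

## Conditional logistic regression

With one case per set, the conditional likelihood is

$$L(\beta) = \prod_s \frac{\exp(x_{\text{case},s}\beta)}
  {\sum_{j \in s} \exp(x_j\beta)},$$

which eliminates all set-level nuisance parameters. The package maximises it
by Newton–Raphson with the analytic score and observed information,
step-halving on any likelihood decrease, β initialised at 0, and convergence
declared when the largest absolute score component falls below 10⁻⁸.
Standard errors come from the inverse observed information; confidence
intervals and p-values are Wald. Design handling:

* a feature constant within **every** set has zero conditional information;
  it is dropped with a message (the likelihood absorbs set-level terms, so
  all other estimates are unchanged — a tested invariant);
* apparent complete separation (|β| > 15 while the likelihood still
  improves) raises an error naming the feature;
* rows with missing covariates are dropped with a message, and any set that
  loses its case or falls below two members is removed.

On 1:1 binary designs the estimator reduces to the discordant-pair ratio
n₁₀/n₀₁ (tested to 10⁻⁶), on tiny fixtures it matches a brute-force
likelihood grid (10⁻⁴), and on random fixtures it agrees with
`survival::coxph(..., method = "exact")` to 10⁻⁵ — the established
implementation is a test oracle only, never the computation path.

All consensus-selected medications plus the four adjustment covariates
(visit rate, diabetes, cardiovascular disease, excess weight) enter one
joint model by default; hypertension is computed upstream but not adjusted
for, and a per-medication mode is available but non-default. No
multiple-testing correction is applied, matching the screening character of
the analysis.

## The synthetic generator: what it emulates and what it does not

`sim_config()` defaults describe the study conditions: 120,000 subjects;
study window 2001–2019 (half-open, ISO dates); 800 ATC level-5 classes with
baseline ever-exposure prevalence log-uniform on [0.0005, 0.35] (the heavy
right-skew of real dispensing data); demographic margins matching the
published cohort (48.8% male; five districts; 88.1% secular Jewish; SES
centred at 6.5, SD 1.9; three periphery bands; birth years centred so index
ages concentrate near 44); physician-visit rates Gamma-distributed with mean
7.2 visits/year; enrollment starting up to six years before the window with
a 12% dropout rate.

Outcomes follow a discrete annual-hazard model: per person-year, the
diagnosis probability is `baseline_annual_hazard` × exp(Σ planted log-OR ×
lagged ever-exposure + Σ comorbidity log-odds). A dynamic cohort with
calendar-time risk sets is what makes density matching downstream a real
operation rather than a formality. The default hazard, 10⁻⁴/year, is the
rare-disease regime in which conditional odds ratios approximate the planted
hazard ratios; the absolute incidence is a stand-in (no registry data feed
the generator) and is not a quantity the package claims to reproduce. At
that hazard the default population yields a few hundred emergent cases;
analyses at the published design size (941 cases) use either
`plant_case_registry()`, which plants a case registry with known counts
(including deliberately under-enrolled and flagged cases, and an optional
risk-set-support guard), or `simulate_matched_sets()`, which generates
matched sets directly with exact within-set conditional odds ratios
(controls exposed at p₀, the case at logit⁻¹(logit p₀ + log OR)).

Confounding by indication is generated, not assumed away: a comorbidity can
carry both an exposure log-odds (for its indicated classes) and an outcome
log-odds, and both can be switched off. This is the key limitation of the
real-world design — an association can reflect the underlying condition
rather than the drug — and the generator exists partly so that this failure
mode can be produced on demand.

What the generator does **not** emulate: dose, adherence, switching or
recency (exposure is ever/never by design); correlated co-prescribing
(null classes are independent); secular prescribing trends; registry-grade
case ascertainment. Passing tests therefore demonstrate correctness of the
pipeline's logic and calibration under a clean generative model, not
robustness to the full messiness of real dispensing data.

## Numerical and design choices

* Dates are ISO-8601; all intervals are half-open `[start, end)`; the lag
  and enrollment boundaries are strict (`<`), each pinned by a boundary
  test.
* Index age uses birth year, not birth date, because matching is on birth
  year.
* A month is 365.25/12 days for visit-rate denominators.
* Greedy index-date-ordered matching with uniform sampling; no caliper or
  optimal matching — risk-set sampling is the design being modelled. A risk
  set smaller than the ratio is an error unless short sets are explicitly
  allowed (then a logged warning).
* The rare-drug rule implements the stated percentage (< 0.1% of cohort
  members) with the count threshold logged.
* Screening rows are treated as exchangeable (the matched structure is
  ignored at that stage); the matched likelihood handles the structure at
  the estimation stage.
* `screening_config(nthread = 1)` keeps every xgboost call bit-reproducible;
  the full screen is a pure function of (data, configuration).

## Problem sizes used by the test suite

The acceptance-level tests run at the published design size — 941 sets of
1 case + 10 controls, 800 classes — with the screen scaled to 20 runs at
budget 10 (signal recovery) and 10 runs at budget 5 (null calibration), and
odds-ratio recovery averaged over 25 seeded replicates. These sizes, fixed
here, keep the whole suite in the tens of minutes on a single core while
leaving every structural check (matching exactness, exclusion ledger,
closed-form oracles) at full size.

## Known limitations

* The consensus rule's "associated" criterion (any positive Shapley
  importance) is permissive: in cohorts with strong signals the boosted
  models run long enough to touch many null features, so features passing
  the 50% clause in an *alternative* cohort include spurious ones. The rule
  is calibrated in the sense tested — under the global null fewer than 1%
  of classes pass — and the regression stage, not the screen, carries the
  inferential weight.
* Wald intervals are first-order; no exact conditional or permutation
  inference is offered.
* The generator's independence assumptions (between classes, and between
  flags and outcome) make the null calibration cleaner than real data would
  be.
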