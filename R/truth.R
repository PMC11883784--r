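#' Missingness mechanism for the synthetic cohort
#'
#' Describes how wave-level completion is generated. `wave_retention` gives
#' the base probability that a person completes each wave; under
#' `mar_baseline` an additive log-odds shift per IL-6 tertile is applied
#' (attrition depending on baseline exposure, which full-information ML
#' tolerates), and under `mnar_score` a log-odds shift per latent-score unit
#' is applied (missingness depending on the unobserved outcome itself, the
#' stress case where likelihood-based fitting is biased).
#'
#' @param mechanism one of `"none"`, `"mcar"`, `"mar_baseline"`, `"mnar_score"`.
#' @param wave_retention base per-wave completion probability; scalar or one
#'   value per scheduled wave. Ignored (forced to 1) when `mechanism = "none"`.
#' @param tertile_log_odds length-3 additive log-odds shift for
#'   bottom/middle/top tertile (`mar_baseline` only).
#' @param score_log_odds log-odds shift per latent score unit
#'   (`mnar_score` only); negative values make high scorers drop out.
#' @return an object of class `missingness_model`.
#' @export
missingness_model <- function(mechanism = c("none", "mcar", "mar_baseline", "mnar_score"),
                              wave_retention = 1,
                              tertile_log_odds = c(0, 0, 0),
                              score_log_odds = 0) {
  mechanism <- match.arg(mechanism)
  if (any(wave_retention < 0 | wave_retention > 1))
    stopf("wave_retention must lie in [0, 1]")
  if (length(tertile_log_odds) != 3L)
    stopf("tertile_log_odds must have length 3 (bottom, middle, top)")
  structure(list(mechanism = mechanism,
                 wave_retention = wave_retention,
                 tertile_log_odds = tertile_log_odds,
                 score_log_odds = score_log_odds),
            class = "missingness_model")
}

#' Generative parameter set for a synthetic cohort
#'
#' Bundles every parameter the simulator uses: the population polynomial
#' trajectory of the reference (bottom-tertile) group, per-tertile offsets
#' with age interactions, covariate effects, the person-level random-effect
#' covariance `G`, the residual variance, the baseline biomarker law, the
#' assessment schedule and the missingness mechanism. Parameter-recovery
#' tests check fitted models against this object.
#'
#' Coefficient vectors are ordered by power of centered age
#' (order 0 .. `fixed_degree`), in score units per centered-year^k.
#'
#' @param n_individuals number of persons.
#' @param center_age reference age subtracted before polynomial terms (years).
#' @param fixed_degree polynomial order of the population trajectory (1-4).
#' @param beta_reference coefficients of the reference-group trajectory,
#'   length `fixed_degree + 1`.
#' @param group_offsets named list with elements `middle` and `top`, each a
#'   vector of length `fixed_degree + 1` (main effect + age interactions).
#' @param covariate_effects named list of fixed effects for the generated
#'   covariates: `sex` (added for females), `logbmi` (per SD of log BMI),
#'   `ses` (per ordinal SES step), `smoking` (per smoking level),
#'   `batch`, `centre`.
#' @param random_degree order of individual random slopes (0-4,
#'   at most `fixed_degree`).
#' @param G unstructured random-effect covariance, dimension
#'   `random_degree + 1`; must be symmetric positive semidefinite.
#' @param sigma2 residual variance (score units squared); `>= 0`
#'   (0 gives the exact noiseless limit used by recovery oracles).
#' @param il6_distribution list with `meanlog`, `sdlog`, and `exponentiate`
#'   (`TRUE` for a raw pg/ml-like scale, `FALSE` to stay on a log2-type
#'   normalised scale).
#' @param crp_distribution list with `meanlog`, `sdlog` of log CRP (mg/L).
#' @param crp_correlation correlation of log CRP with log IL-6.
#' @param instrument_bounds length-2 numeric, min/max of the symptom score.
#' @param rounding_enabled round and clip scores to integer instrument units?
#'   Defaults to `FALSE` so estimator-correctness tests see the continuous
#'   latent scale; enable for realism runs.
#' @param schedule list with `ages` (strictly increasing wave target ages,
#'   all `>= center_age`) and `jitter_sd` (per-wave age jitter SD, scalar or
#'   per wave).
#' @param covariate_distributions list of generator settings for covariates
#'   (see defaults in the profile constructors).
#' @param missingness a [missingness_model()].
#' @param seed integer RNG seed; identical truths give bit-identical cohorts.
#' @return an object of class `simulation_truth`.
#' @seealso [alspac_truth()], [ukb_truth()], [simulate_cohort()]
#' @export
simulation_truth <- function(n_individuals,
                             center_age,
                             fixed_degree,
                             beta_reference,
                             group_offsets,
                             covariate_effects = list(sex = 0, logbmi = 0, ses = 0,
                                                      smoking = 0, batch = 0, centre = 0),
                             random_degree = 1,
                             G = diag(random_degree + 1),
                             sigma2 = 1,
                             il6_distribution = list(meanlog = 0, sdlog = 1, exponentiate = TRUE),
                             crp_distribution = list(meanlog = -0.5, sdlog = 1),
                             crp_correlation = 0.4,
                             instrument_bounds = c(0, 26),
                             rounding_enabled = FALSE,
                             schedule = list(ages = c(10, 13, 16), jitter_sd = 0),
                             covariate_distributions = list(),
                             missingness = missingness_model("none"),
                             seed = 1L) {
  cd_defaults <- list(p_female = 0.55, bmi_meanlog = log(17.5), bmi_sdlog = 0.12,
                      ses_levels = 2L, smoking_p = c(0.6, 0.25, 0.15),
                      n_batches = 1L, n_centres = 1L,
                      p_medication = 0.14, p_inflam = 0.0, p_died = 0.0)
  covariate_distributions <- utils::modifyList(cd_defaults, covariate_distributions)
  truth <- structure(list(
    n_individuals = as.integer(n_individuals),
    center_age = center_age,
    fixed_degree = as.integer(fixed_degree),
    beta_reference = beta_reference,
    group_offsets = group_offsets,
    covariate_effects = utils::modifyList(
      list(sex = 0, logbmi = 0, ses = 0, smoking = 0, batch = 0, centre = 0),
      covariate_effects),
    random_degree = as.integer(random_degree),
    G = as.matrix(G),
    sigma2 = sigma2,
    il6_distribution = il6_distribution,
    crp_distribution = crp_distribution,
    crp_correlation = crp_correlation,
    instrument_bounds = instrument_bounds,
    rounding_enabled = isTRUE(rounding_enabled),
    schedule = schedule,
    covariate_distributions = covariate_distributions,
    missingness = missingness,
    seed = as.integer(seed)), class = "simulation_truth")
  validate_truth(truth)
  truth
}

validate_truth <- function(truth) {
  d <- truth$fixed_degree; q <- truth$random_degree
  if (truth$n_individuals < 1L) stopf("n_individuals must be >= 1")
  if (d < 1L || d > 4L) stopf("fixed_degree must be in 1..4")
  if (q < 0L || q > d) stopf("random_degree must satisfy 0 <= random_degree <= fixed_degree")
  if (length(truth$beta_reference) != d + 1L)
    stopf("beta_reference must have length fixed_degree + 1 (= %d)", d + 1L)
  if (!all(c("middle", "top") %in% names(truth$group_offsets)))
    stopf("group_offsets must have elements 'middle' and 'top'")
  for (g in c("middle", "top"))
    if (length(truth$group_offsets[[g]]) != d + 1L)
      stopf("group_offsets$%s must have length fixed_degree + 1 (= %d)", g, d + 1L)
  if (!all(dim(truth$G) == c(q + 1L, q + 1L)))
    stopf("G must be a %d x %d matrix", q + 1L, q + 1L)
  if (!is_psd(truth$G))
    stopf("G is not a symmetric positive semidefinite matrix")
  if (truth$sigma2 < 0) stopf("sigma2 must be >= 0")
  ages <- truth$schedule$ages
  if (length(ages) == 0L) stopf("schedule must contain at least one wave age")
  if (any(diff(ages) <= 0)) stopf("schedule ages must be strictly increasing")
  if (any(ages < truth$center_age)) stopf("schedule ages must all be >= center_age")
  js <- truth$schedule$jitter_sd
  if (any(js < 0)) stopf("jitter SDs must be >= 0")
  if (diff(truth$instrument_bounds) <= 0) stopf("instrument_bounds must be increasing")
  if (!inherits(truth$missingness, "missingness_model"))
    stopf("missingness must be a missingness_model")
  invisible(truth)
}

#' Youth-cohort simulation profile (SMFQ-like instrument, ages 10-28)
#'
#' Defaults emulate an ALSPAC-like cohort: 11 assessment waves between ages
#' 10 and 28, SMFQ scores bounded 0-26, serum IL-6 in pg/ml (log-normal with
#' tertile cutoffs near 0.59 and 1.12 pg/ml), CRP in mg/L with a small
#' fraction above the 10 mg/L exclusion threshold, and reference-trajectory
#' coefficients set to the cohort's published fully adjusted estimates
#' (intercept 1.1192, quadratic 0.1355, quartic 0.0003; linear and cubic
#' terms are below printed precision and set to 0) with a top-tertile x
#' linear-age interaction of 0.3581.
#'
#' @param n_individuals cohort size.
#' @param seed RNG seed.
#' @param ... overrides passed to [simulation_truth()].
#' @return a `simulation_truth`.
#' @export
alspac_truth <- function(n_individuals = 5000, seed = 1L, ...) {
  args <- list(
    n_individuals = n_individuals,
    center_age = 10,
    fixed_degree = 4L,
    beta_reference = c(1.1192, 0, 0.1355, 0, 0.0003),
    group_offsets = list(middle = c(0, 0, 0, 0, 0),
                         top = c(0, 0.3581, 0, 0, 0)),
    covariate_effects = list(sex = 0.5, logbmi = 0.1, ses = -0.2,
                             smoking = 0, batch = 0, centre = 0),
    random_degree = 1L,
    G = diag(c(4, 0.02)),
    sigma2 = 9,
    il6_distribution = list(meanlog = -0.21, sdlog = 0.745, exponentiate = TRUE),
    crp_distribution = list(meanlog = -1.0, sdlog = 1.15),
    crp_correlation = 0.4,
    instrument_bounds = c(0, 26),
    rounding_enabled = FALSE,
    schedule = list(ages = c(10, 12, 14, 17, 18, 19, 22, 23, 24, 26, 28),
                    jitter_sd = 0.3),
    covariate_distributions = list(p_female = 0.55, bmi_meanlog = log(17.5),
                                   bmi_sdlog = 0.12, ses_levels = 2L,
                                   p_medication = 0.14, p_inflam = 0, p_died = 0.001),
    missingness = missingness_model("none"),
    seed = seed)
  do.call(simulation_truth, utils::modifyList(args, list(...)))
}

#' Mid/late-life cohort simulation profile (PHQ-2-like instrument, ages 39-80)
#'
#' Defaults emulate a UK Biobank-like cohort: 8 waves spanning ages ~39-80,
#' PHQ-2 scores bounded 0-6, IL-6 on a log2-type normalised scale (Gaussian
#' with tertile cutoffs near -0.31 and 0.30), and a quadratic reference
#' trajectory with coefficients at the cohort's published fully adjusted
#' estimates (intercept 0.8401; linear and quadratic reference terms below
#' printed precision, set to 0) with tertile main effects middle = 0.1417 and
#' top = 0.2041 and quadratic-age interactions 0.0002 / 0.0003.
#'
#' @inheritParams alspac_truth
#' @return a `simulation_truth`.
#' @export
ukb_truth <- function(n_individuals = 10000, seed = 1L, ...) {
  args <- list(
    n_individuals = n_individuals,
    center_age = 39,
    fixed_degree = 2L,
    beta_reference = c(0.8401, 0, 0),
    group_offsets = list(middle = c(0.1417, 0, 0.0002),
                         top = c(0.2041, 0, 0.0003)),
    covariate_effects = list(sex = 0.15, logbmi = 0.08, ses = 0.04,
                             smoking = 0.06, batch = 0, centre = 0),
    random_degree = 1L,
    G = diag(c(0.8, 0.001)),
    sigma2 = 2,
    il6_distribution = list(meanlog = 0, sdlog = 0.713, exponentiate = FALSE),
    crp_distribution = list(meanlog = 0.2, sdlog = 1.0),
    crp_correlation = 0.45,
    instrument_bounds = c(0, 6),
    rounding_enabled = FALSE,
    schedule = list(ages = c(40, 45, 50, 55, 60, 65, 70, 75), jitter_sd = 2),
    covariate_distributions = list(p_female = 0.54, bmi_meanlog = log(27),
                                   bmi_sdlog = 0.16, ses_levels = 5L,
                                   n_batches = 6L, n_centres = 10L,
                                   p_medication = 0.27, p_inflam = 0.16,
                                   p_died = 0.03),
    missingness = missingness_model("none"),
    seed = seed)
  do.call(simulation_truth, utils::modifyList(args, list(...)))
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat("Synthetic cohort truth\n")
  cat(sprintf("  persons: %d, waves: %d (ages %s)\n", x$n_individuals,
              length(x$schedule$ages),
              paste(range(x$schedule$ages), collapse = "-")))
  cat(sprintf("  fixed degree %d, random degree %d, sigma2 = %g\n",
              x$fixed_degree, x$random_degree, x$sigma2))
  cat(sprintf("  beta_reference: %s\n", paste(signif(x$beta_reference, 4), collapse = ", ")))
  cat(sprintf("  missingness: %s\n", x$missingness$mechanism))
  invisible(x)
}
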