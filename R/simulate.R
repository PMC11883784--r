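#' Draw per-person assessment ages from a wave schedule
#'
#' Each person's age at wave `w` is the schedule target age plus Gaussian
#' jitter. Jittered ages falling below `center_age` are truncated to
#' `center_age` (and counted in the `n_truncated` attribute), and ages are
#' sorted within person so assessment times are monotone.
#'
#' @param schedule list with `ages` (wave target ages) and `jitter_sd`
#'   (scalar or per-wave SD, years).
#' @param n number of persons.
#' @param seed optional seed; `NULL` (default) uses the current RNG state,
#'   which is how [simulate_cohort()] calls it.
#' @param center_age lower truncation bound for jittered ages
#'   (default `-Inf`, no truncation).
#' @return an `n` x `n_waves` matrix of ages with attribute `n_truncated`.
#' @export
assign_wave_ages <- function(schedule, n, seed = NULL, center_age = -Inf) {
  targets <- schedule$ages
  js <- rep(schedule$jitter_sd, length.out = length(targets))
  if (any(js < 0)) stopf("jitter SDs must be >= 0")
  if (!is.null(seed)) set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  W <- length(targets)
  ages <- matrix(rep(targets, each = n), nrow = n) +
    matrix(stats::rnorm(n * W, 0, rep(js, each = n)), nrow = n)
  n_trunc <- sum(ages < center_age)
  if (n_trunc > 0) {
    ages[ages < center_age] <- center_age
    message(sprintf("assign_wave_ages: %d jittered age(s) truncated to center_age = %g",
                    n_trunc, center_age))
  }
  ## enforce within-person monotonicity (jitter can swap adjacent waves)
  ages <- t(apply(ages, 1L, sort))
  if (W == 1L) ages <- matrix(ages, nrow = n)
  attr(ages, "n_truncated") <- n_trunc
  ages
}

#' Simulate a synthetic longitudinal cohort
#'
#' Generates a full cohort under a [simulation_truth()]: baseline covariates
#' and biomarkers, per-person assessment ages, person-level random effects
#' drawn from `G`, latent polynomial trajectory scores with tertile-linked
#' fixed effects, optional rounding/clipping to the instrument scale, and
#' wave-level missingness under the configured mechanism.
#'
#' Random numbers are consumed in a fixed, documented order so that seeds
#' are stable across versions: (1) covariates and flags, (2) IL-6/CRP,
#' (3) wave ages, (4) random effects, (5) residuals, (6) missingness.
#' Identical truths therefore produce bit-identical cohorts.
#'
#' @param truth a [simulation_truth()].
#' @return an object of class `cohort_simulation`: a list with
#'   * `symptoms`: long table (`person_id`, `wave`, `age_years`, `score`)
#'     of completed waves only;
#'   * `baseline`: one row per person (biomarkers, covariates, flags);
#'   * `latent`: pre-missingness oracle record (`ages`, `scores_complete`,
#'     `latent_scores`, `random_effects`, `tertile`, `observed`,
#'     `retention_prob`);
#'   * `truth`: the generating parameter set.
#' @export
simulate_cohort <- function(truth) {
  validate_truth(truth)
  n <- truth$n_individuals
  d <- truth$fixed_degree
  q <- truth$random_degree
  W <- length(truth$schedule$ages)
  cd <- truth$covariate_distributions
  set.seed(truth$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")

  ## (1) covariates and flags
  female <- stats::rbinom(n, 1L, cd$p_female)
  bmi <- stats::rlnorm(n, cd$bmi_meanlog, cd$bmi_sdlog)
  ses_idx <- sample.int(cd$ses_levels, n, replace = TRUE)
  smk_idx <- sample.int(3L, n, replace = TRUE, prob = cd$smoking_p)
  batch <- sample.int(cd$n_batches, n, replace = TRUE)
  centre <- sample.int(cd$n_centres, n, replace = TRUE)
  on_medication <- stats::rbinom(n, 1L, cd$p_medication) == 1L
  inflam_condition <- stats::rbinom(n, 1L, cd$p_inflam) == 1L
  died_after_baseline <- stats::rbinom(n, 1L, cd$p_died) == 1L
  ## alternative SES marker (deprivation-quintile-like), correlated with ses
  ses_sd <- stats::sd(ses_idx)
  ses_z <- if (is.finite(ses_sd) && ses_sd > 0) (ses_idx - mean(ses_idx)) / ses_sd else 0
  ses_lat <- 0.6 * ses_z + sqrt(1 - 0.36) * stats::rnorm(n)
  ses_alt_idx <- findInterval(ses_lat, stats::quantile(ses_lat, (1:4) / 5)) + 1L

  ## (2) biomarkers: bivariate Gaussian on the log scale
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  il6_log <- truth$il6_distribution$meanlog + truth$il6_distribution$sdlog * z1
  rho <- truth$crp_correlation
  crp_log <- truth$crp_distribution$meanlog +
    truth$crp_distribution$sdlog * (rho * z1 + sqrt(1 - rho^2) * z2)
  il6 <- if (isTRUE(truth$il6_distribution$exponentiate)) exp(il6_log) else il6_log
  crp <- exp(crp_log)

  ## (3) wave ages
  ages <- assign_wave_ages(truth$schedule, n, seed = NULL,
                           center_age = truth$center_age)

  ## (4) person-level random effects b_i ~ N(0, G)
  b <- matrix(stats::rnorm(n * (q + 1L)), nrow = n) %*% t(psd_sqrt(truth$G))

  ## (5) residuals
  eps <- matrix(stats::rnorm(n * W, 0, sqrt(truth$sigma2)), nrow = n)

  ## fixed trajectory coefficients per person (tertile-linked)
  tert <- assign_tertiles(stats::setNames(il6, seq_len(n)))
  grp <- tert$group
  coefs <- matrix(rep(truth$beta_reference, each = n), nrow = n)
  for (g in c("middle", "top")) {
    sel <- grp == g
    if (any(sel))
      coefs[sel, ] <- coefs[sel, , drop = FALSE] +
        matrix(rep(truth$group_offsets[[g]], each = sum(sel)), nrow = sum(sel))
  }

  ce <- truth$covariate_effects
  logbmi_z <- zscale(log(bmi), warn_label = "log(bmi)")
  covar_shift <- ce$sex * female + ce$logbmi * logbmi_z +
    ce$ses * (ses_idx - 1L) + ce$smoking * (smk_idx - 1L) +
    ce$batch * (batch - 1L) + ce$centre * (centre - 1L)

  C <- ages - truth$center_age
  y <- matrix(covar_shift, nrow = n, ncol = W)
  for (k in 0:d) y <- y + coefs[, k + 1L] * C^k
  for (k in 0:q) y <- y + b[, k + 1L] * C^k
  y <- y + eps

  score <- y
  if (truth$rounding_enabled)
    score <- pmin(pmax(round(y), truth$instrument_bounds[1]), truth$instrument_bounds[2])

  ## (6) missingness
  mm <- truth$missingness
  if (mm$mechanism == "none") {
    p_obs <- matrix(1, n, W)
    observed <- matrix(TRUE, n, W)
  } else {
    eta <- matrix(stats::qlogis(rep(rep(mm$wave_retention, length.out = W), each = n)),
                  nrow = n)
    if (mm$mechanism == "mar_baseline") {
      shift <- mm$tertile_log_odds[match(as.character(grp), c("bottom", "middle", "top"))]
      eta <- eta + shift
    } else if (mm$mechanism == "mnar_score") {
      eta <- eta + mm$score_log_odds * y
    }
    p_obs <- stats::plogis(eta)
    observed <- matrix(stats::runif(n * W), nrow = n) < p_obs
  }

  idx <- which(t(observed))           # row-major: person-major ordering
  person <- rep(seq_len(n), each = W)[idx]
  wave <- rep(seq_len(W), times = n)[idx]
  symptoms <- data.frame(person_id = person,
                         wave = wave,
                         age_years = t(ages)[idx],
                         score = t(score)[idx])

  ses_lab <- if (cd$ses_levels == 2L) c("low", "high")[ses_idx] else paste0("q", ses_idx)
  baseline <- data.frame(
    person_id = seq_len(n),
    il6 = il6, crp = crp,
    sex = c("male", "female")[female + 1L],
    bmi = bmi,
    ses = ses_lab,
    ses_alt = paste0("q", ses_alt_idx),
    smoking = c("never", "former", "current")[smk_idx],
    batch = paste0("b", batch),
    centre = paste0("c", centre),
    on_medication = on_medication,
    inflam_condition = inflam_condition,
    bmi_ge_40 = bmi >= 40,
    died_after_baseline = died_after_baseline)

  structure(list(symptoms = symptoms,
                 baseline = baseline,
                 latent = list(ages = ages,
                               scores_complete = score,
                               latent_scores = y,
                               random_effects = b,
                               tertile = grp,
                               observed = observed,
                               retention_prob = p_obs),
                 truth = truth),
            class = "cohort_simulation")
}

#' @export
print.cohort_simulation <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d persons, %d symptom rows (%d waves scheduled)\n",
              nrow(x$baseline), nrow(x$symptoms), ncol(x$latent$ages)))
  cat(sprintf("  missingness: %s; rounding: %s\n",
              x$truth$missingness$mechanism, x$truth$rounding_enabled))
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Writes `symptoms.csv`, `baseline.csv` and `truth.json` (UTF-8, header
#' row, '.' decimal separator) to `dir`.
#'
#' @param sim a `cohort_simulation`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(sim$symptoms, file.path(dir, "symptoms.csv"), row.names = FALSE)
  utils::write.csv(sim$baseline, file.path(dir, "baseline.csv"), row.names = FALSE)
  tr <- sim$truth
  tr$missingness <- unclass(tr$missingness)
  tr$G <- unname(apply(tr$G, 1L, identity, simplify = FALSE))
  jsonlite::write_json(unclass(tr), file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing `symptoms.csv` and `baseline.csv`.
#' @return list with `symptoms` and `baseline` data frames.
#' @export
read_cohort <- function(dir) {
  list(symptoms = utils::read.csv(file.path(dir, "symptoms.csv")),
       baseline = utils::read.csv(file.path(dir, "baseline.csv")))
}
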