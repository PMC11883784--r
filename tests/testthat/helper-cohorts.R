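# Shared fixtures: small synthetic cohorts and cached fits. Everything is
# generated in code under fixed seeds; expensive fits are memoised so several
# test files can reuse them.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, force(expr), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

## quiet wrappers: age-jitter truncation messages and instrument-bound
## warnings are expected for the published-coefficient truths
sim_quiet <- function(truth) suppressMessages(simulate_cohort(truth))
prep_quiet <- function(baseline, symptoms, config)
  suppressWarnings(build_prepared_cohort(baseline, symptoms, config))

small_alspac <- function(n = 400, seed = 101, ...)
  sim_quiet(alspac_truth(n_individuals = n, seed = seed, ...))

small_ukb <- function(n = 600, seed = 202, ...)
  sim_quiet(ukb_truth(n_individuals = n, seed = seed, ...))

## a moderate ALSPAC-like cohort + quadratic fit reused across contrast and
## sensitivity tests
shared_prep <- function() memo("shared_prep", {
  sim <- small_alspac(n = 500, seed = 42)
  prep_quiet(sim$baseline, sim$symptoms, analysis_config("alspac_like"))
})

shared_fit <- function() memo("shared_fit", {
  spec <- growth_spec(2, 1, covariates = c("sex", "logbmi_z", "ses"))
  fit_growth_model(shared_prep(), spec, keep_model = FALSE)
})

## hand-made toy fit: degree-1 trajectory, single (reference) group
toy_fit <- function(beta = c("(Intercept)" = 2, age1 = 0.5),
                    V = diag(c(0.01, 1e-4))) {
  fit_result(beta, V,
             info = list(degree = 1L, levels = "bottom", reference = "bottom",
                         covariate_info = list(), center_age = 0,
                         age_range = c(0, 10)))
}

## toy two-group fit with a pure main-effect offset and no interaction noise
toy_group_fit <- function() {
  nm <- c("(Intercept)", "age1", "grp_top", "grp_top_age1")
  beta <- stats::setNames(c(1, 0.2, 0.5, 0), nm)
  V <- diag(c(0.02, 1e-4, 0.01, 0))
  fit_result(beta, V,
             info = list(degree = 1L, levels = c("bottom", "top"),
                         reference = "bottom", covariate_info = list(),
                         center_age = 0, age_range = c(0, 18)))
}

## brute-force Benjamini-Hochberg step-up (independent oracle)
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (j in seq_len(m)) {
    cand <- vapply(j:m, function(k) m * p[o[k]] / k, numeric(1))
    adj[o[j]] <- min(1, min(cand))
  }
  adj
}
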