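test_that("design columns follow the documented order and counting rule", {
  sim <- small_alspac(n = 120, seed = 33)
  prep <- prep_quiet(sim$baseline, sim$symptoms, analysis_config("alspac_like"))

  ## d = 1, two groups (collapse middle+top into one level), no covariates
  prep2 <- prep
  prep2$data$two <- factor(ifelse(prep$data$tertile == "top", "top", "rest"),
                           levels = c("rest", "top"))
  des1 <- build_design(prep2, growth_spec(1, 0, group_var = "two",
                                          reference = "rest"))
  expect_identical(des1$fixed_cols, c("age1", "grp_top", "grp_top_age1"))

  ## d = 4, tertiles, 3 covariates -> 1 + 4 + 2 + 8 + covariate dummies
  des4 <- build_design(prep, growth_spec(4, 1,
                                         covariates = c("sex", "logbmi_z", "ses")))
  expect_length(des4$fixed_cols, 4 + 2 + 8 + 3)  # +1 implicit intercept = 18
  expect_identical(des4$fixed_cols[1:7],
                   c("age1", "age2", "age3", "age4", "grp_middle", "grp_top",
                     "grp_middle_age1"))

  ## a person with a single observation still contributes a valid row
  one <- prep
  keep <- !duplicated(one$data$person_id)
  one$data <- one$data[keep | one$data$person_id != one$data$person_id[1], ]
  expect_silent(build_design(one, growth_spec(2, 1)))

  ## single-level grouping is rank-deficient by construction
  prep3 <- prep
  prep3$data$mono <- "only"
  expect_error(build_design(prep3, growth_spec(1, 0, group_var = "mono")),
               "single level")
})

test_that("noiseless simulation is interpolated to the generating coefficients", {
  tr <- alspac_truth(n_individuals = 150, seed = 4, sigma2 = 1e-12,
                     G = matrix(0, 2, 2),
                     covariate_effects = list(sex = 0, logbmi = 0, ses = 0))
  sim <- sim_quiet(tr)
  prep <- prep_quiet(sim$baseline, sim$symptoms, analysis_config("alspac_like"))
  fit <- suppressWarnings(fit_growth_model(prep, growth_spec(4, 1)))
  truth <- c(tr$beta_reference[1], tr$beta_reference[-1],
             tr$group_offsets$middle[1], tr$group_offsets$top[1],
             tr$group_offsets$middle[-1], tr$group_offsets$top[-1])
  est <- fit$beta[c("(Intercept)", paste0("age", 1:4), "grp_middle", "grp_top",
                    paste0("grp_middle_age", 1:4), paste0("grp_top_age", 1:4))]
  expect_lt(max(abs(est - truth)), 1e-6)
})

test_that("with no random-effect variance the MLE equals ordinary least squares", {
  tr <- alspac_truth(n_individuals = 120, seed = 5, sigma2 = 4, G = matrix(0, 2, 2))
  sim <- sim_quiet(tr)
  prep <- prep_quiet(sim$baseline, sim$symptoms, analysis_config("alspac_like"))
  spec <- growth_spec(4, 1, covariates = c("sex", "logbmi_z", "ses"))
  fit <- suppressWarnings(fit_growth_model(prep, spec))
  des <- build_design(prep, spec)
  X <- as.matrix(cbind(1, des$frame[des$fixed_cols]))
  ols <- qr.solve(X, des$frame$score)
  expect_lt(max(abs(fit$beta - ols)), 1e-8)
  expect_true(fit$singular)  # G is estimated on the boundary
})

test_that("moderate-noise simulation recovers every fixed effect within 3 SEs", {
  tr <- alspac_truth(n_individuals = 2000, seed = 6, fixed_degree = 1L,
                     beta_reference = c(1.5, 0.3),
                     group_offsets = list(middle = c(0.2, 0), top = c(0.6, 0.05)),
                     G = diag(c(2, 0.01)), sigma2 = 4)
  sim <- sim_quiet(tr)
  prep <- prep_quiet(sim$baseline, sim$symptoms, analysis_config("alspac_like"))
  fit <- fit_growth_model(prep, growth_spec(1, 1,
                                            covariates = c("sex", "logbmi_z", "ses")))
  truth <- c(`(Intercept)` = 1.5, age1 = 0.3, grp_middle = 0.2, grp_top = 0.6,
             grp_middle_age1 = 0, grp_top_age1 = 0.05)
  se <- sqrt(diag(fit$V))[names(truth)]
  expect_true(all(abs(fit$beta[names(truth)] - truth) < 3 * se))
})

test_that("estimates are invariant to row order and to the reference coding", {
  prep <- shared_prep()
  spec <- growth_spec(2, 1, covariates = "sex")
  f1 <- fit_growth_model(prep, spec, keep_model = FALSE)
  prep_sh <- prep
  set.seed(1)
  prep_sh$data <- prep_sh$data[sample(nrow(prep_sh$data)), ]
  f2 <- fit_growth_model(prep_sh, spec, keep_model = FALSE)
  expect_lt(max(abs(f1$beta - f2$beta)), 1e-8)

  ## recoding the reference tertile reparameterizes but predicts identically
  f3 <- fit_growth_model(prep, growth_spec(2, 1, covariates = "sex",
                                           reference = "top"),
                         keep_model = FALSE)
  for (g in c("bottom", "middle", "top"))
    expect_equal(predict_score(f1, g, 16)$estimate,
                 predict_score(f3, g, 16)$estimate, tolerance = 1e-5)
})

test_that("degree ladder reports BIC identities, nesting, and picks by BIC", {
  prep <- shared_prep()
  cmp <- select_degree(prep, candidates = 1:3, random_degree = 1,
                       covariates = "sex")
  tab <- cmp$table
  expect_equal(tab$bic, -2 * tab$loglik + tab$n_params * log(nrow(prep$data)),
               tolerance = 1e-10)
  ## likelihood is monotone over nested candidates
  expect_true(all(diff(tab$loglik) >= -1e-6))
  expect_identical(cmp$chosen, tab$degree[which.min(tab$bic)])
  expect_true(all(tab$lrt_stat[-1] >= 0))
})

test_that("random-structure fallback engages rather than failing outright", {
  ## a cohort with essentially no slope variance makes high random orders
  ## ill-conditioned; requesting q = 2 must at worst fall back, not error
  tr <- ukb_truth(n_individuals = 150, seed = 44, G = diag(c(0.8, 1e-8)),
                  schedule = list(ages = c(40, 45, 50), jitter_sd = 0.5))
  sim <- sim_quiet(tr)
  prep <- prep_quiet(sim$baseline, sim$symptoms, analysis_config("ukb_like"))
  fit <- suppressWarnings(fit_growth_model(prep, growth_spec(2, 2)))
  expect_s3_class(fit, "growth_fit")
  expect_true(fit$converged)
  used <- fit$info$random_degree_used
  expect_true(used <= 2)
  if (used < 2) expect_match(fit$fallback_applied, "reduced")
})

test_that("fit results round-trip through JSON with names and covariance intact", {
  fit <- shared_fit()
  path <- withr::local_tempfile(fileext = ".json")
  write_fit_json(fit, path)
  back <- read_fit_json(path)
  expect_equal(back$beta, fit$beta)
  expect_equal(unname(back$V), unname(fit$V), tolerance = 1e-12)
  expect_equal(back$sigma2, fit$sigma2)
  ## reloaded fits drive the contrast machinery identically
  expect_equal(contrast_scores(back, "top", "bottom", 16)$diff,
               contrast_scores(fit, "top", "bottom", 16)$diff)
})
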