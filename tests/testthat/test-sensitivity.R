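test_that("sex-split grouping yields six populated cells and errors on empty ones", {
  prep <- shared_prep()
  prep6 <- sex_split_groups(prep)
  tab <- table(prep6$baseline$sex_tertile)
  expect_length(tab, 6L)
  expect_true(all(tab > 0))
  ## cells are roughly balanced in a balanced cohort
  expect_lt(max(tab) / min(tab), 2.5)

  broken <- prep
  broken$data$sex <- "female"
  broken$baseline$sex <- "female"
  expect_error(sex_split_groups(broken), "empty sex x tertile cell")
})

test_that("a female-specific tertile effect is recovered only within females", {
  ## plant a sex-specific effect by post-hoc construction: add an offset to
  ## the scores of female top-tertile persons only
  sim <- small_alspac(n = 1500, seed = 55, fixed_degree = 2L,
                      beta_reference = c(2, 0.4, -0.01),
                      group_offsets = list(middle = c(0, 0, 0), top = c(0, 0, 0)),
                      G = diag(c(2, 0.01)), sigma2 = 4)
  boost <- 1.2
  fem_top <- sim$baseline$person_id[sim$baseline$sex == "female" &
                                      sim$latent$tertile == "top"]
  sel <- sim$symptoms$person_id %in% fem_top
  sim$symptoms$score[sel] <- sim$symptoms$score[sel] + boost
  prep <- prep_quiet(sim$baseline, sim$symptoms, analysis_config("alspac_like"))
  prep6 <- sex_split_groups(prep)
  fit6 <- fit_growth_model(prep6, growth_spec(2, 1, group_var = "sex_tertile",
                                              reference = "male_bottom"),
                           keep_model = FALSE)
  age <- 16
  cf <- contrast_scores(fit6, "female_top", "female_bottom", age)
  cm <- contrast_scores(fit6, "male_top", "male_bottom", age)
  expect_lt(abs(cf$diff - boost), 3 * cf$se)
  expect_lt(abs(cm$diff), 3 * cm$se)
})

test_that("inverse normal transform matches the Blom closed form and rank order", {
  expect_equal(inverse_normal_transform(c(3, 1, 2)),
               c(0.8694, -0.8694, 0), tolerance = 1e-4)
  ## middle value of a symmetric odd-length input maps to 0
  expect_equal(inverse_normal_transform(c(10, 20, 30, 40, 50))[3], 0)
  set.seed(61)
  x <- rlnorm(200)
  y <- inverse_normal_transform(x)
  expect_identical(order(y), order(x))
  ## monotone transforms of the input leave the result unchanged
  expect_equal(inverse_normal_transform(log(x)), y)
  expect_error(inverse_normal_transform(rep(2, 5)), "distinct")
})

test_that("continuous-exposure model recovers a linear-in-exposure truth", {
  ## build scores whose group structure is monotone in IL-6: use tertile
  ## offsets that increase bottom < middle < top
  sim <- small_alspac(n = 1200, seed = 57, fixed_degree = 1L,
                      beta_reference = c(2, 0.3),
                      group_offsets = list(middle = c(0.4, 0), top = c(0.8, 0)),
                      G = diag(c(2, 0.01)), sigma2 = 4)
  prep <- prep_quiet(sim$baseline, sim$symptoms, analysis_config("alspac_like"))
  fit_c <- continuous_il6_model(prep, fixed_degree = 1)
  expect_gt(fit_c$beta[["il6_int"]] / sqrt(fit_c$V["il6_int", "il6_int"]), 3)
  ## and the tertile model shows monotone offsets
  fit_t <- fit_growth_model(prep, growth_spec(1, 1), keep_model = FALSE)
  expect_gt(fit_t$beta[["grp_middle"]], 0)
  expect_gt(fit_t$beta[["grp_top"]], fit_t$beta[["grp_middle"]])
})

test_that("flag exclusions re-run the pipeline with correct bookkeeping", {
  prep <- shared_prep()
  spec <- growth_spec(2, 1, covariates = "sex")
  grid <- c(10, 16, 22)

  ## nobody flagged -> identical to the main run
  none <- prep
  none$raw$baseline$on_medication <- FALSE
  res0 <- suppressWarnings(exclusion_rerun(none, "on_medication", spec, grid))
  expect_identical(res0$n_removed, 0L)
  main <- fit_growth_model(prep, spec, keep_model = FALSE)
  expect_equal(res0$fit$beta, main$beta, tolerance = 1e-10)

  ## outcome-independent flags shift contrasts by less than 3 combined SEs
  res1 <- suppressWarnings(exclusion_rerun(prep, "on_medication", spec, grid))
  expect_identical(res1$n_removed,
                   sum(prep$baseline$on_medication))
  mt <- contrast_table(main, grid)
  comb <- sqrt(res1$contrasts$se^2 + mt$se^2)
  expect_true(all(abs(res1$contrasts$diff - mt$diff) < 3 * comb))
  expect_error(exclusion_rerun(prep, "no_such_flag", spec, grid), "not in baseline")
})

test_that("attrition regression is null without attrition and directional under it", {
  ## complete data: counts constant -> degenerate with NA inference
  prep_c <- shared_prep()
  expect_warning(res_c <- attrition_regression(prep_c), "constant")
  expect_true(all(is.na(res_c$coefficients$p)))

  ## exposure-linked attrition: negative, significant top coefficient
  mm <- missingness_model("mar_baseline", wave_retention = 0.85,
                          tertile_log_odds = c(0, -0.3, -0.6))
  sim <- sim_quiet(ukb_truth(n_individuals = 8000, seed = 66, missingness = mm))
  prep_m <- prep_quiet(sim$baseline, sim$symptoms, analysis_config("ukb_like"))
  res_m <- attrition_regression(prep_m)
  top <- res_m$coefficients[res_m$coefficients$term == "top", ]
  expect_lt(top$estimate, 0)
  expect_lt(top$p, 0.001)

  ## invitational waves can be excluded from the count
  res_x <- attrition_regression(prep_m, excluded_waves = c(7, 8))
  expect_true(all(res_x$counts$n_completed <= 6))
})

test_that("no-attrition replicates show ~no tertile-count association", {
  hits <- 0L
  for (s in 1:8) {
    mm <- missingness_model("mcar", wave_retention = 0.8)
    sim <- sim_quiet(ukb_truth(n_individuals = 800, seed = 700 + s,
                               missingness = mm,
                               schedule = list(ages = c(40, 50, 60, 70),
                                               jitter_sd = 1)))
    prep <- prep_quiet(sim$baseline, sim$symptoms, analysis_config("ukb_like"))
    res <- attrition_regression(prep)
    if (any(abs(res$coefficients$t) >= 3)) hits <- hits + 1L
  }
  expect_lte(hits, 2L)
})

test_that("minimum-assessment refits drop the right persons", {
  prep <- shared_prep()
  spec <- growth_spec(2, 1)
  grid <- c(10, 16)
  r1 <- suppressWarnings(min_assessments_rerun(prep, 1, spec, grid))
  expect_identical(r1$n_removed, 0L)
  main <- fit_growth_model(prep, spec, keep_model = FALSE)
  expect_equal(r1$fit$beta, main$beta, tolerance = 1e-10)

  ## hand-built counts: persons with 1,1,2,2,3 rows and k = 2 keep 3 persons
  bl <- data.frame(person_id = 1:5, il6 = c(0.2, 0.6, 1.0, 2.0, 3.0),
                   crp = 1, bmi = 20)
  sy <- data.frame(person_id = c(1, 2, 3, 3, 4, 4, 5, 5, 5),
                   age_years = c(10, 10, 10, 13, 10, 13, 10, 13, 16),
                   score = c(3, 4, 5, 6, 2, 3, 4, 5, 6))
  cfg <- analysis_config("alspac_like", min_assessments = 2L)
  prep2 <- suppressWarnings(build_prepared_cohort(bl, sy, cfg))
  expect_identical(sort(as.integer(as.character(prep2$baseline$person_id))),
                   c(3L, 4L, 5L))
  expect_error(min_assessments_rerun(prep, 0, spec, grid), ">= 1")
})
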