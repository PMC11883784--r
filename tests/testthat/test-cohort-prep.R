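test_that("CRP exclusion removes at and above the threshold, inclusively", {
  bl <- data.frame(person_id = 1:4, crp = c(1.0, 9.99, 10.0, 12.3))
  out <- exclude_high_crp(bl)
  expect_identical(out$person_id, 1:2)
  expect_identical(attr(out, "n_removed"), 2L)

  low <- data.frame(person_id = 1:3, crp = c(1, 2, 3))
  out2 <- exclude_high_crp(low)
  expect_identical(out2$person_id, low$person_id)
  expect_identical(attr(out2, "n_removed"), 0L)

  expect_error(exclude_high_crp(bl, threshold = 0), "> 0")
  expect_error(exclude_high_crp(data.frame(person_id = 1)), "crp")
})

test_that("CRP removal count matches a brute-force recount on skewed values", {
  set.seed(31)
  crp <- rlnorm(1000, meanlog = 0.5, sdlog = 1.2)
  bl <- data.frame(person_id = seq_along(crp), crp = crp)
  out <- exclude_high_crp(bl)
  expect_identical(attr(out, "n_removed"), sum(crp >= 10))
  expect_identical(nrow(out), sum(crp < 10))
})

test_that("missing CRP is retained by default and droppable by flag", {
  bl <- data.frame(person_id = 1:3, crp = c(NA, 2, 11))
  keep <- exclude_high_crp(bl)
  expect_identical(keep$person_id, 1:2)
  expect_identical(attr(keep, "n_missing_crp"), 1L)
  drop <- exclude_high_crp(bl, drop_missing = TRUE)
  expect_identical(drop$person_id, 2L)
})

test_that("tertile assignment splits exact thirds and handles near-thirds", {
  t9 <- assign_tertiles(setNames(1:9, 1:9))
  expect_identical(as.character(t9$group), rep(c("bottom", "middle", "top"), each = 3))

  t10 <- assign_tertiles(setNames(1:10, 1:10))
  sizes <- table(t10$group)
  expect_lte(max(sizes) - min(sizes), 1)
  ## sort-and-slice oracle: concatenating sorted groups reproduces the input
  v <- setNames(1:10, 1:10)
  recon <- c(sort(v[t10$group == "bottom"]), sort(v[t10$group == "middle"]),
             sort(v[t10$group == "top"]))
  expect_identical(unname(recon), 1:10)

  expect_error(assign_tertiles(rep(5, 10)), "identical")
  expect_error(assign_tertiles(c(1, 2)), "at least 3")
})

test_that("tertile cutoffs are non-decreasing and ties go to the upper group", {
  v <- setNames(c(1, 2, 2, 2, 3, 4, 5, 6, 7), 1:9)
  t <- assign_tertiles(v)
  expect_true(all(diff(t$cutoffs) >= 0))
  at_cut <- v == t$cutoffs["q13"]
  expect_true(all(t$group[at_cut] != "bottom"))
})

test_that("covariate transforms log BMI and Z-scale with the documented policies", {
  bl <- data.frame(person_id = 1:3, bmi = c(20, 25, 31.25))
  out <- transform_covariates(bl)
  expect_equal(out$logbmi, c(2.9957, 3.2189, 3.4420), tolerance = 1e-4)
  expect_equal(out$logbmi_z, c(-1, 0, 1), tolerance = 1e-6)

  set.seed(5)
  bl2 <- data.frame(person_id = 1:50, bmi = rlnorm(50, 3, 0.2),
                    townsend = rnorm(50))
  out2 <- transform_covariates(bl2, continuous = "townsend")
  expect_lt(abs(mean(out2$townsend_z)), 1e-10)
  expect_equal(sd(out2$townsend_z), 1, tolerance = 1e-10)

  constant <- data.frame(person_id = 1:3, bmi = rep(exp(1), 3))
  expect_warning(out3 <- transform_covariates(constant), "zero variance")
  expect_identical(out3$logbmi_z, rep(0, 3))

  bad <- data.frame(person_id = 1:3, bmi = c(-1, 20, 25))
  expect_warning(out4 <- transform_covariates(bad), "non-positive")
  expect_true(is.na(out4$logbmi[1]))
})

test_that("age centering is an exact shift and round-trips", {
  expect_equal(as.numeric(center_age(c(10, 13, 16), 10)), c(0, 3, 6))
  expect_equal(as.numeric(center_age(c(39, 86), 39)), c(0, 47))
  set.seed(8)
  a <- runif(100, 10, 30)
  expect_equal(as.numeric(center_age(a, 12)) + 12, a)
})

test_that("prepared cohort bookkeeping counts each exclusion step", {
  bl <- data.frame(person_id = 1:5, il6 = c(0.2, 0.5, 0.9, 1.5, 3),
                   crp = c(1, 2, 11, 3, 4), bmi = rep(20, 5),
                   sex = rep(c("male", "female"), length.out = 5))
  ## person 3 carries CRP 11; person 5 has no symptom rows at all
  sy <- data.frame(person_id = rep(c(1, 2, 4), each = 2),
                   age_years = rep(c(10, 13), 3),
                   score = rep(c(3, 5), 3))
  cfg <- analysis_config("alspac_like")
  prep <- suppressWarnings(build_prepared_cohort(bl, sy, cfg))
  expect_identical(nrow(prep$baseline), 3L)  # 1 lost to CRP, 1 to no outcome
  log <- prep$inclusion_log
  expect_identical(log$n_removed[log$step == "crp_ge_10"], 1L)
  expect_identical(log$n_removed[log$step == "lt_1_assessments"], 1L)
  ## person 3 (CRP 11) is excluded even though il6 would place it mid-range
  expect_false("3" %in% as.character(prep$baseline$person_id))
})

test_that("no-exclusion simulation keeps every simulated symptom row", {
  sim <- small_ukb(n = 200, seed = 21,
                   crp_distribution = list(meanlog = -2, sdlog = 0.3))
  prep <- prep_quiet(sim$baseline, sim$symptoms, analysis_config("ukb_like"))
  expect_identical(nrow(prep$data), nrow(sim$symptoms))
})

test_that("tertiles are computed on the post-exclusion sample", {
  set.seed(77)
  n <- 90
  bl <- data.frame(person_id = 1:n, il6 = exp(rnorm(n)), crp = runif(n, 0, 5),
                   bmi = rlnorm(n, 3, 0.1))
  bl$crp[bl$il6 > quantile(bl$il6, 0.8)] <- 12  # high-CRP persons carry high IL-6
  sy <- data.frame(person_id = rep(1:n, each = 2), age_years = rep(c(10, 13), n),
                   score = rpois(2 * n, 4))
  cfg <- analysis_config("alspac_like")
  prep <- build_prepared_cohort(bl, sy, cfg)
  kept <- exclude_high_crp(bl)
  oracle <- assign_tertiles(setNames(kept$il6, kept$person_id))
  expect_identical(as.character(prep$baseline$tertile),
                   as.character(oracle$group[as.character(prep$baseline$person_id)]))
  ## and those cutoffs differ from the pre-exclusion ones, so order matters
  pre <- assign_tertiles(setNames(bl$il6, bl$person_id))
  expect_false(isTRUE(all.equal(pre$cutoffs, prep$cutoffs)))
})

test_that("preparation is idempotent and exclusions are monotone", {
  sim <- small_alspac(n = 150, seed = 23)
  cfg <- analysis_config("alspac_like")
  prep1 <- prep_quiet(sim$baseline, sim$symptoms, cfg)
  ## re-run on the already-included raw rows: nothing changes
  bl2 <- sim$baseline[as.character(sim$baseline$person_id) %in%
                        as.character(prep1$baseline$person_id), ]
  prep2 <- prep_quiet(bl2, prep1$data[c("person_id", "wave", "age_years", "score")],
                      cfg)
  expect_identical(as.character(prep2$baseline$person_id),
                   as.character(prep1$baseline$person_id))
  expect_identical(as.character(prep2$baseline$tertile),
                   as.character(prep1$baseline$tertile))
  expect_equal(prep2$data$score, prep1$data$score)
  ## adding an exclusion rule never grows the cohort
  cfg2 <- analysis_config("alspac_like", exclude_flags = "on_medication")
  prep3 <- prep_quiet(sim$baseline, sim$symptoms, cfg2)
  expect_lte(nrow(prep3$baseline), nrow(prep1$baseline))
  ## every included person is in exactly one tertile
  expect_false(any(is.na(prep1$baseline$tertile)))
})
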