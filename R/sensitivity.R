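#' Split tertile groups by sex
#'
#' Replaces the 3-level tertile grouping with the 6-level sex x tertile
#' grouping (male_bottom, ..., female_top) so the unchanged fit/contrast
#' machinery estimates sex-specific trajectories. Within-sex contrasts are
#' then extracted as e.g. `female_top` vs `female_bottom`.
#'
#' @param prep a `prepared_cohort` whose data contain `sex` and `tertile`.
#' @return the cohort with an added 6-level `sex_tertile` column (in both
#'   `data` and `baseline`).
#' @export
sex_split_groups <- function(prep) {
  for (col in c("sex", "tertile"))
    if (!col %in% names(prep$data)) stopf("prepared data lack column '%s'", col)
  lv <- as.vector(outer(c("bottom", "middle", "top"), c("male", "female"),
                        function(t, s) paste(s, t, sep = "_")))
  mk <- function(sex, tert) factor(paste(sex, tert, sep = "_"), levels = lv)
  g <- mk(prep$data$sex, prep$data$tertile)
  empty <- lv[!lv %in% unique(as.character(g))]
  if (length(empty))
    stopf("empty sex x tertile cell(s): %s", paste(empty, collapse = ", "))
  prep$data$sex_tertile <- g
  prep$baseline$sex_tertile <- mk(prep$baseline$sex, prep$baseline$tertile)
  prep
}

#' Rank-based inverse normal transform
#'
#' Maps values to normal quantiles via `qnorm((r - c) / (n - 2c + 1))` with
#' average ranks for ties and the Blom offset `c = 3/8` by default (so
#' `n = 3` distinct values map to -0.8694, 0, 0.8694). Monotone in the input
#' ranks. Set `scale = TRUE` to additionally Z-scale the result.
#'
#' @param values numeric vector, at least 2 distinct non-missing values.
#' @param offset rank offset (3/8 = Blom).
#' @param scale Z-scale the transformed values?
#' @return transformed vector (missing values preserved).
#' @export
inverse_normal_transform <- function(values, offset = 3/8, scale = FALSE) {
  ok <- !is.na(values)
  v <- values[ok]
  if (length(unique(v)) < 2L) stopf("need at least 2 distinct values")
  n <- length(v)
  r <- rank(v, ties.method = "average")
  out <- values
  out[ok] <- stats::qnorm((r - offset) / (n - 2 * offset + 1))
  if (scale) out[ok] <- zscale(out[ok], warn_label = "INT values")
  out
}

#' Continuous-exposure growth model
#'
#' Sensitivity check on tertile categorisation: replaces the tertile terms
#' with a single continuous IL-6 term (inverse normal transformed, then
#' Z-scaled) plus its interactions with every age power, and fits the same
#' mixed model.
#'
#' @param prep a `prepared_cohort` (its data must carry `il6`).
#' @param fixed_degree,random_degree,covariates,method as in [growth_spec()].
#' @return a `growth_fit` with coefficient `il6_int` (per SD of transformed
#'   IL-6) and interactions `il6_int_age<k>`.
#' @export
continuous_il6_model <- function(prep, fixed_degree, random_degree = 1,
                                 covariates = character(), method = "ML") {
  if (!"il6" %in% names(prep$baseline)) stopf("baseline lacks 'il6'")
  int_by_person <- inverse_normal_transform(
    stats::setNames(prep$baseline$il6, prep$baseline$person_id), scale = TRUE)
  prep$data$il6_int <- as.numeric(
    int_by_person[match(as.character(prep$data$person_id),
                        as.character(prep$baseline$person_id))])
  spec <- growth_spec(fixed_degree, random_degree, covariates = covariates,
                      method = method, continuous_var = "il6_int")
  fit_growth_model(prep, spec, keep_model = FALSE)
}

#' Re-run the pipeline after a flag-based exclusion
#'
#' Drops persons with the given boolean flag set, rebuilds the prepared
#' cohort from the retained raw tables (tertiles recomputed on the retained
#' sample), refits and recomputes the contrast table.
#'
#' @param prep the main-run `prepared_cohort` (carries its raw inputs).
#' @param flag name of a logical baseline column (e.g. `"on_medication"`,
#'   `"inflam_condition"`, `"bmi_ge_40"`, `"died_after_baseline"`).
#' @param spec the [growth_spec()] of the main analysis.
#' @param age_grid,pairs as in [contrast_table()].
#' @param freeze_tertiles reuse the main run's tertile assignment instead of
#'   recomputing it on the retained sample?
#' @return list with `fit`, `contrasts`, `n_removed`, and `prep` (the
#'   re-prepared cohort).
#' @export
exclusion_rerun <- function(prep, flag, spec, age_grid, pairs = NULL,
                            freeze_tertiles = FALSE) {
  bl <- prep$raw$baseline
  if (!flag %in% names(bl)) stopf("flag column '%s' not in baseline", flag)
  f <- bl[[flag]]
  n_removed <- sum(!is.na(f) & f & as.character(bl$person_id) %in%
                     as.character(prep$baseline$person_id))
  bl2 <- bl[is.na(f) | !f, , drop = FALSE]
  prep2 <- build_prepared_cohort(bl2, prep$raw$symptoms, prep$config)
  if (freeze_tertiles) {
    old <- prep$baseline$tertile[match(as.character(prep2$baseline$person_id),
                                       as.character(prep$baseline$person_id))]
    prep2$baseline$tertile <- old
    prep2$data$tertile <- prep2$baseline$tertile[
      match(as.character(prep2$data$person_id),
            as.character(prep2$baseline$person_id))]
    prep2$cutoffs <- prep$cutoffs
  }
  fit <- fit_growth_model(prep2, spec, keep_model = FALSE)
  list(fit = fit, contrasts = contrast_table(fit, age_grid, pairs),
       n_removed = n_removed, prep = prep2)
}

#' Attrition regression of completed-wave counts on tertile
#'
#' Ordinary least squares of each person's number of completed assessments
#' (over non-excluded waves) on tertile indicators with the bottom tertile
#' as reference. A negative, significant top-tertile coefficient indicates
#' exposure-dependent attrition. Waves only a subset of persons were invited
#' to (e.g. imaging visits) can be excluded from the count.
#'
#' @param prep a `prepared_cohort`.
#' @param excluded_waves wave labels to drop from the count (requires a
#'   `wave` column in the prepared data).
#' @return object of class `attrition_result`: list with `counts`
#'   (per-person data frame) and `coefficients` (estimate, se, t, p per
#'   tertile term). Zero-variance counts give `NA` inference with a warning.
#' @export
attrition_regression <- function(prep, excluded_waves = NULL) {
  d <- prep$data
  if (!is.null(excluded_waves)) {
    if (!"wave" %in% names(d)) stopf("prepared data lack a 'wave' column")
    d <- d[!d$wave %in% excluded_waves, , drop = FALSE]
  }
  cnt <- as.data.frame(table(person_id = d$person_id), stringsAsFactors = FALSE)
  names(cnt)[2] <- "n_completed"
  bl <- prep$baseline
  cnt$tertile <- bl$tertile[match(cnt$person_id, as.character(bl$person_id))]
  cnt <- cnt[!is.na(cnt$tertile), , drop = FALSE]
  if (length(unique(cnt$tertile)) < 2L) stopf("only one tertile present")
  if (stats::var(cnt$n_completed) == 0) {
    warning("completed-wave counts are constant; inference undefined", call. = FALSE)
    co <- data.frame(term = c("middle", "top"), estimate = 0, se = NA_real_,
                     t = NA_real_, p = NA_real_)
  } else {
    m <- stats::lm(n_completed ~ tertile, data = cnt)
    sm <- summary(m)$coefficients
    keep <- grep("^tertile", rownames(sm))
    co <- data.frame(term = sub("^tertile", "", rownames(sm)[keep]),
                     estimate = sm[keep, 1], se = sm[keep, 2],
                     t = sm[keep, 3], p = sm[keep, 4])
  }
  rownames(co) <- NULL
  structure(list(counts = cnt, coefficients = co,
                 excluded_waves = excluded_waves),
            class = "attrition_result")
}

#' @export
print.attrition_result <- function(x, ...) {
  cat("Attrition regression (completed waves ~ tertile, reference bottom)\n")
  print(x$coefficients, row.names = FALSE)
  invisible(x)
}

#' Refit restricted to persons with at least k assessments
#'
#' @param prep the main-run `prepared_cohort`.
#' @param k minimum number of symptom assessments (`k = 1` reproduces the
#'   main run).
#' @param spec the main [growth_spec()].
#' @param age_grid,pairs as in [contrast_table()].
#' @return list with `fit`, `contrasts`, `n_removed`, `prep`.
#' @export
min_assessments_rerun <- function(prep, k = 2, spec, age_grid, pairs = NULL) {
  if (k < 1) stopf("k must be >= 1")
  cfg <- prep$config
  cfg$min_assessments <- as.integer(k)
  prep2 <- build_prepared_cohort(prep$raw$baseline, prep$raw$symptoms, cfg)
  fit <- fit_growth_model(prep2, spec, keep_model = FALSE)
  list(fit = fit, contrasts = contrast_table(fit, age_grid, pairs),
       n_removed = nrow(prep$baseline) - nrow(prep2$baseline), prep = prep2)
}
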