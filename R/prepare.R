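#' Exclude persons with high C-reactive protein
#'
#' Removes baseline rows with CRP at or above `threshold` mg/L, the
#' conventional proxy for acute infection or chronic inflammatory illness.
#' The boundary is inclusive: `crp >= threshold` is removed. Rows with
#' missing CRP are retained and flagged by default (`drop_missing = TRUE`
#' drops them instead).
#'
#' @param baseline baseline data frame with a `crp` column (mg/L).
#' @param threshold exclusion threshold in mg/L; must be positive.
#' @param drop_missing drop rows with missing CRP?
#' @return the filtered baseline, with attributes `n_removed` (count at or
#'   above threshold) and `n_missing_crp`.
#' @export
exclude_high_crp <- function(baseline, threshold = 10, drop_missing = FALSE) {
  if (!"crp" %in% names(baseline)) stopf("baseline has no 'crp' column")
  if (!is.numeric(threshold) || threshold <= 0) stopf("threshold must be > 0")
  miss <- is.na(baseline$crp)
  high <- !miss & baseline$crp >= threshold
  keep <- !high & (!drop_missing | !miss)
  out <- baseline[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(high)
  attr(out, "n_missing_crp") <- sum(miss)
  out
}

#' Assign biomarker tertile groups
#'
#' Splits persons into bottom/middle/top thirds of a biomarker using the
#' empirical 1/3 and 2/3 quantiles (type-7 interpolation by default).
#' Boundaries are half-open below: values strictly below the lower cutoff
#' are `bottom`, values in `[q1/3, q2/3)` are `middle`, and values at or
#' above the upper cutoff are `top`, so ties at a cutoff deterministically
#' go to the upper group.
#'
#' @param values named numeric vector (names = person ids) of the biomarker
#'   on the analysis scale; at least 3 non-missing, not all equal.
#' @param quantile_type quantile estimator passed to [stats::quantile()].
#' @return list with `group` (factor bottom/middle/top named by person) and
#'   `cutoffs` (min, q1/3, q2/3, max).
#' @export
assign_tertiles <- function(values, quantile_type = 7) {
  v <- values[!is.na(values)]
  if (length(v) < 3L) stopf("need at least 3 non-missing values to form tertiles")
  if (length(unique(v)) == 1L) stopf("all values identical; tertile grouping is degenerate")
  qs <- stats::quantile(v, c(1, 2) / 3, type = quantile_type, names = FALSE)
  grp <- cut(v, breaks = c(-Inf, qs, Inf), right = FALSE,
             labels = c("bottom", "middle", "top"))
  names(grp) <- names(v)
  list(group = grp,
       cutoffs = c(min = min(v), q13 = qs[1], q23 = qs[2], max = max(v)))
}

#' Add analysis-scale covariate columns
#'
#' Adds `logbmi` and its Z-scaled version `logbmi_z`, and Z-scales any
#' further continuous covariates named in `continuous` (mean 0, SD 1 over
#' the rows supplied). Rows with non-positive BMI are flagged invalid: their
#' transformed values are `NA` and they are excluded from the scaling.
#' Zero-variance continuous columns are emitted as all-zero with a warning.
#'
#' @param baseline baseline data frame.
#' @param continuous character vector of additional numeric columns to
#'   Z-scale (each gains a `<name>_z` column).
#' @return the augmented baseline; attribute `n_invalid_bmi` counts flagged
#'   rows.
#' @export
transform_covariates <- function(baseline, continuous = character()) {
  out <- baseline
  n_bad <- 0L
  if ("bmi" %in% names(out)) {
    bad <- !is.na(out$bmi) & out$bmi <= 0
    n_bad <- sum(bad)
    if (n_bad > 0)
      warning(sprintf("%d row(s) with non-positive BMI flagged invalid", n_bad),
              call. = FALSE)
    lb <- rep(NA_real_, nrow(out))
    ok <- !bad & !is.na(out$bmi)
    lb[ok] <- log(out$bmi[ok])
    out$logbmi <- lb
    out$logbmi_z <- zscale(lb, warn_label = "logbmi")
  }
  for (col in continuous) {
    if (!col %in% names(out)) stopf("continuous covariate '%s' not found", col)
    out[[paste0(col, "_z")]] <- zscale(out[[col]], warn_label = col)
  }
  attr(out, "n_invalid_bmi") <- n_bad
  out
}

## Categorical covariates enter the design dummy-coded against a declared
## reference level (male; never-smoker; low SES), not the alphabetical first
## level, so fitted intercepts refer to the conventional baseline person.
declare_reference_levels <- function(df) {
  orders <- list(sex = c("male", "female"),
                 smoking = c("never", "former", "current"),
                 ses = c("low", "high"))
  for (col in intersect(names(orders), names(df))) {
    vals <- unique(as.character(df[[col]]))
    lv <- intersect(orders[[col]], vals)
    if (length(lv) == length(vals))
      df[[col]] <- factor(df[[col]], levels = lv)
    else
      df[[col]] <- factor(df[[col]])
  }
  for (col in intersect(c("ses_alt", "batch", "centre"), names(df)))
    df[[col]] <- factor(df[[col]])
  df
}

#' Center assessment ages
#'
#' @param ages numeric ages (years).
#' @param center reference age, conventionally the cohort's minimum
#'   assessment age.
#' @return `ages - center`; negative values are permitted but counted in the
#'   `n_negative` attribute.
#' @export
center_age <- function(ages, center) {
  out <- ages - center
  attr(out, "n_negative") <- sum(out < 0, na.rm = TRUE)
  out
}

#' Build an analysis-ready cohort
#'
#' Applies the preparation pipeline in a fixed, logged order: (1) CRP
#' exclusion, (2) optional flag-based exclusions, (3) the minimum-assessment
#' rule, then computes IL-6 tertiles on the post-exclusion sample, derives
#' the transformed covariates, and merges baseline information onto the long
#' symptom table with a centered-age column. Each step's removal count is
#' recorded in the inclusion log.
#'
#' @param baseline baseline table (one row per person).
#' @param symptoms long symptom table (`person_id`, `age_years`, `score`,
#'   optionally `wave`).
#' @param config an [analysis_config()].
#' @return an object of class `prepared_cohort`: list with `data` (long
#'   analysis table with `age_c` and `tertile`), `baseline` (included
#'   persons with transforms and tertile), `cutoffs`, `inclusion_log`,
#'   `config`, and `raw` (the input tables, kept so sensitivity re-runs are
#'   self-contained).
#' @export
build_prepared_cohort <- function(baseline, symptoms, config) {
  stopifnot(inherits(config, "analysis_config"))
  for (col in c("person_id", "il6"))
    if (!col %in% names(baseline)) stopf("baseline lacks column '%s'", col)
  for (col in c("person_id", "age_years", "score"))
    if (!col %in% names(symptoms)) stopf("symptoms lacks column '%s'", col)
  if (anyDuplicated(baseline$person_id)) stopf("person_id must be unique in baseline")

  log <- list()
  step <- function(name, before, removed) {
    log[[length(log) + 1L]] <<- data.frame(step = name, n_before = before,
                                           n_removed = removed,
                                           n_after = before - removed)
  }
  n0 <- nrow(baseline)

  ## 1. CRP exclusion
  bl <- exclude_high_crp(baseline, threshold = config$crp_threshold,
                         drop_missing = config$drop_missing_crp)
  step(sprintf("crp_ge_%g", config$crp_threshold), n0, n0 - nrow(bl))

  ## 2. flag-based exclusions
  for (flag in config$exclude_flags) {
    if (!flag %in% names(bl)) stopf("exclusion flag '%s' not in baseline", flag)
    nb <- nrow(bl)
    f <- bl[[flag]]
    bl <- bl[is.na(f) | !f, , drop = FALSE]   # flagged TRUE -> removed
    step(paste0("flag_", flag), nb, nb - nrow(bl))
  }

  ## 3. minimum number of symptom assessments
  sy <- symptoms[!is.na(symptoms$score), , drop = FALSE]
  counts <- table(sy$person_id)
  enough <- names(counts)[counts >= config$min_assessments]
  nb <- nrow(bl)
  bl <- bl[as.character(bl$person_id) %in% enough, , drop = FALSE]
  step(sprintf("lt_%d_assessments", config$min_assessments), nb, nb - nrow(bl))
  if (nrow(bl) == 0L) stopf("no persons remain after exclusions")

  ## tertiles on the included sample only
  tert <- assign_tertiles(stats::setNames(bl$il6, bl$person_id),
                          quantile_type = config$quantile_type)
  bl$tertile <- tert$group

  bl <- transform_covariates(bl)
  bl <- declare_reference_levels(bl)

  sy <- sy[as.character(sy$person_id) %in% as.character(bl$person_id), , drop = FALSE]
  keep_cols <- intersect(c("person_id", "tertile", "sex", "logbmi_z", "ses",
                           "ses_alt", "smoking", "batch", "centre", "il6"), names(bl))
  dat <- merge(sy, bl[keep_cols], by = "person_id", sort = TRUE)
  dat <- dat[order(dat$person_id, dat$age_years), , drop = FALSE]
  rownames(dat) <- NULL
  dat$age_c <- center_age(dat$age_years, config$center_age)
  oob <- dat$score < config$instrument_bounds[1] | dat$score > config$instrument_bounds[2]
  if (any(oob))
    warning(sprintf("%d score(s) outside instrument bounds [%g, %g]",
                    sum(oob), config$instrument_bounds[1], config$instrument_bounds[2]),
            call. = FALSE)

  structure(list(data = dat,
                 baseline = bl,
                 cutoffs = tert$cutoffs,
                 inclusion_log = do.call(rbind, log),
                 config = config,
                 raw = list(baseline = baseline, symptoms = symptoms)),
            class = "prepared_cohort")
}

#' @export
print.prepared_cohort <- function(x, ...) {
  cat(sprintf("Prepared cohort (%s): %d persons, %d observations\n",
              x$config$profile, nrow(x$baseline), nrow(x$data)))
  cat(sprintf("  tertile cutoffs: %s\n",
              paste(signif(x$cutoffs, 3), collapse = " / ")))
  cat("  inclusion log:\n")
  print(x$inclusion_log, row.names = FALSE)
  invisible(x)
}

#' Write prepared-cohort artifacts
#'
#' Emits `prepared.csv` (the long analysis table) and `inclusion_log.json`.
#'
#' @param prep a `prepared_cohort`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_prepared <- function(prep, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(prep$data, file.path(dir, "prepared.csv"), row.names = FALSE)
  jsonlite::write_json(prep$inclusion_log, file.path(dir, "inclusion_log.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
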