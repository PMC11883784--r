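#' Design row for a predicted trajectory score
#'
#' Builds the fixed-design row whose inner product with the fixed-effect
#' vector gives the population-average predicted score for one group at one
#' age, under a covariate profile. The default profile sets Z-scaled
#' continuous covariates to 0 and categorical covariates to their reference
#' level; because the model contains no group x covariate or age x covariate
#' interactions, group contrasts are invariant to this choice.
#'
#' @param fit a `growth_fit`.
#' @param group group level (e.g. `"top"`); must be a level of the fit.
#' @param age age in years on the original scale; centering is applied
#'   internally.
#' @param profile optional named list overriding covariate entries: numeric
#'   values for numeric covariates, level names for categorical ones.
#' @return named numeric vector matching `names(fit$beta)`.
#' @export
prediction_row <- function(fit, group, age, profile = NULL) {
  info <- fit$info
  if (!is.null(info$levels) && !group %in% info$levels)
    stopf("group '%s' is not a level of this fit (%s)", group,
          paste(info$levels, collapse = ", "))
  cc <- age - info$center_age
  row <- stats::setNames(numeric(length(fit$beta)), names(fit$beta))
  row["(Intercept)"] <- 1
  for (k in seq_len(info$degree)) row[paste0("age", k)] <- cc^k
  if (!is.null(info$levels) && group != info$reference) {
    gcol <- paste0("grp_", safe_name(group))
    row[gcol] <- 1
    for (k in seq_len(info$degree)) row[paste0(gcol, "_age", k)] <- cc^k
  }
  for (cv in names(info$covariate_info)) {
    ci <- info$covariate_info[[cv]]
    if (identical(ci$type, "numeric")) {
      row[cv] <- profile[[cv]] %||% 0
    } else {
      lev <- profile[[cv]] %||% ci$levels[1]
      if (!lev %in% ci$levels) stopf("'%s' is not a level of covariate '%s'", lev, cv)
      if (lev != ci$levels[1]) row[paste0(cv, "_", safe_name(lev))] <- 1
    }
  }
  row
}

#' Predicted trajectory score at one age
#'
#' Point estimate `row'beta` and standard error `sqrt(row' V row)` for the
#' population-average score of one group at one age, with a 95% Wald
#' confidence interval (normal quantile 1.96).
#'
#' @inheritParams prediction_row
#' @return one-row data frame: `group`, `age`, `estimate`, `se`, `lo`, `hi`.
#' @export
predict_score <- function(fit, group, age, profile = NULL) {
  r <- prediction_row(fit, group, age, profile)
  est <- sum(r * fit$beta)
  se <- sqrt(max(0, drop(r %*% fit$V %*% r)))
  data.frame(group = group, age = age, estimate = est, se = se,
             lo = est - 1.96 * se, hi = est + 1.96 * se)
}

#' Delta-method contrast of two trajectory scores
#'
#' Pairwise difference of predicted scores of two groups at one age. The
#' score is linear in the fixed effects, so the delta method is exact and
#' reduces to the linear contrast `L = row_a - row_b`:
#' `diff = L'beta`, `se = sqrt(L' V L)`, a 95% Wald interval and a
#' two-sided normal p-value. The implementation verifies that the contrast
#' equals the difference of the two predictions (delta-method exactness).
#'
#' A zero standard error with a nonzero difference is degenerate: the
#' p-value is reported as 0 with a warning. The self-contrast
#' (`group_a == group_b`) returns `diff = 0`, `se = 0`, `p = NA`.
#'
#' @param fit a `growth_fit`.
#' @param group_a,group_b group levels to compare (a minus b).
#' @param age age in years.
#' @param profile covariate profile (contrasts are invariant to it).
#' @return one-row data frame: `group_a`, `group_b`, `age`, `diff`, `se`,
#'   `lo`, `hi`, `p`.
#' @export
contrast_scores <- function(fit, group_a, group_b, age, profile = NULL) {
  ra <- prediction_row(fit, group_a, age, profile)
  rb <- prediction_row(fit, group_b, age, profile)
  L <- ra - rb
  diff <- sum(L * fit$beta)
  se <- sqrt(max(0, drop(L %*% fit$V %*% L)))
  ## delta-method exactness: the linear contrast must equal the difference
  ## of the two predictions
  alt <- sum(ra * fit$beta) - sum(rb * fit$beta)
  stopifnot(abs(diff - alt) <= 1e-8 * max(1, abs(diff)))
  if (se == 0 && diff != 0) {
    warning("degenerate contrast variance (se = 0 with nonzero difference)",
            call. = FALSE)
    p <- 0
  } else if (se == 0) {
    p <- NA_real_
  } else {
    p <- 2 * stats::pnorm(-abs(diff) / se)
  }
  data.frame(group_a = group_a, group_b = group_b, age = age, diff = diff,
             se = se, lo = diff - 1.96 * se, hi = diff + 1.96 * se, p = p)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment: the adjusted p-value of the
#' j-th smallest p is `min over k >= j of m p_(k) / k`, capped at 1.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, order-preserving.
#' @export
bh_fdr <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) stopf("p-values must lie in [0, 1]")
  out <- pvalues
  out[ok] <- stats::p.adjust(pvalues[ok], method = "BH")
  out
}

#' Pairwise contrast table over an age grid
#'
#' Computes every requested pairwise contrast at every grid age and applies
#' FDR adjustment. The adjustment family is, by default, one contrast pair
#' across the age grid (family size = grid length), matching the convention
#' of counting one test per time point per comparison; `fdr_family =
#' "pooled"` instead adjusts over all pairs and ages jointly.
#'
#' Grid ages outside the observed age support of the fit are permitted but
#' flagged in the `extrapolated` column.
#'
#' @param fit a `growth_fit`.
#' @param age_grid numeric vector of ages (years); must be non-empty.
#' @param pairs list of length-2 character vectors `c(group_a, group_b)`;
#'   default: all pairs of fit levels against lower levels
#'   (top-bottom, top-middle, middle-bottom for tertiles).
#' @param profile covariate profile.
#' @param fdr_family `"per_pair"` (default) or `"pooled"`.
#' @return data frame of class `contrast_table`: `pair`, `group_a`,
#'   `group_b`, `age`, `diff`, `se`, `lo`, `hi`, `p`, `p_fdr`,
#'   `extrapolated`; attribute `fdr_family_size` records the family size.
#' @export
contrast_table <- function(fit, age_grid, pairs = NULL, profile = NULL,
                           fdr_family = c("per_pair", "pooled")) {
  fdr_family <- match.arg(fdr_family)
  if (length(age_grid) == 0L) stopf("age grid is empty")
  if (is.null(pairs)) {
    lv <- rev(setdiff(fit$info$levels, NULL))
    pairs <- list()
    for (i in seq_along(lv)) for (j in seq_along(lv))
      if (i < j) pairs[[length(pairs) + 1L]] <- c(lv[i], lv[j])
  }
  rows <- list()
  for (pr in pairs) for (a in age_grid)
    rows[[length(rows) + 1L]] <- contrast_scores(fit, pr[1], pr[2], a, profile)
  tab <- do.call(rbind, rows)
  tab$pair <- paste(tab$group_a, tab$group_b, sep = ":")
  tab$extrapolated <- tab$age < fit$info$age_range[1] | tab$age > fit$info$age_range[2]
  if (fdr_family == "per_pair") {
    tab$p_fdr <- NA_real_
    for (p in unique(tab$pair)) {
      sel <- tab$pair == p
      tab$p_fdr[sel] <- bh_fdr(tab$p[sel])
    }
    fam <- length(age_grid)
  } else {
    tab$p_fdr <- bh_fdr(tab$p)
    fam <- nrow(tab)
  }
  tab <- tab[c("pair", "group_a", "group_b", "age", "diff", "se", "lo", "hi",
               "p", "p_fdr", "extrapolated")]
  rownames(tab) <- NULL
  attr(tab, "fdr_family_size") <- fam
  class(tab) <- c("contrast_table", class(tab))
  tab
}

#' Standardised (Z-score) contrasts via refit on the standardised outcome
#'
#' To compare score differences across cohorts measured on different
#' instruments, the symptom score is Z-scored over all person-wave
#' observations in the cohort, the identical model is refitted, and the
#' contrasts recomputed; the standardised difference is emitted alongside
#' the raw-scale contrast as `z_std`. This refit-on-standardised-outcome
#' operationalisation is this package's choice of standardisation; because
#' the model is linear, it coincides (up to fitting tolerance) with dividing
#' raw differences by the overall outcome SD.
#'
#' @param prep the `prepared_cohort` the fit came from.
#' @param spec the [growth_spec()] used for the raw-scale fit.
#' @param age_grid,pairs,profile,fdr_family as in [contrast_table()].
#' @param raw_table optional precomputed raw-scale [contrast_table()] to
#'   annotate (recomputed if `NULL`).
#' @return the raw-scale contrast table with an additional `z_std` column.
#' @export
standardize_contrasts <- function(prep, spec, age_grid, pairs = NULL,
                                  profile = NULL, fdr_family = "per_pair",
                                  raw_table = NULL) {
  y <- prep$data$score
  s <- stats::sd(y)
  if (!is.finite(s) || s == 0) stopf("outcome has zero variance; cannot standardise")
  if (is.null(raw_table)) {
    fit <- fit_growth_model(prep, spec, keep_model = FALSE)
    raw_table <- contrast_table(fit, age_grid, pairs, profile, fdr_family)
  }
  prep_z <- prep
  prep_z$data$score <- (y - mean(y)) / s
  fit_z <- fit_growth_model(prep_z, spec, keep_model = FALSE)
  tab_z <- contrast_table(fit_z, age_grid, pairs, profile, fdr_family)
  key <- function(t) paste(t$pair, t$age)
  raw_table$z_std <- tab_z$diff[match(key(raw_table), key(tab_z))]
  raw_table
}
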