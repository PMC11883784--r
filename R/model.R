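#' Specification of a multilevel polynomial growth-curve model
#'
#' Describes the fixed polynomial trajectory in centered age, the group
#' variable whose levels receive main effects and interactions with every
#' age power, the person-level random-coefficient order, and the covariate
#' adjustment set. The model fitted is a Gaussian linear mixed model
#'
#' \deqn{y_{ij} = \sum_k \beta_k c_{ij}^k + \sum_g (\gamma_{g0} +
#'   \sum_k \gamma_{gk} c_{ij}^k)\,[G_i = g] + x_i'\delta + \sum_k b_{ik}
#'   c_{ij}^k + e_{ij}}
#'
#' with centered age \eqn{c}, unstructured random-effect covariance and the
#' likelihood computed over observed rows only (full-information maximum
#' likelihood: no imputation of missing waves).
#'
#' @param fixed_degree polynomial order of the fixed trajectory (1-4).
#' @param random_degree order of individual random slopes (0 =
#'   random intercept only); at most `fixed_degree`.
#' @param group_var name of the grouping column in the prepared data
#'   (default `"tertile"`); ignored when `continuous_var` is set.
#' @param covariates character vector of covariate columns (numeric columns
#'   enter as-is; character/factor columns are dummy-coded against their
#'   first level).
#' @param method `"ML"` (default; required for the selection ladder) or
#'   `"REML"`.
#' @param reference reference level of the group variable (`NULL`: `"bottom"`
#'   when present, otherwise the first level).
#' @param continuous_var optional numeric exposure column replacing the
#'   group terms with a single main effect plus age interactions (used by
#'   the continuous-IL-6 sensitivity model).
#' @return an object of class `growth_spec`.
#' @export
growth_spec <- function(fixed_degree, random_degree = 1, group_var = "tertile",
                        covariates = character(), method = c("ML", "REML"),
                        reference = NULL, continuous_var = NULL) {
  method <- match.arg(method)
  fixed_degree <- as.integer(fixed_degree)
  random_degree <- as.integer(random_degree)
  if (fixed_degree < 1L || fixed_degree > 4L) stopf("fixed_degree must be in 1..4")
  if (random_degree < 0L || random_degree > fixed_degree)
    stopf("random_degree must satisfy 0 <= q <= fixed_degree")
  structure(list(fixed_degree = fixed_degree, random_degree = random_degree,
                 group_var = group_var, covariates = covariates,
                 method = method, reference = reference,
                 continuous_var = continuous_var),
            class = "growth_spec")
}

## Expand the prepared long table into named design columns.
## Column order is deterministic: age^1..^d, group main effects (non-reference
## levels), group x age^k interactions (group-major), covariates. The
## intercept is implicit ("(Intercept)" in the fitted coefficient vector).

#' Build the fixed and random design for a growth model
#'
#' @param prep a `prepared_cohort`.
#' @param spec a [growth_spec()].
#' @return list with `frame` (model frame: `score`, `person_id`, design
#'   columns on the raw centered-age scale), `fixed_cols` (ordered design
#'   column names), `powers` (age power carried by each column, used for
#'   exact rescaling), and `info` (structure needed to rebuild prediction
#'   rows: degree, group levels, reference, covariate coding, center age,
#'   observed age range).
#' @export
build_design <- function(prep, spec) {
  stopifnot(inherits(prep, "prepared_cohort"), inherits(spec, "growth_spec"))
  d <- prep$data
  cc <- d$age_c
  dd <- spec$fixed_degree
  frame <- data.frame(score = d$score, person_id = factor(d$person_id))
  powers <- integer()
  cols <- character()
  for (k in seq_len(dd)) {
    nm <- paste0("age", k)
    frame[[nm]] <- cc^k
    cols <- c(cols, nm); powers[nm] <- k
  }

  info <- list(degree = dd, random_degree = spec$random_degree,
               group_var = spec$group_var, continuous_var = spec$continuous_var,
               center_age = prep$config$center_age,
               age_range = range(d$age_years), covariate_info = list())

  if (is.null(spec$continuous_var)) {
    if (!spec$group_var %in% names(d)) stopf("group column '%s' not found", spec$group_var)
    g <- factor(d[[spec$group_var]])
    ref <- spec$reference %||% (if ("bottom" %in% levels(g)) "bottom" else levels(g)[1])
    if (!ref %in% levels(g)) stopf("reference level '%s' not present", ref)
    g <- stats::relevel(g, ref)
    if (nlevels(g) < 2L)
      stopf("group variable '%s' has a single level; design is rank-deficient",
            spec$group_var)
    if (any(table(g) == 0L))
      stopf("empty group level(s): %s",
            paste(levels(g)[table(g) == 0L], collapse = ", "))
    main_cols <- character()
    for (lev in levels(g)[-1]) {
      nm <- paste0("grp_", safe_name(lev))
      frame[[nm]] <- as.numeric(g == lev)
      main_cols <- c(main_cols, nm); powers[nm] <- 0L
    }
    int_cols <- character()
    for (lev in levels(g)[-1]) for (k in seq_len(dd)) {
      nm <- paste0("grp_", safe_name(lev), "_age", k)
      frame[[nm]] <- as.numeric(g == lev) * cc^k
      int_cols <- c(int_cols, nm); powers[nm] <- k
    }
    cols <- c(cols, main_cols, int_cols)
    info$levels <- levels(g)
    info$reference <- ref
  } else {
    v <- d[[spec$continuous_var]]
    if (is.null(v) || !is.numeric(v)) stopf("continuous_var must name a numeric column")
    nm0 <- safe_name(spec$continuous_var)
    frame[[nm0]] <- v; powers[nm0] <- 0L
    cols <- c(cols, nm0)
    for (k in seq_len(dd)) {
      nm <- paste0(nm0, "_age", k)
      frame[[nm]] <- v * cc^k
      cols <- c(cols, nm); powers[nm] <- k
    }
    info$levels <- NULL
    info$reference <- NULL
  }

  for (cv in spec$covariates) {
    if (!cv %in% names(d)) stopf("covariate '%s' not found in prepared data", cv)
    x <- d[[cv]]
    if (is.numeric(x)) {
      frame[[cv]] <- x; cols <- c(cols, cv); powers[cv] <- 0L
      info$covariate_info[[cv]] <- list(type = "numeric")
    } else {
      f <- factor(x)
      for (lev in levels(f)[-1]) {
        nm <- paste0(cv, "_", safe_name(lev))
        frame[[nm]] <- as.numeric(f == lev)
        cols <- c(cols, nm); powers[nm] <- 0L
      }
      info$covariate_info[[cv]] <- list(type = "factor", levels = levels(f))
    }
  }

  X <- cbind(`(Intercept)` = 1, as.matrix(frame[cols]))
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    aliased <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):ncol(X)]]
    stopf("design is rank deficient; aliased column(s): %s",
          paste(aliased, collapse = ", "))
  }
  list(frame = frame, fixed_cols = cols, powers = powers, info = info)
}

#' Construct a growth-model fit result
#'
#' Container for a fitted (or externally supplied) model: the fixed-effect
#' vector, its covariance, the random-effect covariance, residual variance
#' and fit statistics. Mostly created by [fit_growth_model()]; the
#' constructor is exported so toy results and results read from JSON can be
#' fed to the contrast machinery.
#'
#' @param beta named fixed-effect vector (first element `"(Intercept)"`).
#' @param V covariance matrix of `beta` (symmetric, same dimension).
#' @param info design description as produced by [build_design()] (`degree`,
#'   `levels`, `reference`, `covariate_info`, `center_age`, `age_range`).
#' @param G random-effect covariance matrix (or `NULL`).
#' @param sigma2 residual variance.
#' @param loglik,df,n_obs,n_individuals fit statistics.
#' @param converged,singular,fallback_applied convergence diagnostics.
#' @return an object of class `growth_fit`.
#' @export
fit_result <- function(beta, V, info, G = NULL, sigma2 = NA_real_,
                       loglik = NA_real_, df = NA_integer_,
                       n_obs = NA_integer_, n_individuals = NA_integer_,
                       converged = TRUE, singular = FALSE,
                       fallback_applied = NULL) {
  V <- as.matrix(V)
  if (length(beta) != nrow(V) || nrow(V) != ncol(V))
    stopf("dim(V) must match length(beta)")
  if (is.null(names(beta))) stopf("beta must be named")
  dimnames(V) <- list(names(beta), names(beta))
  structure(list(beta = beta, V = V, G = G, sigma2 = sigma2,
                 loglik = loglik, df = df, n_obs = n_obs,
                 n_individuals = n_individuals, info = info,
                 converged = converged, singular = singular,
                 fallback_applied = fallback_applied),
            class = "growth_fit")
}

#' Fit the multilevel growth-curve model
#'
#' Maximum-likelihood (or REML) estimation via [lme4::lmer()] of the model
#' described by `spec`, with person-level random polynomial coefficients and
#' unstructured covariance. The likelihood is computed over observed rows
#' only, so missing waves are handled by full-information ML under the
#' missing-at-random assumption.
#'
#' Age polynomials are internally rescaled (centered age divided by its
#' maximum) for optimizer conditioning; estimates, their covariance, and `G`
#' are transformed back exactly, so reported coefficients are per power of
#' centered age in years.
#'
#' If the optimizer fails to converge at random order `q`, the model is
#' refitted at `q - 1` and so on down to a random intercept; the applied
#' fallback is recorded. Singular (boundary) `G` fits are flagged, not
#' errored. Non-convergence at `q = 0` is an error.
#'
#' @param prep a `prepared_cohort`.
#' @param spec a [growth_spec()].
#' @param keep_model keep the underlying `merMod` object as attribute
#'   `"model"`? (Needed by nothing downstream, useful for inspection.)
#' @return a `growth_fit`; see [fit_result()].
#' @export
fit_growth_model <- function(prep, spec, keep_model = TRUE) {
  des <- build_design(prep, spec)
  frame <- des$frame
  if (nlevels(frame$person_id) < 2L) stopf("need at least 2 persons")

  s <- max(abs(prep$data$age_c))
  if (!is.finite(s) || s == 0) s <- 1
  scaled <- frame
  for (nm in des$fixed_cols)
    if (des$powers[[nm]] > 0) scaled[[nm]] <- frame[[nm]] / s^des$powers[[nm]]

  try_lmer <- function(form, optimizer) {
    warns <- character()
    cand <- withCallingHandlers(
      tryCatch(lme4::lmer(form, data = scaled, REML = spec$method == "REML",
                          control = lme4::lmerControl(
                            optimizer = optimizer,
                            optCtrl = if (optimizer == "bobyqa")
                              list(maxfun = 2e5) else list())),
               error = function(e) e),
      warning = function(w) {
        warns <<- c(warns, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    if (inherits(cand, "error"))
      return(list(fit = NULL, msgs = conditionMessage(cand)))
    opt_msgs <- unlist(cand@optinfo$conv$lme4$messages)
    bad <- grepl("failed to converge|convergence code", c(warns, opt_msgs),
                 ignore.case = TRUE)
    list(fit = cand, msgs = c(warns, opt_msgs)[bad], clean = !any(bad))
  }

  fit <- NULL; used_q <- NA_integer_; fallback <- NULL; diag_msgs <- character()
  for (q in seq(spec$random_degree, 0L)) {
    rpart <- paste(c("1", if (q > 0) paste0("age", seq_len(q))), collapse = " + ")
    form <- stats::as.formula(paste("score ~", paste(des$fixed_cols, collapse = " + "),
                                    "+ (", rpart, "| person_id)"))
    ## convergence warnings from the default optimizer are frequently false
    ## alarms from the gradient check; retry with bobyqa before degrading
    ## the random structure
    for (optim in c("nloptwrap", "bobyqa")) {
      res <- try_lmer(form, optim)
      if (!is.null(res$fit) && isTRUE(res$clean)) break
      diag_msgs <- c(diag_msgs, sprintf("q=%d/%s: %s", q, optim,
                                        paste(res$msgs, collapse = "; ")))
    }
    if (!is.null(res$fit) && isTRUE(res$clean)) { fit <- res$fit; used_q <- q; break }
  }
  if (is.null(fit))
    stopf("model did not converge at any random order; diagnostics: %s",
          paste(diag_msgs, collapse = " | "))
  if (used_q < spec$random_degree)
    fallback <- sprintf("random degree reduced from %d to %d (%s)",
                        spec$random_degree, used_q,
                        paste(diag_msgs, collapse = " | "))

  ## exact back-transform from the scaled-age parameterization
  beta_s <- lme4::fixef(fit)
  pw <- c(0L, des$powers[des$fixed_cols])
  Dinv <- 1 / s^pw
  beta <- beta_s * Dinv
  V <- as.matrix(stats::vcov(fit)) * tcrossprod(Dinv)
  Gs <- as.matrix(lme4::VarCorr(fit)$person_id)
  Dq <- 1 / s^(0:used_q)
  G <- Gs * tcrossprod(Dq)
  dimnames(G) <- NULL

  info <- des$info
  info$random_degree_used <- used_q
  out <- fit_result(beta = beta, V = V, info = info, G = G,
                    sigma2 = stats::sigma(fit)^2,
                    loglik = as.numeric(stats::logLik(fit)),
                    df = attr(stats::logLik(fit), "df"),
                    n_obs = nrow(frame),
                    n_individuals = nlevels(frame$person_id),
                    converged = TRUE,
                    singular = lme4::isSingular(fit),
                    fallback_applied = fallback)
  if (keep_model) attr(out, "model") <- fit
  out
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("Growth-curve fit: degree %d, random degree %d, n_obs = %d, n = %d\n",
              x$info$degree, x$info$random_degree_used %||% x$info$random_degree,
              x$n_obs, x$n_individuals))
  cat(sprintf("  logLik = %.2f, sigma2 = %.4g%s%s\n", x$loglik, x$sigma2,
              if (isTRUE(x$singular)) " [singular G]" else "",
              if (!is.null(x$fallback_applied)) " [fallback applied]" else ""))
  est <- cbind(estimate = x$beta, se = sqrt(diag(x$V)))
  print(round(est, 4))
  invisible(x)
}

#' Polynomial-order selection ladder
#'
#' Fits the growth model at each candidate fixed degree (ML enforced so the
#' likelihoods are comparable), reports log-likelihood, parameter count and
#' BIC (`-2 logLik + n_params log(n_obs)`), likelihood-ratio tests between
#' consecutive nested candidates, and the chosen degree: lowest BIC, ties
#' resolved toward the lower degree. The random structure is held constant
#' across candidates.
#'
#' @param prep a `prepared_cohort`.
#' @param candidates increasing vector of fixed degrees (subset of 1..4).
#' @param random_degree random order used for every candidate; must not
#'   exceed the smallest candidate.
#' @param group_var,covariates,reference passed to [growth_spec()].
#' @param keep_fits retain the individual `growth_fit` objects?
#' @return an object of class `model_comparison`: list with `table`
#'   (per-candidate statistics), `chosen`, `criterion`, and optionally
#'   `fits`.
#' @export
select_degree <- function(prep, candidates = 1:4, random_degree = 1,
                          group_var = "tertile", covariates = character(),
                          reference = NULL, keep_fits = FALSE) {
  candidates <- sort(unique(as.integer(candidates)))
  if (random_degree > min(candidates))
    stopf("random_degree must not exceed the smallest candidate degree")
  rows <- list(); fits <- list(); failures <- character()
  for (dg in candidates) {
    spec <- growth_spec(dg, random_degree, group_var = group_var,
                        covariates = covariates, method = "ML",
                        reference = reference)
    f <- tryCatch(fit_growth_model(prep, spec, keep_model = FALSE),
                  error = function(e) e)
    if (inherits(f, "error")) {
      failures <- c(failures, sprintf("degree %d: %s", dg, conditionMessage(f)))
      next
    }
    rows[[as.character(dg)]] <- data.frame(
      degree = dg, loglik = f$loglik, n_params = f$df,
      bic = -2 * f$loglik + f$df * log(f$n_obs),
      singular = f$singular,
      fallback = !is.null(f$fallback_applied))
    if (keep_fits) fits[[as.character(dg)]] <- f
  }
  if (length(rows) == 0L)
    stopf("no candidate degree could be fitted: %s", paste(failures, collapse = " | "))
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab$lrt_stat <- tab$lrt_df <- tab$lrt_p <- NA_real_
  if (nrow(tab) > 1L) for (i in 2:nrow(tab)) {
    tab$lrt_stat[i] <- max(0, 2 * (tab$loglik[i] - tab$loglik[i - 1]))
    tab$lrt_df[i] <- tab$n_params[i] - tab$n_params[i - 1]
    tab$lrt_p[i] <- stats::pchisq(tab$lrt_stat[i], tab$lrt_df[i], lower.tail = FALSE)
  }
  chosen <- tab$degree[which.min(tab$bic)]   # table is degree-ascending: ties -> lower
  structure(list(table = tab, chosen = chosen, criterion = "BIC",
                 failures = failures, fits = if (keep_fits) fits),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Polynomial-order comparison (criterion:", x$criterion, ")\n")
  print(x$table, row.names = FALSE)
  cat("chosen degree:", x$chosen, "\n")
  if (length(x$failures)) cat("failed candidates:", paste(x$failures, collapse = "; "), "\n")
  invisible(x)
}

#' Write a fit to JSON
#'
#' Stores `beta`, `V`, `G`, `sigma2`, `loglik` and the design info with full
#' column names, so the fit can be reloaded with [read_fit_json()] and fed
#' to the contrast machinery.
#'
#' @param fit a `growth_fit`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  payload <- list(beta = as.list(fit$beta),
                  beta_names = names(fit$beta),
                  V = apply(fit$V, 1L, identity, simplify = FALSE),
                  G = if (!is.null(fit$G)) apply(fit$G, 1L, identity, simplify = FALSE),
                  sigma2 = fit$sigma2, loglik = fit$loglik, df = fit$df,
                  n_obs = fit$n_obs, n_individuals = fit$n_individuals,
                  converged = fit$converged, singular = fit$singular,
                  fallback_applied = fit$fallback_applied, info = fit$info)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a fit written by [write_fit_json()]
#'
#' @param path JSON path.
#' @return a `growth_fit`.
#' @export
read_fit_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  beta <- stats::setNames(unlist(p$beta), p$beta_names)
  V <- if (is.list(p$V)) do.call(rbind, p$V) else as.matrix(p$V)
  info <- p$info
  info$covariate_info <- lapply(info$covariate_info, as.list)
  fit_result(beta = beta, V = V, info = info,
             G = if (!is.null(p$G)) as.matrix(p$G),
             sigma2 = p$sigma2, loglik = p$loglik, df = p$df,
             n_obs = p$n_obs, n_individuals = p$n_individuals,
             converged = isTRUE(p$converged), singular = isTRUE(p$singular),
             fallback_applied = p$fallback_applied)
}
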