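# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

## Z-scale a numeric vector; zero-variance input is mapped to all zeros with a
## warning (the column carries no information but keeps the design conformable).
zscale <- function(x, warn_label = deparse(substitute(x))) {
  ok <- !is.na(x)
  s <- stats::sd(x[ok])
  if (!is.finite(s) || s == 0) {
    warning(sprintf("column '%s' has zero variance; Z-scaled column set to 0",
                    warn_label), call. = FALSE)
    x[ok] <- 0
    return(x)
  }
  x[ok] <- (x[ok] - mean(x[ok])) / s
  x
}

is_psd <- function(M, tol = 1e-8) {
  if (!isSymmetric(unname(M), tol = 1e-8)) return(FALSE)
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  all(ev >= -tol * max(1, abs(ev[1])))
}

## matrix square root for PSD matrices (chol fails on singular G)
psd_sqrt <- function(M) {
  e <- eigen(M, symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(M)) %*% t(e$vectors)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

## sanitize a level for use inside a design-column name
safe_name <- function(x) gsub("[^A-Za-z0-9]+", "_", as.character(x))
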