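#' Person measurement under the partial credit model
#'
#' Estimates each row's latent location given calibrated thresholds, by
#' maximum likelihood (MLE) or Warm's weighted likelihood (WLE). The WLE
#' maximizes the log-likelihood plus half the log of the test information,
#' which removes the leading-order bias of the MLE and yields finite
#' estimates at extreme raw scores (flagged `extreme`). Standard errors
#' are 1/sqrt(test information) at the estimate. With complete data both
#' estimators are functions of the raw score only (raw-score sufficiency).
#'
#' @param am `analysis_matrix` or integer matrix (0..m codes, `NA` missing).
#' @param fit `pcm_fit` or threshold matrix (rows in column order of `am`).
#' @param method `"WLE"` (default) or `"MLE"`.
#' @return tibble of class `person_estimates`: one row per row of `am`
#'   with `theta`, `se`, `method`, `raw_score`, `max_score`, `n_items`,
#'   `extreme`, plus the row metadata when `am` carries it.
#' @export
estimate_persons <- function(am, fit, method = c("WLE", "MLE")) {
  method <- match.arg(method)
  X <- if (inherits(am, "analysis_matrix")) am$scores else as.matrix(am)
  tau <- thresholds(fit)
  stopifnot(ncol(X) == nrow(tau))
  obs <- !is.na(X)
  if (any(rowSums(obs) == 0L)) stop("row(s) with all responses missing", call. = FALSE)

  raw <- rowSums(X, na.rm = TRUE)
  maxs <- drop(obs %*% rep(ncol(tau), nrow(tau)))
  extreme <- raw == 0L | raw == maxs

  theta <- solve_theta(X, tau, wle = (method == "WLE"))
  if (method == "MLE") theta[extreme] <- ifelse(raw[extreme] == 0L, -Inf, Inf)

  info <- test_information(theta, tau, obs)
  se <- ifelse(is.finite(theta) & info > 0, 1 / sqrt(info), NA_real_)

  out <- tibble::tibble(
    theta = theta, se = se, method = method,
    raw_score = as.integer(raw), max_score = as.integer(maxs),
    n_items = rowSums(obs), extreme = extreme
  )
  if (inherits(am, "analysis_matrix")) out <- dplyr::bind_cols(am$meta, out)
  class(out) <- c("person_estimates", class(out))
  out
}

#' @rdname estimate_persons
#' @param responses a single response vector (length = number of items).
#' @export
estimate_person <- function(responses, fit, method = c("WLE", "MLE")) {
  estimate_persons(matrix(responses, nrow = 1L,
                          ncol = length(responses),
                          dimnames = list(NULL, rownames(thresholds(fit)))),
                   fit, method)
}

# Vectorized damped Newton on the (weighted) likelihood score equation,
# with uniroot fallback for stragglers. f(theta) = r - sum E_i(theta)
# [+ sum mu3_i / (2 sum V_i) for WLE], monotone decreasing in theta.
solve_theta <- function(X, tau, wle, tol = 1e-9, max_iter = 100L) {
  n <- nrow(X); I <- ncol(X)
  obs <- !is.na(X)
  raw <- rowSums(X, na.rm = TRUE)
  theta <- numeric(n)
  active <- rep(TRUE, n)
  if (!wle) {
    maxs <- drop(obs %*% rep(ncol(tau), nrow(tau)))
    active <- raw > 0L & raw < maxs   # extremes have no finite MLE
  }
  score_fun <- function(th, rows) {
    E <- V <- J <- numeric(length(th))
    for (i in seq_len(I)) {
      oi <- obs[rows, i]
      if (!any(oi)) next
      mom <- pcm_moments(th[oi], tau[i, ])
      E[oi] <- E[oi] + mom$e
      V[oi] <- V[oi] + mom$v
      J[oi] <- J[oi] + mom$mu3
    }
    f <- raw[rows] - E
    if (wle) f <- f + J / (2 * V)
    list(f = f, info = V)
  }
  rows <- which(active)
  for (it in seq_len(max_iter)) {
    if (length(rows) == 0L) break
    sc <- score_fun(theta[rows], rows)
    step <- pmin(pmax(sc$f / pmax(sc$info, 1e-10), -1), 1)
    theta[rows] <- theta[rows] + step
    done <- abs(sc$f) < tol & abs(step) < 1e-8
    rows <- rows[!done]
  }
  if (length(rows) > 0L) {
    for (r in rows) {
      f1 <- function(t) score_fun(t, r)$f
      theta[r] <- tryCatch(stats::uniroot(f1, c(-30, 30), tol = 1e-10)$root,
                           error = function(e) theta[r])
    }
  }
  theta
}

# Sum over observed items of Var(X_i | theta); obs may be NULL (all observed)
test_information <- function(theta, tau, obs = NULL) {
  n <- length(theta)
  info <- numeric(n)
  fin <- is.finite(theta)
  for (i in seq_len(nrow(tau))) {
    use <- fin & (if (is.null(obs)) TRUE else obs[, i])
    if (!any(use)) next
    info[use] <- info[use] + pcm_moments(theta[use], tau[i, ])$v
  }
  info[!fin] <- 0
  info
}

# WLE/MLE measure for a given raw score on a complete instrument
solve_score_equation <- function(r, tau, wle = TRUE) {
  f <- function(th) {
    E <- V <- J <- 0
    for (i in seq_len(nrow(tau))) {
      mom <- pcm_moments(th, tau[i, ])
      E <- E + mom$e; V <- V + mom$v; J <- J + mom$mu3
    }
    out <- r - E
    if (wle) out <- out + J / (2 * V)
    out
  }
  stats::uniroot(f, c(-30, 30), tol = 1e-10)$root
}

#' Person separation index
#'
#' Rasch-side internal reliability: the share of observed person-estimate
#' variance not attributable to measurement error,
#' PSI = (var(theta_hat) - mean(se^2)) / var(theta_hat), floored at 0.
#' Ranges from 0 (all error) to 1 (no error). Persons with zero test
#' information (no finite SE) are excluded.
#'
#' @param persons `person_estimates` tibble (or any data frame with
#'   `theta` and `se` columns).
#' @return PSI in \[0, 1\], or `NA` if fewer than 2 usable persons or the
#'   estimate variance is zero.
#' @export
person_separation_index <- function(persons) {
  ok <- is.finite(persons$theta) & is.finite(persons$se)
  th <- persons$theta[ok]; se <- persons$se[ok]
  if (length(th) < 2L) return(NA_real_)
  v <- stats::var(th)
  if (v == 0) return(NA_real_)
  max(0, (v - mean(se^2)) / v)
}
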