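#' Standardized response residuals and class intervals
#'
#' For every observed response, the standardized residual
#' z = (x - E\[x\]) / sqrt(Var\[x\]) with moments evaluated under the fitted
#' model at the person's estimate. Persons are ranked by their estimate
#' and partitioned into `G` class intervals of near-equal size (ties
#' broken by row order), the grouping used by item-trait chi-squares and
#' DIF analysis.
#'
#' @param am `analysis_matrix` or integer matrix.
#' @param fit `pcm_fit` or threshold matrix.
#' @param persons optional precomputed `person_estimates` for the same
#'   rows; computed by WLE if omitted.
#' @param G number of class intervals (default 10, so that the item-trait
#'   chi-square has 9 degrees of freedom).
#' @return object of class `residual_table`: list with matrices `z`,
#'   `expected`, `variance`, the response matrix `x`, vectors `theta`,
#'   `class_interval`, the `meta` tibble (if available) and `G`.
#' @export
standardized_residuals <- function(am, fit, persons = NULL, G = 10) {
  X <- if (inherits(am, "analysis_matrix")) am$scores else as.matrix(am)
  tau <- thresholds(fit)
  if (is.null(colnames(X))) {
    colnames(X) <- rownames(tau) %||% paste0("I", seq_len(ncol(X)))
  }
  if (is.null(persons)) persons <- estimate_persons(am, fit, method = "WLE")
  theta <- persons$theta
  n <- nrow(X)
  if (G > n) stop("more class intervals than persons", call. = FALSE)

  E <- V <- matrix(NA_real_, n, ncol(X), dimnames = dimnames(X))
  for (i in seq_len(ncol(X))) {
    oi <- !is.na(X[, i]) & is.finite(theta)
    if (!any(oi)) next
    mom <- pcm_moments(theta[oi], tau[i, ])
    E[oi, i] <- mom$e
    V[oi, i] <- mom$v
  }
  z <- (X - E) / sqrt(V)
  # conditional-on-raw-score moments: the exact null moments of the
  # responses under the fitted model, free of person-estimation bias;
  # used by the item fit residual, the class-interval chi-square and the
  # DIF ANOVA (where they guarantee mean 0 / variance 1 within every
  # class interval under the null, regardless of group composition)
  cond <- pcm_conditional_moments(X, tau)
  z_cond <- (X - cond$e) / sqrt(cond$v)
  z_cond[!is.na(cond$v) & cond$v < 1e-10] <- NA_real_

  ci <- as.integer(ceiling(rank(theta, ties.method = "first") * G / n))
  structure(list(
    z = z, z_cond = z_cond, expected = E, variance = V, cond = cond,
    x = X, theta = theta,
    class_interval = ci, G = as.integer(G),
    meta = if (inherits(am, "analysis_matrix")) am$meta else NULL,
    tau = tau
  ), class = "residual_table")
}

#' Standardized item fit residual
#'
#' Summarizes item-person interaction misfit: the sum of squared
#' standardized residuals for the item, standardized against its model
#' mean and variance through a Wilson-Hilferty cube-root normalization.
#' Values near 0 indicate fit; the conventional acceptable band is
#' +/- 2.5. Negative values indicate over-discrimination (responses more
#' deterministic than the model expects), positive values
#' under-discrimination. Items with fewer than `min_obs` observations are
#' returned as `NA` (not evaluable).
#'
#' @param rt `residual_table`.
#' @param min_obs minimum observations per item (default 30).
#' @return tibble with `item_id`, `fit_residual`, `n_obs`,
#'   `flag_misfit` (|fit residual| > 2.5).
#' @export
item_fit_residual <- function(rt, min_obs = 30) {
  ids <- colnames(rt$z)
  out <- tibble::tibble(item_id = ids, fit_residual = NA_real_,
                        n_obs = 0L, flag_misfit = NA)
  for (i in seq_along(ids)) {
    # conditional (given raw score) standardization: exact null moments,
    # persons with degenerate conditional distributions drop out
    cv <- rt$cond$v[, i]
    ok <- !is.na(rt$x[, i]) & !is.na(cv) & cv > 1e-10
    n <- sum(ok)
    out$n_obs[i] <- n
    if (n < min_obs) next
    z2 <- (rt$x[ok, i] - rt$cond$e[ok, i])^2 / cv[ok]
    U <- sum(z2)
    EU <- n                                   # E[z^2 | r] = 1 exactly
    VU <- sum(pmax(rt$cond$mu4[ok, i] / cv[ok]^2 - 1, 1e-10))
    nu <- 2 * EU^2 / VU                       # matched chi-square df
    wh <- ((U / EU)^(1 / 3) - (1 - 2 / (9 * nu))) / sqrt(2 / (9 * nu))
    out$fit_residual[i] <- wh
    out$flag_misfit[i] <- abs(wh) > 2.5
  }
  out
}

#' Item-trait interaction chi-square over class intervals
#'
#' Within each class interval the summed observed-minus-expected score is
#' squared and standardized by the summed model variance; the statistic is
#' the total over intervals with df = G - 1 (empty intervals are merged
#' into their neighbour, reducing df). With large samples, `n_adjust`
#' rescales the chi-square by `n_adjust / n` before the p-value is
#' computed (no rescaling when n <= n_adjust), mitigating excessive
#' power; the raw statistic is always reported too.
#'
#' @param rt `residual_table`.
#' @param n_adjust effective sample size for the p-value (default 500;
#'   `NULL` disables the adjustment).
#' @return tibble with `item_id`, `chi_square` (raw), `chi_square_adj`,
#'   `df`, `p_value`, `n_obs`, `flag_chi2` (p < 0.05).
#' @export
item_trait_chi_square <- function(rt, n_adjust = 500) {
  stopifnot(rt$G >= 2L)
  ids <- colnames(rt$z)
  res <- lapply(seq_along(ids), function(i) {
    # conditional (given raw score) moments standardize the interval sums
    # exactly under the fitted model; extreme-raw-score persons have a
    # degenerate conditional distribution and drop out naturally
    cv <- rt$cond$v[, i]
    ok <- !is.na(rt$x[, i]) & !is.na(cv)
    d <- (rt$x[, i] - rt$cond$e[, i])[ok]
    g <- rt$class_interval[ok]
    dg <- tapply(d, g, sum)
    vg <- tapply(cv[ok], g, sum)
    keep <- !is.na(dg) & vg > 1e-10
    # Rao-Robson quadratic form: the covariance of the interval sums is
    # deflated by threshold estimation along the sensitivity profiles
    # c_k = Cov(X, 1[X >= k] | r) (= -dE[X|r]/dtau_k); inverting the
    # corrected covariance restores the chi-square(G-1) calibration
    m <- ncol(rt$tau)
    Tk <- matrix(rt$cond$tail[ok, i, ], ncol = m)
    ck <- matrix(rt$cond$xtail[ok, i, ], ncol = m) - rt$cond$e[ok, i] * Tk
    infoU <- matrix(0, m, m)
    for (k in seq_len(m)) for (l in k:m) {
      infoU[k, l] <- infoU[l, k] <- sum(Tk[, max(k, l)] - Tk[, k] * Tk[, l])
    }
    Cvg <- rowsum(ck, g)[keep, , drop = FALSE]
    Sig <- diag(as.numeric(vg[keep]), nrow = sum(keep)) -
      Cvg %*% tryCatch(solve(infoU, t(Cvg)),
                       error = function(e) matrix(0, m, sum(keep)))
    ee <- eigen(Sig, symmetric = TRUE)
    pos <- ee$values > 1e-8 * max(ee$values)
    Sinv <- ee$vectors[, pos, drop = FALSE] %*%
      (t(ee$vectors[, pos, drop = FALSE]) / ee$values[pos])
    chi <- as.numeric(t(dg[keep]) %*% Sinv %*% dg[keep])
    df <- sum(keep) - 1L                 # empty/degenerate intervals merged
    n <- sum(ok)
    fac <- if (!is.null(n_adjust) && n > n_adjust) n_adjust / n else 1
    chi_adj <- chi * fac
    p <- stats::pchisq(chi_adj, df, lower.tail = FALSE)
    tibble::tibble(item_id = ids[i], chi_square = chi, chi_square_adj = chi_adj,
                   df = df, p_value = p, n_obs = n, flag_chi2 = p < 0.05)
  })
  dplyr::bind_rows(res)
}

#' Targeting coverage of persons by the item threshold range
#'
#' Percentage of person estimates lying within the span of the item
#' thresholds — the region where the instrument measures with reasonable
#' precision. `direction = "span"` gives the converse reading: the share
#' of the threshold span covered by the person range.
#'
#' @param persons `person_estimates` (or data frame with `theta`).
#' @param fit `pcm_fit` or threshold matrix.
#' @param direction `"persons"` (default) or `"span"`.
#' @return percentage in \[0, 100\].
#' @export
targeting_coverage <- function(persons, fit, direction = c("persons", "span")) {
  direction <- match.arg(direction)
  tau <- thresholds(fit)
  th <- persons$theta[is.finite(persons$theta)]
  stopifnot(length(th) >= 1L, length(tau) >= 1L)
  lo <- min(tau); hi <- max(tau)
  if (direction == "persons") {
    100 * mean(th >= lo & th <= hi)
  } else {
    ov <- max(0, min(hi, max(th)) - max(lo, min(th)))
    100 * ov / (hi - lo)
  }
}

#' Residual correlations and local-dependence flags
#'
#' Pearson correlations of the standardized-residual columns over persons
#' (pairwise-complete). Two flag rules are applied: rule A, r > 0.30
#' absolute criterion; rule B, r above the mean of all pairwise residual
#' correlations plus 0.30 (on locally independent data the mean pairwise
#' residual correlation is slightly negative, about -1/(L-1), so the
#' rule-B critical value sits below 0.3). Pairs with fewer than
#' `min_pairs` joint observations are excluded.
#'
#' @param rt `residual_table`.
#' @param min_pairs minimum joint observations per pair (default 10).
#' @return list with `pairs` tibble (`item_a`, `item_b`, `r`, `n`,
#'   `flag_abs`, `flag_mean`), `mean_r`, `critical_abs` (0.30),
#'   `critical_mean` (mean_r + 0.30), `n_excluded`.
#' @export
residual_correlation_flags <- function(rt, min_pairs = 10) {
  z <- rt$z
  stopifnot(ncol(z) >= 3L)
  ids <- colnames(z)
  cmb <- utils::combn(seq_along(ids), 2L)
  r <- n <- numeric(ncol(cmb))
  for (j in seq_len(ncol(cmb))) {
    a <- z[, cmb[1, j]]; b <- z[, cmb[2, j]]
    ok <- !is.na(a) & !is.na(b)
    n[j] <- sum(ok)
    r[j] <- if (n[j] >= min_pairs && stats::sd(a[ok]) > 0 && stats::sd(b[ok]) > 0)
      stats::cor(a[ok], b[ok]) else NA_real_
  }
  keep <- !is.na(r)
  mean_r <- mean(r[keep])
  pairs <- tibble::tibble(
    item_a = ids[cmb[1, ]], item_b = ids[cmb[2, ]], r = r, n = as.integer(n),
    flag_abs = r > 0.30, flag_mean = r > mean_r + 0.30
  )[keep, ]
  list(pairs = pairs, mean_r = mean_r, critical_abs = 0.30,
       critical_mean = mean_r + 0.30, n_excluded = sum(!keep))
}

#' Scale-level Rasch measurement theory summary
#'
#' Assembles the per-item fit report and the scale-level percentages
#' (coverage, % items beyond the +/-2.5 fit-residual band, % items with
#' chi-square p < 0.05 at the adjusted n, % disordered thresholds, % item
#' pairs beyond the residual-correlation critical values, PSI), mirroring
#' a development-summary table.
#'
#' @param am `analysis_matrix`.
#' @param fit `pcm_fit`.
#' @param persons optional `person_estimates`.
#' @param G class intervals (default 10).
#' @param n_adjust chi-square p-value sample-size adjustment (default 500).
#' @param dif optional DIF table from [dif_screen()]; adds the % items
#'   with DIF p < 0.05 column.
#' @return list of class `fit_report` with `item_table` and `scale_summary`.
#' @export
fit_report <- function(am, fit, persons = NULL, G = 10, n_adjust = 500,
                       dif = NULL) {
  if (is.null(persons)) persons <- estimate_persons(am, fit, method = "WLE")
  rt <- standardized_residuals(am, fit, persons, G = G)
  fr <- item_fit_residual(rt)
  chi <- item_trait_chi_square(rt, n_adjust = n_adjust)
  ord <- threshold_order_check(fit)
  rc <- residual_correlation_flags(rt)
  item_table <- fit$items |>
    dplyr::select("item_id", "location", "se_location") |>
    dplyr::left_join(fr, by = "item_id") |>
    dplyr::left_join(chi, by = "item_id") |>
    dplyr::left_join(ord, by = "item_id")

  dif_pct <- NA_real_
  if (!is.null(dif)) {
    by_item <- dif |>
      dplyr::group_by(.data$item_id) |>
      dplyr::summarise(any_dif = any(.data$flag_uniform | .data$flag_nonuniform,
                                     na.rm = TRUE))
    dif_pct <- 100 * mean(by_item$any_dif)
  }
  ev <- !is.na(fr$fit_residual)
  scale_summary <- tibble::tibble(
    n_items = ncol(am$scores %||% am),
    n_persons = nrow(rt$z),
    coverage_pct = targeting_coverage(persons, fit),
    pct_fit_residual_gt_2.5 = 100 * mean(abs(fr$fit_residual[ev]) > 2.5),
    pct_chi2_p_lt_0.05 = 100 * mean(chi$flag_chi2),
    pct_disordered = 100 * mean(!ord$ordered),
    pct_rescorr_gt_0.30 = 100 * mean(rc$pairs$flag_abs),
    pct_rescorr_gt_mean_0.30 = 100 * mean(rc$pairs$flag_mean),
    rescorr_critical_mean = rc$critical_mean,
    pct_dif_p_lt_0.05 = dif_pct,
    psi = person_separation_index(persons)
  )
  structure(list(item_table = item_table, scale_summary = scale_summary,
                 residuals = rt, residual_correlations = rc),
            class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat("<fit_report>\n")
  print(x$scale_summary)
  invisible(x)
}
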