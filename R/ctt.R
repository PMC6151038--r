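#' Cronbach's alpha
#'
#' alpha = (k/(k-1)) (1 - sum(item variances) / var(total)), computed on
#' complete-item respondents.
#'
#' @param x numeric matrix/data frame, persons x items.
#' @return alpha, or `NA` if fewer than 3 complete respondents, fewer
#'   than 2 items, or zero total variance.
#' @export
cronbach_alpha <- function(x) {
  x <- as.matrix(x)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  k <- ncol(x)
  if (k < 2L || nrow(x) < 3L) return(NA_real_)
  vt <- stats::var(rowSums(x))
  if (vt == 0) return(NA_real_)
  (k / (k - 1)) * (1 - sum(apply(x, 2L, stats::var)) / vt)
}

#' Sample skewness (adjusted Fisher-Pearson)
#'
#' The bias-adjusted standardized third moment,
#' g1 * sqrt(n(n-1))/(n-2), the convention of mainstream statistical
#' packages for survey reporting. Wraps `e1071::skewness(type = 2)`.
#'
#' @param scores numeric vector.
#' @return skewness, or `NA` if n < 3 or zero variance.
#' @export
skewness_adj <- function(scores) {
  scores <- scores[!is.na(scores)]
  if (length(scores) < 3L || stats::sd(scores) == 0) return(NA_real_)
  e1071::skewness(scores, type = 2)
}

#' Classical test theory scale evaluation
#'
#' Computes the CTT battery for one administered scale: per-item means,
#' SDs, missing and don't-know percentages and corrected item-total
#' correlations (CITC: each item against the sum of the remaining items),
#' and scale-level sum-score statistics on complete-item respondents —
#' theoretical and observed score range, mean (SD), floor and ceiling
#' percentages (at the theoretical minimum/maximum of the administered
#' item set), skewness, Cronbach's alpha, and the mean and range of the
#' inter-item correlations. Criterion flags: CITC < 0.30, alpha < 0.80,
#' floor or ceiling >= 15%, |skewness| > 1, item missing >= 10%.
#'
#' Sum scores use the external 1..m+1 metric and complete-item
#' respondents only (no imputation); the n used is reported.
#'
#' @param am `analysis_matrix`.
#' @return list of class `ctt_report` with `item_table` and
#'   `scale_summary` tibbles.
#' @export
ctt_report <- function(am) {
  X <- am$scores + 1L    # external 1..5 coding for sum scores
  k <- ncol(X)
  stopifnot(k >= 2L)
  complete <- stats::complete.cases(X)
  n_complete <- sum(complete)
  if (n_complete < 2L) stop("fewer than 2 complete-item respondents", call. = FALSE)
  Xc <- X[complete, , drop = FALSE]
  total <- rowSums(Xc)

  citc <- vapply(seq_len(k), function(i) {
    rest <- rowSums(Xc[, -i, drop = FALSE])
    if (stats::sd(Xc[, i]) == 0 || stats::sd(rest) == 0) return(NA_real_)
    stats::cor(Xc[, i], rest)
  }, numeric(1))

  item_table <- tibble::tibble(
    item_id = colnames(X),
    mean = colMeans(X, na.rm = TRUE),
    sd = apply(X, 2L, stats::sd, na.rm = TRUE),
    missing_pct = 100 * am$miss_prop,
    dk_pct = 100 * am$dk_prop,
    citc = citc,
    flag_citc = citc < 0.30,
    flag_missing = 100 * am$miss_prop >= 10
  )

  max_cat <- am$items$max_score + 1L  # external max per item
  theo_min <- k * 1L
  theo_max <- sum(max_cat)
  iic <- stats::cor(Xc)
  iic_off <- iic[upper.tri(iic)]
  alpha <- cronbach_alpha(Xc)
  floor_pct <- 100 * mean(total == theo_min)
  ceiling_pct <- 100 * mean(total == theo_max)
  skw <- skewness_adj(total)

  scale_summary <- tibble::tibble(
    n_items = k,
    n_complete = n_complete,
    theoretical_min = theo_min, theoretical_max = theo_max,
    observed_min = min(total), observed_max = max(total),
    mean_sum = mean(total), sd_sum = stats::sd(total),
    citc_min = min(citc, na.rm = TRUE), citc_max = max(citc, na.rm = TRUE),
    floor_pct = floor_pct, ceiling_pct = ceiling_pct,
    skewness = skw,
    alpha = alpha,
    mean_iic = mean(iic_off), iic_min = min(iic_off), iic_max = max(iic_off),
    flag_alpha = alpha < 0.80,
    flag_floor_ceiling = floor_pct >= 15 || ceiling_pct >= 15,
    flag_skewness = abs(skw) > 1
  )
  structure(list(item_table = item_table, scale_summary = scale_summary),
            class = "ctt_report")
}

#' @export
print.ctt_report <- function(x, ...) {
  cat("<ctt_report>\n")
  print(x$scale_summary)
  invisible(x)
}
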