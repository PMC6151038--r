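#' Known-group comparison from summary statistics
#'
#' Pooled-variance Student t-test between two groups given (n, mean, SD)
#' triples, with df = n1 + n2 - 2 and Cohen's d = |m1 - m2| / pooled SD.
#' Printed group summaries of a validation report can be fed straight in.
#'
#' @param n1,mean1,sd1 first group.
#' @param n2,mean2,sd2 second group.
#' @param label1,label2 optional group labels.
#' @return one-row tibble with `t`, `df`, `p_value` (two-sided),
#'   `cohen_d` (non-negative; the sign of the difference is carried by
#'   `mean_diff`), and the inputs.
#' @export
known_group_ttest <- function(n1, mean1, sd1, n2, mean2, sd2,
                              label1 = "group1", label2 = "group2") {
  stopifnot(n1 >= 2, n2 >= 2, sd1 > 0, sd2 > 0)
  df <- n1 + n2 - 2
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df)
  t <- (mean1 - mean2) / (sp * sqrt(1 / n1 + 1 / n2))
  tibble::tibble(
    label1 = label1, label2 = label2,
    n1 = n1, mean1 = mean1, sd1 = sd1,
    n2 = n2, mean2 = mean2, sd2 = sd2,
    mean_diff = mean1 - mean2,
    t = t, df = df,
    p_value = 2 * stats::pt(-abs(t), df),
    cohen_d = abs(mean1 - mean2) / sp
  )
}

#' Spearman rank correlation between two measures
#'
#' Rank correlation with average ranks for ties, on complete pairs.
#'
#' @param x,y numeric vectors.
#' @return one-row tibble with `r_s` and `n` (complete pairs); `r_s` is
#'   `NA` (not evaluable) for a constant vector.
#' @export
spearman_corr <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  stopifnot(sum(ok) >= 3L)
  x <- x[ok]; y <- y[ok]
  r <- if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_
       else stats::cor(x, y, method = "spearman")
  tibble::tibble(r_s = r, n = sum(ok))
}

#' Correction for attenuation
#'
#' Divides an observed correlation by the square root of the product of
#' the two measures' reliabilities, estimating the correlation between
#' the error-free constructs. Values above 1 are returned as-is with an
#' over-correction warning.
#'
#' @param r_obs observed correlation.
#' @param rel_a,rel_b reliabilities in (0, 1].
#' @return disattenuated correlation.
#' @export
disattenuate <- function(r_obs, rel_a, rel_b) {
  stopifnot(rel_a > 0, rel_a <= 1, rel_b > 0, rel_b <= 1)
  r <- r_obs / sqrt(rel_a * rel_b)
  if (any(abs(r) > 1)) {
    warning("disattenuated correlation exceeds 1 in absolute value ",
            "(over-correction)", call. = FALSE)
  }
  r
}

#' Carry-over assessment: first versus subsequent presentation
#'
#' Compares the measures of respondents who assessed an object first in
#' their sequence against those who assessed it after at least one other
#' object, with a pooled-variance t-test per object (and framing, when
#' present). A systematic first-vs-subsequent difference indicates that
#' earlier assessments prime later ones.
#'
#' @param persons `person_estimates` (or data frame) with columns
#'   `theta`, `position`, `object` and optionally `framing`.
#' @param measure column to compare (default `"theta"`).
#' @return tibble with one row per object (x framing): ns, means, SDs of
#'   the first and subsequent strata, `t`, `df`, `p_value`, `cohen_d`;
#'   strata with fewer than 2 usable persons are not evaluable (`NA`).
#' @export
carry_over_assessment <- function(persons, measure = "theta") {
  d <- as.data.frame(persons)
  stopifnot(all(c(measure, "position", "object") %in% names(d)))
  d <- d[is.finite(d[[measure]]) & !is.na(d$position), ]
  d$first <- d$position == 1
  grp_vars <- intersect(c("object", "framing"), names(d))
  split_keys <- interaction(d[grp_vars], drop = TRUE)
  out <- lapply(levels(split_keys), function(k) {
    dd <- d[split_keys == k, ]
    x1 <- dd[[measure]][dd$first]
    x2 <- dd[[measure]][!dd$first]
    base <- tibble::as_tibble(dd[1, grp_vars, drop = FALSE])
    if (length(x1) < 2L || length(x2) < 2L ||
        stats::sd(x1) == 0 || stats::sd(x2) == 0) {
      return(dplyr::bind_cols(base, tibble::tibble(
        n_first = length(x1), n_subsequent = length(x2),
        mean_first = NA_real_, mean_subsequent = NA_real_,
        sd_first = NA_real_, sd_subsequent = NA_real_,
        t = NA_real_, df = NA_real_, p_value = NA_real_, cohen_d = NA_real_)))
    }
    tt <- known_group_ttest(length(x1), mean(x1), stats::sd(x1),
                            length(x2), mean(x2), stats::sd(x2),
                            "first", "subsequent")
    dplyr::bind_cols(base, tibble::tibble(
      n_first = tt$n1, n_subsequent = tt$n2,
      mean_first = tt$mean1, mean_subsequent = tt$mean2,
      sd_first = tt$sd1, sd_subsequent = tt$sd2,
      t = tt$t, df = tt$df, p_value = tt$p_value, cohen_d = tt$cohen_d))
  })
  dplyr::bind_rows(out)
}
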