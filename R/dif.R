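#' Differential item functioning by ANOVA of standardized residuals
#'
#' For one item, a two-way fixed-effects ANOVA of the standardized
#' residuals with the person factor (e.g. sex, smoking group, assessment
#' object) and the class interval as factors, using type-II sums of
#' squares on the unbalanced grid. The residuals are standardized by
#' their conditional-on-raw-score moments, which makes them mean 0 and
#' variance 1 within every class interval under the no-DIF null whatever
#' the group composition — group factors whose latent means differ would
#' otherwise inflate the F-tests through heteroscedastic extreme
#' intervals. A significant main effect of the
#' factor indicates uniform DIF (a constant shift in item difficulty for
#' a group); a significant factor-by-class-interval interaction indicates
#' non-uniform DIF (group differences that change along the latent
#' continuum). Tests are test-wise at `alpha` (default 0.05, no
#' multiplicity correction); an optional Bonferroni correction across
#' items is available via `bonferroni`.
#'
#' Factor levels with fewer than `min_level_n` persons are dropped with a
#' warning; items are reported not-evaluable (`NA`) if fewer than two
#' levels remain.
#'
#' @param rt `residual_table`.
#' @param factor_values character/factor vector over the rows of the
#'   residual table (or the name of a column of its `meta`).
#' @param alpha test-wise significance level (default 0.05).
#' @param min_level_n minimum persons per level (default 20).
#' @param bonferroni if `TRUE`, flags use `alpha / n_items`.
#' @return tibble with one row per item: `F_uniform`, `p_uniform`,
#'   `F_nonuniform`, `p_nonuniform`, `flag_uniform`, `flag_nonuniform`.
#' @export
dif_anova <- function(rt, factor_values, alpha = 0.05, min_level_n = 20,
                      bonferroni = FALSE) {
  if (is.character(factor_values) && length(factor_values) == 1L) {
    stopifnot(!is.null(rt$meta), factor_values %in% names(rt$meta))
    fname <- factor_values
    factor_values <- rt$meta[[factor_values]]
  } else fname <- "factor"
  f <- factor(factor_values)
  tab <- table(f)
  small <- names(tab)[tab < min_level_n]
  if (length(small) > 0L) {
    warning("dropping factor level(s) with < ", min_level_n, " persons: ",
            paste(small, collapse = ", "), call. = FALSE)
    f[f %in% small] <- NA
    f <- droplevels(f)
  }
  ids <- colnames(rt$z)
  crit <- if (bonferroni) alpha / length(ids) else alpha
  out <- lapply(seq_along(ids), function(i) {
    base <- tibble::tibble(item_id = ids[i], factor = fname,
                           F_uniform = NA_real_, p_uniform = NA_real_,
                           F_nonuniform = NA_real_, p_nonuniform = NA_real_,
                           flag_uniform = NA, flag_nonuniform = NA)
    d <- data.frame(z = rt$z_cond[, i], g = f,
                    ci = factor(rt$class_interval))
    d <- d[stats::complete.cases(d), ]
    if (nlevels(droplevels(d$g)) < 2L || nrow(d) < 10L) return(base)
    d$g <- droplevels(d$g); d$ci <- droplevels(d$ci)
    aov2 <- tryCatch(
      suppressMessages(car::Anova(stats::lm(z ~ g * ci, data = d), type = 2)),
      error = function(e) NULL)
    if (is.null(aov2)) return(base)
    rn <- rownames(aov2)
    gi <- match("g", rn); xi <- match("g:ci", rn)
    base$F_uniform <- aov2$`F value`[gi]
    base$p_uniform <- aov2$`Pr(>F)`[gi]
    base$F_nonuniform <- aov2$`F value`[xi]
    base$p_nonuniform <- aov2$`Pr(>F)`[xi]
    base$flag_uniform <- !is.na(base$p_uniform) && base$p_uniform < crit
    base$flag_nonuniform <- !is.na(base$p_nonuniform) && base$p_nonuniform < crit
    base
  })
  dplyr::bind_rows(out)
}

#' Screen all items for DIF across several person factors
#'
#' Runs [dif_anova()] for each factor (columns of the residual table's
#' metadata, e.g. group, age band, sex, education, object, framing) and
#' stacks the results, with a scale-level summary of the percentage of
#' items flagged.
#'
#' @param rt `residual_table` carrying row metadata.
#' @param factors character vector of metadata column names.
#' @param ... passed to [dif_anova()].
#' @return tibble of per-item-by-factor DIF results; attribute
#'   `summary` holds the scale-level flag percentages per factor.
#' @export
dif_screen <- function(rt, factors = c("group", "age_band", "sex",
                                       "education", "object", "framing"),
                       ...) {
  stopifnot(!is.null(rt$meta))
  factors <- intersect(factors, names(rt$meta))
  usable <- factors[vapply(factors, function(f)
    length(unique(stats::na.omit(rt$meta[[f]]))) >= 2L, logical(1))]
  res <- lapply(usable, function(f) {
    r <- dif_anova(rt, f, ...)
    r$factor <- f
    r
  })
  out <- dplyr::bind_rows(res)
  smry <- out |>
    dplyr::group_by(.data$factor) |>
    dplyr::summarise(
      pct_items_uniform = 100 * mean(.data$flag_uniform, na.rm = TRUE),
      pct_items_nonuniform = 100 * mean(.data$flag_nonuniform, na.rm = TRUE),
      pct_items_any = 100 * mean(.data$flag_uniform | .data$flag_nonuniform,
                                 na.rm = TRUE))
  attr(out, "summary") <- smry
  out
}
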