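#' Item-reduction criteria
#'
#' The flag thresholds driving the iterative reduction loop: fit
#' residuals beyond +/-`max_fit_residual`; class-interval chi-square
#' p < `chi2_alpha` at the adjusted sample size `n_adjust`; disordered
#' thresholds; residual correlations beyond the chosen rule
#' (`"mean"` = mean of all pairwise residual correlations + 0.30,
#' `"abs"` = 0.30); DIF p < `dif_alpha` on any screened factor.
#'
#' @param max_fit_residual default 2.5.
#' @param chi2_alpha default 0.05.
#' @param n_adjust default 500.
#' @param dif_alpha default 0.05.
#' @param residual_corr_rule `"mean"` (default) or `"abs"`.
#' @param dif_familywise if `TRUE` (default) the *removal* DIF flag
#'   controls the error rate per item across all screened factors
#'   (Bonferroni over the uniform and non-uniform tests); the reported
#'   per-factor flags stay test-wise. With many factors, test-wise
#'   flagging would discard several clean items per iteration by chance
#'   alone.
#' @param max_removals_per_iteration default 6.
#' @param max_iterations default 3.
#' @param G class intervals (default 10).
#' @return list of class `reduction_criteria`.
#' @export
reduction_criteria <- function(max_fit_residual = 2.5, chi2_alpha = 0.05,
                               n_adjust = 500, dif_alpha = 0.05,
                               residual_corr_rule = c("mean", "abs"),
                               dif_familywise = TRUE,
                               max_removals_per_iteration = 6,
                               max_iterations = 3, G = 10) {
  stopifnot(max_fit_residual > 0, chi2_alpha > 0, chi2_alpha < 1,
            dif_alpha > 0, dif_alpha < 1)
  structure(list(
    max_fit_residual = max_fit_residual, chi2_alpha = chi2_alpha,
    n_adjust = n_adjust, dif_alpha = dif_alpha,
    residual_corr_rule = match.arg(residual_corr_rule),
    dif_familywise = dif_familywise,
    max_removals_per_iteration = max_removals_per_iteration,
    max_iterations = max_iterations, G = G
  ), class = "reduction_criteria")
}

#' Combine the diagnostic flags for every item
#'
#' Merges the fit report, DIF table and residual-correlation flags of one
#' calibration into a per-item boolean flag vector: `misfit`, `chi2`,
#' `disordered`, `local_dependence`, `dif`, plus ranking statistics.
#'
#' @param report `fit_report` for the current calibration.
#' @param dif DIF table from [dif_screen()] (or `NULL`).
#' @param criteria `reduction_criteria`.
#' @return tibble, one row per item.
#' @export
flag_items <- function(report, dif = NULL, criteria = reduction_criteria()) {
  it <- report$item_table
  rc <- report$residual_correlations
  ld_col <- if (criteria$residual_corr_rule == "mean") "flag_mean" else "flag_abs"
  ld_items <- unique(c(rc$pairs$item_a[rc$pairs[[ld_col]]],
                       rc$pairs$item_b[rc$pairs[[ld_col]]]))
  out <- tibble::tibble(
    item_id = it$item_id,
    fit_residual = it$fit_residual,
    misfit = !is.na(it$fit_residual) &
      abs(it$fit_residual) > criteria$max_fit_residual,
    chi2 = !is.na(it$p_value) & it$p_value < criteria$chi2_alpha,
    disordered = !it$ordered,
    local_dependence = it$item_id %in% ld_items,
    dif = FALSE, dif_F = NA_real_
  )
  if (!is.null(dif) && nrow(dif) > 0L) {
    n_tests <- 2L * length(unique(dif$factor))
    crit <- if (isTRUE(criteria$dif_familywise))
      criteria$dif_alpha / n_tests else criteria$dif_alpha
    by_item <- dif |>
      dplyr::group_by(.data$item_id) |>
      dplyr::summarise(
        dif = any(stats::na.omit(c(.data$p_uniform, .data$p_nonuniform))
                  < crit),
        dif_F = suppressWarnings(max(c(.data$F_uniform, .data$F_nonuniform),
                                     na.rm = TRUE)))
    out$dif <- by_item$dif[match(out$item_id, by_item$item_id)]
    out$dif_F <- by_item$dif_F[match(out$item_id, by_item$item_id)]
    out$dif[is.na(out$dif)] <- FALSE
  }
  out$any_flag <- out$misfit | out$chi2 | out$disordered |
    out$local_dependence | out$dif
  out
}

#' Iterative item reduction with an auditable trail
#'
#' Repeats calibrate -> diagnose -> flag -> remove until no item is
#' flagged or `max_iterations` is reached. In `auto` mode, removals are
#' ranked misfit first (by |fit residual|), then DIF (by largest F), then
#' local dependence (one member per flagged pair — the one fitting
#' worse), capped at `max_removals_per_iteration`; in `interactive` mode
#' a `chooser` callback receives the flag table and returns the item ids
#' to remove. Removals never reduce the scale below 3 items, so even a
#' pool where every item is flagged (item fit is relative, so heavy
#' contamination pushes the clean items' fit residuals outward too) is
#' pruned worst-first rather than emptied. Deterministic given data,
#' criteria and mode.
#'
#' @param am `analysis_matrix` of the initial item pool (>= 3 items).
#' @param criteria `reduction_criteria`.
#' @param mode `"auto"` or `"interactive"`.
#' @param dif_factors metadata columns screened for DIF each iteration
#'   (`NULL` to skip DIF flags).
#' @param chooser function(flag_table) -> character item ids
#'   (interactive mode only).
#' @return list of class `reduction_trail`: per-iteration snapshots
#'   (`flags`, `removed`, `reasons`, scale summary), `retained` and
#'   `removed_total`.
#' @export
reduce_scale <- function(am, criteria = reduction_criteria(),
                         mode = c("auto", "interactive"),
                         dif_factors = c("group", "sex", "object", "framing"),
                         chooser = NULL) {
  mode <- match.arg(mode)
  stopifnot(ncol(am$scores) >= 3L)
  current <- am
  iterations <- list()
  removed_total <- character(0)

  for (iter in seq_len(criteria$max_iterations)) {
    fit <- calibrate_items(current)
    persons <- estimate_persons(current, fit, method = "WLE")
    rt <- standardized_residuals(current, fit, persons, G = criteria$G)
    dif <- NULL
    if (!is.null(dif_factors) && !is.null(rt$meta)) {
      dif <- dif_screen(rt, factors = dif_factors, alpha = criteria$dif_alpha)
    }
    report <- fit_report(current, fit, persons, G = criteria$G,
                         n_adjust = criteria$n_adjust, dif = dif)
    flags <- flag_items(report, dif, criteria)

    removable <- flags$misfit | flags$dif | flags$local_dependence |
      flags$disordered
    if (!any(removable)) {
      iterations[[iter]] <- list(flags = flags, removed = character(0),
                                 reasons = character(0),
                                 scale_summary = report$scale_summary)
      break
    }
    # heavily contaminated pools can flag every item (fit is relative:
    # strong under-discrimination pushes the clean items negative); the
    # loop then proceeds worst-first — the per-iteration cap and the
    # 3-item floor prevent emptying the scale
    if (mode == "interactive") {
      stopifnot(is.function(chooser))
      remove <- intersect(chooser(flags), flags$item_id[flags$any_flag])
      reasons <- stats::setNames(rep("operator", length(remove)), remove)
    } else {
      picks <- character(0); reasons <- character(0)
      mis <- flags[flags$misfit, ]
      mis <- mis$item_id[order(-abs(mis$fit_residual))]
      picks <- c(picks, mis)
      reasons <- c(reasons, stats::setNames(rep("misfit", length(mis)), mis))
      dif_it <- flags[flags$dif & !flags$item_id %in% picks, ]
      dif_it <- dif_it$item_id[order(-dif_it$dif_F)]
      picks <- c(picks, dif_it)
      reasons <- c(reasons, stats::setNames(rep("dif", length(dif_it)), dif_it))
      # local dependence: one member per flagged pair, the worse-fitting one
      rc <- report$residual_correlations$pairs
      ld_col <- if (criteria$residual_corr_rule == "mean") "flag_mean" else "flag_abs"
      ld_pairs <- rc[rc[[ld_col]], , drop = FALSE]
      for (j in seq_len(nrow(ld_pairs))) {
        pr <- c(ld_pairs$item_a[j], ld_pairs$item_b[j])
        if (any(pr %in% picks)) next
        fr <- abs(flags$fit_residual[match(pr, flags$item_id)])
        victim <- pr[which.max(ifelse(is.na(fr), -Inf, fr))]
        picks <- c(picks, victim)
        reasons <- c(reasons, stats::setNames("local_dependence", victim))
      }
      dis <- flags$item_id[flags$disordered & !flags$item_id %in% picks]
      picks <- c(picks, dis)
      reasons <- c(reasons, stats::setNames(rep("disordered", length(dis)), dis))
      # a chi-square flag alone is supporting evidence, not a removal
      # driver; keep only one member of each locally dependent pair
      for (j in seq_len(nrow(ld_pairs))) {
        pr <- c(ld_pairs$item_a[j], ld_pairs$item_b[j])
        if (all(pr %in% picks)) {
          fr <- abs(flags$fit_residual[match(pr, flags$item_id)])
          keeper <- pr[which.min(ifelse(is.na(fr), Inf, fr))]
          picks <- setdiff(picks, keeper)
          reasons <- reasons[names(reasons) != keeper]
        }
      }
      remove <- utils::head(picks, criteria$max_removals_per_iteration)
      reasons <- reasons[remove]
    }
    keep_n <- ncol(current$scores) - length(remove)
    if (keep_n < 3L) {
      remove <- utils::head(remove, ncol(current$scores) - 3L)
      reasons <- reasons[remove]
    }

    iterations[[iter]] <- list(flags = flags, removed = remove,
                               reasons = reasons,
                               scale_summary = report$scale_summary)
    removed_total <- c(removed_total, remove)
    if (length(remove) == 0L) break
    keep <- setdiff(colnames(current$scores), remove)
    current <- subset_items(current, keep)
  }

  structure(list(
    iterations = iterations,
    retained = colnames(current$scores),
    removed_total = removed_total,
    criteria = criteria
  ), class = "reduction_trail")
}

#' Restrict an analysis matrix to a subset of items
#' @param am `analysis_matrix`.
#' @param item_ids item ids to keep.
#' @export
subset_items <- function(am, item_ids) {
  idx <- match(item_ids, colnames(am$scores))
  stopifnot(!anyNA(idx))
  out <- am
  out$scores <- am$scores[, idx, drop = FALSE]
  out$items <- am$items[idx, ]
  out$dk_prop <- am$dk_prop[idx]
  out$miss_prop <- am$miss_prop[idx]
  all_missing <- rowSums(!is.na(out$scores)) == 0L
  if (any(all_missing)) {
    out$scores <- out$scores[!all_missing, , drop = FALSE]
    out$meta <- out$meta[!all_missing, ]
    out$n_dropped_rows <- out$n_dropped_rows + sum(all_missing)
  }
  out
}

#' @export
print.reduction_trail <- function(x, ...) {
  cat("<reduction_trail> ", length(x$iterations), " iteration(s); removed ",
      length(x$removed_total), " item(s); retained ",
      length(x$retained), "\n", sep = "")
  for (i in seq_along(x$iterations)) {
    it <- x$iterations[[i]]
    cat("  iter ", i, ": removed [",
        paste(it$removed, collapse = ", "), "]\n", sep = "")
  }
  invisible(x)
}

#' Write a human-readable markdown audit report of a reduction trail
#' @param trail `reduction_trail`.
#' @param path output path.
#' @export
write_reduction_report <- function(trail, path) {
  lines <- c("# Item reduction audit", "",
             sprintf("Retained %d item(s): %s", length(trail$retained),
                     paste(trail$retained, collapse = ", ")),
             sprintf("Removed %d item(s) over %d iteration(s).",
                     length(trail$removed_total), length(trail$iterations)),
             "")
  for (i in seq_along(trail$iterations)) {
    it <- trail$iterations[[i]]
    lines <- c(lines, sprintf("## Iteration %d", i), "")
    if (length(it$removed) == 0L) {
      lines <- c(lines, "No removals.", "")
    } else {
      lines <- c(lines, "| item | reason |", "|------|--------|",
                 sprintf("| %s | %s |", it$removed, it$reasons[it$removed]), "")
    }
    fl <- it$flags[it$flags$any_flag, ]
    if (nrow(fl) > 0L) {
      lines <- c(lines,
                 sprintf("Flagged: %s.",
                         paste(sprintf("%s (%s)", fl$item_id,
                                       apply(fl[, c("misfit", "chi2", "disordered",
                                                    "local_dependence", "dif")], 1,
                                             function(r) paste(names(r)[as.logical(r)],
                                                               collapse = "+"))),
                               collapse = ", ")), "")
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Serialize a reduction trail to JSON
#' @param trail `reduction_trail`.
#' @param path output path.
#' @export
write_reduction_trail <- function(trail, path) {
  out <- list(
    retained = trail$retained,
    removed_total = trail$removed_total,
    iterations = lapply(trail$iterations, function(it) list(
      removed = it$removed,
      reasons = as.list(it$reasons),
      flags = it$flags,
      scale_summary = it$scale_summary
    ))
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
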