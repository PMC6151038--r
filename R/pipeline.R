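#' Run the full development-and-validation pipeline
#'
#' Orchestrates the stages in dependency order on a generated (or
#' supplied) dataset, per scale: calibration, person measurement, RMT
#' diagnostics, DIF screen, CTT evaluation, the raw-score conversion
#' table, and the construct-validity analyses (known groups, VAS
#' correlations with disattenuation, carry-over). Every number in the
#' report is recomputable by calling the module functions directly; the
#' report carries a provenance block (seed, config echo, versions,
#' stage timings).
#'
#' @param config `generator_config` describing the dataset to simulate,
#'   or a precomputed result of [generate_survey()].
#' @param scales scales to evaluate.
#' @param G class intervals.
#' @param n_adjust chi-square p-value adjustment.
#' @param out_dir optional directory; when given, CSV/JSON reports are
#'   written there.
#' @return list of class `evaluation_report` with one entry per scale
#'   (`fit`, `persons`, `rmt`, `dif`, `ctt`, `conversion`, `validity`)
#'   plus `provenance`.
#' @export
run_pipeline <- function(config = generator_config(), scales = c("health", "addiction"),
                         G = 10, n_adjust = 500, out_dir = NULL) {
  t0 <- Sys.time()
  sim <- if (inherits(config, "generator_config")) generate_survey(config) else config
  ds <- sim$data
  cf <- sim$truth$config
  timings <- c(simulate = as.numeric(Sys.time() - t0, units = "secs"))

  report <- list()
  for (s in scales) {
    ts <- Sys.time()
    am <- to_analysis_matrix(ds, scale = s, bank = cf$bank)
    fit <- calibrate_items(am)
    persons <- estimate_persons(am, fit, method = "WLE")
    rt <- standardized_residuals(am, fit, persons, G = G)
    dif <- dif_screen(rt)
    rmt <- fit_report(am, fit, persons, G = G, n_adjust = n_adjust, dif = dif)
    # CTT sum scores need a fixed administered form: restrict to the
    # objects receiving the scale's largest item set
    n_app <- vapply(cf$objects, function(o)
      nrow(applicable_items(cf$bank, s, o)), numeric(1))
    ctt <- ctt_report(to_analysis_matrix(ds, scale = s,
                                         object = cf$objects[n_app == max(n_app)],
                                         bank = cf$bank))

    # conversion table for the full administered form of the scale
    full_obj <- cf$objects[1]
    conv_items <- applicable_items(cf$bank, s, full_obj)
    conv <- build_conversion_table(fit$tau[conv_items$item_id, , drop = FALSE])

    validity <- pipeline_validity(persons, sim$truth$vas, s)
    report[[s]] <- list(fit = fit, persons = persons, rmt = rmt, dif = dif,
                        ctt = ctt, conversion = conv, validity = validity)
    timings[s] <- as.numeric(Sys.time() - ts, units = "secs")
  }

  report$provenance <- list(
    seed = cf$seed,
    n_respondents = length(unique(ds$respondent_id)),
    scales = scales, G = G, n_adjust = n_adjust,
    package_version = as.character(utils::packageVersion("raschval")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    stage_seconds = as.list(round(timings, 2))
  )
  class(report) <- "evaluation_report"
  if (!is.null(out_dir)) write_evaluation_report(report, out_dir)
  report
}

pipeline_validity <- function(persons, vas, scale) {
  out <- list()
  # known groups: personal vs general framing among current smokers;
  # current vs never smokers; intenders vs non-intenders (object CC)
  cc <- persons[persons$object == "CC" & is.finite(persons$theta), ]
  grp_stats <- function(d) c(n = nrow(d), m = mean(d$theta), s = stats::sd(d$theta))
  cmp <- function(d1, d2, l1, l2) {
    if (nrow(d1) < 2L || nrow(d2) < 2L) return(NULL)
    s1 <- grp_stats(d1); s2 <- grp_stats(d2)
    known_group_ttest(s1["n"], s1["m"], s1["s"], s2["n"], s2["m"], s2["s"], l1, l2)
  }
  cs <- cc[cc$group %in% c("CS_NIQ", "CS_IQ"), ]
  out$known_groups <- dplyr::bind_rows(
    cmp(cs[cs$framing == "P", ], cs[cs$framing == "G", ], "CS personal", "CS general"),
    cmp(cs, cc[cc$group == "NS", ], "current smokers", "never smokers"),
    cmp(cc[cc$group == "CS_IQ", ], cc[cc$group == "CS_NIQ", ],
        "CS intend to quit", "CS no intention")
  )
  if (!is.null(vas)) {
    v <- vas[vas$scale == scale, ]
    key_p <- paste(persons$respondent_id, persons$object, persons$framing)
    key_v <- paste(v$respondent_id, v$object, v$framing)
    mi <- match(key_p, key_v)
    ok <- !is.na(mi) & is.finite(persons$theta)
    conv <- lapply(unique(persons$object[ok]), function(o) {
      sel <- ok & persons$object == o
      sc <- spearman_corr(persons$theta[sel], v$vas[mi[sel]])
      sc$object <- o
      sc
    })
    out$convergent <- dplyr::bind_rows(conv)
  }
  out$carry_over <- carry_over_assessment(persons)
  out
}

#' Write an evaluation report to disk
#'
#' CSV tables mirroring the development-report structures (item
#' calibration, RMT scale summary, DIF, CTT, conversion table, validity)
#' plus a JSON provenance block.
#'
#' @param report `evaluation_report`.
#' @param out_dir directory (created if needed).
#' @export
write_evaluation_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (s in setdiff(names(report), "provenance")) {
    r <- report[[s]]
    write_calibration(r$fit, file.path(out_dir, paste0(s, "_calibration.csv")))
    readr::write_csv(r$rmt$item_table,
                     file.path(out_dir, paste0(s, "_rmt_items.csv")), progress = FALSE)
    readr::write_csv(r$rmt$scale_summary,
                     file.path(out_dir, paste0(s, "_rmt_summary.csv")), progress = FALSE)
    readr::write_csv(r$dif, file.path(out_dir, paste0(s, "_dif.csv")), progress = FALSE)
    readr::write_csv(r$ctt$item_table,
                     file.path(out_dir, paste0(s, "_ctt_items.csv")), progress = FALSE)
    readr::write_csv(r$ctt$scale_summary,
                     file.path(out_dir, paste0(s, "_ctt_summary.csv")), progress = FALSE)
    write_conversion_table(r$conversion,
                           file.path(out_dir, paste0(s, "_conversion.csv")))
    if (!is.null(r$validity$known_groups)) {
      readr::write_csv(r$validity$known_groups,
                       file.path(out_dir, paste0(s, "_known_groups.csv")),
                       progress = FALSE)
    }
    readr::write_csv(r$validity$carry_over,
                     file.path(out_dir, paste0(s, "_carry_over.csv")), progress = FALSE)
  }
  jsonlite::write_json(report$provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report> scales:",
      paste(setdiff(names(x), "provenance"), collapse = ", "), "\n")
  for (s in setdiff(names(x), "provenance")) {
    cat("--", s, "--\n")
    print(x[[s]]$rmt$scale_summary)
  }
  invisible(x)
}
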