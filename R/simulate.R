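#' Configuration for the synthetic risk-perception survey generator
#'
#' Bundles every knob of the generator emulating a stratified web-panel
#' survey: four equally sized smoking-status strata, each respondent
#' randomized to one risk framing (personal or general) and assessing up
#' to five objects in a random sequence; 18 health-risk and 7
#' addiction-risk items with published default locations; 5-category
#' responses drawn from the partial credit model with "don't know"
#' thinning; auxiliary VAS measures with a target reliability; and
#' optional planted defects (uniform / non-uniform DIF, misfitting items,
#' carry-over shifts).
#'
#' Defaults encode the study conditions: 410 respondents per stratum,
#' object-by-framing latent means from the published object-means table,
#' group offsets consistent with the known-group comparisons, person SD
#' 2.9 logits, threshold offsets spanning +/-3.5 logits about the item
#' location (so that thresholds cover roughly -4.5..+4 logits), an 8-15%
#' "don't know" band (default rate 0.12), and VAS reliability 0.6.
#'
#' @param n_per_group respondents per smoking-status stratum.
#' @param objects assessment objects to administer.
#' @param framings framings to randomize respondents over.
#' @param bank item bank (default [pri_item_bank()]).
#' @param threshold_offsets step offsets added to each item location.
#' @param object_means named list per scale of framing x object latent
#'   mean matrices (logits).
#' @param group_offsets named vector of latent shifts per stratum.
#' @param person_sd within-group latent SD (logits); a scalar or a named
#'   per-scale vector (default: health 2.9, addiction 3.4, reflecting the
#'   larger dispersion of the published addiction-scale measures).
#' @param person_cor share of latent variance common to all of a
#'   respondent's object-framing traits (repeated-measures correlation).
#' @param dk_rate "don't know" probability per administered response;
#'   scalar or named per-item vector.
#' @param dk_mnar if `TRUE`, never-smokers under the personal framing
#'   get `dk_mnar_multiplier` times the rate (stress-test mode).
#' @param dk_mnar_multiplier see above.
#' @param carry_over named per-object logit shift applied when the
#'   object is not assessed first (default all zero).
#' @param ns_personal_skip objects not administered to never smokers
#'   under the personal framing.
#' @param vas emit auxiliary VAS measures?
#' @param vas_reliability target reliability of the VAS scores.
#' @param vas_truth_cor correlation of the VAS construct with the latent
#'   risk trait.
#' @param seed integer seed; every stochastic routine is derived from it.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(n_per_group = 410,
                             objects = c("CC", "THS", "ECIG", "NRT", "CESS"),
                             framings = c("P", "G"),
                             bank = pri_item_bank(),
                             threshold_offsets = c(-3.5, -3.5 / 3, 3.5 / 3, 3.5),
                             object_means = default_object_means(),
                             group_offsets = c(CS_NIQ = -1.2, CS_IQ = -0.4,
                                               FS = 0.6, NS = 1.0),
                             person_sd = c(health = 2.9, addiction = 3.4),
                             person_cor = 0.5,
                             dk_rate = 0.12,
                             dk_mnar = FALSE,
                             dk_mnar_multiplier = 2,
                             carry_over = NULL,
                             ns_personal_skip = c("NRT", "CESS"),
                             vas = TRUE,
                             vas_reliability = 0.6,
                             vas_truth_cor = 0.8,
                             seed = 20140201) {
  stopifnot(n_per_group >= 1, person_sd > 0,
            all(dk_rate >= 0), all(dk_rate <= 1),
            person_cor >= 0, person_cor <= 1,
            vas_reliability > 0, vas_reliability <= 1,
            abs(vas_truth_cor) <= 1,
            all(diff(threshold_offsets) > 0))
  if (is.null(carry_over)) {
    carry_over <- stats::setNames(rep(0, length(objects)), objects)
  }
  structure(list(
    n_per_group = as.integer(n_per_group), objects = objects,
    framings = framings, bank = bank,
    threshold_offsets = threshold_offsets, object_means = object_means,
    group_offsets = group_offsets, person_sd = person_sd,
    person_cor = person_cor, dk_rate = dk_rate, dk_mnar = dk_mnar,
    dk_mnar_multiplier = dk_mnar_multiplier, carry_over = carry_over,
    ns_personal_skip = ns_personal_skip, vas = vas,
    vas_reliability = vas_reliability, vas_truth_cor = vas_truth_cor,
    dif_injections = list(), misfit_injections = list(),
    seed = as.integer(seed)
  ), class = "generator_config")
}

#' Default object-by-framing latent means (logits)
#'
#' Published object means of the Rasch-based measures, per scale and
#' framing, used as generator defaults.
#' @return named list (`health`, `addiction`) of 2 x 5 matrices
#'   (framings P/G by objects CC/THS/ECIG/NRT/CESS).
#' @export
default_object_means <- function() {
  obj <- c("CC", "THS", "ECIG", "NRT", "CESS")
  list(
    health = matrix(c(2.12, 0.51, -0.15, -1.47, -0.69,
                      2.51, 0.63, -0.17, -0.70, 0.07),
                    2, 5, byrow = TRUE, dimnames = list(c("P", "G"), obj)),
    addiction = matrix(c(2.91, 1.23, 0.61, -0.30, -0.89,
                         3.73, 1.69, 0.75, 0.30, -0.04),
                       2, 5, byrow = TRUE, dimnames = list(c("P", "G"), obj))
  )
}

#' Plant differential item functioning in a generator configuration
#'
#' Uniform DIF shifts every threshold of the item by `value` logits for
#' the focal level of the factor; non-uniform DIF draws the focal level's
#' responses with the item's cumulative logits scaled by a discrimination
#' `value` different from 1, breaking the common Rasch slope.
#'
#' @param config `generator_config`.
#' @param item item id.
#' @param factor metadata column defining the groups (e.g. `"sex"`).
#' @param level focal level receiving the defect.
#' @param kind `"uniform"` (value = logit shift) or `"nonuniform"`
#'   (value = discrimination).
#' @param value shift or discrimination.
#' @return modified `generator_config`. A second injection on the same
#'   item and factor replaces the first with a warning.
#' @export
inject_dif <- function(config, item, factor, level,
                       kind = c("uniform", "nonuniform"), value) {
  kind <- match.arg(kind)
  stopifnot(item %in% config$bank$item_id)
  key <- paste(item, factor, sep = ":")
  if (key %in% names(config$dif_injections)) {
    warning("replacing existing DIF injection on ", key, call. = FALSE)
  }
  config$dif_injections[[key]] <-
    list(item = item, factor = factor, level = level, kind = kind, value = value)
  config
}

#' Plant an item violating the common discrimination of the Rasch model
#'
#' The item's responses are drawn with cumulative logits scaled by `a`
#' for everyone: `a < 1` yields an under-discriminating (noisy) item,
#' `a > 1` an over-discriminating one.
#'
#' @param config `generator_config`.
#' @param item item id.
#' @param a discrimination multiplier.
#' @export
inject_misfit <- function(config, item, a) {
  stopifnot(item %in% config$bank$item_id, a > 0)
  config$misfit_injections[[item]] <- a
  config
}

#' Generate a synthetic survey
#'
#' Draws a full response dataset plus the generating truth. Latent traits
#' are normal per group-object-framing cell around the configured means,
#' with a respondent-level shared component; responses come from the
#' partial credit model at the item's true thresholds (after any planted
#' defect); "don't know" thinning is applied missing-completely-at-random
#' at the configured rate (optionally inflated for never smokers under
#' the personal framing); each respondent assesses their administered
#' objects in an independently randomized sequence, with any configured
#' carry-over shift applied from the second position on.
#'
#' @param config `generator_config`.
#' @return list with `data` (a `response_dataset`), and `truth`: list of
#'   `persons` (true latent traits per respondent-object-framing-scale),
#'   `items` (true thresholds and defect labels), `vas` (auxiliary
#'   measures, if configured) and the `config`.
#' @export
generate_survey <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  withr::with_seed(config$seed, generate_survey_impl(config))
}

generate_survey_impl <- function(cf) {
  lv <- survey_levels()
  groups <- names(cf$group_offsets)
  n <- cf$n_per_group * length(groups)
  balanced <- function(values, size) sample(rep_len(values, size))

  resp <- tibble::tibble(
    respondent_id = sprintf("R%05d", seq_len(n)),
    group = rep(groups, each = cf$n_per_group)
  )
  resp <- resp |>
    dplyr::group_by(.data$group) |>
    dplyr::mutate(
      framing = balanced(cf$framings, dplyr::n()),
      age_band = balanced(lv$age_band, dplyr::n()),
      sex = balanced(lv$sex, dplyr::n()),
      education = balanced(lv$education, dplyr::n())
    ) |>
    dplyr::ungroup()

  # administered objects and presentation order per respondent
  seq_list <- lapply(seq_len(n), function(j) {
    obs <- cf$objects
    if (resp$group[j] == "NS" && resp$framing[j] == "P") {
      obs <- setdiff(obs, cf$ns_personal_skip)
    }
    sample(obs)
  })
  plan <- tibble::tibble(
    respondent_id = rep(resp$respondent_id, lengths(seq_list)),
    object = unlist(seq_list),
    position = unlist(lapply(lengths(seq_list), seq_len))
  ) |>
    dplyr::left_join(resp, by = "respondent_id")

  scales <- unique(cf$bank$scale)
  sd_of <- function(s) {
    if (length(cf$person_sd) > 1L) unname(cf$person_sd[[s]]) else
      unname(cf$person_sd[[1]])
  }
  # respondent-level shared latent component per scale
  shared <- sapply(scales, function(s)
    stats::rnorm(n, 0, sd_of(s) * sqrt(cf$person_cor)),
    simplify = FALSE)

  # true item parameters (thresholds = location + offsets)
  items_truth <- cf$bank
  m <- length(cf$threshold_offsets)
  tau_true <- outer(items_truth$location, rep(1, m)) +
    outer(rep(1, nrow(items_truth)), cf$threshold_offsets)
  rownames(tau_true) <- items_truth$item_id
  items_truth$defect <- ifelse(items_truth$item_id %in% names(cf$misfit_injections),
                               "misfit", "none")
  for (inj in cf$dif_injections) {
    items_truth$defect[items_truth$item_id == inj$item] <-
      paste0(inj$kind, "_dif")
  }

  persons_truth <- NULL
  records <- list()
  for (s in scales) {
    mu <- cf$object_means[[s]]
    theta_s <- mu[cbind(match(plan$framing, rownames(mu)),
                        match(plan$object, colnames(mu)))] +
      cf$group_offsets[plan$group] +
      shared[[s]][match(plan$respondent_id, resp$respondent_id)] +
      stats::rnorm(nrow(plan), 0, sd_of(s) * sqrt(1 - cf$person_cor))
    theta_eff <- theta_s + ifelse(plan$position > 1,
                                  cf$carry_over[plan$object], 0)
    persons_truth <- dplyr::bind_rows(persons_truth, dplyr::bind_cols(
      plan[, c("respondent_id", "group", "framing", "object", "position")],
      tibble::tibble(scale = s, theta = theta_s, theta_effective = theta_eff)))

    s_items <- items_truth[items_truth$scale == s, ]
    for (ii in seq_len(nrow(s_items))) {
      it <- s_items$item_id[ii]
      rows <- which(vapply(plan$object,
                           function(o) o %in% s_items$applicable_objects[[ii]],
                           logical(1)))
      if (length(rows) == 0L) next
      tau_i <- tau_true[it, ]
      a_i <- rep(cf$misfit_injections[[it]] %||% 1, length(rows))
      shift <- rep(0, length(rows))
      for (inj in cf$dif_injections) {
        if (inj$item != it) next
        focal <- plan[[inj$factor]][rows] == inj$level
        if (inj$kind == "uniform") shift[focal] <- shift[focal] + inj$value
        else a_i[focal] <- inj$value
      }
      x <- integer(length(rows))
      for (a_val in unique(a_i)) {
        sel <- a_i == a_val
        x[sel] <- pcm_simulate(theta_eff[rows][sel] - shift[sel], tau_i, a = a_val)
      }
      dk_p <- if (length(cf$dk_rate) > 1L) cf$dk_rate[[it]] else cf$dk_rate
      dk_p <- rep(dk_p, length(rows))
      if (cf$dk_mnar) {
        mnar <- plan$group[rows] == "NS" & plan$framing[rows] == "P"
        dk_p[mnar] <- pmin(1, dk_p[mnar] * cf$dk_mnar_multiplier)
      }
      dk <- stats::runif(length(rows)) < dk_p
      records[[paste(s, it)]] <- tibble::tibble(
        respondent_id = plan$respondent_id[rows],
        group = plan$group[rows], age_band = plan$age_band[rows],
        sex = plan$sex[rows], education = plan$education[rows],
        object = plan$object[rows], framing = plan$framing[rows],
        position = plan$position[rows], item_id = it,
        response = ifelse(dk, NA_integer_, x + 1L),
        dont_know = dk
      )
    }
  }
  ds <- dplyr::bind_rows(records) |>
    dplyr::arrange(.data$respondent_id, .data$object, .data$framing,
                   .data$item_id)
  class(ds) <- c("response_dataset", class(ds))
  attr(ds, "read_report") <- list(n_read = nrow(ds), n_kept = nrow(ds),
                                  n_rejected = 0L, rejected_rows = list())

  vas <- NULL
  if (isTRUE(cf$vas)) {
    vas_rows <- list()
    for (s in scales) {
      pt <- persons_truth[persons_truth$scale == s, ]
      zstd <- (pt$theta - mean(pt$theta)) / stats::sd(pt$theta)
      v <- cf$vas_truth_cor * zstd +
        sqrt(1 - cf$vas_truth_cor^2) * stats::rnorm(nrow(pt))
      noise_sd <- sqrt((1 - cf$vas_reliability) / cf$vas_reliability)
      obs <- v + stats::rnorm(nrow(pt), 0, noise_sd)
      vas_rows[[s]] <- dplyr::bind_cols(
        pt[, c("respondent_id", "object", "framing")],
        tibble::tibble(scale = s,
                       vas = pmin(pmax(50 + 15 * obs, 0), 100)))
    }
    vas <- dplyr::bind_rows(vas_rows)
  }

  truth_tau <- stats::setNames(as.data.frame(tau_true),
                               paste0("tau", seq_len(m)))
  list(
    data = ds,
    truth = list(
      persons = persons_truth,
      items = dplyr::bind_cols(
        items_truth[, c("item_id", "scale", "label", "location", "defect")],
        tibble::as_tibble(truth_tau)),
      vas = vas,
      config = cf
    )
  )
}
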