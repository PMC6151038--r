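#' Default item bank for the perceived-risk instrument
#'
#' Returns the item specifications of the two final scales: an 18-item
#' Perceived Health Risk scale applicable to every assessment object, and a
#' 7-item Perceived Addiction Risk scale with object-dependent applicability
#' (4 items administered for Cessation, 6 for all other objects, 3 of the 7
#' applicable everywhere). Item locations (in logits, sum-to-zero within
#' scale) and their published standard errors serve as generator defaults.
#'
#' All items use a 5-category rating ("no risk" ... "very high risk"),
#' coded 1..5 in files and 0..4 internally.
#'
#' @param recenter logical; if `TRUE` (default) locations are recentred to
#'   sum exactly to zero within each scale (the printed values carry
#'   rounding drift of ~0.01 logits).
#' @return A tibble with columns `item_id`, `scale` ("health"/"addiction"),
#'   `label`, `location`, `se_location`, `n_categories`, and
#'   `applicable_objects` (list column of object codes).
#' @export
pri_item_bank <- function(recenter = TRUE) {
  all_obj <- c("CC", "THS", "ECIG", "NRT", "CESS")
  no_cess <- c("CC", "THS", "ECIG", "NRT")
  health <- tibble::tribble(
    ~item_id, ~label, ~location, ~se_location,
    "H01", "Cough lasting for days",  0.150, 0.021,
    "H02", "Gum health",              0.035, 0.022,
    "H03", "Lung cancer",            -0.477, 0.021,
    "H04", "Wheezing",               -0.193, 0.021,
    "H05", "Mouth throat cancer",    -0.058, 0.022,
    "H06", "Aging faster",           -0.015, 0.021,
    "H07", "Minor illnesses",         0.176, 0.022,
    "H08", "Respiratory infection",  -0.051, 0.022,
    "H09", "Serious illness",         0.049, 0.022,
    "H10", "Reduced stamina",         0.135, 0.022,
    "H11", "Emphysema",              -0.132, 0.021,
    "H12", "Cough in the morning",    0.045, 0.021,
    "H13", "Sense of taste",         -0.288, 0.022,
    "H14", "Heart disease",          -0.147, 0.021,
    "H15", "Earlier death",           0.426, 0.022,
    "H16", "Sores mouth throat",      0.319, 0.022,
    "H17", "Unfit",                   0.001, 0.022,
    "H18", "Other cancer",            0.150, 0.021
  )
  health$scale <- "health"
  health$applicable_objects <- rep(list(all_obj), nrow(health))

  # Applicability convention for the addiction scale: one item (A07) is
  # Cessation-only; three items carry past-tense wording and are kept for
  # Cessation as well; the remaining three are administered for every
  # object except Cessation. This yields the 4-item Cessation form and the
  # 6-item form for all other objects.
  addiction <- tibble::tribble(
    ~item_id, ~label, ~location, ~se_location, ~applicable_objects,
    "A01", "Being unable quit",             0.428, 0.028, list(no_cess),
    "A02", "Feeling addicted",             -0.133, 0.025, list(all_obj),
    "A03", "To feel better",                0.311, 0.026, list(no_cess),
    "A04", "Feeling like have to smoke",    0.105, 0.026, list(no_cess),
    "A05", "Cannot stop",                   0.230, 0.028, list(all_obj),
    "A06", "Feeling unable quit",           0.097, 0.028, list(all_obj),
    "A07", "Anxiety situation people smoke", -1.038, 0.054, list("CESS")
  )
  addiction$scale <- "addiction"
  addiction$applicable_objects <- lapply(addiction$applicable_objects, `[[`, 1)

  bank <- dplyr::bind_rows(health, addiction)
  bank$n_categories <- 5L
  if (recenter) {
    bank <- bank |>
      dplyr::group_by(.data$scale) |>
      dplyr::mutate(location = .data$location - mean(.data$location)) |>
      dplyr::ungroup()
  }
  bank[, c("item_id", "scale", "label", "location", "se_location",
           "n_categories", "applicable_objects")]
}

#' Items of a scale applicable to an assessment object
#'
#' @param bank item bank tibble (as from [pri_item_bank()]).
#' @param scale `"health"` or `"addiction"`.
#' @param object single object code, or `NULL` for the union over objects.
#' @return The subset of `bank`, in bank order.
#' @export
applicable_items <- function(bank, scale, object = NULL) {
  sub <- bank[bank$scale == scale, ]
  if (!is.null(object)) {
    keep <- vapply(sub$applicable_objects, function(x) object %in% x, logical(1))
    sub <- sub[keep, ]
  }
  if (nrow(sub) == 0L) {
    stop("no items of scale '", scale, "' are applicable to object '",
         object, "'", call. = FALSE)
  }
  sub
}

#' Recognized factor levels of the survey design
#' @keywords internal
survey_levels <- function() {
  list(
    group   = c("CS_NIQ", "CS_IQ", "FS", "NS"),
    object  = c("CC", "THS", "ECIG", "NRT", "CESS"),
    framing = c("P", "G"),
    age_band = c("18-30", "31-45", "46+"),
    sex = c("M", "F"),
    education = c("HS_or_less", "some_college_plus")
  )
}
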