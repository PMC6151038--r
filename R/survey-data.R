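#' Read survey responses from CSV
#'
#' Reads a long-format (canonical) or wide-format response file into a
#' validated response dataset. Ratings are kept on the external 1..5 coding;
#' the literal token `"DK"` marks a "don't know" response and an empty cell
#' a missing response. Rows with a malformed rating are rejected
#' record-by-record and listed in the attached read report; an unknown
#' object, framing or group code is a fatal error.
#'
#' Long format columns: `respondent_id, group, age_band, sex, education,
#' object, framing, position, item_id, response`. Wide format: one row per
#' respondent-object-framing with metadata columns plus one column per
#' item id (and optionally `position`).
#'
#' @param path path to a CSV file (RFC-4180, UTF-8, header row).
#' @param format `"long"` (default) or `"wide"`.
#' @param bank item bank used to validate item ids and applicability;
#'   defaults to [pri_item_bank()].
#' @return A tibble of class `response_dataset` with the long-format
#'   columns above (`response` integer, `NA` for missing, and a logical
#'   `dont_know` column). Attribute `read_report` holds counts of rejected
#'   rows with reasons.
#' @export
read_responses <- function(path, format = c("long", "wide"),
                           bank = pri_item_bank()) {
  format <- match.arg(format)
  stopifnot(file.exists(path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (format == "wide") raw <- wide_to_long(raw, bank)
  validate_responses(raw, bank)
}

wide_to_long <- function(raw, bank) {
  meta_cols <- intersect(
    c("respondent_id", "group", "age_band", "sex", "education",
      "object", "framing", "position"), names(raw))
  item_cols <- intersect(bank$item_id, names(raw))
  if (length(item_cols) == 0L) {
    stop("wide file contains no recognized item columns", call. = FALSE)
  }
  tidyr::pivot_longer(raw, cols = dplyr::all_of(item_cols),
                      names_to = "item_id", values_to = "response")
}

validate_responses <- function(raw, bank) {
  needed <- c("respondent_id", "object", "framing", "item_id", "response")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0L) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (opt in c("group", "age_band", "sex", "education", "position")) {
    if (!opt %in% names(raw)) raw[[opt]] <- NA_character_
  }
  lv <- survey_levels()
  bad_obj <- setdiff(unique(raw$object), lv$object)
  if (length(bad_obj) > 0L) {
    stop("unknown object code(s): ", paste(bad_obj, collapse = ", "), call. = FALSE)
  }
  bad_fr <- setdiff(unique(raw$framing), lv$framing)
  if (length(bad_fr) > 0L) {
    stop("unknown framing code(s): ", paste(bad_fr, collapse = ", "), call. = FALSE)
  }
  bad_grp <- setdiff(setdiff(unique(raw$group), NA), lv$group)
  if (length(bad_grp) > 0L) {
    stop("unknown group code(s): ", paste(bad_grp, collapse = ", "), call. = FALSE)
  }

  n0 <- nrow(raw)
  raw$.row <- seq_len(n0)
  rejects <- list()

  unknown_item <- !raw$item_id %in% bank$item_id
  if (any(unknown_item)) {
    rejects$unknown_item <- raw$.row[unknown_item]
    raw <- raw[!unknown_item, ]
  }

  resp <- trimws(raw$response)
  dk <- !is.na(resp) & toupper(resp) == "DK"
  miss <- is.na(resp) | resp == ""
  num <- suppressWarnings(as.integer(resp))
  valid_num <- !dk & !miss & !is.na(num) & num >= 1L & num <= 5L &
    resp == as.character(num)
  bad <- !dk & !miss & !valid_num
  if (any(bad)) {
    rejects$malformed_rating <- raw$.row[bad]
    raw <- raw[!bad, ]
    dk <- dk[!bad]; miss <- miss[!bad]; num <- num[!bad]; valid_num <- valid_num[!bad]
  }

  # applicability: an item recorded for an object must be applicable there
  app <- stats::setNames(bank$applicable_objects, bank$item_id)
  ok_app <- mapply(function(it, ob) ob %in% app[[it]], raw$item_id, raw$object)
  if (any(!ok_app)) {
    rejects$not_applicable <- raw$.row[!ok_app]
    raw <- raw[ok_app, ]
    dk <- dk[ok_app]; num <- num[ok_app]
  }

  key <- paste(raw$respondent_id, raw$object, raw$framing, raw$item_id)
  dup <- duplicated(key)
  if (any(dup)) {
    rejects$duplicate_record <- raw$.row[dup]
    raw <- raw[!dup, ]
    dk <- dk[!dup]; num <- num[!dup]
  }

  out <- tibble::tibble(
    respondent_id = raw$respondent_id,
    group = raw$group, age_band = raw$age_band, sex = raw$sex,
    education = raw$education,
    object = raw$object, framing = raw$framing,
    position = suppressWarnings(as.integer(raw$position)),
    item_id = raw$item_id,
    response = ifelse(dk, NA_integer_, num),
    dont_know = dk
  )
  report <- list(
    n_read = n0, n_kept = nrow(out),
    n_rejected = n0 - nrow(out),
    rejected_rows = rejects
  )
  structure(out, read_report = report,
            class = c("response_dataset", class(out)))
}

#' Build a response dataset from an in-memory long tibble
#'
#' Applies the same validation as [read_responses()].
#' @param df long-format tibble (columns as in [read_responses()]).
#' @param bank item bank.
#' @export
as_response_dataset <- function(df, bank = pri_item_bank()) {
  df <- dplyr::mutate(df, dplyr::across(dplyr::everything(), as.character))
  validate_responses(df, bank)
}

#' Write a response dataset to long CSV
#'
#' Inverse of [read_responses()]: ratings written as 1..5, don't-know as
#' the token `"DK"`, missing as an empty cell.
#' @param ds response dataset.
#' @param path output path.
#' @export
write_responses <- function(ds, path) {
  out <- ds
  out$response <- ifelse(out$dont_know, "DK",
                         ifelse(is.na(out$response), "", as.character(out$response)))
  out$dont_know <- NULL
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read report of a response dataset
#' @param ds response dataset.
#' @export
read_report <- function(ds) attr(ds, "read_report")

#' Select responses into a persons-by-items analysis matrix
#'
#' Restricts a response dataset to one scale and to the requested objects
#' and framings, keeps only items applicable to each record's object, and
#' returns an integer matrix on the internal 0..4 coding with one row per
#' respondent-object-framing. Don't-know responses are converted to
#' missing for all model-based computation but tallied separately; rows
#' with all items missing are dropped and counted.
#'
#' @param ds response dataset.
#' @param scale `"health"` or `"addiction"`.
#' @param object object code(s) to include; `NULL` for all.
#' @param framing framing code(s) to include; `NULL` for all.
#' @param bank item bank.
#' @return An object of class `analysis_matrix`: list with `scores`
#'   (integer matrix, `NA` = missing), `meta` (row metadata tibble),
#'   `items` (item tibble with `max_score`), `dk_prop` and `miss_prop`
#'   (per-item proportions among administered responses), and
#'   `n_dropped_rows`.
#' @export
to_analysis_matrix <- function(ds, scale, object = NULL, framing = NULL,
                               bank = pri_item_bank()) {
  sel <- ds[ds$item_id %in% bank$item_id[bank$scale == scale], ]
  if (!is.null(object))  sel <- sel[sel$object %in% object, ]
  if (!is.null(framing)) sel <- sel[sel$framing %in% framing, ]
  if (nrow(sel) == 0L) {
    stop("empty selection: scale=", scale,
         " object=", paste(object %||% "all", collapse = "/"),
         " framing=", paste(framing %||% "all", collapse = "/"), call. = FALSE)
  }
  items <- if (!is.null(object) && length(object) == 1L) {
    applicable_items(bank, scale, object)
  } else {
    bank[bank$scale == scale, ]
  }
  items <- items[items$item_id %in% unique(sel$item_id), ]

  sel$.rowkey <- paste(sel$respondent_id, sel$object, sel$framing, sep = "\r")
  rowkeys <- unique(sel$.rowkey)
  ri <- match(sel$.rowkey, rowkeys)
  ci <- match(sel$item_id, items$item_id)
  keep <- !is.na(ci)
  scores <- matrix(NA_integer_, nrow = length(rowkeys), ncol = nrow(items),
                   dimnames = list(NULL, items$item_id))
  scores[cbind(ri[keep], ci[keep])] <- sel$response[keep] - 1L
  dkmat <- matrix(FALSE, nrow = length(rowkeys), ncol = nrow(items))
  dkmat[cbind(ri[keep], ci[keep])] <- sel$dont_know[keep]
  administered <- matrix(FALSE, nrow = length(rowkeys), ncol = nrow(items))
  administered[cbind(ri[keep], ci[keep])] <- TRUE

  first <- !duplicated(sel$.rowkey)
  meta <- tibble::tibble(
    respondent_id = sel$respondent_id[first],
    group = sel$group[first], age_band = sel$age_band[first],
    sex = sel$sex[first], education = sel$education[first],
    object = sel$object[first], framing = sel$framing[first],
    position = sel$position[first]
  )[match(rowkeys, sel$.rowkey[first]), ]

  all_missing <- rowSums(!is.na(scores)) == 0L
  n_dropped <- sum(all_missing)
  if (n_dropped > 0L) {
    scores <- scores[!all_missing, , drop = FALSE]
    dkmat <- dkmat[!all_missing, , drop = FALSE]
    administered <- administered[!all_missing, , drop = FALSE]
    meta <- meta[!all_missing, ]
  }

  n_adm <- colSums(administered)
  dk_prop <- ifelse(n_adm > 0, colSums(dkmat) / n_adm, NA_real_)
  miss_prop <- ifelse(n_adm > 0,
                      colSums(is.na(scores) & administered & !dkmat) / n_adm,
                      NA_real_)
  structure(list(
    scores = scores, meta = meta,
    items = dplyr::mutate(items, max_score = .data$n_categories - 1L),
    dk_prop = stats::setNames(dk_prop, items$item_id),
    miss_prop = stats::setNames(miss_prop, items$item_id),
    n_dropped_rows = n_dropped
  ), class = "analysis_matrix")
}

#' @export
print.analysis_matrix <- function(x, ...) {
  cat("<analysis_matrix> ", nrow(x$scores), " rows x ", ncol(x$scores),
      " items (", x$n_dropped_rows, " all-missing rows dropped)\n", sep = "")
  invisible(x)
}

#' Per-item missing-data and don't-know summary
#'
#' Percentages are computed among administered responses; items with
#' missing (don't-know excluded) at or above 10% are flagged, following
#' the "item-level missing data should be < 10%" data-quality rule.
#'
#' @param am analysis matrix.
#' @return tibble with `item_id`, `missing_pct`, `dk_pct`, `valid_pct`,
#'   `flag_missing`.
#' @export
missing_summary <- function(am) {
  stopifnot(nrow(am$scores) > 0L)
  tibble::tibble(
    item_id = colnames(am$scores),
    missing_pct = unname(100 * am$miss_prop),
    dk_pct = unname(100 * am$dk_prop),
    valid_pct = unname(100 * (1 - am$miss_prop - am$dk_prop)),
    flag_missing = unname(100 * am$miss_prop >= 10)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
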