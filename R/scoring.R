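#' Raw-score to measure conversion table
#'
#' For a complete-data administration of a fixed item set, raw-score
#' sufficiency makes the latent measure a function of the raw score only.
#' The table gives, for every raw score 0..sum(m_i), the WLE measure
#' solving the weighted score equation (finite at the extremes thanks to
#' Warm's correction), its standard error from the test information, and
#' a linear 0-100 scaled score: s = 50 + 50 * theta / Theta with
#' Theta = max(|extreme measures|), so a measure of 0 (the calibration
#' mean) maps to 50 and the longer extreme reaches its bound exactly.
#' When the two extreme measures are asymmetric about zero the shorter
#' tail does not reach its bound; this is flagged in the table metadata.
#'
#' @param fit `pcm_fit` or threshold matrix of the administered item set.
#' @return tibble of class `conversion_table` with `raw_score`, `logit`,
#'   `se`, `score_0_100`; attributes `theta_scale` (Theta) and
#'   `symmetric`.
#' @export
build_conversion_table <- function(fit) {
  tau <- thresholds(fit)
  M <- nrow(tau) * ncol(tau)
  theta <- vapply(0:M, solve_score_equation, numeric(1), tau = tau, wle = TRUE)
  if (any(diff(theta) <= 0)) {
    stop("non-monotonic measures across raw scores: solver failure", call. = FALSE)
  }
  info <- test_information(theta, tau)
  se <- 1 / sqrt(info)
  Theta <- max(abs(theta[1]), abs(theta[length(theta)]))
  s <- pmin(pmax(50 + 50 * theta / Theta, 0), 100)
  out <- tibble::tibble(raw_score = 0:M, logit = theta, se = se,
                        score_0_100 = s)
  attr(out, "theta_scale") <- Theta
  attr(out, "symmetric") <- isTRUE(all.equal(abs(theta[1]),
                                             abs(theta[length(theta)]),
                                             tolerance = 1e-6))
  class(out) <- c("conversion_table", class(out))
  out
}

#' Map a logit measure to the 0-100 scaled metric of a conversion table
#'
#' The linear transform s = 50 + 50 * theta / Theta of the table,
#' clamped to \[0, 100\].
#'
#' @param theta logit measure(s).
#' @param table a `conversion_table`.
#' @return scaled score(s).
#' @export
logit_to_0_100 <- function(theta, table) {
  Theta <- attr(table, "theta_scale")
  pmin(pmax(50 + 50 * theta / Theta, 0), 100)
}

#' Serialize a conversion table to CSV
#' @param table `conversion_table`.
#' @param path output path.
#' @export
write_conversion_table <- function(table, path) {
  readr::write_csv(tibble::as_tibble(table), path, progress = FALSE)
  invisible(path)
}
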