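#' Partial credit model category probabilities
#'
#' For a person at `theta` and an item with thresholds `tau` (length m),
#' the probability of category x in 0..m is proportional to
#' exp(sum_{k<=x} (theta - tau_k)), with the empty sum equal to 0.
#' A threshold marks the latent location where two adjacent categories are
#' equally probable; thresholds need not be ordered.
#'
#' @param theta numeric vector of person locations (logits).
#' @param tau numeric vector of item thresholds (logits).
#' @param a discrimination multiplier applied to the cumulative logits
#'   (default 1 = the Rasch case; values other than 1 are used only by the
#'   generator to plant misfitting items).
#' @return matrix `length(theta)` x `(m+1)` of probabilities; rows sum to 1.
#' @export
pcm_category_probs <- function(theta, tau, a = 1) {
  stopifnot(all(is.finite(tau)))
  m <- length(tau)
  # cumulative logit for category x: x*theta - sum(tau[1:x])
  cs <- c(0, cumsum(tau))
  eta <- a * (outer(theta, 0:m) - matrix(cs, length(theta), m + 1L, byrow = TRUE))
  mx <- eta[, 1L]
  for (j in seq_len(m)) mx <- pmax(mx, eta[, j + 1L])
  w <- exp(eta - mx)
  w / rowSums(w)
}

#' Expected score, variance and higher central moments under the PCM
#'
#' @param theta person locations.
#' @param tau thresholds.
#' @param a discrimination multiplier (generator use only).
#' @return `pcm_expected_score()` returns E[X|theta]; `pcm_moments()` a
#'   list with `e` (mean), `v` (variance), `mu3`, `mu4` (third and fourth
#'   central moments), each a vector over `theta`.
#' @export
pcm_expected_score <- function(theta, tau, a = 1) {
  p <- pcm_category_probs(theta, tau, a)
  drop(p %*% (0:length(tau)))
}

#' @rdname pcm_expected_score
#' @export
pcm_moments <- function(theta, tau, a = 1) {
  p <- pcm_category_probs(theta, tau, a)
  x <- 0:length(tau)
  e <- drop(p %*% x)
  d1 <- outer(e, x, function(ee, xx) xx - ee)
  list(
    e = e,
    v = rowSums(p * d1^2),
    mu3 = rowSums(p * d1^3),
    mu4 = rowSums(p * d1^4)
  )
}

#' Draw PCM responses
#'
#' @param theta person locations (one response per element).
#' @param tau thresholds.
#' @param a discrimination multiplier.
#' @return integer vector of categories 0..m.
#' @export
pcm_simulate <- function(theta, tau, a = 1) {
  p <- pcm_category_probs(theta, tau, a)
  cp <- t(apply(p, 1L, cumsum))
  u <- stats::runif(length(theta))
  as.integer(rowSums(u > cp[, -ncol(cp), drop = FALSE]))
}

# P(X >= k), k = 1..m, per theta: needed by calibration derivatives
pcm_tail_probs <- function(theta, tau) {
  p <- pcm_category_probs(theta, tau)
  m <- length(tau)
  tp <- matrix(0, nrow(p), m)
  tp[, m] <- p[, m + 1L]
  if (m > 1L) for (k in (m - 1L):1L) tp[, k] <- tp[, k + 1L] + p[, k + 1L]
  tp
}
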