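# Shared fixtures: small instruments and simulated response matrices.

# threshold matrix: locations + symmetric step offsets
make_tau <- function(locations, offsets = c(-3.5, -3.5 / 3, 3.5 / 3, 3.5)) {
  tau <- outer(locations, rep(1, length(offsets))) +
    outer(rep(1, length(locations)), offsets)
  rownames(tau) <- sprintf("T%02d", seq_along(locations))
  tau
}

# default-style 18-item health-like truth, centred
health_tau <- function() {
  loc <- seq(-0.45, 0.45, length.out = 18)
  make_tau(loc - mean(loc))
}

# simulate a persons-by-items PCM matrix at given true thetas
sim_pcm_matrix <- function(theta, tau, a = NULL) {
  X <- sapply(seq_len(nrow(tau)), function(i)
    pcm_simulate(theta, tau[i, ], a = if (is.null(a)) 1 else a[i]))
  colnames(X) <- rownames(tau)
  X
}

# wrap a plain matrix as an analysis_matrix with metadata for DIF tests
as_am <- function(X, meta = NULL) {
  n <- nrow(X)
  if (is.null(meta)) {
    meta <- tibble::tibble(
      respondent_id = sprintf("R%05d", seq_len(n)),
      group = NA_character_, age_band = NA_character_, sex = NA_character_,
      education = NA_character_, object = "CC", framing = "P",
      position = 1L)
  }
  structure(list(
    scores = X, meta = meta,
    items = tibble::tibble(item_id = colnames(X), scale = "health",
                           label = colnames(X), n_categories = ncol(X) * 0 + 5L,
                           max_score = apply(X, 2, max, na.rm = TRUE) * 0 + 4L),
    dk_prop = stats::setNames(rep(0, ncol(X)), colnames(X)),
    miss_prop = stats::setNames(colMeans(is.na(X)), colnames(X)),
    n_dropped_rows = 0L
  ), class = "analysis_matrix")
}

# exact raw-score distribution at a fixed theta (independent oracle for
# person-estimator bias checks): convolution of per-item category dists
raw_score_dist <- function(theta, tau) {
  p <- 1
  for (i in seq_len(nrow(tau))) {
    pi <- drop(pcm_category_probs(theta, tau[i, ]))
    new <- numeric(length(p) + length(pi) - 1L)
    for (c in seq_along(pi)) {
      idx <- c:(c + length(p) - 1L)
      new[idx] <- new[idx] + p * pi[c]
    }
    p <- new
  }
  p  # P(raw = 0 .. M)
}

# any complete response pattern with the requested raw score (raw-score
# sufficiency makes the particular pattern irrelevant)
score_pattern <- function(r, I, m = 4L) {
  x <- integer(I)
  for (i in seq_len(I)) {
    take <- min(m, r)
    x[i] <- take
    r <- r - take
  }
  stopifnot(r == 0L)
  x
}

# tiny long-format response tibble for IO tests
small_long_df <- function() {
  tibble::tibble(
    respondent_id = rep(c("r1", "r2", "r3"), each = 2),
    group = "FS", age_band = "18-30", sex = "F", education = "HS_or_less",
    object = "CC", framing = "P", position = 1L,
    item_id = rep(c("H01", "H02"), 3),
    response = c("1", "5", "3", "2", "4", "1")
  )
}
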