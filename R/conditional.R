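# Conditional response moments given the raw score.
#
# For the Rasch family the distribution of a response vector conditional
# on its raw score is free of the person parameter:
#   P(x_i = c | r) = eps_i(c) * gamma_{-i}(r - c) / gamma(r),
# with eps_i(c) = exp(-sum_{k<=c} tau_ik) and gamma the convolution of
# the eps vectors over the administered items (the elementary
# symmetric-function recursion). These moments standardize residual
# statistics without the bias incurred by evaluating expectations at an
# estimated person location. Persons with extreme raw scores have a
# degenerate conditional distribution (variance 0) and drop out of the
# conditional statistics naturally.

# shift-add polynomial product; a, b coefficient vectors (degree 0..)
conv_poly <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (j in seq_along(b)) {
    if (b[j] != 0) {
      idx <- j:(j + length(a) - 1L)
      out[idx] <- out[idx] + a * b[j]
    }
  }
  out
}

# Conditional mean, variance and fourth central moment of each observed
# response given the person's observed item set and raw score.
# X: n x I matrix (0..m, NA missing); tau: I x m thresholds.
pcm_conditional_moments <- function(X, tau) {
  n <- nrow(X); I <- ncol(X); m <- ncol(tau)
  E <- V <- K4 <- matrix(NA_real_, n, I, dimnames = dimnames(X))
  # conditional tail probabilities P(X_i >= k | r) and cross moments
  # E[X_i 1(X_i >= k) | r]: the sensitivities of the conditional moments
  # to the estimated thresholds
  TT <- XT <- array(NA_real_, c(n, I, m))
  obs <- !is.na(X)
  mask_key <- apply(obs, 1L, function(o) paste(which(o), collapse = ","))
  raw <- rowSums(X, na.rm = TRUE)

  # log-scaled eps vectors per item (category weights at theta = 0)
  eps <- lapply(seq_len(I), function(i) {
    le <- -c(0, cumsum(tau[i, ]))
    s <- max(le)
    list(v = exp(le - s), ls = s)
  })

  for (key in unique(mask_key)) {
    rows <- which(mask_key == key)
    S <- which(obs[rows[1], ])
    nS <- length(S)
    if (nS == 0L) next
    # prefix/suffix convolutions with log-scale bookkeeping
    pre <- vector("list", nS + 1L); pre_ls <- numeric(nS + 1L)
    pre[[1]] <- 1
    for (j in seq_len(nS)) {
      v <- conv_poly(pre[[j]], eps[[S[j]]]$v)
      s <- max(v)
      pre[[j + 1L]] <- v / s
      pre_ls[j + 1L] <- pre_ls[j] + eps[[S[j]]]$ls + log(s)
    }
    suf <- vector("list", nS + 1L); suf_ls <- numeric(nS + 1L)
    suf[[nS + 1L]] <- 1
    for (j in nS:1L) {
      v <- conv_poly(suf[[j + 1L]], eps[[S[j]]]$v)
      s <- max(v)
      suf[[j]] <- v / s
      suf_ls[j] <- suf_ls[j + 1L] + eps[[S[j]]]$ls + log(s)
    }
    gam <- pre[[nS + 1L]]; gam_ls <- pre_ls[nS + 1L]
    r_idx <- raw[rows] + 1L                     # gamma index of each raw score

    for (j in seq_len(nS)) {
      i <- S[j]
      gmi <- conv_poly(pre[[j]], suf[[j + 1L]])
      gmi_ls <- pre_ls[j] + suf_ls[j + 1L]
      # P(c | r) over c = 0..m for each person in this mask
      ev <- eps[[i]]$v
      P <- matrix(0, length(rows), m + 1L)
      for (c in 0:m) {
        pos <- r_idx - c
        okc <- pos >= 1L & pos <= length(gmi)
        P[okc, c + 1L] <- ev[c + 1L] * gmi[pos[okc]]
      }
      # common factors (eps_i log-scale, gamma denominator) cancel row-wise
      rs <- rowSums(P)
      P <- P / rs
      x_cat <- 0:m
      e <- drop(P %*% x_cat)
      d <- outer(e, x_cat, function(ee, xx) xx - ee)
      E[rows, i] <- e
      V[rows, i] <- rowSums(P * d^2)
      K4[rows, i] <- rowSums(P * d^4)
      for (k in seq_len(m)) {
        sel <- (k + 1L):(m + 1L)
        TT[rows, i, k] <- rowSums(P[, sel, drop = FALSE])
        XT[rows, i, k] <- drop(P[, sel, drop = FALSE] %*% x_cat[sel])
      }
    }
  }
  list(e = E, v = V, mu4 = K4, tail = TT, xtail = XT)
}
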