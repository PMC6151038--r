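test_that("standardized residuals follow the Bernoulli mean/variance formula", {
  # dichotomous item, P(1) = 0.75 at theta = log 3, observed x = 1
  tau <- matrix(0, 1, 1)
  persons <- tibble::tibble(theta = log(3), se = 1)
  rt <- standardized_residuals(matrix(1L, 1, 1), tau, persons, G = 1)
  expect_equal(unname(rt$z[1, 1]), 0.25 / sqrt(0.1875), tolerance = 1e-10)
})

test_that("class intervals are near-equal-sized and per-item residual means are small", {
  set.seed(301)
  tau <- health_tau()[1:10, ]
  X <- sim_pcm_matrix(rnorm(503, 0, 2.9), tau)
  rt <- standardized_residuals(X, tau, G = 10)
  sizes <- table(rt$class_interval)
  expect_lte(diff(range(sizes)), 1)
  expect_true(all(abs(colMeans(rt$z, na.rm = TRUE)) < 3 / sqrt(503)))
  expect_error(standardized_residuals(X[1:5, ], tau, G = 10), "class intervals")
})

test_that("item-trait chi-square: df = G - 1 and the large-n adjustment scales the statistic", {
  set.seed(302)
  tau <- health_tau()[1:6, ]
  X <- sim_pcm_matrix(rnorm(2000, 0, 2.9), tau)
  rt <- standardized_residuals(X, tau, G = 10)
  raw <- item_trait_chi_square(rt, n_adjust = NULL)
  adj <- item_trait_chi_square(rt, n_adjust = 500)
  expect_true(all(raw$df == 9L))
  expect_equal(adj$chi_square_adj, adj$chi_square * 500 / 2000, tolerance = 1e-12)
  expect_equal(raw$chi_square, adj$chi_square)
  expect_equal(adj$p_value,
               pchisq(adj$chi_square_adj, adj$df, lower.tail = FALSE))
  # no scaling at n <= n_adjust
  rt500 <- standardized_residuals(X[1:500, ], tau, G = 10)
  a500 <- item_trait_chi_square(rt500, n_adjust = 500)
  expect_equal(a500$chi_square_adj, a500$chi_square)
})

test_that("threshold ordering is classified strictly", {
  tau <- rbind(c(-1, 0, 1), c(0, -0.5, 1))
  ord <- threshold_order_check(tau)
  expect_equal(ord$ordered, c(TRUE, FALSE))
})

test_that("targeting coverage counts persons inside the threshold span", {
  persons <- tibble::tibble(theta = c(-1, 0, 1))
  tau <- matrix(c(-0.5, 2), 1)
  expect_equal(targeting_coverage(persons, tau), 100 * 2 / 3, tolerance = 1e-10)
  tau2 <- matrix(c(-2, 2), 1)
  expect_equal(targeting_coverage(persons, tau2), 100)
  # invariance under common translation
  expect_equal(targeting_coverage(tibble::tibble(theta = persons$theta + 5),
                                  tau + 5),
               targeting_coverage(persons, tau))
})

test_that("residual correlations: duplicates are flagged, independence gives negative mean", {
  set.seed(303)
  tau <- health_tau()[1:8, ]
  X <- sim_pcm_matrix(rnorm(600, 0, 2.9), tau)
  Xdup <- cbind(X, dup = X[, 1])
  taud <- rbind(tau, dup = tau[1, ])
  rt <- standardized_residuals(Xdup, taud, G = 10)
  rc <- residual_correlation_flags(rt)
  pair <- rc$pairs[rc$pairs$item_a == "T01" & rc$pairs$item_b == "dup", ]
  expect_gt(pair$r, 0.8)
  expect_true(pair$flag_abs && pair$flag_mean)

  # locally independent items: mean pairwise residual correlation is
  # negative (~ -1/(L-1)), so the mean+0.3 critical value sits below 0.3
  rt0 <- standardized_residuals(X, tau, G = 10)
  rc0 <- residual_correlation_flags(rt0)
  expect_lt(rc0$mean_r, 0)
  expect_lt(rc0$critical_mean, 0.3)
  expect_equal(sum(rc0$pairs$flag_mean), 0)
})

test_that("fit residuals are calibrated on fitting data and signed by discrimination", {
  set.seed(304)
  tau <- health_tau()
  theta <- rnorm(500, 0, 2.9)
  X <- sim_pcm_matrix(theta, tau)
  fit <- calibrate_items(X)
  rt <- standardized_residuals(X, fit)
  fr <- item_fit_residual(rt)
  expect_gte(mean(abs(fr$fit_residual) <= 2.5), 0.9)

  # under-discrimination (a = 0.4) -> large positive fit residual;
  # over-discrimination (a = 2) -> negative
  a <- rep(1, 18); a[5] <- 0.4
  Xu <- sim_pcm_matrix(theta, tau, a = a)
  fru <- item_fit_residual(standardized_residuals(Xu, calibrate_items(Xu)))
  expect_gt(fru$fit_residual[5], 2.5)
  a[5] <- 2
  Xo <- sim_pcm_matrix(theta, tau, a = a)
  fro <- item_fit_residual(standardized_residuals(Xo, calibrate_items(Xo)))
  expect_lt(fro$fit_residual[5], -2.5)
})

test_that("fit_report assembles item table and scale summary coherently", {
  set.seed(305)
  sim <- generate_survey(generator_config(n_per_group = 60, objects = "CC",
                                          seed = 305, vas = FALSE))
  am <- to_analysis_matrix(sim$data, "health", object = "CC")
  fit <- calibrate_items(am)
  rep <- fit_report(am, fit)
  expect_equal(nrow(rep$item_table), 18)
  expect_true(all(c("fit_residual", "chi_square", "p_value", "ordered")
                  %in% names(rep$item_table)))
  s <- rep$scale_summary
  expect_equal(s$n_items, 18)
  expect_true(s$coverage_pct >= 0 && s$coverage_pct <= 100)
  expect_true(s$psi >= 0 && s$psi <= 1)
})
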