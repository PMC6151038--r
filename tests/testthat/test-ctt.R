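test_that("Cronbach's alpha matches closed forms", {
  set.seed(501)
  # exchangeable correlation 0.87, equal variances: standardized alpha
  # k r / (1 + (k-1) r) = 0.979 for k = 7
  n <- 20000; k <- 7; r <- 0.87
  f <- rnorm(n)
  Y <- sapply(1:k, function(i) sqrt(r) * f + sqrt(1 - r) * rnorm(n))
  expect_equal(cronbach_alpha(Y), k * r / (1 + (k - 1) * r), tolerance = 0.01)

  # uncorrelated items -> alpha near zero
  Y0 <- matrix(rnorm(2 * 20000), ncol = 2)
  expect_lt(abs(cronbach_alpha(Y0)), 0.05)

  # k = 2 with equal variances: alpha equals the Spearman-Brown step-up
  a <- rnorm(500); b <- 0.6 * a + rnorm(500)
  a <- a / sd(a); b <- b / sd(b)
  r12 <- cor(a, b)
  expect_equal(cronbach_alpha(cbind(a, b)), 2 * r12 / (1 + r12),
               tolerance = 1e-10)

  # invariant under adding a constant to any item
  expect_equal(cronbach_alpha(cbind(a + 10, b)), cronbach_alpha(cbind(a, b)),
               tolerance = 1e-10)
  expect_true(is.na(cronbach_alpha(cbind(rep(1, 5), rep(2, 5)))))
})

test_that("skewness follows the adjusted Fisher-Pearson convention", {
  expect_equal(skewness_adj(1:5), 0)
  expect_gt(skewness_adj(c(1, 1, 1, 5)), 0)
  set.seed(502)
  expect_lt(abs(skewness_adj(rnorm(50000))), 0.1)
  expect_true(is.na(skewness_adj(rep(3, 10))))
  # hand-computed g1 * sqrt(n(n-1))/(n-2) for a small vector
  x <- c(2, 4, 7, 11)
  n <- 4; g1 <- mean((x - mean(x))^3) / (mean((x - mean(x))^2))^1.5
  expect_equal(skewness_adj(x), g1 * sqrt(n * (n - 1)) / (n - 2),
               tolerance = 1e-12)
})

test_that("CTT report: score ranges, floor/ceiling and CITC behave as defined", {
  set.seed(503)
  sim <- generate_survey(generator_config(n_per_group = 80, objects = "CC",
                                          seed = 503, vas = FALSE))
  am_h <- to_analysis_matrix(sim$data, "health", object = "CC")
  rep_h <- ctt_report(am_h)
  expect_equal(rep_h$scale_summary$theoretical_min, 18)
  expect_equal(rep_h$scale_summary$theoretical_max, 90)
  am_a <- to_analysis_matrix(sim$data, "addiction", object = "CC")
  rep_a <- ctt_report(am_a)
  expect_equal(rep_a$scale_summary$theoretical_min, 6)
  expect_equal(rep_a$scale_summary$theoretical_max, 30)
  expect_true(all(rep_h$item_table$citc >= -1 & rep_h$item_table$citc <= 1))
  expect_lte(rep_h$scale_summary$floor_pct + rep_h$scale_summary$ceiling_pct, 100)
  # n of complete-item respondents is reported
  expect_lte(rep_h$scale_summary$n_complete, nrow(am_h$scores))
})

test_that("floor and ceiling percentages are direct counts at the theoretical range", {
  # scores (18, 18, 54, 90) on an 18-item scale: floor 50%, ceiling 25%
  X <- rbind(rep(0L, 18), rep(0L, 18),
             rep(2L, 18), rep(4L, 18))
  colnames(X) <- sprintf("H%02d", 1:18)
  am <- as_am(X)
  s <- ctt_report(am)$scale_summary
  expect_equal(s$floor_pct, 50)
  expect_equal(s$ceiling_pct, 25)
  expect_equal(s$observed_min, 18)
  expect_equal(s$observed_max, 90)
})

test_that("CITC against a two-item scale equals the inter-item correlation", {
  set.seed(504)
  X <- cbind(a = sample(0:4, 300, TRUE), b = sample(0:4, 300, TRUE))
  am <- as_am(X)
  rep2 <- ctt_report(am)
  expect_equal(rep2$item_table$citc[1], cor(X[, 1], X[, 2]), tolerance = 1e-10)
  expect_equal(rep2$item_table$citc[2], rep2$item_table$citc[1],
               tolerance = 1e-10)
})
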