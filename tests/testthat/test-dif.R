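make_dif_data <- function(n_per_grp = 250, delta = 0, item = 5, seed = 1,
                          nonuniform_compress = NULL) {
  set.seed(seed)
  tau <- health_tau()[1:10, ]
  grp <- rep(c("A", "B"), each = n_per_grp)
  theta <- rnorm(2 * n_per_grp, 0, 2.9)
  X <- sim_pcm_matrix(theta, tau)
  foc <- grp == "B"
  if (delta != 0) {
    X[foc, item] <- pcm_simulate(theta[foc], tau[item, ] + delta)
  }
  if (!is.null(nonuniform_compress)) {
    # level-dependent difficulty: focal thresholds compressed about the
    # location, steepening the expected-score curve for that group
    tc <- mean(tau[item, ]) +
      nonuniform_compress * (tau[item, ] - mean(tau[item, ]))
    X[foc, item] <- pcm_simulate(theta[foc], tc)
  }
  meta <- tibble::tibble(
    respondent_id = sprintf("R%04d", seq_along(grp)), group = grp,
    age_band = NA_character_, sex = grp, education = NA_character_,
    object = "CC", framing = "P", position = 1L)
  am <- as_am(X, meta)
  fit <- calibrate_items(am)
  standardized_residuals(am, fit)
}

test_that("a homogeneous random split produces flags at about the type-I level", {
  rt <- make_dif_data(seed = 401)
  d <- dif_anova(rt, "group")
  expect_true(all(d$p_uniform >= 0 & d$p_uniform <= 1))
  expect_lte(sum(d$flag_uniform), 3)           # 10 tests at 5%
  expect_lte(sum(d$flag_nonuniform), 3)
})

test_that("an injected uniform shift is detected as uniform DIF", {
  rt <- make_dif_data(delta = 0.5, seed = 402)
  d <- dif_anova(rt, "group")
  expect_lt(d$p_uniform[5], 0.05)
  expect_true(d$flag_uniform[5])
  # the planted item carries the strongest evidence
  expect_equal(which.max(d$F_uniform), 5L)
})

test_that("level-dependent item difficulty is detected as non-uniform DIF", {
  rt <- make_dif_data(nonuniform_compress = 0.45, seed = 403, n_per_grp = 400)
  d <- dif_anova(rt, "group")
  expect_lt(d$p_nonuniform[5], 0.05)
  expect_true(d$flag_nonuniform[5])
})

test_that("DIF statistics are invariant to factor-level relabeling", {
  rt <- make_dif_data(delta = 0.4, seed = 404)
  f <- rt$meta$group
  d1 <- dif_anova(rt, f)
  d2 <- dif_anova(rt, ifelse(f == "A", "zebra", "aard"))
  expect_equal(d1$F_uniform, d2$F_uniform, tolerance = 1e-10)
  expect_equal(d1$F_nonuniform, d2$F_nonuniform, tolerance = 1e-10)
})

test_that("a shift common to all items is absorbed into the person estimates", {
  set.seed(405)
  tau <- health_tau()[1:10, ]
  grp <- rep(c("A", "B"), each = 250)
  theta <- rnorm(500, 0, 2.9)
  X <- sim_pcm_matrix(theta, tau)
  foc <- grp == "B"
  for (i in 1:10) X[foc, i] <- pcm_simulate(theta[foc], tau[i, ] + 0.5)
  meta <- tibble::tibble(respondent_id = sprintf("R%04d", 1:500), group = grp,
                         age_band = NA, sex = NA, education = NA,
                         object = "CC", framing = "P", position = 1L)
  am <- as_am(X, meta)
  rt <- standardized_residuals(am, calibrate_items(am))
  d <- dif_anova(rt, "group")
  expect_lte(sum(d$flag_uniform), 3)           # group difference, not item bias
})

test_that("small factor levels are dropped and lone levels are not evaluable", {
  rt <- make_dif_data(seed = 406, n_per_grp = 100)
  f <- rt$meta$group
  f[1:5] <- "C"                                # level with < 20 persons
  expect_warning(d <- dif_anova(rt, f), "dropping")
  expect_true(all(!is.na(d$p_uniform)))
  expect_warning(d2 <- dif_anova(rt, rep(c("A", "C"), c(195, 5))), "dropping")
  expect_true(all(is.na(d2$p_uniform)))
})

test_that("dif_screen stacks factors and summarises flag percentages", {
  set.seed(407)
  sim <- generate_survey(generator_config(n_per_group = 80, objects = c("CC", "THS"),
                                          seed = 407, vas = FALSE))
  am <- to_analysis_matrix(sim$data, "health")
  rt <- standardized_residuals(am, calibrate_items(am))
  d <- dif_screen(rt, factors = c("sex", "object", "framing"))
  expect_setequal(unique(d$factor), c("sex", "object", "framing"))
  expect_equal(nrow(d), 3 * 18)
  smry <- attr(d, "summary")
  expect_true(all(smry$pct_items_any >= 0 & smry$pct_items_any <= 100))
})
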