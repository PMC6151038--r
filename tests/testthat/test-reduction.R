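test_that("flag_items merges the diagnostic evidence per item", {
  set.seed(901)
  sim <- generate_survey(generator_config(n_per_group = 60, objects = "CC",
                                          seed = 901, vas = FALSE))
  am <- to_analysis_matrix(sim$data, "health", object = "CC")
  fit <- calibrate_items(am)
  rt <- standardized_residuals(am, fit)
  dif <- dif_screen(rt, factors = c("sex", "group"))
  rep <- fit_report(am, fit, dif = dif)
  fl <- flag_items(rep, dif)
  expect_equal(nrow(fl), 18)
  expect_true(all(c("misfit", "chi2", "disordered", "local_dependence",
                    "dif", "any_flag") %in% names(fl)))
  expect_equal(fl$misfit, abs(fl$fit_residual) > 2.5)
})

test_that("a clean scale survives reduction essentially intact", {
  sim <- generate_survey(generator_config(n_per_group = 125, objects = "CC",
                                          seed = 902, vas = FALSE, dk_rate = 0))
  am <- to_analysis_matrix(sim$data, "health", object = "CC")
  trail <- reduce_scale(am, dif_factors = c("sex", "group"))
  # diagnostic flags fire at their type-I rates (~0.4 expected misfit
  # flags and ~0.9 item-familywise DIF flags per pass), so a handful of
  # chance removals is the calibrated behaviour of the loop
  expect_lte(length(trail$removed_total), 4)
  expect_gte(length(trail$retained), 14)
})

test_that("planted misfit and DIF items are recovered by the reduction loop", {
  cfg <- generator_config(n_per_group = 150, objects = "CC", seed = 903,
                          vas = FALSE, dk_rate = 0)
  planted_misfit <- c("H02", "H07", "H11", "H15")
  planted_dif <- c("H04", "H09", "H17")
  for (it in planted_misfit) cfg <- inject_misfit(cfg, it, 0.45)
  for (it in planted_dif) cfg <- inject_dif(cfg, it, "sex", "F", "uniform", 0.8)
  sim <- generate_survey(cfg)
  am <- to_analysis_matrix(sim$data, "health", object = "CC")
  trail <- reduce_scale(am, dif_factors = c("sex", "group"))
  planted <- c(planted_misfit, planted_dif)
  recovered <- intersect(trail$removed_total, planted)
  expect_gte(length(recovered), ceiling(0.8 * length(planted)))
  # collateral removals stay limited (type-I flags plus contamination of
  # person estimates by the seven defective items)
  expect_lte(length(setdiff(trail$removed_total, planted)), 5)
  # reasons recorded for every removal
  for (it in trail$iterations) {
    expect_equal(sort(as.character(names(it$reasons))),
                 sort(as.character(it$removed)))
  }
})

test_that("exactly one member of a duplicated item pair is removed", {
  set.seed(904)
  tau <- health_tau()[1:9, ]
  theta <- rnorm(500, 0, 2.9)
  X <- sim_pcm_matrix(theta, tau)
  X <- cbind(X, T10 = X[, 3])                  # literal duplicate of item 3
  am <- as_am(X)
  trail <- reduce_scale(am, dif_factors = NULL)
  pair <- c("T03", "T10")
  expect_equal(length(intersect(trail$removed_total, pair)), 1)
  expect_true(any(vapply(trail$iterations, function(it)
    any(it$reasons[intersect(names(it$reasons), pair)] %in%
          c("local_dependence", "misfit")), logical(1))))
})

test_that("reduction is deterministic and serializable", {
  sim <- generate_survey(generator_config(n_per_group = 60, objects = "CC",
                                          seed = 905, vas = FALSE))
  am <- to_analysis_matrix(sim$data, "health", object = "CC")
  t1 <- reduce_scale(am, dif_factors = c("sex"))
  t2 <- reduce_scale(am, dif_factors = c("sex"))
  expect_identical(t1$retained, t2$retained)
  expect_identical(t1$removed_total, t2$removed_total)
  path <- withr::local_tempfile(fileext = ".json")
  write_reduction_trail(t1, path)
  parsed <- jsonlite::read_json(path)
  expect_equal(unlist(parsed$retained), t1$retained)
})

test_that("interactive mode removes exactly the operator's choice among flagged", {
  cfg <- generator_config(n_per_group = 125, objects = "CC", seed = 906,
                          vas = FALSE, dk_rate = 0)
  cfg <- inject_misfit(cfg, "H05", 0.4)
  sim <- generate_survey(cfg)
  am <- to_analysis_matrix(sim$data, "health", object = "CC")
  chooser <- function(flags) flags$item_id[which.max(abs(flags$fit_residual))]
  trail <- reduce_scale(am, mode = "interactive", dif_factors = NULL,
                        chooser = chooser,
                        criteria = reduction_criteria(max_iterations = 1))
  expect_equal(trail$iterations[[1]]$removed, "H05")
})

test_that("calibration JSON and the markdown audit report serialize", {
  set.seed(907)
  tau <- health_tau()[1:5, ]
  X <- sim_pcm_matrix(rnorm(250, 0, 2.5), tau)
  fit <- calibrate_items(X)
  jp <- withr::local_tempfile(fileext = ".json")
  write_calibration(fit, jp, format = "json")
  parsed <- jsonlite::read_json(jp)
  expect_equal(length(parsed$items), 5)
  expect_equal(parsed$n_persons, 250)

  am <- as_am(X)
  trail <- reduce_scale(am, dif_factors = NULL,
                        criteria = reduction_criteria(max_iterations = 1))
  mp <- withr::local_tempfile(fileext = ".md")
  write_reduction_report(trail, mp)
  txt <- readLines(mp)
  expect_true(any(grepl("^# Item reduction audit", txt)))
  expect_true(any(grepl("Retained", txt)))
})
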