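test_that("long CSV round-trips bit-exactly and validates cleanly", {
  ds <- as_response_dataset(small_long_df())
  expect_s3_class(ds, "response_dataset")
  expect_equal(nrow(ds), 6)
  expect_equal(read_report(ds)$n_rejected, 0)

  path <- withr::local_tempfile(fileext = ".csv")
  write_responses(ds, path)
  ds2 <- read_responses(path)
  expect_equal(as.data.frame(ds2), as.data.frame(ds))
})

test_that("malformed ratings are rejected record-wise with a report", {
  df <- small_long_df()
  df$response[2] <- "7"
  df$response[4] <- "x"
  ds <- as_response_dataset(df)
  expect_equal(nrow(ds), 4)
  rep <- read_report(ds)
  expect_equal(rep$n_rejected, 2)
  expect_equal(rep$rejected_rows$malformed_rating, c(2L, 4L))
})

test_that("unknown object or framing codes are fatal; duplicates rejected", {
  df <- small_long_df()
  df$object[1] <- "PIPE"
  expect_error(as_response_dataset(df), "unknown object")
  df2 <- small_long_df()
  df2$framing[3] <- "Q"
  expect_error(as_response_dataset(df2), "unknown framing")
  df3 <- rbind(small_long_df(), small_long_df()[1, ])
  ds3 <- as_response_dataset(df3)
  expect_equal(nrow(ds3), 6)
  expect_equal(length(read_report(ds3)$rejected_rows$duplicate_record), 1)
})

test_that("don't-know responses are tallied separately and excluded from scores", {
  df <- small_long_df()
  df$response[1] <- "DK"
  ds <- as_response_dataset(df)
  expect_true(ds$dont_know[1])
  expect_true(is.na(ds$response[1]))
  am <- to_analysis_matrix(ds, "health", object = "CC", framing = "P")
  expect_true(is.na(am$scores[1, "H01"]))
  ms <- missing_summary(am)
  expect_equal(ms$dk_pct[ms$item_id == "H01"], 100 / 3, tolerance = 1e-10)
  expect_equal(ms$missing_pct[ms$item_id == "H01"], 0)
  expect_equal(ms$valid_pct + ms$dk_pct + ms$missing_pct, rep(100, 2))
})

test_that("applicability masks shape the analysis matrices", {
  sim <- generate_survey(generator_config(n_per_group = 20, seed = 701,
                                          vas = FALSE))
  ds <- sim$data
  expect_equal(ncol(to_analysis_matrix(ds, "health", object = "CC")$scores), 18)
  expect_equal(ncol(to_analysis_matrix(ds, "addiction", object = "CESS")$scores), 4)
  expect_equal(ncol(to_analysis_matrix(ds, "addiction", object = "CC")$scores), 6)
  # a record for a non-applicable item is rejected at validation
  df <- small_long_df()
  df$item_id[1] <- "A07"                       # Cessation-only item, object CC
  ds2 <- as_response_dataset(df)
  expect_equal(nrow(ds2), 5)
  expect_equal(length(read_report(ds2)$rejected_rows$not_applicable), 1)
})

test_that("missing flags use the strict < 10% rule at the boundary", {
  # 1 missing among 10 responses of an item -> exactly 10% -> flagged
  df <- tibble::tibble(
    respondent_id = rep(sprintf("r%02d", 1:10), each = 2),
    group = "FS", age_band = "18-30", sex = "M", education = "HS_or_less",
    object = "CC", framing = "P", position = 1L,
    item_id = rep(c("H01", "H02"), 10),
    response = c("", rep("3", 19))
  )
  am <- to_analysis_matrix(as_response_dataset(df), "health", object = "CC",
                           framing = "P")
  ms <- missing_summary(am)
  expect_equal(ms$missing_pct[ms$item_id == "H01"], 10)
  expect_true(ms$flag_missing[ms$item_id == "H01"])
  expect_false(ms$flag_missing[ms$item_id == "H02"])
})

test_that("all-missing rows are dropped with a count, empty selections are fatal", {
  df <- small_long_df()
  df$response[1:2] <- ""                       # r1 entirely missing
  ds <- as_response_dataset(df)
  am <- to_analysis_matrix(ds, "health", object = "CC", framing = "P")
  expect_equal(nrow(am$scores), 2)
  expect_equal(am$n_dropped_rows, 1)
  expect_error(to_analysis_matrix(ds, "health", object = "NRT"),
               "empty selection")
})

test_that("the wide-format reader recovers the long structure", {
  wide <- tibble::tibble(
    respondent_id = c("r1", "r2"), group = "NS", age_band = "46+",
    sex = "F", education = "some_college_plus",
    object = "THS", framing = "G", position = 2L,
    H01 = c("2", "4"), H02 = c("5", "DK"))
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(wide, path)
  ds <- read_responses(path, format = "wide")
  expect_equal(nrow(ds), 4)
  expect_equal(sort(unique(ds$item_id)), c("H01", "H02"))
  expect_true(ds$dont_know[ds$respondent_id == "r2" & ds$item_id == "H02"])
})
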