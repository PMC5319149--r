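test_that("the nine-state taxonomy is total and correctly paired", {
  hs <- health_states()
  expect_equal(nrow(hs), 9L)
  expect_equal(hs$rank, 1:9)
  expect_equal(hs$severity,
               c("mild", "mild", "mild", "moderate", "moderate",
                 "marked", "marked", "severe", "severe"))
  expect_equal(hs$bone,
               c("none", "BP", "SSC", "none", "SSC", "none", "SSC",
                 "none", "SSC"))
  # BP only within the mild band; other bands pair only with none/SSC
  expect_true(all(hs$severity[hs$bone == "BP"] == "mild"))
  expect_true(all(hs$bone[hs$severity != "mild"] %in% c("none", "SSC")))
})

test_that("states resolve by rank and by name, and reject junk", {
  expect_equal(health_state(7)$name, "Marked with SSC")
  expect_equal(health_state("severe with ssc")$rank, 9L)
  expect_equal(state_severity(5), "moderate")
  expect_error(health_state(0), "1\\.\\.9")
  expect_error(health_state(10), "1\\.\\.9")
  expect_error(health_state("mildish"), "unknown health state")
})

test_that("packaged utility coefficients load and validate", {
  uc <- table1_coefs("printed")
  expect_s3_class(uc, "utility_coefficients")
  expect_equal(uc$constant, 0.880)
  expect_equal(uc$d_severe, -0.168)
  expect_equal(uc$age_at_init, -0.002)
  expect_equal(uc$mean_female, 0.691)
  expect_equal(uc$mean_age, 53.9)
  # calibrated default differs only in the age coefficient
  expect_equal(default_utility_coefficients()$age_at_init, -0.0015)
})

test_that("utility coefficient files are schema-checked", {
  src <- system.file("extdata", "table1_utility.csv", package = "gd1markov")
  df <- read.csv(src)

  f1 <- withr::local_tempfile(fileext = ".csv")
  write.csv(df[df$term != "bone_pain", ], f1, row.names = FALSE)
  expect_error(load_utility_coefficients(f1), "bone_pain")

  f2 <- withr::local_tempfile(fileext = ".csv")
  df2 <- df; df2$value[df2$term == "mean_female"] <- 1.5
  write.csv(df2, f2, row.names = FALSE)
  expect_error(load_utility_coefficients(f2), "mean_female")

  f3 <- withr::local_tempfile(fileext = ".csv")
  write.csv(rbind(df, df[1, ]), f3, row.names = FALSE)
  expect_error(load_utility_coefficients(f3), "duplicate")

  expect_error(load_utility_coefficients("no/such/file.csv"), "not found")
})

test_that("packaged transition coefficients load with the full layout", {
  tc <- table2_coefs()
  expect_s3_class(tc, "transition_coefficients")
  expect_equal(unname(tc$prev_state),
               c(1.305, 0.840, 2.581, 1.253, 4.504, 3.617, 4.213, 6.072))
  expect_equal(unname(tc$years_on_tx), c(0.293, 0.315))
  expect_equal(unname(tc$baseline_d), c(-0.150, 0.873, 1.349))
  expect_equal(tc$not_splenectomized, -1.089)
  expect_equal(tc$cutpoints,
               c(0.740, 1.662, 1.727, 5.054, 5.835, 6.577, 8.808, 9.066))
})

test_that("transition coefficient files reject broken cutpoints", {
  src <- system.file("extdata", "table2_transitions.csv", package = "gd1markov")
  df <- read.csv(src)

  f1 <- withr::local_tempfile(fileext = ".csv")
  df1 <- df
  i2 <- df1$term == "cutpoint_2"; i3 <- df1$term == "cutpoint_3"
  df1$value[i2] <- 1.727; df1$value[i3] <- 1.662
  write.csv(df1, f1, row.names = FALSE)
  expect_error(load_transition_coefficients(f1), "nondecreasing")

  f2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(df[df$term != "cutpoint_8", ], f2, row.names = FALSE)
  expect_error(load_transition_coefficients(f2), "cutpoint_8")

  expect_error(
    transition_coefficients(prev_state = rep(0, 8),
                            years_on_tx = c(0, 0),
                            baseline_d = c(0, 0, 0),
                            not_splenectomized = 0,
                            cutpoints = 1:7),
    "8 cutpoints")
})

test_that("life tables enforce contiguity, bounds and terminal extinction", {
  good <- flat_life_table(0.01)
  expect_s3_class(good, "life_table")

  f <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(age = 0:110, qx = c(rep(0.01, 110), 1))
  write.csv(df[df$age != 50, ], f, row.names = FALSE)
  expect_error(load_life_table(f), "contiguous")

  expect_error(life_table(0:110, c(rep(0.01, 110), 0.9)), "maximum age")
  expect_error(life_table(0:110, c(rep(1.2, 110), 1)), "\\[0, 1\\]")
  expect_error(life_table(0:80, c(rep(0.01, 80), 1)), "at least age 100")
})

test_that("coefficient objects round-trip through CSV and JSON", {
  uc <- table1_coefs("printed")
  tc <- table2_coefs()
  for (ext in c(".csv", ".json")) {
    fu <- withr::local_tempfile(fileext = ext)
    ft <- withr::local_tempfile(fileext = ext)
    write_utility_coefficients(uc, fu)
    write_transition_coefficients(tc, ft)
    expect_equal(load_utility_coefficients(fu), uc)
    expect_equal(load_transition_coefficients(ft), tc)
  }
})
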