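test_that("the panel log-likelihood matches a brute-force evaluation", {
  tc <- table2_coefs()
  panel <- tiny_state_panel()
  # brute force: per row, rebuild the linear predictor and the category
  # probability from the raw coefficient arithmetic
  brute <- 0
  for (i in seq_len(nrow(panel))) {
    lp <- 0
    if (panel$prev_state[i] > 1) {
      lp <- lp + tc$prev_state[[as.character(panel$prev_state[i])]]
    }
    if (panel$years_on_tx[i] != "1") {
      lp <- lp + tc$years_on_tx[[panel$years_on_tx[i]]]
    }
    if (panel$baseline_d[i] != "mild") {
      lp <- lp + tc$baseline_d[[panel$baseline_d[i]]]
    }
    if (panel$spleen[i] == "intact") lp <- lp + tc$not_splenectomized
    cum <- c(0, logistic(tc$cutpoints - lp), 1)
    k <- panel$state[i]
    brute <- brute + log(cum[k + 1] - cum[k])
  }
  expect_equal(transition_loglik(panel, tc), brute, tolerance = 1e-12)
})

test_that("the ordered-logit fit maximizes the package's own likelihood", {
  spec <- simulation_spec(n_patients = 400, n_years = 8, seed = 42)
  panel <- simulate_panel(spec)
  fit <- fit_transition_model(panel)
  # the reported log-likelihood is the package likelihood at the optimum
  expect_equal(transition_loglik(panel, fit$coefficients), fit$loglik,
               tolerance = 1e-6)
  # and no perturbation of the fit improves it (local maximum)
  expect_gt(fit$loglik, transition_loglik(panel, table2_coefs()) - 1e-8)
  pert <- fit$coefficients
  pert$not_splenectomized <- pert$not_splenectomized + 0.05
  expect_lt(transition_loglik(panel, pert), fit$loglik)
  expect_equal(length(fit$se), 22L)
  expect_true(all(is.finite(fit$se) & fit$se > 0))
})

test_that("degenerate or sparse state panels fail with diagnostics", {
  panel <- tiny_state_panel()
  panel$state <- 4L
  expect_error(fit_transition_model(panel), "single outcome category")
  panel2 <- tiny_state_panel()
  expect_error(fit_transition_model(panel2), "unobserved")
})

test_that("duplicating every row leaves point estimates unchanged", {
  spec <- simulation_spec(n_patients = 250, n_years = 6, seed = 42)
  panel <- simulate_panel(spec)
  fit1 <- fit_transition_model(panel)
  doubled <- rbind(panel, transform(panel, patient = patient + 10000L))
  fit2 <- fit_transition_model(doubled)
  expect_equal(unclass(fit2$coefficients)[1:4],
               unclass(fit1$coefficients)[1:4], tolerance = 1e-4)
  expect_equal(fit2$coefficients$cutpoints, fit1$coefficients$cutpoints,
               tolerance = 1e-4)
})

test_that("a zero-noise utility panel is recovered exactly", {
  truth <- table1_coefs("printed")
  spec <- simulation_spec(n_patients = 120, n_years = 8, seed = 42,
                          utility_coefs = truth, utility_noise_sd = 0,
                          n_utility_obs = 4)
  states <- simulate_panel(spec)
  up <- simulate_utility_panel(spec, states)
  # sandwich warns about the (intended) perfect fit
  fit <- suppressWarnings(fit_utility_model(up))
  cf <- fit$coefficients
  for (term in c("constant", "d_moderate", "d_marked", "d_severe",
                 "bone_pain", "ssc", "female", "age_at_init")) {
    expect_equal(cf[[term]], truth[[term]], tolerance = 1e-8)
  }
  expect_equal(cf$mean_female, mean(up$female))
  expect_equal(cf$mean_age, mean(up$age_at_init))
})

test_that("shifting all utilities by a constant moves only the intercept", {
  spec <- simulation_spec(n_patients = 100, n_years = 6, seed = 42,
                          n_utility_obs = 3)
  up <- simulate_utility_panel(spec, simulate_panel(spec))
  f1 <- fit_utility_model(up)
  up2 <- up; up2$utility <- up2$utility + 0.05
  f2 <- fit_utility_model(up2)
  expect_equal(f2$coefficients$constant, f1$coefficients$constant + 0.05,
               tolerance = 1e-10)
  expect_equal(f2$coefficients$d_severe, f1$coefficients$d_severe,
               tolerance = 1e-10)
  expect_equal(f2$coefficients$female, f1$coefficients$female,
               tolerance = 1e-10)
})

test_that("recycled predictions equal the mean of per-row predictions", {
  spec <- simulation_spec(n_patients = 150, n_years = 8, seed = 42,
                          n_utility_obs = 3)
  up <- simulate_utility_panel(spec, simulate_panel(spec))
  fit <- fit_utility_model(up)
  cf <- fit$coefficients
  # fix the state at severe+SSC for every subject, average the per-row
  # predictions over the observed covariates
  per_row <- cf$constant + cf$d_severe + cf$bone_pain + cf$ssc +
    cf$female * up$female + cf$age_at_init * up$age_at_init
  recycled <- state_utility(9, cf, covariate_profile(mean(up$female),
                                                     mean(up$age_at_init)))
  expect_equal(mean(per_row), recycled, tolerance = 1e-12)
})

test_that("utility fits reject degenerate designs", {
  spec <- simulation_spec(n_patients = 50, n_years = 6, seed = 42)
  up <- simulate_utility_panel(spec, simulate_panel(spec))
  expect_error(fit_utility_model(up[up$patient == 1, ]), "two patients")
  # bone pain constant across rows makes it collinear with the intercept
  up2 <- up[up$state %in% c(2, 3, 5), ]
  expect_error(fit_utility_model(up2), "collinear")
})

test_that("transition coefficient bias shrinks with the sample size", {
  truth <- table2_coefs()
  slope_vec <- function(cf) {
    c(cf$prev_state, cf$years_on_tx, cf$baseline_d, cf$not_splenectomized)
  }
  bias <- sapply(c(500, 5000), function(n) {
    panel <- simulate_panel(simulation_spec(n_patients = n, n_years = 10,
                                            seed = 42))
    fit <- fit_transition_model(panel)
    sqrt(sum((slope_vec(fit$coefficients) - slope_vec(truth))^2))
  })
  expect_lt(bias[2], 0.6 * bias[1])
})
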