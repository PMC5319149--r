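test_that("extreme cutpoints make trajectories deterministic", {
  coefs <- transition_coefficients(
    prev_state = rep(0, 8), years_on_tx = c(0, 0), baseline_d = c(0, 0, 0),
    not_splenectomized = 0, cutpoints = seq(100, 100.7, by = 0.1))
  spec <- simulation_spec(n_patients = 30, n_years = 5, seed = 42,
                          transition_coefs = coefs)
  panel <- simulate_panel(spec)
  # everyone collapses onto rank 1 from the first transition on
  expect_true(all(panel$state == 1L))
})

test_that("panels are reproducible by seed", {
  s1 <- simulate_panel(simulation_spec(n_patients = 40, seed = 42))
  s2 <- simulate_panel(simulation_spec(n_patients = 40, seed = 42))
  s3 <- simulate_panel(simulation_spec(n_patients = 40, seed = 43))
  expect_identical(s1, s2)
  expect_false(identical(s1, s3))
})

test_that("panel structure matches its contract", {
  spec <- simulation_spec(n_patients = 60, n_years = 13, seed = 42)
  panel <- simulate_panel(spec)
  # year indices strictly increasing within patient; prev state chains
  for (id in unique(panel$patient)[1:10]) {
    sub <- panel[panel$patient == id, ]
    expect_true(all(diff(sub$year) == 1))
    if (nrow(sub) > 1) {
      expect_equal(sub$prev_state[-1], sub$state[-nrow(sub)])
    }
    expect_equal(unique(sub$baseline_d),
                 state_severity(sub$prev_state[1]))
  }
  expect_true(all(panel$years_on_tx[panel$year == 1] == "1"))
  expect_true(all(panel$years_on_tx[panel$year >= 3] == "3plus"))
  expect_true(all(panel$year <= 13))
})

test_that("one-step frequencies agree with the model probabilities", {
  spec <- simulation_spec(n_patients = 5000, n_years = 3, seed = 42)
  panel <- simulate_panel(spec)
  rows <- panel$year == 1 & panel$prev_state == 1 &
    panel$baseline_d == "mild" & panel$spleen == "splenectomized"
  p_hat <- mean(panel$state[rows] == 1)
  p_true <- logistic(0.740)
  n <- sum(rows)
  expect_gt(n, 100)
  expect_lt(abs(p_hat - p_true), 3 * sqrt(p_true * (1 - p_true) / n))
})

test_that("utility observations sit on the linear predictor plus noise", {
  spec0 <- simulation_spec(n_patients = 50, n_years = 6, seed = 42,
                           utility_noise_sd = 0)
  states <- simulate_panel(spec0)
  up <- simulate_utility_panel(spec0, states)
  uc <- spec0$utility_coefs
  for (i in seq_len(nrow(up))) {
    expect_equal(up$utility[i],
                 state_utility(up$state[i], uc,
                               covariate_profile(up$female[i],
                                                 up$age_at_init[i])),
                 tolerance = 1e-12)
  }
  expect_identical(attr(up, "clipped"), 0L)
})

test_that("large samples center the mild utility on its prediction", {
  spec <- simulation_spec(n_patients = 3000, n_years = 2, seed = 42,
                          n_utility_obs = 2)
  up <- simulate_utility_panel(spec, simulate_panel(spec))
  mild <- up$state == 1
  pred <- state_utility(1, spec$utility_coefs,
                        covariate_profile(spec$prop_female, spec$age_mean))
  # total sd combines observation noise with female/age heterogeneity
  expect_lt(abs(mean(up$utility[mild]) - pred), 3 * 0.11 / sqrt(sum(mild)))
})

test_that("utilities are clipped to the EQ-5D range and the count logged", {
  spec <- simulation_spec(n_patients = 200, n_years = 4, seed = 42,
                          utility_noise_sd = 2)
  expect_message(up <- simulate_utility_panel(spec, simulate_panel(spec)),
                 "clipped")
  expect_true(all(up$utility >= -0.594 & up$utility <= 1))
  expect_gt(attr(up, "clipped"), 0)
})

test_that("simulate-fit-project closes the loop on lifetime outcomes", {
  spec <- simulation_spec(n_patients = 2000, n_years = 10, seed = 42,
                          n_utility_obs = 3)
  states <- simulate_panel(spec)
  tfit <- fit_transition_model(states)
  ufit <- fit_utility_model(simulate_utility_panel(spec, states))
  mort <- gd1_mortality()
  truth_out <- project_outcomes(scenario("Mild", "intact"),
                                matrices = all_matrices(),
                                mortality = mort)
  fit_out <- project_outcomes(
    scenario("Mild", "intact"),
    utility_coefs = ufit$coefficients,
    matrices = all_matrices(tfit$coefficients),
    mortality = mort)
  expect_lt(abs(fit_out$undiscounted_qalys / truth_out$undiscounted_qalys - 1),
            0.05)
  expect_lt(abs(fit_out$discounted_qalys / truth_out$discounted_qalys - 1),
            0.05)
  expect_lt(abs(fit_out$share_mild - truth_out$share_mild), 5)
})
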