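# Shared fixtures, built in code.

table1_coefs <- function(age_coef = "printed") {
  default_utility_coefficients(age_coef)
}

table2_coefs <- function() {
  default_transition_coefficients()
}

# hand-rolled logistic CDF, kept separate from the implementation's plogis
logistic <- function(x) 1 / (1 + exp(-x))

# a small state panel covering several covariate patterns, written by hand
tiny_state_panel <- function() {
  data.frame(
    patient = rep(1:4, each = 3),
    year = rep(1:3, 4),
    state = c(1, 2, 1, 4, 4, 5, 7, 6, 4, 9, 8, 8),
    prev_state = c(1, 1, 2, 4, 4, 4, 7, 7, 6, 9, 9, 8),
    years_on_tx = rep(c("1", "2", "3plus"), 4),
    baseline_d = rep(c("mild", "moderate", "marked", "severe"), each = 3),
    spleen = rep(c("intact", "splenectomized"), each = 3, length.out = 12),
    stringsAsFactors = FALSE
  )
}

# row-stochastic 9x9 matrix with Dirichlet-like rows
random_stochastic_matrix <- function() {
  m <- matrix(stats::rgamma(81, shape = 1), 9, 9)
  m / rowSums(m)
}

# minimal matrix set covering one (D, spleen) stratum at all three T levels
constant_matrix_set <- function(P, baseline_d = "mild", spleen = "intact") {
  keys <- sprintf("T%s_D%s_%s", c("1", "2", "3plus"), baseline_d, spleen)
  stats::setNames(rep(list(P), 3), keys)
}

# life table with constant qx (terminal forced to 1)
flat_life_table <- function(q, max_age = 110L) {
  qx <- rep(q, max_age + 1L)
  qx[length(qx)] <- 1
  life_table(0:max_age, qx)
}
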