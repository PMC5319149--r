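#' Specification for a synthetic longitudinal cohort
#'
#' Defines the data-generating process for synthetic panels with the
#' statistical structure the estimation routines assume, emulating a
#' longitudinal severity-score study: a fixed number of adult patients,
#' annual health-state observations from treatment start, a fixed baseline
#' severity category and splenectomy status per patient, and sparse
#' utility observations. Defaults mirror the source study: 133 treated
#' patients followed for a mean (SD) of 13.3 (6.1) years; baseline states
#' concentrated on the three most common states (19% mild, 28% moderate,
#' 28% marked with SSC, remainder uniform over the other six); 67.2%
#' with intact spleens; utility-sample composition 69.1% female with mean
#' age 53.9 at treatment initiation.
#'
#' @param n_patients Number of patients.
#' @param n_years Maximum follow-up years; individual follow-up is a
#'   rounded Normal(`followup_mean`, `followup_sd`) clamped to
#'   `[1, n_years]`.
#' @param seed Integer seed; the same spec yields the same panels.
#' @param transition_coefs True [transition_coefficients()] generating the
#'   annual transitions.
#' @param utility_coefs True [utility_coefficients()] generating utility
#'   observations.
#' @param utility_noise_sd SD of the Gaussian observation noise added to
#'   the utility linear predictor.
#' @param baseline_probs Probability 9-vector over baseline state ranks.
#' @param prop_intact Proportion of patients with intact spleens.
#' @param followup_mean,followup_sd Follow-up length distribution (years).
#' @param prop_female Proportion female.
#' @param age_mean,age_sd Age at treatment initiation distribution
#'   (years); draws are clamped to [18, 90] (the instrument is validated
#'   for adults).
#' @param n_utility_obs Utility observations sampled per patient (capped
#'   at the patient's follow-up length).
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_patients = 133L, n_years = 13L, seed = 1L,
                            transition_coefs = default_transition_coefficients(),
                            utility_coefs = default_utility_coefficients(),
                            utility_noise_sd = 0.1,
                            baseline_probs = default_baseline_probs(),
                            prop_intact = 0.672,
                            followup_mean = 13.3, followup_sd = 6.1,
                            prop_female = 0.691,
                            age_mean = 53.9, age_sd = 15,
                            n_utility_obs = 2L) {
  stopifnot(n_patients >= 1L, n_years >= 1L,
            length(baseline_probs) == 9L, all(baseline_probs >= 0),
            abs(sum(baseline_probs) - 1) < 1e-8,
            prop_intact >= 0, prop_intact <= 1,
            utility_noise_sd >= 0)
  structure(list(n_patients = as.integer(n_patients),
                 n_years = as.integer(n_years), seed = as.integer(seed),
                 transition_coefs = transition_coefs,
                 utility_coefs = utility_coefs,
                 utility_noise_sd = utility_noise_sd,
                 baseline_probs = baseline_probs,
                 prop_intact = prop_intact,
                 followup_mean = followup_mean, followup_sd = followup_sd,
                 prop_female = prop_female,
                 age_mean = age_mean, age_sd = age_sd,
                 n_utility_obs = as.integer(n_utility_obs)),
            class = "simulation_spec")
}

#' Default baseline state distribution
#'
#' The three most common observed starting states at their study shares
#' (19% mild, 28% moderate, 28% marked with SSC), the remaining 25%
#' spread uniformly over the other six states.
#'
#' @return A probability 9-vector.
#' @export
default_baseline_probs <- function() {
  p <- rep(0.25 / 6, 9)
  p[1] <- 0.19; p[4] <- 0.28; p[7] <- 0.28
  p
}

years_cat <- function(t) c("1", "2", "3plus")[pmin(t, 3L)]

#' Simulate a longitudinal state panel
#'
#' Draws, per patient, a baseline state, spleen status and follow-up
#' length, then samples each year's state from the ordered-logit
#' next-state distribution at the patient's covariates (previous state,
#' years on treatment clamped at 3+, baseline severity of the initial
#' state, spleen status).
#'
#' @param spec A [simulation_spec()].
#' @return A data frame with columns `patient`, `year`, `state`,
#'   `prev_state`, `years_on_tx`, `baseline_d`, `spleen`.
#' @export
simulate_panel <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  coefs <- spec$transition_coefs
  sev <- health_states()$severity
  # next-state distributions for the 24 scenarios x 9 previous states
  mats <- all_matrices(coefs)
  followup <- pmin(pmax(round(stats::rnorm(spec$n_patients,
                                           spec$followup_mean,
                                           spec$followup_sd)), 1L),
                   spec$n_years)
  baseline <- sample.int(9L, spec$n_patients, replace = TRUE,
                         prob = spec$baseline_probs)
  spleen <- ifelse(stats::runif(spec$n_patients) < spec$prop_intact,
                   "intact", "splenectomized")
  rows <- vector("list", spec$n_patients)
  for (i in seq_len(spec$n_patients)) {
    L <- followup[i]
    d <- sev[baseline[i]]
    st <- integer(L)
    prev <- baseline[i]
    for (t in seq_len(L)) {
      P <- mats[[sprintf("T%s_D%s_%s", years_cat(t), d, spleen[i])]]
      st[t] <- sample.int(9L, 1L, prob = P[prev, ])
      prev <- st[t]
    }
    rows[[i]] <- data.frame(patient = i, year = seq_len(L), state = st,
                            prev_state = c(baseline[i], st[-L]),
                            years_on_tx = years_cat(seq_len(L)),
                            baseline_d = d, spleen = spleen[i],
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Simulate a sparse utility panel on top of a state panel
#'
#' Per patient, draws a female flag and an age at treatment initiation,
#' samples a few of the patient's state-years, and generates observed
#' utilities as the utility linear predictor plus Gaussian noise, clipped
#' to the UK EQ-5D value-set range [-0.594, 1]. The number of clipped
#' observations is reported via a message and the `"clipped"` attribute.
#'
#' @param spec A [simulation_spec()].
#' @param states A state panel from [simulate_panel()].
#' @return A data frame with columns `patient`, `state`, `utility`,
#'   `female`, `age_at_init`, and attribute `clipped`.
#' @export
simulate_utility_panel <- function(spec, states) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed + 1L)
  uc <- spec$utility_coefs
  ids <- unique(states$patient)
  female <- stats::rbinom(length(ids), 1L, spec$prop_female)
  age <- pmin(pmax(stats::rnorm(length(ids), spec$age_mean, spec$age_sd),
                   18), 90)
  rows <- vector("list", length(ids))
  for (j in seq_along(ids)) {
    sub <- states[states$patient == ids[j], , drop = FALSE]
    k <- min(spec$n_utility_obs, nrow(sub))
    pick <- sort(sample.int(nrow(sub), k))
    st <- sub$state[pick]
    lp <- vapply(st, function(r) {
      d <- utility_design_row(r)
      uc$constant + sum(d * c(uc$d_moderate, uc$d_marked, uc$d_severe,
                              uc$bone_pain, uc$ssc)) +
        uc$female * female[j] + uc$age_at_init * age[j]
    }, numeric(1))
    rows[[j]] <- data.frame(patient = ids[j], state = st,
                            utility = lp + stats::rnorm(k, 0,
                                                        spec$utility_noise_sd),
                            female = female[j], age_at_init = age[j])
  }
  out <- do.call(rbind, rows)
  lo <- out$utility < -0.594
  hi <- out$utility > 1
  n_clip <- sum(lo) + sum(hi)
  if (n_clip > 0) {
    out$utility[lo] <- -0.594
    out$utility[hi] <- 1
    message(n_clip, " utility observation(s) clipped to the EQ-5D range ",
            "[-0.594, 1]")
  }
  attr(out, "clipped") <- n_clip
  out
}
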