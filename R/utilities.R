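#' Covariate profile for recycled predictions
#'
#' The utility regression includes sex and age at treatment initiation.
#' Predicted state utilities are produced by the method of recycled
#' predictions: the state indicators are fixed at each state's values and
#' the remaining covariates are averaged over the estimation sample. Under
#' the identity link this equals evaluating the linear predictor at the
#' covariate means, which is what this profile carries.
#'
#' @param prop_female Proportion female, in [0, 1].
#' @param mean_age_at_init Mean age at treatment initiation (years).
#' @return An object of class `covariate_profile`.
#' @export
covariate_profile <- function(prop_female, mean_age_at_init) {
  if (!is.finite(prop_female) || prop_female < 0 || prop_female > 1) {
    stop("prop_female must be a proportion in [0, 1]", call. = FALSE)
  }
  if (!is.finite(mean_age_at_init) || mean_age_at_init < 0) {
    stop("mean_age_at_init must be a nonnegative number of years",
         call. = FALSE)
  }
  structure(list(prop_female = prop_female,
                 mean_age_at_init = mean_age_at_init),
            class = "covariate_profile")
}

#' Default covariate profile: the estimation-sample means
#'
#' @param coefs A [utility_coefficients()] object whose stored sample means
#'   are used.
#' @return A [covariate_profile()].
#' @export
estimation_profile <- function(coefs = default_utility_coefficients()) {
  covariate_profile(coefs$mean_female, coefs$mean_age)
}

# Design row of the utility regression for one health state.
# Bone pain enters for the mild+BP state and for every SSC state (the
# published prediction rule: the bone-pain effect is included when
# computing utilities of SSC-containing states).
utility_design_row <- function(rank) {
  st <- health_state(rank)
  c(d_moderate = as.numeric(st$severity == "moderate"),
    d_marked   = as.numeric(st$severity == "marked"),
    d_severe   = as.numeric(st$severity == "severe"),
    bone_pain  = as.numeric(st$bone %in% c("BP", "SSC")),
    ssc        = as.numeric(st$bone == "SSC"))
}

#' Predicted utility of one health state
#'
#' Evaluates the utility regression's linear predictor for a health state
#' with the sex/age covariates at the profile values (recycled
#' predictions under an identity link). Utilities are on the EQ-5D scale
#' where 1 is full health and 0 is dead.
#'
#' @param state Health-state rank (1..9) or name.
#' @param coefs A [utility_coefficients()] object.
#' @param profile A [covariate_profile()]; defaults to the estimation-sample
#'   means stored in `coefs`.
#' @return A single utility value. A warning is raised if it falls outside
#'   (0, 1); no censoring is applied.
#' @examples
#' state_utility("Mild", default_utility_coefficients())
#' @export
state_utility <- function(state, coefs, profile = estimation_profile(coefs)) {
  stopifnot(inherits(coefs, "utility_coefficients"),
            inherits(profile, "covariate_profile"))
  d <- utility_design_row(health_state(state)$rank)
  u <- coefs$constant +
    d[["d_moderate"]] * coefs$d_moderate +
    d[["d_marked"]] * coefs$d_marked +
    d[["d_severe"]] * coefs$d_severe +
    d[["bone_pain"]] * coefs$bone_pain +
    d[["ssc"]] * coefs$ssc +
    coefs$female * profile$prop_female +
    coefs$age_at_init * profile$mean_age_at_init
  if (u <= 0 || u >= 1) {
    warning("predicted utility ", round(u, 4), " lies outside (0, 1); ",
            "no censoring is applied", call. = FALSE)
  }
  unname(u)
}

#' Predicted utilities for all nine health states
#'
#' @inheritParams state_utility
#' @return A named numeric vector of length 9, indexed by state rank, with
#'   the state names as names.
#' @examples
#' round(utility_table(default_utility_coefficients()), 3)
#' @export
utility_table <- function(coefs, profile = estimation_profile(coefs)) {
  u <- vapply(1:9, state_utility, numeric(1), coefs = coefs, profile = profile)
  stats::setNames(u, health_states()$name)
}
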