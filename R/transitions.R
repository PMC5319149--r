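#' Scenario key for a transition matrix
#'
#' Annual transition matrices are computed for every combination of
#' years on treatment (1, 2, 3+), baseline DS3 severity category (the
#' category at treatment start) and splenectomy status: 3 x 4 x 2 = 24
#' matrices in all.
#'
#' @param years_on_tx `1`, `2` or `"3plus"` (numeric 3 and `">=3"` are
#'   accepted synonyms for `"3plus"`).
#' @param baseline_d One of `"mild"`, `"moderate"`, `"marked"`, `"severe"`.
#' @param spleen `"splenectomized"` (total splenectomy before treatment) or
#'   `"intact"` (intact or partially resected spleen).
#' @return An object of class `scenario_key`.
#' @export
scenario_key <- function(years_on_tx, baseline_d, spleen) {
  t <- as.character(years_on_tx)
  if (t %in% c("3", ">=3", "3+")) t <- "3plus"
  if (!t %in% c("1", "2", "3plus")) {
    stop("years_on_tx must be 1, 2 or \"3plus\"", call. = FALSE)
  }
  baseline_d <- match.arg(baseline_d, c("mild", "moderate", "marked", "severe"))
  spleen <- match.arg(spleen, c("splenectomized", "intact"))
  structure(list(years_on_tx = t, baseline_d = baseline_d, spleen = spleen),
            class = "scenario_key")
}

#' @export
format.scenario_key <- function(x, ...) {
  sprintf("T%s_D%s_%s", x$years_on_tx, x$baseline_d, x$spleen)
}

#' @export
print.scenario_key <- function(x, ...) {
  cat("<scenario_key>", format(x), "\n")
  invisible(x)
}

#' Linear predictor of the transition model
#'
#' The proportional-odds linear predictor for a patient in previous state
#' `prev` under a given scenario: previous-state contrast + years-on-
#' treatment contrast + baseline DS3 contrast + splenectomy term (the
#' `not_splenectomized` coefficient applies when the spleen is intact).
#' All reference categories (previous state mild, first treatment year,
#' mild baseline, splenectomized) contribute zero.
#'
#' @param prev Previous health state (rank 1..9 or name).
#' @param key A [scenario_key()].
#' @param coefs A [transition_coefficients()] object.
#' @return The linear predictor (a single number). Larger values shift the
#'   next-state distribution toward worse ranks.
#' @export
linear_predictor <- function(prev, key, coefs) {
  stopifnot(inherits(key, "scenario_key"),
            inherits(coefs, "transition_coefficients"))
  r <- health_state(prev)$rank
  lp <- if (r == 1L) 0 else unname(coefs$prev_state[as.character(r)])
  if (key$years_on_tx != "1") {
    lp <- lp + unname(coefs$years_on_tx[key$years_on_tx])
  }
  if (key$baseline_d != "mild") {
    lp <- lp + unname(coefs$baseline_d[key$baseline_d])
  }
  if (key$spleen == "intact") lp <- lp + coefs$not_splenectomized
  lp
}

#' Ordered-logit category probabilities
#'
#' Converts a linear predictor into next-state probabilities over the nine
#' ranked states under the proportional-odds model:
#' `P(rank <= k) = plogis(cutpoint_k - lp)` for k = 1..8, with category
#' probabilities as successive differences and `P(rank = 9)` the
#' complement.
#'
#' @param lp Linear predictor.
#' @param cutpoints Nondecreasing numeric vector of length 8.
#' @return A probability 9-vector summing to 1.
#' @examples
#' category_probabilities(0, default_transition_coefficients()$cutpoints)
#' @export
category_probabilities <- function(lp, cutpoints) {
  if (length(cutpoints) != 8L || is.unsorted(cutpoints)) {
    stop("cutpoints must be 8 nondecreasing values", call. = FALSE)
  }
  cum <- stats::plogis(cutpoints - lp)
  p <- diff(c(0, cum, 1))
  # successive differences of a nondecreasing cumulative are >= 0 up to
  # rounding; clamp any -0-sized negatives
  p[p < 0] <- 0
  stats::setNames(p, health_states()$name)
}

#' Annual transition matrix for one scenario
#'
#' Row r holds the next-state distribution for patients currently in state
#' r under the scenario's fixed covariates. Because every covariate is
#' categorical and fixed within a scenario, the recycled prediction equals
#' the direct prediction at those covariate values.
#'
#' @param key A [scenario_key()].
#' @param coefs A [transition_coefficients()] object.
#' @return A 9 x 9 row-stochastic matrix of class `transition_matrix`,
#'   rows = previous state, columns = next state.
#' @export
transition_matrix <- function(key, coefs) {
  rows <- t(vapply(1:9, function(r) {
    category_probabilities(linear_predictor(r, key, coefs), coefs$cutpoints)
  }, numeric(9)))
  dimnames(rows) <- list(health_states()$name, health_states()$name)
  structure(rows, class = c("transition_matrix", "matrix", "array"),
            key = key)
}

#' @export
print.transition_matrix <- function(x, digits = 4, ...) {
  key <- attr(x, "key")
  if (!is.null(key)) cat("Annual transition matrix,", format(key), "\n")
  print(round(unclass(x), digits))
  invisible(x)
}

#' All 24 annual transition matrices
#'
#' One matrix per combination of years on treatment (1, 2, 3+), baseline
#' DS3 category (mild, moderate, marked, severe) and splenectomy status.
#'
#' @param coefs A [transition_coefficients()] object; defaults to the
#'   packaged published coefficients.
#' @return A named list of 24 [transition_matrix()] objects; names are
#'   `T<years>_D<baseline>_<spleen>` (e.g. `"T1_Dmild_intact"`).
#' @export
all_matrices <- function(coefs = default_transition_coefficients()) {
  keys <- expand.grid(years_on_tx = c("1", "2", "3plus"),
                      baseline_d = c("mild", "moderate", "marked", "severe"),
                      spleen = c("splenectomized", "intact"),
                      stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(keys)), function(i) {
    transition_matrix(scenario_key(keys$years_on_tx[i], keys$baseline_d[i],
                                   keys$spleen[i]), coefs)
  })
  names(out) <- vapply(out, function(m) format(attr(m, "key")), character(1))
  out
}
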