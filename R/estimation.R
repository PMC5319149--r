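# Longitudinal panels and regression fitting.
#
# StatePanel schema (one row per observed annual transition):
#   patient, year, state (current rank 1..9), prev_state (rank 1..9),
#   years_on_tx ("1"/"2"/"3plus"), baseline_d (severity category),
#   spleen ("intact"/"splenectomized")
# UtilityPanel schema:
#   patient, state (rank 1..9), utility, female (0/1), age_at_init

# Indicator design matrix mirroring the transition coefficient layout.
transition_design <- function(panel) {
  prev <- as.integer(panel$prev_state)
  X <- cbind(
    sapply(2:9, function(r) as.numeric(prev == r)),
    years_2 = as.numeric(panel$years_on_tx == "2"),
    years_3plus = as.numeric(panel$years_on_tx == "3plus"),
    d_moderate = as.numeric(panel$baseline_d == "moderate"),
    d_marked = as.numeric(panel$baseline_d == "marked"),
    d_severe = as.numeric(panel$baseline_d == "severe"),
    not_splenectomized = as.numeric(panel$spleen == "intact")
  )
  colnames(X)[1:8] <- paste0("prev_", 2:9)
  X
}

#' Ordered-logit log-likelihood of a state panel
#'
#' Evaluates the proportional-odds log-likelihood of observed annual
#' transitions under a given coefficient set: each row contributes
#' `log(P(rank = state))` from [category_probabilities()] at that row's
#' linear predictor. Useful for verifying fitted models against a direct
#' likelihood evaluation.
#'
#' @param panel A state panel (see [simulate_panel()] for the schema).
#' @param coefs A [transition_coefficients()] object.
#' @return The log-likelihood (a single number).
#' @export
transition_loglik <- function(panel, coefs) {
  stopifnot(inherits(coefs, "transition_coefficients"))
  ll <- 0
  for (i in seq_len(nrow(panel))) {
    key <- scenario_key(panel$years_on_tx[i], panel$baseline_d[i],
                        panel$spleen[i])
    p <- category_probabilities(linear_predictor(panel$prev_state[i], key,
                                                 coefs), coefs$cutpoints)
    ll <- ll + log(p[[as.integer(panel$state[i])]])
  }
  ll
}

# Per-observation score of the proportional-odds log-likelihood at
# (beta, zeta); columns ordered as c(colnames(X), cutpoints 1..8).
polr_scores <- function(X, y, beta, zeta) {
  eta <- as.numeric(X %*% beta)
  K <- length(zeta) + 1L
  z <- c(-Inf, zeta, Inf)
  Fk <- stats::plogis(z[y + 1L] - eta)       # F(zeta_k - eta)
  Fk1 <- stats::plogis(z[y] - eta)           # F(zeta_{k-1} - eta)
  fk <- stats::dlogis(z[y + 1L] - eta)
  fk1 <- stats::dlogis(z[y] - eta)
  p <- Fk - Fk1
  dl_deta <- -(fk - fk1) / p
  S <- X * dl_deta
  Sz <- matrix(0, nrow(X), K - 1L)
  for (k in seq_len(K - 1L)) {
    Sz[, k] <- (fk * (y == k) - fk1 * (y == k + 1L)) / p
  }
  cbind(S, Sz)
}

cluster_meat <- function(scores, cluster) {
  cs <- rowsum(scores, group = cluster)
  crossprod(as.matrix(cs))
}

# Observed information at (beta, zeta): central-difference Jacobian of the
# analytic total score. polr's own optim() Hessian is a finite difference
# of the log-likelihood and is too inaccurate for closely spaced cutpoints,
# so it is not used.
polr_information <- function(X, y, beta, zeta, h = 1e-6) {
  k <- length(beta) + length(zeta)
  th <- c(beta, zeta)
  total <- function(th) {
    colSums(polr_scores(X, y, th[seq_along(beta)],
                        th[length(beta) + seq_along(zeta)]))
  }
  H <- matrix(0, k, k)
  for (j in seq_len(k)) {
    e <- rep(0, k); e[j] <- h
    H[, j] <- (total(th + e) - total(th - e)) / (2 * h)
  }
  -(H + t(H)) / 2
}

#' Fit the annual transition model to a longitudinal state panel
#'
#' Maximum-likelihood proportional-odds (ordered logistic) regression of
#' the current-year state rank on the previous-year state, years on
#' treatment, baseline DS3 category and splenectomy status, with
#' standard errors robust to heteroscedasticity and to repeated
#' observations per patient (cluster-robust sandwich, clustered by
#' patient). Point estimation delegates to [MASS::polr()]; the
#' per-cluster scores and the sandwich are computed analytically.
#'
#' @param panel A state panel (schema as produced by [simulate_panel()]).
#' @return A list of class `gd1_transition_fit` with elements
#'   `coefficients` (a [transition_coefficients()] object), `se` (named
#'   cluster-robust standard errors, slopes then cutpoints), `vcov`,
#'   `loglik`, `n_patients`, `n_obs`, and `fit` (the underlying `polr`
#'   object).
#' @export
fit_transition_model <- function(panel) {
  y <- as.integer(panel$state)
  if (length(unique(y)) < 2L) {
    stop("transition panel is degenerate: a single outcome category (rank ",
         unique(y), ") was observed", call. = FALSE)
  }
  missing_out <- setdiff(1:9, unique(y))
  if (length(missing_out)) {
    stop("outcome rank(s) ", paste(missing_out, collapse = ", "),
         " unobserved; the 9-category cutpoint layout cannot be estimated",
         call. = FALSE)
  }
  X <- transition_design(panel)
  unseen <- colnames(X)[colSums(X) == 0]
  if (length(unseen)) {
    stop("predictor level(s) unobserved in the panel: ",
         paste(unseen, collapse = ", "), call. = FALSE)
  }
  df <- data.frame(.y = factor(y, levels = 1:9), X, check.names = FALSE)
  fml <- stats::reformulate(sprintf("`%s`", colnames(X)), response = ".y")
  fit <- tryCatch(
    MASS::polr(fml, data = df, method = "logistic"),
    error = function(e) stop("ordered-logit fit failed (possible separation ",
                             "or non-convergence): ", conditionMessage(e),
                             call. = FALSE)
  )
  beta <- stats::setNames(fit$coefficients, colnames(X))
  zeta <- unname(fit$zeta)
  scores <- polr_scores(X, y, beta, zeta)
  M <- cluster_meat(scores, panel$patient)
  Hinv <- solve(polr_information(X, y, beta, zeta))
  V <- Hinv %*% M %*% Hinv
  nm <- c(colnames(X), paste0("cutpoint_", 1:8))
  dimnames(V) <- list(nm, nm)
  coefs <- transition_coefficients(
    prev_state = stats::setNames(beta[paste0("prev_", 2:9)], as.character(2:9)),
    years_on_tx = stats::setNames(beta[c("years_2", "years_3plus")],
                                  c("2", "3plus")),
    baseline_d = stats::setNames(beta[c("d_moderate", "d_marked", "d_severe")],
                                 c("moderate", "marked", "severe")),
    not_splenectomized = unname(beta["not_splenectomized"]),
    cutpoints = zeta
  )
  structure(list(coefficients = coefs,
                 se = stats::setNames(sqrt(diag(V)), nm),
                 vcov = V,
                 loglik = as.numeric(stats::logLik(fit)),
                 n_patients = length(unique(panel$patient)),
                 n_obs = nrow(panel),
                 fit = fit),
            class = "gd1_transition_fit")
}

#' @export
print.gd1_transition_fit <- function(x, ...) {
  cat(sprintf(
    "Proportional-odds transition model: %d observations, %d patients\n",
    x$n_obs, x$n_patients))
  cat(sprintf("Log-likelihood %.2f; cluster-robust SEs (by patient)\n",
              x$loglik))
  print(x$coefficients)
  invisible(x)
}

# Utility design matrix mirroring the utility coefficient layout.
utility_design <- function(panel) {
  D <- t(vapply(as.integer(panel$state), utility_design_row, numeric(5)))
  cbind(D, female = as.numeric(panel$female),
        age_at_init = as.numeric(panel$age_at_init))
}

#' Fit the health-state utility regression to a utility panel
#'
#' Linear (identity-link) regression of observed utilities on the DS3
#' severity contrasts, bone pain, SSC, sex and age at treatment
#' initiation. With an independence working correlation and identity
#' link, the GEE point estimates coincide with ordinary least squares;
#' repeated observations per patient are handled by cluster-robust
#' standard errors ([sandwich::vcovCL()], clustered by patient). The
#' estimation-sample means of the female flag and age are stored in the
#' returned coefficients for recycled predictions.
#'
#' @param panel A utility panel (schema as produced by
#'   [simulate_utility_panel()]).
#' @return A list of class `gd1_utility_fit` with elements `coefficients`
#'   (a [utility_coefficients()] object), `se`, `vcov`, `n_patients`,
#'   `n_obs`, and `fit` (the underlying `lm`).
#' @export
fit_utility_model <- function(panel) {
  if (length(unique(panel$patient)) < 2L) {
    stop("at least two patients are required", call. = FALSE)
  }
  X <- utility_design(panel)
  df <- data.frame(.u = as.numeric(panel$utility), X, check.names = FALSE)
  fml <- stats::reformulate(sprintf("`%s`", colnames(X)), response = ".u")
  fit <- stats::lm(fml, data = df)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop("collinear utility design: coefficient(s) not estimable: ",
         paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
  }
  V <- sandwich::vcovCL(fit, cluster = panel$patient)
  nm <- c("constant", colnames(X))
  names(cf) <- nm
  dimnames(V) <- list(nm, nm)
  coefs <- utility_coefficients(
    constant = unname(cf["constant"]),
    d_moderate = unname(cf["d_moderate"]),
    d_marked = unname(cf["d_marked"]),
    d_severe = unname(cf["d_severe"]),
    bone_pain = unname(cf["bone_pain"]),
    ssc = unname(cf["ssc"]),
    female = unname(cf["female"]),
    age_at_init = unname(cf["age_at_init"]),
    mean_female = mean(as.numeric(panel$female)),
    mean_age = mean(as.numeric(panel$age_at_init))
  )
  structure(list(coefficients = coefs,
                 se = stats::setNames(sqrt(diag(V)), nm),
                 vcov = V,
                 n_patients = length(unique(panel$patient)),
                 n_obs = nrow(panel),
                 fit = fit),
            class = "gd1_utility_fit")
}

#' @export
print.gd1_utility_fit <- function(x, ...) {
  cat(sprintf("Utility regression (identity link): %d observations, %d patients\n",
              x$n_obs, x$n_patients))
  cat("Cluster-robust SEs (by patient)\n")
  print(x$coefficients)
  invisible(x)
}
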