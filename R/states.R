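#' The nine ranked GD1 health states
#'
#' The alive health-state space is built from the DS3 total-score severity
#' category (mild, moderate, marked, severe) crossed with bone involvement:
#' within the mild band, bone pain (BP) and severe skeletal complications
#' (SSC; lytic lesions, avascular necrosis, or fracture) are distinguished;
#' the moderate, marked and severe bands distinguish only the presence of
#' SSC. The resulting nine mutually exclusive states are rank ordered from
#' least (1) to most (9) severe; this ordering is the outcome scale of the
#' ordinal transition regression. Death is handled separately by the
#' mortality and Markov modules and is represented as index 10 in cohort
#' traces, never as an ordinal outcome category.
#'
#' @return A data frame with 9 rows and columns `rank` (integer 1..9),
#'   `name` (label used in printed tables), `severity` (factor level among
#'   mild/moderate/marked/severe) and `bone` (none/BP/SSC).
#' @examples
#' health_states()
#' @export
health_states <- function() {
  data.frame(
    rank = 1:9,
    name = c("Mild", "Mild with BP", "Mild with SSC",
             "Moderate", "Moderate with SSC",
             "Marked", "Marked with SSC",
             "Severe", "Severe with SSC"),
    severity = c("mild", "mild", "mild", "moderate", "moderate",
                 "marked", "marked", "severe", "severe"),
    bone = c("none", "BP", "SSC", "none", "SSC", "none", "SSC", "none", "SSC"),
    stringsAsFactors = FALSE
  )
}

#' Resolve a health state by rank or by name
#'
#' @param state An integer rank in 1..9, or a state name as printed by
#'   [health_states()] (case-insensitive).
#' @return A one-row data frame with columns `rank`, `name`, `severity`,
#'   `bone`.
#' @examples
#' health_state(9)
#' health_state("marked with ssc")
#' @export
health_state <- function(state) {
  hs <- health_states()
  if (is.numeric(state)) {
    if (length(state) != 1L || is.na(state) || state != as.integer(state) ||
        state < 1L || state > 9L) {
      stop("state rank must be a single integer in 1..9", call. = FALSE)
    }
    return(hs[as.integer(state), , drop = FALSE])
  }
  if (is.character(state)) {
    i <- match(tolower(state), tolower(hs$name))
    if (is.na(i)) {
      stop("unknown health state: ", state, call. = FALSE)
    }
    return(hs[i, , drop = FALSE])
  }
  stop("state must be a rank (1..9) or a state name", call. = FALSE)
}

#' @rdname health_state
#' @export
state_severity <- function(state) health_state(state)$severity

# Dead occupies index 10 in cohort traces; kept out of the ordinal scale.
DEAD_INDEX <- 10L
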