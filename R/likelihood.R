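# Hidden-Markov likelihood of coded capture histories, conditioned on first
# capture as a juvenile at age zero.

# Internal: arrays + C++ forward pass for a whole set.
.set_loglik <- function(design, theta, set, compiled = compile_design(design),
                        per_individual = FALSE) {
  years <- set$years
  max_age <- max(years) - min(set$birth_years)
  arr <- .model_arrays(design, theta, compiled, max_age, years)
  birth_col <- match(set$birth_years, years)
  ll <- forward_loglik_cpp(
    set$events, birth_col,
    as.numeric(arr$M), as.numeric(arr$E), dim(arr$M)[3L]
  )
  if (per_individual) ll else sum(ll)
}

#' Log-likelihood of a capture history set under a design and coefficients
#'
#' Sums the forward-algorithm contribution of every history. Histories that
#' are impossible under `theta` contribute `-Inf`.
#'
#' @param design A [model_design()].
#' @param theta Coefficient vector on the link scale (length `K` of the
#'   compiled design).
#' @param set A `capture_history_set`.
#' @param per_individual Return the vector of per-history contributions
#'   instead of their sum.
#' @return A numeric scalar (or vector).
#' @export
mecmr_loglik <- function(design, theta, set, per_individual = FALSE) {
  compiled <- compile_design(design)
  if (length(theta) != compiled$K) {
    stop("theta must have length K = ", compiled$K, call. = FALSE)
  }
  .set_loglik(design, theta, set, compiled, per_individual)
}

#' Log-likelihood contribution of a single capture history
#'
#' Forward-algorithm value for one history given as the event codes from the
#' birth year onward. The first event must be code 1 (the model conditions
#' on first capture as a juvenile at age zero), so a history of length one
#' contributes exactly zero.
#'
#' @param events Integer vector of event codes (0-5) starting in the birth
#'   year.
#' @param design A [model_design()].
#' @param theta Coefficient vector on the link scale.
#' @param birth_year Calendar year of birth (defaults to 0; only matters for
#'   designs with year-block detection).
#' @return The log-likelihood contribution; `-Inf` (with attribute
#'   `impossible = TRUE`) if the history has probability zero under `theta`.
#' @export
history_loglik <- function(events, design, theta, birth_year = 0L) {
  years <- birth_year + seq_along(events) - 1L
  set <- capture_history_set(
    ids = "h1", birth_years = birth_year,
    events = matrix(as.integer(events), nrow = 1L),
    years = years, validate = FALSE
  )
  ll <- mecmr_loglik(design, theta, set, per_individual = TRUE)[1L]
  if (is.infinite(ll) && ll < 0) attr(ll, "impossible") <- TRUE
  ll
}
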