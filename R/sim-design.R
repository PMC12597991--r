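# The model design corresponding to the generative model of sim_config, and
# the generating coefficient vector on the link scale. Refitting this design
# to a simulated cohort is the package's parameter-recovery surface.

#' Model design of the synthetic-cohort generative process
#'
#' Quadratic-logistic recruitment, linear-logistic survival on standardized
#' age, quality-stratified linear-logistic arrival and departure, constant
#' subadult detection, quality-stratified year-block adult detection
#' (baseline vs hurricane block) and constant dead recovery.
#'
#' @param config A `sim_config`.
#' @param label Model label for comparison tables.
#' @return A [model_design()].
#' @export
generating_design <- function(config, label = "generating") {
  years <- seq(config$birth_year_range[1L], config$study_end)
  blocks <- list(
    baseline = setdiff(years, config$hurricane_years),
    hurricane = intersect(config$hurricane_years, years)
  )
  if (length(blocks$hurricane) == 0L) blocks <- blocks["baseline"]
  model_design(
    phi = param_form("phi",
      age_form = "linear",
      age_center = config$surv_age_center, age_scale = config$surv_age_scale
    ),
    psiB = param_form("psiB", age_form = "linear", by_quality = TRUE),
    psiNB = param_form("psiNB", age_form = "linear", by_quality = TRUE),
    psiR = param_form("psiR", age_form = "quadratic"),
    pSA = param_form("pSA"),
    p = param_form("p", by_quality = TRUE, time_form = "blocks", blocks = blocks),
    pFD = param_form("pFD"),
    label = label
  )
}

#' Generating coefficient vector of a simulation configuration
#'
#' The link-scale coefficients of [generating_design()] whose implied
#' probabilities are exactly those the simulator draws from.
#'
#' @param config A `sim_config`.
#' @return A named numeric vector matching the compiled design layout.
#' @export
theta_from_config <- function(config) {
  design <- generating_design(config)
  compiled <- compile_design(design)
  det <- config$detect_by_block_and_quality
  p_lo <- qlogis(det["lo", "baseline"])
  p_hi <- qlogis(det["hi", "baseline"])
  has_hurr <- length(intersect(config$hurricane_years,
    seq(config$birth_year_range[1L], config$study_end))) > 0L
  p_block_lo <- if (has_hurr) c(p_lo, qlogis(det["lo", "hurricane"])) else p_lo
  p_block_hi <- if (has_hurr) c(p_hi, qlogis(det["hi", "hurricane"])) else p_hi
  theta <- c(
    config$surv_coeffs,
    config$arrival_coeffs_by_quality$lo,
    config$arrival_coeffs_by_quality$hi,
    config$departure_coeffs_by_quality$lo,
    config$departure_coeffs_by_quality$hi,
    config$recruit_coeffs,
    qlogis(config$p_subadult),
    p_block_lo,
    p_block_hi,
    qlogis(config$p_dead_recovery)
  )
  if (length(theta) != compiled$K) {
    stop("internal error: generating theta does not match compiled design",
      call. = FALSE
    )
  }
  setNames(theta, compiled$labels)
}
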