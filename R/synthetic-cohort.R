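# Synthetic cohort generator: individual life histories and coded capture
# histories drawn from the generative model the likelihood describes, with
# known truth, so every downstream stage has a parameter-recovery surface.
# The population is the conditional one the likelihood is written for:
# pre-recruitment individuals survive with probability one.

#' Build a simulation configuration
#'
#' All structural parameters of the generative model. Age-dependent
#' parameters are linear- or quadratic-logistic in age (years); survival
#' uses a standardized age `z = (age - center) / scale` so its slope is
#' reported per standardized unit, the convention under which fitted
#' survival slopes are usually printed.
#'
#' @param n_individuals Cohort size.
#' @param birth_year_range Length-2 integer vector of first and last birth
#'   years.
#' @param study_end Final occasion year.
#' @param quality_mix Proportion of high-quality recruits in \[0, 1\].
#' @param recruit_coeffs Quadratic-logistic coefficients (b0, b1, b2) for
#'   recruitment psiR(age); the implied probability must stay at or below
#'   1/3 at every age (three simultaneous exit routes from J share one
#'   value).
#' @param surv_coeffs Linear-logistic (b0, b1) for adult survival phi(age).
#' @param surv_age_center,surv_age_scale Standardization of age in the
#'   survival form.
#' @param arrival_coeffs_by_quality,departure_coeffs_by_quality Named lists
#'   (`lo`, `hi`) of linear-logistic (b0, b1) for the arrival psiB(age) and
#'   departure psiNB(age) transitions per quality class.
#' @param detect_by_block_and_quality 2x2 matrix of adult detection
#'   probabilities, rows `lo`/`hi` quality, columns `baseline`/`hurricane`
#'   year blocks.
#' @param hurricane_years Years forming the distinct low-detection block.
#' @param p_subadult Subadult detection probability.
#' @param p_dead_recovery Probability a death year yields a dead recovery.
#' @param fecundity List with `mean_clutches` (mean of the positive clutch
#'   count per season), `max_clutches` (cap), `mean_clutch_size`,
#'   `sd_clutch_size`.
#' @param seed Optional default seed used by the simulators.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 500L,
                       birth_year_range = c(1966L, 2002L),
                       study_end = 2018L,
                       quality_mix = 0.5,
                       recruit_coeffs = c(-9.167336, 0.9646657, -0.03014580),
                       surv_coeffs = c(2.746256, -0.49),
                       surv_age_center = 22,
                       surv_age_scale = 8,
                       arrival_coeffs_by_quality = list(
                         lo = c(0.03364006, -0.04363677),
                         hi = c(1.86803853, -0.03543366)
                       ),
                       departure_coeffs_by_quality = list(
                         lo = c(0.85347853, -0.02635373),
                         hi = c(-0.40181485, -0.02620488)
                       ),
                       detect_by_block_and_quality = matrix(
                         c(0.94, 0.50, 0.975, 0.60),
                         nrow = 2, byrow = TRUE,
                         dimnames = list(c("lo", "hi"), c("baseline", "hurricane"))
                       ),
                       hurricane_years = c(2002L, 2003L),
                       p_subadult = 0.99,
                       p_dead_recovery = 0.5,
                       fecundity = list(
                         mean_clutches = 3.5, max_clutches = 10,
                         mean_clutch_size = 110, sd_clutch_size = 15
                       ),
                       seed = NULL) {
  cfg <- structure(
    list(
      n_individuals = as.integer(n_individuals),
      birth_year_range = as.integer(birth_year_range),
      study_end = as.integer(study_end),
      quality_mix = quality_mix,
      recruit_coeffs = recruit_coeffs,
      surv_coeffs = surv_coeffs,
      surv_age_center = surv_age_center,
      surv_age_scale = surv_age_scale,
      arrival_coeffs_by_quality = arrival_coeffs_by_quality,
      departure_coeffs_by_quality = departure_coeffs_by_quality,
      detect_by_block_and_quality = detect_by_block_and_quality,
      hurricane_years = as.integer(hurricane_years),
      p_subadult = p_subadult,
      p_dead_recovery = p_dead_recovery,
      fecundity = fecundity,
      seed = seed
    ),
    class = "sim_config"
  )
  validate_config(cfg)
  cfg
}

#' Default simulation configuration anchored to the fitted study estimates
#'
#' The defaults reproduce the point estimates of the motivating study
#' system: recruitment is quadratic-logistic with probability 0.02 at age 7
#' rising to 0.19 at age 16 (its maximum); adult survival averages 0.91
#' across ages 7-45 and declines with age with logit slope -0.49 per
#' standardized age unit; the high-quality arrival probability falls from
#' 0.78 at age 17 to 0.66 at age 34 and the low-quality one from 0.33 to
#' 0.19; adult detection is 0.94/0.975 (low/high quality) with a distinct
#' drop in the 2002-2003 hurricane block; dead recovery is 0.5; breeders
#' lay up to 10 clutches of roughly 110 (SD 15) eggs.
#'
#' @param ... Overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
default_config <- function(...) {
  sim_config(...)
}

#' Validate a simulation configuration
#'
#' @param config A `sim_config`.
#' @return `config`, invisibly; errors describe the offending field.
#' @export
validate_config <- function(config) {
  probs <- c(
    config$quality_mix, config$detect_by_block_and_quality,
    config$p_subadult, config$p_dead_recovery
  )
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (config$birth_year_range[1L] > config$birth_year_range[2L] ||
    config$birth_year_range[2L] > config$study_end) {
    stop("birth years must precede the study end", call. = FALSE)
  }
  ages <- 0:(config$study_end - config$birth_year_range[1L])
  rec <- logistic_age(config$recruit_coeffs, ages)
  if (any(rec > 1 / 3)) {
    stop("recruitment probability exceeds 1/3 at age ",
      ages[which(rec > 1 / 3)[1L]],
      call. = FALSE
    )
  }
  if (config$n_individuals < 1L) stop("need at least one individual", call. = FALSE)
  invisible(config)
}

# Parameter lookups used by the simulator.
.cfg_phi <- function(config, age) {
  logistic_age(
    config$surv_coeffs, age,
    config$surv_age_center, config$surv_age_scale
  )
}
.cfg_detect <- function(config, quality, year) {
  block <- ifelse(year %in% config$hurricane_years, "hurricane", "baseline")
  config$detect_by_block_and_quality[cbind(quality, block)]
}

#' Simulate a cohort of life histories and coded capture histories
#'
#' Each individual starts in the juvenile state in its birth year and is
#' always detected as a juvenile (code 1). Annual updates draw, in order,
#' survival (pre-recruitment states survive with probability one, matching
#' the conditioning of the likelihood), the state transition (recruitment
#' splits J/SA exits between the two breeder quality classes, which are
#' fixed for life once assigned), and the observation event. Dead
#' individuals pass through freshly-dead (FD), in which year alone a dead
#' recovery (code 5) may be observed, then remain dead and unobserved.
#' Individuals alive at the study end are right-censored.
#'
#' @param config A `sim_config`.
#' @param seed Integer seed (defaults to `config$seed`).
#' @return A list with `truth` (a list: `quality`, `recruit_age`,
#'   `death_year`, `states` matrix over the state space, `years`) and
#'   `histories` (a validated `capture_history_set`).
#' @export
simulate_cohort <- function(config, seed = config$seed) {
  validate_config(config)
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_individuals
  years <- seq(config$birth_year_range[1L], config$study_end)
  nyr <- length(years)
  byrs <- seq(config$birth_year_range[1L], config$birth_year_range[2L])
  birth <- byrs[sample.int(length(byrs), n, replace = TRUE)]
  ids <- sprintf("ind%04d", seq_len(n))
  # state codes 1..8 follow the package state order J SA NB- NB+ B- B+ FD D
  states <- matrix(NA_integer_, n, nyr, dimnames = list(ids, years))
  events <- matrix(NA_integer_, n, nyr, dimnames = list(ids, years))
  states[cbind(seq_len(n), match(birth, years))] <- 1L
  for (t in seq_len(nyr - 1L)) {
    yr <- years[t]
    born_next <- which(birth == years[t + 1L])
    states[cbind(born_next, rep(t + 1L, length(born_next)))] <- 1L
    cur <- states[, t]
    act <- which(!is.na(cur))
    if (length(act) == 0L) next
    s <- cur[act]
    age <- yr - birth[act]
    nxt <- s
    # survival step: adults may die; FD moves to D; J/SA survive surely
    adult <- s %in% 3:6
    if (any(adult)) {
      phi <- .cfg_phi(config, age[adult])
      dies <- runif(sum(adult)) > phi
      nxt[adult][dies] <- 7L
    }
    nxt[s == 7L] <- 8L
    # transition step, conditional on survival
    live <- which(nxt == s & s %in% 1:6)
    if (length(live) > 0L) {
      sl <- s[live]
      al <- age[live]
      u <- runif(length(live))
      rec <- logistic_age(config$recruit_coeffs, al)
      hi <- runif(length(live)) < config$quality_mix
      isJ <- sl == 1L
      # J: stay with 1 - 3 psiR, to SA with psiR, to a breeder class with 2 psiR
      nxt[live][isJ & u < rec] <- 2L
      toB <- isJ & u >= rec & u < 3 * rec
      nxt[live][toB] <- ifelse(hi[toB], 6L, 5L)
      isSA <- sl == 2L
      toB <- isSA & u < 2 * rec
      nxt[live][toB] <- ifelse(hi[toB], 6L, 5L)
      arrL <- logistic_age(config$arrival_coeffs_by_quality$lo, al)
      arrH <- logistic_age(config$arrival_coeffs_by_quality$hi, al)
      depL <- logistic_age(config$departure_coeffs_by_quality$lo, al)
      depH <- logistic_age(config$departure_coeffs_by_quality$hi, al)
      nxt[live][sl == 3L & u < arrL] <- 5L
      nxt[live][sl == 4L & u < arrH] <- 6L
      nxt[live][sl == 5L & u < depL] <- 3L
      nxt[live][sl == 6L & u < depH] <- 4L
    }
    states[act, t + 1L] <- nxt
  }
  # observation events per occasion
  for (t in seq_len(nyr)) {
    yr <- years[t]
    s <- states[, t]
    idx <- which(!is.na(s))
    if (length(idx) == 0L) next
    si <- s[idx]
    ev <- integer(length(idx))
    ev[si == 1L] <- 1L
    sa <- si == 2L
    ev[sa] <- ifelse(runif(sum(sa)) < config$p_subadult, 2L, 0L)
    for (code in 3:6) {
      sel <- si == code
      if (!any(sel)) next
      q <- if (code %in% c(3L, 5L)) "lo" else "hi"
      pdet <- .cfg_detect(config, rep(q, sum(sel)), rep(yr, sum(sel)))
      ev[sel] <- ifelse(
        runif(sum(sel)) < pdet,
        if (code %in% 3:4) 3L else 4L, 0L
      )
    }
    fd <- si == 7L
    ev[fd] <- ifelse(runif(sum(fd)) < config$p_dead_recovery, 5L, 0L)
    ev[si == 8L] <- 0L
    events[idx, t] <- ev
  }
  state_labels <- matrix(.states[states],
    nrow = n,
    dimnames = list(ids, years)
  )
  recruit_age <- vapply(seq_len(n), function(i) {
    w <- which(states[i, ] %in% 3:6)[1L]
    if (is.na(w)) NA_integer_ else as.integer(years[w] - birth[i])
  }, integer(1))
  death_year <- vapply(seq_len(n), function(i) {
    w <- which(states[i, ] == 7L)[1L]
    if (is.na(w)) NA_integer_ else as.integer(years[w])
  }, integer(1))
  quality <- vapply(seq_len(n), function(i) {
    w <- which(states[i, ] %in% c(4L, 6L))[1L]
    if (!is.na(w)) {
      return("high")
    }
    w <- which(states[i, ] %in% c(3L, 5L))[1L]
    if (!is.na(w)) "low" else NA_character_
  }, character(1))
  truth <- list(
    ids = ids, birth_years = as.integer(birth), quality = quality,
    recruit_age = recruit_age, death_year = death_year,
    states = state_labels, state_codes = states, years = years
  )
  histories <- capture_history_set(ids, birth, events, years)
  list(truth = truth, histories = histories)
}

# Zero-truncated Poisson draws via the inverse-cdf trick.
#' Draw from a zero-truncated Poisson distribution
#'
#' @param n Number of draws.
#' @param lambda Rate of the untruncated Poisson.
#' @return Integer vector of positive counts.
#' @export
rztpois <- function(n, lambda) {
  qpois(runif(n, dpois(0, lambda), 1), lambda)
}

#' Simulate per-season reproductive output for a cohort
#'
#' For every season an individual spends in a breeder state (restricted to
#' seasons detected as breeding, event code 4, when `histories` is
#' supplied), the clutch count is drawn from a zero-truncated Poisson whose
#' mean matches `fecundity$mean_clutches` (capped at `max_clutches`: a
#' breeder lays at least one and at most the configured maximum), and the
#' egg total is the clutch count times a rounded normal per-clutch size
#' truncated at one.
#'
#' @param truth The `truth` element of a [simulate_cohort()] result.
#' @param config The `sim_config` used to simulate the cohort.
#' @param histories Optional `capture_history_set`; when given, records are
#'   produced only for seasons whose observed event is code 4.
#' @param seed Optional integer seed.
#' @return A `breeding_records` data frame.
#' @export
simulate_breeding_output <- function(truth, config, histories = NULL,
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  b_state <- truth$state_codes %in% c(5L, 6L)
  dim(b_state) <- dim(truth$state_codes)
  if (!is.null(histories)) {
    b_state <- b_state & !is.na(histories$events) & histories$events == 4L
  }
  idx <- which(b_state, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    return(breeding_records(character(), integer(), integer(), integer()))
  }
  fec <- config$fecundity
  lambda <- uniroot(
    function(l) l / (1 - exp(-l)) - fec$mean_clutches,
    c(1e-8, 1e3)
  )$root
  n_cl <- pmin(rztpois(nrow(idx), lambda), fec$max_clutches)
  size <- pmax(1, round(rnorm(nrow(idx), fec$mean_clutch_size, fec$sd_clutch_size)))
  ord <- order(idx[, 1L], idx[, 2L])
  breeding_records(
    truth$ids[idx[ord, 1L]],
    truth$years[idx[ord, 2L]],
    n_cl[ord],
    (n_cl * size)[ord]
  )
}
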