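# Shared fixtures: a tiny hand-built capture-history set, a homogeneous
# (age- and quality-constant) simulation configuration for null
# calibration, and a vectorized exhaustive path-sum oracle for the hidden
# Markov likelihood.

small_set <- function() {
  years <- 1990:1995
  ev <- rbind(
    c(1L, 1L, 2L, 4L, 0L, 4L),
    c(NA, 1L, 1L, 1L, 2L, 3L),
    c(1L, 1L, 4L, 0L, 5L, 0L)
  )
  capture_history_set(c("a", "b", "c"), c(1990L, 1991L, 1990L), ev, years)
}

# Homogeneous generative model: constant survival/transitions/detection and
# identical quality classes, used wherever the first-order Markov null must
# hold exactly.
null_sim_config <- function(n = 500L, birth_year_range = c(1970L, 1985L),
                            study_end = 2000L, ...) {
  sim_config(
    n_individuals = n,
    birth_year_range = birth_year_range,
    study_end = study_end,
    quality_mix = 0.5,
    recruit_coeffs = c(qlogis(0.15), 0, 0),
    surv_coeffs = c(qlogis(0.9), 0),
    surv_age_center = 0, surv_age_scale = 1,
    arrival_coeffs_by_quality = list(
      lo = c(qlogis(0.5), 0), hi = c(qlogis(0.5), 0)
    ),
    departure_coeffs_by_quality = list(
      lo = c(qlogis(0.3), 0), hi = c(qlogis(0.3), 0)
    ),
    detect_by_block_and_quality = matrix(
      c(0.85, 0.85, 0.85, 0.85),
      nrow = 2,
      dimnames = list(c("lo", "hi"), c("baseline", "hurricane"))
    ),
    hurricane_years = integer(0),
    p_subadult = 0.99,
    p_dead_recovery = 0.5,
    ...
  )
}

# Exhaustive path-sum log-likelihood over all 8^(T-1) state sequences,
# fully independent of the forward-algorithm implementation (it only shares
# the probability arrays, whose construction is tested separately).
brute_loglik <- function(events, design, theta, birth_year = 0L) {
  Tn <- length(events)
  if (Tn == 1L) {
    return(0)
  }
  cmp <- compile_design(design)
  years <- birth_year + 0:(Tn - 1L)
  arr <- mecmr:::.model_arrays(design, theta, cmp, Tn, years)
  paths <- as.matrix(expand.grid(rep(list(1:8), Tn - 1L)))
  st <- cbind(1L, paths) # all sequences start in J at birth
  pr <- rep(1, nrow(st))
  for (t in 2:Tn) {
    pr <- pr * arr$M[cbind(st[, t - 1L], st[, t], t - 1L)] *
      arr$E[cbind(st[, t], events[t] + 1L, t)]
  }
  log(sum(pr))
}

# Multivariate normal draws (Cholesky construction).
rmvn <- function(n, mu, sigma) {
  ch <- chol(sigma)
  matrix(rnorm(n * length(mu)), n) %*% ch + rep(mu, each = n)
}

# Random valid link-scale coefficients for the generating design of a
# config: moderate perturbations that keep recruitment below 1/3.
random_theta <- function(config, sd = 0.3) {
  th <- theta_from_config(config)
  repeat {
    cand <- th + rnorm(length(th), 0, sd)
    ages <- 0:(config$study_end - config$birth_year_range[1L])
    rec <- plogis(cand["psiR.b0"] + cand["psiR.b1"] * ages +
      cand["psiR.b2"] * ages^2)
    if (all(rec <= 1 / 3)) {
      return(cand)
    }
  }
}
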