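# Age-classified matrix population model A = U + F assembled from annual
# survival and egg-production schedules, and the life-history traits derived
# from it: growth rate, net reproductive rate, generation time, life
# expectancies, Gini index of iteroparity, reproductive value, and the pace
# and shape of aging and fecundity.
#
# Census convention: birth-pulse with survival-discounted fertilities
# F[1, x] = phi_x * m_{x+1} (a mother of age x survives the projection
# interval, then reproduces at age x + 1; offspring enter as age-0 eggs).
# Under this convention the dominant eigenvalue of A satisfies the discrete
# Euler-Lotka equation sum_x lambda^(-x) l_x m_x = 1 exactly, which keeps
# lambda, R0, generation time and reproductive value mutually consistent.

#' Assemble an age-classified Leslie model
#'
#' The maternity schedule is `mx = (eggs_by_age / 2) / isrp_population` for
#' ages at or above the age at first reproduction: egg counts are halved to
#' female eggs (a 50:50 egg sex ratio) and discounted by the population
#' inter-seasonal reproductive period, because females do not breed
#' annually. Survival occupies the subdiagonal of `U`; fertilities are the
#' survival-discounted `phi_x * m_(x+1)`. Before any trait is computed the
#' matrix is verified irreducible and ergodic on its reproductive core (the
#' classes up to the last positive fertility; a trailing post-reproductive
#' class is tolerated, as is standard for age-classified models).
#'
#' @param phi_by_age Annual survival per age class, ages `0..n-1` (the last
#'   entry, survival out of the final class, is ignored in `U`).
#' @param eggs_by_age Mean egg count per female per breeding season at each
#'   age (both sexes).
#' @param isrp_population Population-level inter-seasonal reproductive
#'   period in years (>= 1).
#' @param afr Minimum age at first reproduction (default 7).
#' @return An object of class `leslie_model` with `U`, `F`, `A`, `lx`,
#'   `mx`, `afr`, `ages`.
#' @export
build_leslie <- function(phi_by_age, eggs_by_age, isrp_population, afr = 7L) {
  n <- length(phi_by_age)
  if (length(eggs_by_age) != n) {
    stop("schedules must cover the same age range", call. = FALSE)
  }
  if (isrp_population < 1) stop("isrp must be >= 1", call. = FALSE)
  if (any(phi_by_age < 0 | phi_by_age > 1)) {
    stop("survival probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(eggs_by_age < 0)) stop("egg counts must be non-negative", call. = FALSE)
  ages <- 0:(n - 1L)
  mx <- ifelse(ages >= afr, eggs_by_age / 2 / isrp_population, 0)
  if (all(mx == 0)) {
    stop("irreducible Leslie model impossible: no reproduction (all mx zero)",
      call. = FALSE
    )
  }
  U <- matrix(0, n, n)
  U[cbind(2:n, 1:(n - 1L))] <- phi_by_age[1:(n - 1L)]
  Fm <- matrix(0, n, n)
  Fm[1L, 1:(n - 1L)] <- phi_by_age[1:(n - 1L)] * mx[2:n]
  A <- U + Fm
  lx <- cumprod(c(1, phi_by_age[1:(n - 1L)]))
  model <- structure(
    list(U = U, F = Fm, A = A, lx = lx, mx = mx, afr = as.integer(afr), ages = ages),
    class = "leslie_model"
  )
  .check_ergodicity(model)
  model
}

# Irreducibility/ergodicity on the reproductive core: classes 1..k with
# k the last class carrying positive fertility must communicate.
.check_ergodicity <- function(model) {
  f <- model$F[1L, ]
  k <- max(which(f > 0))
  core <- model$A[1:k, 1:k, drop = FALSE]
  n <- nrow(core)
  reach <- (core > 0) + diag(n)
  # boolean matrix powers: reachability within n - 1 steps
  acc <- reach
  for (i in seq_len(ceiling(log2(max(n - 1L, 1L))))) {
    acc <- (acc %*% acc) > 0
  }
  if (!all(acc > 0)) {
    bad <- which(rowSums(acc > 0) < n | colSums(acc > 0) < n)
    stop("Leslie matrix is reducible: age classes ",
      paste(bad - 1L, collapse = ", "),
      " do not communicate with the rest of the reproductive core",
      call. = FALSE
    )
  }
  ev <- Mod(eigen(core, only.values = TRUE)$values)
  if (sum(abs(ev - max(ev)) < 1e-12 * max(ev)) > 1L) {
    warning("Leslie matrix may be non-ergodic: dominant eigenvalue not simple",
      call. = FALSE
    )
  }
  invisible(TRUE)
}

#' @export
print.leslie_model <- function(x, ...) {
  g <- growth_rates(x)
  cat(sprintf(
    "Leslie model: %d age classes, AFR %d, lambda = %.4f\n",
    length(x$ages), x$afr, g[["lambda"]]
  ))
  invisible(x)
}

#' Population growth rates of a Leslie model
#'
#' The dominant eigenvalue lambda (refined by Newton steps on the discrete
#' Euler-Lotka equation, which it satisfies to within 1e-8) and the
#' Malthusian rate `r = ln(lambda)`.
#'
#' @param L A `leslie_model`.
#' @return Named numeric vector `c(lambda, r)`.
#' @export
growth_rates <- function(L) {
  ev <- eigen(L$A, only.values = TRUE)$values
  lambda <- max(Re(ev[abs(Im(ev)) < 1e-8]))
  # polish on Euler-Lotka: f(lambda) = sum lambda^(-x) lx mx - 1 = 0
  f <- function(la) sum(la^(-L$ages) * L$lx * L$mx) - 1
  fp <- function(la) sum(-L$ages * la^(-L$ages - 1) * L$lx * L$mx)
  for (i in 1:50) {
    step <- f(lambda) / fp(lambda)
    lambda <- lambda - step
    if (abs(step) < 1e-14 * lambda) break
  }
  c(lambda = lambda, r = log(lambda))
}

#' Net reproductive rate and generation time
#'
#' `R0 = sum(lx mx)` is the expected lifetime production of female eggs per
#' female. Generation time is `ln(R0) / ln(lambda)` (the time for the
#' population to grow by a factor R0); at replacement (`lambda = 1`) it
#' falls back to the fecundity-weighted mean age of offspring production.
#' The stable-age mean parent age `sum(x lambda^-x lx mx)` (the discounted
#' mean age of mothers) is reported alongside.
#'
#' @param L A `leslie_model`.
#' @return A list with `R0`, `T_gen` and `T_stable`.
#' @export
r0_and_generation_time <- function(L) {
  R0 <- sum(L$lx * L$mx)
  if (R0 <= 0) stop("R0 is zero: no reproduction", call. = FALSE)
  g <- growth_rates(L)
  lambda <- g[["lambda"]]
  T_stable <- sum(L$ages * lambda^(-L$ages) * L$lx * L$mx)
  T_gen <- if (abs(lambda - 1) < 1e-10) {
    sum(L$ages * L$lx * L$mx) / R0
  } else {
    log(R0) / log(lambda)
  }
  list(R0 = R0, T_gen = T_gen, T_stable = T_stable)
}

#' Life expectancies from the fundamental matrix
#'
#' `N = (I - U)^-1` counts the expected years spent in each class; column
#' sums give the expected years lived from entry into a class, inclusive of
#' the entry year. `e0` is the column sum for age 0 and `e_adult` the
#' column sum for the age-at-first-reproduction class (expected years lived
#' from maturity onward).
#'
#' @param L A `leslie_model`.
#' @return Named numeric vector `c(e0, e_adult)`.
#' @export
life_expectancies <- function(L) {
  n <- nrow(L$U)
  N <- tryCatch(solve(diag(n) - L$U), error = function(e) {
    stop("singular (I - U): cannot compute life expectancies", call. = FALSE)
  })
  c(e0 = sum(N[, 1L]), e_adult = sum(N[, L$afr + 1L]))
}

#' Gini index of the survivorship-weighted fecundity schedule
#'
#' Measures the concentration of reproduction over ages: values are sorted
#' ascending and `G = 2 sum(i v_i) / (n sum(v)) - (n + 1) / n`. `G = 0`
#' means equal reproduction across all ages (extreme iteroparity); the
#' upper bound `1 - 1/n` is reached when reproduction is isolated in a
#' single age class (semelparity). Invariant to uniform scaling of the
#' schedule.
#'
#' @param lxmx Schedule of survivorship-weighted fecundity values (at least
#'   2 entries, positive sum).
#' @return The Gini index.
#' @export
gini_index <- function(lxmx) {
  if (length(lxmx) < 2L) stop("need at least 2 schedule entries", call. = FALSE)
  if (any(lxmx < 0)) stop("schedule values must be non-negative", call. = FALSE)
  tot <- sum(lxmx)
  if (tot <= 0) stop("Gini undefined for an all-zero schedule", call. = FALSE)
  v <- sort(lxmx)
  n <- length(v)
  2 * sum(seq_len(n) * v) / (n * tot) - (n + 1) / n
}

#' Age-specific reproductive value
#'
#' The discrete analogue of `v_x / v_0 = (lambda^x / l_x) sum_{y >= x}
#' lambda^-y l_y m_y`: the expected future contribution of eggs to the
#' population by an individual of age x, relative to a newborn, discounting
#' offspring by population growth. The residual reproductive value excludes
#' current-age reproduction. `v_0 / v_0 = 1` exactly by the Euler-Lotka
#' normalization.
#'
#' @param L A `leslie_model`.
#' @return A data frame with `age`, `vx` (relative to v0) and `residual`;
#'   ages with zero survivorship are `NA`.
#' @export
reproductive_value <- function(L) {
  lambda <- growth_rates(L)[["lambda"]]
  disc <- lambda^(-L$ages) * L$lx * L$mx
  tail_sum <- rev(cumsum(rev(disc)))
  vx <- ifelse(L$lx > 0, lambda^(L$ages) / L$lx * tail_sum, NA_real_)
  data.frame(age = L$ages, vx = vx, residual = vx - L$mx)
}

#' Pace and shape of aging and fecundity
#'
#' Pace of aging is the adult life expectancy; pace of fecundity is the
#' survivorship-weighted mean age of offspring production minus the age at
#' first reproduction (the age of the mother, beyond maturity, at laying of
#' an average clutch). The shape measures standardize each process free of
#' its timescale: `shape_surv` is the first moment of the area between the
#' adult survivorship curve (age standardized by adult life expectancy) and
#' the constant-hazard survivorship with the same life expectancy — zero
#' for constant hazard and positive when mortality rises with age;
#' `shape_rep` is the mean deviation of the normalized cumulative adult
#' reproduction curve from the constant-fecundity diagonal — zero for
#' age-constant fecundity and negative when late-life output rises.
#'
#' @param L A `leslie_model`.
#' @return A list with `pace_aging`, `pace_fec`, `shape_surv`,
#'   `shape_rep`.
#' @export
pace_shape <- function(L) {
  afr <- L$afr
  adult <- L$ages >= afr
  la <- L$lx[adult] / L$lx[afr + 1L] # adult survivorship, 1 at maturity
  Lad <- sum(la) # adult life expectancy (counts the entry year)
  x <- seq_along(la) - 1L # years since maturity
  # constant-survival benchmark with the same truncated life expectancy
  smax <- length(la) - 1L
  sstar <- if (Lad >= smax + 1) 1 else {
    uniroot(
      function(s) sum(s^x) - Lad,
      c(1e-12, 1 - 1e-12), tol = 1e-14
    )$root
  }
  lstar <- sstar^x
  shape_surv <- sum((x / Lad) * (lstar - la)) / Lad
  m <- L$mx[adult]
  lm <- (L$lx * L$mx)[adult]
  pace_fec <- sum((L$ages[adult] - afr) * lm) / sum(lm)
  cum <- cumsum(m) / sum(m)
  bench <- seq_along(m) / length(m)
  shape_rep <- mean(cum - bench)
  if (sum(m > 0) == 1L) {
    warning("single-age reproduction: shape_rep is at its boundary", call. = FALSE)
  }
  list(
    pace_aging = Lad, pace_fec = pace_fec,
    shape_surv = shape_surv, shape_rep = shape_rep
  )
}
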