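# Goodness-of-fit components: constructed alternatives, degenerate inputs,
# a fast null calibration, and the overdispersion arithmetic.

# A set whose adult detections are laid out explicitly: `pattern` is a
# matrix of adult events (0/3/4) which is prefixed by a juvenile birth
# occasion to satisfy the history invariants.
adult_set <- function(pattern) {
  n <- nrow(pattern)
  ev <- cbind(rep(1L, n), pattern)
  capture_history_set(
    sprintf("i%04d", seq_len(n)), rep(2000L, n), ev,
    2000:(2000L + ncol(pattern))
  )
}

test_that("constructed transience makes 3.SR significant", {
  # at each occasion, newly seen animals are never seen again while
  # previously seen ones always return
  n_per <- 30L
  Tn <- 6L
  blocks <- list()
  # "old" animals: seen at every occasion
  blocks$old <- matrix(4L, n_per, Tn)
  # "new at t" animals: first adult sighting at t, then silence
  for (t in 2:(Tn - 1L)) {
    m <- matrix(0L, n_per, Tn)
    m[, t] <- 4L
    blocks[[paste0("new", t)]] <- m
  }
  set <- adult_set(do.call(rbind, blocks))
  comp <- test_3sr(set)
  expect_gt(comp$df, 0L)
  expect_lt(comp$p_value, 0.001)
})

test_that("tables with sparse expected counts are excluded from 3.SR", {
  # only two animals: every 2x2 has expected counts below 2
  set <- adult_set(rbind(c(4L, 4L, 4L), c(4L, 0L, 4L)))
  expect_warning(comp <- test_3sr(set), "df = 0")
  expect_equal(comp$df, 0L)
  expect_true(is.na(comp$p_value))
})

test_that("constructed delayed re-encounter makes 3.SM significant", {
  n_per <- 40L
  Tn <- 7L
  old <- matrix(4L, n_per, Tn) # wait 1 always
  new_delay <- matrix(0L, n_per, Tn)
  new_delay[, 3L] <- 4L # first seen at 3
  new_delay[, 6L] <- 4L # re-encountered after 3 occasions
  filler <- matrix(0L, n_per, Tn)
  filler[, 1:4] <- 4L # extra previously-seen mass at occasion 3
  set <- adult_set(rbind(old, new_delay, filler))
  comp <- test_3sm(set)
  expect_gt(comp$df, 0L)
  expect_lt(comp$p_value, 0.001)
})

test_that("perfect alternation regardless of current state triggers WBWA", {
  # memory: previous state determines the next state exactly, with both
  # observable states present at the focal occasion
  n_per <- 25L
  mk <- function(p) matrix(rep(p, n_per), n_per, byrow = TRUE)
  # at the middle occasion the next state copies the previous state exactly,
  # within both current states
  set <- adult_set(rbind(
    mk(c(3L, 4L, 3L)), mk(c(4L, 4L, 4L)),
    mk(c(4L, 3L, 4L)), mk(c(3L, 3L, 3L))
  ))
  comp <- test_wbwa(set)
  expect_gt(comp$df, 0L)
  expect_lt(comp$p_value, 0.001)
})

test_that("a single observable state leaves WBWA without freedom", {
  set <- adult_set(matrix(4L, 30, 5))
  expect_warning(comp <- test_wbwa(set), "df = 0")
  expect_equal(comp$df, 0L)
})

test_that("components are calibrated under the homogeneous null", {
  # a fast version of the full calibration: each component's mean
  # chi-square over replicates should sit near its degrees of freedom
  n_reps <- 60L
  ratios <- matrix(NA_real_, n_reps, 3L)
  for (r in seq_len(n_reps)) {
    cfg <- null_sim_config(n = 250L)
    sim <- simulate_cohort(cfg, seed = 5000L + r)
    comps <- suppressWarnings(
      list(test_3sr(sim$histories), test_3sm(sim$histories), test_wbwa(sim$histories))
    )
    ratios[r, ] <- vapply(comps, function(x) {
      if (x$df > 0L) x$chi2 / x$df else NA_real_
    }, numeric(1))
  }
  for (j in 1:3) {
    v <- ratios[, j][!is.na(ratios[, j])]
    expect_gt(length(v), n_reps * 0.8)
    z <- abs(mean(v) - 1) / (sd(v) / sqrt(length(v)))
    expect_lt(z, 4)
  }
})

test_that("components are invariant to ordering and a constant year shift", {
  cfg <- null_sim_config(n = 150L)
  sim <- simulate_cohort(cfg, seed = 99L)
  ref <- suppressWarnings(gof_tests(sim$histories))
  perm <- sample.int(length(sim$histories$ids))
  shuffled <- capture_history_set(
    sim$histories$ids[perm], sim$histories$birth_years[perm],
    sim$histories$events[perm, ], sim$histories$years
  )
  shifted <- capture_history_set(
    sim$histories$ids, sim$histories$birth_years + 100L,
    sim$histories$events, sim$histories$years + 100L
  )
  for (s in list(shuffled, shifted)) {
    out <- suppressWarnings(gof_tests(s))
    expect_equal(out$total$chi2, ref$total$chi2)
    expect_equal(out$total$df, ref$total$df)
  }
})

test_that("c-hat is the chi-square to df ratio, floored at one", {
  worked <- c_hat(gof_component("total-gof", 149.099, 118L))
  expect_equal(round(worked$c_hat, 4), 1.2636)
  expect_equal(c_hat(gof_component("x", 118, 118L))$c_hat, 1)
  under <- c_hat(gof_component("x", 59, 118L))
  expect_equal(under$c_hat, 1)
  expect_equal(under$raw, 0.5)
  expect_error(c_hat(gof_component("x", 0, 0L)), "df is 0")
})
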