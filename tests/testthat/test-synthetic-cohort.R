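# The cohort generator: determinism, the permitted-transition graph, law of
# large numbers against the configured probabilities, and reproductive
# output.

test_that("identical config and seed give identical cohorts", {
  cfg <- default_config(n_individuals = 80, seed = 9)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$truth$state_codes, b$truth$state_codes)
  expect_identical(a$histories$events, b$histories$events)
  r1 <- simulate_breeding_output(a$truth, cfg, histories = a$histories, seed = 4)
  r2 <- simulate_breeding_output(b$truth, cfg, histories = b$histories, seed = 4)
  expect_identical(r1, r2)
})

test_that("default configuration carries the anchored point estimates", {
  cfg <- default_config()
  expect_equal(cfg$surv_coeffs[2L], -0.49)
  # mean adult survival across ages 7-45 is 0.91
  expect_equal(
    mean(logistic_age(cfg$surv_coeffs, 7:45, cfg$surv_age_center, cfg$surv_age_scale)),
    0.91,
    tolerance = 1e-4
  )
  expect_equal(
    logistic_age(cfg$arrival_coeffs_by_quality$hi, 17), 0.78,
    tolerance = 1e-4
  )
  expect_equal(
    logistic_age(cfg$arrival_coeffs_by_quality$hi, 34), 0.66,
    tolerance = 1e-4
  )
  expect_equal(
    logistic_age(cfg$arrival_coeffs_by_quality$lo, c(17, 34)), c(0.33, 0.19),
    tolerance = 1e-4
  )
  expect_equal(logistic_age(cfg$recruit_coeffs, 7), 0.02, tolerance = 1e-4)
  expect_equal(logistic_age(cfg$recruit_coeffs, 16), 0.19, tolerance = 1e-3)
  # recruitment peaks at 16 and stays below the structural bound
  rec <- logistic_age(cfg$recruit_coeffs, 0:52)
  expect_equal(which.max(rec) - 1L, 16L)
  expect_true(all(rec <= 1 / 3))
})

test_that("invalid configurations are rejected before simulation", {
  expect_error(default_config(p_dead_recovery = 1.2), "\\[0, 1\\]")
  expect_error(
    default_config(recruit_coeffs = c(qlogis(0.4), 0, 0)),
    "1/3"
  )
  expect_error(
    default_config(birth_year_range = c(2010, 2020), study_end = 2005),
    "precede"
  )
})

test_that("state sequences obey the permitted-transition graph", {
  cfg <- default_config(n_individuals = 300, seed = 21)
  sim <- simulate_cohort(cfg)
  st <- sim$truth$state_codes
  allowed <- list(
    `1` = c(1L, 2L, 5L, 6L), `2` = c(2L, 5L, 6L),
    `3` = c(3L, 5L, 7L), `4` = c(4L, 6L, 7L),
    `5` = c(3L, 5L, 7L), `6` = c(4L, 6L, 7L),
    `7` = 8L, `8` = 8L
  )
  for (i in seq_len(nrow(st))) {
    s <- st[i, !is.na(st[i, ])]
    if (length(s) < 2L) next
    for (t in seq_len(length(s) - 1L)) {
      expect_true(s[t + 1L] %in% allowed[[as.character(s[t])]])
    }
  }
  # quality fixed at recruitment: no individual visits both class pairs
  lo <- rowSums(st == 3L | st == 5L, na.rm = TRUE) > 0
  hi <- rowSums(st == 4L | st == 6L, na.rm = TRUE) > 0
  expect_false(any(lo & hi))
  # juveniles always produce event 1; dead recovery only in the FD year
  ev <- sim$histories$events
  expect_true(all(ev[!is.na(st) & st == 1L] == 1L))
  expect_true(all(st[!is.na(ev) & ev == 5L] == 7L))
})

test_that("degenerate parameters pin breeders to annual detection", {
  cfg <- default_config(
    n_individuals = 100, seed = 2,
    departure_coeffs_by_quality = list(lo = c(-40, 0), hi = c(-40, 0)),
    detect_by_block_and_quality = matrix(1, 2, 2,
      dimnames = list(c("lo", "hi"), c("baseline", "hurricane"))
    ),
    p_subadult = 1
  )
  sim <- simulate_cohort(cfg)
  st <- sim$truth$state_codes
  ev <- sim$histories$events
  breeder <- !is.na(st) & (st == 5L | st == 6L)
  expect_true(all(ev[breeder] == 4L))
})

test_that("empirical transition frequencies match the configured values", {
  cfg <- default_config(n_individuals = 4000, seed = 31)
  sim <- simulate_cohort(cfg)
  st <- sim$truth$state_codes
  yrs <- sim$truth$years
  ages <- outer(sim$truth$birth_years, yrs, function(b, y) y - b)
  check_rate <- function(from_codes, to_codes, prob_fn) {
    num <- 0
    expected <- 0
    varsum <- 0
    for (t in seq_len(ncol(st) - 1L)) {
      sel <- which(!is.na(st[, t]) & st[, t] %in% from_codes)
      if (length(sel) == 0L) next
      p <- prob_fn(ages[sel, t])
      num <- num + sum(st[sel, t + 1L] %in% to_codes)
      expected <- expected + sum(p)
      varsum <- varsum + sum(p * (1 - p))
    }
    abs(num - expected) / sqrt(varsum)
  }
  # pooled adult survival against the occupancy-weighted generating value
  z_surv <- check_rate(3:6, 3:6, function(a) mecmr:::.cfg_phi(cfg, a))
  expect_lt(z_surv, 3)
  # arrival by quality (conditional on survival)
  z_arr_lo <- check_rate(3L, 5L, function(a) {
    mecmr:::.cfg_phi(cfg, a) * logistic_age(cfg$arrival_coeffs_by_quality$lo, a)
  })
  z_arr_hi <- check_rate(4L, 6L, function(a) {
    mecmr:::.cfg_phi(cfg, a) * logistic_age(cfg$arrival_coeffs_by_quality$hi, a)
  })
  expect_lt(z_arr_lo, 3)
  expect_lt(z_arr_hi, 3)
  # recruitment out of J (both breeder classes plus the subadult route)
  z_rec <- check_rate(1L, c(2L, 5L, 6L), function(a) {
    3 * logistic_age(cfg$recruit_coeffs, a)
  })
  expect_lt(z_rec, 3)
})

test_that("reproductive output has the configured seasonal mean", {
  cfg <- default_config(
    n_individuals = 800, seed = 41,
    fecundity = list(
      mean_clutches = 5, max_clutches = 50,
      mean_clutch_size = 100, sd_clutch_size = 10
    )
  )
  sim <- simulate_cohort(cfg)
  rec <- simulate_breeding_output(sim$truth, cfg, seed = 42)
  expect_gt(nrow(rec), 1000)
  expect_equal(mean(rec$n_eggs), 500, tolerance = 0.02)
  expect_true(all(rec$n_clutches >= 1L))
  # records are restricted to detected breeding seasons when histories given
  rec2 <- simulate_breeding_output(sim$truth, cfg,
    histories = sim$histories, seed = 42
  )
  ev_at <- sim$histories$events[cbind(
    match(rec2$individual_id, sim$truth$ids),
    match(rec2$season_year, sim$truth$years)
  )]
  expect_true(all(ev_at == 4L))
  # an individual that never breeds has no records
  nb <- setdiff(sim$truth$ids, rec$individual_id)
  if (length(nb) > 0L) {
    expect_false(any(sim$truth$state_codes[match(nb[1], sim$truth$ids), ] %in% 5:6))
  }
})
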