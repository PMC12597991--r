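# Interval construction, the cluster-robust Cox stage and the
# zero-truncated Poisson stage.

# a small hand-built pair of records/histories
toy_intervals <- function() {
  years <- 2000:2016
  ev <- matrix(0L, 2, length(years))
  ev[1, 1] <- 1L
  ev[1, c(11, 12, 15)] <- 4L # breeding at ages 10, 11, 14
  ev[2, 1] <- 1L
  ev[2, 9] <- 4L # single breeding year at age 8
  hist <- capture_history_set(c("a", "b"), c(2000L, 2000L), ev, years)
  rec <- breeding_records(
    c("a", "a", "a", "b"),
    c(2010L, 2011L, 2014L, 2008L),
    c(3L, 2L, 4L, 1L),
    c(300L, 190L, 410L, 95L)
  )
  list(records = rec, histories = hist)
}

test_that("interval construction yields closed and censored rows", {
  tt <- toy_intervals()
  tab <- build_interval_table(tt$records, tt$histories)
  a <- tab[tab$individual_id == "a", ]
  expect_equal(a$interval_years[!a$censored], c(1L, 3L))
  expect_equal(a$experience[!a$censored], c(1L, 2L))
  expect_equal(a$age_at_start[!a$censored], c(10L, 11L))
  expect_equal(a$afr, rep(10L, 3L))
  expect_equal(a$clutches_cumulative[!a$censored], c(3L, 5L))
  # censored tail from the last breeding year to the study end
  expect_equal(a$interval_years[a$censored], 2016L - 2014L)
  b <- tab[tab$individual_id == "b", ]
  expect_true(all(b$censored))
  expect_equal(nrow(b), 1L)
  # no breeding -> empty table
  empty <- build_interval_table(
    breeding_records(character(), integer(), integer(), integer()),
    tt$histories
  )
  expect_equal(nrow(empty), 0L)
})

test_that("records in years without a breeder detection are rejected", {
  tt <- toy_intervals()
  bad <- breeding_records("a", 2012L, 1L, 100L)
  expect_error(build_interval_table(bad, tt$histories), "without a breeder")
})

test_that("a censored interval ends at the dead-recovery year", {
  years <- 2000:2010
  ev <- matrix(0L, 1, 11)
  ev[1, 1] <- 1L
  ev[1, 6] <- 4L
  ev[1, 9] <- 5L # recovered dead in 2008
  hist <- capture_history_set("a", 2000L, ev, years)
  rec <- breeding_records("a", 2005L, 2L, 200L)
  tab <- build_interval_table(rec, hist)
  expect_equal(tab$interval_years, 2008L - 2005L)
  expect_true(tab$censored)
})

# synthetic interval-like table with exponential waits and a binary group
exp_interval_table <- function(n, hr, seed) {
  set.seed(seed)
  grp <- rep(0:1, each = n / 2)
  t <- rexp(n, rate = 0.4 * hr^grp)
  data.frame(
    individual_id = sprintf("s%04d", seq_len(n)),
    interval_years = t, censored = FALSE, group = grp
  )
}

test_that("the Cox stage recovers a two-group hazard ratio", {
  tab <- exp_interval_table(800, hr = 2, seed = 21)
  fit <- fit_cox(tab, "group")
  b <- fit$coefficients
  expect_lt(abs(b$estimate - log(2)) / b$robust_se, 3)
  # a covariate independent of the waits drifts to HR 1
  tab$noise <- rnorm(nrow(tab))
  fit0 <- fit_cox(tab, "noise")
  expect_lt(abs(fit0$coefficients$estimate) / fit0$coefficients$robust_se, 3)
  # no events at all is an error
  tab$censored <- TRUE
  expect_error(fit_cox(tab, "group"), "censored|event")
})

test_that("the partial likelihood is rank-invariant", {
  tab <- exp_interval_table(400, hr = 2, seed = 22)
  f1 <- fit_cox(tab, "group")
  tab2 <- tab
  tab2$interval_years <- tab$interval_years^1.5 # monotone time transform
  f2 <- fit_cox(tab2, "group")
  expect_equal(f1$coefficients$estimate, f2$coefficients$estimate,
    tolerance = 1e-8
  )
})

test_that("the proportionality diagnostic behaves under null and alternative", {
  tab <- exp_interval_table(600, hr = 2, seed = 23)
  fit <- fit_cox(tab, "group")
  out <- ph_check(fit)
  expect_true("GLOBAL" %in% out$covariate)
  expect_equal(out$df[out$covariate == "GLOBAL"], 1)
  expect_gt(out$p[out$covariate == "GLOBAL"], 0.01)
  # a strongly time-varying effect: the group accelerates early and is
  # penalized late
  set.seed(24)
  n <- 1000
  grp <- rep(0:1, each = n / 2)
  t0 <- rexp(n, 0.5)
  t <- ifelse(grp == 1, qexp(pexp(t0, 0.5), 3) + 2.5 * rbinom(n, 1, 0.5), t0)
  tab2 <- data.frame(
    individual_id = sprintf("s%04d", 1:n),
    interval_years = t, censored = FALSE, group = grp
  )
  fit2 <- fit_cox(tab2, "group")
  out2 <- ph_check(fit2)
  expect_lt(out2$p[out2$covariate == "GLOBAL"], 0.01)
})

test_that("zero-truncated Poisson closed forms and recovery", {
  expect_equal(ztp_mean(1), 1 / (1 - exp(-1)), tolerance = 1e-12)
  set.seed(31)
  y <- rztpois(40000, 1)
  expect_equal(mean(y), 1.582, tolerance = 0.01)
  # recovery of a generating age multiplier on the expected-interval scale
  set.seed(32)
  n <- 2000
  age <- runif(n, 8, 40)
  lam <- exp(-0.5 + log(1.094) * (age - 20) / 1) # centred age effect
  tab <- data.frame(
    individual_id = sprintf("z%04d", 1:n),
    interval_years = rztpois(n, exp(-0.5 + log(1.094) * (age - 20))),
    censored = FALSE, age = age - 20
  )
  fit <- fit_ztp(tab, "age")
  b <- fit$coefficients[fit$coefficients$covariate == "age", ]
  expect_lt(abs(b$estimate - log(1.094)) / b$se, 3)
  expect_true(all(fit$fitted_mean >= 1))
  expect_equal(unname(fit$vif[["age"]]), 1)
})

test_that("degenerate ZTP inputs are flagged or rejected", {
  tab <- data.frame(
    individual_id = letters[1:30], interval_years = rep(1L, 30),
    censored = FALSE
  )
  expect_warning(fit <- fit_ztp(tab), "boundary")
  expect_equal(unname(fit$fitted_mean[1L]), 1, tolerance = 1e-3)
  tab$censored <- TRUE
  expect_error(fit_ztp(tab), "closed")
})

test_that("percent change converts log coefficients to percentages", {
  expect_equal(percent_change(0), 0)
  expect_equal(percent_change(log(1.21)), 21, tolerance = 1e-10)
  expect_equal(percent_change(log(0.88)), -12, tolerance = 1e-10)
})
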