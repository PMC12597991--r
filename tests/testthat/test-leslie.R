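# Leslie-matrix assembly and life-history traits.

# helper: build a model from survivorship lx and maternity mx directly
leslie_from_lxmx <- function(lx, mx, afr = NULL) {
  n <- length(lx)
  phi <- c(lx[-1L] / lx[-n], 0)
  phi[!is.finite(phi)] <- 0
  if (is.null(afr)) afr <- min(which(mx > 0)) - 1L
  build_leslie(phi, mx * 2, isrp_population = 1, afr = afr)
}

test_that("growth rate solves the Euler-Lotka equation on worked examples", {
  L <- leslie_from_lxmx(c(1, 0.5), c(0, 4))
  g <- growth_rates(L)
  expect_equal(g[["lambda"]], 2, tolerance = 1e-10)
  rt <- r0_and_generation_time(L)
  expect_equal(rt$R0, 2)
  expect_equal(rt$T_gen, 1, tolerance = 1e-10)
  # replacement-level: single reproductive age with lk mk = 1 (the matrix
  # is periodic, hence the ergodicity caution)
  L2 <- suppressWarnings(leslie_from_lxmx(c(1, 0.5, 0.25), c(0, 0, 4)))
  expect_equal(growth_rates(L2)[["lambda"]], 1, tolerance = 1e-10)
  # scaling fecundity by c leaves the Euler-Lotka identity intact
  L3 <- suppressWarnings(leslie_from_lxmx(c(1, 0.5, 0.25), c(0, 0, 8)))
  lam3 <- growth_rates(L3)[["lambda"]]
  expect_equal(sum(lam3^(-L3$ages) * L3$lx * L3$mx), 1, tolerance = 1e-10)
  expect_gt(lam3, 1)
})

test_that("maternity adjustment halves eggs and discounts by ISRP", {
  phi <- c(rep(1, 7), rep(0.9, 9))
  eggs <- c(rep(0, 7), rep(340, 9))
  L <- build_leslie(phi, eggs, isrp_population = 1.7, afr = 7)
  expect_equal(unname(L$mx[8L]), 100)
  expect_true(all(L$mx[1:7] == 0))
  expect_true(all(L$lx[1:8] == 1)) # pre-maturity survival one
})

test_that("degenerate schedules are rejected", {
  expect_error(
    build_leslie(rep(0.9, 10), rep(0, 10), 1.5, afr = 3),
    "no reproduction"
  )
  expect_error(build_leslie(rep(0.9, 5), rep(10, 4), 1.5), "same age range")
  expect_error(build_leslie(rep(1.2, 5), rep(10, 5), 1.5, afr = 1), "\\[0, 1\\]")
  expect_error(build_leslie(rep(0.9, 5), rep(10, 5), 0.5, afr = 1), ">= 1")
})

test_that("life expectancies come from the fundamental matrix", {
  L <- suppressWarnings(leslie_from_lxmx(c(1, 1, 0.5), c(0, 0, 2), afr = 2))
  expect_equal(unname(life_expectancies(L)[["e0"]]), 2.5)
  # constant survival 0.5 over many classes: geometric series -> 2
  n <- 40
  phi <- rep(0.5, n)
  L2 <- build_leslie(phi, c(0, rep(4, n - 1)), 1, afr = 1)
  expect_equal(unname(life_expectancies(L2)[["e0"]]), 2, tolerance = 1e-6)
  # with pre-adult survival one, e0 decomposes as afr + adult expectancy
  cfg <- default_config()
  phi3 <- c(rep(1, 7), logistic_age(cfg$surv_coeffs, 7:44, 22, 8))
  L3 <- build_leslie(phi3, c(rep(0, 7), rep(390, 38)), 1.7, afr = 7)
  le <- life_expectancies(L3)
  expect_equal(le[["e0"]], 7 + le[["e_adult"]], tolerance = 1e-9)
})

test_that("the Gini index measures concentration of reproduction", {
  expect_equal(gini_index(c(0, 0, 1)), 2 / 3, tolerance = 1e-12)
  expect_equal(gini_index(rep(3.7, 11)), 0, tolerance = 1e-12)
  expect_equal(gini_index(c(0.2, 0.8)), 0.3, tolerance = 1e-12)
  expect_equal(gini_index(c(2, 8)), 0.3, tolerance = 1e-12) # scale invariant
  set.seed(4)
  for (i in 1:20) {
    v <- runif(10)
    expect_equal(gini_index(v), gini_index(v * 37.5), tolerance = 1e-12)
    g <- gini_index(v)
    expect_gte(g, 0)
    expect_lte(g, 1 - 1 / 10)
  }
  expect_error(gini_index(c(0, 0, 0)), "all-zero")
  expect_error(gini_index(1), "at least 2")
})

test_that("reproductive value normalizes at birth and decays after breeding", {
  L <- leslie_from_lxmx(c(1, 0.5, 0.25), c(0, 1, 2))
  rv <- reproductive_value(L)
  expect_equal(rv$vx[1L], 1, tolerance = 1e-10)
  expect_equal(rv$vx[2L], 2, tolerance = 1e-10)
  expect_equal(rv$residual[3L], 0, tolerance = 1e-10) # last reproductive age
  cfg <- default_config()
  phi <- c(rep(1, 7), logistic_age(cfg$surv_coeffs, 7:44, 22, 8))
  L2 <- build_leslie(phi, c(rep(0, 7), rep(390, 38)), 1.7, afr = 7)
  rv2 <- reproductive_value(L2)
  expect_equal(rv2$vx[1L], 1, tolerance = 1e-8)
  expect_true(all(rv2$vx >= 0, na.rm = TRUE))
  expect_equal(rv2$residual[nrow(rv2)], 0, tolerance = 1e-10)
})

test_that("shape measures vanish on constant-rate schedules", {
  n <- 35
  phi <- c(rep(1, 5), rep(0.8, n - 5))
  eggs <- c(rep(0, 5), rep(100, n - 5))
  L <- build_leslie(phi, eggs, 1.5, afr = 5)
  ps <- pace_shape(L)
  expect_lt(abs(ps$shape_surv), 1e-6)
  expect_lt(abs(ps$shape_rep), 1e-6)
  expect_equal(ps$pace_aging, unname(life_expectancies(L)[["e_adult"]]))
  # Gompertz-increasing hazard: survivorship more rectangular -> positive
  h <- 0.05 * exp(0.15 * (0:(n - 6)))
  phi_g <- c(rep(1, 5), pmax(0, 1 - h))
  Lg <- build_leslie(phi_g, eggs, 1.5, afr = 5)
  expect_gt(pace_shape(Lg)$shape_surv, 0)
  # declining fecundity front-loads reproduction -> positive shape_rep;
  # late-life increase -> negative
  eggs_dec <- c(rep(0, 5), seq(200, 10, length.out = n - 5))
  eggs_inc <- c(rep(0, 5), seq(10, 200, length.out = n - 5))
  expect_gt(pace_shape(build_leslie(phi, eggs_dec, 1.5, afr = 5))$shape_rep, 0)
  expect_lt(pace_shape(build_leslie(phi, eggs_inc, 1.5, afr = 5))$shape_rep, 0)
})

test_that("every built model satisfies the matrix identities", {
  set.seed(11)
  for (i in 1:10) {
    n <- sample(20:46, 1)
    afr <- sample(3:8, 1)
    phi <- c(rep(1, afr), runif(n - afr, 0.6, 0.98))
    eggs <- c(rep(0, afr), runif(n - afr, 50, 500))
    isrp_pop <- runif(1, 1, 3)
    L <- build_leslie(phi, eggs, isrp_pop, afr = afr)
    lam <- growth_rates(L)[["lambda"]]
    expect_lt(abs(sum(lam^(-L$ages) * L$lx * L$mx) - 1), 1e-8)
    expect_equal(reproductive_value(L)$vx[1L], 1, tolerance = 1e-8)
  }
})
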