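# Types, validation and file round trips for coded capture histories.

test_that("csv and inp dialects round-trip a set bit-exactly", {
  set <- small_set()
  for (dialect in c("csv", "inp")) {
    path <- withr::local_tempfile(fileext = paste0(".", dialect))
    write_capture_histories(set, path, dialect)
    back <- read_capture_histories(path, dialect)
    expect_identical(back$ids, set$ids)
    expect_identical(back$birth_years, set$birth_years)
    expect_identical(back$years, set$years)
    expect_identical(unname(back$events), unname(set$events))
  }
})

test_that("the inp digit string decodes by position from the birth year", {
  path <- withr::local_tempfile(fileext = ".inp")
  writeLines("t1 1970 100340;", path)
  set <- read_capture_histories(path, "inp")
  expect_identical(set$years, 1970:1975)
  expect_identical(unname(set$events[1, ]), c(1L, 0L, 0L, 3L, 4L, 0L))
})

test_that("malformed files raise parse errors naming the problem", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("foo,bar", "1,2"), p)
  expect_error(read_capture_histories(p, "csv"), "id,birth_year")
  p2 <- withr::local_tempfile(fileext = ".inp")
  writeLines(c("a 1970 1034;", "b 1971 10x4;"), p2)
  expect_error(read_capture_histories(p2, "inp"), "line 2")
  expect_error(read_capture_histories("/nonexistent/file.csv"), "not found")
})

test_that("invariant violations are reported with individual and problem", {
  years <- 2000:2003
  bad <- function(ev) {
    validate_set(capture_history_set(
      "x", 2000L, matrix(ev, 1), years,
      validate = FALSE
    ))
  }
  r <- bad(c(1L, 0L, 5L, 4L))
  expect_match(r$problem, "after dead recovery", all = FALSE)
  r <- bad(c(1L, 7L, 0L, 0L))
  expect_match(r$problem, "invalid event code 7", all = FALSE)
  r <- bad(c(0L, 1L, 2L, 4L))
  expect_match(r$problem, "first event", all = FALSE)
  expect_equal(nrow(validate_set(small_set())), 0L)
  # duplicated ids are a set-level violation
  dup <- capture_history_set(c("a", "a"), c(2000L, 2000L),
    rbind(c(1L, 1L, 1L, 1L), c(1L, 1L, 1L, 1L)), years,
    validate = FALSE
  )
  expect_match(validate_set(dup)$problem, "duplicated", all = FALSE)
})

test_that("the validator accepts exactly the invariant-defined language", {
  # enumerate every event string of length up to 4 and compare against a
  # direct restatement of the invariants
  years <- 2000:2003
  legal <- function(s) {
    if (s[1L] != 1L) {
      return(FALSE)
    }
    deads <- which(s == 5L)
    if (length(deads) > 1L) {
      return(FALSE)
    }
    if (length(deads) == 1L && deads[1L] < length(s) &&
      any(s[(deads[1L] + 1L):length(s)] != 0L)) {
      return(FALSE)
    }
    TRUE
  }
  for (len in 1:4) {
    grids <- as.matrix(expand.grid(rep(list(0:5), len)))
    ok <- apply(grids, 1L, legal)
    rep_ok <- apply(grids, 1L, function(s) {
      set <- capture_history_set("x", 2000L, matrix(as.integer(s), 1),
        2000:(1999L + len),
        validate = FALSE
      )
      nrow(validate_set(set)) == 0L
    })
    expect_identical(rep_ok, ok)
  }
})

test_that("set summaries count recaptures and dead recoveries", {
  s1 <- capture_history_set("a", 2000L, matrix(c(1L, 4L, 4L, 0L), 1), 2000:2003)
  sm <- summarize_set(s1)
  expect_equal(sm$recaptures_mean, 2)
  expect_equal(sm$n_dead_recoveries, 0L)
  # two histories with 2 and 4 recaptures
  s2 <- capture_history_set(
    c("a", "b"), c(2000L, 2000L),
    rbind(
      c(1L, 4L, 4L, 0L, 0L, 0L),
      c(1L, 2L, 3L, 4L, 0L, 5L)
    ), 2000:2005
  )
  sm2 <- summarize_set(s2)
  expect_equal(sm2$recaptures_mean, 3)
  expect_equal(sm2$recaptures_sd, sd(c(2, 4)))
  expect_equal(sm2$n_dead_recoveries, 1L)
  # silence after first capture
  s3 <- capture_history_set("a", 2000L, matrix(c(1L, 0L, 0L, 0L), 1), 2000:2003)
  expect_equal(summarize_set(s3)$recaptures_mean, 0)
  expect_error(
    summarize_set(capture_history_set(
      character(), integer(),
      matrix(integer(), 0, 4), 2000:2003
    )),
    "empty"
  )
})

test_that("breeding records enforce the egg-clutch ordering", {
  expect_error(breeding_records("a", 2000L, 3L, 2L), "n_eggs < n_clutches")
  r <- breeding_records(c("a", "a"), c(2000L, 2001L), c(2L, 0L), c(150L, 0L))
  p <- withr::local_tempfile(fileext = ".csv")
  write_breeding_records(r, p)
  back <- read_breeding_records(p)
  expect_equal(back$n_eggs, r$n_eggs)
})
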