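# Coded capture histories: one event per individual per annual occasion.
# Codes: 0 not observed, 1 juvenile (J), 2 subadult (SA), 3 adult non-breeder
# (NB), 4 adult breeder (B), 5 recovered dead (D). Histories are stored dense,
# one slot per occasion year, NA before an individual's birth year.

.valid_codes <- 0:5

#' Construct a set of coded capture histories
#'
#' Builds the container used throughout the package: a dense individuals x
#' occasions matrix of event codes together with birth years. Occasions are
#' calendar years; an individual's age at occasion `y` is `y - birth_year`
#' (age 0 at birth). Slots before an individual's birth year must be `NA`.
#'
#' @param ids Character vector of unique individual identifiers.
#' @param birth_years Integer vector of birth (cohort) years, one per
#'   individual.
#' @param events Integer matrix, one row per individual and one column per
#'   occasion year, holding event codes 0-5 (`NA` before birth).
#' @param years Integer vector of consecutive occasion years (the columns of
#'   `events`).
#' @param validate If `TRUE` (default), invariant violations raise an error;
#'   set to `FALSE` to build an invalid set for inspection with
#'   [validate_set()].
#' @return An object of class `capture_history_set`.
#' @seealso [read_capture_histories()], [validate_set()], [summarize_set()]
#' @export
capture_history_set <- function(ids, birth_years, events, years,
                                validate = TRUE) {
  ids <- as.character(ids)
  birth_years <- as.integer(birth_years)
  years <- as.integer(years)
  if (is.matrix(events)) {
    storage.mode(events) <- "integer"
  } else {
    events <- matrix(as.integer(events), nrow = length(ids))
  }
  if (length(birth_years) != length(ids)) {
    stop("`birth_years` must have one entry per individual", call. = FALSE)
  }
  if (ncol(events) != length(years)) {
    stop("`events` must have one column per occasion year", call. = FALSE)
  }
  if (length(years) > 1L && any(diff(years) != 1L)) {
    stop("occasion years must be consecutive", call. = FALSE)
  }
  rownames(events) <- ids
  colnames(events) <- years
  set <- structure(
    list(ids = ids, birth_years = birth_years, events = events, years = years),
    class = "capture_history_set"
  )
  if (validate) {
    report <- validate_set(set)
    if (nrow(report) > 0L) {
      stop("invalid capture history set:\n",
        paste(utils::capture.output(print(report)), collapse = "\n"),
        call. = FALSE
      )
    }
  }
  set
}

#' @export
print.capture_history_set <- function(x, ...) {
  cat(
    "Capture history set:", length(x$ids), "individuals,",
    length(x$years), "occasions (", min(x$years), "-", max(x$years), ")\n"
  )
  invisible(x)
}

#' Validate a capture history set against the type invariants
#'
#' Checks every history: codes lie in 0-5, the first event is code 1
#' (juvenile) in the birth year, pre-birth slots are `NA`, at most one code-5
#' (dead recovery) occurs and every later event is 0, adult/subadult codes
#' never precede the first juvenile code, and identifiers are unique. This is
#' a reporting operation: it never throws.
#'
#' @param set A `capture_history_set` (possibly built with
#'   `validate = FALSE`).
#' @return A data frame with columns `individual`, `occasion` (`NA` for
#'   set-level problems) and `problem`; zero rows iff the set is valid.
#' @export
validate_set <- function(set) {
  probs <- list()
  add <- function(individual, occasion, problem) {
    probs[[length(probs) + 1L]] <<- data.frame(
      individual = individual, occasion = occasion, problem = problem,
      stringsAsFactors = FALSE
    )
  }
  dup <- unique(set$ids[duplicated(set$ids)])
  for (d in dup) add(d, NA_integer_, "duplicated individual id")
  years <- set$years
  for (i in seq_along(set$ids)) {
    id <- set$ids[i]
    ev <- set$events[i, ]
    by <- set$birth_years[i]
    if (!by %in% years) {
      add(id, by, "birth year outside occasion range")
      next
    }
    pre <- years < by
    if (any(!is.na(ev[pre]))) {
      add(id, years[pre][which(!is.na(ev[pre]))[1L]], "event before birth year")
    }
    obs <- ev[!pre]
    oyrs <- years[!pre]
    if (anyNA(obs)) {
      add(id, oyrs[which(is.na(obs))[1L]], "missing event after birth")
      obs <- obs[!is.na(obs)]
      oyrs <- oyrs[!is.na(ev[!pre])]
      if (length(obs) == 0L) next
    }
    bad <- !(obs %in% .valid_codes)
    if (any(bad)) {
      add(id, oyrs[which(bad)[1L]], sprintf("invalid event code %d", obs[which(bad)[1L]]))
    }
    if (length(obs) > 0L && (is.na(obs[1L]) || obs[1L] != 1L)) {
      add(id, by, "first event is not juvenile (code 1) in birth year")
    }
    first1 <- match(1L, obs)
    if (!is.na(first1) && first1 > 1L && any(obs[seq_len(first1 - 1L)] %in% 2:4)) {
      add(id, oyrs[which(obs %in% 2:4)[1L]], "adult/subadult code precedes first juvenile code")
    }
    deads <- which(obs == 5L)
    if (length(deads) > 1L) {
      add(id, oyrs[deads[2L]], "more than one dead recovery")
    }
    if (length(deads) >= 1L) {
      after <- obs[seq_along(obs) > deads[1L]]
      if (any(after != 0L, na.rm = TRUE)) {
        ocs <- oyrs[seq_along(obs) > deads[1L]]
        add(id, ocs[which(after != 0L)[1L]], "event after dead recovery")
      }
    }
  }
  if (length(probs) == 0L) {
    return(data.frame(
      individual = character(), occasion = integer(),
      problem = character(), stringsAsFactors = FALSE
    ))
  }
  do.call(rbind, probs)
}

#' Read coded capture histories from disk
#'
#' Two dialects are supported. `csv`: a header row `id,birth_year,<year1>,...`
#' with one integer event code per occasion column (empty cells before birth).
#' `inp`: a MARK-style record `id birth_year <digitstring>;` per line,
#' where the digit string starts in the individual's birth year and runs to
#' the common final study year.
#'
#' @param path Path to the file.
#' @param dialect `"csv"` (canonical) or `"inp"`.
#' @return A validated `capture_history_set`.
#' @export
read_capture_histories <- function(path, dialect = c("csv", "inp")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "csv") {
    df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 3L || names(df)[1L] != "id" || names(df)[2L] != "birth_year") {
      stop("malformed capture-history csv: expected columns id,birth_year,<years...>",
        call. = FALSE
      )
    }
    yrs <- suppressWarnings(as.integer(names(df)[-(1:2)]))
    if (anyNA(yrs)) stop("malformed csv header: non-year occasion column", call. = FALSE)
    ev <- as.matrix(df[, -(1:2), drop = FALSE])
    storage.mode(ev) <- "integer"
    capture_history_set(df$id, df$birth_year, ev, yrs)
  } else {
    lines <- readLines(path)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    recs <- lapply(seq_along(lines), function(i) {
      ln <- sub(";\\s*$", "", lines[i])
      parts <- strsplit(ln, "\\s+")[[1L]]
      if (length(parts) != 3L || !grepl("^[0-9]+$", parts[3L])) {
        stop(sprintf("malformed inp record at line %d: '%s'", i, lines[i]),
          call. = FALSE
        )
      }
      list(
        id = parts[1L], birth = as.integer(parts[2L]),
        codes = as.integer(strsplit(parts[3L], "")[[1L]])
      )
    })
    ends <- vapply(recs, function(r) r$birth + length(r$codes) - 1L, integer(1))
    if (length(unique(ends)) != 1L) {
      stop("inp records do not share a common final study year", call. = FALSE)
    }
    years <- seq(min(vapply(recs, `[[`, integer(1), "birth")), ends[1L])
    ev <- matrix(NA_integer_, length(recs), length(years))
    for (i in seq_along(recs)) {
      j <- match(recs[[i]]$birth, years)
      ev[i, seq(j, length(years))] <- recs[[i]]$codes
    }
    capture_history_set(
      vapply(recs, `[[`, character(1), "id"),
      vapply(recs, `[[`, integer(1), "birth"), ev, years
    )
  }
}

#' Write coded capture histories to disk
#'
#' Inverse of [read_capture_histories()]; `read(write(S)) == S` bit-exact on
#' codes and years for both dialects.
#'
#' @inheritParams read_capture_histories
#' @param set A `capture_history_set`.
#' @return `path`, invisibly.
#' @export
write_capture_histories <- function(set, path, dialect = c("csv", "inp")) {
  dialect <- match.arg(dialect)
  if (dialect == "csv") {
    df <- data.frame(
      id = set$ids, birth_year = set$birth_years,
      set$events, check.names = FALSE, stringsAsFactors = FALSE
    )
    write.csv(df, path, row.names = FALSE, na = "")
  } else {
    lines <- vapply(seq_along(set$ids), function(i) {
      keep <- set$years >= set$birth_years[i]
      sprintf(
        "%s %d %s;", set$ids[i], set$birth_years[i],
        paste(set$events[i, keep], collapse = "")
      )
    }, character(1))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Summary statistics of a capture history set
#'
#' Recaptures per individual are non-zero events after the first occasion;
#' dead recoveries are code-5 events.
#'
#' @param set A valid `capture_history_set`.
#' @return A list with `n_individuals`, `recaptures_mean`, `recaptures_sd`
#'   (sample SD) and `n_dead_recoveries`.
#' @export
summarize_set <- function(set) {
  if (length(set$ids) == 0L) stop("empty capture history set", call. = FALSE)
  recaps <- vapply(seq_along(set$ids), function(i) {
    ev <- set$events[i, set$years >= set$birth_years[i]]
    sum(ev[-1L] != 0L, na.rm = TRUE)
  }, numeric(1))
  list(
    n_individuals = length(set$ids),
    recaptures_mean = mean(recaps),
    recaptures_sd = if (length(recaps) > 1L) sd(recaps) else NA_real_,
    n_dead_recoveries = sum(set$events == 5L, na.rm = TRUE)
  )
}

#' Construct / validate per-season breeding records
#'
#' One record per (individual, breeding season): the number of clutches laid
#' and total eggs. Eggs must be at least the clutch count when any clutch was
#' laid; records should exist only for seasons in which the individual's
#' event is code 4 (detected breeding), which is enforced when records are
#' joined to histories in [build_interval_table()].
#'
#' @param individual_id Character vector of individual identifiers.
#' @param season_year Integer vector of breeding-season (calendar) years.
#' @param n_clutches,n_eggs Non-negative integer vectors.
#' @return A data frame of class `breeding_records`.
#' @export
breeding_records <- function(individual_id, season_year, n_clutches, n_eggs) {
  df <- data.frame(
    individual_id = as.character(individual_id),
    season_year = as.integer(season_year),
    n_clutches = as.integer(n_clutches),
    n_eggs = as.integer(n_eggs),
    stringsAsFactors = FALSE
  )
  if (any(df$n_clutches < 0L) || any(df$n_eggs < 0L)) {
    stop("clutch and egg counts must be non-negative", call. = FALSE)
  }
  bad <- df$n_clutches > 0L & df$n_eggs < df$n_clutches
  if (any(bad)) {
    stop(
      "n_eggs < n_clutches for individual(s): ",
      paste(unique(df$individual_id[bad]), collapse = ", "),
      call. = FALSE
    )
  }
  class(df) <- c("breeding_records", "data.frame")
  df
}

#' Read breeding records from a csv file
#'
#' Expects the header `id,season_year,n_clutches,n_eggs`.
#'
#' @param path Path to the file.
#' @return A `breeding_records` data frame.
#' @export
read_breeding_records <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "season_year", "n_clutches", "n_eggs")
  if (!all(need %in% names(df))) {
    stop("malformed breeding-records csv: expected columns ",
      paste(need, collapse = ","),
      call. = FALSE
    )
  }
  breeding_records(df$id, df$season_year, df$n_clutches, df$n_eggs)
}

#' Write breeding records to a csv file
#'
#' @param records A `breeding_records` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_breeding_records <- function(records, path) {
  df <- data.frame(
    id = records$individual_id, season_year = records$season_year,
    n_clutches = records$n_clutches, n_eggs = records$n_eggs
  )
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
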