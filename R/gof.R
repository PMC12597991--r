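# Goodness-of-fit components for the time-dependent multi-state null:
# transience (3.SR), time-to-re-encounter (3.SM) and memory (WBWA)
# contingency-table tests built from adult sightings (event codes 3 and 4),
# with the classical "pool expected < 2" rule, plus the overdispersion
# coefficient c-hat. Tables are stratified by the observable state at the
# focal occasion so that each component is calibrated (mean chi-square equal
# to its degrees of freedom) under first-order Markov homogeneity.

#' Construct a goodness-of-fit component from its statistic
#'
#' Useful for combining externally computed components (e.g. published
#' chi-square totals) with [c_hat()].
#'
#' @param name Component label.
#' @param chi2 Non-negative chi-square statistic.
#' @param df Degrees of freedom.
#' @param tables Optional list of the contingency tables used.
#' @return A `gof_component`.
#' @export
gof_component <- function(name, chi2, df, tables = list()) {
  stopifnot(chi2 >= 0, df >= 0)
  .gof_component(name, chi2, as.integer(df), tables)
}

.gof_component <- function(name, chi2, df, tables) {
  structure(
    list(
      name = name, chi2 = chi2, df = df,
      p_value = if (df > 0) pchisq(chi2, df, lower.tail = FALSE) else NA_real_,
      tables = tables
    ),
    class = "gof_component"
  )
}

#' @export
print.gof_component <- function(x, ...) {
  cat(sprintf(
    "%s: chi2 = %.3f, df = %d, p = %s (%d tables)\n",
    x$name, x$chi2, x$df,
    if (is.na(x$p_value)) "NA" else format.pval(x$p_value, digits = 3),
    length(x$tables)
  ))
  invisible(x)
}

# Pearson chi-square of a contingency table with margin/expectation guards;
# columns are pooled right-to-left while any expected count is below 2.
.pooled_chisq <- function(tab, min_expected = 2) {
  repeat {
    tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
    if (nrow(tab) < 2L || ncol(tab) < 2L) {
      return(NULL)
    }
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (all(e >= min_expected)) {
      chi2 <- sum((tab - e)^2 / e)
      return(list(chi2 = chi2, df = (nrow(tab) - 1L) * (ncol(tab) - 1L), table = tab))
    }
    if (ncol(tab) > 2L) {
      tab[, ncol(tab) - 1L] <- tab[, ncol(tab) - 1L] + tab[, ncol(tab)]
      tab <- tab[, -ncol(tab), drop = FALSE]
    } else {
      return(NULL) # a 2x2 with a sparse cell cannot be pooled further
    }
  }
}

# Adult sighting columns (codes 3/4) per individual.
.adult_obs <- function(set) {
  ev <- set$events
  ev[is.na(ev)] <- 0L
  list(events = ev, adult = ev == 3L | ev == 4L)
}

.sum_components <- function(name, pieces) {
  pieces <- Filter(Negate(is.null), pieces)
  if (length(pieces) == 0L) {
    warning(name, ": no table satisfied the pooling rule; df = 0", call. = FALSE)
    return(.gof_component(name, 0, 0L, list()))
  }
  .gof_component(
    name,
    sum(vapply(pieces, `[[`, numeric(1), "chi2")),
    sum(vapply(pieces, `[[`, integer(1), "df")),
    lapply(pieces, `[[`, "table")
  )
}

#' Transience component (3.SR) of the goodness-of-fit test
#'
#' For each occasion and observable adult state, crosses newly against
#' previously encountered individuals with whether they are ever
#' re-encountered in an adult state later, testing the null that the
#' re-encounter probability is equal for the two groups. Tables with an
#' expected cell below 2 (not poolable in a 2x2) are excluded.
#'
#' @param set A `capture_history_set` with at least 3 occasions.
#' @return A `gof_component` (chi-square, df, p-value, tables used).
#' @export
test_3sr <- function(set) {
  ao <- .adult_obs(set)
  Tn <- ncol(ao$events)
  if (Tn < 3L) stop("3.SR needs at least 3 occasions", call. = FALSE)
  first_adult <- apply(ao$adult, 1L, function(z) which(z)[1L])
  pieces <- list()
  for (t in seq_len(Tn - 1L)) {
    later <- rowSums(ao$adult[, (t + 1L):Tn, drop = FALSE]) > 0
    for (code in c(3L, 4L)) {
      here <- ao$events[, t] == code
      if (!any(here)) next
      new <- !is.na(first_adult) & first_adult == t
      tab <- table(
        factor(ifelse(new[here], "new", "old"), c("new", "old")),
        factor(ifelse(later[here], "again", "never"), c("again", "never"))
      )
      pieces[[length(pieces) + 1L]] <- .pooled_chisq(unclass(tab))
    }
  }
  .sum_components("3.SR", pieces)
}

#' Time-to-re-encounter component (3.SM) of the goodness-of-fit test
#'
#' Among individuals re-encountered after the focal occasion, crosses newly
#' against previously encountered individuals with the waiting time to the
#' next adult encounter (1, 2, 3+ occasions), per occasion and observable
#' state. Waiting-time categories are pooled right-to-left while any
#' expected count is below 2.
#'
#' @inheritParams test_3sr
#' @return A `gof_component`.
#' @export
test_3sm <- function(set) {
  ao <- .adult_obs(set)
  Tn <- ncol(ao$events)
  if (Tn < 3L) stop("3.SM needs at least 3 occasions", call. = FALSE)
  first_adult <- apply(ao$adult, 1L, function(z) which(z)[1L])
  pieces <- list()
  for (t in seq_len(Tn - 1L)) {
    nxt <- apply(ao$adult[, (t + 1L):Tn, drop = FALSE], 1L, function(z) which(z)[1L])
    for (code in c(3L, 4L)) {
      here <- which(ao$events[, t] == code & !is.na(nxt))
      if (length(here) == 0L) next
      new <- !is.na(first_adult[here]) & first_adult[here] == t
      wait <- pmin(nxt[here], 3L)
      tab <- table(
        factor(ifelse(new, "new", "old"), c("new", "old")),
        factor(wait, 1:3)
      )
      pieces[[length(pieces) + 1L]] <- .pooled_chisq(unclass(tab))
    }
  }
  .sum_components("3.SM", pieces)
}

#' Memory component (WBWA) of the goodness-of-fit test
#'
#' "Where before, where after": for individuals encountered at an occasion
#' in an observable adult state, crosses the state at the previous adult
#' encounter with the state at the next one, stratified by the current
#' state. Under a first-order Markov process the future state is
#' independent of the past state given the present one; large values
#' indicate memory.
#'
#' @param set A `capture_history_set` with at least 3 occasions and both
#'   observable adult states present.
#' @return A `gof_component`.
#' @export
test_wbwa <- function(set) {
  ao <- .adult_obs(set)
  Tn <- ncol(ao$events)
  if (Tn < 3L) stop("WBWA needs at least 3 occasions", call. = FALSE)
  pieces <- list()
  for (t in 2:(Tn - 1L)) {
    prev <- apply(ao$adult[, 1:(t - 1L), drop = FALSE], 1L, function(z) {
      w <- which(z)
      if (length(w)) w[length(w)] else NA_integer_
    })
    nxt <- apply(ao$adult[, (t + 1L):Tn, drop = FALSE], 1L, function(z) which(z)[1L])
    for (code in c(3L, 4L)) {
      here <- which(ao$events[, t] == code & !is.na(prev) & !is.na(nxt))
      if (length(here) == 0L) next
      pstate <- ao$events[cbind(here, prev[here])]
      nstate <- ao$events[cbind(here, t + nxt[here])]
      tab <- table(
        factor(pstate, c(3L, 4L)),
        factor(nstate, c(3L, 4L))
      )
      pieces[[length(pieces) + 1L]] <- .pooled_chisq(unclass(tab))
    }
  }
  .sum_components("WBWA", pieces)
}

#' Run all goodness-of-fit components and their total
#'
#' @inheritParams test_3sr
#' @return A list with components `3.SR`, `3.SM`, `WBWA` and `total` (whose
#'   chi-square and df are the sums of the components).
#' @export
gof_tests <- function(set) {
  comps <- list(test_3sr(set), test_3sm(set), test_wbwa(set))
  total <- .gof_component(
    "total",
    sum(vapply(comps, `[[`, numeric(1), "chi2")),
    sum(vapply(comps, `[[`, integer(1), "df")),
    list()
  )
  setNames(c(comps, list(total)), c("3.SR", "3.SM", "WBWA", "total"))
}

#' Overdispersion coefficient c-hat
#'
#' The ratio of the summed chi-square to the summed degrees of freedom of
#' the goodness-of-fit components, floored at 1 for use in quasi-likelihood
#' criteria (values below 1 indicate underdispersion and are treated as 1);
#' the raw ratio is always reported alongside.
#'
#' @param components A list of `gof_component` objects (e.g. from
#'   [gof_tests()]), or a single component.
#' @return A list with `c_hat` (floored), `raw`, `chi2` and `df`.
#' @export
c_hat <- function(components) {
  if (inherits(components, "gof_component")) components <- list(components)
  components <- components[vapply(components, function(x) x$name != "total", logical(1))]
  chi2 <- sum(vapply(components, `[[`, numeric(1), "chi2"))
  df <- sum(vapply(components, `[[`, integer(1), "df"))
  if (df <= 0L) stop("c-hat undefined: total df is 0", call. = FALSE)
  raw <- chi2 / df
  list(c_hat = max(1, raw), raw = raw, chi2 = chi2, df = df)
}
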