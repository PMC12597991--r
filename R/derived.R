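# Closed-form demographic quantities derived from fitted transition and
# survival parameters, with delta-method uncertainty.

.derived_estimate <- function(name, value, se, inputs, lower_bound = -Inf,
                              upper_bound = Inf, level = 0.95,
                              alternative = NULL) {
  z <- qnorm(1 - (1 - level) / 2)
  ci <- if (is.na(se)) c(NA_real_, NA_real_) else c(value - z * se, value + z * se)
  ci <- pmin(pmax(ci, lower_bound), upper_bound)
  structure(
    list(
      name = name, value = value, se = se, ci = ci, inputs = inputs,
      alternative = alternative
    ),
    class = "derived_estimate"
  )
}

#' @export
print.derived_estimate <- function(x, ...) {
  cat(sprintf(
    "%s = %.4f (SE %s, 95%% CI %.4f-%.4f)\n", x$name, x$value,
    if (is.na(x$se)) "fixed" else sprintf("%.4f", x$se), x$ci[1L], x$ci[2L]
  ))
  invisible(x)
}

#' Delta-method standard error of a transformed estimate
#'
#' `se = sqrt(g' Sigma g)` with `g` the numerically differentiated (central
#' difference) gradient of `fn` at `theta`. For affine `fn` this is exact
#' variance algebra.
#'
#' @param fn Function of the parameter vector returning a scalar.
#' @param theta Parameter estimates.
#' @param vcov Covariance matrix of `theta`.
#' @param step Finite-difference step (default 1e-6).
#' @return The standard error.
#' @export
delta_method <- function(fn, theta, vcov, step = 1e-6) {
  theta <- as.numeric(theta)
  g <- vapply(seq_along(theta), function(i) {
    e <- replace(numeric(length(theta)), i, step)
    (fn(theta + e) - fn(theta - e)) / (2 * step)
  }, numeric(1))
  if (any(!is.finite(g))) stop("non-finite gradient in delta method", call. = FALSE)
  sqrt(max(0, drop(t(g) %*% vcov %*% g)))
}

#' Inter-seasonal reproductive period (ISRP)
#'
#' Expected number of years between successive breeding seasons for a
#' surviving female: `1 + psi_nb / psi_b`, where `psi_nb` is the departure
#' probability (breeder skips next year) and `psi_b` the arrival
#' probability (non-breeder returns to breed). Always at least 1 (annual
#' breeding when no one departs).
#'
#' @param psi_nb Departure probability in \[0, 1\].
#' @param psi_b Arrival probability in (0, 1\].
#' @param vcov Optional 2x2 covariance of `(psi_nb, psi_b)` for a
#'   delta-method standard error.
#' @return A `derived_estimate`.
#' @export
isrp <- function(psi_nb, psi_b, vcov = NULL) {
  if (psi_b <= 0) stop("isrp undefined: arrival probability is zero", call. = FALSE)
  stopifnot(psi_nb >= 0, psi_nb <= 1, psi_b <= 1)
  value <- 1 + psi_nb / psi_b
  se <- if (is.null(vcov)) {
    NA_real_
  } else {
    delta_method(function(p) 1 + p[1L] / p[2L], c(psi_nb, psi_b), vcov)
  }
  .derived_estimate("ISRP", value, se,
    inputs = c(psi_nb = psi_nb, psi_b = psi_b), lower_bound = 1
  )
}

#' Probability of a subsequent reproductive event
#'
#' For a breeder with annual survival `phi`, departure `psi_nb` and arrival
#' `psi_b`:
#' `P = (1 - psi_nb) phi + psi_nb psi_b phi^2 / (1 - (1 - psi_b) phi)`.
#' Reduces to `phi` when no one departs and to 1 when survival is perfect.
#'
#' @inheritParams isrp
#' @param phi Annual survival probability.
#' @param vcov Optional 3x3 covariance of `(psi_nb, psi_b, phi)`.
#' @return A `derived_estimate`.
#' @export
prob_future_reproduction <- function(psi_nb, psi_b, phi, vcov = NULL) {
  stopifnot(
    psi_nb >= 0, psi_nb <= 1, psi_b >= 0, psi_b <= 1, phi >= 0, phi <= 1
  )
  f <- function(p) {
    den <- 1 - (1 - p[2L]) * p[3L]
    if (den <= 0) stop("zero denominator in P", call. = FALSE)
    (1 - p[1L]) * p[3L] + p[1L] * p[2L] * p[3L]^2 / den
  }
  value <- f(c(psi_nb, psi_b, phi))
  se <- if (is.null(vcov)) {
    NA_real_
  } else {
    delta_method(f, c(psi_nb, psi_b, phi), vcov)
  }
  .derived_estimate("P(future reproduction)", value, se,
    inputs = c(psi_nb = psi_nb, psi_b = psi_b, phi = phi),
    lower_bound = 0, upper_bound = 1
  )
}

#' Expected number of future reproductive events
#'
#' Under a geometric model with per-cycle probability `P`, the expectation
#' is reported as `1 / P`; the conventional mean count of remaining
#' successes, `P / (1 - P)`, is reported side by side as `alternative`.
#'
#' @param P Probability of a subsequent reproductive event, in (0, 1\].
#' @param var_P Optional variance of `P` for a delta-method standard error.
#' @return A `derived_estimate` with an `alternative` element.
#' @export
expected_future_events <- function(P, var_P = NULL) {
  if (P <= 0) stop("expected events undefined at P = 0", call. = FALSE)
  stopifnot(P <= 1)
  value <- 1 / P
  se <- if (is.null(var_P)) {
    NA_real_
  } else {
    delta_method(function(p) 1 / p[1L], P, matrix(var_P, 1, 1))
  }
  alt <- if (P < 1) P / (1 - P) else Inf
  .derived_estimate("E(future events)", value, se,
    inputs = c(P = P),
    lower_bound = 1, alternative = alt
  )
}

# Evaluate one structural probability and its delta-method SE from a fit.
.fit_prob <- function(fit, target, stratum, age, year = NA) {
  form <- fit$design$forms[[target]]
  ix <- fit$compiled$index[[target]]
  if (!stratum %in% names(ix)) {
    stop("fit design lacks stratum '", stratum, "' for ", target, call. = FALSE)
  }
  val <- .eval_form(form, fit$theta, ix, stratum, age, year)
  se <- NA_real_
  if (!is.null(fit$vcov) && all(is.finite(diag(fit$vcov)[ix[[stratum]]]))) {
    se <- delta_method(
      function(th) {
        full <- fit$theta
        full[ix[[stratum]]] <- th
        .eval_form(form, full, ix, stratum, age, year)
      },
      fit$theta[ix[[stratum]]],
      fit$vcov[ix[[stratum]], ix[[stratum]], drop = FALSE]
    )
  }
  c(estimate = unname(val), se = unname(se))
}

#' Age curves of survival against breeding-state transitions
#'
#' Evaluates annual survival and the four breeding transitions (arrive,
#' depart, remain breeder, remain non-breeder) per quality class across an
#' age range, with delta-method confidence bands — the paired-curve view of
#' how the survival-transition relationship is modulated by age.
#'
#' @param fit A `mecmr_fit` whose design stratifies the arrival and
#'   departure transitions by quality.
#' @param ages Integer vector of ages to evaluate.
#' @param level Confidence level (default 0.95).
#' @return A data frame with `age`, `quality`, `parameter`, `estimate`,
#'   `se`, `lower`, `upper`.
#' @export
survival_transition_curve <- function(fit, ages, level = 0.95) {
  forms <- fit$design$forms
  missing <- character(0)
  if (!forms$psiB$by_quality) missing <- c(missing, "psiB by quality")
  if (!forms$psiNB$by_quality) missing <- c(missing, "psiNB by quality")
  if (length(missing) > 0L) {
    stop(
      "fit design lacks the stratification needed for the curve: ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  z <- qnorm(1 - (1 - level) / 2)
  rows <- list()
  year1 <- NA
  for (q in c("lo", "hi")) {
    for (par in c("phi", "psiB", "psiNB")) {
      stratum <- if (forms[[par]]$by_quality) q else "all"
      for (a in ages) {
        v <- .fit_prob(fit, par, stratum, a, year1)
        rows[[length(rows) + 1L]] <- data.frame(
          age = a, quality = if (q == "lo") "low" else "high",
          parameter = switch(par,
            phi = "survival", psiB = "arrival", psiNB = "departure"
          ),
          estimate = v[["estimate"]], se = v[["se"]],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  # complements: probability of remaining in the current breeding state
  rem <- out[out$parameter %in% c("arrival", "departure"), ]
  rem$estimate <- 1 - rem$estimate
  rem$parameter <- ifelse(rem$parameter == "arrival",
    "remain non-breeder", "remain breeder"
  )
  out <- rbind(out, rem)
  out$lower <- pmin(pmax(out$estimate - z * out$se, 0), 1)
  out$upper <- pmin(pmax(out$estimate + z * out$se, 0), 1)
  rownames(out) <- NULL
  out
}
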