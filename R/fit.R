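# Maximum-likelihood fitting of the multi-event model by quasi-Newton
# iteration from multiple random link-scale starts, Wald covariance from a
# central finite-difference Hessian, and quasi-likelihood model selection.

# Central-difference Hessian of a scalar function.
.num_hessian <- function(f, x, step = 1e-4) {
  k <- length(x)
  H <- matrix(NA_real_, k, k)
  f0 <- f(x)
  for (i in seq_len(k)) {
    ei <- replace(numeric(k), i, step)
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / step^2
    if (i > 1L) {
      for (j in seq_len(i - 1L)) {
        ej <- replace(numeric(k), j, step)
        H[i, j] <- H[j, i] <-
          (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
            (4 * step^2)
      }
    }
  }
  H
}

# Indices of quality-stratified coefficient pairs (lo block, hi block) in a
# compiled design, used to orient the latent classes after fitting.
.quality_blocks <- function(design, compiled) {
  out <- list()
  for (nm in names(design$forms)) {
    form <- design$forms[[nm]]
    if (!form$by_quality) next
    ix <- compiled$index[[nm]]
    if (form$by_state) {
      out[[paste0(nm, ".NB")]] <- list(lo = ix[["lo.NB"]], hi = ix[["hi.NB"]])
      out[[paste0(nm, ".B")]] <- list(lo = ix[["lo.B"]], hi = ix[["hi.B"]])
    } else {
      out[[nm]] <- list(lo = ix[["lo"]], hi = ix[["hi"]])
    }
  }
  out
}

# The two latent quality classes are exchangeable (the recruitment tie gives
# them equal weight), so every fit is oriented deterministically: "high"
# quality is the class with the larger arrival probability at the reference
# age (falling back to smaller departure, then larger detection).
.orient_quality <- function(design, compiled, theta, ref_age = 17L) {
  qb <- .quality_blocks(design, compiled)
  if (length(qb) == 0L) {
    return(theta)
  }
  score <- NULL
  for (nm in c("psiB", "psiNB", "p.B", "p", "phi")) {
    if (!nm %in% names(qb)) next
    base <- sub("\\..*$", "", nm)
    form <- design$forms[[base]]
    val <- function(ix) {
      if (form$time_form == "blocks") {
        mean(plogis(theta[ix]))
      } else {
        .eval_form(form, theta, setNames(list(ix), "z"), "z", ref_age, NA)
      }
    }
    d <- val(qb[[nm]]$hi) - val(qb[[nm]]$lo)
    score <- if (nm == "psiNB") -d else d
    break
  }
  if (is.null(score) || score >= 0) {
    return(theta)
  }
  for (b in qb) {
    tmp <- theta[b$lo]
    theta[b$lo] <- theta[b$hi]
    theta[b$hi] <- tmp
  }
  theta
}

#' Fit a multi-event capture-mark-recapture model
#'
#' Maximizes the summed forward-algorithm log-likelihood by BFGS quasi-Newton
#' iteration from `n_starts` random initializations drawn uniformly on the
#' link scale in \[-3, 3\]. The best converged optimum is reported together
#' with all per-start deviances (disagreement between starts beyond the
#' tolerance indicates multimodality). The Wald covariance comes from a
#' central finite-difference Hessian of the negative log-likelihood; because
#' the two latent quality classes are exchangeable, fits are oriented so that
#' the "high" class has the larger arrival probability before the Hessian is
#' evaluated.
#'
#' @param design A [model_design()].
#' @param set A validated `capture_history_set`.
#' @param n_starts Number of random starts (default 10).
#' @param seed Optional integer seed for the random starts.
#' @param tolerance Relative deviance convergence tolerance (default 1e-8).
#' @param maxit Maximum BFGS iterations per start.
#' @param start Optional coefficient vector used as the first start.
#' @param hessian Compute the Wald covariance (default `TRUE`).
#' @param fixed Optional named numeric vector pinning coefficients (by label
#'   or index) at given values; used by [check_identifiability()].
#' @return An object of class `mecmr_fit` with elements `theta` (named
#'   estimates), `vcov`, `se`, `deviance` (-2 log-likelihood), `K`, `N`,
#'   `starts` (per-start record) and `design`.
#' @export
fit_mecmr <- function(design, set, n_starts = 10L, seed = NULL,
                      tolerance = 1e-8, maxit = 500L, start = NULL,
                      hessian = TRUE, fixed = NULL) {
  compiled <- compile_design(design)
  K <- compiled$K
  fixed_idx <- integer(0)
  fixed_val <- numeric(0)
  if (!is.null(fixed)) {
    fixed_idx <- if (is.character(names(fixed)) && all(nzchar(names(fixed)))) {
      match(names(fixed), compiled$labels)
    } else {
      as.integer(names(fixed))
    }
    if (anyNA(fixed_idx)) stop("unknown coefficient in `fixed`", call. = FALSE)
    fixed_val <- as.numeric(fixed)
  }
  free <- setdiff(seq_len(K), fixed_idx)
  expand <- function(par) {
    th <- numeric(K)
    th[free] <- par
    th[fixed_idx] <- fixed_val
    th
  }
  negll <- function(par) {
    ll <- tryCatch(
      .set_loglik(design, expand(par), set, compiled),
      error = function(e) -Inf
    )
    if (!is.finite(ll)) {
      return(1e10)
    }
    -ll
  }
  if (!is.null(seed)) set.seed(seed)
  # random starts are uniform on [-3, 3] on the link scale; age-slope
  # coefficients are divided by the span of the (transformed) age covariate
  # so that their contribution across the observed age range also spans
  # about [-3, 3] rather than swamping the intercept
  max_age <- max(set$years) - min(set$birth_years)
  scale_of <- unlist(lapply(names(design$forms), function(nm) {
    form <- design$forms[[nm]]
    k <- .form_ncoef_within(form)
    xmax <- max(abs((c(0, max_age) - form$age_center) / form$age_scale))
    sc <- if (form$time_form == "blocks" || form$age_form %in% c("constant", "factor")) {
      rep(1, k)
    } else {
      xmax^(0:(k - 1L))
    }
    rep(sc, length(.form_strata(form)))
  }))
  # one start per row, drawn row-wise so that the first k starts are the
  # same whatever n_starts is (the best deviance is monotone in n_starts)
  starts <- t(vapply(
    seq_len(n_starts),
    function(i) runif(length(free), -3, 3) / scale_of[free],
    numeric(length(free))
  ))
  if (length(free) == 1L) starts <- matrix(starts, ncol = 1L)
  if (!is.null(start)) {
    if (length(start) != K) stop("`start` must have length K", call. = FALSE)
    starts[1L, ] <- start[free]
  }
  runs <- vector("list", n_starts)
  for (s in seq_len(n_starts)) {
    opt <- tryCatch(
      optim(starts[s, ], negll,
        method = "BFGS",
        control = list(
          maxit = maxit, reltol = tolerance,
          ndeps = rep(1e-5, length(free))
        )
      ),
      error = function(e) NULL
    )
    runs[[s]] <- if (is.null(opt)) {
      list(par = starts[s, ], value = Inf, converged = FALSE)
    } else {
      list(par = opt$par, value = opt$value, converged = opt$convergence == 0L)
    }
  }
  start_log <- data.frame(
    start = seq_len(n_starts),
    deviance = vapply(runs, function(r) 2 * r$value, numeric(1)),
    converged = vapply(runs, `[[`, logical(1), "converged")
  )
  conv <- which(start_log$converged & is.finite(start_log$deviance))
  if (length(conv) == 0L) {
    stop("no start converged; per-start deviances: ",
      paste(signif(start_log$deviance, 6), collapse = ", "),
      call. = FALSE
    )
  }
  best <- conv[which.min(start_log$deviance[conv])]
  theta <- expand(runs[[best]]$par)
  theta <- .orient_quality(design, compiled, theta)
  names(theta) <- compiled$labels
  vc <- NULL
  se <- rep(NA_real_, K)
  if (hessian && length(free) > 0L) {
    H <- .num_hessian(function(p) negll(p), theta[free])
    vc_free <- tryCatch(solve(H), error = function(e) NULL)
    vc <- matrix(NA_real_, K, K, dimnames = list(compiled$labels, compiled$labels))
    if (is.null(vc_free) || any(!is.finite(vc_free)) || any(diag(vc_free) < 0)) {
      warning("singular or indefinite Hessian: Wald covariance unavailable",
        call. = FALSE
      )
    } else {
      vc[free, free] <- (vc_free + t(vc_free)) / 2
      se <- sqrt(pmax(diag(vc), 0))
    }
  }
  structure(
    list(
      design = design, compiled = compiled, theta = theta, vcov = vc, se = se,
      deviance = 2 * runs[[best]]$value, loglik = -runs[[best]]$value,
      K = K, N = length(set$ids), starts = start_log, best_start = best,
      fixed = fixed, tolerance = tolerance
    ),
    class = "mecmr_fit"
  )
}

#' @export
print.mecmr_fit <- function(x, ...) {
  cat(
    "Multi-event CMR fit:", x$design$label, "\n  K =", x$K, " N =", x$N,
    " deviance =", format(x$deviance, digits = 8), "\n"
  )
  print(coef_table(x), digits = 4)
  invisible(x)
}

#' Coefficient table of a fitted multi-event model
#'
#' @param fit A `mecmr_fit`.
#' @param level Confidence level for Wald intervals (default 0.95).
#' @return A data frame with `label`, `estimate`, `se`, `lower`, `upper`
#'   (link scale).
#' @export
coef_table <- function(fit, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  data.frame(
    label = names(fit$theta), estimate = unname(fit$theta), se = fit$se,
    lower = unname(fit$theta) - z * fit$se,
    upper = unname(fit$theta) + z * fit$se,
    stringsAsFactors = FALSE
  )
}

#' @export
coef.mecmr_fit <- function(object, ...) object$theta

#' @export
vcov.mecmr_fit <- function(object, ...) object$vcov

#' Quasi-Schwarz information criterion
#'
#' `QSIC = deviance / c_hat + ln(N) * K`, where `N` is the number of
#' independent sampling units of the likelihood (capture histories) and
#' `c_hat` the overdispersion coefficient from the goodness-of-fit tests
#' (1 when no correction is applied).
#'
#' @param deviance Model deviance (-2 log-likelihood).
#' @param c_hat Overdispersion coefficient, >= 1.
#' @param N Number of capture histories.
#' @param K Number of estimated coefficients.
#' @return The QSIC score.
#' @export
qsic <- function(deviance, c_hat = 1, N, K) {
  if (c_hat < 1) stop("c_hat must be >= 1 (floor underdispersion at 1)", call. = FALSE)
  deviance / c_hat + log(N) * K
}

#' Quasi-AIC with small-sample correction
#'
#' `QAICc = deviance / c_hat + 2K + 2K(K + 1) / (N - K - 1)`; undefined when
#' `N <= K + 1` (returned as `NA` with a warning).
#'
#' @inheritParams qsic
#' @return The QAICc score, or `NA` when undefined.
#' @export
qaicc <- function(deviance, c_hat = 1, N, K) {
  if (N <= K + 1) {
    warning("QAICc undefined for N <= K + 1; omitted", call. = FALSE)
    return(NA_real_)
  }
  deviance / c_hat + 2 * K + 2 * K * (K + 1) / (N - K - 1)
}

#' Rank competing fits by QSIC
#'
#' Sorts fits by ascending QSIC and flags strong evidence only where the
#' QSIC difference to the best model exceeds 7 units; a pair of fits within
#' 7 units is never reported as strongly distinguished.
#'
#' @param fits A list of `mecmr_fit` objects (or a single fit).
#' @param c_hat Overdispersion coefficient applied to every deviance.
#' @return A data frame with `model`, `K`, `deviance`, `QSIC`, `dQSIC`,
#'   `strong_support` (evidence against the model) and `QAICc`, sorted by
#'   QSIC.
#' @export
model_table <- function(fits, c_hat = 1) {
  if (inherits(fits, "mecmr_fit")) fits <- list(fits)
  tb <- data.frame(
    model = vapply(fits, function(f) f$design$label, character(1)),
    K = vapply(fits, `[[`, numeric(1), "K"),
    deviance = vapply(fits, `[[`, numeric(1), "deviance"),
    stringsAsFactors = FALSE
  )
  tb$QSIC <- mapply(function(d, k, n) qsic(d, c_hat, n, k),
    tb$deviance, tb$K, vapply(fits, `[[`, numeric(1), "N")
  )
  tb$QAICc <- mapply(function(d, k, n) qaicc(d, c_hat, n, k),
    tb$deviance, tb$K, vapply(fits, `[[`, numeric(1), "N")
  )
  tb <- tb[order(tb$QSIC), , drop = FALSE]
  tb$dQSIC <- tb$QSIC - tb$QSIC[1L]
  tb$strong_support <- tb$dQSIC > 7
  rownames(tb) <- NULL
  tb[, c("model", "K", "deviance", "QSIC", "dQSIC", "strong_support", "QAICc")]
}

#' Diagnose non-identifiable coefficients by the fix-and-refit procedure
#'
#' Every coefficient whose reported standard error is zero (or unavailable
#' because its Hessian row is numerically null) is fixed at its estimate and
#' the model refitted from the optimum; a deviance unchanged within
#' `tolerance` marks the coefficient non-identifiable.
#'
#' @param fit A converged `mecmr_fit`.
#' @param set The `capture_history_set` the model was fitted to.
#' @param tolerance Absolute deviance change below which a coefficient is
#'   declared non-identifiable (default 1e-3).
#' @param se_threshold Standard errors at or below this value (or `NA`)
#'   trigger the refit check (default 1e-5).
#' @return A data frame with one row per suspect coefficient:
#'   `coefficient`, `se`, `deviance_change`, `identifiable`; zero rows when
#'   every coefficient is well determined.
#' @export
check_identifiability <- function(fit, set, tolerance = 1e-3,
                                  se_threshold = 1e-5) {
  suspects <- which(is.na(fit$se) | fit$se <= se_threshold)
  suspects <- setdiff(suspects, match(names(fit$fixed), names(fit$theta)))
  out <- data.frame(
    coefficient = character(), se = numeric(), deviance_change = numeric(),
    identifiable = logical(), stringsAsFactors = FALSE
  )
  for (i in suspects) {
    fixed <- c(fit$fixed, setNames(fit$theta[i], names(fit$theta)[i]))
    refit <- fit_mecmr(fit$design, set,
      n_starts = 1L, start = fit$theta,
      hessian = FALSE, fixed = fixed, tolerance = fit$tolerance
    )
    dd <- abs(refit$deviance - fit$deviance)
    out <- rbind(out, data.frame(
      coefficient = names(fit$theta)[i], se = fit$se[i], deviance_change = dd,
      identifiable = dd > tolerance, stringsAsFactors = FALSE
    ))
  }
  out
}
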