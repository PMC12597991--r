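# End-to-end orchestration of the synthetic study: simulate, test fit of the
# time-dependent null (GOF + c-hat), fit candidate designs, rank them by
# QSIC, derive demographic quantities from the best fit, assemble Leslie
# schedules from the simulated reproductive output, and model the
# inter-breeding intervals. Every stage hands off through files in the
# output directory; a manifest records seeds and stage parameters so any
# stage can be re-run in isolation.

#' Configure a full pipeline run
#'
#' @param simulation A `sim_config` for the synthetic cohort.
#' @param designs A non-empty list of [model_design()] objects to compare
#'   (defaults to the generating design of `simulation`).
#' @param chat_source `"gof"` to estimate the overdispersion coefficient
#'   from the goodness-of-fit tests, or a fixed numeric value >= 1.
#' @param output_dir Directory for artifacts (created if missing).
#' @param seed Integer master seed; every stochastic stage derives its seed
#'   from it.
#' @param n_starts Random starts per model fit.
#' @param start_values Optional list (parallel to `designs`) of coefficient
#'   vectors used as the first start of each fit; `NULL` entries fall back
#'   to a purely random start.
#' @param max_age Oldest age class of the Leslie schedules.
#' @param figures Render figures (requires ggplot2).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = default_config(),
                            designs = NULL,
                            chat_source = "gof",
                            output_dir = tempfile("mecmr_run_"),
                            seed = 1L,
                            n_starts = 10L,
                            start_values = NULL,
                            max_age = 45L,
                            figures = FALSE) {
  if (is.null(designs)) designs <- list(generating_design(simulation))
  if (length(designs) == 0L) stop("at least one design is required", call. = FALSE)
  if (is.numeric(chat_source) && chat_source < 1) {
    stop("a fixed c-hat must be >= 1", call. = FALSE)
  }
  if (!is.null(start_values) && length(start_values) != length(designs)) {
    stop("`start_values` must parallel `designs`", call. = FALSE)
  }
  structure(
    list(
      simulation = simulation, designs = designs, chat_source = chat_source,
      output_dir = output_dir, seed = as.integer(seed),
      n_starts = as.integer(n_starts), start_values = start_values,
      max_age = as.integer(max_age), figures = isTRUE(figures)
    ),
    class = "pipeline_config"
  )
}

.stage_msg <- function(log, stage, t0) {
  elapsed <- round(as.numeric(Sys.time()) - t0, 2)
  message(sprintf("[mecmr] %-22s %7.2fs", stage, elapsed))
  c(log, setNames(elapsed, stage))
}

#' Run the full synthetic-study pipeline
#'
#' Executes simulate, GOF + c-hat, model fitting and QSIC ranking, derived
#' demography from the best-supported design, Leslie-trait computation from
#' schedules assembled out of the simulated reproductive output, and the
#' interval models, writing every intermediate artifact plus a run manifest
#' to `config$output_dir`. Identical configs (including seed) give
#' identical numeric outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with every stage result and the artifact
#'   paths.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    stop("`config` must be a pipeline_config", call. = FALSE)
  }
  out <- config$output_dir
  if (!dir.exists(out)) {
    ok <- dir.create(out, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out)) {
      stop("cannot create output directory: ", out, call. = FALSE)
    }
  }
  if (file.access(out, 2L) != 0L) {
    stop("output directory is not writable: ", out, call. = FALSE)
  }
  t0 <- as.numeric(Sys.time())
  log <- numeric(0)
  stage <- "simulate"
  res <- tryCatch(
    {
      # -- simulate ------------------------------------------------------
      sim <- simulate_cohort(config$simulation, seed = config$seed)
      breeding <- simulate_breeding_output(
        sim$truth, config$simulation,
        histories = sim$histories, seed = config$seed + 1L
      )
      write_capture_histories(sim$histories, file.path(out, "histories.csv"))
      write_breeding_records(breeding, file.path(out, "breeding.csv"))
      log <- .stage_msg(log, stage, t0)

      # -- goodness of fit ----------------------------------------------
      stage <- "gof"
      gof <- gof_tests(sim$histories)
      chat <- if (identical(config$chat_source, "gof")) {
        c_hat(gof[c("3.SR", "3.SM", "WBWA")])
      } else {
        list(c_hat = config$chat_source, raw = config$chat_source,
          chi2 = NA_real_, df = NA_integer_)
      }
      jsonlite::write_json(
        list(
          components = lapply(gof, function(g) {
            list(name = g$name, chi2 = g$chi2, df = g$df, p_value = g$p_value)
          }),
          c_hat = chat[c("c_hat", "raw", "chi2", "df")]
        ),
        file.path(out, "gof.json"),
        auto_unbox = TRUE, digits = NA, na = "null"
      )
      log <- .stage_msg(log, stage, t0)

      # -- fit candidate designs ----------------------------------------
      stage <- "fit"
      fits <- lapply(seq_along(config$designs), function(i) {
        fit_mecmr(config$designs[[i]], sim$histories,
          n_starts = config$n_starts, seed = config$seed + 100L + i,
          start = if (is.null(config$start_values)) NULL else config$start_values[[i]]
        )
      })
      for (i in seq_along(fits)) {
        lab <- gsub("[^A-Za-z0-9_-]", "_", fits[[i]]$design$label)
        write.csv(coef_table(fits[[i]]),
          file.path(out, sprintf("fit_%s_coefficients.csv", lab)),
          row.names = FALSE
        )
        jsonlite::write_json(
          list(
            model = fits[[i]]$design$label, deviance = fits[[i]]$deviance,
            K = fits[[i]]$K, N = fits[[i]]$N, c_hat = chat$c_hat,
            QSIC = qsic(fits[[i]]$deviance, chat$c_hat, fits[[i]]$N, fits[[i]]$K),
            starts = fits[[i]]$starts
          ),
          file.path(out, sprintf("fit_%s_meta.json", lab)),
          auto_unbox = TRUE, digits = NA, dataframe = "columns"
        )
      }
      tab <- model_table(fits, c_hat = chat$c_hat)
      write.csv(tab, file.path(out, "model_table.csv"), row.names = FALSE)
      best <- fits[[match(tab$model[1L], vapply(
        fits, function(f) f$design$label, character(1)
      ))]]
      log <- .stage_msg(log, stage, t0)

      # -- derived demography -------------------------------------------
      stage <- "derive"
      adult_ages <- seq(7L, config$max_age)
      curves <- tryCatch(
        survival_transition_curve(best, adult_ages),
        error = function(e) NULL
      )
      if (!is.null(curves)) {
        write.csv(curves, file.path(out, "derived_curves.csv"), row.names = FALSE)
      }
      derived <- .derived_table(best, adult_ages)
      write.csv(derived, file.path(out, "derived.csv"), row.names = FALSE)
      log <- .stage_msg(log, stage, t0)

      # -- Leslie schedules and traits ----------------------------------
      stage <- "traits"
      sched <- pipeline_schedules(sim, breeding, best, max_age = config$max_age)
      write.csv(sched$table, file.path(out, "schedules.csv"), row.names = FALSE)
      L <- build_leslie(
        sched$phi_by_age, sched$eggs_by_age, sched$isrp,
        afr = sched$afr
      )
      traits <- leslie_traits(L)
      jsonlite::write_json(traits, file.path(out, "traits.json"),
        auto_unbox = TRUE, digits = NA
      )
      write.csv(
        cbind(reproductive_value(L), lx = L$lx, mx = L$mx, lxmx = L$lx * L$mx),
        file.path(out, "reproductive_value.csv"),
        row.names = FALSE
      )
      log <- .stage_msg(log, stage, t0)

      # -- interval models ----------------------------------------------
      stage <- "intervals"
      itab <- build_interval_table(breeding, sim$histories)
      write.csv(itab, file.path(out, "intervals.csv"), row.names = FALSE)
      interval_models <- NULL
      if (sum(!itab$censored) >= 20L) {
        cox <- fit_cox(itab, c("age_at_start", "experience"))
        zph <- ph_check(cox)
        ztp <- fit_ztp(itab, c("age_at_start", "experience"))
        interval_models <- list(cox = cox, ph = zph, ztp = ztp)
        jsonlite::write_json(
          list(
            cox = list(
              coefficients = cox$coefficients, pseudo_r2 = cox$pseudo_r2,
              loglik = cox$loglik, n = cox$n, n_events = cox$n_events
            ),
            proportionality = zph,
            ztp = list(
              coefficients = ztp$coefficients, loglik = ztp$loglik,
              vif = as.list(ztp$vif)
            )
          ),
          file.path(out, "interval_models.json"),
          auto_unbox = TRUE, digits = NA, dataframe = "columns"
        )
      }
      log <- .stage_msg(log, stage, t0)

      # -- figures (optional) -------------------------------------------
      if (config$figures && requireNamespace("ggplot2", quietly = TRUE)) {
        stage <- "figures"
        .pipeline_figures(out, curves, L, itab)
        log <- .stage_msg(log, stage, t0)
      }

      # -- manifest ------------------------------------------------------
      manifest <- list(
        package_version = as.character(utils::packageVersion("mecmr")),
        seed = config$seed,
        n_individuals = config$simulation$n_individuals,
        designs = vapply(config$designs, function(d) d$label, character(1)),
        chat_source = if (identical(config$chat_source, "gof")) "gof" else "fixed",
        c_hat = chat$c_hat,
        n_starts = config$n_starts,
        stage_seconds = as.list(log)
      )
      jsonlite::write_json(manifest, file.path(out, "manifest.json"),
        auto_unbox = TRUE, digits = NA
      )
      list(
        simulation = sim, breeding = breeding, gof = gof, c_hat = chat,
        fits = fits, model_table = tab, best_fit = best, derived = derived,
        leslie = L, traits = traits, intervals = itab,
        interval_models = interval_models, output_dir = out
      )
    },
    error = function(e) {
      stop(sprintf(
        "pipeline stage '%s' failed: %s (partial artifacts kept in %s)",
        stage, conditionMessage(e), out
      ), call. = FALSE)
    }
  )
  invisible(res)
}

# Age- and quality-indexed derived quantities from a fit.
.derived_table <- function(fit, ages) {
  forms <- fit$design$forms
  if (!forms$psiB$by_quality || !forms$psiNB$by_quality) {
    return(data.frame(
      quality = character(), age = integer(), isrp = numeric(),
      p_future = numeric(), expected_events = numeric()
    ))
  }
  rows <- list()
  for (q in c("lo", "hi")) {
    for (a in ages) {
      arr <- .fit_prob(fit, "psiB", q, a)[["estimate"]]
      dep <- .fit_prob(fit, "psiNB", q, a)[["estimate"]]
      phi <- .fit_prob(
        fit, "phi",
        if (forms$phi$by_quality) q else "all", a
      )[["estimate"]]
      p <- prob_future_reproduction(dep, arr, phi)$value
      rows[[length(rows) + 1L]] <- data.frame(
        quality = if (q == "lo") "low" else "high", age = a,
        isrp = isrp(dep, arr)$value, p_future = p,
        expected_events = expected_future_events(p)$value
      )
    }
  }
  do.call(rbind, rows)
}

#' Assemble Leslie schedules from a pipeline's intermediate results
#'
#' Survival before the age at first reproduction is one (the simulated
#' population, like the likelihood, conditions on survival to recruitment);
#' from maturity on it is the fitted annual survival. The egg schedule is
#' the observed mean egg count per detected breeding season by age (ages
#' with no observations inherit the overall adult mean); the population
#' ISRP is the observed mean closed inter-breeding interval.
#'
#' @param sim Result of [simulate_cohort()].
#' @param breeding A `breeding_records` data frame.
#' @param fit A `mecmr_fit` providing the survival schedule.
#' @param max_age Oldest age class.
#' @param afr Age at first reproduction anchoring the maternity schedule
#'   (default 7, the known maturity age of the study system). The Leslie
#'   growth rate is hypersensitive to reproduction at very young ages, so
#'   the occasional precocious breeding record in a large simulated cohort
#'   must not shift the schedule; records below `afr` are excluded from
#'   the egg means.
#' @param min_support Minimum number of breeding records an age class needs
#'   to contribute its own egg mean (default 3); sparser classes inside the
#'   reproductive span inherit the overall adult mean.
#' @return A list with `phi_by_age`, `eggs_by_age`, `isrp`, `afr` and a
#'   tidy `table`.
#' @export
pipeline_schedules <- function(sim, breeding, fit, max_age = 45L, afr = 7L,
                               min_support = 3L) {
  ages <- 0:max_age
  birth <- sim$truth$birth_years[match(breeding$individual_id, sim$truth$ids)]
  age_at <- breeding$season_year - birth
  keep <- age_at >= afr
  n_at <- table(factor(age_at[keep], levels = ages))
  mean_eggs <- tapply(breeding$n_eggs[keep], factor(age_at[keep], levels = ages), mean)
  eggs <- as.numeric(mean_eggs)
  overall <- mean(breeding$n_eggs[keep])
  eggs[(is.na(eggs) | n_at < min_support) & ages >= afr] <- overall
  eggs[ages < afr] <- 0
  phi_form <- fit$design$forms$phi
  stratum <- if (phi_form$by_quality || phi_form$by_state) {
    names(fit$compiled$index$phi)[1L]
  } else {
    "all"
  }
  phi_ad <- .eval_form(
    phi_form, fit$theta, fit$compiled$index$phi, stratum,
    ages, NA
  )
  phi <- ifelse(ages < afr, 1, phi_ad)
  # observed population-level ISRP: mean closed inter-breeding interval
  isrp_obs <- {
    d <- unlist(lapply(
      split(breeding$season_year, breeding$individual_id),
      function(y) diff(sort(y))
    ))
    if (length(d) == 0L) 1 else mean(d)
  }
  list(
    phi_by_age = phi, eggs_by_age = eggs, isrp = max(1, isrp_obs), afr = afr,
    table = data.frame(age = ages, phi = phi, eggs = eggs)
  )
}

#' All Leslie-matrix life-history traits of a model
#'
#' @param L A `leslie_model`.
#' @return A named list: `lambda`, `r`, `R0`, `T_gen`, `T_stable`, `e0`,
#'   `e_adult`, `gini`, `pace_aging`, `pace_fec`, `shape_surv`,
#'   `shape_rep`, and the Euler-Lotka residual.
#' @export
leslie_traits <- function(L) {
  g <- growth_rates(L)
  rt <- r0_and_generation_time(L)
  le <- life_expectancies(L)
  ps <- pace_shape(L)
  adult <- L$ages >= L$afr
  list(
    lambda = g[["lambda"]], r = g[["r"]],
    R0 = rt$R0, T_gen = rt$T_gen, T_stable = rt$T_stable,
    e0 = le[["e0"]], e_adult = le[["e_adult"]],
    gini = gini_index((L$lx * L$mx)[adult]),
    pace_aging = ps$pace_aging, pace_fec = ps$pace_fec,
    shape_surv = ps$shape_surv, shape_rep = ps$shape_rep,
    euler_lotka_residual =
      sum(g[["lambda"]]^(-L$ages) * L$lx * L$mx) - 1
  )
}

# Minimal figure set rendered from pipeline artifacts (synthetic analogues
# of the study's transition/survival, reproductive-value and interval
# figures).
.pipeline_figures <- function(out, curves, L, itab) {
  fig_dir <- file.path(out, "figures")
  dir.create(fig_dir, showWarnings = FALSE)
  gg <- ggplot2::ggplot
  aes <- ggplot2::aes
  if (!is.null(curves)) {
    p1 <- gg(curves, aes(age, estimate, colour = quality)) +
      ggplot2::geom_line() +
      ggplot2::geom_ribbon(aes(ymin = lower, ymax = upper, fill = quality),
        alpha = 0.2, colour = NA
      ) +
      ggplot2::facet_wrap(~parameter) +
      ggplot2::labs(y = "probability")
    ggplot2::ggsave(file.path(fig_dir, "transitions_by_age.pdf"), p1,
      width = 8, height = 6
    )
  }
  rv <- reproductive_value(L)
  p2 <- gg(rv, aes(age, residual)) +
    ggplot2::geom_line() +
    ggplot2::labs(y = "residual reproductive value (v0 units)")
  ggplot2::ggsave(file.path(fig_dir, "residual_reproductive_value.pdf"), p2,
    width = 6, height = 4
  )
  closed <- itab[!itab$censored, , drop = FALSE]
  if (nrow(closed) > 0L) {
    p3 <- gg(closed, aes(experience, interval_years)) +
      ggplot2::geom_jitter(width = 0.2, height = 0.1, alpha = 0.3) +
      ggplot2::geom_smooth(method = "lm", formula = y ~ x) +
      ggplot2::labs(x = "breeding experience", y = "interval (years)")
    ggplot2::ggsave(file.path(fig_dir, "intervals_by_experience.pdf"), p3,
      width = 6, height = 4
    )
  }
  invisible(NULL)
}
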