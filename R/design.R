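# Declarative model designs: each structural parameter of the multi-event
# model (survival phi, arrival psiB, departure psiNB, recruitment psiR,
# subadult detection pSA, adult detection p, dead-recovery pFD) gets a
# functional form on the link (logit) scale. A design compiles to a finite
# labelled coefficient vector theta.

.targets <- c("phi", "psiB", "psiNB", "psiR", "pSA", "p", "pFD")

#' Describe the functional form of one structural parameter
#'
#' Age-structured parameters (`phi`, `psiB`, `psiNB`, `psiR`) take a
#' constant, linear-logistic, quadratic-logistic or age-factor form; the
#' detection parameters (`p`, `pFD`) take a constant or year-block form.
#' Quality stratification (`by_quality`) fits separate coefficients for the
#' low- and high-quality latent classes; state stratification (`by_state`)
#' separates non-breeders from breeders (detection and survival only).
#'
#' Age enters the link function in years by default (`age_center = 0`,
#' `age_scale = 1`), so coefficients are per-year logit slopes. A non-trivial
#' centring/scaling may be supplied, e.g. for survival, where slopes are
#' conventionally reported per standardized age unit.
#'
#' @param target One of `"phi"`, `"psiB"`, `"psiNB"`, `"psiR"`, `"pSA"`,
#'   `"p"`, `"pFD"`.
#' @param age_form `"constant"`, `"linear"`, `"quadratic"` or `"factor"`.
#' @param by_quality,by_state Logical stratification flags.
#' @param time_form `"constant"` or `"blocks"` (detection parameters only).
#' @param blocks For `time_form = "blocks"`: a named list of integer year
#'   vectors partitioning the occasions, e.g.
#'   `list(baseline = 1974:2001, hurricane = 2002:2003, late = 2004:2018)`.
#' @param age_center,age_scale Affine transform applied to age before the
#'   link function: `x = (age - age_center) / age_scale`.
#' @param age_bins For `age_form = "factor"`: a list of integer age vectors;
#'   the default pools ages 0-6 and 36-45 and fits single-year classes
#'   between.
#' @return An object of class `param_form`.
#' @export
param_form <- function(target, age_form = "constant", by_quality = FALSE,
                       by_state = FALSE, time_form = "constant", blocks = NULL,
                       age_center = 0, age_scale = 1, age_bins = NULL) {
  target <- match.arg(target, .targets)
  age_form <- match.arg(age_form, c("constant", "linear", "quadratic", "factor"))
  time_form <- match.arg(time_form, c("constant", "blocks"))
  if (time_form == "blocks" && !(target %in% c("p", "pFD"))) {
    stop("year blocks are only supported for detection parameters p and pFD",
      call. = FALSE
    )
  }
  if (time_form == "blocks" && age_form != "constant") {
    stop("a parameter may be structured by age or by year blocks, not both",
      call. = FALSE
    )
  }
  if (time_form == "blocks" && (is.null(blocks) || is.null(names(blocks)))) {
    stop("`blocks` must be a named list of year vectors", call. = FALSE)
  }
  if (by_state && !(target %in% c("phi", "p"))) {
    stop("state stratification applies to phi and p only", call. = FALSE)
  }
  if (by_quality && target %in% c("psiR", "pSA", "pFD")) {
    stop(target, " cannot be stratified by quality", call. = FALSE)
  }
  if (target == "psiR" && age_form == "factor") {
    warning(
      "an age-factor form for recruitment is rarely identifiable ",
      "(recruitment movement is not a biological age process); ",
      "consider constant or quadratic",
      call. = FALSE
    )
  }
  if (age_form == "factor" && is.null(age_bins)) {
    age_bins <- c(list(0:6), as.list(7:35), list(36:45))
  }
  structure(
    list(
      target = target, age_form = age_form, by_quality = by_quality,
      by_state = by_state, time_form = time_form, blocks = blocks,
      age_center = age_center, age_scale = age_scale, age_bins = age_bins
    ),
    class = "param_form"
  )
}

#' Assemble a full model design
#'
#' One [param_form()] per structural parameter. Recruitment is always tied:
#' the five cells governing entry to the breeding population (J to SA, J to
#' B-, J to B+, SA to B-, SA to B+) share the single recruitment parameter
#' psiR, so the two latent quality classes receive equal weight at
#' recruitment.
#'
#' @param phi,psiB,psiNB,psiR,pSA,p,pFD [param_form()] objects (defaults:
#'   constant forms).
#' @param label Optional model label used in comparison tables.
#' @return An object of class `model_design`.
#' @export
model_design <- function(phi = param_form("phi"),
                         psiB = param_form("psiB"),
                         psiNB = param_form("psiNB"),
                         psiR = param_form("psiR"),
                         pSA = param_form("pSA"),
                         p = param_form("p"),
                         pFD = param_form("pFD"),
                         label = "model") {
  forms <- list(
    phi = phi, psiB = psiB, psiNB = psiNB, psiR = psiR,
    pSA = pSA, p = p, pFD = pFD
  )
  for (nm in names(forms)) {
    if (!inherits(forms[[nm]], "param_form") || forms[[nm]]$target != nm) {
      stop("argument `", nm, "` must be a param_form with target '", nm, "'",
        call. = FALSE
      )
    }
  }
  structure(list(forms = forms, label = label), class = "model_design")
}

# Strata for a form: quality classes and/or states it distinguishes.
.form_strata <- function(form) {
  q <- if (form$by_quality) c("lo", "hi") else "all"
  s <- if (form$by_state) c("NB", "B") else "all"
  as.vector(outer(q, s, function(a, b) {
    paste0(
      ifelse(a == "all", "", a),
      ifelse(a != "all" & b != "all", ".", ""),
      ifelse(b == "all", "", b)
    )
  }))
}

.form_ncoef_within <- function(form) {
  if (form$time_form == "blocks") {
    return(length(form$blocks))
  }
  switch(form$age_form,
    constant = 1L, linear = 2L, quadratic = 3L,
    factor = length(form$age_bins)
  )
}

.form_coef_names <- function(form) {
  within <- if (form$time_form == "blocks") {
    names(form$blocks)
  } else {
    switch(form$age_form,
      constant = "b0", linear = c("b0", "b1"), quadratic = c("b0", "b1", "b2"),
      factor = vapply(form$age_bins, function(b) {
        if (length(b) > 1L) sprintf("a%d_%d", min(b), max(b)) else sprintf("a%d", b)
      }, character(1))
    )
  }
  strata <- .form_strata(form)
  unlist(lapply(strata, function(s) {
    if (nzchar(s)) paste(form$target, s, within, sep = ".") else paste(form$target, within, sep = ".")
  }))
}

#' Compile a model design to a labelled coefficient layout
#'
#' @param design A [model_design()].
#' @return A list with the coefficient `labels`, total count `K`, and an
#'   index map per parameter block.
#' @export
compile_design <- function(design) {
  idx <- list()
  labels <- character()
  pos <- 0L
  for (nm in names(design$forms)) {
    form <- design$forms[[nm]]
    strata <- .form_strata(form)
    k <- .form_ncoef_within(form)
    block <- list()
    for (s in strata) {
      block[[if (nzchar(s)) s else "all"]] <- pos + seq_len(k)
      pos <- pos + k
    }
    idx[[nm]] <- block
    labels <- c(labels, .form_coef_names(form))
  }
  list(labels = labels, K = pos, index = idx)
}

#' Evaluate a logistic age form
#'
#' `expit(b0 + b1 x)` (linear) or `expit(b0 + b1 x + b2 x^2)` (quadratic)
#' with `x = (age - center) / scale`; a single coefficient gives the
#' constant form. Values are strictly inside (0, 1).
#'
#' @param coeffs Numeric coefficients on the logit scale (length 1, 2 or 3).
#' @param age Integer age(s) in years.
#' @param center,scale Affine age transform.
#' @return Probability vector, same length as `age`.
#' @export
logistic_age <- function(coeffs, age, center = 0, scale = 1) {
  x <- (age - center) / scale
  eta <- switch(as.character(length(coeffs)),
    "1" = rep(coeffs[1L], length(x)),
    "2" = coeffs[1L] + coeffs[2L] * x,
    "3" = coeffs[1L] + coeffs[2L] * x + coeffs[3L] * x^2,
    stop("coefficient count must be 1 (constant), 2 (linear) or 3 (quadratic)",
      call. = FALSE
    )
  )
  plogis(eta)
}

# Evaluate one stratum of a form over ages (vector) and a single year.
.eval_form <- function(form, theta, idx_block, stratum, ages, year) {
  co <- theta[idx_block[[stratum]]]
  if (form$time_form == "blocks") {
    b <- which(vapply(form$blocks, function(y) year %in% y, logical(1)))
    if (length(b) != 1L) {
      stop("year ", year, " not covered by exactly one block of ", form$target,
        call. = FALSE
      )
    }
    return(rep(plogis(co[b]), length(ages)))
  }
  if (form$age_form == "factor") {
    bin <- vapply(ages, function(a) {
      w <- which(vapply(form$age_bins, function(bb) a %in% bb, logical(1)))
      if (length(w) != 1L) {
        stop("age ", a, " not covered by exactly one bin of ", form$target,
          call. = FALSE
        )
      }
      w
    }, integer(1))
    return(plogis(co[bin]))
  }
  logistic_age(co, ages, form$age_center, form$age_scale)
}

# Pick the stratum key for a (quality, state) pair given a form's flags.
.stratum_key <- function(form, quality, state) {
  q <- if (form$by_quality) quality else ""
  s <- if (form$by_state) state else ""
  key <- paste0(q, if (nzchar(q) && nzchar(s)) "." else "", s)
  if (!nzchar(key)) "all" else key
}
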