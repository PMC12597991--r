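# Construction of the survival (phi), conditional transition (psi) and event
# (p) matrices over the eight-state space at a given age and occasion year.
# Rows of every matrix sum to one; the complete state transition matrix is
# the product phi %*% psi.

# Evaluate all structural parameter values at a vector of ages and one year.
.param_values <- function(design, theta, compiled, ages, year) {
  f <- design$forms
  ix <- compiled$index
  ev <- function(nm, stratum) .eval_form(f[[nm]], theta, ix[[nm]], stratum, ages, year)
  phi_of <- function(quality, state) {
    ev("phi", .stratum_key(f$phi, quality, state))
  }
  p_of <- function(quality, state) {
    ev("p", .stratum_key(f$p, quality, state))
  }
  list(
    phiNBlo = phi_of("lo", "NB"), phiNBhi = phi_of("hi", "NB"),
    phiBlo = phi_of("lo", "B"), phiBhi = phi_of("hi", "B"),
    psiBlo = ev("psiB", if (f$psiB$by_quality) "lo" else "all"),
    psiBhi = ev("psiB", if (f$psiB$by_quality) "hi" else "all"),
    psiNBlo = ev("psiNB", if (f$psiNB$by_quality) "lo" else "all"),
    psiNBhi = ev("psiNB", if (f$psiNB$by_quality) "hi" else "all"),
    psiR = ev("psiR", "all"),
    pSA = ev("pSA", "all"),
    pNBlo = p_of("lo", "NB"), pNBhi = p_of("hi", "NB"),
    pBlo = p_of("lo", "B"), pBhi = p_of("hi", "B"),
    pFD = ev("pFD", "all")
  )
}

# Fill the three matrices from scalar parameter values.
.matrices_from_values <- function(v) {
  phi <- diag(8)
  phi[3, 3] <- v$phiNBlo; phi[3, 7] <- 1 - v$phiNBlo
  phi[4, 4] <- v$phiNBhi; phi[4, 7] <- 1 - v$phiNBhi
  phi[5, 5] <- v$phiBlo; phi[5, 7] <- 1 - v$phiBlo
  phi[6, 6] <- v$phiBhi; phi[6, 7] <- 1 - v$phiBhi
  phi[7, 7] <- 0; phi[7, 8] <- 1 # freshly dead moves to dead

  psi <- diag(8)
  psi[1, ] <- c(1 - 3 * v$psiR, v$psiR, 0, 0, v$psiR, v$psiR, 0, 0)
  psi[2, ] <- c(0, 1 - 2 * v$psiR, 0, 0, v$psiR, v$psiR, 0, 0)
  psi[3, ] <- c(0, 0, 1 - v$psiBlo, 0, v$psiBlo, 0, 0, 0)
  psi[4, ] <- c(0, 0, 0, 1 - v$psiBhi, 0, v$psiBhi, 0, 0)
  psi[5, ] <- c(0, 0, v$psiNBlo, 0, 1 - v$psiNBlo, 0, 0, 0)
  psi[6, ] <- c(0, 0, 0, v$psiNBhi, 0, 1 - v$psiNBhi, 0, 0)

  p <- matrix(0, 8, 6)
  p[1, 2] <- 1 # juveniles are always detected as J
  p[2, ] <- c(1 - v$pSA, 0, v$pSA, 0, 0, 0)
  p[3, ] <- c(1 - v$pNBlo, 0, 0, v$pNBlo, 0, 0)
  p[4, ] <- c(1 - v$pNBhi, 0, 0, v$pNBhi, 0, 0)
  p[5, ] <- c(1 - v$pBlo, 0, 0, 0, v$pBlo, 0)
  p[6, ] <- c(1 - v$pBhi, 0, 0, 0, v$pBhi, 0)
  p[7, ] <- c(1 - v$pFD, 0, 0, 0, 0, v$pFD)
  p[8, 1] <- 1 # dead emits "not observed"
  dimnames(phi) <- dimnames(psi) <- list(.states, .states)
  dimnames(p) <- list(.states, .events)
  list(phi = phi, psi = psi, p = p)
}

#' Build the survival, transition and event matrices at one age and year
#'
#' The survival matrix phi sends juveniles and subadults forward with
#' probability one (the likelihood conditions on survival to recruitment),
#' moves adults to the freshly-dead (FD) state with probability `1 - phi`,
#' sends FD deterministically to dead (D), and keeps D absorbing. The
#' transition matrix psi applies the recruitment tie on the juvenile row
#' (`1 - 3 psiR, psiR, 0, 0, psiR, psiR, 0, 0`), lets subadults exit to
#' either breeder class, alternates adults between breeding and non-breeding
#' within a fixed quality class, and never moves mass between quality
#' classes. The event matrix p emits coded events per state: J is detected
#' with probability one, FD emits code 5 with probability pFD in the year of
#' death only, D always emits code 0.
#'
#' @param design A [model_design()].
#' @param theta Coefficient vector compiled against `design`.
#' @param age Integer age in years.
#' @param year Occasion (calendar) year.
#' @return A list of matrices `phi` (8x8), `psi` (8x8) and `p` (8x6), each
#'   row-stochastic.
#' @export
build_matrices <- function(design, theta, age, year) {
  compiled <- compile_design(design)
  if (length(theta) != compiled$K) {
    stop("theta has length ", length(theta), " but the design compiles to K = ",
      compiled$K,
      call. = FALSE
    )
  }
  v <- .param_values(design, theta, compiled, age, year)
  if (3 * v$psiR > 1) {
    stop("recruitment probability ", signif(v$psiR, 4), " at age ", age,
      " exceeds 1/3: the three simultaneous exit routes from J would give ",
      "the juvenile row negative mass",
      call. = FALSE
    )
  }
  .matrices_from_values(lapply(v, function(x) x[[1L]]))
}

# Precompute, for the whole design, the per-age transition products
# M[, , a] = phi(a) %*% psi(a) and per-year event matrices E[, , y].
# Ages are 0..max_age; years span the occasion range.
.model_arrays <- function(design, theta, compiled, max_age, years) {
  ages <- 0:max_age
  v <- .param_values(design, theta, compiled, ages, years[1L])
  # the three tied exit routes from J share one value, so the cell
  # probability is capped just below 1/3 to keep the row stochastic at any
  # link-scale coefficient the optimizer may visit
  v$psiR <- pmin(v$psiR, 1 / 3 - 1e-9)
  M <- build_M_cpp(
    v$phiNBlo, v$phiNBhi, v$phiBlo, v$phiBhi,
    v$psiBlo, v$psiBhi, v$psiNBlo, v$psiNBhi, v$psiR
  )
  E <- array(0, c(8, 6, length(years)))
  # detection varies only through year blocks, so one event matrix is built
  # per distinct (p-block, pFD-block) combination and shared across years
  block_of <- function(form, year) {
    if (form$time_form != "blocks") {
      return(0L)
    }
    which(vapply(form$blocks, function(yy) year %in% yy, logical(1)))[1L]
  }
  keys <- vapply(years, function(y) {
    paste(block_of(design$forms$p, y), block_of(design$forms$pFD, y))
  }, character(1))
  for (k in unique(keys)) {
    y1 <- years[match(k, keys)]
    vy <- .param_values(design, theta, compiled, 0L, y1)
    E[, , keys == k] <- .matrices_from_values(lapply(vy, function(x) x[[1L]]))$p
  }
  list(M = M, E = E, ages = ages, years = years)
}
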