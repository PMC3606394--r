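#' @useDynLib nox1design, .registration = TRUE
#' @importFrom stats rnorm runif setNames
#' @importFrom graphics hist
#' @importFrom utils write.csv
"_PACKAGE"

STATE_NAMES <- c("x1", "x2", "x3", "x4", "x5", "x6", "x7", "x8")
FLUX_NAMES  <- paste0("f", 1:16)
GAMMA_NAMES <- paste0("gamma", 1:16)

#' Stoichiometry matrix of the Nox1 assembly/disassembly network
#'
#' Returns the fixed 8 x 16 stoichiometry matrix `N` of the reaction network,
#' rows indexed by the states `x1..x8` (active Nox1 complex, Nox1/p22,
#' p47phox, phosphorylated p47phox, Rac1-GDP, Rac1-GTP, NoxA1, phosphorylated
#' NoxA1) and columns by the fluxes `f1..f16`. The model evolves as
#' `dX/dt = N %*% F`.
#'
#' Columns: f1 assembles the active complex from x2, x4, x6 and x7; the three
#' recycling pathways f2, f3, f4 each dissociate x1 back into Nox1/p22 plus
#' the three cytosolic subunits, returning exactly one of them in its
#' inactive form (f2 -> NoxA1_P, f3 -> unphosphorylated p47, f4 -> Rac1-GDP);
#' f5..f10 are the three reversible activation/deactivation reactions;
#' f11, f12, f13, f15 are constant influxes of x2, x3, x5, x7; f14 is
#' proteolysis of the active complex and f16 degradation of NoxA1_P.
#'
#' @return An 8 x 16 integer matrix with entries in \{-1, 0, 1\} and
#'   dimnames `(x1..x8, f1..f16)`.
#' @export
#' @examples
#' N <- build_stoichiometry()
#' N[, "f14"]  # proteolysis removes only the active complex
build_stoichiometry <- function() {
  N <- matrix(0L, nrow = 8, ncol = 16,
              dimnames = list(STATE_NAMES, FLUX_NAMES))
  add <- function(flux, consumed, produced) {
    N[consumed, flux] <<- -1L
    N[produced, flux] <<- 1L
  }
  add("f1", c("x2", "x4", "x6", "x7"), "x1")
  add("f2", "x1", c("x2", "x4", "x6", "x8"))
  add("f3", "x1", c("x2", "x3", "x6", "x7"))
  add("f4", "x1", c("x2", "x4", "x5", "x7"))
  add("f5", "x3", "x4")
  add("f6", "x4", "x3")
  add("f7", "x5", "x6")
  add("f8", "x6", "x5")
  add("f9", "x7", "x8")
  add("f10", "x8", "x7")
  N["x2", "f11"] <- 1L
  N["x3", "f12"] <- 1L
  N["x5", "f13"] <- 1L
  N["x1", "f14"] <- -1L
  N["x7", "f15"] <- 1L
  N["x8", "f16"] <- -1L
  N
}

#' Control (unstimulated) signal vector
#'
#' @return Named vector `c(s1 = 1, s2 = 1, s3 = 1)`.
#' @export
control_signals <- function() c(s1 = 1, s2 = 1, s3 = 1)

#' Step one or more signals to a stimulus magnitude
#'
#' Any signal value above 1 is a stimulus; the control value is 1.
#'
#' @param which character subset of `c("s1", "s2", "s3")`.
#' @param magnitude positive scalar, the stepped intensity (default 10).
#' @return Named signal vector.
#' @export
signal_step <- function(which, magnitude = 10) {
  stopifnot(all(which %in% c("s1", "s2", "s3")), magnitude > 0)
  s <- control_signals()
  s[which] <- magnitude
  s
}

check_state <- function(state) {
  stopifnot(length(state) == 8, all(is.finite(state)))
  if (any(state < 0))
    stop("state concentrations must be non-negative")
  invisible(state)
}

#' Mass-action fluxes of the Nox1 network
#'
#' Evaluates the 16 mass-action rate laws: `f1 = gamma1 x2 x4 x6 x7`,
#' `f2 = gamma2 x1`, `f3 = gamma3 x1`, `f4 = gamma4 x1`,
#' `f5 = gamma5 x3 S1`, `f6 = gamma6 x4`, `f7 = gamma7 x5 S2`,
#' `f8 = gamma8 x6`, `f9 = gamma9 x7 S3`, `f10 = gamma10 x8`,
#' `f11..f13, f15` constant, `f14 = gamma14 x1`, `f16 = gamma16 x8`.
#'
#' @param state numeric length-8 non-negative state vector.
#' @param signals named signal vector, e.g. [control_signals()].
#' @param gamma numeric length-16 non-negative rate constants.
#' @return Named numeric length-16 flux vector.
#' @export
evaluate_fluxes <- function(state, signals = control_signals(), gamma) {
  stopifnot(length(gamma) == 16, all(is.finite(gamma)), all(gamma >= 0),
            length(signals) == 3, all(is.finite(signals)), all(signals > 0))
  check_state(state)
  x <- unname(state); g <- unname(gamma); s <- unname(signals)
  f <- c(g[1] * x[2] * x[4] * x[6] * x[7],
         g[2] * x[1],
         g[3] * x[1],
         g[4] * x[1],
         g[5] * x[3] * s[1],
         g[6] * x[4],
         g[7] * x[5] * s[2],
         g[8] * x[6],
         g[9] * x[7] * s[3],
         g[10] * x[8],
         g[11],
         g[12],
         g[13],
         g[14] * x[1],
         g[15],
         g[16] * x[8])
  setNames(f, FLUX_NAMES)
}

#' Time derivative dX/dt = N F
#'
#' @inheritParams evaluate_fluxes
#' @return Named numeric length-8 derivative vector.
#' @export
time_derivative <- function(state, signals = control_signals(), gamma) {
  drop(build_stoichiometry() %*% evaluate_fluxes(state, signals, gamma))
}

#' Jacobian of the right-hand side
#'
#' Analytic Jacobian `d(NF)/dx`, used by the Newton steady-state polish.
#'
#' @inheritParams evaluate_fluxes
#' @return 8 x 8 numeric matrix.
#' @export
rhs_jacobian <- function(state, signals = control_signals(), gamma) {
  x <- unname(state); g <- unname(gamma); s <- unname(signals)
  dF <- matrix(0, nrow = 16, ncol = 8)
  dF[1, 2] <- g[1] * x[4] * x[6] * x[7]
  dF[1, 4] <- g[1] * x[2] * x[6] * x[7]
  dF[1, 6] <- g[1] * x[2] * x[4] * x[7]
  dF[1, 7] <- g[1] * x[2] * x[4] * x[6]
  dF[2, 1] <- g[2]
  dF[3, 1] <- g[3]
  dF[4, 1] <- g[4]
  dF[5, 3] <- g[5] * s[1]
  dF[6, 4] <- g[6]
  dF[7, 5] <- g[7] * s[2]
  dF[8, 6] <- g[8]
  dF[9, 7] <- g[9] * s[3]
  dF[10, 8] <- g[10]
  dF[14, 1] <- g[14]
  dF[16, 8] <- g[16]
  build_stoichiometry() %*% dF
}

#' Integrate the Nox1 network ODE
#'
#' Integrates `dX/dt = N F` with a stiff-capable solver
#' ([deSolve::lsoda()]), using the compiled right-hand side. Small negative
#' solver overshoots (within tolerance) are clipped to zero; larger
#' violations raise an error with solver diagnostics.
#'
#' @param state0 initial state (length 8, non-negative).
#' @param signals named signal vector.
#' @param gamma rate constants (length 16).
#' @param times strictly increasing time grid starting at 0, in model time
#'   units (1 unit = 1 minute).
#' @param rtol,atol solver tolerances (defaults 1e-6 / 1e-9).
#' @param compiled use the compiled C right-hand side (default) or the pure-R
#'   [time_derivative()]; both define the same model.
#' @return A `nox1_trajectory`: data.frame with columns `time`, `x1..x8` and
#'   attribute `converged`.
#' @export
integrate_nox1 <- function(state0, signals = control_signals(), gamma, times,
                           rtol = 1e-6, atol = 1e-9, compiled = TRUE) {
  check_state(state0)
  stopifnot(length(times) >= 2, all(diff(times) > 0))
  parms <- c(unname(gamma), unname(signals))
  if (compiled) {
    out <- deSolve::lsoda(y = setNames(unname(state0), STATE_NAMES),
                          times = times, func = "nox1_derivs", parms = parms,
                          dllname = "nox1design", initfunc = "nox1_init",
                          rtol = rtol, atol = atol)
  } else {
    rhs <- function(t, y, p)
      list(unname(time_derivative(y, signals, gamma)))
    out <- deSolve::lsoda(y = setNames(unname(state0), STATE_NAMES),
                          times = times, func = rhs, parms = NULL,
                          rtol = rtol, atol = atol)
  }
  istate <- attr(out, "istate")[1]
  if (is.null(istate)) istate <- 2L
  if (istate < 0 || nrow(out) < length(times))
    stop("ODE solver failed (istate = ", istate, ") at t = ",
         out[nrow(out), "time"], "; last state: ",
         paste(signif(out[nrow(out), -1], 4), collapse = ", "))
  df <- as.data.frame(unclass(out)[seq_len(nrow(out)), , drop = FALSE])
  states <- as.matrix(df[, STATE_NAMES])
  floor_neg <- -max(1e-6, 1e-6 * max(abs(state0)))
  if (min(states) < floor_neg)
    stop("integrated state fell below the non-negativity tolerance (min = ",
         signif(min(states), 4), ")")
  df[, STATE_NAMES] <- pmax(states, 0)
  structure(df, class = c("nox1_trajectory", "data.frame"), converged = TRUE)
}

#' @export
print.nox1_trajectory <- function(x, ...) {
  cat("Nox1 trajectory: ", nrow(x), " time points on [",
      x$time[1], ", ", x$time[nrow(x)], "]\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 4), ...)
  if (nrow(x) > 4) cat("...\n")
  invisible(x)
}

#' Moiety totals of the four subunit pools
#'
#' In the fully closed system (all influx/efflux and proteolysis rate
#' constants zero) the four totals `x1+x2`, `x1+x3+x4`, `x1+x5+x6`,
#' `x1+x7+x8` are first integrals of the dynamics.
#'
#' @param state length-8 state vector, or a `nox1_trajectory`.
#' @return Named numeric vector (or matrix, one row per time point) with
#'   entries `nox1`, `p47`, `rac1`, `noxa1`.
#' @export
moiety_totals <- function(state) {
  if (inherits(state, "nox1_trajectory") || is.data.frame(state)) {
    m <- as.matrix(state[, STATE_NAMES])
    return(cbind(nox1 = m[, 1] + m[, 2],
                 p47 = m[, 1] + m[, 3] + m[, 4],
                 rac1 = m[, 1] + m[, 5] + m[, 6],
                 noxa1 = m[, 1] + m[, 7] + m[, 8]))
  }
  x <- unname(state)
  c(nox1 = x[1] + x[2], p47 = x[1] + x[3] + x[4],
    rac1 = x[1] + x[5] + x[6], noxa1 = x[1] + x[7] + x[8])
}
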