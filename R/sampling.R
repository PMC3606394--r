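#' Table of the 8 initial-condition codes
#'
#' Each code is a binary triple over the three cytosolic subunit states
#' (phosphorylated p47, GTP-bound Rac1, phosphorylated NoxA1): bit 0 means
#' the active form is drawn from the low truncated Gaussian (inactive form
#' dominant), bit 1 from the high one. Code 1 = (0,0,0) ... code 8 = (1,1,1).
#'
#' @param code integer in 1..8.
#' @return Named integer vector `c(p47P, rac1GTP, noxa1P)`.
#' @export
ic_code_bits <- function(code) {
  stopifnot(length(code) == 1, code %in% 1:8)
  bits <- as.integer(intToBits(code - 1))[3:1]
  setNames(bits, c("p47P", "rac1GTP", "noxa1P"))
}

#' Draw an active-form concentration from the truncated Gaussians
#'
#' Bit 0: draw from N(25, sd 5), values at or below 5 set to 5, values
#' above 50 set to 50. Bit 1: draw from N(75, sd 5), values at or below 50
#' set to 50, values above 95 set to 95. The clamping produces point masses
#' at the interval bounds, as specified.
#'
#' @param bit 0 or 1.
#' @param n number of draws.
#' @param sd standard deviation of the Gaussian (default 5; 0 gives the
#'   degenerate mean, useful in tests).
#' @return Numeric vector of length `n` in `[5, 50]` (bit 0) or `[50, 95]`
#'   (bit 1).
#' @export
sample_active_fraction <- function(bit, n = 1, sd = 5) {
  stopifnot(bit %in% c(0, 1))
  if (bit == 0) {
    x <- rnorm(n, mean = 25, sd = sd)
    pmin(pmax(x, 5), 50)
  } else {
    x <- rnorm(n, mean = 75, sd = sd)
    pmin(pmax(x, 50), 95)
  }
}

#' Sample an initial (reference) state for a given code
#'
#' The active forms x4 (p47_P), x6 (Rac1_GTP), x8 (NoxA1_P) are drawn per
#' the three code bits; their partners are the complements to the fixed
#' pair total (default 100), so `x3 + x4 = x5 + x6 = x7 + x8 = 100`. The
#' complex concentrations x1, x2 are set to configurable nominals; all
#' reported responsiveness results are fold changes of x1 normalized to
#' its control steady state, so these nominals only rescale the derived
#' rate constants.
#'
#' @param code initial-condition code, 1..8.
#' @param x1_ss,x2_ss nominal complex concentrations (defaults 10, 100).
#' @param pair_total fixed active + inactive total (default 100).
#' @param sd Gaussian standard deviation passed to
#'   [sample_active_fraction()].
#' @return Named length-8 state vector.
#' @export
sample_initial_state <- function(code, x1_ss = 10, x2_ss = 100,
                                 pair_total = 100, sd = 5) {
  bits <- ic_code_bits(code)
  x4 <- sample_active_fraction(bits[["p47P"]], sd = sd)
  x6 <- sample_active_fraction(bits[["rac1GTP"]], sd = sd)
  x8 <- sample_active_fraction(bits[["noxa1P"]], sd = sd)
  setNames(c(x1_ss, x2_ss, pair_total - x4, x4, pair_total - x6, x6,
             pair_total - x8, x8), STATE_NAMES)
}

#' Sample an independent flux basis, log10-uniformly
#'
#' Each independent flux is `10^u` with `u ~ U(lo, hi)` i.i.d. The eighth
#' flux (`f9` or `f10`) is selected by [select_eighth_flux()]; draws whose
#' derived partner would be negative are rejected and the whole basis
#' redrawn, keeping the stated distribution on the feasible region.
#'
#' @param range_log10 length-2 `(lo, hi)`; the generic range is `c(0, 2)`
#'   (fluxes in 1..100) and the screening range `c(-2, 2)`.
#' @param f14_zero pin the proteolytic flux to exactly 0 instead of
#'   sampling it (the sensitized regime).
#' @param max_attempts rejection cap before erroring.
#' @return An [independent_fluxes()] object; attribute `attempts` records
#'   the number of draws used.
#' @export
sample_flux_basis <- function(range_log10 = c(0, 2), f14_zero = FALSE,
                              max_attempts = 1000L) {
  stopifnot(length(range_log10) == 2, range_log10[1] < range_log10[2])
  draw <- function() 10^runif(1, range_log10[1], range_log10[2])
  for (attempt in seq_len(max_attempts)) {
    f2 <- draw(); f3 <- draw(); f4 <- draw(); f6 <- draw(); f8 <- draw()
    f14 <- if (f14_zero) 0 else draw()
    f16 <- draw()
    sel <- select_eighth_flux(f2, f16)
    eighth <- draw()
    feasible <- if (sel == "f9") eighth + f2 - f16 >= 0 else
      eighth + f16 - f2 >= 0
    if (feasible) {
      ind <- independent_fluxes(f2, f3, f4, f6, f8, f14, f16,
                                eighth = eighth, selector = sel)
      attr(ind, "attempts") <- attempt
      return(ind)
    }
  }
  stop("no feasible flux basis in ", max_attempts, " attempts")
}

#' Sample the reversible-reaction rate constants
#'
#' The rate constants of the three deactivation/activation reversible
#' reactions (gamma6, gamma8, gamma9: dephosphorylation of p47_P,
#' GDP-loading of Rac1_GTP, phosphorylation of NoxA1) are drawn i.i.d.
#' either "slow" from U(0, 1) or "fast" from U(10, 100).
#'
#' @param mode `"slow"` or `"fast"`.
#' @return Named numeric vector `c(gamma6, gamma8, gamma9)`.
#' @export
sample_rate_constants <- function(mode = c("slow", "fast")) {
  mode <- match.arg(mode)
  lim <- if (mode == "slow") c(0, 1) else c(10, 100)
  setNames(runif(3, lim[1], lim[2]), c("gamma6", "gamma8", "gamma9"))
}

#' Sample a complete steady-state parameterization
#'
#' Draws an initial state for the given code and an independent flux basis,
#' completes the flux vector and back-derives the rate constants, so the
#' sampled state is an exact steady state under control signals.
#'
#' @inheritParams sample_initial_state
#' @inheritParams sample_flux_basis
#' @return A `nox1_param` with the sampled `code` attached as an attribute.
#' @export
sample_parameterization <- function(code, range_log10 = c(0, 2),
                                    f14_zero = FALSE, x1_ss = 10,
                                    x2_ss = 100) {
  state <- sample_initial_state(code, x1_ss = x1_ss, x2_ss = x2_ss)
  ind <- sample_flux_basis(range_log10, f14_zero = f14_zero)
  param <- steady_parameterization(state, complete_fluxes(ind))
  attr(param, "code") <- code
  param
}
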