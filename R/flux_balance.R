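#' Independent steady-state flux basis
#'
#' The steady-state balance constraints leave an 8-dimensional basis among
#' the 16 fluxes. The basis used throughout is `f2, f3, f4, f6, f8, f14,
#' f16` plus either `f9` or `f10` (the `selector`), chosen by
#' [select_eighth_flux()] from the relative sizes of `f2` and `f16`.
#'
#' @param f2,f3,f4,f6,f8,f14,f16 non-negative steady-state fluxes.
#' @param eighth non-negative value of the selected eighth flux.
#' @param selector `"f9"` or `"f10"`.
#' @return An object of class `independent_fluxes`.
#' @export
independent_fluxes <- function(f2, f3, f4, f6, f8, f14, f16,
                               eighth, selector = c("f10", "f9")) {
  selector <- match.arg(selector)
  v <- c(f2 = f2, f3 = f3, f4 = f4, f6 = f6, f8 = f8,
         f14 = f14, f16 = f16, eighth = eighth)
  stopifnot(all(is.finite(v)), all(v >= 0))
  structure(list(f2 = f2, f3 = f3, f4 = f4, f6 = f6, f8 = f8,
                 f14 = f14, f16 = f16, eighth = eighth,
                 selector = selector),
            class = "independent_fluxes")
}

#' Choose the eighth independent flux
#'
#' The NoxA1 phosphorylation balance couples `f9 + f2 = f10 + f16`; one of
#' `f9`/`f10` is sampled and the other derived. The selector is `"f9"` when
#' `f2 < f16` and `"f10"` otherwise; samples for which the derived partner
#' would be negative are rejected by the samplers and redrawn.
#'
#' @param f2,f16 non-negative steady-state fluxes.
#' @return `"f9"` or `"f10"`.
#' @export
select_eighth_flux <- function(f2, f16) {
  stopifnot(f2 >= 0, f16 >= 0)
  if (f2 < f16) "f9" else "f10"
}

#' Complete a full steady-state flux vector from the 8-flux basis
#'
#' Applies the steady-state balances: `f1 = f2+f3+f4+f14`,
#' `f5 = f3+f6+f14`, `f7 = f4+f8+f14`, `f11 = f12 = f13 = f14`,
#' `f15 = f14+f16`, and `f9 + f2 = f10 + f16` for the dependent member of
#' the `f9`/`f10` pair.
#'
#' @param ind an [independent_fluxes()] object.
#' @return Named numeric length-16 flux vector satisfying `N F = 0`.
#' @export
#' @examples
#' ind <- independent_fluxes(f2 = 10, f3 = 10, f4 = 10, f6 = 5, f8 = 5,
#'                           f14 = 0, f16 = 0, eighth = 20, selector = "f9")
#' complete_fluxes(ind)  # f1 = 30, f5 = 15, f7 = 15, f10 = 30
complete_fluxes <- function(ind) {
  stopifnot(inherits(ind, "independent_fluxes"))
  if (ind$selector == "f9") {
    f9 <- ind$eighth
    f10 <- f9 + ind$f2 - ind$f16
    if (f10 < 0)
      stop("infeasible basis: derived f10 = ", signif(f10, 6), " < 0")
  } else {
    f10 <- ind$eighth
    f9 <- f10 + ind$f16 - ind$f2
    if (f9 < 0)
      stop("infeasible basis: derived f9 = ", signif(f9, 6), " < 0")
  }
  setNames(c(ind$f2 + ind$f3 + ind$f4 + ind$f14,     # f1
             ind$f2, ind$f3, ind$f4,
             ind$f3 + ind$f6 + ind$f14,              # f5
             ind$f6,
             ind$f4 + ind$f8 + ind$f14,              # f7
             ind$f8, f9, f10,
             ind$f14, ind$f14, ind$f14,              # f11..f13
             ind$f14,
             ind$f14 + ind$f16,                      # f15
             ind$f16),
           FLUX_NAMES)
}

#' Rate constants making a chosen state an exact steady state
#'
#' Inverts the mass-action rate laws at the reference state with all
#' signals at their control value 1: `gamma_i = f_i / monomial_i(state)`;
#' constant influxes get `gamma = f`. A zero flux yields `gamma = 0`.
#'
#' @param flux_ss named length-16 steady-state flux vector.
#' @param state_ss length-8 reference state.
#' @return Named numeric length-16 rate-constant vector.
#' @export
derive_rate_constants <- function(flux_ss, state_ss) {
  stopifnot(length(flux_ss) == 16, all(flux_ss >= 0))
  check_state(state_ss)
  x <- unname(state_ss)
  monomial <- c(x[2] * x[4] * x[6] * x[7], x[1], x[1], x[1],
                x[3], x[4], x[5], x[6], x[7], x[8],
                1, 1, 1, x[1], 1, x[8])
  f <- unname(flux_ss)
  g <- numeric(16)
  nz <- f > 0
  if (any(nz & monomial == 0))
    stop("degenerate state: nonzero flux ",
         paste(FLUX_NAMES[nz & monomial == 0], collapse = ", "),
         " has a zero-valued mass-action monomial")
  g[nz] <- f[nz] / monomial[nz]
  setNames(g, GAMMA_NAMES)
}

#' Steady-state parameterization
#'
#' Bundles a reference state, the rate constants derived from a
#' flux-balanced flux vector, and that flux vector. By construction the
#' reference state is an exact steady state under control signals; this is
#' asserted on construction via [verify_steady()].
#'
#' @param state_ss length-8 reference state (the unstimulated
#'   ready-to-respond state).
#' @param flux_ss named length-16 flux vector from [complete_fluxes()].
#' @param check assert the steady-state residual is at most `1e-9` (default
#'   TRUE).
#' @return Object of class `nox1_param` with elements `state`, `gamma`,
#'   `flux`.
#' @export
steady_parameterization <- function(state_ss, flux_ss, check = TRUE) {
  gamma <- derive_rate_constants(flux_ss, state_ss)
  param <- structure(list(state = setNames(unname(state_ss), STATE_NAMES),
                          gamma = gamma,
                          flux = setNames(unname(flux_ss), FLUX_NAMES)),
                     class = "nox1_param")
  if (check) {
    res <- verify_steady(param)
    if (res > 1e-9)
      stop("parameterization is not at steady state (relative residual ",
           signif(res, 3), ")")
  }
  param
}

#' @export
print.nox1_param <- function(x, ...) {
  cat("Nox1 steady-state parameterization\n")
  cat("  state:", paste(signif(x$state, 4), collapse = " "), "\n")
  cat("  steady-state residual:", signif(verify_steady(x), 3), "\n")
  inv <- x$flux[c("f2", "f3", "f4", "f14", "f16")]
  cat("  disassembly fluxes:",
      paste(names(inv), signif(inv, 4), sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Maximum relative steady-state residual
#'
#' `max_i |dXi/dt| / max(Xi, floor)` at the reference state under control
#' signals; pipeline assertions require this to be at most `1e-9`.
#'
#' @param param a `nox1_param`.
#' @param floor small positive scale guard (default 1e-6).
#' @return Non-negative scalar.
#' @export
verify_steady <- function(param, floor = 1e-6) {
  dx <- time_derivative(param$state, control_signals(), param$gamma)
  max(abs(dx) / pmax(param$state, floor))
}

#' Serialize / restore a parameterization as JSON
#'
#' @param param a `nox1_param`.
#' @param path file path.
#' @param provenance optional named list (seed, sample index, ...) stored
#'   alongside the numbers.
#' @return `write_param_json` returns `path` invisibly; `read_param_json`
#'   returns the restored `nox1_param`.
#' @export
write_param_json <- function(param, path, provenance = NULL) {
  obj <- list(state = as.list(param$state),
              gamma = as.list(param$gamma),
              flux = as.list(param$flux),
              provenance = provenance)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_param_json
#' @export
read_param_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  steady_parameterization(unlist(obj$state), unlist(obj$flux))
}
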