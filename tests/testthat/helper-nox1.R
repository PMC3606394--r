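# Independent oracles and fixture generators (built in code at test time).

# Hand-coded expansion of the eight balance equations, written directly
# from the reaction list -- independent of the stoichiometry matrix path.
oracle_rhs <- function(x, s, g) {
  f1 <- g[1] * x[2] * x[4] * x[6] * x[7]
  f2 <- g[2] * x[1]; f3 <- g[3] * x[1]; f4 <- g[4] * x[1]
  f5 <- g[5] * x[3] * s[1]; f6 <- g[6] * x[4]
  f7 <- g[7] * x[5] * s[2]; f8 <- g[8] * x[6]
  f9 <- g[9] * x[7] * s[3]; f10 <- g[10] * x[8]
  f11 <- g[11]; f12 <- g[12]; f13 <- g[13]
  f14 <- g[14] * x[1]; f15 <- g[15]; f16 <- g[16] * x[8]
  c(f1 - f2 - f3 - f4 - f14,
    -f1 + f2 + f3 + f4 + f11,
    f3 - f5 + f6 + f12,
    -f1 + f2 + f4 + f5 - f6,
    f4 - f7 + f8 + f13,
    -f1 + f2 + f3 + f7 - f8,
    -f1 + f3 + f4 - f9 + f10 + f15,
    f2 + f9 - f10 - f16)
}

# A random flux vector satisfying the eight steady-state balances, built
# row by row from the balance identities themselves (not via the package's
# complete_fluxes).
random_balanced_fluxes <- function() {
  f2 <- runif(1, 0, 50); f3 <- runif(1, 0, 50); f4 <- runif(1, 0, 50)
  f6 <- runif(1, 0, 50); f8 <- runif(1, 0, 50)
  f14 <- runif(1, 0, 10); f16 <- runif(1, 0, 10)
  f9 <- runif(1, 0, 50) + max(f16 - f2, 0)
  f10 <- f9 + f2 - f16
  c(f1 = f2 + f3 + f4 + f14, f2 = f2, f3 = f3, f4 = f4,
    f5 = f3 + f6 + f14, f6 = f6, f7 = f4 + f8 + f14, f8 = f8,
    f9 = f9, f10 = f10, f11 = f14, f12 = f14, f13 = f14,
    f14 = f14, f15 = f14 + f16, f16 = f16)
}

random_basis <- function(range = c(0, 2), f14_zero = FALSE) {
  sample_flux_basis(range_log10 = range, f14_zero = f14_zero)
}

random_param <- function(code = sample.int(8, 1), range = c(0, 2),
                         f14_zero = FALSE) {
  sample_parameterization(code, range_log10 = range, f14_zero = f14_zero)
}

# A steady parameterization whose S1/S2 channels are disconnected
# (f5 = f7 = 0 hence gamma5 = gamma7 = 0): signals cannot enter.
within_zero_coupling <- function(p) {
  st <- sample_initial_state(1)
  ind <- independent_fluxes(f2 = 10, f3 = 0, f4 = 0, f6 = 0, f8 = 0,
                            f14 = 0, f16 = 0, eighth = 5,
                            selector = "f10")
  steady_parameterization(st, complete_fluxes(ind))
}

# A fully closed parameterization: no proteolysis, no influx/efflux.
closed_param <- function(code = 1) {
  state <- sample_initial_state(code)
  f2 <- runif(1, 1, 50)
  # with f16 = 0 the balance forces f10 = f9 + f2
  ind <- independent_fluxes(f2 = f2, f3 = runif(1, 1, 50),
                            f4 = runif(1, 1, 50), f6 = runif(1, 1, 20),
                            f8 = runif(1, 1, 20), f14 = 0, f16 = 0,
                            eighth = f2 + runif(1, 1, 50),
                            selector = "f10")
  steady_parameterization(state, complete_fluxes(ind))
}
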