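#' The seven recycling-module designs
#'
#' Each design is a nonempty subset of the three recycling pathways
#' \{f2, f3, f4\}: 1 = \{f2\}, 2 = \{f3\}, 3 = \{f4\}, 4 = \{f2, f3\},
#' 5 = \{f2, f4\}, 6 = \{f3, f4\}, 7 = \{f2, f3, f4\}.
#'
#' @return Named list of character vectors, one per design index.
#' @export
module_designs <- function() {
  list(`1` = "f2", `2` = "f3", `3` = "f4",
       `4` = c("f2", "f3"), `5` = c("f2", "f4"), `6` = c("f3", "f4"),
       `7` = c("f2", "f3", "f4"))
}

#' Scenario configuration for the module-design grid
#'
#' @param system `"closed"` (f16 = 0, and with f14 = 0 also
#'   f11 = f12 = f13 = f15 = 0 — no material exchange) or `"open"`
#'   (f16 > 0).
#' @param rates `"slow"` (gamma6, gamma8, gamma9 ~ U(0,1)) or `"fast"`
#'   (~ U(10,100)).
#' @param scenario for the open system: 1 (net NoxA1 -> NoxA1_P, i.e.
#'   f9 > f10, equivalently f16 > f2) or 2 (f9 <= f10, f16 <= f2).
#'   Ignored when closed.
#' @return Object of class `scenario_config`.
#' @export
scenario_config <- function(system = c("closed", "open"),
                            rates = c("slow", "fast"), scenario = NULL) {
  system <- match.arg(system)
  rates <- match.arg(rates)
  if (system == "open") {
    stopifnot(!is.null(scenario), scenario %in% c(1, 2))
  } else {
    scenario <- NA_integer_
  }
  structure(list(system = system, rates = rates,
                 scenario = as.integer(scenario)),
            class = "scenario_config")
}

#' Sample the NoxA1-phosphorylation flux triple for a scenario
#'
#' Given the recycling flux `f2` and the sampled phosphorylation flux
#' `f9`, draws `f16` consistent with the scenario and derives `f10` from
#' the balance `f9 + f2 = f10 + f16`. Closed system: `f16 = 0`,
#' `f10 = f9 + f2`. Scenario 1 (`f9 > f10`, i.e. `f16 > f2`): the flux
#' imbalance `e = f16 - f2` is drawn log10-uniform on `[0.01, 100]`,
#' rejecting draws with `f10 = f9 - e < 0`. Scenario 2 (`f9 <= f10`, i.e.
#' `f16 <= f2`): `f16` is drawn log10-uniform on `[0.01, 100]` and
#' rejected until `f16 <= f2`; when `f2` is too small for any admissible
#' draw (the designs lacking the f2 pathway), the cell is structurally
#' infeasible at an exact steady state and runs at the boundary
#' `f9 = f10` with a vanishing `f16 = 1e-6`, flagged as such.
#'
#' @param scenario a [scenario_config()].
#' @param f2 recycling flux through the f2 pathway (>= 0).
#' @param f9 sampled NoxA1 phosphorylation flux (>= 0).
#' @param max_attempts rejection cap.
#' @return List `f9`, `f10`, `f16`, `structural_infeasible`, `attempts`.
#' @export
scenario_flux_sampler <- function(scenario, f2, f9, max_attempts = 1000L) {
  stopifnot(inherits(scenario, "scenario_config"), f2 >= 0, f9 >= 0)
  if (scenario$system == "closed")
    return(list(f9 = f9, f10 = f9 + f2, f16 = 0,
                structural_infeasible = FALSE, attempts = 1L))
  if (scenario$scenario == 1L) {
    for (attempt in seq_len(max_attempts)) {
      e <- 10^runif(1, -2, 2)
      if (f9 - e >= 0)
        return(list(f9 = f9, f10 = f9 - e, f16 = f2 + e,
                    structural_infeasible = FALSE, attempts = attempt))
    }
    # f9 below the smallest drawable imbalance: run at the boundary
    return(list(f9 = f9, f10 = 0, f16 = f2 + f9,
                structural_infeasible = FALSE, attempts = max_attempts))
  }
  # scenario 2: f16 <= f2
  if (f2 < 0.01)
    return(list(f9 = f9, f10 = f9 + f2 - 1e-6, f16 = 1e-6,
                structural_infeasible = TRUE, attempts = 1L))
  for (attempt in seq_len(max_attempts)) {
    f16 <- 10^runif(1, -2, 2)
    if (f16 <= f2)
      return(list(f9 = f9, f10 = f9 + f2 - f16, f16 = f16,
                  structural_infeasible = FALSE, attempts = attempt))
  }
  stop("no admissible f16 draw in ", max_attempts, " attempts")
}

#' Parameterize one Monte-Carlo sample of a recycling-module design
#'
#' Fair-comparison contract: the active-complex production flux is fixed
#' at `f1 = 100` and proteolysis at `f14 = 0` (hence no subunit influxes),
#' the reference state uses initial-condition code 1 (free p47, Rac1-GDP
#' and NoxA1 dominant), and the reversible-reaction rate constants gamma6,
#' gamma8, gamma9 are drawn per the rates mode, giving `f6 = gamma6 x4`,
#' `f8 = gamma8 x6`, `f9 = gamma9 x7`. The 100 units of recycling flux are
#' apportioned among the design's present pathways by a uniform Dirichlet
#' draw (or equally, for deterministic work); absent pathways get exactly
#' zero flux and rate constant. `f16`/`f10` follow the scenario via
#' [scenario_flux_sampler()].
#'
#' @param design design index 1..7.
#' @param scenario a [scenario_config()].
#' @param apportion `"dirichlet"` or `"equal"` split of the recycling flux.
#' @param f1 total production flux (default 100).
#' @param x1_ss,x2_ss nominal complex concentrations.
#' @return A `nox1_param` with attributes `design` and
#'   `structural_infeasible`.
#' @export
parameterize_module <- function(design, scenario,
                                apportion = c("dirichlet", "equal"),
                                f1 = 100, x1_ss = 10, x2_ss = 100) {
  apportion <- match.arg(apportion)
  stopifnot(design %in% 1:7)
  present <- module_designs()[[design]]
  state <- sample_initial_state(1, x1_ss = x1_ss, x2_ss = x2_ss)
  g <- sample_rate_constants(scenario$rates)
  f6 <- g[["gamma6"]] * state[["x4"]]
  f8 <- g[["gamma8"]] * state[["x6"]]
  f9 <- g[["gamma9"]] * state[["x7"]]
  w <- if (apportion == "equal") rep(1 / length(present), length(present))
  else {
    e <- stats::rexp(length(present))
    e / sum(e)
  }
  rec <- setNames(c(0, 0, 0), c("f2", "f3", "f4"))
  rec[present] <- f1 * w
  sc <- scenario_flux_sampler(scenario, rec[["f2"]], f9)
  flux <- setNames(numeric(16), FLUX_NAMES)
  flux["f1"] <- f1
  flux[c("f2", "f3", "f4")] <- rec
  flux["f5"] <- rec[["f3"]] + f6
  flux["f6"] <- f6
  flux["f7"] <- rec[["f4"]] + f8
  flux["f8"] <- f8
  flux["f9"] <- sc$f9
  flux["f10"] <- sc$f10
  flux["f15"] <- sc$f16
  flux["f16"] <- sc$f16
  param <- steady_parameterization(state, flux)
  attr(param, "design") <- design
  attr(param, "structural_infeasible") <- sc$structural_infeasible
  param
}

#' Monte-Carlo comparison of the seven recycling-module designs
#'
#' For each design, draws `n` parameterizations under the given scenario
#' and runs the on/off protocol with a combined S1 & S2 stimulus (the
#' AngII-like treatment), recording the steady-state fold change of x1 and
#' the on/off response times.
#'
#' @param scenario a [scenario_config()].
#' @param n samples per design (default 2000).
#' @param seed RNG seed.
#' @param magnitude stimulus intensity (default 10).
#' @param designs subset of 1..7.
#' @param measure_times also measure on/off response times via the full
#'   [on_off_protocol()] (default TRUE); FALSE computes fold changes only,
#'   which is considerably faster.
#' @param tol response-time band half-width (default 0.02).
#' @return List with `samples` (tidy rows: design, sample, fold, on_time,
#'   off_time, flags) and `summary` (per-design mean and sd of each
#'   metric, failure counts).
#' @export
compare_modules <- function(scenario, n = 2000, seed = 1, magnitude = 10,
                            designs = 1:7, measure_times = TRUE,
                            tol = 0.02) {
  signals <- signal_step(c("s1", "s2"), magnitude)
  # One derived substream per sample index, shared by all designs: the
  # state and reversible-rate draws of sample i are identical across
  # designs, so differences are attributable to the module structure.
  set.seed(seed)
  substream <- sample.int(2147483646L, n)
  rows <- list()
  k <- 0L
  for (d in designs) {
    for (i in seq_len(n)) {
      set.seed(substream[i])
      param <- tryCatch(parameterize_module(d, scenario),
                        error = function(e) NULL)
      k <- k + 1L
      if (is.null(param)) {
        rows[[k]] <- data.frame(design = d, sample = i, fold = NA_real_,
                                on_time = NA_real_, off_time = NA_real_,
                                ok = FALSE, structural_infeasible = NA)
        next
      }
      res <- tryCatch({
        if (measure_times) {
          m <- on_off_protocol(param, signals, tol = tol)
          data.frame(design = d, sample = i, fold = m$fold,
                     on_time = m$on_time, off_time = m$off_time,
                     ok = m$on_converged && m$off_converged,
                     structural_infeasible =
                       attr(param, "structural_infeasible"))
        } else {
          fc <- fold_change(param, signals)
          data.frame(design = d, sample = i, fold = fc$fold,
                     on_time = NA_real_, off_time = NA_real_,
                     ok = fc$converged,
                     structural_infeasible =
                       attr(param, "structural_infeasible"))
        }
      }, error = function(e)
        data.frame(design = d, sample = i, fold = NA_real_,
                   on_time = NA_real_, off_time = NA_real_, ok = FALSE,
                   structural_infeasible = NA))
      rows[[k]] <- res
    }
  }
  samples <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(samples, samples$design),
                                function(s) {
    use <- s[s$ok %in% TRUE, , drop = FALSE]
    data.frame(design = s$design[1], n = nrow(s), n_ok = nrow(use),
               mean_fold = mean(use$fold), sd_fold = stats::sd(use$fold),
               mean_on_time = mean(use$on_time, na.rm = TRUE),
               sd_on_time = stats::sd(use$on_time, na.rm = TRUE),
               mean_off_time = mean(use$off_time, na.rm = TRUE),
               sd_off_time = stats::sd(use$off_time, na.rm = TRUE))
  }))
  rownames(summ) <- NULL
  list(samples = samples, summary = summ, scenario = scenario)
}
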