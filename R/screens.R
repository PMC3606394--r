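#' AngII treatment screen (conditions 1 and 2)
#'
#' AngII is represented as a combined S1 & S2 step. Condition 1: after 4
#' hours (t = 240) the total Nox1 protein (x1 + x2) has changed by at most
#' `stability_tol` relative to control. Condition 2: at 30 minutes the
#' system is at a (quasi-)steady state — `|dx1/dt| * 30 / x1 < qss_tol` —
#' with x1 up-regulated at least `up_tol`-fold over control.
#'
#' @param param a `nox1_param`.
#' @param magnitude stimulus intensity (default 10).
#' @param stability_tol relative band for "not significantly changed"
#'   (default 0.05).
#' @param up_tol fold threshold for "up-regulated" (default 1.1).
#' @param qss_tol quasi-steady-state threshold at t = 30 (default 0.05).
#' @return List of logicals `cond1`, `cond2`, plus `solver_ok`.
#' @export
angii_screen <- function(param, magnitude = 10, stability_tol = 0.05,
                         up_tol = 1.1, qss_tol = 0.05) {
  signals <- signal_step(c("s1", "s2"), magnitude)
  traj <- tryCatch(
    integrate_nox1(param$state, signals, param$gamma,
                   times = c(0, 30, 240)),
    error = function(e) NULL)
  if (is.null(traj))
    return(list(cond1 = NA, cond2 = NA, solver_ok = FALSE))
  s0 <- as.numeric(traj[1, STATE_NAMES])
  s30 <- as.numeric(traj[2, STATE_NAMES])
  s240 <- as.numeric(traj[3, STATE_NAMES])
  total0 <- s0[1] + s0[2]
  cond1 <- abs((s240[1] + s240[2]) - total0) / total0 <= stability_tol
  dx30 <- time_derivative(pmax(s30, 0), signals, param$gamma)
  qss <- abs(dx30[1]) * 30 / max(s30[1], 1e-12) < qss_tol
  cond2 <- qss && (s30[1] / s0[1] >= up_tol)
  list(cond1 = cond1, cond2 = cond2, solver_ok = TRUE)
}

#' PMA treatment screen (condition 3)
#'
#' PMA acts through PKC, i.e. an S1 step alone: x1 at 30 minutes must be
#' up-regulated at least `up_tol`-fold over control.
#'
#' @inheritParams angii_screen
#' @return List with logical `cond3` and `solver_ok`.
#' @export
pma_screen <- function(param, magnitude = 10, up_tol = 1.1) {
  signals <- signal_step("s1", magnitude)
  traj <- tryCatch(
    integrate_nox1(param$state, signals, param$gamma, times = c(0, 30)),
    error = function(e) NULL)
  if (is.null(traj))
    return(list(cond3 = NA, solver_ok = FALSE))
  list(cond3 = traj$x1[2] / traj$x1[1] >= up_tol, solver_ok = TRUE)
}

#' Monte-Carlo screening against the three experimental observations
#'
#' Samples steady-state parameterizations with independent fluxes
#' log10-uniform on `range_log10` (default U(-2, 2), fluxes in 0.01..100)
#' and initial-condition codes uniform on 1..8, and applies the AngII
#' 4-hour protein-stability, AngII 30-minute up-regulated quasi-steady
#' state, and PMA 30-minute up-regulation screens.
#'
#' @param n number of samples.
#' @param seed RNG seed (the run is bit-reproducible given `n` and `seed`).
#' @param range_log10 log10 flux sampling range.
#' @param magnitude stimulus intensity.
#' @param stability_tol,up_tol,qss_tol screen thresholds, see
#'   [angii_screen()].
#' @return Tidy data.frame, one row per sample: code, the disassembly
#'   fluxes, `recycling = f2+f3+f4`, `log10_f14`, `log10_recycling`, the
#'   three condition flags and `pass_all`.
#' @export
run_screening <- function(n = 10000, seed = 1, range_log10 = c(-2, 2),
                          magnitude = 10, stability_tol = 0.05,
                          up_tol = 1.1, qss_tol = 0.05) {
  set.seed(seed)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    code <- sample.int(8, 1)
    param <- sample_parameterization(code, range_log10 = range_log10)
    a <- angii_screen(param, magnitude, stability_tol, up_tol, qss_tol)
    p <- pma_screen(param, magnitude, up_tol)
    fl <- param$flux
    rows[[i]] <- data.frame(
      sample = i, code = code,
      f2 = fl[["f2"]], f3 = fl[["f3"]], f4 = fl[["f4"]],
      f14 = fl[["f14"]], f16 = fl[["f16"]],
      recycling = fl[["f2"]] + fl[["f3"]] + fl[["f4"]],
      cond1 = a$cond1, cond2 = a$cond2, cond3 = p$cond3,
      solver_ok = a$solver_ok && p$solver_ok)
  }
  out <- do.call(rbind, rows)
  out$log10_f14 <- log10(out$f14)
  out$log10_recycling <- log10(out$recycling)
  out$pass_all <- out$solver_ok & out$cond1 & out$cond2 & out$cond3
  out$pass_all[is.na(out$pass_all)] <- FALSE
  rownames(out) <- NULL
  out
}

#' Flux-distribution summary of a retained screening set
#'
#' Summarizes the proteolytic (`f14`) versus collective recycling
#' (`f2+f3+f4`) flux distributions of the retained parameter sets, the
#' log10 separation between them, and the individual recycling fluxes.
#'
#' @param screened data.frame from [run_screening()].
#' @param retained logical vector selecting rows (default `pass_all`).
#' @return List: `n_retained`, `mean_ratio` (mean recycling / mean
#'   proteolytic flux), `log10_separation` (difference of mean log10
#'   fluxes), per-flux means, and histogram breaks/counts on the log10
#'   scale.
#' @export
flux_distribution_summary <- function(screened,
                                      retained = screened$pass_all) {
  keep <- screened[retained, , drop = FALSE]
  if (nrow(keep) == 0)
    return(list(n_retained = 0L, mean_ratio = NA_real_,
                log10_separation = NA_real_))
  breaks <- seq(-2.5, 2.5, by = 0.25)
  clamp <- function(v) pmin(pmax(v, -2.5 + 1e-9), 2.5 - 1e-9)
  h <- function(v) hist(clamp(v), breaks = breaks, plot = FALSE)$counts
  list(
    n_retained = nrow(keep),
    mean_ratio = mean(keep$recycling) / mean(keep$f14),
    log10_separation = mean(keep$log10_recycling) - mean(keep$log10_f14),
    mean_f2 = mean(keep$f2), mean_f3 = mean(keep$f3),
    mean_f4 = mean(keep$f4), mean_f14 = mean(keep$f14),
    mean_recycling = mean(keep$recycling),
    breaks = breaks,
    hist_f14 = h(keep$log10_f14),
    hist_recycling = h(keep$log10_recycling))
}

#' Responsiveness profile over initial-condition codes and signal sets
#'
#' The first functional-effectiveness criterion: for each of the 8
#' initial-condition codes and each signal set (S1, S2, S3, S1&S2), sample
#' parameterizations (independent fluxes log10-uniform, proteolysis either
#' pinned to zero or sampled) and record the steady-state fold change of
#' x1 under the stepped signals.
#'
#' @param n samples per (code x signal set) cell.
#' @param seed RNG seed.
#' @param codes integer subset of 1..8.
#' @param signal_sets named list of character vectors, defaults to the four
#'   canonical sets.
#' @param f14_zero pin the proteolytic flux to zero (default TRUE, the
#'   sensitized regime).
#' @param range_log10 log10 flux range (default c(0, 2)).
#' @param magnitude stimulus intensity (default 10).
#' @return List with `samples` (tidy per-sample folds) and `summary`
#'   (per-cell min, quartiles, max, mean — the box-and-whisker surface).
#' @export
responsiveness_profile <- function(n = 2000, seed = 1, codes = 1:8,
                                   signal_sets = list(
                                     S1 = "s1", S2 = "s2", S3 = "s3",
                                     `S1&S2` = c("s1", "s2")),
                                   f14_zero = TRUE, range_log10 = c(0, 2),
                                   magnitude = 10) {
  set.seed(seed)
  rows <- list()
  k <- 0L
  for (code in codes) {
    for (set_name in names(signal_sets)) {
      signals <- signal_step(signal_sets[[set_name]], magnitude)
      for (i in seq_len(n)) {
        param <- sample_parameterization(code, range_log10 = range_log10,
                                         f14_zero = f14_zero)
        fc <- tryCatch(fold_change(param, signals),
                       error = function(e) list(fold = NA_real_,
                                                converged = FALSE))
        k <- k + 1L
        rows[[k]] <- data.frame(code = code, signal_set = set_name,
                                sample = i, fold = fc$fold,
                                converged = fc$converged)
      }
    }
  }
  samples <- do.call(rbind, rows)
  cells <- split(samples, list(samples$code, samples$signal_set),
                 drop = TRUE)
  summary <- do.call(rbind, lapply(cells, function(d) {
    q <- stats::quantile(d$fold, c(0, 0.25, 0.5, 0.75, 1), na.rm = TRUE)
    data.frame(code = d$code[1], signal_set = d$signal_set[1],
               n = nrow(d), mean = mean(d$fold, na.rm = TRUE),
               min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5])
  }))
  rownames(summary) <- NULL
  list(samples = samples, summary = summary)
}
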