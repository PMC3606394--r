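steady_residual <- function(state, signals, gamma, floor = 1e-6) {
  dx <- time_derivative(state, signals, gamma)
  max(abs(dx) / pmax(state, floor))
}

# Newton polish of a steady state. The SVD pseudo-inverse handles the rank
# deficiency caused by conserved moiety pools; the iteration is
# non-monotone (full steps, best iterate kept) because the first step from
# a slow-manifold point routinely raises the residual before quadratic
# convergence sets in.
newton_polish <- function(state, signals, gamma, max_iter = 25,
                          floor = 1e-6) {
  x <- pmax(unname(state), 0)
  best_x <- x
  best_res <- steady_residual(x, signals, gamma, floor)
  for (i in seq_len(max_iter)) {
    r <- unname(time_derivative(x, signals, gamma))
    if (max(abs(r)) == 0) break
    J <- rhs_jacobian(x, signals, gamma)
    step <- tryCatch(-drop(MASS::ginv(J, tol = 1e-12) %*% r),
                     error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) break
    x <- pmax(x + step, 0)
    res <- steady_residual(x, signals, gamma, floor)
    if (!is.finite(res) || res > 1e6 * max(best_res, 1e-12)) break
    if (res < best_res) {
      best_x <- x
      best_res <- res
    }
    if (best_res < 1e-13) break
  }
  setNames(best_x, STATE_NAMES)
}

#' Find the steady state under a given signal vector
#'
#' Integrates from `state0` in geometrically growing time chunks until the
#' relative derivative measure `max_i |dXi/dt| / max(Xi, floor)` drops
#' below `tol` (default 1e-8 per time unit), then polishes the endpoint
#' with a damped Newton iteration on the algebraic steady-state equations.
#' Non-convergence within `t_max` is flagged, not raised.
#'
#' @param param a `nox1_param`.
#' @param signals named signal vector.
#' @param tol relative derivative tolerance declaring steadiness.
#' @param t_max integration horizon cap (default 1e4 time units).
#' @param floor scale guard in the relative measure.
#' @param polish apply the Newton polish (default TRUE).
#' @return List with `state`, `converged`, `t_reached` (integration time
#'   spent), and `residual`.
#' @export
find_steady_state <- function(param, signals = control_signals(),
                              tol = 1e-8, t_max = 1e4, floor = 1e-6,
                              polish = TRUE) {
  gamma <- param$gamma
  x <- param$state
  t_done <- 0
  chunk <- 25
  converged <- steady_residual(x, signals, gamma, floor) < tol
  while (!converged && t_done < t_max) {
    chunk <- min(chunk, t_max - t_done)
    traj <- integrate_nox1(x, signals, gamma, times = c(0, chunk))
    x <- setNames(as.numeric(traj[nrow(traj), STATE_NAMES]), STATE_NAMES)
    t_done <- t_done + chunk
    chunk <- chunk * 2
    converged <- steady_residual(x, signals, gamma, floor) < tol
  }
  if (polish) {
    cand <- newton_polish(x, signals, gamma, floor = floor)
    if (steady_residual(cand, signals, gamma, floor) <=
        steady_residual(x, signals, gamma, floor)) x <- cand
    converged <- converged || steady_residual(x, signals, gamma, floor) < tol
  }
  list(state = x, converged = converged, t_reached = t_done,
       residual = steady_residual(x, signals, gamma, floor))
}

#' Steady-state fold change of the active Nox1 complex
#'
#' New steady-state x1 under the stepped signals divided by the control
#' steady-state x1 (the reference state of the parameterization, which is
#' "1" after normalization).
#'
#' @param param a `nox1_param`.
#' @param signals stepped signal vector, e.g. `signal_step(c("s1","s2"))`.
#' @param ... passed to [find_steady_state()].
#' @return List with `fold` and `converged`.
#' @export
fold_change <- function(param, signals, ...) {
  if (all(signals == 1))
    return(list(fold = 1, converged = TRUE))
  ss <- find_steady_state(param, signals, ...)
  list(fold = unname(ss$state["x1"] / param$state["x1"]),
       converged = ss$converged)
}

# First grid time after which |x1 - target| stays within tol * |target|.
band_hitting_time <- function(times, x1, target, tol) {
  ok <- abs(x1 - target) <= tol * max(abs(target), 1e-12)
  stays <- rev(cumprod(rev(ok))) > 0
  if (!any(stays)) return(NA_real_)
  times[which(stays)[1]]
}

#' On/off response protocol
#'
#' Applies the stepped signals, measures the time for x1 to settle within a
#' relative tolerance band (default 2%) of its new steady state ("on"
#' response), then resets all signals to the control value 1 and measures
#' the return time toward the control steady state ("off" response). The
#' response time is the first grid time after which x1 remains inside the
#' band for the rest of the window.
#'
#' @param param a `nox1_param`.
#' @param signals stepped signal vector.
#' @param tol relative band half-width (default 0.02).
#' @param n_grid dense-output grid size per phase (default 600).
#' @param ... passed to [find_steady_state()].
#' @return List: `fold`, `on_time`, `off_time`, `on_converged`,
#'   `off_converged`, `returned` (did the off phase end within the band
#'   around the control steady state).
#' @export
on_off_protocol <- function(param, signals, tol = 0.02, n_grid = 600, ...) {
  x1c <- unname(param$state["x1"])
  if (all(signals == 1))
    return(list(fold = 1, on_time = 0, off_time = 0, on_converged = TRUE,
                off_converged = TRUE, returned = TRUE))
  ss_on <- find_steady_state(param, signals, ...)
  fold <- unname(ss_on$state["x1"] / x1c)
  horizon_on <- max(ss_on$t_reached, 1)
  traj_on <- integrate_nox1(param$state, signals, param$gamma,
                            times = seq(0, horizon_on,
                                        length.out = n_grid + 1))
  on_time <- band_hitting_time(traj_on$time, traj_on$x1,
                               unname(ss_on$state["x1"]), tol)

  off_start <- ss_on$state
  ss_off <- find_steady_state(list(state = off_start, gamma = param$gamma),
                              control_signals(), ...)
  horizon_off <- max(ss_off$t_reached, 1)
  traj_off <- integrate_nox1(off_start, control_signals(), param$gamma,
                             times = seq(0, horizon_off,
                                         length.out = n_grid + 1))
  off_time <- band_hitting_time(traj_off$time, traj_off$x1, x1c, tol)
  returned <- abs(traj_off$x1[nrow(traj_off)] - x1c) <= tol * x1c
  list(fold = fold, on_time = on_time, off_time = off_time,
       on_converged = ss_on$converged, off_converged = ss_off$converged,
       returned = returned)
}
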