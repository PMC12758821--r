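#' Transient dawn-phenomenon glucose input
#'
#' Gaussian exogenous glucose input active from its center time onward:
#' \eqn{G_A \exp(-(t-t_c)^2/(2 G_w^2))} for \eqn{t \ge t_c}, and 0 before
#' \eqn{t_c}. Models the early-morning (dawn phenomenon) glucose rise.
#'
#' @param t time in minutes since window start (vectorized).
#' @param params a [model_parameters()] object.
#' @return Input rate in mg/dl/min, same length as \code{t}; values lie in
#'   \code{[0, GA]}.
#' @export
spike_input <- function(t, params) {
  stopifnot(is.numeric(t), all(is.finite(t)))
  out <- numeric(length(t))
  on <- t >= params$tc
  if (any(on)) {
    z <- (t[on] - params$tc) / params$Gw
    out[on] <- params$GA * exp(-0.5 * z * z)
  }
  out
}

#' Right-hand sides of the coupled system
#'
#' \code{glucose_rate} evaluates \eqn{dG/dt}: basal hepatic production,
#' heart-rate modulation, Michaelis-Menten uptake, linear clearance and the
#' dawn spike. \code{heart_rate_rate} evaluates \eqn{dH/dt}: relaxation
#' toward the resting rate plus sympathetic glucose drive.
#'
#' @param G plasma glucose, mg/dl (>= 0).
#' @param H heart rate, BPM (>= 0).
#' @param t time, minutes (only the glucose equation is time-dependent).
#' @param params a [model_parameters()] object.
#' @return Rate of change: mg/dl/min for glucose, BPM/min for heart rate.
#' @export
glucose_rate <- function(G, H, t, params) {
  stopifnot(all(G >= 0), all(H >= 0))
  params$Rg +
    params$alphaG * G * (H - params$Hsleep) / params$Hsleep -
    params$kg * G / (G + params$Kg) -
    params$Eg * G +
    spike_input(t, params)
}

#' @rdname glucose_rate
#' @export
heart_rate_rate <- function(G, H, params) {
  stopifnot(all(G >= 0), all(H >= 0))
  -params$betaH * (H - params$Hsleep) +
    params$Hv * (G - params$Gsleep) / params$Gsleep
}

#' Integrator settings
#'
#' Tolerances and maximum step for the adaptive Dormand-Prince solver.
#' Defaults are stringent (rel 1e-6, abs 1e-8) with a 1-minute cap on the
#' step size so the Gaussian transient is always resolved (its width is at
#' least 10 min within the feasible bounds).
#'
#' @param rel_tol relative tolerance.
#' @param abs_tol absolute tolerance.
#' @param max_step maximum internal step, minutes.
#' @return An \code{integrator_settings} list.
#' @export
integrator_settings <- function(rel_tol = 1e-6, abs_tol = 1e-8, max_step = 1) {
  stopifnot(rel_tol > 0, abs_tol > 0, max_step > 0)
  structure(list(rel_tol = rel_tol, abs_tol = abs_tol, max_step = max_step),
            class = "integrator_settings")
}

# Internal: raise a classed condition the fitting layer converts to a penalty.
.solver_failure <- function(msg) {
  stop(errorCondition(msg, class = c("glucohr_solver_failure", "error")))
}

# Internal: one smooth segment (spike indicator constant) via deSolve.
.integrate_segment <- function(state, times, params, spike_on, settings) {
  if (length(times) == 1L)
    return(matrix(c(times, state), nrow = 1L))
  out <- suppressWarnings(deSolve::ode(
    y = state, times = times,
    func = "glucohr_derivs", parms = .parm_vector(params, spike_on),
    dllname = "glucohr", initfunc = "glucohr_initmod",
    method = "ode45",
    rtol = settings$rel_tol, atol = settings$abs_tol,
    hmax = settings$max_step))
  out <- unclass(out)
  if (nrow(out) < length(times) || anyNA(out) || !all(is.finite(out)))
    .solver_failure("ODE integration failed (non-finite state or premature stop)")
  out
}

#' Simulate the coupled glucose/heart-rate trajectory
#'
#' Integrates the system with an adaptive Dormand-Prince 4/5 solver
#' (deSolve's \code{ode45} method, compiled right-hand side) and samples the
#' solution on the requested time grid. Because the spike indicator
#' \eqn{\chi_{t \ge t_c}} makes the right-hand side discontinuous at
#' \eqn{t_c}, integration is split at \eqn{t_c} and the two smooth segments
#' are concatenated, preserving the solver's error control.
#'
#' Tiny negative undershoots (within the absolute tolerance) are clipped to
#' zero; larger negativity is treated as solver failure, since the true
#' solution is provably non-negative.
#'
#' @param params a [model_parameters()] object.
#' @param G0 initial glucose, mg/dl (>= 0).
#' @param H0 initial heart rate, BPM (>= 0).
#' @param times increasing time grid in minutes (default 0 to 600 by 5).
#' @param settings an [integrator_settings()] object.
#' @return A \code{trajectory}: a data frame with columns \code{time},
#'   \code{glucose}, \code{heart_rate}, one row per grid point.
#' @examples
#' p <- model_parameters(Rg = 8.2, alphaG = 0.001, kg = 9, Kg = 9,
#'                       Eg = 0.001, betaH = 0.6, Hv = 5, GA = 1, Gw = 250,
#'                       Gsleep = 105, Hsleep = 90)
#' tr <- simulate_trajectory(p, G0 = 118, H0 = 90)
#' head(tr)
#' @export
simulate_trajectory <- function(params, G0, H0,
                                times = seq(0, 600, by = 5),
                                settings = integrator_settings()) {
  stopifnot(inherits(params, "model_parameters"),
            is.finite(G0), is.finite(H0), G0 >= 0, H0 >= 0,
            length(times) >= 2L, all(diff(times) > 0))
  state <- c(G0, H0)
  t0 <- times[1L]
  tend <- times[length(times)]
  tc <- params$tc

  if (params$GA > 0 && tc > t0 && tc < tend) {
    pre <- times[times <= tc]
    had_tc <- length(pre) > 0 && pre[length(pre)] == tc
    if (!had_tc) pre <- c(pre, tc)
    seg1 <- .integrate_segment(state, pre, params, spike_on = 0, settings)
    state_tc <- seg1[nrow(seg1), 2:3]
    post <- c(tc, times[times > tc])
    seg2 <- .integrate_segment(state_tc, post, params, spike_on = 1, settings)
    out <- rbind(if (had_tc) seg1 else seg1[-nrow(seg1), , drop = FALSE],
                 seg2[-1L, , drop = FALSE])
  } else {
    spike_on <- params$GA > 0 && tc <= t0
    out <- .integrate_segment(state, times, params, spike_on, settings)
  }

  vals <- out[, 2:3, drop = FALSE]
  if (any(vals < -settings$abs_tol))
    .solver_failure("state went negative beyond the absolute tolerance")
  vals[vals < 0] <- 0

  structure(
    data.frame(time = out[, 1L], glucose = vals[, 1L],
               heart_rate = vals[, 2L]),
    class = c("trajectory", "data.frame"))
}

#' Write / read a trajectory as CSV
#'
#' Uses the column schema \code{t_min,glucose_mgdl,hr_bpm} shared by the
#' synthetic generator and the preprocessing pipeline, so fitting consumes
#' simulated and wearable-derived series identically.
#'
#' @param traj a \code{trajectory} or \code{observed_series} data frame with
#'   columns \code{time}/\code{t_min}, \code{glucose}, \code{heart_rate}.
#' @param path file path.
#' @return \code{write_trajectory_csv} returns \code{path} invisibly;
#'   \code{read_trajectory_csv} returns a \code{trajectory} data frame.
#' @export
write_trajectory_csv <- function(traj, path) {
  tcol <- if ("time" %in% names(traj)) traj$time else traj$t_min
  df <- data.frame(t_min = tcol, glucose_mgdl = traj$glucose,
                   hr_bpm = traj$heart_rate)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("t_min", "glucose_mgdl", "hr_bpm") %in% names(df)))
  structure(
    data.frame(time = df$t_min, glucose = df$glucose_mgdl,
               heart_rate = df$hr_bpm),
    class = c("trajectory", "data.frame"))
}
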