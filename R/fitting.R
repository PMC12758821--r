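# Internal: sum of per-signal mean squared errors over the paired samples.
mse_loss <- function(model_G, model_H, obs_G, obs_H) {
  stopifnot(length(model_G) == length(obs_G),
            length(model_H) == length(obs_H))
  mean((model_G - obs_G)^2) + mean((model_H - obs_H)^2)
}

#' Data-misfit loss for a candidate parameter vector
#'
#' Simulates the system from initial conditions equal to the first observed
#' glucose/heart-rate values, samples the solution at the observation times,
#' and returns the sum of the two per-signal mean squared errors
#' \deqn{L(\theta) = \frac{1}{N}\sum_i (G(t_i;\theta)-G_{obs}(t_i))^2 +
#'       \frac{1}{N}\sum_i (H(t_i;\theta)-H_{obs}(t_i))^2.}
#' Solver failures (non-finite state, step collapse) return the penalty
#' value instead of propagating, which steers the swarm away from
#' pathological parameter regions.
#'
#' @param params a [model_parameters()] candidate.
#' @param observed an [observed_series()].
#' @param settings an [integrator_settings()] object.
#' @param penalty loss assigned on integration failure.
#' @param weights optional length-2 numeric \code{c(wG, wH)} multiplying the
#'   glucose and heart-rate MSE terms (default unweighted, the literal
#'   form above).
#' @return Non-negative scalar loss.
#' @export
fit_loss <- function(params, observed, settings = integrator_settings(),
                     penalty = 1e10, weights = c(1, 1)) {
  stopifnot(inherits(observed, "observed_series"), nrow(observed) > 0)
  traj <- tryCatch(
    simulate_trajectory(params, G0 = observed$glucose[1],
                        H0 = observed$heart_rate[1],
                        times = observed$time, settings = settings),
    glucohr_solver_failure = function(e) NULL)
  if (is.null(traj)) return(penalty)
  weights[1] * mean((traj$glucose - observed$glucose)^2) +
    weights[2] * mean((traj$heart_rate - observed$heart_rate)^2)
}

#' Relative discrete l2 error percentage
#'
#' \eqn{\|A\|_r = 100 \cdot \|A_{mod} - A_{obs}\|_{l2} / \|A_{obs}\|_{l2}},
#' the fit-quality metric reported per signal.
#'
#' @param model model series.
#' @param obs observed series (same length, not all zero).
#' @return Percentage (scalar >= 0).
#' @examples
#' relative_error(c(1, 2), c(1, 1))  # 70.71068
#' @export
relative_error <- function(model, obs) {
  stopifnot(length(model) == length(obs))
  denom <- sqrt(sum(obs^2))
  if (denom == 0) stop("observed series has zero l2 norm")
  100 * sqrt(sum((model - obs)^2)) / denom
}

#' Particle swarm optimizer configuration
#'
#' Swarm settings for bounded global minimization. Defaults: 60 particles,
#' 300 iterations, constriction-style inertia \code{w = 0.729} and
#' acceleration \code{c1 = c2 = 1.49445} (standard stable choices).
#'
#' @param n_particles swarm size (>= 2).
#' @param max_iter iteration budget.
#' @param inertia inertia weight \eqn{w}.
#' @param c1,c2 cognitive / social acceleration coefficients.
#' @param penalty loss assigned to failed objective evaluations.
#' @param velocity_clamp per-dimension cap on |velocity| as a fraction of
#'   the bound range, preventing bound-bouncing.
#' @param seed RNG seed for reproducible swarms.
#' @return A \code{pso_config} list.
#' @export
pso_config <- function(n_particles = 60, max_iter = 300, inertia = 0.729,
                       c1 = 1.49445, c2 = 1.49445, penalty = 1e10,
                       velocity_clamp = 0.2, seed = NULL) {
  stopifnot(n_particles >= 2, max_iter >= 1,
            inertia > 0, c1 > 0, c2 > 0, velocity_clamp > 0)
  structure(list(n_particles = n_particles, max_iter = max_iter,
                 inertia = inertia, c1 = c1, c2 = c2, penalty = penalty,
                 velocity_clamp = velocity_clamp, seed = seed),
            class = "pso_config")
}

#' Bounded particle swarm minimization
#'
#' Classical global-best PSO with the velocity/position updates
#' \deqn{v_i \leftarrow w v_i + c_1 r_1 (p_i^{best} - x_i)
#'       + c_2 r_2 (g^{best} - x_i), \qquad x_i \leftarrow x_i + v_i,}
#' with \eqn{r_1, r_2} uniform on \eqn{[0,1]} drawn independently per
#' particle and dimension. Positions start uniform within the box,
#' velocities start at zero; velocities are clamped to a fraction of each
#' bound range, and positions leaving the box are clamped to the boundary
#' with their velocity component zeroed. Deterministic given
#' \code{config$seed}.
#'
#' @param objective function of a numeric vector returning a scalar; must be
#'   total on the box (use a penalty for failures).
#' @param lower,upper numeric bound vectors (equal length,
#'   \code{lower < upper}).
#' @param config a [pso_config()].
#' @return List with \code{par} (best position), \code{value} (best
#'   objective), \code{history} (global-best value per iteration,
#'   non-increasing) and \code{n_evals}.
#' @examples
#' fit <- pso_minimize(function(x) (x - 3)^2, 0, 10,
#'                     pso_config(n_particles = 20, max_iter = 50, seed = 1))
#' fit$par
#' @export
pso_minimize <- function(objective, lower, upper, config = pso_config()) {
  stopifnot(length(lower) == length(upper), all(lower < upper))
  d <- length(lower)
  n <- config$n_particles
  if (!is.null(config$seed)) set.seed(config$seed)
  rng <- upper - lower
  vmax <- config$velocity_clamp * rng

  X <- matrix(stats::runif(n * d), n, d)
  X <- sweep(sweep(X, 2, rng, `*`), 2, lower, `+`)
  V <- matrix(0, n, d)

  eval_all <- function(M) apply(M, 1, function(x) {
    v <- objective(x)
    if (!is.finite(v)) config$penalty else v
  })

  f <- eval_all(X)
  n_evals <- n
  # an all-penalty initial swarm (every particle in a region where the
  # objective fails) would collapse onto a penalized point; redraw instead
  retries <- 0L
  while (all(f >= config$penalty) && retries < 20L) {
    X <- matrix(stats::runif(n * d), n, d)
    X <- sweep(sweep(X, 2, rng, `*`), 2, lower, `+`)
    f <- eval_all(X)
    n_evals <- n_evals + n
    retries <- retries + 1L
  }
  P <- X
  pf <- f
  gi <- which.min(pf)
  gbest <- P[gi, ]
  gf <- pf[gi]
  history <- numeric(config$max_iter)

  for (it in seq_len(config$max_iter)) {
    r1 <- matrix(stats::runif(n * d), n, d)
    r2 <- matrix(stats::runif(n * d), n, d)
    V <- config$inertia * V +
      config$c1 * r1 * (P - X) +
      config$c2 * r2 * (matrix(gbest, n, d, byrow = TRUE) - X)
    V <- pmin(pmax(V, matrix(-vmax, n, d, byrow = TRUE)),
              matrix(vmax, n, d, byrow = TRUE))
    X <- X + V
    lo <- matrix(lower, n, d, byrow = TRUE)
    hi <- matrix(upper, n, d, byrow = TRUE)
    out <- X < lo | X > hi
    X <- pmin(pmax(X, lo), hi)
    V[out] <- 0

    f <- eval_all(X)
    n_evals <- n_evals + n
    better <- f < pf
    P[better, ] <- X[better, , drop = FALSE]
    pf[better] <- f[better]
    gi <- which.min(pf)
    if (pf[gi] < gf) {
      gf <- pf[gi]
      gbest <- P[gi, ]
    }
    history[it] <- gf
  }
  list(par = as.numeric(gbest), value = gf, history = history,
       n_evals = n_evals)
}

#' Estimate model parameters from an observed series
#'
#' Minimizes [fit_loss()] over the bounded parameter box with particle swarm
#' optimization. By default the clearance rate \code{Eg} is held fixed at
#' 0.001 (its estimate pins to that value even under widened bounds, so the
#' search runs over the remaining 8 parameters); pass
#' \code{fix_Eg = FALSE} to free all 9. The baselines \code{Gsleep} and
#' \code{Hsleep} and the spike center \code{tc} are fixed inputs: for
#' synthetic data they are known, for wearable data they default to the 5th
#' percentile of each observed signal (a robust nocturnal floor).
#'
#' @param observed an [observed_series()].
#' @param bounds a [parameter_bounds()] object.
#' @param config a [pso_config()]; set \code{config$seed} for
#'   reproducibility.
#' @param fix_Eg hold \code{Eg = 0.001} fixed (default TRUE).
#' @param tc spike center time, minutes.
#' @param Gsleep,Hsleep fixed baselines; default 5th percentile of the
#'   observed glucose / heart-rate series.
#' @param settings an [integrator_settings()] object.
#' @param weights optional loss weights, see [fit_loss()].
#' @return A \code{fit_result} list: \code{parameters} (fitted
#'   [model_parameters()]), \code{loss}, \code{rel_err_G} and
#'   \code{rel_err_H} (percent), \code{trajectory} (best-fit simulation on
#'   the observation grid), \code{history}, \code{n_evals},
#'   \code{converged}, \code{seed} and \code{fixed}.
#' @export
fit_parameters <- function(observed, bounds = parameter_bounds(),
                           config = pso_config(), fix_Eg = TRUE,
                           tc = 480,
                           Gsleep = NULL, Hsleep = NULL,
                           settings = integrator_settings(),
                           weights = c(1, 1)) {
  stopifnot(inherits(observed, "observed_series"))
  if (is.null(Gsleep))
    Gsleep <- as.numeric(stats::quantile(observed$glucose, 0.05))
  if (is.null(Hsleep))
    Hsleep <- as.numeric(stats::quantile(observed$heart_rate, 0.05))

  free <- .free_parameter_names
  if (fix_Eg) free <- setdiff(free, "Eg")
  b <- bounds[free, , drop = FALSE]

  build_params <- function(x) {
    v <- stats::setNames(as.list(x), free)
    if (fix_Eg) v$Eg <- 0.001
    model_parameters(Rg = v$Rg, alphaG = v$alphaG, kg = v$kg, Kg = v$Kg,
                     Eg = v$Eg, betaH = v$betaH, Hv = v$Hv, GA = v$GA,
                     Gw = v$Gw, tc = tc, Gsleep = Gsleep, Hsleep = Hsleep)
  }
  objective <- function(x)
    fit_loss(build_params(x), observed, settings,
             penalty = config$penalty, weights = weights)

  res <- pso_minimize(objective, b[, "lower"], b[, "upper"], config)
  if (res$value >= config$penalty)
    stop("no candidate parameter vector integrated successfully ",
         "(all-penalty loss landscape)")

  theta <- build_params(res$par)
  traj <- simulate_trajectory(theta, G0 = observed$glucose[1],
                              H0 = observed$heart_rate[1],
                              times = observed$time, settings = settings)
  structure(list(
    parameters = theta,
    loss = res$value,
    rel_err_G = relative_error(traj$glucose, observed$glucose),
    rel_err_H = relative_error(traj$heart_rate, observed$heart_rate),
    trajectory = traj,
    history = res$history,
    n_evals = res$n_evals,
    converged = res$value < config$penalty,
    seed = config$seed,
    fixed = list(tc = tc, Gsleep = Gsleep, Hsleep = Hsleep,
                 Eg = if (fix_Eg) 0.001 else NULL)
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Glucose-heart-rate model fit (particle swarm)\n")
  cat(sprintf("  loss = %.6g over %d evaluations\n", x$loss, x$n_evals))
  cat(sprintf("  relative l2 errors: glucose %.2f%%, heart rate %.2f%%\n",
              x$rel_err_G, x$rel_err_H))
  print(x$parameters)
  invisible(x)
}

#' Serialize a fit result to JSON
#'
#' @param fit a \code{fit_result} from [fit_parameters()].
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "fit_result"))
  jsonlite::write_json(list(
    theta_hat = unclass(fit$parameters),
    loss = fit$loss,
    rel_err_G = fit$rel_err_G,
    rel_err_H = fit$rel_err_H,
    n_evals = fit$n_evals,
    converged = fit$converged,
    seed = fit$seed,
    fixed = fit$fixed
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
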