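#' Observed (measured or synthetic) nocturnal series
#'
#' Paired glucose/heart-rate observations on a uniform time grid: either the
#' output of the preprocessing pipeline or a synthetic series from
#' [generate_synthetic_patient()].
#'
#' @param times minutes since window start, uniform grid.
#' @param glucose observed glucose, mg/dl.
#' @param heart_rate observed heart rate, BPM.
#' @param meta provenance list (synthetic seed, subject label, ...).
#' @return An \code{observed_series} data frame with columns \code{time},
#'   \code{glucose}, \code{heart_rate} and a \code{meta} attribute.
#' @export
observed_series <- function(times, glucose, heart_rate, meta = list()) {
  stopifnot(length(times) == length(glucose),
            length(times) == length(heart_rate),
            all(is.finite(times)), all(is.finite(glucose)),
            all(is.finite(heart_rate)),
            all(glucose >= 0), all(heart_rate >= 0))
  if (length(times) > 2L) {
    d <- diff(times)
    stopifnot(all(d > 0), max(abs(d - d[1])) < 1e-8 * max(1, d[1]))
  }
  structure(
    data.frame(time = times, glucose = glucose, heart_rate = heart_rate),
    meta = meta,
    class = c("observed_series", "data.frame"))
}

#' Generate a synthetic nocturnal patient series
#'
#' Simulates the coupled system on a uniform grid over the nocturnal window
#' (default 0-600 min in 5-min steps, i.e. 121 points) and optionally adds
#' independent Poisson(\eqn{\lambda = 1}) measurement noise, mimicking the
#' count-like quantization noise of continuous glucose monitors.
#'
#' By default noise is added to the glucose signal only: CGM readings carry
#' sensor noise while the averaged heart-rate channel is treated as smooth.
#' Set \code{noise_targets = c("glucose", "heart_rate")} to perturb both
#' signals. Raw Poisson(1) draws shift the mean by +1; a mean-centered
#' variant (draw minus 1, floored at zero to keep values non-negative) is
#' available via \code{centered = TRUE}.
#'
#' @param params a [model_parameters()] object (the generating truth).
#' @param G0,H0 initial glucose (mg/dl) and heart rate (BPM).
#' @param horizon window length in minutes.
#' @param step sampling interval in minutes.
#' @param noise_on add Poisson noise? When \code{FALSE} the output equals
#'   the noiseless simulation exactly.
#' @param seed RNG seed; required when \code{noise_on} for reproducibility.
#' @param noise_targets character subset of
#'   \code{c("glucose", "heart_rate")}.
#' @param centered subtract the Poisson mean (1) from each draw.
#' @param settings an [integrator_settings()] object.
#' @return An [observed_series()] with
#'   \code{attr(, "meta")$seed} recording provenance.
#' @examples
#' p <- model_parameters(Rg = 8.2, alphaG = 0.001, kg = 9, Kg = 9,
#'                       Eg = 0.001, betaH = 0.6, Hv = 5, GA = 1, Gw = 250,
#'                       Gsleep = 105, Hsleep = 90)
#' obs <- generate_synthetic_patient(p, G0 = 118, H0 = 90, seed = 1)
#' nrow(obs)  # 121 samples
#' @export
generate_synthetic_patient <- function(params, G0, H0, horizon = 600,
                                       step = 5, noise_on = TRUE,
                                       seed = NULL,
                                       noise_targets = "glucose",
                                       centered = FALSE,
                                       settings = integrator_settings()) {
  stopifnot(horizon > 0, step > 0)
  noise_targets <- match.arg(noise_targets,
                             c("glucose", "heart_rate"),
                             several.ok = TRUE)
  times <- seq(0, horizon, by = step)
  traj <- simulate_trajectory(params, G0, H0, times, settings)
  g <- traj$glucose
  h <- traj$heart_rate
  if (noise_on) {
    if (is.null(seed)) stop("a seed is required when noise_on = TRUE")
    set.seed(seed)
    n <- length(times)
    if ("glucose" %in% noise_targets) {
      eps <- stats::rpois(n, lambda = 1)
      g <- g + if (centered) eps - 1 else eps
    }
    if ("heart_rate" %in% noise_targets) {
      eps <- stats::rpois(n, lambda = 1)
      h <- h + if (centered) eps - 1 else eps
    }
    g <- pmax(g, 0)
    h <- pmax(h, 0)
  }
  observed_series(times, g, h,
                  meta = list(source = "synthetic", seed = seed,
                              noise_on = noise_on,
                              noise_targets = if (noise_on) noise_targets else character(0),
                              centered = centered,
                              params = params, G0 = G0, H0 = H0))
}

#' Generate a labelled synthetic cohort across risk categories
#'
#' Rejection-samples parameter vectors uniformly within the feasible bounds
#' until each requested risk category (low / moderate / high) holds
#' \code{n_per_category} subjects, then simulates a noisy series for each.
#' Enables end-to-end pipeline tests spanning the full risk stratification.
#'
#' @param n_per_category subjects per category (>= 1).
#' @param bounds a [parameter_bounds()] object.
#' @param seed RNG seed (required; drives both sampling and noise).
#' @param G0,H0 initial conditions shared across subjects.
#' @param Gsleep,Hsleep,tc fixed (non-estimated) quantities.
#' @param max_draws cap on rejection-sampling draws; if a category is still
#'   unpopulated the function fails naming it.
#' @param ... further arguments passed to [generate_synthetic_patient()].
#' @return A list of entries, each with elements \code{series},
#'   \code{params}, \code{category} and \code{score}.
#' @export
generate_cohort <- function(n_per_category, bounds = parameter_bounds(),
                            seed, G0 = 118, H0 = 90,
                            Gsleep = 105, Hsleep = 90, tc = 480,
                            max_draws = 10000, ...) {
  stopifnot(n_per_category >= 1, inherits(bounds, "parameter_bounds"))
  if (missing(seed)) stop("a seed is required")
  set.seed(seed)
  want <- c(low = n_per_category, moderate = n_per_category,
            high = n_per_category)
  got <- c(low = 0L, moderate = 0L, high = 0L)
  out <- list()
  draws <- 0L
  while (any(got < want)) {
    draws <- draws + 1L
    if (draws > max_draws) {
      missing_cat <- names(want)[got < want]
      stop("category ", paste(missing_cat, collapse = ", "),
           " not reachable within ", max_draws, " draws")
    }
    x <- stats::runif(nrow(bounds), bounds[, "lower"], bounds[, "upper"])
    names(x) <- rownames(bounds)
    p <- model_parameters(Rg = x[["Rg"]], alphaG = x[["alphaG"]],
                          kg = x[["kg"]], Kg = x[["Kg"]], Eg = x[["Eg"]],
                          betaH = x[["betaH"]], Hv = x[["Hv"]],
                          GA = x[["GA"]], Gw = x[["Gw"]], tc = tc,
                          Gsleep = Gsleep, Hsleep = Hsleep)
    risk <- risk_score(p)
    cat_i <- risk$category
    if (got[[cat_i]] >= want[[cat_i]]) next
    noise_seed <- sample.int(.Machine$integer.max - 1L, 1L)
    series <- tryCatch(
      generate_synthetic_patient(p, G0 = G0, H0 = H0, seed = noise_seed, ...),
      glucohr_solver_failure = function(e) NULL)
    if (is.null(series)) next
    got[[cat_i]] <- got[[cat_i]] + 1L
    out[[length(out) + 1L]] <- list(series = series, params = p,
                                    category = cat_i, score = risk$score)
  }
  out
}
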