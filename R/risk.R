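#' Latin hypercube sample over a box
#'
#' Stratified uniform sampling: each dimension is divided into \code{n}
#' equal-probability strata containing exactly one sample, with strata
#' permuted independently across dimensions.
#'
#' @param ranges k x 2 matrix (columns lower, upper; rownames name the
#'   parameters), or a \code{parameter_bounds} object.
#' @param n number of samples (>= 2).
#' @param seed RNG seed.
#' @return n x k numeric matrix, columns named after the rows of
#'   \code{ranges}.
#' @export
lhs_sample <- function(ranges, n, seed = NULL) {
  ranges <- as.matrix(ranges)
  stopifnot(ncol(ranges) == 2, n >= 2, all(ranges[, 1] < ranges[, 2]))
  if (!is.null(seed)) set.seed(seed)
  u <- lhs::randomLHS(n, nrow(ranges))
  out <- sweep(u, 2, ranges[, 2] - ranges[, 1], `*`)
  out <- sweep(out, 2, ranges[, 1], `+`)
  colnames(out) <- rownames(ranges)
  out
}

#' Nocturnal summary outputs of a trajectory
#'
#' The two glucose summaries the sensitivity analysis targets: the maximum
#' nocturnal glucose and the glucose at the final measurement time.
#'
#' @param traj a \code{trajectory} or [observed_series()].
#' @return Named numeric \code{c(max_night_glucose, final_glucose)}, mg/dl.
#' @export
nocturnal_outputs <- function(traj) {
  stopifnot(nrow(traj) > 0)
  c(max_night_glucose = max(traj$glucose),
    final_glucose = traj$glucose[nrow(traj)])
}

#' Partial rank correlation coefficients
#'
#' Rank-transforms every column, then for each parameter j regresses both
#' rank(x_j) and rank(y) on the ranks of all other parameters and takes the
#' Pearson correlation of the two residual vectors. The p-value uses
#' \eqn{t = r\sqrt{(n-2-p)/(1-r^2)}} on \eqn{n-2-p} degrees of freedom,
#' where p is the number of controlled parameters. PRCC is invariant under
#' monotone transformations of inputs or output, making it the standard
#' monotone-robust global sensitivity measure.
#'
#' @param samples n x k parameter matrix (no constant column; n >= k + 3).
#' @param y length-n output vector.
#' @return Data frame with columns \code{parameter}, \code{prcc},
#'   \code{p_value}.
#' @export
prcc <- function(samples, y) {
  samples <- as.matrix(samples)
  n <- nrow(samples)
  k <- ncol(samples)
  stopifnot(length(y) == n, n >= k + 3)
  if (any(apply(samples, 2, stats::sd) == 0))
    stop("constant parameter column: PRCC undefined (widen its range)")
  R <- apply(samples, 2, rank)
  ry <- rank(y)
  nms <- colnames(samples)
  if (is.null(nms)) nms <- paste0("x", seq_len(k))

  res <- lapply(seq_len(k), function(j) {
    Z <- cbind(1, R[, -j, drop = FALSE])
    qz <- qr(Z)
    if (qz$rank < ncol(Z)) {
      warning("near-singular rank regression; ridge-stabilized")
      ZtZ <- crossprod(Z) + 1e-8 * diag(ncol(Z))
      ex <- R[, j] - Z %*% solve(ZtZ, crossprod(Z, R[, j]))
      ey <- ry - Z %*% solve(ZtZ, crossprod(Z, ry))
    } else {
      ex <- qr.resid(qz, R[, j])
      ey <- qr.resid(qz, ry)
    }
    r <- suppressWarnings(stats::cor(ex, ey))
    if (!is.finite(r)) r <- 0
    r <- max(-1, min(1, r))
    df <- n - 2 - (k - 1)
    p <- if (abs(r) >= 1) 0 else {
      tval <- r * sqrt(df / (1 - r^2))
      2 * stats::pt(-abs(tval), df)
    }
    c(r, p)
  })
  m <- do.call(rbind, res)
  data.frame(parameter = nms, prcc = m[, 1], p_value = m[, 2],
             stringsAsFactors = FALSE)
}

#' LHS-PRCC global sensitivity analysis
#'
#' Samples the nine estimated parameters by Latin hypercube within a
#' fractional spread about a center vector (intersected with the feasible
#' bounds), simulates each sample noiselessly, and computes PRCC with
#' p-values for the two nocturnal glucose outputs. Sensitivity of the model
#' itself is assessed, so no measurement noise is added.
#'
#' @param center a [model_parameters()] object (e.g. a fitted vector).
#' @param spread fractional half-width of each parameter range about its
#'   center (default 0.2 = +/-20\%); must be > 0 (zero would give constant
#'   columns).
#' @param n number of LHS samples.
#' @param seed RNG seed.
#' @param G0,H0 initial conditions; default to the center's baselines.
#' @param bounds feasible box used to truncate the ranges.
#' @param times simulation grid.
#' @param settings an [integrator_settings()] object.
#' @return A \code{sensitivity_result} list: \code{parameters},
#'   \code{prcc} and \code{p_value} (k x 2 matrices, one column per
#'   output), \code{outputs} labels, \code{n}, \code{n_failed}, \code{seed}.
#' @export
sensitivity_analysis <- function(center, spread = 0.2, n = 500, seed = NULL,
                                 G0 = NULL, H0 = NULL,
                                 bounds = parameter_bounds(),
                                 times = seq(0, 600, by = 5),
                                 settings = integrator_settings()) {
  stopifnot(inherits(center, "model_parameters"), n >= 12)
  if (spread <= 0)
    stop("spread must be > 0 (zero spread gives constant columns)")
  if (is.null(G0)) G0 <- center$Gsleep
  if (is.null(H0)) H0 <- center$Hsleep

  cv <- unlist(center)[.free_parameter_names]
  lo <- pmax(cv * (1 - spread), bounds[.free_parameter_names, "lower"])
  hi <- pmin(cv * (1 + spread), bounds[.free_parameter_names, "upper"])
  bad <- lo >= hi
  if (any(bad))
    stop("empty sampling range for ",
         paste(.free_parameter_names[bad], collapse = ", "),
         " after truncation to the feasible bounds")
  ranges <- cbind(lower = lo, upper = hi)
  rownames(ranges) <- .free_parameter_names

  samples <- lhs_sample(ranges, n, seed)
  outs <- matrix(NA_real_, n, 2,
                 dimnames = list(NULL, c("max_night_glucose",
                                         "final_glucose")))
  for (i in seq_len(n)) {
    x <- samples[i, ]
    p <- model_parameters(Rg = x[["Rg"]], alphaG = x[["alphaG"]],
                          kg = x[["kg"]], Kg = x[["Kg"]], Eg = x[["Eg"]],
                          betaH = x[["betaH"]], Hv = x[["Hv"]],
                          GA = x[["GA"]], Gw = x[["Gw"]], tc = center$tc,
                          Gsleep = center$Gsleep, Hsleep = center$Hsleep)
    traj <- tryCatch(simulate_trajectory(p, G0, H0, times, settings),
                     glucohr_solver_failure = function(e) NULL)
    if (!is.null(traj)) outs[i, ] <- nocturnal_outputs(traj)
  }
  ok <- stats::complete.cases(outs)
  if (sum(ok) < nrow(ranges) + 3)
    stop("too many failed simulations for PRCC")

  pr <- lapply(colnames(outs), function(lab)
    prcc(samples[ok, , drop = FALSE], outs[ok, lab]))
  prcc_m <- vapply(pr, function(d) d$prcc, numeric(nrow(ranges)))
  p_m <- vapply(pr, function(d) d$p_value, numeric(nrow(ranges)))
  dimnames(prcc_m) <- dimnames(p_m) <-
    list(.free_parameter_names, colnames(outs))

  structure(list(parameters = .free_parameter_names,
                 prcc = prcc_m, p_value = p_m,
                 outputs = colnames(outs),
                 n = sum(ok), n_failed = sum(!ok), seed = seed,
                 ranges = ranges),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("LHS-PRCC sensitivity (n = %d samples%s)\n", x$n,
              if (x$n_failed) paste0(", ", x$n_failed, " failed") else ""))
  df <- data.frame(prcc_max = round(x$prcc[, 1], 3),
                   p_max = signif(x$p_value[, 1], 3),
                   prcc_final = round(x$prcc[, 2], 3),
                   p_final = signif(x$p_value[, 2], 3))
  rownames(df) <- x$parameters
  print(df)
  invisible(x)
}

#' Weighted metabolic risk score
#'
#' Composite score over the four sensitivity-dominant parameters:
#' \deqn{S = 10 R_g + 100 k_g + 10000 \alpha_g + 100 (1 - \beta_H).}
#' The weights compensate the parameters' feasible ranges and their PRCC
#' magnitudes so each term contributes proportionally to its physiological
#' influence on nocturnal glucose. Higher basal production, uptake strain
#' and heart-rate modulation raise the score; stronger parasympathetic
#' damping (larger \eqn{\beta_H}) lowers it.
#'
#' @param params a [model_parameters()] object (typically fitted); only
#'   \code{Rg}, \code{kg}, \code{alphaG} and \code{betaH} enter the score.
#' @return A \code{risk_assessment} list: \code{score}, \code{category}
#'   (\code{"low"}, \code{"moderate"} or \code{"high"}) and
#'   \code{components} (the four weighted terms).
#' @examples
#' p <- model_parameters(Rg = 9.165, alphaG = 0.002, kg = 10, Kg = 8.904,
#'                       Eg = 0.001, betaH = 0.579, Hv = 3.893, GA = 0.974,
#'                       Gw = 263.86, Gsleep = 105, Hsleep = 90)
#' risk_score(p)$score  # 1153.75
#' @export
risk_score <- function(params) {
  stopifnot(inherits(params, "model_parameters"))
  components <- c(Rg = 10 * params$Rg,
                  kg = 100 * params$kg,
                  alphaG = 10000 * params$alphaG,
                  betaH = 100 * (1 - params$betaH))
  S <- sum(components)
  structure(list(score = S, category = categorize_risk(S),
                 components = components),
            class = "risk_assessment")
}

#' @export
print.risk_assessment <- function(x, ...) {
  cat(sprintf("Metabolic risk score S = %.1f -> %s risk\n",
              x$score, x$category))
  print(round(x$components, 3))
  invisible(x)
}

#' Risk category from a score
#'
#' Half-open stratification: \eqn{S > 1000} high risk (strong metabolic
#' dysregulation), \eqn{500 < S \le 1000} moderate risk (early-stage
#' dysregulation), \eqn{S \le 500} low risk (normal regulation).
#'
#' @param S finite numeric score (vectorized).
#' @return Character vector in \code{c("low", "moderate", "high")}.
#' @examples
#' categorize_risk(c(500, 1000, 1000.1))
#' @export
categorize_risk <- function(S) {
  stopifnot(all(is.finite(S)))
  ifelse(S > 1000, "high", ifelse(S > 500, "moderate", "low"))
}
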