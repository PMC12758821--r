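#' Coefficients of the equilibrium cubic
#'
#' With the spike disabled (\eqn{G_A = 0}) the steady states of the system
#' satisfy a cubic in glucose, \eqn{A G^3 + B G^2 + C G + D = 0}, obtained by
#' substituting the heart-rate nullcline
#' \eqn{H^* = H_{sleep} + (H_v/\beta_H)(G^* - G_{sleep})/G_{sleep}} into the
#' glucose equation and multiplying through by \eqn{(G + K_g)}:
#' \deqn{A = \gamma = \alpha_G H_v / (\beta_H H_{sleep} G_{sleep}),\quad
#'       B = A K_g - A G_{sleep} - E_g,}
#' \deqn{C = R_g - A K_g G_{sleep} - E_g K_g - k_g,\quad
#'       D = R_g K_g.}
#'
#' @param params a [model_parameters()] object; \code{GA} is ignored (treated
#'   as 0).
#' @return Named numeric vector \code{c(A, B, C, D)}. \code{A = 0} when
#'   \code{alphaG = 0} or \code{Hv = 0} (degenerate, quadratic case).
#' @export
cubic_coefficients <- function(params) {
  stopifnot(inherits(params, "model_parameters"))
  A <- params$alphaG * params$Hv /
    (params$betaH * params$Hsleep * params$Gsleep)
  B <- A * params$Kg - A * params$Gsleep - params$Eg
  C <- params$Rg - A * params$Kg * params$Gsleep -
    params$Eg * params$Kg - params$kg
  D <- params$Rg * params$Kg
  c(A = A, B = B, C = C, D = D)
}

# Autonomous glucose residual after eliminating H via its nullcline.
.autonomous_g_residual <- function(G, params, A) {
  params$Rg + A * G * (G - params$Gsleep) -
    params$kg * G / (G + params$Kg) - params$Eg * G
}

#' Equilibria of the autonomous system
#'
#' Solves the equilibrium cubic numerically (via the polynomial companion
#' solver, with a Newton polish on the un-cleared residual) and returns all
#' physiological roots \eqn{G^* > 0}, each paired with
#' \eqn{H^* = H_{sleep} + (H_v/\beta_H)(G^* - G_{sleep})/G_{sleep}}.
#' Degenerate leading coefficients (\code{alphaG = 0} or \code{Hv = 0})
#' reduce the cubic to a quadratic or linear equation, which is solved
#' directly. Non-positive and complex roots are kept separately for
#' diagnostics, as is the Descartes sign condition (opposite signs of B and
#' C, necessary for two positive roots of the full cubic).
#'
#' @param params a [model_parameters()] object; the spike is ignored.
#' @return An \code{equilibrium_result} list with elements
#'   \code{coefficients} (A, B, C, D), \code{gamma} (the composite coupling
#'   constant, equal to A), \code{points} (data frame \code{G_star},
#'   \code{H_star}, possibly zero rows), \code{all_roots} (complex vector),
#'   \code{degenerate} flag and \code{descartes_opposite_signs} flag.
#' @export
equilibrium_points <- function(params) {
  co <- cubic_coefficients(params)
  A <- co[["A"]]; B <- co[["B"]]; C <- co[["C"]]; D <- co[["D"]]
  # polyroot takes ascending-degree coefficients; strip degenerate leaders
  asc <- c(D, C, B, A)
  while (length(asc) > 1L && asc[length(asc)] == 0)
    asc <- asc[-length(asc)]
  degenerate <- (A == 0)
  roots <- if (length(asc) <= 1L) complex(0) else polyroot(asc)

  is_real <- abs(Im(roots)) < 1e-8 * pmax(1, abs(Re(roots)))
  g_real <- Re(roots[is_real])
  g_pos <- sort(g_real[g_real > 0])

  # Newton polish on the residual before clearing (G + Kg); a few steps
  # push the RHS residual to ~1e-12 even for ill-scaled coefficients.
  if (length(g_pos)) {
    g_pos <- vapply(g_pos, function(g) {
      for (i in 1:5) {
        f <- .autonomous_g_residual(g, params, A)
        h <- 1e-7 * max(1, abs(g))
        fp <- (.autonomous_g_residual(g + h, params, A) -
               .autonomous_g_residual(g - h, params, A)) / (2 * h)
        if (!is.finite(fp) || fp == 0) break
        gn <- g - f / fp
        if (!is.finite(gn) || gn <= 0) break
        g <- gn
      }
      g
    }, numeric(1))
  }

  h_star <- params$Hsleep + (params$Hv / params$betaH) *
    (g_pos - params$Gsleep) / params$Gsleep

  structure(list(
    coefficients = co,
    gamma = A,
    points = data.frame(G_star = g_pos, H_star = h_star),
    all_roots = roots,
    degenerate = degenerate,
    descartes_opposite_signs = is.finite(B) && is.finite(C) && (B * C < 0)
  ), class = "equilibrium_result")
}

#' @export
print.equilibrium_result <- function(x, ...) {
  cat("Equilibria of the autonomous glucose-heart-rate system\n")
  cat(sprintf("  cubic coefficients: A=%.4g B=%.4g C=%.4g D=%.4g%s\n",
              x$coefficients["A"], x$coefficients["B"],
              x$coefficients["C"], x$coefficients["D"],
              if (x$degenerate) " (degenerate: A = 0)" else ""))
  if (nrow(x$points)) print(x$points) else cat("  no positive real root\n")
  invisible(x)
}

#' Jacobian of the autonomous system at an equilibrium
#'
#' @param params a [model_parameters()] object.
#' @param G_star equilibrium glucose, mg/dl.
#' @param H_star equilibrium heart rate, BPM.
#' @return 2x2 numeric matrix with entries
#'   \code{J11 = alphaG*(H*-Hsleep)/Hsleep - kg*Kg/(G*+Kg)^2 - Eg},
#'   \code{J12 = alphaG*G*/Hsleep}, \code{J21 = Hv/Gsleep},
#'   \code{J22 = -betaH}.
#' @export
jacobian_at <- function(params, G_star, H_star) {
  stopifnot(inherits(params, "model_parameters"),
            is.finite(G_star), is.finite(H_star))
  J11 <- params$alphaG * (H_star - params$Hsleep) / params$Hsleep -
    params$kg * params$Kg / (G_star + params$Kg)^2 - params$Eg
  J12 <- params$alphaG * G_star / params$Hsleep
  J21 <- params$Hv / params$Gsleep
  J22 <- -params$betaH
  matrix(c(J11, J21, J12, J22), nrow = 2,
         dimnames = list(c("G", "H"), c("G", "H")))
}

# Single-equilibrium stability classification.
.stability_one <- function(params, G_star, H_star) {
  J <- jacobian_at(params, G_star, H_star)
  tr <- J[1, 1] + J[2, 2]
  det <- J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]
  disc <- as.complex(tr^2 - 4 * det)
  eig <- c((tr + sqrt(disc)) / 2, (tr - sqrt(disc)) / 2)
  gamma <- params$alphaG * params$Hv /
    (params$betaH * params$Hsleep * params$Gsleep)
  degenerate_gamma <- gamma == 0
  G_threshold <- if (degenerate_gamma) Inf else
    min(params$Gsleep + (params$Eg + params$betaH) / gamma,
        params$Gsleep / 2 + params$Eg / (2 * gamma))
  structure(list(
    G_star = G_star, H_star = H_star,
    jacobian = J, trace = tr, determinant = det, eigenvalues = eig,
    is_stable = all(Re(eig) < 0),
    gamma = gamma, G_threshold = G_threshold,
    degenerate_gamma = degenerate_gamma
  ), class = "stability_report")
}

#' Local stability of the autonomous equilibria
#'
#' Classifies each equilibrium from the eigenvalues of the Jacobian
#' (quadratic formula on the characteristic polynomial). For a 2x2 system
#' this is equivalent to the Routh-Hurwitz pair trace < 0, determinant > 0.
#' Also reports the sufficient-condition threshold
#' \eqn{G^* < \min\{G_{sleep} + (E_g+\beta_H)/\gamma,\;
#'       G_{sleep}/2 + E_g/(2\gamma)\}} with
#' \eqn{\gamma = \alpha_G H_v/(\beta_H H_{sleep} G_{sleep})}; when
#' \eqn{\gamma = 0} the threshold is reported as \code{Inf} with a
#' degeneracy flag. The threshold is a diagnostic only; classification
#' always comes from the eigenvalues.
#'
#' @param params a [model_parameters()] object.
#' @param eq an \code{equilibrium_result} from [equilibrium_points()], or a
#'   data frame with columns \code{G_star}, \code{H_star}.
#' @return A list of \code{stability_report} objects, one per equilibrium,
#'   each holding \code{jacobian}, \code{trace}, \code{determinant},
#'   \code{eigenvalues}, \code{is_stable}, \code{gamma},
#'   \code{G_threshold} and \code{degenerate_gamma}.
#' @export
assess_stability <- function(params, eq) {
  pts <- if (inherits(eq, "equilibrium_result")) eq$points else eq
  if (!NROW(pts)) stop("no equilibrium to assess")
  lapply(seq_len(nrow(pts)), function(i)
    .stability_one(params, pts$G_star[i], pts$H_star[i]))
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("Equilibrium (G*=%.4f, H*=%.4f): %s\n", x$G_star, x$H_star,
              if (x$is_stable) "locally asymptotically stable" else "unstable"))
  cat(sprintf("  trace=%.6g det=%.6g eigen=[%s]\n", x$trace, x$determinant,
              paste(format(x$eigenvalues, digits = 6), collapse = ", ")))
  cat(sprintf("  sufficient-condition threshold G* < %.6g%s\n", x$G_threshold,
              if (x$degenerate_gamma) " (gamma = 0, threshold degenerate)" else ""))
  invisible(x)
}

#' Serialize a stability analysis to JSON
#'
#' @param params a [model_parameters()] object.
#' @param path file path.
#' @return \code{path}, invisibly. The JSON holds the cubic coefficients,
#'   roots, per-equilibrium eigenvalues and stability flags.
#' @export
write_stability_json <- function(params, path) {
  eq <- equilibrium_points(params)
  reports <- if (nrow(eq$points)) assess_stability(params, eq) else list()
  payload <- list(
    coefficients = as.list(eq$coefficients),
    gamma = eq$gamma,
    degenerate = eq$degenerate,
    descartes_opposite_signs = eq$descartes_opposite_signs,
    all_roots = lapply(eq$all_roots, function(z)
      list(re = Re(z), im = Im(z))),
    equilibria = lapply(reports, function(r) list(
      G_star = r$G_star, H_star = r$H_star,
      trace = r$trace, determinant = r$determinant,
      eigenvalues = lapply(r$eigenvalues, function(z)
        list(re = Re(z), im = Im(z))),
      is_stable = r$is_stable,
      G_threshold = r$G_threshold,
      degenerate_gamma = r$degenerate_gamma)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
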