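#' Model parameter set for the glucose-heart-rate system
#'
#' Bundles every rate constant, baseline and spike parameter of the coupled
#' nocturnal glucose/heart-rate ODE system into a validated object.
#'
#' The glucose equation is
#' \deqn{dG/dt = R_g + \alpha_G G (H - H_{sleep})/H_{sleep}
#'       - k_g G/(G + K_g) - E_g G
#'       + G_A \exp(-(t-t_c)^2 / (2 G_w^2)) \chi_{t \ge t_c},}
#' and the heart-rate equation is
#' \deqn{dH/dt = -\beta_H (H - H_{sleep}) + H_v (G - G_{sleep})/G_{sleep}.}
#'
#' @param Rg basal glucose production rate, mg/dl/min.
#' @param alphaG heart-rate modulation coefficient of glucose, 1/min
#'   (may be 0, which decouples glucose from heart rate).
#' @param kg glucose consumption gain rate of the Michaelis-Menten uptake
#'   term, 1/min.
#' @param Kg glucose transporter saturation level, mg/dl.
#' @param Eg linear glucose clearance rate, 1/min.
#' @param betaH heart-rate decay rate toward the resting rate, 1/min.
#' @param Hv coupling strength of glucose to heart rate, BPM/min
#'   (may be 0, which decouples heart rate from glucose).
#' @param GA magnitude of the transient dawn-phenomenon glucose spike,
#'   mg/dl/min (0 disables the spike).
#' @param Gw duration (Gaussian width) of the spike, min.
#' @param tc center time of the spike, minutes since window start. Defaults
#'   to 480 min, a late-night/dawn position on a 600-min horizon; it is a
#'   fixed input, not an estimated parameter.
#' @param Gsleep baseline sleep glucose concentration, mg/dl.
#' @param Hsleep baseline sleep heart rate, BPM.
#'
#' @return An object of class \code{model_parameters} (a named list).
#' @examples
#' p <- model_parameters(Rg = 8.2, alphaG = 0.001, kg = 9, Kg = 9,
#'                       Eg = 0.001, betaH = 0.6, Hv = 5, GA = 1, Gw = 250,
#'                       Gsleep = 105, Hsleep = 90)
#' p
#' @seealso [simulate_trajectory()], [parameter_bounds()], [risk_score()]
#' @export
model_parameters <- function(Rg, alphaG, kg, Kg, Eg, betaH, Hv, GA, Gw,
                             tc = 480, Gsleep = 105, Hsleep = 90) {
  p <- list(Rg = Rg, alphaG = alphaG, kg = kg, Kg = Kg, Eg = Eg,
            betaH = betaH, Hv = Hv, GA = GA, Gw = Gw, tc = tc,
            Gsleep = Gsleep, Hsleep = Hsleep)
  if (!all(vapply(p, function(v) is.numeric(v) && length(v) == 1L,
                  logical(1))))
    stop("all model parameters must be single finite numbers")
  p <- lapply(p, function(v) as.numeric(v)[[1L]])
  vals <- unlist(p)
  if (!all(is.finite(vals)))
    stop("all model parameters must be single finite numbers")
  nonneg <- c("Rg", "alphaG", "kg", "Eg", "Hv", "GA")
  pos <- c("Kg", "betaH", "Gw", "Gsleep", "Hsleep")
  if (any(vals[nonneg] < 0))
    stop("parameters ", paste(nonneg[vals[nonneg] < 0], collapse = ", "),
         " must be >= 0")
  if (any(vals[pos] <= 0))
    stop("parameters ", paste(pos[vals[pos] <= 0], collapse = ", "),
         " must be > 0")
  structure(p, class = "model_parameters")
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("Glucose-heart-rate model parameters:\n")
  v <- unlist(x)
  print(round(v, 6))
  invisible(x)
}

#' @export
as.data.frame.model_parameters <- function(x, ...) {
  data.frame(parameter = names(x), value = unname(unlist(x)),
             stringsAsFactors = FALSE)
}

# Internal: numeric vector in the layout the compiled RHS expects.
.parm_vector <- function(params, spike_on) {
  c(params$Rg, params$alphaG, params$kg, params$Kg, params$Eg,
    params$betaH, params$Hv, params$GA, params$Gw, params$tc,
    params$Gsleep, params$Hsleep, as.numeric(spike_on))
}

# Names of the parameters that are estimated (bounded) during fitting.
.free_parameter_names <- c("Rg", "alphaG", "kg", "Kg", "Eg", "betaH",
                           "Hv", "GA", "Gw")

#' Feasible box bounds for the estimated parameters
#'
#' Lower/upper bounds for the nine estimated parameters. The defaults are the
#' physiological ranges used to constrain the particle swarm optimizer.
#'
#' @param ... optional per-parameter overrides, each a length-2 numeric
#'   \code{c(lower, upper)}, e.g. \code{Rg = c(1, 5)}.
#' @return A \code{parameter_bounds} object: a 9 x 2 matrix with rownames
#'   \code{Rg, alphaG, kg, Kg, Eg, betaH, Hv, GA, Gw} and columns
#'   \code{lower}, \code{upper}.
#' @examples
#' parameter_bounds()
#' parameter_bounds(Rg = c(7, 9), Gw = c(200, 300))
#' @export
parameter_bounds <- function(...) {
  b <- rbind(Rg     = c(0.001, 10),
             alphaG = c(0.001, 0.1),
             kg     = c(0.001, 10),
             Kg     = c(1, 10),
             Eg     = c(0.001, 5),
             betaH  = c(0.001, 1),
             Hv     = c(0.001, 30),
             GA     = c(0.01, 20),
             Gw     = c(10, 300))
  colnames(b) <- c("lower", "upper")
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), rownames(b))
    if (length(bad)) stop("unknown parameter(s) in bounds: ",
                          paste(bad, collapse = ", "))
    for (nm in names(over)) {
      v <- as.numeric(over[[nm]])
      if (length(v) != 2L || !all(is.finite(v)))
        stop("bounds for ", nm, " must be a finite length-2 numeric")
      b[nm, ] <- v
    }
  }
  if (any(b[, "lower"] >= b[, "upper"]))
    stop("each lower bound must be strictly below its upper bound")
  structure(b, class = c("parameter_bounds", class(b)))
}

#' Write / read model parameters as flat JSON
#'
#' Parameters are stored as a flat key-value block keyed by the field-standard
#' symbol names (\code{Rg}, \code{alphaG}, \code{kg}, \code{Kg}, \code{Eg},
#' \code{betaH}, \code{Hv}, \code{GA}, \code{Gw}, \code{tc}, \code{Gsleep},
#' \code{Hsleep}).
#'
#' @param params a \code{model_parameters} object.
#' @param path file path.
#' @return \code{write_parameters_json} returns \code{path} invisibly;
#'   \code{read_parameters_json} returns a \code{model_parameters} object.
#' @export
write_parameters_json <- function(params, path) {
  stopifnot(inherits(params, "model_parameters"))
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_parameters_json
#' @export
read_parameters_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(model_parameters, as.list(x))
}
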