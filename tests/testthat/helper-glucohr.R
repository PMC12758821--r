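# Shared fixtures and independent oracles for the test suite.

# Synthetic patient 1: generating truth and initial conditions.
tc1_params <- function() {
  model_parameters(Rg = 8.2, alphaG = 0.001, kg = 9, Kg = 9, Eg = 0.001,
                   betaH = 0.6, Hv = 5, GA = 1, Gw = 250,
                   Gsleep = 105, Hsleep = 90)
}

# Independent fixed-step RK4 integrator (pure R, classical 4th order).
# Kept free of any package internals so it can serve as an oracle for the
# adaptive solver. Steps are aligned with the grid so the spike switch-on
# at tc (a grid multiple in all uses here) sits on a step boundary.
rk4_oracle <- function(p, G0, H0, times, h = 0.01) {
  rhs <- function(t, y) {
    spike <- if (t >= p$tc) p$GA * exp(-0.5 * ((t - p$tc) / p$Gw)^2) else 0
    c(p$Rg + p$alphaG * y[1] * (y[2] - p$Hsleep) / p$Hsleep -
        p$kg * y[1] / (y[1] + p$Kg) - p$Eg * y[1] + spike,
      -p$betaH * (y[2] - p$Hsleep) + p$Hv * (y[1] - p$Gsleep) / p$Gsleep)
  }
  out <- matrix(NA_real_, length(times), 2)
  y <- c(G0, H0)
  out[1, ] <- y
  for (k in seq_along(times)[-1]) {
    t0 <- times[k - 1]
    nstep <- round((times[k] - t0) / h)
    hh <- (times[k] - t0) / nstep
    for (i in seq_len(nstep)) {
      t <- t0 + (i - 1) * hh
      k1 <- rhs(t, y)
      k2 <- rhs(t + hh / 2, y + hh / 2 * k1)
      k3 <- rhs(t + hh / 2, y + hh / 2 * k2)
      k4 <- rhs(t + hh, y + hh * k3)
      y <- y + hh / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    out[k, ] <- y
  }
  out
}

# Uniform draw of a parameter set within the feasible box (baselines fixed).
random_params <- function(bounds = parameter_bounds()) {
  x <- stats::runif(nrow(bounds), bounds[, "lower"], bounds[, "upper"])
  names(x) <- rownames(bounds)
  model_parameters(Rg = x[["Rg"]], alphaG = x[["alphaG"]], kg = x[["kg"]],
                   Kg = x[["Kg"]], Eg = x[["Eg"]], betaH = x[["betaH"]],
                   Hv = x[["Hv"]], GA = x[["GA"]], Gw = x[["Gw"]])
}

# Write a raw wearable-style CSV fixture (timestamp,value) and return the path.
write_raw_csv <- function(timestamps, values, path = tempfile(fileext = ".csv")) {
  df <- data.frame(timestamp = format(timestamps, "%Y-%m-%d %H:%M:%S"),
                   value = values)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
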