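test_that("spike input is off before its center and Gaussian after", {
  p <- tc1_params()
  expect_identical(spike_input(p$tc - 1, p), 0)
  expect_equal(spike_input(p$tc, p), p$GA)
  p1 <- model_parameters(Rg = 1, alphaG = 0, kg = 1, Kg = 1, Eg = 0.1,
                         betaH = 0.5, Hv = 1, GA = 1, Gw = 20, tc = 100)
  expect_equal(spike_input(100 + 20, p1), exp(-1 / 2), tolerance = 1e-12)
  tgrid <- seq(0, 600, by = 1)
  v <- spike_input(tgrid, p1)
  expect_true(all(v >= 0 & v <= p1$GA))
  expect_true(all(v[tgrid < 100] == 0))
})

test_that("glucose rate matches term-by-term hand evaluation", {
  # only basal production survives
  p0 <- model_parameters(Rg = 1, alphaG = 0, kg = 0, Kg = 1, Eg = 0,
                         betaH = 0.5, Hv = 1, GA = 0, Gw = 10)
  expect_equal(glucose_rate(50, 120, 33, p0), 1)
  expect_equal(glucose_rate(0, 40, 7, p0), 1)
  # modulation vanishes at the resting heart rate
  p1 <- model_parameters(Rg = 2, alphaG = 0.05, kg = 0, Kg = 1, Eg = 0,
                         betaH = 0.5, Hv = 1, GA = 0, Gw = 10, Hsleep = 70)
  expect_equal(glucose_rate(150, 70, 0, p1), 2)
  # full hand evaluation: 1 + 0.5 - 1.81818... - 1
  p2 <- model_parameters(Rg = 1, alphaG = 0.01, kg = 2, Kg = 10, Eg = 0.01,
                         betaH = 0.5, Hv = 1, GA = 0, Gw = 10,
                         Gsleep = 100, Hsleep = 60)
  expect_equal(glucose_rate(100, 90, 0, p2),
               1 + 0.5 - 200 / 110 - 1, tolerance = 1e-12)
})

test_that("heart-rate rate matches hand evaluation and vanishes at baseline", {
  p <- model_parameters(Rg = 1, alphaG = 0.01, kg = 1, Kg = 10, Eg = 0.01,
                        betaH = 0.5, Hv = 10, GA = 0, Gw = 10,
                        Gsleep = 100, Hsleep = 60)
  expect_equal(heart_rate_rate(100, 60, p), 0)
  expect_equal(heart_rate_rate(100, 90, p), -15)
  expect_equal(heart_rate_rate(120, 90, p), -15 + 2)
})

test_that("an equilibrium initial condition yields a constant trajectory", {
  p <- tc1_params()
  p$GA <- 0
  p <- do.call(model_parameters, p)
  eq <- equilibrium_points(p)
  stable <- Filter(function(r) r$is_stable, assess_stability(p, eq))
  expect_gte(length(stable), 1)
  G <- stable[[1]]$G_star
  H <- stable[[1]]$H_star
  tr <- simulate_trajectory(p, G, H, times = seq(0, 300, by = 5))
  expect_lt(max(abs(tr$glucose - G)), 10 * 1e-8 * max(1, G))
  expect_lt(max(abs(tr$heart_rate - H)), 10 * 1e-8 * max(1, H))
})

test_that("decoupled heart rate follows the exponential relaxation closed form", {
  # Hv = 0 and alphaG = 0 decouple H: H(t) = Hsleep + (H0-Hsleep) e^(-betaH t)
  p <- model_parameters(Rg = 1, alphaG = 0, kg = 1, Kg = 10, Eg = 0.01,
                        betaH = 0.1, Hv = 0, GA = 0, Gw = 10,
                        Gsleep = 100, Hsleep = 60)
  tr <- simulate_trajectory(p, G0 = 100, H0 = 90, times = seq(0, 10, by = 1))
  expect_equal(tr$heart_rate[11], 60 + 30 * exp(-1), tolerance = 1e-6)
  expect_equal(round(tr$heart_rate[11], 4), 71.0364)
})

test_that("adaptive solution agrees with a fixed-step RK4 oracle", {
  times <- seq(0, 200, by = 5)
  set.seed(11)
  for (i in 1:3) {
    p <- random_params()
    tr <- tryCatch(simulate_trajectory(p, 118, 90, times),
                   glucohr_solver_failure = function(e) NULL)
    if (is.null(tr)) next
    oracle <- rk4_oracle(p, 118, 90, times, h = 0.01)
    rel <- abs(cbind(tr$glucose, tr$heart_rate) - oracle) /
      pmax(1, abs(oracle))
    expect_lt(max(rel), 1e-4)
  }
  # and for the reference synthetic patient with its dawn spike
  p <- tc1_params()
  tr <- simulate_trajectory(p, 118, 90, times = seq(0, 600, by = 5))
  oracle <- rk4_oracle(p, 118, 90, seq(0, 600, by = 5), h = 0.01)
  rel <- abs(cbind(tr$glucose, tr$heart_rate) - oracle) / pmax(1, abs(oracle))
  expect_lt(max(rel), 1e-4)
})

test_that("trajectories stay non-negative and finite on feasible-box draws", {
  set.seed(21)
  n_ok <- 0
  for (i in 1:25) {
    p <- random_params()
    tr <- tryCatch(simulate_trajectory(p, 118, 90),
                   glucohr_solver_failure = function(e) NULL)
    if (is.null(tr)) next  # strong-coupling blow-up signals cleanly
    n_ok <- n_ok + 1
    expect_true(all(tr$glucose >= 0))
    expect_true(all(tr$heart_rate >= 0))
    expect_true(all(is.finite(tr$glucose)) && all(is.finite(tr$heart_rate)))
    expect_lt(max(tr$glucose, tr$heart_rate), 1e6)
  }
  expect_gte(n_ok, 15)
})

test_that("integration failure raises the classed solver-failure condition", {
  # runaway coupling corner: quadratic cross-term dominates and blows up
  p <- model_parameters(Rg = 10, alphaG = 0.1, kg = 0.001, Kg = 1,
                        Eg = 0.001, betaH = 0.001, Hv = 30, GA = 20,
                        Gw = 300, tc = 0)
  expect_error(simulate_trajectory(p, 500, 300),
               class = "glucohr_solver_failure")
})

test_that("post-spike trajectory relaxes back to the pre-spike equilibrium", {
  # stable autonomous equilibrium + narrow pulse: the excursion decays
  p <- model_parameters(Rg = 8.2, alphaG = 0.001, kg = 9, Kg = 9,
                        Eg = 0.001, betaH = 0.6, Hv = 5, GA = 2, Gw = 15,
                        tc = 200, Gsleep = 105, Hsleep = 90)
  p0 <- p; p0$GA <- 0
  p0 <- do.call(model_parameters, p0)
  eq <- equilibrium_points(p0)
  st <- Filter(function(r) r$is_stable, assess_stability(p0, eq))[[1]]
  tr <- simulate_trajectory(p, st$G_star, st$H_star,
                            times = seq(0, 1500, by = 5))
  late <- tr[tr$time >= p$tc + 10 * p$Gw + 600, ]
  expect_lt(max(abs(late$glucose - st$G_star)) / st$G_star, 0.01)
  expect_lt(max(abs(late$heart_rate - st$H_star)) / st$H_star, 0.01)
})

test_that("trajectory CSV round-trips through the shared schema", {
  p <- tc1_params()
  tr <- simulate_trajectory(p, 118, 90, times = seq(0, 100, by = 5))
  path <- tempfile(fileext = ".csv")
  write_trajectory_csv(tr, path)
  expect_identical(readLines(path, n = 1), "t_min,glucose_mgdl,hr_bpm")
  back <- read_trajectory_csv(path)
  expect_equal(back$glucose, tr$glucose, tolerance = 1e-10)
  expect_equal(back$heart_rate, tr$heart_rate, tolerance = 1e-10)
  expect_equal(back$time, tr$time)
})

test_that("parameter validation rejects malformed inputs", {
  expect_error(model_parameters(Rg = -1, alphaG = 0, kg = 1, Kg = 1,
                                Eg = 0.1, betaH = 0.5, Hv = 1, GA = 0,
                                Gw = 10), "Rg")
  expect_error(model_parameters(Rg = 1, alphaG = 0, kg = 1, Kg = 0,
                                Eg = 0.1, betaH = 0.5, Hv = 1, GA = 0,
                                Gw = 10), "Kg")
  expect_error(model_parameters(Rg = Inf, alphaG = 0, kg = 1, Kg = 1,
                                Eg = 0.1, betaH = 0.5, Hv = 1, GA = 0,
                                Gw = 10))
  expect_error(parameter_bounds(Rg = c(5, 2)))
  expect_error(parameter_bounds(bogus = c(0, 1)), "bogus")
})

test_that("parameters round-trip through flat JSON", {
  p <- tc1_params()
  path <- tempfile(fileext = ".json")
  write_parameters_json(p, path)
  back <- read_parameters_json(path)
  expect_equal(unclass(back), unclass(p), tolerance = 1e-12)
})
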