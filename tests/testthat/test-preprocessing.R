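test_that("the default nocturnal grid has 110 five-minute offsets", {
  g <- night_grid()
  expect_equal(g$n, 110)
  expect_equal(g$offsets[1], 0)
  expect_equal(g$offsets[110], 545)
  expect_true(all(diff(g$offsets) == 5))
})

test_that("loading cleans, sorts and deduplicates raw exports", {
  ts <- as.POSIXct("2024-03-01 22:00:00", tz = "UTC") + c(600, 0, 300)
  path <- write_raw_csv(ts, c(102, 100, 101))
  # inject a blank value and a bad timestamp
  lines <- readLines(path)
  writeLines(c(lines, "2024-03-01 23:00:00,", "not-a-date,99"), path)
  s <- suppressMessages(load_time_series(path, "glucose"))
  expect_equal(nrow(s), 3)
  expect_equal(attr(s, "n_dropped"), 2)
  expect_equal(s$value, c(100, 101, 102))  # sorted ascending
  # duplicate timestamps: keep first, warn
  path2 <- write_raw_csv(rep(ts[2], 2), c(100, 999))
  expect_warning(s2 <- load_time_series(path2, "glucose"), "duplicate")
  expect_equal(s2$value, 100)
  # degenerate files error
  empty <- tempfile(fileext = ".csv")
  writeLines("timestamp,value", empty)
  expect_error(load_time_series(empty, "glucose"))
})

test_that("night windows span 21:00-09:00 inclusive and key by evening date", {
  base <- as.POSIXct("2024-03-01 12:00:00", tz = "UTC")
  ts <- c(base,                               # noon: excluded
          base + 9 * 3600,                    # 21:00 sharp: included
          base + 14 * 3600,                   # 02:00 next day -> night of 03-01
          base + 21 * 3600,                   # 09:00 next day: included
          base + 22 * 3600)                   # 10:00 next day: excluded
  path <- write_raw_csv(ts, 1:5)
  nights <- extract_night_windows(load_time_series(path, "glucose"))
  expect_length(nights, 1)
  expect_named(nights, "2024-03-01")
  expect_equal(nights[["2024-03-01"]]$value, c(2, 3, 4))
})

test_that("a constructed 3-night fixture reproduces per-night counts", {
  mk_night <- function(day, n) {
    start <- as.POSIXct(paste0("2024-03-0", day, " 23:00:00"), tz = "UTC")
    start + seq(0, by = 1800, length.out = n)
  }
  ts <- c(mk_night(1, 4), mk_night(3, 7), mk_night(5, 5))
  path <- write_raw_csv(ts, seq_along(ts))
  nights <- extract_night_windows(load_time_series(path, "glucose"))
  expect_equal(vapply(nights, nrow, 0L),
               c("2024-03-01" = 4L, "2024-03-03" = 7L, "2024-03-05" = 5L))
})

test_that("interpolation is linear with flagged edge fill", {
  g <- night_grid()
  day <- as.Date("2024-03-01")
  mk <- function(clock, val) {
    ts <- as.POSIXct(paste(day, clock), tz = "UTC")
    data.frame(timestamp = ts, value = val)
  }
  night <- do.call(rbind, list(mk("23:30:00", 100), mk("23:40:00", 110)))
  night <- structure(night, kind = "glucose", night_date = day,
                     class = c("raw_record_series", "data.frame"))
  out <- interpolate_to_grid(night, g)
  expect_equal(out$value[out$offset == 5], 105)   # 23:35, halfway
  expect_equal(out$value[out$offset == 0], 100)
  expect_equal(out$value[out$offset == 10], 110)
  # beyond the observed span: nearest-edge fill, flagged
  expect_true(all(out$value[out$offset > 10] == 110))
  flags <- attr(out, "extrapolated")
  expect_false(any(flags[g$offsets <= 10]))
  expect_true(all(flags[g$offsets > 10]))
  # records already on the grid pass through unchanged
  night2 <- structure(
    data.frame(timestamp = as.POSIXct(paste(day, "23:30:00"), tz = "UTC") +
                 g$offsets * 60,
               value = sin(g$offsets / 50) + 2),
    kind = "glucose", night_date = day,
    class = c("raw_record_series", "data.frame"))
  out2 <- interpolate_to_grid(night2, g)
  expect_equal(out2$value, sin(g$offsets / 50) + 2, tolerance = 1e-10)
  # single-record nights are dropped with a warning
  expect_warning(res <- interpolate_to_grid(night2[1, ], g), "fewer than 2")
  expect_null(res)
})

test_that("averaging across nights is an elementwise mean", {
  mk <- function(vals) data.frame(offset = c(0, 5), value = vals)
  avg <- average_across_nights(list(mk(c(100, 110)), mk(c(102, 108))))
  expect_equal(avg$value, c(101, 109))
  one <- average_across_nights(list(mk(c(7, 9))))
  expect_equal(one$value, c(7, 9))
  same <- average_across_nights(rep(list(mk(c(3, 4))), 5))
  expect_equal(same$value, c(3, 4))
  # order invariance
  a <- average_across_nights(list(mk(c(1, 2)), mk(c(5, 8)), mk(c(0, 2))))
  b <- average_across_nights(list(mk(c(5, 8)), mk(c(0, 2)), mk(c(1, 2))))
  expect_equal(a$value, b$value)
  expect_error(average_across_nights(list(mk(c(1, 2)),
                                          data.frame(offset = c(0, 10),
                                                     value = c(1, 2)))))
})

test_that("Savitzky-Golay smoothing reproduces cubics exactly", {
  x <- seq_len(110)
  expect_equal(smooth_series(rep(5, 110)), rep(5, 110), tolerance = 1e-10)
  cubic <- 2 + 0.5 * x - 0.01 * x^2 + 3e-4 * x^3
  expect_equal(smooth_series(cubic), cubic, tolerance = 1e-8)
  noisy <- cubic + sin(x)
  sm <- smooth_series(noisy)
  expect_length(sm, 110)
  expect_error(smooth_series(rep(1, 20), window = 31), "odd window")
  expect_error(smooth_series(rep(1, 20), window = 30), "odd")
})

test_that("an interior smoothed point equals the windowed cubic regression", {
  set.seed(41)
  y <- cumsum(rnorm(110))
  sm <- smooth_series(y, window = 31, polyorder = 3)
  i <- 60  # interior point with a full window
  idx <- (i - 15):(i + 15)
  z <- idx - i
  fit <- stats::lm(y[idx] ~ z + I(z^2) + I(z^3))
  expect_equal(sm[i], unname(stats::coef(fit)[1]), tolerance = 1e-8)
})

test_that("the full subject pipeline recovers a known nocturnal profile", {
  g <- night_grid()
  truth_g <- function(off) 110 + 15 * sin(off / 120)
  truth_h <- function(off) 62 + 5 * cos(off / 200)
  set.seed(42)
  days <- as.Date("2024-03-01") + 0:5
  mk_signal <- function(truth, step_min, jitter) {
    do.call(rbind, lapply(seq_along(days), function(i) {
      # records every `step_min` minutes from 22:00 to 09:00, timestamp jitter
      off <- seq(-90, 570, by = step_min)
      ts <- as.POSIXct(paste(days[i], "23:30:00"), tz = "UTC") +
        off * 60 + stats::runif(length(off), -jitter, jitter)
      data.frame(timestamp = ts, value = truth(off) + stats::rnorm(length(off), 0, 1))
    }))
  }
  gl <- mk_signal(truth_g, 5, 20)
  hr <- mk_signal(truth_h, 1, 5)
  gpath <- write_raw_csv(gl$timestamp, gl$value)
  hpath <- write_raw_csv(hr$timestamp, hr$value)
  diag_path <- tempfile(fileext = ".json")
  obs <- preprocess_subject(gpath, hpath, diagnostics_path = diag_path)
  expect_s3_class(obs, "observed_series")
  expect_equal(nrow(obs), 110)
  expect_equal(obs$time, g$offsets)
  rel_l2 <- function(a, b) sqrt(sum((a - b)^2)) / sqrt(sum(b^2))
  expect_lt(rel_l2(obs$glucose, truth_g(g$offsets)), 0.02)
  expect_lt(rel_l2(obs$heart_rate, truth_h(g$offsets)), 0.02)
  meta <- attr(obs, "meta")
  expect_equal(meta$glucose_nights, 6)
  expect_equal(meta$hr_nights, 6)
  d <- jsonlite::read_json(diag_path)
  expect_equal(d$glucose$n_nights, 6)
})

test_that("observed series CSV round-trips through the shared schema", {
  s <- observed_series(seq(0, 50, 5), 100 + 0:10, 60 + 0:10)
  path <- tempfile(fileext = ".csv")
  write_series_csv(s, path)
  expect_identical(readLines(path, n = 1), "t_min,glucose_mgdl,hr_bpm")
  back <- read_series_csv(path)
  expect_equal(back$glucose, s$glucose)
  expect_equal(back$heart_rate, s$heart_rate)
})
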