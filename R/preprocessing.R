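#' Uniform nocturnal sampling grid
#'
#' Fixed 5-minute grid anchored at a nightly clock time. The default runs
#' from 23:30 to 08:36 the next morning with the end treated as an exclusive
#' bound, giving offsets \{0, 5, ..., 545\} -- 110 points. (08:36 itself is
#' not a multiple of 5 minutes from 23:30, so the stated end time cannot be
#' a grid point; the last on-grid time is 08:35.)
#'
#' @param anchor nightly start clock time, \code{"HH:MM"}.
#' @param end morning end clock time, \code{"HH:MM"}, exclusive.
#' @param step grid interval, minutes.
#' @return A \code{night_grid} list with \code{offsets} (minutes since the
#'   anchor), \code{anchor}, \code{end}, \code{step} and \code{n}.
#' @export
night_grid <- function(anchor = "23:30", end = "08:36", step = 5) {
  stopifnot(step > 0)
  a <- .clock_minutes(anchor)
  e <- .clock_minutes(end)
  total <- (e - a) %% (24 * 60)
  if (total == 0) stop("grid must span a positive interval")
  offsets <- seq(0, by = step, length.out = ceiling(total / step))
  structure(list(offsets = offsets, anchor = anchor, end = end,
                 step = step, n = length(offsets)),
            class = "night_grid")
}

# Per-element tolerant parse: unparseable entries become NA (then dropped)
# instead of aborting the load.
.parse_timestamps <- function(x) {
  x <- as.character(x)
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01",
                    tz = "UTC")
  for (fmt in c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M")) {
    need <- is.na(out)
    if (!any(need)) break
    out[need] <- as.POSIXct(strptime(x[need], fmt, tz = "UTC"), tz = "UTC")
  }
  out
}

.clock_minutes <- function(hhmm) {
  parts <- as.integer(strsplit(hhmm, ":", fixed = TRUE)[[1]])
  stopifnot(length(parts) == 2, !anyNA(parts))
  parts[1] * 60 + parts[2]
}

#' Load a raw timestamped wearable export
#'
#' Reads a CSV with columns \code{timestamp,value}, parses timestamps
#' (ISO-8601 \code{T} separator or \code{"YYYY-MM-DD HH:MM:SS"}), drops
#' unparseable or non-finite rows (count recorded), keeps the first of any
#' duplicated timestamps (with a warning) and sorts ascending. Timestamps
#' are treated as naive local clock times (parsed in a fixed zone), which
#' sidesteps daylight-saving ambiguity.
#'
#' @param path CSV file path.
#' @param kind \code{"glucose"} (mg/dl) or \code{"heart_rate"} (BPM).
#' @return A \code{raw_record_series} data frame with columns
#'   \code{timestamp} (POSIXct) and \code{value}; attributes \code{kind} and
#'   \code{n_dropped}.
#' @export
load_time_series <- function(path, kind = c("glucose", "heart_rate")) {
  kind <- match.arg(kind)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("timestamp", "value") %in% names(df)))
    stop("expected columns `timestamp,value` in ", path)
  if (nrow(df) == 0) stop("empty file: ", path)
  ts <- .parse_timestamps(df$timestamp)
  val <- suppressWarnings(as.numeric(df$value))
  keep <- !is.na(ts) & is.finite(val)
  n_dropped <- sum(!keep)
  if (!any(keep)) stop("no parseable rows in ", path)
  if (n_dropped > 0)
    message("load_time_series: dropped ", n_dropped, " invalid row(s)")
  ts <- ts[keep]; val <- val[keep]
  o <- order(ts)
  ts <- ts[o]; val <- val[o]
  dup <- duplicated(ts)
  if (any(dup)) {
    warning("duplicate timestamps: keeping first of ", sum(dup), " duplicate(s)")
    ts <- ts[!dup]; val <- val[!dup]
  }
  structure(data.frame(timestamp = ts, value = val),
            kind = kind, n_dropped = n_dropped,
            class = c("raw_record_series", "data.frame"))
}

#' Split a record series into per-night windows
#'
#' A night spans 21:00 on day \emph{d} to 09:00 on day \emph{d}+1, both
#' boundaries inclusive; records outside every window are discarded. Nights
#' are keyed by the calendar date of their 21:00 anchor.
#'
#' @param series a \code{raw_record_series} from [load_time_series()].
#' @param evening_start evening boundary, \code{"HH:MM"} (inclusive).
#' @param morning_end morning boundary, \code{"HH:MM"} (inclusive).
#' @return A named list (by anchor date) of \code{raw_record_series},
#'   each carrying a \code{night_date} attribute.
#' @export
extract_night_windows <- function(series, evening_start = "21:00",
                                  morning_end = "09:00") {
  stopifnot(inherits(series, "raw_record_series"))
  ev <- .clock_minutes(evening_start)
  mo <- .clock_minutes(morning_end)
  lt <- as.POSIXlt(series$timestamp, tz = "UTC")
  tod <- lt$hour * 60 + lt$min + lt$sec / 60
  date <- as.Date(series$timestamp, tz = "UTC")
  anchor <- rep(as.Date(NA), nrow(series))
  anchor[tod >= ev] <- date[tod >= ev]
  anchor[tod <= mo] <- date[tod <= mo] - 1L
  keep <- !is.na(anchor)
  if (!any(keep)) return(list())
  split_idx <- split(which(keep), as.character(anchor[keep]))
  out <- lapply(names(split_idx), function(nm) {
    structure(series[split_idx[[nm]], , drop = FALSE],
              kind = attr(series, "kind"),
              night_date = as.Date(nm),
              class = c("raw_record_series", "data.frame"))
  })
  names(out) <- names(split_idx)
  out
}

#' Linearly interpolate one night onto the uniform grid
#'
#' Maps a night's irregular records onto the grid offsets by linear
#' interpolation between bracketing records. Grid points outside the night's
#' observed span are filled with the nearest edge value and flagged.
#'
#' @param night one element of [extract_night_windows()] output.
#' @param grid a [night_grid()].
#' @return A data frame \code{offset}, \code{value} with an
#'   \code{extrapolated} logical attribute (one flag per grid point), or
#'   \code{NULL} (with a warning) when the night has fewer than 2 usable
#'   records.
#' @export
interpolate_to_grid <- function(night, grid) {
  stopifnot(inherits(night, "raw_record_series"), inherits(grid, "night_grid"))
  if (nrow(night) < 2L) {
    warning("night dropped: fewer than 2 usable records")
    return(NULL)
  }
  night_date <- attr(night, "night_date")
  anchor_min <- .clock_minutes(grid$anchor)
  # grid anchor falls after noon -> same calendar day as the 21:00 anchor;
  # before noon -> next morning
  anchor_day <- if (anchor_min >= 12 * 60) night_date else night_date + 1L
  anchor_abs <- as.POSIXct(paste(anchor_day,
                                 sprintf("%02d:%02d:00", anchor_min %/% 60,
                                         anchor_min %% 60)), tz = "UTC")
  x <- as.numeric(difftime(night$timestamp, anchor_abs, units = "mins"))
  y <- night$value
  fit <- stats::approx(x, y, xout = grid$offsets, method = "linear",
                       rule = 2, ties = "ordered")
  extrapolated <- grid$offsets < min(x) | grid$offsets > max(x)
  structure(data.frame(offset = grid$offsets, value = fit$y),
            extrapolated = extrapolated)
}

#' Pointwise average across nights
#'
#' Elementwise mean of per-night gridded series sharing an identical offset
#' grid; the time axis of the result is minutes since the nightly anchor.
#' Averaging is permutation-invariant in the order of nights.
#'
#' @param nights list of data frames from [interpolate_to_grid()]
#'   (\code{NULL} entries are removed).
#' @return Data frame \code{offset}, \code{value}; attribute
#'   \code{n_nights}.
#' @export
average_across_nights <- function(nights) {
  nights <- Filter(Negate(is.null), nights)
  if (!length(nights)) stop("no usable nights to average")
  off <- nights[[1]]$offset
  for (n in nights)
    if (!isTRUE(all.equal(n$offset, off)))
      stop("all nights must share an identical grid")
  m <- vapply(nights, function(n) n$value, numeric(length(off)))
  m <- matrix(m, nrow = length(off))
  structure(data.frame(offset = off, value = rowMeans(m)),
            n_nights = length(nights))
}

#' Savitzky-Golay smoothing
#'
#' Least-squares local-polynomial smoothing that preserves local trends and
#' extrema; by construction the filter reproduces any polynomial up to the
#' fit order exactly (including at the edges, which are handled by
#' polynomial fits within truncated windows). Output length equals input
#' length.
#'
#' @param values numeric series.
#' @param window odd window length in points (default 31).
#' @param polyorder polynomial order (default 3, cubic).
#' @return Smoothed numeric vector, same length as \code{values}.
#' @export
smooth_series <- function(values, window = 31, polyorder = 3) {
  stopifnot(is.numeric(values), polyorder >= 0)
  if (window %% 2 == 0) stop("window must be odd")
  if (length(values) < window)
    stop("series length (", length(values), ") is below the window (",
         window, "); use a smaller odd window")
  as.numeric(signal::sgolayfilt(values, p = polyorder, n = window))
}

#' Preprocess one subject's raw wearable exports
#'
#' Full pipeline replicating the nocturnal preparation protocol: load and
#' clean each export, extract 21:00-09:00 night windows, linearly
#' interpolate each night onto the fixed 5-minute grid, average pointwise
#' across nights, and Savitzky-Golay smooth (window 31, cubic) each signal.
#' Glucose and heart rate come out temporally aligned on the same offsets.
#'
#' @param glucose_file CSV (\code{timestamp,value}) of CGM readings, mg/dl.
#' @param hr_file CSV (\code{timestamp,value}) of heart-rate readings, BPM.
#' @param grid a [night_grid()].
#' @param window,polyorder Savitzky-Golay settings.
#' @param diagnostics_path optional path for a JSON sidecar of per-night
#'   coverage diagnostics.
#' @return An [observed_series()] on the grid offsets; its \code{meta}
#'   attribute holds per-signal night counts and extrapolation flags.
#' @export
preprocess_subject <- function(glucose_file, hr_file, grid = night_grid(),
                               window = 31, polyorder = 3,
                               diagnostics_path = NULL) {
  one_signal <- function(path, kind) {
    raw <- load_time_series(path, kind)
    nights <- extract_night_windows(raw)
    if (!length(nights)) stop("no nocturnal records in ", path)
    gridded <- lapply(nights, function(n) {
      tryCatch(interpolate_to_grid(n, grid),
               warning = function(w) {
                 message("preprocess: ", conditionMessage(w), " (",
                         kind, ", night ", attr(n, "night_date"), ")")
                 NULL
               })
    })
    usable <- !vapply(gridded, is.null, logical(1))
    avg <- average_across_nights(gridded[usable])
    list(values = smooth_series(avg$value, window, polyorder),
         n_nights = sum(usable),
         nights = names(nights)[usable],
         extrapolated = lapply(gridded[usable],
                               function(g) which(attr(g, "extrapolated"))))
  }
  g <- one_signal(glucose_file, "glucose")
  h <- one_signal(hr_file, "heart_rate")
  meta <- list(source = "wearable",
               glucose_nights = g$n_nights, hr_nights = h$n_nights,
               grid = unclass(grid))
  if (!is.null(diagnostics_path)) {
    jsonlite::write_json(list(
      glucose = list(n_nights = g$n_nights, nights = g$nights,
                     extrapolated_points = g$extrapolated),
      heart_rate = list(n_nights = h$n_nights, nights = h$nights,
                        extrapolated_points = h$extrapolated)),
      diagnostics_path, auto_unbox = TRUE, digits = NA)
  }
  observed_series(grid$offsets, pmax(g$values, 0), pmax(h$values, 0),
                  meta = meta)
}

#' Write / read an observed series as CSV
#'
#' Same \code{t_min,glucose_mgdl,hr_bpm} schema as trajectories, so the
#' fitting stage consumes synthetic and preprocessed real data identically.
#'
#' @param series an [observed_series()].
#' @param path file path.
#' @return \code{write_series_csv} returns \code{path} invisibly;
#'   \code{read_series_csv} returns an [observed_series()].
#' @export
write_series_csv <- function(series, path) {
  df <- data.frame(t_min = series$time, glucose_mgdl = series$glucose,
                   hr_bpm = series$heart_rate)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_series_csv
#' @export
read_series_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("t_min", "glucose_mgdl", "hr_bpm") %in% names(df)))
  observed_series(df$t_min, df$glucose_mgdl, df$hr_bpm,
                  meta = list(source = path))
}
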