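# Meteorological time series: loading, validation, resampling, synthesis.

#' Canonical weather attribute names
#'
#' The six meteorological attributes understood by the package, in their
#' canonical order: wind speed (m/s), air temperature (deg C), relative
#' humidity (%), atmospheric pressure (hPa), precipitation (mm) and global
#' radiation (kJ m-2 min-1).
#'
#' @return Character vector of attribute names.
#' @export
weather_attributes <- function() {
  c("wind", "temperature", "humidity", "pressure", "precipitation", "radiation")
}

#' Construct a weather series
#'
#' A `weather_series` holds a strictly increasing, evenly spaced sequence of
#' timestamps and one or more named real-valued attribute series measured at
#' those times. Timestamps are timezone-naive local time (stored as UTC);
#' all model times are hours since local midnight.
#'
#' @param time `POSIXct` vector, strictly increasing with constant spacing.
#' @param values data frame (or named list) of numeric attribute series, one
#'   row (element) per timestamp.
#' @return An object of class `weather_series` with fields `time`, `values`
#'   (data frame) and `cadence` (seconds).
#' @export
weather_series <- function(time, values) {
  time <- as_time(time)
  values <- as.data.frame(values)
  if (nrow(values) != length(time)) {
    stop("attribute series length does not match timestamps")
  }
  if (length(time) < 2L) stop("need at least two timestamps")
  dt <- diff(as.numeric(time))
  if (any(dt <= 0)) stop("non-monotone timestamps")
  cadence <- dt[1L]
  if (any(abs(dt - cadence) > 1e-6 * cadence)) {
    stop("irregular cadence: timestamps are not evenly spaced")
  }
  if (!all(vapply(values, is.numeric, logical(1L)))) {
    stop("all weather attributes must be numeric")
  }
  if (any(!is.finite(as.matrix(values)))) {
    stop("non-finite values in weather attributes")
  }
  structure(
    list(time = time, values = values, cadence = cadence),
    class = "weather_series"
  )
}

#' @export
print.weather_series <- function(x, ...) {
  cat(sprintf(
    "<weather_series> %d steps @ %gs, %s to %s\n  attributes: %s\n",
    length(x$time), x$cadence,
    format(x$time[1L], "%Y-%m-%d %H:%M"),
    format(x$time[length(x$time)], "%Y-%m-%d %H:%M"),
    paste(names(x$values), collapse = ", ")
  ))
  invisible(x)
}

# Parse timestamps as timezone-naive local time. Accepts POSIXct, ISO-8601
# strings ("2008-06-12T04:00:00" or with a space), or plain dates.
as_time <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  if (is.numeric(x)) {
    return(as.POSIXct(x, origin = "1970-01-01", tz = "UTC"))
  }
  x <- gsub("T", " ", as.character(x), fixed = TRUE)
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M", "%Y-%m-%d"))
  if (any(is.na(out))) stop("unparseable timestamps")
  out
}

# Hours since local midnight for each timestamp.
time_of_day <- function(time) {
  (as.numeric(time) %% 86400) / 3600
}

#' Load a weather CSV
#'
#' Reads a CSV with an ISO-8601 `time` column and one column per requested
#' attribute. The cadence is inferred from the first interval and verified
#' constant. Short runs of missing values (up to `max_gap` seconds) are
#' filled by linear interpolation; longer gaps are an error, as the model
#' assumes a complete record.
#'
#' @param path CSV file path.
#' @param attribute_names attributes to keep; default: all of
#'   [weather_attributes()] present in the file.
#' @param max_gap maximum gap (seconds) to interpolate across; default 3600.
#' @return A [weather_series()].
#' @export
load_weather <- function(path, attribute_names = NULL, max_gap = 3600) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"time" %in% names(df)) stop("weather CSV must have a 'time' column")
  time <- as_time(df$time)
  if (is.null(attribute_names)) {
    attribute_names <- intersect(weather_attributes(), names(df))
    if (length(attribute_names) == 0L) attribute_names <- setdiff(names(df), "time")
  }
  missing_attr <- setdiff(attribute_names, names(df))
  if (length(missing_attr) > 0L) {
    stop("unknown attribute name(s): ", paste(missing_attr, collapse = ", "))
  }
  dt <- diff(as.numeric(time))
  if (any(dt <= 0)) stop("non-monotone timestamps")
  cadence <- stats::median(dt)
  if (any(abs(dt - cadence) > 1e-6 * cadence)) {
    stop("irregular cadence beyond tolerance")
  }
  vals <- df[attribute_names]
  for (a in attribute_names) {
    v <- as.numeric(vals[[a]])
    if (anyNA(v)) {
      v <- fill_gaps(v, cadence, max_gap, a)
    }
    vals[[a]] <- v
  }
  weather_series(time, vals)
}

# Linear interpolation of NA runs no longer than max_gap seconds.
fill_gaps <- function(v, cadence, max_gap, name) {
  idx <- seq_along(v)
  na <- is.na(v)
  if (na[1L] || na[length(v)]) {
    stop(sprintf("attribute '%s' has missing values at the record boundary", name))
  }
  runs <- rle(na)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  too_long <- runs$values & (runs$lengths * cadence > max_gap)
  if (any(too_long)) {
    stop(sprintf("attribute '%s' has a gap longer than %gs", name, max_gap))
  }
  stats::approx(idx[!na], v[!na], xout = idx)$y
}

#' Resample a weather series to a coarser cadence
#'
#' Aggregates to blocks of `step` seconds: block means for continuous
#' attributes, block sums for precipitation (an accumulated quantity). The
#' output timestamp of each block is its first member's timestamp.
#'
#' @param ws a [weather_series()].
#' @param step target cadence in seconds; must be a multiple of the cadence.
#' @return A [weather_series()] with cadence `step`.
#' @export
resample_weather <- function(ws, step) {
  stopifnot(inherits(ws, "weather_series"))
  if (step == ws$cadence) return(ws)
  k <- step / ws$cadence
  if (abs(k - round(k)) > 1e-9 || k < 1) {
    stop("step must be a positive multiple of the cadence")
  }
  k <- as.integer(round(k))
  n <- length(ws$time)
  nblock <- n %/% k
  if (nblock < 2L) stop("series too short for requested step")
  use <- seq_len(nblock * k)
  block <- rep(seq_len(nblock), each = k)
  vals <- lapply(names(ws$values), function(a) {
    v <- ws$values[[a]][use]
    s <- as.numeric(tapply(v, block, sum))
    if (a == "precipitation") s else s / k
  })
  names(vals) <- names(ws$values)
  weather_series(ws$time[use[seq(1L, by = k, length.out = nblock)]],
                 as.data.frame(vals))
}

default_weather_params <- function() {
  list(
    wind          = list(baseline = 2,    diurnal = 1,    seasonal = 0.5,  noise_sd = 1,   tau_hours = 12, peak_hour = 14),
    temperature   = list(baseline = 26,   diurnal = 4,    seasonal = 4,    noise_sd = 2.5, tau_hours = 48, peak_hour = 15),
    humidity      = list(baseline = 70,   diurnal = -10,  seasonal = 5,    noise_sd = 8,   tau_hours = 24, peak_hour = 15),
    pressure      = list(baseline = 1008, diurnal = 1,    seasonal = 3,    noise_sd = 4,   tau_hours = 72, peak_hour = 10),
    precipitation = list(baseline = -0.3, diurnal = 0.05, seasonal = 0.05, noise_sd = 0.5, tau_hours = 12, peak_hour = 16),
    radiation     = list(baseline = 0.8,  diurnal = 1,    seasonal = 0.3,  noise_sd = 0.3, tau_hours = 6,  peak_hour = 12.5)
  )
}

#' Synthesize a field-like weather series
#'
#' Generates an evenly spaced multi-attribute record emulating a mid-latitude
#' station in summer: for each attribute, baseline + seasonal sinusoid
#' (365-day period, peaking around 1 August) + diurnal sinusoid (24-h period,
#' peaking at `peak_hour`; mid-afternoon for temperature) + AR(1) noise.
#' Precipitation is clipped at zero. Reproducible under a fixed seed.
#'
#' @param start,end start and end timestamps (inclusive start; the series
#'   covers `[start, end)` on the step grid).
#' @param step cadence in seconds (default 60, a per-minute station record).
#' @param params named list per attribute with entries `baseline`, `diurnal`,
#'   `seasonal`, `noise_sd` and optionally `peak_hour` and `tau_hours` (the
#'   e-folding time of the AR(1) noise); defaults emulate a temperate summer
#'   paddy-field site, including synoptic (day-to-day) variability with
#'   correlation times of half a day to three days so that, as in real
#'   records, threshold crossings are not locked to the time of day.
#' @param seed integer seed for the noise.
#' @return A [weather_series()].
#' @export
synth_weather <- function(start, end, step = 60, params = default_weather_params(),
                          seed = 1L) {
  start <- as_time(start); end <- as_time(end)
  if (end <= start) stop("end must be after start")
  time <- seq(start, end, by = step)
  if (time[length(time)] >= end) time <- time[time < end]
  n <- length(time)
  tsec <- as.numeric(time)
  tod <- (tsec %% 86400) / 3600
  doy <- (tsec %% (365 * 86400)) / 86400
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  vals <- list()
  for (a in names(params)) {
    p <- params[[a]]
    if (is.null(p$noise_sd) || p$noise_sd < 0) {
      if (!is.null(p$noise_sd) && p$noise_sd < 0) stop("negative noise sd")
      p$noise_sd <- 0
    }
    peak <- if (is.null(p$peak_hour)) 15 else p$peak_hour
    # seasonal peak ~ day 213 (1 Aug); doy measured from the epoch works
    # because only the within-year phase matters for a seasonal sinusoid.
    seasonal <- p$seasonal * cos(2 * pi * (doy - 213) / 365)
    diurnal <- p$diurnal * cos(2 * pi * (tod - peak) / 24)
    tau <- if (is.null(p$tau_hours)) 24 else p$tau_hours
    ar <- exp(-step / (tau * 3600))
    noise <- if (p$noise_sd > 0) {
      innov_sd <- p$noise_sd * sqrt(1 - ar^2)
      as.numeric(stats::filter(stats::rnorm(n, 0, innov_sd), ar,
                               method = "recursive"))
    } else {
      numeric(n)
    }
    v <- p$baseline + seasonal + diurnal + noise
    if (a == "precipitation") v <- pmax(v, 0)
    vals[[a]] <- v
  }
  weather_series(time, as.data.frame(vals))
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

#' Write a weather series to CSV
#'
#' @param ws a [weather_series()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_weather <- function(ws, path) {
  df <- cbind(time = format(ws$time, "%Y-%m-%dT%H:%M:%S"), ws$values)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Check that the record covers [from, to]; used before feature construction.
check_weather_coverage <- function(ws, from, to) {
  if (as.numeric(ws$time[1L]) > as.numeric(from) + 1e-6 ||
      as.numeric(ws$time[length(ws$time)]) < as.numeric(to) - 1e-6) {
    stop(sprintf(
      "insufficient weather coverage: record spans [%s, %s], need [%s, %s]",
      format(ws$time[1L]), format(ws$time[length(ws$time)]),
      format(as_time(from)), format(as_time(to))
    ))
  }
  invisible(TRUE)
}
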