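# Unified response and gate functions, clock basis, environmental-response
# feature, scaling and design-matrix construction.

#' Environmental-response parameters
#'
#' Bundles the gene-specific parameters of the nonlinear environmental
#' response: the memory period over which stimuli are integrated, the
#' stimulus threshold, the shape parameter interpolating between
#' dose-dependent and dose-independent responses, the gate sharpness,
#' gate threshold and gate phase, the response sign, and the weather
#' attribute the gene responds to.
#'
#' @param period_p memory period in hours (> 0).
#' @param threshold_theta stimulus threshold, in the units of `factor`.
#' @param gamma_f response shape: large negative = dose-dependent (linear in
#'   the excess over threshold), large positive = dose-independent (step).
#' @param gamma_g gate sharpness: small = smooth cosine-like gate, large =
#'   rectangular gate.
#' @param theta_g gate threshold; below -1 the gate is effectively always
#'   open (no-gate model), above 1 always closed.
#' @param psi gate phase in hours, wrapped to `[0, 24)`; the gate is fully
#'   open at `psi`.
#' @param sign_rho +1 = responds to stimuli above the threshold, -1 = below.
#' @param factor weather attribute name (see [weather_attributes()]).
#' @return An object of class `response_params`.
#' @export
response_params <- function(period_p, threshold_theta, gamma_f, gamma_g,
                            theta_g, psi, sign_rho = 1,
                            factor = "temperature") {
  stopifnot(period_p > 0, sign_rho %in% c(-1, 1))
  structure(
    list(period_p = period_p, threshold_theta = threshold_theta,
         gamma_f = gamma_f, gamma_g = gamma_g, theta_g = theta_g,
         psi = psi %% 24, sign_rho = sign_rho, factor = factor),
    class = "response_params"
  )
}

#' @export
print.response_params <- function(x, ...) {
  cat(sprintf(
    paste0("<response_params> factor=%s sign=%+d p=%.3gh theta=%.4g ",
           "gamma_f=%.3g gamma_g=%.3g theta_g=%.3g psi=%.3gh\n"),
    x$factor, x$sign_rho, x$period_p, x$threshold_theta,
    x$gamma_f, x$gamma_g, x$theta_g, x$psi
  ))
  invisible(x)
}

#' Unified dose-dependent / dose-independent response function
#'
#' Computes `max(0, tanh(sign_rho * exp(gamma_f) * x)) * sqrt(exp(-2*gamma_f) + 1)`.
#' As `gamma_f -> -Inf` this approaches the dose-dependent response
#' `max(0, sign_rho * x)`; as `gamma_f -> +Inf` it approaches the
#' dose-independent 0/1 step at the threshold. The square-root normalizer
#' keeps the output scale nearly constant across `gamma_f`.
#'
#' @param x stimulus excess over the threshold (vectorized).
#' @param gamma_f shape parameter.
#' @param sign_rho +1 or -1.
#' @return Non-negative numeric vector, same length as `x`.
#' @export
response_fn <- function(x, gamma_f, sign_rho = 1) {
  stopifnot(sign_rho %in% c(-1, 1))
  # sqrt(exp(-2g)+1), computed without overflow for very negative g
  scale <- if (gamma_f < 0) {
    exp(-gamma_f) * sqrt(1 + exp(2 * gamma_f))
  } else {
    sqrt(exp(-2 * gamma_f) + 1)
  }
  pmax(0, tanh(sign_rho * exp(gamma_f) * x)) * scale
}

#' Unified 24-h periodic gate function
#'
#' With `h(C) = tanh(exp(gamma_g) * (C - theta_g))` and
#' `C = cos(2*pi*(T - psi)/24)`, returns `(h(C) - h(-1)) / (h(1) - h(-1))`,
#' a value in `[0, 1]` equal to 1 at `T = psi`. Small `gamma_g` with
#' `theta_g = 0` gives a smooth cosine-like gate; large `gamma_g` gives a
#' rectangular gate whose opening length is set by `theta_g`; `theta_g < -1`
#' with large `gamma_g` is the no-gate (always open) limit.
#'
#' The ratio is evaluated through log-domain sinh/cosh differences when
#' `exp(gamma_g)` is large, where the naive tanh form underflows; if the
#' denominator is still degenerate the analytic limit is returned (1 for
#' `theta_g < -1`, 0 for `theta_g > 1`).
#'
#' @param T time of day in hours (vectorized; any real, 24-h periodic).
#' @param psi gate phase in hours.
#' @param gamma_g gate sharpness.
#' @param theta_g gate threshold.
#' @return Numeric vector in `[0, 1]`.
#' @export
gate_fn <- function(T, psi, gamma_g, theta_g) {
  C <- cos(2 * pi * (T - psi) / 24)
  a <- exp(gamma_g)
  h1 <- tanh(a * (1 - theta_g))
  hm1 <- tanh(a * (-1 - theta_g))
  denom <- h1 - hm1
  if (is.finite(denom) && denom > 1e-8) {
    out <- (tanh(a * (C - theta_g)) - hm1) / denom
    # refine in log space where the direct form loses precision
    if (a > 20) {
      out <- gate_log_form(C, a, theta_g)
    }
  } else {
    out <- rep(if (theta_g < -1) 1 else 0, length(C))
  }
  pmin(1, pmax(0, out))
}

# Stable evaluation of (tanh(a(C-t)) - tanh(a(-1-t))) / (tanh(a(1-t)) - tanh(a(-1-t)))
# via tanh(x)-tanh(y) = sinh(x-y)/(cosh(x) cosh(y)):
# ratio = sinh(a(C+1)) cosh(a(1-t)) / (sinh(2a) cosh(a(C-t))).
gate_log_form <- function(C, a, theta_g) {
  logcosh <- function(x) abs(x) + log1p(exp(-2 * abs(x))) - log(2)
  logsinh <- function(x) x + log1p(-exp(-2 * x)) - log(2) # x > 0
  u <- a * (C + 1)
  out <- numeric(length(C))
  pos <- u > 0
  if (any(pos)) {
    lr <- logsinh(u[pos]) + logcosh(a * (1 - theta_g)) -
      logsinh(2 * a) - logcosh(a * (C[pos] - theta_g))
    out[pos] <- exp(lr)
  }
  out
}

#' Scale a vector to range 1 and mean 0
#'
#' Divides by the range and centers, returning the scaled vector together
#' with a `scale_spec` (offset, scale) that reapplies the identical affine
#' map to new data: `scaled = v / scale - offset`. A constant vector has
#' range zero; it is mapped to all zeros and flagged degenerate (the column
#' is then excluded from fitting by the penalty).
#'
#' @param v numeric vector, length >= 2.
#' @return List with `scaled` and `spec` (class `scale_spec`, fields
#'   `offset`, `scale`, `degenerate`).
#' @export
scale_unit_range <- function(v) {
  stopifnot(length(v) >= 2L)
  rng <- max(v) - min(v)
  if (rng < 1e-12) {
    spec <- structure(list(offset = 0, scale = 1, degenerate = TRUE),
                      class = "scale_spec")
    return(list(scaled = numeric(length(v)), spec = spec))
  }
  u <- v / rng
  off <- mean(u)
  spec <- structure(list(offset = off, scale = rng, degenerate = FALSE),
                    class = "scale_spec")
  list(scaled = u - off, spec = spec)
}

#' Reapply a stored scale to new data
#'
#' @param spec a `scale_spec` from [scale_unit_range()].
#' @param v numeric vector.
#' @return Scaled vector (`v / scale - offset`; zeros if degenerate).
#' @export
apply_scale <- function(spec, v) {
  stopifnot(inherits(spec, "scale_spec"))
  if (isTRUE(spec$degenerate)) return(numeric(length(v)))
  v / spec$scale - spec$offset
}

#' Circadian clock basis
#'
#' Returns the 24-h harmonic basis `cos(2*pi*t/24)`, `sin(2*pi*t/24)` with
#' `t` the hours since local midnight of each sample. A gene's clock phase
#' is recovered from the two regression coefficients afterwards.
#'
#' @param sample_times `POSIXct` (or parseable) sample timestamps.
#' @return N x 2 matrix with columns `clock_cos`, `clock_sin`.
#' @export
clock_basis <- function(sample_times) {
  t <- time_of_day(as_time(sample_times))
  ang <- 2 * pi * t / 24
  cbind(clock_cos = cos(ang), clock_sin = sin(ang))
}

#' Environmental-response feature
#'
#' For each sample time `t_j`, sums `gate(T) * response(w_T - theta)` over
#' all weather integration steps `T` in the closed window `[t_j - p, t_j]`,
#' where `p` is the memory period. The weather series should already be at
#' the desired integration step (see [resample_weather()]); the sum runs
#' over the steps whose timestamps fall in the window.
#'
#' @param ws a [weather_series()] at the integration cadence.
#' @param sample_times sample timestamps; the record must cover
#'   `[min(sample_times) - p, max(sample_times)]`.
#' @param rp a [response_params()].
#' @return Numeric vector of unscaled feature values, one per sample.
#' @export
env_response_feature <- function(ws, sample_times, rp) {
  stopifnot(inherits(ws, "weather_series"), inherits(rp, "response_params"))
  sample_times <- as_time(sample_times)
  if (!rp$factor %in% names(ws$values)) {
    stop("weather series has no attribute '", rp$factor, "'")
  }
  check_weather_coverage(ws, min(sample_times) - rp$period_p * 3600,
                         max(sample_times))
  w <- ws$values[[rp$factor]]
  g <- gate_on_grid(ws, rp$psi, rp$gamma_g, rp$theta_g)
  f <- response_fn(w - rp$threshold_theta, rp$gamma_f, rp$sign_rho)
  windowed_sums(g * f, as.numeric(ws$time), as.numeric(sample_times),
                rp$period_p * 3600)
}

# Gate values along a weather grid. The gate is a function of time of day
# only, so when the cadence divides a day evenly it is evaluated on the
# distinct within-day grid points and indexed, not on every timestamp.
gate_on_grid <- function(ws, psi, gamma_g, theta_g) {
  step <- ws$cadence
  if (86400 %% step == 0 && round(as.numeric(ws$time[1L])) %% step == 0) {
    k <- 86400 / step
    idx <- (round(as.numeric(ws$time)) %/% step) %% k + 1L
    tod_u <- (seq_len(k) - 1L) * step / 3600
    gate_fn(tod_u, psi, gamma_g, theta_g)[idx]
  } else {
    gate_fn(time_of_day(ws$time), psi, gamma_g, theta_g)
  }
}

# Sum of v over weather steps with timestamp in [t - p_sec, t], per sample,
# via a cumulative sum (half-open interval arithmetic with closed ends).
windowed_sums <- function(v, wt, st, p_sec) {
  cs <- c(0, cumsum(v))
  eps <- 1e-6
  hi <- findInterval(st + eps, wt)          # last step <= t
  lo <- findInterval(st - p_sec - eps, wt)  # last step < t - p
  if (any(hi == 0)) stop("insufficient weather coverage")
  cs[hi + 1L] - cs[lo + 1L]
}

design_roles <- function() {
  c("intercept", "age", "clock_cos", "clock_sin", "response",
    "age_clock_cos", "age_clock_sin", "age_response", "genotype")
}

# Penalty group structure over the design columns (intercept unpenalized).
design_groups <- function() {
  list(age = 2L, clock = c(3L, 4L), response = 5L,
       age_clock = c(6L, 7L), age_response = 8L, genotype = 9L)
}

#' Build the per-gene design matrix
#'
#' Assembles the N x 9 covariate matrix: intercept, scaled age, clock
#' cos/sin, scaled environmental response, age x clock interactions, age x
#' response interaction, and binary genotype. Age and response are scaled to
#' mean 0 / range 1 ([scale_unit_range()]); the interaction columns are
#' element-wise products of the scaled parents and are not themselves
#' rescaled, so predictions on new samples reuse the stored scale specs.
#'
#' @param sample_times sample timestamps (length N).
#' @param ages days after transplanting (length N).
#' @param genotypes 0/1 vector (length N).
#' @param ws a [weather_series()] at the integration cadence.
#' @param rp a [response_params()], or `NULL` for a design without an
#'   environmental term (response columns zero and flagged degenerate).
#' @param scale_specs optional list with `age` and `response` scale specs
#'   from a training design, applied instead of refitting the scaling (used
#'   for prediction on new samples).
#' @return Object of class `design_matrix`: list with `values` (N x 9
#'   matrix, columns named by role), `scale_specs`, `sample_times`.
#' @export
build_design_matrix <- function(sample_times, ages, genotypes, ws, rp,
                                scale_specs = NULL) {
  sample_times <- as_time(sample_times)
  n <- length(sample_times)
  if (length(ages) != n || length(genotypes) != n) {
    stop("sample_times, ages and genotypes must have the same length")
  }
  if (!all(genotypes %in% c(0, 1))) stop("genotype values must be 0 or 1")
  r_raw <- if (is.null(rp)) numeric(n) else env_response_feature(ws, sample_times, rp)
  if (is.null(scale_specs)) {
    ds <- scale_unit_range(ages)
    rs <- scale_unit_range(r_raw)
    scale_specs <- list(age = ds$spec, response = rs$spec)
    d <- ds$scaled; r <- rs$scaled
  } else {
    d <- apply_scale(scale_specs$age, ages)
    r <- apply_scale(scale_specs$response, r_raw)
  }
  cb <- clock_basis(sample_times)
  X <- cbind(
    intercept = rep(1, n), age = d,
    clock_cos = cb[, 1L], clock_sin = cb[, 2L],
    response = r,
    age_clock_cos = d * cb[, 1L], age_clock_sin = d * cb[, 2L],
    age_response = d * r,
    genotype = as.numeric(genotypes)
  )
  structure(
    list(values = X, scale_specs = scale_specs, sample_times = sample_times),
    class = "design_matrix"
  )
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("<design_matrix> %d x %d (%s)\n", nrow(x$values), ncol(x$values),
              paste(colnames(x$values), collapse = ", ")))
  invisible(x)
}
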