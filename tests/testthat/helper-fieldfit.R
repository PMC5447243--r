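# Shared fixtures and independent oracles, all built in code.

# Small deterministic weather series: `hours` of data at `step` seconds,
# temperature as a diurnal sinusoid around 25 C plus a fixed ramp.
tiny_weather <- function(hours = 24 * 5, step = 600,
                         start = "2008-06-01 00:00:00") {
  t0 <- as.POSIXct(start, tz = "UTC")
  time <- t0 + seq(0, hours * 3600 - step, by = step)
  tod <- (as.numeric(time) %% 86400) / 3600
  ramp <- seq(0, 3, length.out = length(time))
  weather_series(time, data.frame(
    temperature = 25 + 5 * cos(2 * pi * (tod - 15) / 24) + ramp,
    wind = 2 + 0.5 * sin(2 * pi * tod / 24)
  ))
}

# Sample table with n samples every `every` hours starting after `offset_h`
# hours, ages in days, all one genotype.
tiny_samples <- function(n = 24, every = 4, offset_h = 48,
                         start = "2008-06-01 00:00:00", genotype = 0) {
  t0 <- as.POSIXct(start, tz = "UTC")
  time <- t0 + offset_h * 3600 + seq(0, by = every * 3600, length.out = n)
  data.frame(
    sample_id = sprintf("s%03d", seq_len(n)),
    time = time,
    age = 11 + as.numeric(time - t0, units = "days"),
    genotype = genotype
  )
}

# Brute-force double-loop oracle for the environmental-response feature.
brute_feature <- function(ws, sample_times, rp) {
  st <- as.numeric(sample_times)
  wt <- as.numeric(ws$time)
  w <- ws$values[[rp$factor]]
  sapply(st, function(t) {
    tot <- 0
    for (m in seq_along(wt)) {
      if (wt[m] >= t - rp$period_p * 3600 - 1e-6 && wt[m] <= t + 1e-6) {
        T_h <- (wt[m] %% 86400) / 3600
        tot <- tot + gate_fn(T_h, rp$psi, rp$gamma_g, rp$theta_g) *
          response_fn(w[m] - rp$threshold_theta, rp$gamma_f, rp$sign_rho)
      }
    }
    tot
  })
}

# Independent slow solver for the adaptive group lasso: proximal gradient
# (ISTA) on the full coefficient vector with a global step size, run to a
# tight fixed point.
prox_gradient_oracle <- function(X, y, w, zeta, lambda, iters = 200000L) {
  X <- if (inherits(X, "design_matrix")) X$values else X
  groups <- list(age = 2L, clock = c(3L, 4L), response = 5L,
                 age_clock = c(6L, 7L), age_response = 8L, genotype = 9L)
  keep <- apply(X, 2, function(v) max(v) - min(v)) >= 1e-12
  keep[1] <- TRUE
  A <- 2 * crossprod(X, w * X)
  b <- 2 * crossprod(X, w * y)[, 1]
  L <- max(eigen(A, symmetric = TRUE, only.values = TRUE)$values)
  beta <- numeric(ncol(X))
  for (it in seq_len(iters)) {
    grad <- A %*% beta - b
    z <- beta - grad / L
    z[!keep] <- 0
    newb <- z
    for (g in names(groups)) {
      idx <- groups[[g]]
      if (!all(keep[idx]) || !is.finite(zeta[[g]])) {
        newb[idx] <- 0
        next
      }
      nrm <- sqrt(sum(z[idx]^2))
      newb[idx] <- if (nrm > 0) z[idx] * max(0, 1 - lambda * zeta[[g]] / (L * nrm)) else 0
    }
    if (max(abs(newb - beta)) < 1e-12) {
      beta <- newb
      break
    }
    beta <- newb
  }
  stats::setNames(as.numeric(beta), colnames(X))
}

# Penalized objective value.
gl_objective <- function(X, y, w, zeta, lambda, beta) {
  X <- if (inherits(X, "design_matrix")) X$values else X
  groups <- list(age = 2L, clock = c(3L, 4L), response = 5L,
                 age_clock = c(6L, 7L), age_response = 8L, genotype = 9L)
  pen <- 0
  for (g in names(groups)) {
    nrm <- sqrt(sum(beta[groups[[g]]]^2))
    if (nrm > 0) pen <- pen + zeta[[g]] * nrm
  }
  sum(w * (y - X %*% beta)^2) + lambda * pen
}

# Brute-force leave-one-out CV by refitting.
brute_loocv <- function(X, y, w = NULL) {
  X <- if (inherits(X, "design_matrix")) X$values else X
  n <- nrow(X)
  if (is.null(w)) w <- rep(1, n)
  vals <- sapply(seq_len(n), function(j) {
    bj <- stats::lm.wfit(X[-j, , drop = FALSE], y[-j], w[-j])$coefficients
    w[j] * (y[j] - sum(X[j, ] * bj))^2
  })
  list(cv_error = mean(vals), cv_se = stats::sd(vals) / sqrt(n))
}

# A small fast grid for tests that exercise the full pipeline.
test_grid <- function() {
  grid_spec(period_p = c(3, 12, 24),
            theta_quantiles = c(0.25, 0.5, 0.75),
            gamma_f = c(-4, 4), gamma_g = c(0, 6),
            theta_g = c(-1.5, 0.3), psi = c(0, 8, 16))
}
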