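# Unified response and gate functions, scaling, clock basis, response
# feature and design construction.

test_that("response_fn matches direct evaluation and its analytic limits", {
  expect_equal(response_fn(0, 0, 1), 0)
  expect_equal(response_fn(1, 0, 1), tanh(1) * sqrt(2), tolerance = 1e-12)
  expect_equal(response_fn(0.5, -8, 1), 0.5, tolerance = 1e-4) # dose-dependent limit
  expect_equal(response_fn(0.5, 8, 1), 1, tolerance = 1e-4)    # dose-independent limit
  # dd limit: sup over [-2, 2] within 1e-3 of max(0, x) for gamma_f <= -6
  x <- seq(-2, 2, by = 0.01)
  for (gf in c(-6, -8, -10)) {
    expect_lt(max(abs(response_fn(x, gf, 1) - pmax(0, x))), 1e-3)
  }
  # di limit: 0/1 step outside |x| < 1e-2 for gamma_f >= 6
  xo <- x[abs(x) >= 1e-2]
  for (gf in c(6, 8, 10)) {
    expect_lt(max(abs(response_fn(xo, gf, 1) - as.numeric(xo > 0))), 1e-3)
  }
  # below-threshold sign mirrors the argument
  expect_equal(response_fn(-0.5, -8, -1), 0.5, tolerance = 1e-4)
  expect_equal(response_fn(0.5, -8, -1), 0)
})

test_that("gate_fn is 1 at the phase, bounded, periodic, and attains its limits", {
  expect_equal(gate_fn(12, 12, 3, 0.2), 1)
  expect_equal(gate_fn(5.5, 5.5, -2, 0.9), 1)
  tt <- seq(0, 24, by = 0.1)
  # no-gate limit
  expect_true(all(gate_fn(tt, 0, 10, -2) >= 0.999))
  # 12-h rectangular gate: open exactly where cos(2 pi (T - psi)/24) > 0
  g <- gate_fn(tt, 12, 10, 0)
  expect_true(all(g[tt > 6 + 1e-6 & tt < 18 - 1e-6] > 0.5))
  expect_true(all(g[tt < 6 - 1e-6 | tt > 18 + 1e-6] < 0.5))
  # cosine-like regime matches the (cos+1)/2 shape in rank order
  gc <- gate_fn(tt, 9, 0, 0)
  ref <- (cos(2 * pi * (tt - 9) / 24) + 1) / 2
  expect_gt(stats::cor(gc, ref, method = "spearman"), 0.99)
  # always within [0, 1] across a spread of parameters
  set.seed(5)
  for (k in 1:25) {
    g <- gate_fn(tt, runif(1, 0, 24), runif(1, -10, 10), runif(1, -3, 3))
    expect_true(all(g >= 0 & g <= 1))
  }
  expect_equal(gate_fn(tt, 7, 2, 0.3), gate_fn(tt + 24, 7, 2, 0.3))
})

test_that("scale_unit_range yields range 1 / mean 0 and a reusable spec", {
  s <- scale_unit_range(c(0, 1, 2))
  expect_equal(s$scaled, c(-0.5, 0, 0.5))
  expect_equal(apply_scale(s$spec, 4), 1.5)
  d <- scale_unit_range(c(5, 5, 5))
  expect_true(d$spec$degenerate)
  expect_equal(d$scaled, c(0, 0, 0))
  set.seed(11)
  for (k in 1:20) {
    v <- rnorm(sample(5:50, 1)) * 10^sample(-3:3, 1)
    s <- scale_unit_range(v)
    expect_equal(max(s$scaled) - min(s$scaled), 1, tolerance = 1e-12)
    expect_equal(mean(s$scaled), 0, tolerance = 1e-12)
    expect_equal(apply_scale(s$spec, v), s$scaled, tolerance = 1e-12)
  }
})

test_that("clock_basis is the 24-h harmonic pair on hours since midnight", {
  t0 <- as.POSIXct("2008-06-01 00:00:00", tz = "UTC")
  cb <- clock_basis(c(t0, t0 + 6 * 3600, t0 + 24 * 3600))
  expect_equal(cb[1, ], c(clock_cos = 1, clock_sin = 0), tolerance = 1e-12)
  expect_equal(cb[2, ], c(clock_cos = 0, clock_sin = 1), tolerance = 1e-12)
  expect_equal(cb[3, ], cb[1, ], tolerance = 1e-12)
})

test_that("env_response_feature equals the brute-force double loop", {
  ws <- tiny_weather(hours = 96, step = 3600)
  samples <- tiny_samples(n = 8, every = 6, offset_h = 50)
  set.seed(7)
  for (k in 1:8) {
    rp <- response_params(
      period_p = sample(c(1, 4, 13), 1), threshold_theta = runif(1, 22, 30),
      gamma_f = runif(1, -6, 6), gamma_g = runif(1, -2, 6),
      theta_g = runif(1, -2, 1), psi = runif(1, 0, 24),
      sign_rho = sample(c(-1, 1), 1), factor = "temperature")
    expect_equal(env_response_feature(ws, samples$time, rp),
                 brute_feature(ws, samples$time, rp), tolerance = 1e-10)
  }
})

test_that("env_response_feature edge cases: zero response, single-step memory, coverage", {
  ws <- tiny_weather(hours = 96, step = 3600)
  samples <- tiny_samples(n = 6, every = 6, offset_h = 50)
  high <- response_params(6, 1e4, 0, 0, -2, 0, 1, "temperature")
  expect_equal(env_response_feature(ws, samples$time, high), rep(0, 6))
  # memory shorter than one integration step: single-term sum at the
  # sample time (the window [t - p, t] is closed, so p equal to a whole
  # step would also pick up the preceding grid point)
  one <- response_params(0.5, 24, 0, 2, 0.2, 10, 1, "temperature")
  idx <- match(as.numeric(samples$time), as.numeric(ws$time))
  expected <- gate_fn((as.numeric(ws$time[idx]) %% 86400) / 3600, 10, 2, 0.2) *
    response_fn(ws$values$temperature[idx] - 24, 0, 1)
  expect_equal(env_response_feature(ws, samples$time, one), expected,
               tolerance = 1e-12)
  far <- response_params(400, 24, 0, 0, -2, 0, 1, "temperature")
  expect_error(env_response_feature(ws, samples$time, far),
               "insufficient weather coverage")
})

test_that("build_design_matrix assembles scaled columns and interactions", {
  ws <- tiny_weather(hours = 96, step = 3600)
  samples <- tiny_samples(n = 12, every = 4, offset_h = 48)
  rp <- response_params(6, 26, -2, 1, 0, 12, 1, "temperature")
  dm <- build_design_matrix(samples$time, samples$age, samples$genotype, ws, rp)
  X <- dm$values
  expect_equal(dim(X), c(12L, 9L))
  expect_true(all(X[, "intercept"] == 1))
  expect_true(all(X[, "genotype"] == 0))
  expect_equal(max(X[, "age"]) - min(X[, "age"]), 1, tolerance = 1e-12)
  expect_equal(mean(X[, "response"]), 0, tolerance = 1e-12)
  expect_equal(X[, "age_response"], X[, "age"] * X[, "response"])
  expect_equal(X[, "age_clock_cos"], X[, "age"] * X[, "clock_cos"])
  expect_error(build_design_matrix(samples$time, samples$age[-1],
                                   samples$genotype, ws, rp), "same length")
  expect_error(build_design_matrix(samples$time, samples$age,
                                   rep(2, 12), ws, rp), "0 or 1")
  # stored scale specs reapply identically on new data
  dm2 <- build_design_matrix(samples$time, samples$age, samples$genotype, ws,
                             rp, scale_specs = dm$scale_specs)
  expect_equal(dm2$values, dm$values, tolerance = 1e-12)
})
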