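# Prediction, fit metrics, phases, response curves and recovery summaries.

test_that("r_squared matches hand arithmetic and its shift identity", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(r_squared(c(1, 2, 3), rep(2, 3)), 0)
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 4)), 0.5)
  expect_error(r_squared(c(2, 2, 2), c(1, 2, 3)), "constant")
  set.seed(1)
  obs <- rnorm(20); cshift <- 0.7
  expect_equal(r_squared(obs, obs + cshift),
               1 - 20 * cshift^2 / sum((obs - mean(obs))^2))
})

test_that("phase_of maps clock coefficients to hours", {
  mk <- function(bc, bs) {
    stats::setNames(c(0, 0, bc, bs, 0, 0, 0, 0, 0), fieldfit:::design_roles())
  }
  expect_equal(phase_of(mk(1, 0)), 0)
  expect_equal(phase_of(mk(0, 1)), 6)
  expect_equal(phase_of(mk(-1, 0)), 12)
  expect_equal(phase_of(mk(0, -1)), 18)
  expect_error(phase_of(mk(0, 0)), "both zero")
})

test_that("phase recovery from noiseless harmonic fits is exact to 0.05 h", {
  n <- 180
  t0 <- as.POSIXct("2008-06-12", tz = "UTC")
  time <- t0 + seq(0, by = 4 * 3600, length.out = n)
  tod <- (as.numeric(time) %% 86400) / 3600
  X <- cbind(intercept = rep(1, n), age = scale_unit_range(seq_len(n))$scaled,
             clock_cos = cos(2 * pi * tod / 24), clock_sin = sin(2 * pi * tod / 24),
             response = 0, age_clock_cos = 0, age_clock_sin = 0,
             age_response = 0, genotype = 0)
  for (phi0 in seq(0, 21, by = 3)) {
    y <- 5 + 2 * cos(2 * pi * (tod - phi0) / 24)
    beta <- suppressWarnings(wls_fit(X, y))
    err <- abs(phase_of(beta) - phi0)
    expect_lt(min(err, 24 - err), 0.05)
  }
})

test_that("response_curve reconstructs the fitted response shape", {
  m <- structure(list(
    gene_id = "g", factor = "temperature",
    response_params = response_params(6, 25, 0, 0, -2, 0, 1, "temperature"),
    coefficients = stats::setNames(c(5, 0, 0, 0, 1, 0, 0, 0, 0),
                                   fieldfit:::design_roles())),
    class = "fieldfit_gene")
  expect_equal(response_curve(m, 26), tanh(1) * sqrt(2), tolerance = 1e-12)
  expect_true(all(response_curve(m, seq(15, 25, by = 0.5)) == 0))
  m$coefficients["response"] <- 0
  expect_true(all(response_curve(m, seq(15, 35)) == 0))
  m$response_params <- NULL
  expect_error(response_curve(m, 20), "no response term")
})

test_that("predictions reproduce fitted values on training samples and respect periodicity", {
  ws <- synth_weather("2008-06-01", "2008-09-19", step = 600, seed = 40)
  samples <- sampling_design("4h", 2008)
  tod <- (as.numeric(samples$time) %% 86400) / 3600
  set.seed(41)
  y <- 5 + 1.5 * cos(2 * pi * (tod - 14) / 24) + rnorm(180, 0, 0.2)
  m <- suppressWarnings(fit_gene(y, NULL, samples, ws,
                                 fit_options(factors = "temperature",
                                             grid = test_grid())))
  expect_equal(predict(m, samples, ws), fitted(m), tolerance = 1e-8)
  expect_equal(residuals(m), y - fitted(m))
  # clock-only model: same prediction one day apart at equal age
  two <- data.frame(sample_id = c("a", "b"),
                    time = samples$time[1] + c(0, 24 * 3600),
                    age = c(20, 20), genotype = c(0, 0))
  if (is.null(m$response_params)) {
    p <- predict(m, two)
    expect_equal(p[1], p[2], tolerance = 1e-12)
  }
  # constant model predicts its intercept everywhere
  mc <- suppressWarnings(fit_gene(rep(3.3, 180) + rnorm(180, 0, 1e-6),
                                  NULL, samples, ws,
                                  fit_options(factors = "temperature",
                                              grid = test_grid())))
  if (mc$constant) {
    expect_equal(unname(predict(mc, two)), rep(coef(mc)[["intercept"]], 2))
  }
})

test_that("recovery_summary scores structure matches, factors and circular phases", {
  mk_model <- function(id, beta, factor = "none", rp = NULL) {
    structure(list(gene_id = id, response_params = rp, factor = factor,
                   coefficients = stats::setNames(beta, fieldfit:::design_roles())),
              class = "fieldfit_gene")
  }
  tl <- structure(list(
    list(gene_id = "a", structure = "clock", clock = list(amp = 2, phase = 23),
         response = NULL, alpha = 5, dispersion = 0.1),
    list(gene_id = "b", structure = character(0), clock = NULL,
         response = NULL, alpha = 5, dispersion = 0.1)
  ), class = "truth_library")
  ph1 <- 2 * pi * 1 / 24 # fitted phase 1 h
  models <- list(
    mk_model("a", c(5, 0, cos(ph1), sin(ph1), 0, 0, 0, 0, 0)),
    mk_model("b", c(5, 0, 0.4, 0.2, 0, 0, 0, 0, 0))
  )
  rs <- recovery_summary(models, tl)
  expect_equal(rs$n_variable_matched, 1L)
  expect_equal(rs$n_constant_correct, 0L) # constant truth fitted with a clock
  expect_equal(rs$phase_errors, 2) # 23 h vs 1 h wraps to 2 h
  expect_equal(sum(rs$confusion), 2)
  expect_equal(unname(rs$confusion["none", "none"]), 2)
  # perfect agreement scores 100% with zero phase error
  ph23 <- 2 * pi * 23 / 24
  rs2 <- recovery_summary(list(
    mk_model("a", c(5, 0, cos(ph23), sin(ph23), 0, 0, 0, 0, 0)),
    mk_model("b", c(5, 0, 0, 0, 0, 0, 0, 0, 0))), tl)
  expect_equal(rs2$n_variable_matched, 1L)
  expect_equal(rs2$n_constant_correct, 1L)
  expect_equal(rs2$phase_errors, 0, tolerance = 1e-9)
  expect_error(recovery_summary(models[1], tl), "not all present")
})
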