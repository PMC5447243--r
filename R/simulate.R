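# Synthetic benchmark: field sampling designs, schedule fixtures, a truth
# library of generative gene models, and negative-binomial read counts.

design_table <- function() {
  data.frame(
    design_id = c("2h", "4h", "6h", "8h", "12h"),
    interval_hours = c(2, 4, 6, 8, 12),
    replicates_per_time = c(1, 2, 3, 4, 6),
    stringsAsFactors = FALSE
  )
}

#' Field sampling design schedules
#'
#' Generates the weekly 24-h sampling schedules: 15 weekly dates from
#' June 12 to September 18, each covering 24 h of slots at the design's
#' interval with its replicate count (2-h x 1, 4-h x 2, 6-h x 3, 8-h x 4 or
#' 12-h x 6 -- every design yields 12 sample slots per date, 180 samples in
#' total). Ages are days after a June 1 transplanting. The 2009 evaluation
#' schedule is the 2-h single-replicate design with `year = 2009`.
#'
#' @param design_id one of `"2h"`, `"4h"`, `"6h"`, `"8h"`, `"12h"`.
#' @param year 2008 (training) or 2009 (evaluation).
#' @return Sample table: data frame with `sample_id`, `time`, `age`,
#'   `genotype` (all 0: a single cultivar) and `replicate`.
#' @export
sampling_design <- function(design_id = "4h", year = 2008) {
  dt <- design_table()
  row <- dt[dt$design_id == design_id, ]
  if (nrow(row) == 0L) stop("unknown design_id '", design_id, "'")
  interval <- row$interval_hours
  reps <- row$replicates_per_time
  dates <- seq(as.Date(sprintf("%d-06-12", year)),
               as.Date(sprintf("%d-09-18", year)), by = "7 days")
  hours <- seq(0, 24 - interval, by = interval)
  transplant <- as.Date(sprintf("%d-06-01", year))
  recs <- expand.grid(replicate = seq_len(reps), hour = hours, date = dates,
                      KEEP.OUT.ATTRS = FALSE)
  time <- as_time(paste0(format(recs$date), " 00:00:00")) + recs$hour * 3600
  data.frame(
    sample_id = sprintf("%s_%d_%s", design_id, year,
                        formatC(seq_len(nrow(recs)), width = 3, flag = "0")),
    time = time,
    age = as.numeric(recs$date - transplant),
    genotype = 0,
    replicate = recs$replicate,
    stringsAsFactors = FALSE
  )
}

fixture_block <- function(start, interval_min, n_times, reps, group) {
  t0 <- as_time(start)
  times <- t0 + rep(seq(0, by = interval_min * 60, length.out = n_times),
                    each = reps)
  data.frame(time = times, replicate = rep(seq_len(reps), times = n_times),
             group = group, stringsAsFactors = FALSE)
}

finish_fixture <- function(blocks, year, prefix) {
  df <- do.call(rbind, blocks)
  transplant <- as.Date(sprintf("%d-06-01", year))
  df$age <- as.numeric(as.Date(df$time) - transplant)
  df$genotype <- 0
  df$sample_id <- sprintf("%s_%s", prefix,
                          formatC(seq_len(nrow(df)), width = 3, flag = "0"))
  df[c("sample_id", "time", "age", "genotype", "replicate", "group")]
}

#' Sampling-schedule fixture for the 2008 field season
#'
#' The six sample groups of the 2008 rice field season (461 samples in
#' total): a 24-h course at 2-h intervals with 8 replicates (104); nine
#' 48-h courses at 2-h intervals (225); weekly noon samples in triplicate
#' (51); weekly midnight samples in duplicate (34); a 10-min evening course
#' (19); and a 10-min pre-dawn course in duplicate (28).
#'
#' @return Sample table with a `group` column.
#' @export
schedule_fixture_2008 <- function() {
  blocks <- list(
    fixture_block("2008-08-12 07:00:00", 120, 13L, 8L, "24h_course"),
    do.call(rbind, lapply(
      c("2008-06-05", "2008-06-19", "2008-07-03", "2008-07-17", "2008-08-07",
        "2008-08-14", "2008-08-21", "2008-08-28", "2008-09-11"),
      function(d) fixture_block(paste(d, "10:00:00"), 120, 25L, 1L, "48h_course")
    )),
    do.call(rbind, lapply(
      format(seq(as.Date("2008-06-03"), by = "7 days", length.out = 17L)),
      function(d) fixture_block(paste(d, "12:00:00"), 0, 1L, 3L, "weekly_noon")
    )),
    do.call(rbind, lapply(
      format(seq(as.Date("2008-06-04"), by = "7 days", length.out = 17L)),
      function(d) fixture_block(paste(d, "00:00:00"), 0, 1L, 2L, "weekly_midnight")
    )),
    fixture_block("2008-08-07 17:00:00", 10, 19L, 1L, "evening_10min"),
    fixture_block("2008-08-08 03:50:00", 10, 14L, 2L, "predawn_10min")
  )
  finish_fixture(blocks, 2008, "s2008")
}

#' Sampling-schedule fixture for the 2009 evaluation season
#'
#' The six 2009 sample groups (108 samples): a 48-h course at 6-h intervals
#' in duplicate (18); a 24-h course at 2-h intervals with 6 replicates
#' (78); and four small spot collections (2 + 2 + 4 + 4).
#'
#' @return Sample table with a `group` column.
#' @export
schedule_fixture_2009 <- function() {
  blocks <- list(
    fixture_block("2009-08-10 12:00:00", 360, 9L, 2L, "48h_course"),
    fixture_block("2009-08-24 07:00:00", 120, 13L, 6L, "24h_course"),
    fixture_block("2009-08-31 12:00:00", 0, 1L, 2L, "spot_noon"),
    fixture_block("2009-08-31 18:00:00", 0, 1L, 2L, "spot_evening"),
    fixture_block("2009-10-08 11:00:00", 0, 1L, 4L, "spot_oct8"),
    fixture_block("2009-10-09 11:00:00", 0, 1L, 4L, "spot_oct9")
  )
  finish_fixture(blocks, 2009, "s2009")
}

#' Mean-dispersion trend
#'
#' Parametric stand-in for an empirically estimated RNA-Seq mean-dispersion
#' trend: `phi(mu) = phi0 + a / mu`, monotone non-increasing in the mean,
#' with defaults typical of published human RNA-Seq trends. Injectable
#' wherever dispersions are derived, so an empirical trend can be
#' substituted.
#'
#' @param mean_expression positive mean expression (count scale).
#' @param phi0 asymptotic dispersion (default 0.05).
#' @param a inverse-mean coefficient (default 3).
#' @return Dispersion value(s), > 0.
#' @export
dispersion_trend <- function(mean_expression, phi0 = 0.05, a = 3) {
  if (any(mean_expression <= 0)) stop("mean expression must be positive")
  phi0 + a / mean_expression
}

truth_entry <- function(gene_id, structure, clock = NULL, age = NULL,
                        response = NULL, age_clock = NULL,
                        age_response = NULL, alpha, dispersion) {
  list(gene_id = gene_id, structure = structure, clock = clock, age = age,
       response = response, age_clock = age_clock,
       age_response = age_response, alpha = alpha, dispersion = dispersion)
}

# Gate presets spanning the gate regimes: always open, smooth cosine-like,
# rectangular afternoon window.
gate_none <- list(gamma_g = 6, theta_g = -2, psi = 0)
gate_cos <- list(gamma_g = 0, theta_g = 0, psi = 14)
gate_rect <- list(gamma_g = 6, theta_g = 0.3, psi = 14)

# Below-threshold (cool-responsive) genes are gated around dawn, when low
# temperatures actually occur; above-threshold genes around mid-afternoon.
# Dose-independent thresholds sit in the tails of the temperature
# distribution so that crossings differ from day to day, and gated entries
# integrate over at least half a day: both choices keep the generative
# signature identifiable against the circadian clock at the benchmark's
# sample size (a near-always-on gated step is indistinguishable from the
# clock curve itself).
truth_response <- function(kind, sign, gate, p) {
  psi <- gate$psi
  if (sign < 0 && psi != 0) psi <- 4
  response_params(
    period_p = p,
    threshold_theta = if (kind == "dd") {
      if (sign > 0) 27 else 25
    } else {
      if (sign > 0) 30 else 24
    },
    gamma_f = if (kind == "dd") -4 else 4,
    gamma_g = gate$gamma_g, theta_g = gate$theta_g, psi = psi,
    sign_rho = sign, factor = "temperature"
  )
}

#' Generative truth library for the synthetic benchmark
#'
#' Builds the 31 variably expressed generative gene models spanning the
#' model space -- circadian clocks at assorted phases, temperature
#' responses (dose-dependent and dose-independent, above- and
#' below-threshold, with no / cosine / rectangular gates and memory
#' periods from 3 h to 24 h), age trends, and clock x age / response x age
#' interactions -- plus `constant_genes` constantly expressed genes. Log2
#' effect sizes are 1.5-2; each gene's log (natural) average expression is
#' drawn from Normal(5, 1) (mean counts around 150) and its dispersion
#' from [dispersion_trend()] at that mean.
#'
#' Each entry records `structure`: the set of design groups expected
#' non-zero when the model is expressed in the fitted sin/cos basis (a
#' truth clock term `(cos + 1)/2` contributes only the clock group, its
#' constant half being absorbed by the intercept, while a truth
#' age x clock product also excites the age main effect).
#'
#' @param seed integer seed (for the `alpha` draws).
#' @param constant_genes number of constant genes to append (default 0).
#' @param trend dispersion trend function (default [dispersion_trend()]).
#' @return List of truth entries; class `truth_library`.
#' @export
truth_library <- function(seed = 1L, constant_genes = 0L,
                          trend = dispersion_trend) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  entries <- list()
  add <- function(structure, ...) {
    id <- sprintf("var%02d", length(entries) + 1L)
    alpha <- stats::rnorm(1L, 5, 1)
    entries[[length(entries) + 1L]] <<- truth_entry(
      id, structure, ..., alpha = alpha, dispersion = trend(exp(alpha)))
  }
  for (ph in c(0, 4, 8, 12, 16, 20)) {
    add("clock", clock = list(amp = 2, phase = ph))
  }
  add("age", age = list(amp = 2))
  add("age", age = list(amp = -2))
  resp_space <- list(
    list("dd", 1, gate_none, 6), list("dd", 1, gate_cos, 24),
    list("dd", 1, gate_rect, 48), list("dd", -1, gate_none, 3),
    list("dd", -1, gate_cos, 24), list("dd", -1, gate_rect, 12),
    list("di", 1, gate_none, 12), list("di", 1, gate_cos, 24),
    list("di", 1, gate_rect, 24), list("di", -1, gate_none, 6),
    list("di", -1, gate_cos, 48), list("di", -1, gate_rect, 24)
  )
  for (rs in resp_space) {
    add("response",
        response = list(amp = 2, rp = do.call(truth_response, rs)))
  }
  add(c("clock", "age"), clock = list(amp = 1.5, phase = 6),
      age = list(amp = 1.5))
  add(c("clock", "age"), clock = list(amp = 1.5, phase = 18),
      age = list(amp = -1.5))
  # a truth age x clock product (d * (cos+1)/2) excites age and age_clock
  add(c("clock", "age", "age_clock"), clock = list(amp = 1.5, phase = 8),
      age_clock = list(amp = 1.5))
  add(c("clock", "age", "age_clock"), clock = list(amp = 1.5, phase = 20),
      age_clock = list(amp = 1.5))
  add(c("response", "age_response"),
      response = list(amp = 2, rp = truth_response("dd", 1, gate_none, 6)),
      age_response = list(amp = 1.5))
  add(c("response", "age_response"),
      response = list(amp = 2, rp = truth_response("di", -1, gate_cos, 48)),
      age_response = list(amp = 1.5))
  add(c("clock", "response"), clock = list(amp = 1.5, phase = 4),
      response = list(amp = 2, rp = truth_response("dd", 1, gate_none, 3)))
  add(c("clock", "response"), clock = list(amp = 1.5, phase = 16),
      response = list(amp = 2, rp = truth_response("di", 1, gate_rect, 24)))
  add(c("clock", "age", "response"), clock = list(amp = 1.5, phase = 10),
      age = list(amp = 1.5),
      response = list(amp = 2, rp = truth_response("dd", 1, gate_cos, 24)))
  add(c("clock", "age", "age_clock"), clock = list(amp = 2, phase = 22),
      age_clock = list(amp = 1.5))
  add(c("clock", "response", "age_response"),
      clock = list(amp = 1.5, phase = 2),
      response = list(amp = 2, rp = truth_response("dd", 1, gate_none, 6)),
      age_response = list(amp = 1.5))
  stopifnot(length(entries) == 31L)
  if (constant_genes > 0L) {
    for (k in seq_len(constant_genes)) {
      alpha <- stats::rnorm(1L, 5, 1)
      entries[[length(entries) + 1L]] <- truth_entry(
        sprintf("const%04d", k), character(0), alpha = alpha,
        dispersion = trend(exp(alpha)))
    }
  }
  structure(entries, class = "truth_library")
}

#' @export
print.truth_library <- function(x, ...) {
  nvar <- sum(vapply(x, function(e) length(e$structure) > 0, logical(1L)))
  cat(sprintf("<truth_library> %d genes (%d variable, %d constant)\n",
              length(x), nvar, length(x) - nvar))
  invisible(x)
}

#' True log2 mean expression under a truth library
#'
#' Evaluates each generative model's log2 mean at the schedule's samples:
#' `log2(exp(alpha))` plus the clock term
#' (`amp * (cos(2*pi*(t - phase)/24) + 1)/2`),
#' the age term (`amp * scaled age`), the environmental response
#' (`amp * scaled response feature`), and the interaction products.
#'
#' @param truth a [truth_library()].
#' @param samples sample table (`time`, `age`).
#' @param ws [weather_series()] covering the schedule plus the longest
#'   memory period.
#' @return gene x sample matrix of log2 means.
#' @export
truth_signals <- function(truth, samples, ws) {
  n <- nrow(samples)
  d <- scale_unit_range(samples$age)$scaled
  tod <- time_of_day(as_time(samples$time))
  out <- matrix(0, length(truth), n,
                dimnames = list(vapply(truth, `[[`, "", "gene_id"), NULL))
  for (i in seq_along(truth)) {
    e <- truth[[i]]
    s <- rep(e$alpha * log2(exp(1)), n)
    clock_curve <- NULL
    if (!is.null(e$clock)) {
      clock_curve <- (cos(2 * pi * (tod - e$clock$phase) / 24) + 1) / 2
      s <- s + e$clock$amp * clock_curve
    }
    if (!is.null(e$age)) s <- s + e$age$amp * d
    r_scaled <- NULL
    if (!is.null(e$response)) {
      r_scaled <- scale_unit_range(
        env_response_feature(ws, samples$time, e$response$rp))$scaled
      s <- s + e$response$amp * r_scaled
    }
    if (!is.null(e$age_clock)) {
      cc <- clock_curve
      if (is.null(cc)) {
        cc <- (cos(2 * pi * (tod - e$age_clock$phase) / 24) + 1) / 2
      }
      s <- s + e$age_clock$amp * d * cc
    }
    if (!is.null(e$age_response)) {
      rr <- r_scaled
      if (is.null(rr)) {
        rr <- scale_unit_range(
          env_response_feature(ws, samples$time, e$age_response$rp))$scaled
      }
      s <- s + e$age_response$amp * d * rr
    }
    out[i, ] <- s
  }
  out
}

#' Negative-binomial read counts from a truth library
#'
#' Draws `counts ~ NB(mean = mu, variance = mu + phi * mu^2)` with
#' `mu = 2^truth_signals(...)` per gene and sample. Reproducible under the
#' seed.
#'
#' @inheritParams truth_signals
#' @param seed integer seed.
#' @return gene x sample count matrix.
#' @export
nb_counts <- function(truth, samples, ws, seed = 1L) {
  mu <- 2^truth_signals(truth, samples, ws)
  if (any(!is.finite(mu))) stop("non-finite mean expression")
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  out <- mu
  for (i in seq_len(nrow(mu))) {
    out[i, ] <- stats::rnbinom(ncol(mu), mu = mu[i, ],
                               size = 1 / truth[[i]]$dispersion)
  }
  colnames(out) <- samples$sample_id
  out
}

#' Simulate the full synthetic benchmark
#'
#' Generates synthetic station weather for the season (unless supplied),
#' the requested sampling design, the truth library (31 variable models
#' plus constant genes), and negative-binomial counts.
#'
#' @param design_id sampling design (default `"4h"`).
#' @param year season year (default 2008).
#' @param constant_genes constant genes to add (default 200).
#' @param seed master seed; weather, truth and counts use seeds derived
#'   from it.
#' @param ws optional [weather_series()]; synthesized at `step` if absent.
#' @param step weather cadence in seconds for synthesis (default 600).
#' @return List: `counts`, `samples`, `truth`, `weather`.
#' @export
simulate_benchmark <- function(design_id = "4h", year = 2008,
                               constant_genes = 200L, seed = 1L,
                               ws = NULL, step = 600) {
  seed <- as.integer(seed)
  samples <- sampling_design(design_id, year)
  if (is.null(ws)) {
    ws <- synth_weather(sprintf("%d-06-01 00:00:00", year),
                        sprintf("%d-09-19 00:00:00", year),
                        step = step, seed = seed %% 100000L + 11L)
  }
  truth <- truth_library(seed = seed %% 100000L + 77L,
                         constant_genes = constant_genes)
  counts <- nb_counts(truth, samples, ws, seed = seed %% 100000L + 131L)
  list(counts = counts, samples = samples, truth = truth, weather = ws)
}
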