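# RNA-Seq support: log-cpm transform, mean-variance trend, precision
# weights, and pseudo-RNA-Seq generation from intensity data.

#' Log counts per million
#'
#' `y = log2((r + 0.5) / (R_j + 1) * 1e6)` with `r` the read count and
#' `R_j` the column (library) total. The 0.5/1 offsets stabilize zeros.
#'
#' @param counts gene x sample matrix of non-negative counts.
#' @return Matrix of log-cpm values, same dimensions.
#' @export
log_cpm <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts")
  R <- colSums(counts)
  if (any(R <= 0)) stop("every sample must have a positive library size")
  log2(sweep(counts + 0.5, 2L, (R + 1) / 1e6, "/"))
}

# Smooth one gene's log-cpm series over sampling time by LOWESS, per
# calendar year of data.
smooth_over_time <- function(y, tnum, year, span, iters = 3L) {
  out <- numeric(length(y))
  for (yr in unique(year)) {
    sel <- year == yr
    if (sum(sel) < 4L || stats::var(tnum[sel]) == 0) {
      out[sel] <- mean(y[sel])
      next
    }
    fit <- stats::lowess(tnum[sel], y[sel], f = span, iter = iters)
    out[sel] <- stats::approx(fit$x, fit$y, xout = tnum[sel],
                              ties = "ordered", rule = 2)$y
  }
  out
}

#' Voom-style precision weights from counts
#'
#' Converts counts to log-cpm, smooths each gene's series over sampling
#' time (LOWESS, per year of data) to obtain residual standard deviations,
#' fits a LOWESS mean-variance trend of square-root standard deviation
#' against average log-count, and returns per-observation precision
#' weights `lo(smoothed log-count)^-4`, where `lo()` is the piecewise
#' linear trend (constant extrapolation beyond its range).
#'
#' @param counts gene x sample count matrix (>= 10 genes, >= 10 samples).
#' @param sample_times sample timestamps.
#' @param span_time LOWESS span for the per-gene time smoothing.
#' @param span_trend LOWESS span for the mean-variance trend.
#' @return Object of class `voom_weights`: `log_cpm`, `weights` (both gene
#'   x sample), `trend` (the `lo()` function), `mean_log_counts`.
#' @export
voom_weights <- function(counts, sample_times, span_time = 0.3,
                         span_trend = 0.5) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 10L || ncol(counts) < 10L) {
    stop("need at least 10 genes and 10 samples to estimate the trend")
  }
  time <- as_time(sample_times)
  stopifnot(length(time) == ncol(counts))
  y <- log_cpm(counts)
  R <- colSums(counts)
  Rbar <- exp(mean(log(R + 1)))
  tnum <- as.numeric(time)
  year <- as.integer(format(time, "%Y"))
  smoothed <- t(apply(y, 1L, smooth_over_time, tnum = tnum, year = year,
                      span = span_time))
  sigma <- sqrt(rowMeans((y - smoothed)^2))
  rbar <- rowMeans(y) + log2(Rbar) - log2(1e6)
  if (max(rbar) - min(rbar) < 1e-10) {
    stop("degenerate mean-variance trend: all gene mean log-counts identical")
  }
  lofit <- stats::lowess(rbar, sqrt(sigma), f = span_trend, iter = 3L)
  lo <- stats::approxfun(lofit$x, lofit$y, rule = 2, ties = "ordered")
  lam <- sweep(smoothed, 2L, log2(R + 1) - log2(1e6), "+")
  pred <- matrix(lo(lam), nrow(y), ncol(y))
  pred <- pmax(pred, 1e-4) # guard: predicted sqrt-sd must stay positive
  w <- pred^-4
  dimnames(w) <- dimnames(y) <- dimnames(counts)
  structure(
    list(log_cpm = y, weights = w, trend = lo, mean_log_counts = rbar,
         sigma = sigma, smoothed_log_cpm = smoothed),
    class = "voom_weights"
  )
}

#' @export
print.voom_weights <- function(x, ...) {
  cat(sprintf("<voom_weights> %d genes x %d samples, weight range [%.3g, %.3g]\n",
              nrow(x$weights), ncol(x$weights), min(x$weights), max(x$weights)))
  invisible(x)
}

#' Pseudo-RNA-Seq counts from log2 intensities
#'
#' For each sample, draws counts from a multinomial with total `total_reads`
#' and gene probabilities proportional to `2^signal` (a base-2 softmax of
#' the log2 intensities), so column sums equal `total_reads` exactly.
#'
#' @param signals gene x sample matrix of log2 intensities.
#' @param total_reads reads per sample (default 1e8).
#' @param seed integer seed.
#' @return gene x sample count matrix.
#' @export
pseudo_rnaseq <- function(signals, total_reads = 1e8, seed = 1L) {
  signals <- as.matrix(signals)
  if (any(!is.finite(signals))) stop("non-finite signals")
  stopifnot(total_reads >= 1)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  out <- apply(signals, 2L, function(s) {
    p <- 2^(s - max(s))
    stats::rmultinom(1L, total_reads, p / sum(p))[, 1L]
  })
  dimnames(out) <- dimnames(signals)
  out
}
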