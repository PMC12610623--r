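#' Photon-arrival stream
#'
#' Container for the raw output of one FCS detector channel: a nondecreasing
#' sequence of photon arrival times over a known acquisition span.
#'
#' @param timestamps Arrival times in seconds, nondecreasing, all within
#'   `[0, duration]`.
#' @param duration Total acquisition span, seconds (> 0).
#' @param channel_id Detector label (default `"ch1"`).
#' @return An object of class `photon_stream`.
#' @export
photon_stream <- function(timestamps, duration, channel_id = "ch1") {
  .check_number(duration, "duration", positive = TRUE)
  if (length(timestamps)) {
    .check_number(timestamps, "timestamps", nonnegative = TRUE, len = NULL)
    if (is.unsorted(timestamps)) {
      stop("'timestamps' must be nondecreasing", call. = FALSE)
    }
    if (max(timestamps) > duration) {
      stop("'timestamps' must lie within [0, duration]", call. = FALSE)
    }
  }
  structure(
    list(timestamps = as.numeric(timestamps), duration = duration,
         channel_id = channel_id),
    class = "photon_stream"
  )
}

#' @export
print.photon_stream <- function(x, ...) {
  cat(sprintf("Photon stream '%s': %d photons over %.4g s (%.3g kHz)\n",
              x$channel_id, length(x$timestamps), x$duration,
              length(x$timestamps) / x$duration / 1e3))
  invisible(x)
}

#' Binned intensity trace
#'
#' @param counts Nonnegative integer photon counts per bin.
#' @param bin_width Bin width in seconds (> 0).
#' @return An object of class `intensity_trace`.
#' @export
intensity_trace <- function(counts, bin_width) {
  .check_number(bin_width, "bin_width", positive = TRUE)
  .check_number(counts, "counts", nonnegative = TRUE, len = NULL)
  structure(list(counts = as.numeric(counts), bin_width = bin_width),
            class = "intensity_trace")
}

#' Bin a photon stream into an intensity trace
#'
#' Bin k (1-based) counts the photons with arrival time in
#' `[(k-1) * bin_width, k * bin_width)`. The trace is truncated to whole
#' bins, so photons arriving after the last full bin are dropped. An empty
#' stream yields an all-zero trace.
#'
#' @param stream A [photon_stream()].
#' @param bin_width Bin width in seconds; must be positive and smaller than
#'   the stream duration.
#' @return An [intensity_trace()].
#' @export
bin_stream <- function(stream, bin_width) {
  stopifnot(inherits(stream, "photon_stream"))
  .check_number(bin_width, "bin_width", positive = TRUE)
  if (bin_width >= stream$duration) {
    stop("'bin_width' must be smaller than the stream duration",
         call. = FALSE)
  }
  n_bins <- floor(stream$duration / bin_width)
  ts <- stream$timestamps
  ts <- ts[ts < n_bins * bin_width]
  idx <- floor(ts / bin_width) + 1L
  counts <- tabulate(idx, nbins = n_bins)
  intensity_trace(counts, bin_width)
}

#' Correlation curve
#'
#' @param lags Strictly increasing positive lag times, seconds.
#' @param values Correlation values G at each lag.
#' @param sigma Optional per-lag standard errors (>= 0, same length).
#' @return An object of class `correlation_curve`.
#' @export
correlation_curve <- function(lags, values, sigma = NULL) {
  .check_number(lags, "lags", positive = TRUE, len = NULL)
  if (length(lags) > 1 && any(diff(lags) <= 0)) {
    stop("'lags' must be strictly increasing", call. = FALSE)
  }
  .check_number(values, "values", len = NULL)
  if (length(values) != length(lags)) {
    stop("'values' must match 'lags' in length", call. = FALSE)
  }
  if (!is.null(sigma)) {
    .check_number(sigma, "sigma", nonnegative = TRUE, len = NULL)
    if (length(sigma) != length(lags)) {
      stop("'sigma' must match 'lags' in length", call. = FALSE)
    }
  }
  structure(list(lags = as.numeric(lags), values = as.numeric(values),
                 sigma = if (is.null(sigma)) NULL else as.numeric(sigma)),
            class = "correlation_curve")
}

#' @export
print.correlation_curve <- function(x, ...) {
  cat(sprintf(
    "Correlation curve: %d lags, %.3g s to %.3g s, G(first lag) = %.4g\n",
    length(x$lags), min(x$lags), max(x$lags), x$values[1]))
  invisible(x)
}

#' @export
as.data.frame.correlation_curve <- function(x, ...) {
  d <- data.frame(lag_s = x$lags, G = x$values)
  if (!is.null(x$sigma)) d$sigma <- x$sigma
  d
}

# Symmetric-normalization fluctuation estimator at a single integer lag:
# G(k) = <I_t I_{t+k}> / (<I_t>_left <I_{t+k}>_right) - 1, means over the
# overlapping segments. The symmetric normalization removes the long-lag
# bias so that G -> 0 for uncorrelated data and the amplitude is directly
# comparable to the closed-form model with baseline ~ 0.
.g_at_lag <- function(counts, k) {
  n <- length(counts)
  left <- counts[seq_len(n - k)]
  right <- counts[(k + 1):n]
  m_l <- mean(left)
  m_r <- mean(right)
  mean(left * right) / (m_l * m_r) - 1
}

#' Autocorrelate an intensity trace
#'
#' Computes the normalized fluctuation autocorrelation
#' G(tau) = <dI(t) dI(t+tau)> / <I>^2 with symmetric normalization (segment
#' means over the overlapping parts of the trace), so that G decays to 0 at
#' long lags for uncorrelated data. Lag 0, dominated by shot noise, is
#' excluded.
#'
#' Two schemes are available. `"direct"` evaluates every integer lag up to
#' `max_lag` bins at the trace's native resolution (O(n * max_lag)).
#' `"multi_tau"` uses the standard logarithmic correlator layout: the first
#' `points_per_octave` lags at native resolution, then the trace is coarsened
#' by summing adjacent bin pairs and the next `points_per_octave / 2` lags are
#' evaluated at the doubled bin width, repeating until the coarsened trace is
#' too short. This covers microsecond-to-second lags at a cost that is
#' effectively linear in the trace length.
#'
#' @param trace An [intensity_trace()] with at least 2 bins and nonzero mean.
#' @param scheme `"multi_tau"` (default) or `"direct"`.
#' @param points_per_octave Lags per octave for the multi-tau scheme; must be
#'   even. Default 16.
#' @param max_lag For the direct scheme: largest lag in bins (default
#'   `floor(n/4)`).
#' @return A [correlation_curve()].
#' @export
#' @examples
#' tr <- intensity_trace(rpois(4096, 20), 1e-6)
#' g <- autocorrelate(tr, scheme = "multi_tau")
autocorrelate <- function(trace, scheme = c("multi_tau", "direct"),
                          points_per_octave = 16,
                          max_lag = NULL) {
  stopifnot(inherits(trace, "intensity_trace"))
  scheme <- match.arg(scheme)
  counts <- trace$counts
  n <- length(counts)
  if (n < 2) stop("trace must have at least 2 bins", call. = FALSE)
  if (mean(counts) == 0) {
    stop("all-zero trace: normalization by the mean intensity is undefined",
         call. = FALSE)
  }

  if (scheme == "direct") {
    if (is.null(max_lag)) max_lag <- max(1L, floor(n / 4))
    max_lag <- min(max_lag, n - 2L)
    lags_bins <- seq_len(max_lag)
    values <- vapply(lags_bins, function(k) .g_at_lag(counts, k), numeric(1))
    return(correlation_curve(lags_bins * trace$bin_width, values))
  }

  m <- as.integer(points_per_octave)
  if (m < 2 || m %% 2 != 0) {
    stop("'points_per_octave' must be an even integer >= 2", call. = FALSE)
  }
  lag_times <- numeric(0)
  values <- numeric(0)
  level_counts <- counts
  width <- trace$bin_width
  level <- 0L
  repeat {
    lag_set <- if (level == 0L) seq_len(m) else (m / 2 + 1):m
    # need enough overlap for a stable segment mean
    lag_set <- lag_set[lag_set <= length(level_counts) - 2L]
    if (!length(lag_set)) break
    vals <- vapply(lag_set, function(k) .g_at_lag(level_counts, k),
                   numeric(1))
    lag_times <- c(lag_times, lag_set * width)
    values <- c(values, vals)
    # coarsen: sum adjacent bin pairs, double the width
    nc <- length(level_counts)
    if (nc < 2L * (m + 2L)) break
    nc <- nc - nc %% 2L
    level_counts <- level_counts[seq(1, nc, by = 2)] +
      level_counts[seq(2, nc, by = 2)]
    width <- width * 2
    level <- level + 1L
  }
  correlation_curve(lag_times, values)
}

#' Average repeat correlation curves
#'
#' Pointwise mean over repeat measurements sharing one lag grid, with the
#' pointwise standard error of the mean as `sigma`.
#'
#' @param curves List of [correlation_curve()] objects on identical lag
#'   grids.
#' @return A [correlation_curve()] with `sigma` filled in.
#' @export
average_curves <- function(curves) {
  if (!length(curves)) stop("'curves' must be a nonempty list", call. = FALSE)
  stopifnot(all(vapply(curves, inherits, logical(1), "correlation_curve")))
  lags <- curves[[1]]$lags
  for (cu in curves) {
    if (length(cu$lags) != length(lags) ||
        !isTRUE(all.equal(cu$lags, lags, tolerance = 1e-12))) {
      stop("all curves must share an identical lag grid", call. = FALSE)
    }
  }
  vals <- do.call(rbind, lapply(curves, `[[`, "values"))
  mean_v <- colMeans(vals)
  n <- nrow(vals)
  se <- if (n > 1) apply(vals, 2, stats::sd) / sqrt(n) else rep(0, ncol(vals))
  correlation_curve(lags, mean_v, se)
}
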