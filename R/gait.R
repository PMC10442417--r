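#' Treadmill gait analysis
#'
#' Stride measurements from a reconstructed foot trajectory of an animal
#' walking on a treadmill of known belt speed. The aggregate stride
#' duration is the wavelength (1/frequency) of the dominant peak of the
#' Fourier magnitude spectrum of the foot-position time series -- an
#' estimate that aggregates over many cycles and so resists the sampling
#' noise of a modest frame rate. Individual stride durations are the
#' peak-to-peak times of the trace. Multiplying durations by the belt speed
#' gives stride lengths; asymmetric outliers beyond a sigma cutoff
#' (default 2.3) from the mean are flagged.
#'
#' @name gait_analysis
NULL

#' A foot-position time series
#'
#' @param samples numeric vector: foot position along the motion axis, one
#'   value per frame (mm or arbitrary units).
#' @param fps frames per second (> 0).
#' @param joint_name which joint the trace comes from (e.g. "left_ankle").
#' @param detrended has a baseline already been removed?
#' @return Object of class `foot_trace`.
#' @export
foot_trace <- function(samples, fps, joint_name = "left_ankle",
                       detrended = FALSE) {
  if (fps <= 0) stop("fps must be positive")
  structure(list(samples = as.numeric(samples), fps = fps,
                 joint_name = joint_name, detrended = detrended),
            class = "foot_trace")
}

#' Remove the slow baseline from a foot trace
#'
#' Subtracts a centered moving-average baseline (window 1 s, edge-padded),
#' removing offset and drift while preserving the stride oscillation.
#'
#' @param trace a `foot_trace`.
#' @param window_s smoothing window in seconds (default 1).
#' @return A detrended `foot_trace`.
#' @export
detrend_trace <- function(trace, window_s = 1) {
  x <- trace$samples
  if (length(x) < 4L) stop("trace too short to detrend")
  w <- max(3L, round(trace$fps * window_s))
  if (w %% 2L == 0L) w <- w + 1L
  half <- (w - 1L) %/% 2L
  xp <- c(rep(x[1L], half), x, rep(x[length(x)], half))
  baseline <- as.numeric(stats::filter(xp, rep(1 / w, w), sides = 2L))
  baseline <- baseline[(half + 1L):(half + length(x))]
  foot_trace(x - baseline, trace$fps, trace$joint_name, detrended = TRUE)
}

# dominant frequency by FFT magnitude with parabolic peak interpolation,
# searched in [f_min, fps/2)
spectral_peak <- function(x, fps, f_min = 1) {
  n <- length(x)
  mag <- Mod(stats::fft(x - mean(x)))[seq_len(floor(n / 2))]
  freqs <- (seq_len(floor(n / 2)) - 1L) * fps / n
  band <- which(freqs >= f_min & freqs < fps / 2)
  if (length(band) < 3L) stop("trace too short for spectral analysis")
  mb <- mag[band]
  k <- band[which.max(mb)]
  if (max(mb) <= 0 || max(mb) < 4 * stats::median(mb))
    stop("no dominant spectral peak: trace shows no gait rhythm")
  # parabolic interpolation around the peak bin
  delta <- 0
  if (k > 1L && k < floor(n / 2)) {
    m0 <- mag[k - 1L]; m1 <- mag[k]; m2 <- mag[k + 1L]
    den <- m0 - 2 * m1 + m2
    if (abs(den) > .Machine$double.eps) delta <- 0.5 * (m0 - m2) / den
    delta <- max(-0.5, min(0.5, delta))
  }
  (k - 1L + delta) * fps / n
}

#' Aggregate stride estimate from the Fourier spectrum
#'
#' The dominant frequency of the (detrended) foot trace in [1, fps/2) Hz,
#' with parabolic interpolation around the peak bin; the aggregate stride
#' length is belt speed / frequency.
#'
#' @param trace a `foot_trace`; detrended automatically if not already.
#' @param belt_speed treadmill belt speed, mm/s.
#' @param f_min lower edge of the search band, Hz (default 1, below the
#'   physiological stride band, to keep residual drift out).
#' @return List with `peak_frequency_hz` and `stride_length_mm`.
#' @export
aggregate_stride <- function(trace, belt_speed, f_min = 1) {
  if (!trace$detrended) trace <- detrend_trace(trace)
  if (length(trace$samples) < 2 * trace$fps)
    stop("need at least 2 seconds of trace for spectral analysis")
  f <- spectral_peak(trace$samples, trace$fps, f_min)
  list(peak_frequency_hz = f, stride_length_mm = belt_speed / f)
}

# local maxima with topographic prominence and a minimum separation;
# separation enforced greedily from the highest peak down
find_peaks <- function(x, min_prominence, min_distance) {
  n <- length(x)
  cand <- which(diff(sign(diff(x))) < 0) + 1L
  if (length(cand) == 0L) return(integer(0))
  prom <- vapply(cand, function(i) {
    lmin <- x[i]; j <- i
    while (j > 1L && x[j - 1L] <= x[i]) { j <- j - 1L; lmin <- min(lmin, x[j]) }
    lmin_l <- if (j == 1L && x[j] <= x[i]) min(lmin, x[1L]) else lmin
    rmin <- x[i]; j <- i
    while (j < n && x[j + 1L] <= x[i]) { j <- j + 1L; rmin <- min(rmin, x[j]) }
    x[i] - max(lmin_l, rmin)
  }, numeric(1))
  keep <- cand[prom >= min_prominence]
  if (length(keep) <= 1L) return(keep)
  ord <- keep[order(x[keep], decreasing = TRUE)]
  sel <- integer(0)
  for (i in ord)
    if (all(abs(i - sel) >= min_distance)) sel <- c(sel, i)
  sort(sel)
}

#' Individual stride measurements from peak-to-peak times
#'
#' Detects stride peaks (minimum prominence 0.25 x the trace SD, minimum
#' separation half the aggregate period) and measures successive
#' peak-to-peak durations; lengths are durations x belt speed. Stride
#' lengths beyond `sigma` sample standard deviations from the mean
#' (computed once over all strides) are flagged as outliers.
#'
#' @inheritParams aggregate_stride
#' @param sigma outlier cutoff in standard deviations (default 2.3).
#' @return Object of class `stride_result`.
#' @export
individual_strides <- function(trace, belt_speed, sigma = 2.3, f_min = 1) {
  if (!trace$detrended) trace <- detrend_trace(trace)
  agg <- aggregate_stride(trace, belt_speed, f_min)
  x <- trace$samples
  peaks <- find_peaks(x, min_prominence = 0.25 * stats::sd(x),
                      min_distance = 0.5 / agg$peak_frequency_hz * trace$fps)
  if (length(peaks) < 2L) stop("fewer than 2 stride peaks detected")
  durations <- diff(peaks) / trace$fps
  lengths <- durations * belt_speed
  excl <- if (length(lengths) >= 3L)
    exclude_outliers(lengths, sigma) else
      list(kept = lengths, excluded = numeric(0),
           outlier_mask = rep(FALSE, length(lengths)))
  structure(list(
    aggregate_stride_length_mm = agg$stride_length_mm,
    peak_frequency_hz = agg$peak_frequency_hz,
    individual_durations_s = durations,
    individual_lengths_mm = lengths,
    peak_indices = peaks,
    outlier_mask = excl$outlier_mask,
    outlier_sigma_used = sigma,
    belt_speed_mm_s = belt_speed,
    joint_name = trace$joint_name
  ), class = "stride_result")
}

#' @export
print.stride_result <- function(x, ...) {
  cat(sprintf(paste0("<stride_result> %s: %.2f Hz, aggregate stride %.1f mm; ",
                     "%d strides (%d outliers beyond %.1f sigma)\n"),
              x$joint_name, x$peak_frequency_hz, x$aggregate_stride_length_mm,
              length(x$individual_lengths_mm), sum(x$outlier_mask),
              x$outlier_sigma_used))
  invisible(x)
}

#' Flag values beyond a sigma cutoff from the mean
#'
#' Single pass: the mean and sample SD are computed once from all values,
#' and values with |x - mean| > sigma x SD are excluded. Zero-variance
#' input excludes nothing.
#'
#' @param values numeric vector (>= 3 values).
#' @param sigma cutoff in standard deviations (default 2.3).
#' @return List with `kept`, `excluded`, and logical `outlier_mask`.
#' @export
exclude_outliers <- function(values, sigma = 2.3) {
  if (length(values) < 3L) stop("need at least 3 values")
  s <- stats::sd(values)
  mask <- if (s == 0) rep(FALSE, length(values)) else
    abs(values - mean(values)) > sigma * s
  list(kept = values[!mask], excluded = values[mask], outlier_mask = mask)
}
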