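#' Zero-phase Butterworth band-pass filter
#'
#' Applies a fifth-order Butterworth band-pass (default 1-16 Hz) in
#' forward-backward (zero-phase) mode, so temporal peak locations used by
#' the regularity features are not lag-shifted. The effective magnitude
#' response is the square of the single-pass response.
#'
#' @param x numeric vector, one channel.
#' @param sample_rate sampling rate in Hz; must exceed `2 * high`.
#' @param low,high passband edges in Hz.
#' @param order filter order (of the underlying low/high-pass prototype).
#' @return filtered vector, same length as `x`.
#' @export
bandpass <- function(x, sample_rate, low = 1, high = 16, order = 5) {
  if (!all(is.finite(x))) stop("signal contains non-finite samples")
  nyq <- sample_rate / 2
  if (high >= nyq) {
    stop("high cutoff (", high, " Hz) must be below the Nyquist frequency (",
         nyq, " Hz)")
  }
  if (low <= 0 || low >= high) stop("need 0 < low < high")
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Time-domain integration with drift suppression
#'
#' Integrates a band-passed channel once (angular velocity -> angle) or
#' twice (acceleration -> displacement) by cumulative trapezoid. The
#' band-pass is re-applied after each integration pass: integrating
#' broadband noise produces a low-frequency random walk that would
#' otherwise dominate the displacement, and the re-filter removes it
#' together with the constant of integration.
#'
#' @param x numeric vector, already band-passed.
#' @param sample_rate sampling rate in Hz.
#' @param times 1 or 2 integration passes.
#' @param low,high,order re-filter parameters, see [bandpass()].
#' @return integrated vector, same length as `x`, zero mean.
#' @export
integrate_signal <- function(x, sample_rate, times = 1,
                             low = 1, high = 16, order = 5) {
  if (!times %in% c(1, 2)) stop("times must be 1 or 2")
  dt <- 1 / sample_rate
  for (i in seq_len(times)) {
    x <- as.numeric(pracma::cumtrapz(x)) * dt
    x <- bandpass(x, sample_rate, low = low, high = high, order = order)
  }
  x
}

#' Extract the central analysis window of a channel
#'
#' Drops the first and last 10 s (start-up and wind-down artifacts), then
#' takes a 30-s window centered in what remains ("middle part" of the
#' recording). A 50-s recording is the minimum and yields exactly the
#' trimmed region.
#'
#' @param x numeric vector, one channel.
#' @param sample_rate sampling rate in Hz.
#' @param drop_head_s,drop_tail_s seconds trimmed at each end.
#' @param keep_s window length in seconds.
#' @return vector of `round(keep_s * sample_rate)` samples.
#' @export
segment_middle <- function(x, sample_rate, drop_head_s = 10,
                           drop_tail_s = 10, keep_s = 30) {
  n <- length(x)
  need <- (drop_head_s + drop_tail_s + keep_s) * sample_rate
  if (n < need) {
    stop(sprintf(
      "recording too short: %.2f s, need at least %.2f s (%g s head + %g s window + %g s tail)",
      n / sample_rate, need / sample_rate, drop_head_s, keep_s, drop_tail_s))
  }
  head_n <- round(drop_head_s * sample_rate)
  tail_n <- round(drop_tail_s * sample_rate)
  keep_n <- round(keep_s * sample_rate)
  avail <- n - head_n - tail_n
  start <- head_n + floor((avail - keep_n) / 2) # 0-based offset into x
  x[(start + 1):(start + keep_n)]
}

apply_axes <- function(m, f) {
  out <- do.call(cbind, lapply(1:3, function(j) f(m[, j])))
  colnames(out) <- c("x", "y", "z")
  out
}

#' Derive the four processed signals from a recording
#'
#' Band-passes acceleration and angular velocity, derives displacement
#' (double integration of acceleration) and angle (single integration of
#' angular velocity), then segments all four identically to the central
#' 30-s window. Filtering precedes segmentation so filter edge transients
#' fall in the trimmed regions. Each segmented axis is demeaned: the
#' band-pass removes DC over the full record, but cutting a finite window
#' reintroduces a small offset, which is removed so every processed axis
#' is exactly zero-mean.
#'
#' @param rec a [tremor_recording()] in SI units.
#' @param low,high,order band-pass parameters, see [bandpass()].
#' @param drop_head_s,drop_tail_s,keep_s segmentation parameters, see
#'   [segment_middle()].
#' @return An object of class `tremor_signals`: list with `acceleration`,
#'   `angular_velocity`, `displacement`, `angle` (each an M x 3 matrix,
#'   M = `round(keep_s * sample_rate)`) and `sample_rate`.
#' @export
process_recording <- function(rec, low = 1, high = 16, order = 5,
                              drop_head_s = 10, drop_tail_s = 10,
                              keep_s = 30) {
  stopifnot(inherits(rec, "tremor_recording"))
  fs <- rec$sample_rate
  bp <- function(x) bandpass(x, fs, low = low, high = high, order = order)
  seg <- function(x) {
    w <- segment_middle(x, fs, drop_head_s = drop_head_s,
                        drop_tail_s = drop_tail_s, keep_s = keep_s)
    w - mean(w)
  }
  acc <- apply_axes(rec$accel, bp)
  gyr <- apply_axes(rec$gyro, bp)
  disp <- apply_axes(acc, function(x) {
    integrate_signal(x, fs, times = 2, low = low, high = high, order = order)
  })
  ang <- apply_axes(gyr, function(x) {
    integrate_signal(x, fs, times = 1, low = low, high = high, order = order)
  })
  structure(
    list(acceleration = apply_axes(acc, seg),
         angular_velocity = apply_axes(gyr, seg),
         displacement = apply_axes(disp, seg),
         angle = apply_axes(ang, seg),
         sample_rate = fs),
    class = "tremor_signals"
  )
}

#' @export
print.tremor_signals <- function(x, ...) {
  cat(sprintf("<tremor_signals> %d samples at %g Hz (%.1f s window)\n",
              nrow(x$acceleration), x$sample_rate,
              nrow(x$acceleration) / x$sample_rate))
  invisible(x)
}
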