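#' Composite magnitude of a tri-axial signal
#'
#' Collapses the three axes into a single nonnegative magnitude series,
#' `sqrt(x(t)^2 + y(t)^2 + z(t)^2)` per sample, so that tremor amplitude is
#' measured independently of sensor orientation. Temporal features (peak
#' amplitudes, regularity) are computed on this composite.
#'
#' @param xyz numeric M x 3 matrix.
#' @return numeric vector of length M.
#' @export
composite <- function(xyz) {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3)
  if (!all(is.finite(xyz))) stop("non-finite values in tri-axial signal")
  sqrt(rowSums(xyz^2))
}

# Local maxima / minima of a numeric vector (interior points only). A
# two-sample plateau at an extremum (the turning point falling exactly
# between samples) is attributed to its first sample.
local_extrema <- function(v) {
  n <- length(v)
  if (n < 3) return(list(max = integer(0), min = integer(0)))
  core <- v[2:(n - 1)]
  list(max = which(core > v[1:(n - 2)] & core >= v[3:n]) + 1L,
       min = which(core < v[1:(n - 2)] & core <= v[3:n]) + 1L)
}

# Enforce strict alternation of peak types: within any run of same-type
# extrema keep only the extremal one (highest max / lowest min).
canonicalize_alternation <- function(idx, type, value) {
  keep <- rep(TRUE, length(idx))
  run_start <- 1
  for (i in seq_along(idx)[-1]) {
    if (type[i] != type[run_start]) {
      run_start <- i
    } else {
      # same-type run: keep the better of current champion and i
      champ <- which(keep[run_start:i])[1] + run_start - 1
      if (type[i] == "max") {
        if (value[i] > value[champ]) { keep[champ] <- FALSE } else keep[i] <- FALSE
      } else {
        if (value[i] < value[champ]) { keep[champ] <- FALSE } else keep[i] <- FALSE
      }
    }
  }
  keep
}

#' Detect alternating positive and negative peaks of a composite signal
#'
#' Positive peaks are local maxima and negative peaks local minima of the
#' composite magnitude. Candidate extrema are canonicalized to strict
#' alternation (within a same-type run only the extremal point survives),
#' then maxima/minima pairs with local prominence below
#' `min_prominence_frac` of the composite's interquartile range are
#' discarded (noise ripple), and positive peaks closer together than
#' `min_separation_s` are thinned keeping the higher (oscillations above
#' the 16 Hz analysis band are not tremor).
#'
#' @param values composite magnitude series (nonnegative vector).
#' @param sample_rate sampling rate in Hz.
#' @param min_separation_s minimum spacing of positive peaks, seconds;
#'   default half the period at 16 Hz.
#' @param min_prominence_frac prominence floor as a fraction of IQR.
#' @return An object of class `peak_train`: list with data frames `pp` and
#'   `np` (columns `index`, `time`, `value`) and logical `degenerate`
#'   (fewer than 2 positive peaks).
#' @export
detect_peaks <- function(values, sample_rate,
                         min_separation_s = 1 / 32,
                         min_prominence_frac = 0.05) {
  stopifnot(length(values) >= 3)
  prom_floor <- min_prominence_frac * stats::IQR(values)
  ex <- local_extrema(values)
  idx <- c(ex$max, ex$min)
  type <- rep(c("max", "min"), c(length(ex$max), length(ex$min)))
  o <- order(idx)
  idx <- idx[o]; type <- type[o]
  val <- values[idx]

  repeat {
    if (length(idx) == 0) break
    keep <- canonicalize_alternation(idx, type, val)
    idx <- idx[keep]; type <- type[keep]; val <- val[keep]
    # local prominence: height of a max above its higher flanking min
    # (and depth of a min below its lower flanking max)
    drop <- rep(FALSE, length(idx))
    for (i in seq_along(idx)) {
      nb <- val[intersect(c(i - 1, i + 1), seq_along(idx))]
      if (length(nb) == 0) next
      prom <- if (type[i] == "max") val[i] - max(nb) else min(nb) - val[i]
      if (prom < prom_floor) drop[i] <- TRUE
    }
    if (!any(drop)) break
    idx <- idx[!drop]; type <- type[!drop]; val <- val[!drop]
  }

  # thin positive peaks violating the minimum separation (keep the higher)
  min_gap <- min_separation_s * sample_rate
  repeat {
    pp_i <- which(type == "max")
    if (length(pp_i) < 2) break
    gaps <- diff(idx[pp_i])
    close_pair <- which(gaps < min_gap)
    if (length(close_pair) == 0) break
    j <- close_pair[1]
    loser <- if (val[pp_i[j]] <= val[pp_i[j + 1]]) pp_i[j] else pp_i[j + 1]
    idx <- idx[-loser]; type <- type[-loser]; val <- val[-loser]
    keep <- canonicalize_alternation(idx, type, val)
    idx <- idx[keep]; type <- type[keep]; val <- val[keep]
  }

  pp <- data.frame(index = idx[type == "max"],
                   time = (idx[type == "max"] - 1) / sample_rate,
                   value = val[type == "max"])
  np <- data.frame(index = idx[type == "min"],
                   time = (idx[type == "min"] - 1) / sample_rate,
                   value = val[type == "min"])
  structure(list(pp = pp, np = np, degenerate = nrow(pp) < 2),
            class = "peak_train")
}

#' Mean peak-to-peak tremor amplitude
#'
#' For each positive peak with a negative peak on both sides, two
#' half-cycle amplitudes are formed — `Amp1_i = |pp_i - np_i|` against the
#' preceding trough and `Amp2_i = |np_(i+1) - pp_i|` against the following
#' one — and the feature is the mean over peaks of `(Amp1_i + Amp2_i) / 2`.
#' Degenerate trains (fewer than two usable peaks) return 0 with a warning.
#'
#' @param peaks a [detect_peaks()] result.
#' @return mean amplitude in composite-signal units.
#' @export
mean_amplitude <- function(peaks) {
  stopifnot(inherits(peaks, "peak_train"))
  pp <- peaks$pp; np <- peaks$np
  if (peaks$degenerate || nrow(np) < 2) {
    warning("degenerate peak train: mean amplitude set to 0")
    return(0)
  }
  amps <- numeric(0)
  for (i in seq_len(nrow(pp))) {
    before <- np$value[np$index < pp$index[i]]
    after <- np$value[np$index > pp$index[i]]
    if (length(before) == 0 || length(after) == 0) next
    a1 <- abs(pp$value[i] - before[length(before)])
    a2 <- abs(after[1] - pp$value[i])
    amps <- c(amps, (a1 + a2) / 2)
  }
  if (length(amps) == 0) {
    warning("no positive peak flanked by negative peaks: mean amplitude 0")
    return(0)
  }
  mean(amps)
}

#' Tremor rhythm regularity
#'
#' The intervals between successive positive peaks measure the tremor
#' period; their mean is the average regularity (seconds) and their
#' standard deviation quantifies rhythm variability.
#'
#' @param peaks a [detect_peaks()] result.
#' @return list with `avg` and `sd`, both in seconds (0 with a warning on
#'   degenerate trains).
#' @export
regularity <- function(peaks) {
  stopifnot(inherits(peaks, "peak_train"))
  if (nrow(peaks$pp) < 2) {
    warning("fewer than 2 positive peaks: regularity set to 0")
    return(list(avg = 0, sd = 0))
  }
  iv <- diff(peaks$pp$time)
  list(avg = mean(iv), sd = if (length(iv) > 1) stats::sd(iv) else 0)
}

# Welch power spectral density of one channel: Hann-windowed overlapping
# segments, one-sided density normalised by fs * sum(w^2).
welch_psd <- function(x, sample_rate, window = 512, overlap = 0.5) {
  n <- length(x)
  if (n < 2 * window) {
    stop("signal too short for spectral estimate: ", n,
         " samples, need at least ", 2 * window)
  }
  w <- as.numeric(signal::hanning(window))
  step <- max(1, round(window * (1 - overlap)))
  starts <- seq(1, n - window + 1, by = step)
  half <- window %/% 2 + 1
  acc <- numeric(half)
  for (s in starts) {
    seg <- x[s:(s + window - 1)] * w
    X <- stats::fft(seg)[1:half]
    P <- Mod(X)^2 / (sample_rate * sum(w^2))
    P[2:(half - 1)] <- 2 * P[2:(half - 1)] # fold negative frequencies
    acc <- acc + P
  }
  list(freq = (0:(half - 1)) * sample_rate / window,
       power = acc / length(starts))
}

#' Axis-averaged power spectrum of a tri-axial signal
#'
#' Estimates a Welch periodogram per axis and averages the three spectra
#' at each frequency, yielding one spectrum reflecting the 3-D movement.
#'
#' @param xyz numeric M x 3 matrix.
#' @param sample_rate sampling rate in Hz.
#' @param window Welch segment length in samples (default 512, about 0.244
#'   Hz resolution at 125 Hz).
#' @param overlap fractional segment overlap.
#' @return An object of class `tremor_spectrum`: list with `freq` (Hz,
#'   uniform grid from 0 to Nyquist) and `power` (nonnegative).
#' @export
averaged_spectrum <- function(xyz, sample_rate, window = 512, overlap = 0.5) {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3)
  per_axis <- lapply(1:3, function(j) welch_psd(xyz[, j], sample_rate,
                                                window = window,
                                                overlap = overlap))
  structure(
    list(freq = per_axis[[1]]$freq,
         power = (per_axis[[1]]$power + per_axis[[2]]$power +
                    per_axis[[3]]$power) / 3),
    class = "tremor_spectrum"
  )
}

#' Peak and mean frequency and their power values
#'
#' Over the analysis band (0, `fmax`] Hz: the peak frequency is the
#' frequency of maximum power; the mean frequency is the power-weighted
#' mean frequency, `sum(f_i P_i) / sum(P_i)`; peak power is the power at
#' the peak frequency and mean power the power at the grid frequency
#' nearest the mean frequency.
#'
#' @param sp a [averaged_spectrum()] result.
#' @param fmax upper edge of the analysis band in Hz.
#' @return list with `peak_freq`, `mean_freq` (Hz), `peak_power`,
#'   `mean_power` (all 0 with a warning for an all-zero spectrum).
#' @export
spectral_features <- function(sp, fmax = 16) {
  stopifnot(inherits(sp, "tremor_spectrum"))
  in_band <- sp$freq > 0 & sp$freq <= fmax
  f <- sp$freq[in_band]
  p <- sp$power[in_band]
  if (sum(p) <= 0) {
    warning("spectrum carries no power in (0, ", fmax, "] Hz")
    return(list(peak_freq = 0, mean_freq = 0, peak_power = 0, mean_power = 0))
  }
  i_pk <- which.max(p)
  mf <- sum(f * p) / sum(p)
  list(peak_freq = f[i_pk],
       mean_freq = mf,
       peak_power = p[i_pk],
       mean_power = p[which.min(abs(f - mf))])
}

#' Adaptive frequency-band powers
#'
#' The tremor band is the 6-Hz window centered on the mean frequency
#' (3 Hz each side, clamped to `[0, fmax]`); the low band runs from 0 Hz up
#' to it and the high band from it up to `fmax`. Absolute band powers are
#' sums of spectral power per band with each bin assigned to exactly one
#' band (`[0, f_tr1)`, `[f_tr1, f_tr2]`, `(f_tr2, fmax]`); relative powers
#' are each band's share of the total power over `[0, fmax]` and sum to 1.
#'
#' @param sp a [averaged_spectrum()] result.
#' @param mean_freq mean frequency in Hz (from [spectral_features()]).
#' @param fmax upper edge of the analysis band in Hz.
#' @param half_width half-width of the tremor band in Hz.
#' @return list with `P_low`, `P_tr`, `P_high`, `Prl_low`, `Prl_tr`,
#'   `Prl_high`.
#' @export
band_features <- function(sp, mean_freq, fmax = 16, half_width = 3) {
  stopifnot(inherits(sp, "tremor_spectrum"))
  stopifnot(mean_freq >= 0, mean_freq <= fmax)
  f_tr1 <- max(mean_freq - half_width, 0)
  f_tr2 <- min(mean_freq + half_width, fmax)
  f <- sp$freq[sp$freq <= fmax]
  p <- sp$power[sp$freq <= fmax]
  P_low <- sum(p[f < f_tr1])
  P_tr <- sum(p[f >= f_tr1 & f <= f_tr2])
  P_high <- sum(p[f > f_tr2])
  total <- P_low + P_tr + P_high
  if (total <= 0) {
    warning("zero total power: relative band powers set to 0")
    rel <- c(0, 0, 0)
  } else {
    rel <- c(P_low, P_tr, P_high) / total
  }
  list(P_low = P_low, P_tr = P_tr, P_high = P_high,
       Prl_low = rel[1], Prl_tr = rel[2], Prl_high = rel[3])
}

signal_feature_names <- c(
  "mean_amplitude", "avg_regularity", "sd_regularity",
  "peak_freq", "mean_freq", "peak_power", "mean_power",
  "P_low", "P_tr", "P_high", "Prl_low", "Prl_tr", "Prl_high",
  "log_mean_amplitude", "log_peak_power", "log_mean_power",
  "log_P_low", "log_P_tr", "log_P_high"
)

signal_abbrevs <- c(acceleration = "acc", angular_velocity = "gyro",
                    displacement = "disp", angle = "angle")

#' Canonical feature names
#'
#' The 76 feature columns in canonical order: signals `acc`, `gyro`,
#' `disp`, `angle`, each contributing 19 features named
#' `<signal>.<feature>`. Feature selection indices are only reproducible
#' against this fixed ordering.
#'
#' @return character vector of length 76.
#' @export
feature_names <- function() {
  as.character(vapply(unname(signal_abbrevs), function(s) {
    paste(s, signal_feature_names, sep = ".")
  }, character(length(signal_feature_names))))
}

# 19 features of one processed tri-axial signal.
extract_signal_features <- function(xyz, sample_rate, window = 512,
                                    overlap = 0.5, min_separation_s = 1 / 32,
                                    min_prominence_frac = 0.05,
                                    log_eps = 1e-12) {
  comp <- composite(xyz)
  peaks <- detect_peaks(comp, sample_rate,
                        min_separation_s = min_separation_s,
                        min_prominence_frac = min_prominence_frac)
  amp <- if (peaks$degenerate) 0 else suppressWarnings(mean_amplitude(peaks))
  reg <- suppressWarnings(regularity(peaks))
  sp <- averaged_spectrum(xyz, sample_rate, window = window, overlap = overlap)
  spf <- suppressWarnings(spectral_features(sp))
  bf <- suppressWarnings(band_features(sp, spf$mean_freq))
  lg <- function(v) log10(max(v, log_eps))
  c(mean_amplitude = amp, avg_regularity = reg$avg, sd_regularity = reg$sd,
    peak_freq = spf$peak_freq, mean_freq = spf$mean_freq,
    peak_power = spf$peak_power, mean_power = spf$mean_power,
    P_low = bf$P_low, P_tr = bf$P_tr, P_high = bf$P_high,
    Prl_low = bf$Prl_low, Prl_tr = bf$Prl_tr, Prl_high = bf$Prl_high,
    log_mean_amplitude = lg(amp), log_peak_power = lg(spf$peak_power),
    log_mean_power = lg(spf$mean_power), log_P_low = lg(bf$P_low),
    log_P_tr = lg(bf$P_tr), log_P_high = lg(bf$P_high))
}

#' Extract the 76-feature vector of a processed recording
#'
#' Computes the 19 temporal and spectral features for each of the four
#' processed signals (acceleration, angular velocity, displacement, angle):
#' 3 temporal features from the peak train of the composite magnitude, 4
#' spectral location/power features and 6 adaptive band-power features from
#' the axis-averaged spectrum, and 6 base-10 logarithms (floored at
#' `log_eps` so tremor-free recordings stay finite).
#'
#' @param signals a [process_recording()] result.
#' @param window,overlap spectral estimator parameters, see
#'   [averaged_spectrum()].
#' @param min_separation_s,min_prominence_frac peak-detection parameters,
#'   see [detect_peaks()].
#' @param log_eps floor applied inside the log features.
#' @return named numeric vector of length 76 in [feature_names()] order.
#' @export
extract_features <- function(signals, window = 512, overlap = 0.5,
                             min_separation_s = 1 / 32,
                             min_prominence_frac = 0.05, log_eps = 1e-12) {
  stopifnot(inherits(signals, "tremor_signals"))
  out <- unlist(lapply(names(signal_abbrevs), function(nm) {
    v <- extract_signal_features(
      signals[[nm]], signals$sample_rate, window = window, overlap = overlap,
      min_separation_s = min_separation_s,
      min_prominence_frac = min_prominence_frac, log_eps = log_eps)
    names(v) <- paste(signal_abbrevs[[nm]], names(v), sep = ".")
    v
  }))
  stopifnot(identical(names(out), feature_names()))
  out
}

#' Build a feature matrix from a list of recordings
#'
#' Runs [process_recording()] and [extract_features()] on each recording
#' and assembles the feature table (one row per recording, canonical
#' columns, `label` last).
#'
#' @param recordings list of [tremor_recording()] objects.
#' @param labels optional integer labels 0-4; defaults to the labels stored
#'   in the recordings' metadata.
#' @param ... passed to [extract_features()].
#' @return data frame with 76 feature columns plus `label`.
#' @export
extract_dataset <- function(recordings, labels = NULL, ...) {
  stopifnot(length(recordings) > 0)
  if (is.null(labels)) {
    labels <- vapply(recordings, function(r) {
      if (is.null(r$meta$label)) NA_integer_ else as.integer(r$meta$label)
    }, integer(1))
  }
  stopifnot(length(labels) == length(recordings))
  rows <- lapply(recordings, function(r) {
    extract_features(process_recording(r), ...)
  })
  df <- as.data.frame(do.call(rbind, rows))
  df$label <- as.integer(labels)
  df
}
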