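#' Severity class profile for the tremor simulator
#'
#' Maps a UPDRS rest-tremor score to simulator parameters. Amplitude and
#' the fraction of time the tremor is present both grow with severity,
#' following the clinical ladder (score 1 "slight and infrequently
#' present" through score 4 "marked in amplitude and present most of the
#' time"). The numeric defaults are simulator conventions, not clinical
#' measurements.
#'
#' @param label UPDRS class 0-4.
#' @param tremor_amplitude oscillation amplitude on the acceleration
#'   channels, m/s^2.
#' @param duty_cycle stationary fraction of time the tremor is active.
#' @param freq_range interval the tremor frequency is drawn from, Hz.
#' @param harmonic_ratio relative amplitude of the second harmonic.
#' @param noise_sd white-noise standard deviation (m/s^2 accel; the gyro
#'   channels use half this value in rad/s).
#' @param drift_sd standard deviation of the slow baseline random walk.
#' @param gyro_scale angular-velocity amplitude per unit of acceleration
#'   amplitude, (rad/s) / (m/s^2).
#' @return An object of class `class_profile`.
#' @export
class_profile <- function(label, tremor_amplitude, duty_cycle,
                          freq_range = c(4, 6), harmonic_ratio = 0.1,
                          noise_sd = 0.02, drift_sd = 0.05,
                          gyro_scale = 0.5) {
  stopifnot(label %in% 0:4, tremor_amplitude >= 0,
            duty_cycle >= 0, duty_cycle <= 1,
            length(freq_range) == 2, freq_range[1] > 1, freq_range[2] < 16,
            freq_range[1] <= freq_range[2])
  structure(list(label = as.integer(label),
                 tremor_amplitude = tremor_amplitude,
                 duty_cycle = duty_cycle, freq_range = freq_range,
                 harmonic_ratio = harmonic_ratio, noise_sd = noise_sd,
                 drift_sd = drift_sd, gyro_scale = gyro_scale),
            class = "class_profile")
}

#' Default severity profiles
#'
#' Amplitudes follow a geometric ladder (0, 0.05, 0.15, 0.45, 1.35 m/s^2)
#' and duty cycles (0, 0.3, 0.8, 0.9, 0.95): successive severity scores
#' roughly triple the tremor amplitude, and higher scores have the tremor
#' present most of the time.
#'
#' @return list of five [class_profile()] objects, classes 0-4.
#' @export
default_profiles <- function() {
  amp <- c(0, 0.05, 0.15, 0.45, 1.35)
  duty <- c(0, 0.3, 0.8, 0.9, 0.95)
  lapply(0:4, function(cl) {
    class_profile(cl, tremor_amplitude = amp[cl + 1],
                  duty_cycle = duty[cl + 1])
  })
}

# Two-state Markov on/off gate with stationary duty cycle `duty` and mean
# on-dwell `dwell_s` seconds; duty 0/1 are degenerate all-off/all-on.
markov_gate <- function(n, sample_rate, duty, dwell_s = 2) {
  if (duty >= 1) return(rep(1, n))
  if (duty <= 0) return(rep(0, n))
  p_off <- 1 / (dwell_s * sample_rate)          # leave "on"
  p_on <- p_off * duty / (1 - duty)             # leave "off"
  state <- as.integer(stats::runif(1) < duty)   # stationary start
  g <- integer(n)
  flips <- stats::runif(n)
  for (i in seq_len(n)) {
    g[i] <- state
    p_leave <- if (state == 1) p_off else p_on
    if (flips[i] < p_leave) state <- 1L - state
  }
  g
}

random_unit_vector <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

scaled_random_walk <- function(n, sd_target) {
  w <- cumsum(stats::rnorm(n))
  s <- stats::sd(w)
  if (s == 0 || sd_target == 0) return(numeric(n))
  w / s * sd_target
}

#' Simulate one resting-tremor IMU recording
#'
#' The tremor component is an amplitude-modulated near-sinusoid:
#' `A g(t) [sin(2 pi f t + phi) + h sin(4 pi f t + phi2)]` with the
#' frequency `f` drawn once per recording from the profile's range, and
#' `g(t)` a two-state Markov on/off gate whose stationary on-fraction is
#' the profile's duty cycle (mean on-dwell 2 s, so intermittent tremor has
#' realistic run lengths). The component is projected onto one random unit
#' 3-vector for the accelerometer and an independent one for the gyroscope
#' (wrist and finger sensing axes are not aligned); each of the six
#' channels additionally carries white noise and a slow random-walk drift.
#' Deterministic given `seed`.
#'
#' @param profile a [class_profile()].
#' @param duration_s recording length in seconds (>= 50 so the
#'   preprocessing window fits).
#' @param sample_rate sampling rate in Hz.
#' @param seed integer seed.
#' @param id,hand metadata for the resulting recording.
#' @return a [tremor_recording()] with the profile's label attached.
#' @export
simulate_recording <- function(profile, duration_s = 60, sample_rate = 125,
                               seed = 1, id = NULL, hand = NA_character_) {
  stopifnot(inherits(profile, "class_profile"))
  if (duration_s < 50) stop("duration_s must be >= 50 (preprocessing window)")
  set.seed(seed)
  n <- round(duration_s * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate

  f <- stats::runif(1, profile$freq_range[1], profile$freq_range[2])
  phi <- stats::runif(2, 0, 2 * pi)
  gate <- markov_gate(n, sample_rate, profile$duty_cycle)
  wave <- gate * (sin(2 * pi * f * t + phi[1]) +
                    profile$harmonic_ratio * sin(4 * pi * f * t + phi[2]))

  u_acc <- random_unit_vector()
  u_gyr <- random_unit_vector()
  amp_acc <- profile$tremor_amplitude
  amp_gyr <- profile$tremor_amplitude * profile$gyro_scale

  accel <- outer(wave * amp_acc, u_acc)
  gyro <- outer(wave * amp_gyr, u_gyr)
  for (j in 1:3) {
    accel[, j] <- accel[, j] + stats::rnorm(n, sd = profile$noise_sd) +
      scaled_random_walk(n, profile$drift_sd)
    gyro[, j] <- gyro[, j] + stats::rnorm(n, sd = profile$noise_sd / 2) +
      scaled_random_walk(n, profile$drift_sd / 2)
  }

  rec <- tremor_recording(accel, gyro, sample_rate = sample_rate,
                          id = id %||% sprintf("sim-c%d-s%d", profile$label, seed),
                          hand = hand, label = profile$label)
  attr(rec, "sim_freq") <- f
  rec
}

#' Simulate a labelled dataset of tremor recordings
#'
#' Draws independent recordings with per-recording sub-seeds derived from
#' the master seed, so the whole dataset is reproducible bit-for-bit. The
#' default class counts (79, 22, 22, 6, 2) mirror the imbalanced severity
#' distribution of a movement-disorder clinic population, with few
#' severe-tremor recordings.
#'
#' @param class_counts integer vector of length 5: recordings per class
#'   0-4.
#' @param profiles list of five [class_profile()] objects.
#' @param duration_s,sample_rate see [simulate_recording()].
#' @param seed master seed.
#' @return list with `recordings` (list of [tremor_recording()]), `labels`
#'   (integer vector), and `freqs` (the drawn tremor frequency per
#'   recording, `NA` where amplitude is 0).
#' @export
simulate_dataset <- function(class_counts = c(79, 22, 22, 6, 2),
                             profiles = default_profiles(),
                             duration_s = 60, sample_rate = 125, seed = 1) {
  stopifnot(length(class_counts) == 5, all(class_counts >= 0))
  n <- sum(class_counts)
  if (n == 0) stop("all class counts are zero")
  labels <- rep(0:4, class_counts)
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1, n)
  recordings <- vector("list", n)
  freqs <- numeric(n)
  for (i in seq_len(n)) {
    prof <- profiles[[labels[i] + 1]]
    recordings[[i]] <- simulate_recording(prof, duration_s = duration_s,
                                          sample_rate = sample_rate,
                                          seed = sub_seeds[i],
                                          id = sprintf("sim-%03d", i))
    freqs[i] <- if (prof$tremor_amplitude > 0) {
      attr(recordings[[i]], "sim_freq")
    } else NA_real_
  }
  list(recordings = recordings, labels = labels, freqs = freqs)
}
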