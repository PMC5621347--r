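# Independent oracles used across tests.

# Magnitude of a digital filter's frequency response at frequency f (Hz),
# evaluated directly from the transfer-function polynomials at z = e^{iw}.
# Independent of any time-domain filtering code path.
tf_magnitude <- function(b, a, f, sample_rate) {
  z <- exp(-1i * 2 * pi * f / sample_rate * (seq_along(b) - 1))
  num <- sum(b * z)
  z <- exp(-1i * 2 * pi * f / sample_rate * (seq_along(a) - 1))
  den <- sum(a * z)
  Mod(num / den)
}

# Steady-state amplitude of a (possibly filtered) sinusoid: peak magnitude
# after discarding settling margins at both ends.
steady_amplitude <- function(x, margin_frac = 0.25) {
  n <- length(x)
  m <- floor(n * margin_frac)
  max(abs(x[(m + 1):(n - m)]))
}

# Exhaustive greedy "most unrelated first" ordering over an explicit
# absolute-correlation matrix; mirrors the selection contract by direct
# enumeration rather than sharing code with pairwise_order().
brute_greedy_order <- function(r_abs, extension = "minimax") {
  p <- ncol(r_abs)
  best <- NULL
  best_val <- Inf
  for (i in 1:(p - 1)) for (j in (i + 1):p) {
    if (r_abs[i, j] < best_val) { best_val <- r_abs[i, j]; best <- c(i, j) }
  }
  sel <- best
  while (length(sel) < p) {
    rest <- setdiff(1:p, sel)
    scores <- sapply(rest, function(k) {
      v <- r_abs[k, sel]
      if (extension == "minimax") max(v) else mean(v)
    })
    sel <- c(sel, rest[which.min(scores)])
  }
  sel
}

# Brute-force 1-NN leave-one-out predictions: each point takes the label of
# its nearest *other* point (Euclidean).
brute_1nn_loocv <- function(X, y) {
  X <- as.matrix(X)
  n <- nrow(X)
  sapply(seq_len(n), function(i) {
    d <- sqrt(rowSums((X - matrix(X[i, ], n, ncol(X), byrow = TRUE))^2))
    d[i] <- Inf
    y[which.min(d)]
  })
}

# A recording whose acceleration is a pure sinusoid on one axis (zero
# elsewhere), for analytic-ratio tests.
sine_recording <- function(freq, amp = 1, duration_s = 60, sample_rate = 125,
                           axis = 1) {
  n <- round(duration_s * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  accel <- matrix(0, n, 3)
  accel[, axis] <- amp * sin(2 * pi * freq * t)
  tremor_recording(accel, matrix(0, n, 3), sample_rate = sample_rate)
}

# Spectrum object on a uniform grid with point masses at given frequencies.
point_mass_spectrum <- function(freqs, powers, df = 0.25, fmax_grid = 62.5) {
  grid <- seq(0, fmax_grid, by = df)
  power <- numeric(length(grid))
  for (i in seq_along(freqs)) {
    power[which.min(abs(grid - freqs[i]))] <- powers[i]
  }
  structure(list(freq = grid, power = power), class = "tremor_spectrum")
}

# Hand-built alternating peak train (times in seconds).
make_peak_train <- function(pp_t, pp_v, np_t, np_v, sample_rate = 125) {
  structure(list(
    pp = data.frame(index = round(pp_t * sample_rate) + 1, time = pp_t,
                    value = pp_v),
    np = data.frame(index = round(np_t * sample_rate) + 1, time = np_t,
                    value = np_v),
    degenerate = length(pp_t) < 2), class = "peak_train")
}
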