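fs <- 125

test_that("composite magnitude is the per-sample Euclidean norm", {
  expect_equal(composite(cbind(3, 4, 0)), 5)
  expect_equal(composite(matrix(0, 10, 3)), rep(0, 10))
  t <- (0:999) / fs
  s <- sin(2 * pi * 5 * t)
  expect_equal(composite(cbind(s, 0, 0)), abs(s))
  expect_error(composite(cbind(NA, 1, 1)), "non-finite")
})

test_that("peak detection counts rectified-sine lobes and flags degeneracy", {
  t <- (seq_len(30 * fs) - 1) / fs
  c5 <- abs(sin(2 * pi * 5 * t)) # 10 lobes per second
  pk <- detect_peaks(c5, fs)
  expect_false(pk$degenerate)
  expect_true(abs(nrow(pk$pp) - 300) <= 1)

  mono <- detect_peaks(seq_len(100) / 10, fs)
  expect_true(mono$degenerate)
  expect_equal(nrow(mono$pp), 0)
})

test_that("detected peaks strictly alternate and sit on true extrema", {
  rec <- simulate_recording(default_profiles()[[3]], seed = 21) # class 2
  comp <- composite(process_recording(rec)$acceleration)
  pk <- detect_peaks(comp, fs)
  ev <- rbind(data.frame(i = pk$pp$index, type = "max"),
              data.frame(i = pk$np$index, type = "min"))
  ev <- ev[order(ev$i), ]
  expect_gt(nrow(ev), 4)
  expect_true(all(ev$type[-1] != ev$type[-nrow(ev)])) # interleaving
  expect_true(all(diff(pk$pp$time) > 0))
  # oracle: every reported extremum is a true local extremum of the series
  n <- length(comp)
  is_max <- c(FALSE, comp[2:(n - 1)] > comp[1:(n - 2)] &
                comp[2:(n - 1)] > comp[3:n], FALSE)
  is_min <- c(FALSE, comp[2:(n - 1)] < comp[1:(n - 2)] &
                comp[2:(n - 1)] < comp[3:n], FALSE)
  expect_true(all(is_max[pk$pp$index]))
  expect_true(all(is_min[pk$np$index]))
})

test_that("mean amplitude averages the two half-cycle amplitudes per peak", {
  # constant-amplitude train: peaks at A, troughs at 0
  tr <- make_peak_train(pp_t = c(0.1, 0.3, 0.5), pp_v = c(2, 2, 2),
                        np_t = c(0.0, 0.2, 0.4, 0.6), np_v = c(0, 0, 0, 0))
  expect_equal(mean_amplitude(tr), 2)

  # hand-enumerated: pp (2, 4) between troughs at 0 ->
  # ((|2-0|+|0-2|)/2 + (|4-0|+|0-4|)/2) / 2 = 3
  tr2 <- make_peak_train(pp_t = c(0.1, 0.3), pp_v = c(2, 4),
                         np_t = c(0.0, 0.2, 0.4), np_v = c(0, 0, 0))
  expect_equal(mean_amplitude(tr2), 3)

  # degenerate trains return 0 with a warning
  flat <- detect_peaks(rep(0, 100) + 1e-12 * seq_len(100), fs)
  expect_warning(a <- mean_amplitude(flat), "degenerate|peak")
  expect_equal(a, 0)
})

test_that("regularity summarizes positive-peak intervals", {
  tr <- make_peak_train(pp_t = c(0, 0.2, 0.4, 0.6), pp_v = rep(1, 4),
                        np_t = c(0.1, 0.3, 0.5), np_v = rep(0, 3))
  r <- regularity(tr)
  expect_equal(r$avg, 0.2)
  expect_equal(r$sd, 0)

  tr2 <- make_peak_train(pp_t = c(0, 0.1, 0.3), pp_v = rep(1, 3),
                         np_t = c(0.05, 0.2), np_v = rep(0, 2))
  expect_equal(regularity(tr2)$avg, 0.15)

  # rectified 5 Hz: lobes every 0.1 s
  t <- (seq_len(30 * fs) - 1) / fs
  pk <- detect_peaks(abs(sin(2 * pi * 5 * t)), fs)
  expect_equal(regularity(pk)$avg, 0.1, tolerance = 1 / fs / 0.1)
})

test_that("axis averaging divides single-axis power by three", {
  set.seed(2)
  x <- rnorm(2048)
  sp1 <- averaged_spectrum(cbind(x, 0, 0), fs)
  sp3 <- averaged_spectrum(cbind(x, x, x), fs)
  expect_equal(sp1$power, sp3$power / 3, tolerance = 1e-12)
  expect_true(all(sp1$power >= 0))
  expect_equal(sp1$freq[1], 0)
  expect_equal(sp1$freq[length(sp1$freq)], fs / 2)
})

test_that("a 5 Hz tone peaks within one bin of 5 Hz", {
  t <- (seq_len(30 * fs) - 1) / fs
  sp <- averaged_spectrum(cbind(sin(2 * pi * 5 * t), 0, 0), fs)
  bin <- fs / 512
  expect_lt(abs(sp$freq[which.max(sp$power)] - 5), bin + 1e-9)
  expect_error(averaged_spectrum(matrix(rnorm(300), 100, 3), fs), "too short")
})

test_that("white-noise band power is a stable estimate", {
  # Monte-Carlo oracle: total 0-16 Hz power across seeded replicates stays
  # within 20% of the replicate mean
  totals <- sapply(1:10, function(s) {
    set.seed(s)
    sp <- averaged_spectrum(matrix(rnorm(3750 * 3), 3750, 3), fs)
    sum(sp$power[sp$freq <= 16])
  })
  expect_true(all(abs(totals - mean(totals)) / mean(totals) < 0.2))
})

test_that("spectral location features follow the power-weighted definitions", {
  sp <- point_mass_spectrum(5, 1)
  f <- spectral_features(sp)
  expect_equal(f$peak_freq, 5)
  expect_equal(f$mean_freq, 5)
  expect_equal(f$peak_power, 1)

  # equal mass at 4 and 6 Hz balances to 5 Hz
  expect_equal(spectral_features(point_mass_spectrum(c(4, 6), c(1, 1)))$mean_freq, 5)
  # (1, 3) at (2, 6) Hz -> (2*1 + 6*3) / 4 = 5
  f2 <- spectral_features(point_mass_spectrum(c(2, 6), c(1, 3)))
  expect_equal(f2$mean_freq, 5)
  expect_equal(f2$peak_freq, 6)
  expect_equal(f2$mean_power, 0) # nearest grid bin to 5 Hz carries no mass

  expect_warning(z <- spectral_features(point_mass_spectrum(5, 0)), "no power")
  expect_equal(z$peak_freq, 0)
})

test_that("adaptive bands partition the 0-16 Hz power", {
  sp <- point_mass_spectrum(c(1, 5, 10), c(2, 6, 4))
  bf <- band_features(sp, mean_freq = 5) # bands [0,2), [2,8], (8,16]
  expect_equal(bf$P_low, 2)
  expect_equal(bf$P_tr, 6)
  expect_equal(bf$P_high, 4)
  expect_equal(bf$Prl_low + bf$Prl_tr + bf$Prl_high, 1)

  solo <- band_features(point_mass_spectrum(5, 3), mean_freq = 5)
  expect_equal(solo$Prl_tr, 1)
  expect_equal(solo$Prl_low, 0)

  # mean frequency near the edge clamps the lower band away
  clamp <- band_features(point_mass_spectrum(c(1, 3), c(1, 1)), mean_freq = 2)
  expect_equal(clamp$P_low, 0)
  expect_equal(clamp$Prl_tr, 1)
})

test_that("the 76-feature vector is canonical, normalized and deterministic", {
  rec <- simulate_recording(default_profiles()[[4]], seed = 9)
  sig <- process_recording(rec)
  fv <- extract_features(sig)
  expect_identical(names(fv), feature_names())
  for (s in c("acc", "gyro", "disp", "angle")) {
    expect_equal(unname(fv[paste0(s, ".Prl_low")] + fv[paste0(s, ".Prl_tr")] +
                          fv[paste0(s, ".Prl_high")]), 1, tolerance = 1e-9)
    expect_equal(unname(fv[paste0(s, ".log_peak_power")]),
                 log10(unname(fv[paste0(s, ".peak_power")])))
  }
  expect_true(all(is.finite(fv)))
  expect_identical(fv, extract_features(sig))
})

test_that("mean frequency stays inside the power-carrying range", {
  for (s in 1:5) {
    set.seed(s)
    f1 <- runif(1, 2, 7); f2 <- f1 + runif(1, 0, 6)
    sp <- point_mass_spectrum(c(f1, f2), runif(2, 0.5, 2))
    mf <- spectral_features(sp)$mean_freq
    expect_gte(mf, f1 - fs / 512)
    expect_lte(mf, f2 + fs / 512)
  }
})

test_that("mean amplitude scales linearly with tremor amplitude", {
  base <- class_profile(3, tremor_amplitude = 0.4, duty_cycle = 1,
                        noise_sd = 0.001, drift_sd = 0.001)
  dbl <- class_profile(3, tremor_amplitude = 0.8, duty_cycle = 1,
                       noise_sd = 0.001, drift_sd = 0.001)
  f1 <- extract_features(process_recording(simulate_recording(base, seed = 4)))
  f2 <- extract_features(process_recording(simulate_recording(dbl, seed = 4)))
  expect_equal(unname(f2["acc.mean_amplitude"] / f1["acc.mean_amplitude"]),
               2, tolerance = 0.05)
})

test_that("tremor-free recordings sit far below marked tremor in amplitude", {
  prof <- default_profiles()
  f0 <- extract_features(process_recording(simulate_recording(prof[[1]], seed = 13)))
  f3 <- extract_features(process_recording(simulate_recording(prof[[4]], seed = 13)))
  expect_gte(unname(f3["acc.mean_amplitude"] / f0["acc.mean_amplitude"]), 5)
})
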