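test_that("FFT spectra locate pure tones to sub-resolution accuracy", {
  t <- seq(0, 5, by = 0.01)
  sp <- fft_spectrum(transient(t, cos(2 * pi * c_cm_ps * 180 * t)))
  pk <- find_beat_peaks(sp)
  expect_equal(nrow(pk), 1L)
  expect_lt(abs(pk$freq_cm1 - 180), sp$resolution_cm1 / 2)
  expect_equal(pk$magnitude, 1, tolerance = 0.02)  # unit-cosine normalization
  # a constant transient has nothing above numerical zero once the mean
  # is removed
  expect_lt(max(fft_spectrum(transient(t, rep(3, length(t))))$magnitude),
            1e-12)
  expect_error(fft_spectrum(transient(c(0, 1), c(1, 1))), "at least 8")
})

test_that("random tones across 20-600 cm^-1 are recovered within half a resolution element", {
  set.seed(21)
  t <- seq(0, 6, by = 0.005)
  for (k in 1:10) {
    nu <- stats::runif(1, 20, 600)
    sp <- fft_spectrum(transient(t, cos(2 * pi * c_cm_ps * nu * t + 0.3)))
    pk <- find_beat_peaks(sp, prominence_frac = 0.2)
    expect_equal(nrow(pk), 1L)
    expect_lt(abs(pk$freq_cm1 - nu), sp$resolution_cm1 / 2)
  }
})

test_that("115 and 180 cm^-1 tones are resolved on a 7.5 ps record", {
  t <- seq(0, 7.5, by = 0.005)
  y <- cos(2 * pi * c_cm_ps * 115 * t) + 0.8 * cos(2 * pi * c_cm_ps * 180 * t)
  pk <- find_beat_peaks(fft_spectrum(transient(t, y)), prominence_frac = 0.2)
  expect_equal(nrow(pk), 2L)
  expect_equal(pk$freq_cm1, c(115, 180), tolerance = 0.01)
})

test_that("decay isolation self-normalizes and recovers the pure beat", {
  t <- seq(0, 7.5, by = 0.005)
  # pure decaying exponential -> isolated transient ~ 0 everywhere
  iso0 <- isolate_beats(transient(t, 3 * exp(-t / 5)), baseline = "exp")
  expect_lt(max(abs(iso0$y)), 1e-6)
  # modulated decay -> ratio mode returns the modulation
  y <- exp(-t / 5) * (1 + 0.2 * cos(2 * pi * c_cm_ps * 180 * t))
  iso <- isolate_beats(transient(t, y), baseline = "exp")
  late <- t > 0.2
  expect_lt(max(abs(iso$y[late] - 0.2 * cos(2 * pi * c_cm_ps * 180 * t[late]))),
            0.01)
  # constant input, subtract mode -> all zeros
  isoc <- isolate_beats(transient(t, rep(4, length(t))),
                        baseline = "constant", mode = "subtract")
  expect_equal(isoc$y, rep(0, length(t)), tolerance = 1e-12)
  # ratio mode refuses a baseline through zero
  expect_error(isolate_beats(transient(t, exp(-t / 1.5) - 0.4),
                             baseline = "exp"), "crosses zero")
  # corrected-AIC auto selection prefers the bi-exponential when warranted
  yb <- 2 * exp(-t / 0.8) + exp(-t / 6)
  isob <- isolate_beats(transient(t, yb), baseline = "auto")
  expect_equal(isob$meta$baseline$kind, "biexp")
  expect_lt(max(abs(isob$y)), 1e-6)
})

test_that("FFT(eKE) equals column-wise analysis and masks beat-free regions", {
  t <- seq(0, 5, by = 0.01)
  beat <- 0.3 * cos(2 * pi * c_cm_ps * 180 * t)
  eke <- seq(100, 2100, by = 200)
  # the 180 cm^-1 beat is present only below 1000 cm^-1
  m <- sapply(eke, function(e) 1 + if (e < 1000) beat else 0 * beat)
  map <- trpes_map(t, eke, m)
  fe <- fft_vs_eke(map, bin_cm1 = NULL, floor_frac = 0,
                   baseline = "constant", mode = "subtract")
  i180 <- which.min(abs(fe$freq_cm1 - 180))
  hit <- fe$magnitude[i180, ] > 0.1
  expect_equal(hit, eke < 1000)
  # column-separability: identical to running the pieces by hand
  man <- fft_spectrum(isolate_beats(transient(t, m[, 1]),
                                    baseline = "constant", mode = "subtract"))
  expect_identical(fe$magnitude[, 1], man$magnitude)
  # a beat-free map is flat everywhere
  flat <- fft_vs_eke(trpes_map(t, eke, sapply(eke, function(e) exp(-t / 3))),
                     bin_cm1 = NULL, floor_frac = 0, baseline = "exp")
  expect_lt(max(flat$magnitude, na.rm = TRUE), 1e-6)
  expect_error(fft_vs_eke(trpes_map(t, c(1, 2), matrix(0, length(t), 2))),
               "empty map")
})

test_that("spectrograms are window-invariant for stationary tones", {
  t <- seq(0, 7.5, by = 0.005)
  sg <- fft_vs_time(transient(t, cos(2 * pi * c_cm_ps * 180 * t)))
  idx <- sg$freq_cm1 >= 165 & sg$freq_cm1 <= 195
  pkmag <- apply(sg$magnitude[, idx], 1, max)
  inner <- pkmag[sg$window_center_ps >= 2.5 & sg$window_center_ps <= 5]
  expect_lt((max(inner) - min(inner)) / max(inner), 0.02)
  expect_equal(mean(inner), 1, tolerance = 0.02)
  expect_error(fft_vs_time(transient(seq(0, 2, 0.01), rep(1, 201)),
                           window_fwhm_ps = 3), "longer than record")
})

test_that("spectrogram band decay tracks the beat dampening lifetime", {
  t <- seq(0, 7.5, by = 0.005)
  y <- exp(-t / 1.4) * cos(2 * pi * c_cm_ps * 180 * t)
  sg <- fft_vs_time(transient(t, y))
  bm <- band_magnitude(sg, 180, 15)
  use <- bm$window_center_ps >= 1 & bm$window_center_ps <= 5
  slope <- stats::coef(stats::lm(log(magnitude) ~ window_center_ps,
                                 data = bm[use, ]))[2]
  expect_equal(unname(-1 / slope), 1.4, tolerance = 0.15)
})

test_that("revival detection finds the analytic rephasing time of a level triplet", {
  # gaps 55 and 63 cm^-1 share the ~60 cm^-1 band; they rephase after
  # 1/(c * 8 cm^-1) = 4.17 ps
  wp <- wavepacket(c(0, 55, 118))
  tr <- survival_probability(wp, seq(0, 7.5, by = 0.005))
  sg <- fft_vs_time(tr)
  rv <- detect_revival(sg, 59, 12)
  expect_equal(length(rv), 1L)
  expect_equal(rv, 1 / (c_cm_ps * 8), tolerance = 0.1)
  # an undamped single tone never revives (monotone band)
  t <- seq(0, 7.5, by = 0.005)
  sg1 <- fft_vs_time(transient(t, cos(2 * pi * c_cm_ps * 180 * t)))
  expect_length(detect_revival(sg1, 180, 15), 0L)
  # neither does a monotonically damped tone
  sg2 <- fft_vs_time(transient(t, exp(-t / 1.4) * cos(2 * pi * c_cm_ps * 180 * t)))
  expect_length(detect_revival(sg2, 180, 15), 0L)
  expect_error(detect_revival(sg1, 5000, 10), "outside")
})
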