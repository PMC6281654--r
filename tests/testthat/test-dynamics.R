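test_that("survival probability has its closed forms", {
  # one level: no beats, P = 1 everywhere
  p1 <- survival_probability(wavepacket(137), seq(0, 5, by = 0.01))
  expect_equal(p1$y, rep(1, length(p1$y)), tolerance = 1e-14)
  # two equal levels: (1 + cos(2 pi c dE t)) / 2, first zero at 1/(2 c dE)
  t <- seq(0, 3, by = 0.002)
  p2 <- survival_probability(wavepacket(c(0, 179)), t)
  expect_equal(p2$y, (1 + cos(2 * pi * c_cm_ps * 179 * t)) / 2,
               tolerance = 1e-12)
  t0 <- 1 / (2 * c_cm_ps * 179)
  expect_lt(survival_probability(wavepacket(c(0, 179)), c(0, t0))$y[2], 1e-12)
  # beat period of the 179 cm^-1 gap is 0.1864 ps
  expect_equal(beat_period_ps(179), 0.18636, tolerance = 1e-4)
})

test_that("per-level phases shift individual beats; global and 2*pi phases are inert", {
  t <- seq(0, 3, by = 0.002)
  wp <- wavepacket(c(0, 179), mode_label = c("lo", "hi"))
  wq <- apply_mode_phase(wp, "hi", pi / 2)
  # the beat term picks up the phase difference: cos(w t + pi/2)
  expect_equal(survival_probability(wq, t)$y,
               (1 + cos(2 * pi * c_cm_ps * 179 * t + pi / 2)) / 2,
               tolerance = 1e-12)
  # phase 0 and 2*pi leave P unchanged at machine precision
  expect_equal(survival_probability(apply_mode_phase(wp, "hi", 0), t)$y,
               survival_probability(wp, t)$y, tolerance = 1e-14)
  expect_equal(survival_probability(apply_mode_phase(wp, "hi", 2 * pi), t)$y,
               survival_probability(wp, t)$y, tolerance = 1e-12)
  # a global phase on all levels is inert too
  wall <- apply_mode_phase(wp, ".", 0.77)
  expect_equal(survival_probability(wall, t)$y,
               survival_probability(wp, t)$y, tolerance = 1e-12)
  expect_warning(apply_mode_phase(wp, "absent", 1), "no level matches")
  expect_error(apply_mode_phase(wp, "absent", 1, on_missing = "error"),
               "no level matches")
})

test_that("P stays in [0, 1], is even at zero phase, and revives on commensurate grids", {
  set.seed(11)
  for (k in 1:20) {
    n <- sample(2:6, 1)
    e <- sort(stats::runif(n, 0, 600))
    while (any(diff(e) <= 0.5)) e <- sort(stats::runif(n, 0, 600))
    wp <- wavepacket(e, stats::runif(n, 0.1, 1), stats::runif(n, 0, 2 * pi))
    p <- survival_probability(wp, seq(0, 10, by = 0.02))
    expect_true(all(p$y >= -1e-12 & p$y <= 1 + 1e-12))
  }
  # evenness with zero phases
  wp0 <- wavepacket(c(0, 83, 190), c(0.8, 0.5, 0.33))
  tpos <- seq(0, 4, by = 0.01)
  expect_equal(survival_probability(wp0, tpos)$y,
               rev(survival_probability(wp0, rev(-tpos))$y),
               tolerance = 1e-12)
  # all gaps multiples of 60 cm^-1 -> full revival with period 1/(60 c)
  wpc <- wavepacket(c(0, 60, 120, 300), c(1, 0.8, 0.6, 0.4))
  period <- 1 / (c_cm_ps * 60)
  ta <- seq(0, 0.5, by = 0.005)
  expect_equal(survival_probability(wpc, ta)$y,
               survival_probability(wpc, ta + period)$y, tolerance = 1e-9)
})

test_that("IRF smoothing preserves constants, attenuates beats by the Gaussian factor", {
  t <- seq(0, 5, by = 0.005)
  const <- transient(t, rep(2.5, length(t)))
  expect_equal(smooth_with_irf(const, 0.2)$y, const$y, tolerance = 1e-12)
  # FWHM 0 is the identity, bit for bit
  tr <- transient(t, cos(2 * pi * c_cm_ps * 179 * t))
  expect_identical(smooth_with_irf(tr, 0)$y, tr$y)
  # cosine attenuation: exp(-(pi c nu w)^2 / (4 log 2))
  for (nu in c(115, 179, 358)) {
    trc <- transient(t, cos(2 * pi * c_cm_ps * nu * t))
    sm <- smooth_with_irf(trc, 0.1)
    mid <- t > 0.5 & t < 4.5
    att <- exp(-(pi * c_cm_ps * nu * 0.1)^2 / (4 * log(2)))
    expect_equal(max(sm$y[mid]), att, tolerance = 0.02)
  }
  expect_error(smooth_with_irf(transient(seq(0, 5, 0.05), rep(1, 101)), 0.1),
               "too coarse")
})

test_that("FFT of P peaks only at pairwise gaps with magnitude 2 a_n^2 a_m^2", {
  wp <- wavepacket(c(0, 83, 190), c(0.8, 0.5, 0.33))
  p <- wp$amplitudes^2
  tr <- survival_probability(wp, seq(0, 12.5, by = 0.005))
  pk <- find_beat_peaks(fft_spectrum(tr), prominence_frac = 0.05)
  gaps <- pairwise_gaps(wp$energies_cm1)        # 83, 107, 190
  expect_equal(nrow(pk), length(gaps))
  expect_equal(sort(pk$freq_cm1), gaps, tolerance = 0.01)
  # gaps 83 (0-83), 107 (83-190), 190 (0-190); pk is freq-sorted
  want <- c(2 * p[1] * p[2], 2 * p[2] * p[3], 2 * p[1] * p[3])
  expect_equal(pk$magnitude, want, tolerance = 0.01)
})
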