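test_that("synthetic LIF spectra follow the geometric progression rules", {
  # one progression: sticks at 0, 179, 358, 537 with ratio-0.7 intensities
  sp <- generate_lif_spectrum(data.frame(freq_cm1 = 179, max_v = 3,
                                         decay_ratio = 0.7))
  expect_equal(sp$levels$energy_cm1, c(0, 179, 358, 537))
  expect_equal(sp$levels$intensity, c(1, 0.7, 0.49, 0.343))
  # two progressions with combinations: 600 = 179 + 421 present
  sp2 <- generate_lif_spectrum(data.frame(freq_cm1 = c(179, 421),
                                          max_v = c(1, 1),
                                          decay_ratio = c(0.7, 0.5)))
  expect_true(600 %in% sp2$levels$energy_cm1)
  expect_false(600 %in% generate_lif_spectrum(
    data.frame(freq_cm1 = c(179, 421), max_v = c(1, 1),
               decay_ratio = c(0.7, 0.5)),
    combinations = FALSE)$levels$energy_cm1)
  # the approximate level list carries all assigned beat gaps
  gaps <- pairwise_gaps(ma_lif_spectrum()$levels$energy_cm1)
  for (g in c(55, 63, 116, 179)) expect_true(any(abs(gaps - g) < 0.5))
})

test_that("ionization models are row-stochastic with Delta-v preservation", {
  expect_error(ionization_model(c(0, 179), matrix(c(1, 0.5, 0, 0.4), 2, 2),
                                2000), "sum to 1")
  ion <- ma_ionization_model(ma_lif_spectrum(), leak = 0.2)
  expect_equal(rowSums(ion$fc), rep(1, nrow(ion$fc)), tolerance = 1e-12)
  # nu179 v = 2 level projects mainly onto cation v+ = 2
  i <- which(ma_lif_spectrum()$levels$mode_label == "nu179_v2")
  expect_equal(ion$fc[i, 3], 0.8)
  expect_equal(ion$fc[i, 1], 0.2)
})

test_that("interference requires a common final state", {
  sp <- stick_spectrum(c(0, 179, 358), c(1, 1, 1))
  pm <- pump_pulse(500, center_cm1 = 150)
  t <- seq(0, 5, by = 0.01)
  eke <- seq(0, 2500, by = 25)
  # diagonal FC: every level its own cation state -> no beats anywhere
  iond <- ionization_model(c(0, 179, 358), diag(3), 1500, 100)
  mapd <- generate_trpes(synthetic_spec(sp, pm, iond, t_ps = t, eke_cm1 = eke,
                                        irf_fwhm_ps = 0, noise_sigma = 0))
  expect_lt(max(apply(mapd$intensity, 2, function(x) max(x) - min(x))), 1e-12)
  # single shared final state: beats at every pairwise gap, localized on
  # the (single, highest-eKE) photoelectron feature
  ion0 <- ionization_model(0, matrix(1, 3, 1), 1500, 250)
  map0 <- generate_trpes(synthetic_spec(sp, pm, ion0, t_ps = t, eke_cm1 = eke,
                                        irf_fwhm_ps = 0, noise_sigma = 0))
  mid <- integrate_eke(map0)
  pk <- find_beat_peaks(fft_spectrum(mid), prominence_frac = 0.05)
  expect_equal(sort(pk$freq_cm1), c(179, 358), tolerance = 0.05)
  modulation <- apply(map0$intensity, 2, function(x) max(x) - min(x))
  # all beat modulation sits inside the feature spanning the channel
  # centers (1500..1858) broadened by the 250 cm^-1 bandwidth
  expect_true(all(eke[modulation > 0.05 * max(modulation)] > 1200))
})

test_that("every generated channel conserves energy", {
  sp <- ma_lif_spectrum()
  spec <- ma_scenario("348", noise_sigma = 0, rng_seed = 1)
  map <- generate_trpes(spec)
  ch <- map$meta$channels
  wp <- build_wavepacket(spec$spectrum, spec$pump)
  ion <- spec$ionization
  resid <- ch$eke_center_cm1 + ion$cation_levels_cm1[ch$v + 1L] -
    wp$energies_cm1[ch$n]
  expect_equal(resid, rep(ion$eke_offset_cm1, nrow(ch)), tolerance = 1e-9)
})

test_that("the eKE-integrated generator reduces to the 1-D correlator", {
  # matched configuration: equal populations, one shared final state,
  # undamped, noiseless, final-state eKE reference
  sp <- stick_spectrum(c(0, 179, 358), c(1, 1, 1))
  pm <- pump_pulse(1e6, center_cm1 = 179)    # flat pump -> equal amplitudes
  ion <- ionization_model(0, matrix(1, 3, 1), 1500, 250)
  spec <- synthetic_spec(sp, pm, ion, t_ps = seq(0, 5, by = 0.005),
                         eke_cm1 = seq(0, 3000, by = 10), decay_ps = 20,
                         irf_fwhm_ps = 0, noise_sigma = 0)
  y2 <- integrate_eke(generate_trpes(spec, eke_reference = "final_state"))$y
  wp <- build_wavepacket(sp, pm)
  y1 <- survival_probability(wp, spec$t_ps)$y * exp(-spec$t_ps / 20)
  expect_equal(y2 / max(y2), y1 / max(y1), tolerance = 1e-6)
})

test_that("noise is seed-reproducible around a seed-independent core", {
  sp <- stick_spectrum(c(0, 179), c(1, 1))
  pm <- pump_pulse(500, center_cm1 = 89.5)
  ion <- ionization_model(0, matrix(1, 2, 1), 1500, 250)
  mk <- function(sig, seed) generate_trpes(synthetic_spec(
    sp, pm, ion, t_ps = seq(0, 2, by = 0.01), eke_cm1 = seq(500, 2500, 100),
    noise_sigma = sig, rng_seed = seed))
  core <- mk(0, 1)$intensity
  expect_identical(core, mk(0, 99)$intensity)   # core independent of seed
  a1 <- mk(0.02, 7)$intensity
  expect_identical(a1, mk(0.02, 7)$intensity)   # same seed, same noise
  a2 <- mk(0.02, 8)$intensity
  expect_gt(max(abs(a1 - a2)), 0)               # different seed differs
  # both realizations scatter around the same core at the right scale
  sig_abs <- 0.02 * max(abs(core))
  expect_lt(max(abs(a1 - core)), 6 * sig_abs)
  expect_equal(stats::sd(a1 - core), sig_abs, tolerance = 0.1)
})

test_that("fixture suites are byte-identical under a fixed seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  make_fixture_suite(d1, seed = 7)
  make_fixture_suite(d2, seed = 7)
  fls <- list.files(d1)
  expect_true(all(c("348_map.csv", "344_map.csv", "330_map.csv",
                    "menA330_map.csv", "beat_free_map.csv",
                    "manifest.json") %in% fls))
  for (f in fls)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  # null recovery on the beat-free control: any "beat" the seeding picks
  # out of the noise floor fits with amplitude below 3x the noise level
  tr <- read_transient(file.path(d1, "beat_free_transient.csv"))
  i <- seq(1, length(tr$t_ps), by = 2)
  tr <- transient(tr$t_ps[i], tr$y[i])
  m <- init_from_fft(tr, max_beats = 2)
  if (!is.null(m$beats)) {
    fit <- fit_transient(tr, m, multistart = 1)
    # observed modulation depth: fitted amplitude times the IRF
    # attenuation at its frequency (B itself is the pre-IRF amplitude)
    b <- fit$model$beats$amplitude *
      exp(-(pi * c_cm_ps * fit$model$beats$freq_cm1 * 0.1)^2 / (4 * log(2)))
    expect_true(all(abs(b) < 3 * 0.01))
  } else {
    expect_null(m$beats)
  }
})

test_that("the MA-like ionization model spreads the 180 cm^-1 beat over eKE", {
  map <- generate_trpes(ma_scenario("348", rng_seed = 2))
  fe <- fft_vs_eke(map, bin_cm1 = 100, baseline = "exp", floor_frac = 0.05)
  i180 <- which.min(abs(fe$freq_cm1 - 179))
  prof <- fe$magnitude[i180, ]
  hits <- which(prof > 0.3 * max(prof, na.rm = TRUE))
  expect_gte(length(hits), 2L)
})
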