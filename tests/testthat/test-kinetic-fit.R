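test_that("the kinetic model evaluates to its closed forms", {
  t <- seq(0, 7.5, by = 0.01)
  # no beats, no IRF: a plain gated exponential
  m <- beat_fit_model(data.frame(amplitude = 2, lifetime_ps = 3),
                      irf_fwhm_ps = 0, offset = 0.1)
  expect_equal(model_eval(m, t)$y, 2 * exp(-t / 3) + 0.1, tolerance = 1e-12)
  # zero-amplitude beats equal the decay-only model exactly
  mb0 <- beat_fit_model(data.frame(amplitude = 2, lifetime_ps = 3),
                        data.frame(amplitude = 0, freq_cm1 = 180,
                                   phase_rad = 0, damp_ps = 1),
                        irf_fwhm_ps = 0, offset = 0.1)
  expect_equal(model_eval(mb0, t)$y, model_eval(m, t)$y, tolerance = 1e-14)
  # undamped 180 cm^-1 beat, no IRF: exact modulated decay with 0.1864 ps
  # period
  mb <- beat_fit_model(data.frame(amplitude = 1, lifetime_ps = 5),
                       data.frame(amplitude = 0.2, freq_cm1 = 180,
                                  phase_rad = 0, damp_ps = Inf),
                       irf_fwhm_ps = 0)
  expect_equal(model_eval(mb, t)$y,
               exp(-t / 5) * (1 + 0.2 * cos(2 * pi * c_cm_ps * 180 * t)),
               tolerance = 1e-12)
  # additive mode
  ma <- beat_fit_model(data.frame(amplitude = 1, lifetime_ps = 5),
                       data.frame(amplitude = 0.2, freq_cm1 = 180,
                                  phase_rad = 0, damp_ps = Inf),
                       irf_fwhm_ps = 0, beats_mode = "additive")
  expect_equal(model_eval(ma, t)$y,
               exp(-t / 5) + 0.2 * cos(2 * pi * c_cm_ps * 180 * t),
               tolerance = 1e-12)
})

test_that("FFT seeding finds the beats that are present and nothing else", {
  t <- seq(0, 7.5, by = 0.01)
  tr1 <- make_beat_transient(t, 180, 0.2, Inf)
  m1 <- init_from_fft(tr1)
  expect_equal(nrow(m1$beats), 1L)
  expect_lt(abs(m1$beats$freq_cm1 - 180), 1 / (c_cm_ps * 7.5))
  # beat-free decay seeds no beat components
  m0 <- init_from_fft(transient(t, 2.3 * exp(-t / 5)))
  expect_null(m0$beats)
  # two beats seed two components
  m2 <- init_from_fft(make_beat_transient(t, c(115, 180), c(0.2, 0.15), Inf))
  expect_equal(nrow(m2$beats), 2L)
  expect_equal(sort(m2$beats$freq_cm1), c(115, 180), tolerance = 0.05)
})

test_that("noiseless self-consistency recovers every free parameter", {
  t <- seq(0, 7.5, by = 0.025)
  truth <- beat_fit_model(data.frame(amplitude = 1, lifetime_ps = 20),
                          data.frame(amplitude = 0.15, freq_cm1 = 180,
                                     phase_rad = 0.3, damp_ps = 1.4,
                                     group = 1L),
                          irf_fwhm_ps = 0.1, offset = 0.02)
  tr <- model_eval(truth, t)
  fit <- fit_transient(tr, init_from_fft(tr), multistart = 2, seed = 3)
  expect_true(fit$converged)
  p <- stats::setNames(fit$parameters$value, fit$parameters$name)
  expect_equal(p[["A1"]], 1, tolerance = 1e-4)
  expect_equal(p[["tau1"]], 20, tolerance = 1e-4)
  expect_equal(p[["B1"]], 0.15, tolerance = 1e-4)
  expect_equal(p[["nu1"]], 180, tolerance = 1e-6)
  expect_equal(p[["taud1"]], 1.4, tolerance = 1e-4)
  expect_equal(p[["offset"]], 0.02, tolerance = 1e-3)
  dphi <- abs(p[["phi1"]] - 0.3) %% (2 * pi)
  expect_lt(min(dphi, 2 * pi - dphi), 1e-4)
  # the paper's own consistency check: fitted frequency vs FFT peak
  pk <- find_beat_peaks(fft_spectrum(isolate_beats(tr, baseline = "exp")))
  expect_lt(abs(p[["nu1"]] - pk$freq_cm1[which.max(pk$magnitude)]),
            1 / (c_cm_ps * 7.5))
})

test_that("fits demand enough data per free parameter", {
  t <- seq(0, 1, by = 0.05)
  tr <- make_beat_transient(t, 180, 0.2, Inf)
  m <- init_from_fft(tr)
  expect_error(fit_transient(transient(t[1:20], tr$y[1:20]), m),
               "5 data points per free parameter")
})

test_that("seeded replicates recover frequency and dampening with honest errors", {
  t <- seq(0, 7.5, by = 0.01)
  truth <- beat_fit_model(data.frame(amplitude = 1, lifetime_ps = 20),
                          data.frame(amplitude = 0.15, freq_cm1 = 180,
                                     phase_rad = 1.1, damp_ps = 1.4,
                                     group = 1L),
                          irf_fwhm_ps = 0.1)
  y0 <- model_eval(truth, t)$y
  res <- 1 / (c_cm_ps * 7.5)
  errs_nu <- errs_tau <- cover <- numeric(0)
  for (r in 1:20) {
    set.seed(3000 + r)
    y <- y0 + stats::rnorm(length(y0), sd = 0.02 * max(y0))
    fit <- fit_transient(transient(t, y),
                         init_from_fft(transient(t, y), max_beats = 1,
                                       prominence_frac = 0.2),
                         multistart = 1, seed = r)
    p <- stats::setNames(fit$parameters$value, fit$parameters$name)
    se <- stats::setNames(fit$parameters$std_error, fit$parameters$name)
    errs_nu <- c(errs_nu, abs(p[["nu1"]] - 180))
    errs_tau <- c(errs_tau, abs(p[["taud1"]] - 1.4) / 1.4)
    cover <- c(cover, abs(p[["taud1"]] - 1.4) <= se[["taud1"]])
  }
  expect_lt(stats::median(errs_nu), res)
  expect_lt(stats::median(errs_tau), 0.2)
  # +-1 SE interval coverage should be in the right ballpark
  expect_gte(mean(cover), 0.35)
  expect_lte(mean(cover), 0.95)
})
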