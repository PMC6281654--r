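#' 2-D TR-PES map
#'
#' Photoelectron intensity as a function of pump-probe delay and
#' electron kinetic energy (eKE).
#'
#' @param t_ps Uniform, increasing delay grid (ps).
#' @param eke_cm1 Increasing eKE grid (cm^-1).
#' @param intensity Matrix of intensities, `length(t_ps)` rows by
#'   `length(eke_cm1)` columns.
#' @param meta Named list of provenance metadata.
#' @return An object of class `trpes_map`.
#' @export
trpes_map <- function(t_ps, eke_cm1, intensity, meta = list()) {
  intensity <- as.matrix(intensity)
  if (nrow(intensity) != length(t_ps) || ncol(intensity) != length(eke_cm1))
    stop("'intensity' must be length(t_ps) x length(eke_cm1)")
  if (any(diff(t_ps) <= 0) || any(diff(eke_cm1) <= 0))
    stop("grids must be strictly increasing")
  dt <- diff(t_ps)
  if (max(dt) - min(dt) > 1e-9) stop("'t_ps' must be uniform")
  structure(list(t_ps = as.numeric(t_ps), eke_cm1 = as.numeric(eke_cm1),
                 intensity = intensity, meta = meta),
            class = "trpes_map")
}

#' @export
print.trpes_map <- function(x, ...) {
  cat(sprintf("<trpes_map> %d delays x %d eKE bins, t %.3g-%.3g ps, eKE %.0f-%.0f cm^-1\n",
              length(x$t_ps), length(x$eke_cm1),
              min(x$t_ps), max(x$t_ps), min(x$eke_cm1), max(x$eke_cm1)))
  invisible(x)
}

#' Integrate a TR-PES map over an eKE window
#'
#' @param map A [trpes_map()].
#' @param eke_range Length-2 numeric range in cm^-1, or NULL for the
#'   whole axis.
#' @return A [transient()].
#' @export
integrate_eke <- function(map, eke_range = NULL) {
  stopifnot(inherits(map, "trpes_map"))
  keep <- if (is.null(eke_range)) rep(TRUE, length(map$eke_cm1)) else
    map$eke_cm1 >= eke_range[1] & map$eke_cm1 <= eke_range[2]
  if (!any(keep)) stop("no eKE bins inside 'eke_range'")
  transient(map$t_ps, rowSums(map$intensity[, keep, drop = FALSE]),
            meta = c(map$meta,
                     list(eke_range = if (is.null(eke_range))
                       range(map$eke_cm1) else eke_range)))
}

taper_window <- function(n, taper) {
  i <- seq_len(n) - 1L
  switch(taper,
         hann = 0.5 * (1 - cos(2 * pi * i / (n - 1))),
         hamming = 0.54 - 0.46 * cos(2 * pi * i / (n - 1)),
         rect = rep(1, n),
         stop("unknown taper: ", taper))
}

#' Beat-frequency FFT spectrum of a transient
#'
#' Mean-subtracted, tapered, zero-padded magnitude spectrum with the
#' frequency axis in wavenumbers (`nu = f / c`).  Negative delays are
#' excluded (beats exist only for t > 0).  Magnitudes are normalized so
#' that a unit-amplitude cosine spanning the whole record gives a unit
#' peak; the nominal resolution is `1 / (c T)` for record length `T`.
#'
#' @param tr A [transient()] with at least 8 samples at t >= 0.
#' @param taper `"hann"` (default), `"hamming"` or `"rect"`.
#' @param pad_factor Zero-padding factor (default 8); the FFT length is
#'   the next power of two >= `pad_factor * n`.
#' @return An object of class `fft_spectrum` with fields `freq_cm1`,
#'   `magnitude`, `resolution_cm1` and the analysis parameters.
#' @seealso [find_beat_peaks()], [fft_vs_time()], [fft_vs_eke()]
#' @export
fft_spectrum <- function(tr, taper = c("hann", "hamming", "rect"),
                         pad_factor = 8L) {
  stopifnot(inherits(tr, "transient"))
  taper <- match.arg(taper)
  keep <- tr$t_ps >= 0
  y <- tr$y[keep]
  n <- length(y)
  if (n < 8L) stop("need at least 8 samples at t >= 0")
  dt <- t_step(tr)
  w <- taper_window(n, taper)
  yw <- (y - mean(y)) * w
  nfft <- 2^ceiling(log2(n * max(1L, as.integer(pad_factor))))
  ft <- stats::fft(c(yw, rep(0, nfft - n)))
  nh <- nfft %/% 2L
  freq_cm1 <- (0:nh) / (nfft * dt) / .c_cm_ps
  structure(list(freq_cm1 = freq_cm1,
                 magnitude = 2 * Mod(ft[1:(nh + 1L)]) / sum(w),
                 resolution_cm1 = 1 / (.c_cm_ps * n * dt),
                 taper = taper, pad_factor = as.integer(pad_factor),
                 dt_ps = dt, n_samples = n),
            class = "fft_spectrum")
}

#' @export
print.fft_spectrum <- function(x, ...) {
  cat(sprintf("<fft_spectrum> 0-%.0f cm^-1, resolution %.2f cm^-1 (%s taper, pad %d)\n",
              max(x$freq_cm1), x$resolution_cm1, x$taper, x$pad_factor))
  invisible(x)
}

# peak prominence: height above the higher of the two valleys separating
# the peak from taller neighbours (or the record edge)
peak_prominence <- function(mag, i) {
  left <- mag[seq_len(i - 1L)]
  right <- mag[seq.int(i + 1L, length(mag))]
  hi_l <- which(left > mag[i])
  hi_r <- which(right > mag[i])
  vall <- min(if (length(hi_l)) left[seq.int(max(hi_l), i - 1L)] else left)
  valr <- min(if (length(hi_r)) right[seq_len(min(hi_r))] else right)
  mag[i] - max(vall, valr)
}

#' Locate beat peaks in an FFT spectrum
#'
#' Finds local maxima whose prominence exceeds `prominence_frac` of the
#' global maximum, excluding the DC region, and refines each frequency
#' by 3-point parabolic interpolation.
#'
#' @param spec An [fft_spectrum()].
#' @param prominence_frac Prominence threshold as a fraction of the
#'   maximum magnitude (default 0.05).
#' @param min_freq_cm1 Peaks below this are discarded; defaults to the
#'   spectral resolution (excludes the DC bin and its leakage).
#' @param max_freq_cm1 Optional upper frequency cut; `NULL` (default)
#'   searches up to Nyquist.
#' @return A data.frame with columns `freq_cm1`, `magnitude` and
#'   `prominence`, sorted by frequency (possibly 0 rows).
#' @export
find_beat_peaks <- function(spec, prominence_frac = 0.05,
                            min_freq_cm1 = NULL, max_freq_cm1 = NULL) {
  stopifnot(inherits(spec, "fft_spectrum"))
  if (is.null(min_freq_cm1)) min_freq_cm1 <- spec$resolution_cm1
  if (is.null(max_freq_cm1)) max_freq_cm1 <- Inf
  m <- spec$magnitude
  f <- spec$freq_cm1
  n <- length(m)
  out <- data.frame(freq_cm1 = numeric(0), magnitude = numeric(0),
                    prominence = numeric(0))
  if (n < 3L || max(m) <= 0) return(out)
  cand <- which(m[2:(n - 1L)] > m[1:(n - 2L)] &
                  m[2:(n - 1L)] >= m[3:n]) + 1L
  cand <- cand[f[cand] >= min_freq_cm1 & f[cand] <= max_freq_cm1]
  if (!length(cand)) return(out)
  prom <- vapply(cand, function(i) peak_prominence(m, i), numeric(1))
  keep <- prom >= prominence_frac * max(m)
  cand <- cand[keep]
  prom <- prom[keep]
  if (!length(cand)) return(out)
  df <- f[2] - f[1]
  refine <- vapply(cand, function(i) {
    m1 <- m[i - 1L]; m2 <- m[i]; m3 <- m[i + 1L]
    den <- m1 - 2 * m2 + m3
    delta <- if (den == 0) 0 else 0.5 * (m1 - m3) / den
    f[i] + delta * df
  }, numeric(1))
  out <- data.frame(freq_cm1 = refine, magnitude = m[cand],
                    prominence = prom)
  out[order(out$freq_cm1), , drop = FALSE]
}

# exponential decay convolved with a Gaussian IRF (analytic form);
# sigma = 0 reduces to the step-function exponential
exp_conv_irf <- function(t, tau, sigma) {
  if (sigma <= 0) return(ifelse(t >= 0, exp(-t / tau), 0))
  erfc <- function(x) 2 * stats::pnorm(-x * sqrt(2))
  0.5 * exp(sigma^2 / (2 * tau^2) - t / tau) *
    erfc((sigma / tau - t / sigma) / sqrt(2))
}

decay_eval <- function(t, kind, par, sigma) {
  switch(kind,
         constant = rep(par[["c0"]], length(t)),
         exp = par[["c0"]] + par[["A1"]] * exp_conv_irf(t, par[["tau1"]], sigma),
         biexp = par[["c0"]] +
           par[["A1"]] * exp_conv_irf(t, par[["tau1"]], sigma) +
           par[["A2"]] * exp_conv_irf(t, par[["tau2"]], sigma),
         stop("unknown baseline kind: ", kind))
}

aicc_from_rss <- function(rss, n, k) {
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / max(n - k - 1, 1)
}

# fit a slowly-varying decay baseline to (t, y); returns list(kind, par,
# fitted, aicc)
fit_decay_baseline <- function(t, y, kind = c("auto", "constant", "exp", "biexp"),
                               irf_fwhm_ps = 0) {
  kind <- match.arg(kind)
  sigma <- fwhm_to_sigma(irf_fwhm_ps)
  span <- max(t) - min(t)
  fit_one <- function(k) {
    if (k == "constant") {
      par <- c(c0 = mean(y))
      fitted <- rep(par[["c0"]], length(y))
      return(list(kind = k, par = par, fitted = fitted,
                  aicc = aicc_from_rss(sum((y - fitted)^2) + 1e-300,
                                       length(y), 1)))
    }
    start <- if (k == "exp")
      c(A1 = max(y) - min(y), tau1 = span / 3, c0 = min(y))
    else
      c(A1 = (max(y) - min(y)) / 2, tau1 = span / 10,
        A2 = (max(y) - min(y)) / 2, tau2 = span / 2, c0 = min(y))
    lower <- rep(-Inf, length(start))
    names(lower) <- names(start)
    lower[grep("^tau", names(start))] <- 1e-3
    fit <- try(minpack.lm::nls.lm(
      par = start,
      fn = function(p) y - decay_eval(t, k, as.list(p), sigma),
      lower = lower,
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (inherits(fit, "try-error")) return(NULL)
    par <- fit$par
    fitted <- decay_eval(t, k, as.list(par), sigma)
    list(kind = k, par = unlist(par), fitted = fitted,
         aicc = aicc_from_rss(sum((y - fitted)^2) + 1e-300,
                              length(y), length(par)))
  }
  cands <- if (kind == "auto") c("constant", "exp", "biexp") else kind
  fits <- Filter(Negate(is.null), lapply(cands, fit_one))
  if (!length(fits)) stop("baseline fit failure")
  fits[[which.min(vapply(fits, `[[`, numeric(1), "aicc"))]]
}

#' Isolate quantum beats from the overall population decay
#'
#' Fits a slowly-varying baseline (constant, IRF-convolved single
#' exponential, or bi-exponential; `"auto"` picks the best by corrected
#' AIC) to the t >= 0 part of a transient and returns either the ratio
#' `y / baseline - 1` (default, "normalizing to the overall decay") or
#' the difference `y - baseline`.
#'
#' @param tr A [transient()].
#' @param baseline `"auto"` (default), `"constant"`, `"exp"` or
#'   `"biexp"`.
#' @param mode `"ratio"` (default) or `"subtract"`.
#' @param irf_fwhm_ps Gaussian IRF FWHM used in the baseline model (ps).
#' @return A [transient()] restricted to t >= 0; the fitted baseline
#'   parameters are recorded in `meta$baseline`.
#' @export
isolate_beats <- function(tr, baseline = c("auto", "constant", "exp", "biexp"),
                          mode = c("ratio", "subtract"),
                          irf_fwhm_ps = 0) {
  stopifnot(inherits(tr, "transient"))
  baseline <- match.arg(baseline)
  mode <- match.arg(mode)
  keep <- tr$t_ps >= 0
  t <- tr$t_ps[keep]
  y <- tr$y[keep]
  if (length(t) < 8L) stop("too few samples at t >= 0")
  bl <- fit_decay_baseline(t, y, baseline, irf_fwhm_ps)
  iso <- if (mode == "ratio") {
    if (any(bl$fitted <= 0))
      stop("baseline crosses zero; ratio mode impossible (use mode = 'subtract')")
    y / bl$fitted - 1
  } else {
    y - bl$fitted
  }
  meta <- tr$meta
  meta$baseline <- list(kind = bl$kind, par = bl$par, mode = mode,
                        irf_fwhm_ps = irf_fwhm_ps)
  transient(t, iso, meta)
}

#' Beat spectra as a function of electron kinetic energy, FFT(eKE)
#'
#' Bins the eKE axis of a TR-PES map, then applies [isolate_beats()]
#' followed by [fft_spectrum()] to each binned column.  Columns whose
#' peak intensity falls below `floor_frac` of the map maximum are
#' masked (all-NA), not zero-filled.
#'
#' @param map A [trpes_map()].
#' @param bin_cm1 Minimum eKE bin width in cm^-1 (default 50); native
#'   columns are grouped to reach it.  `NULL` keeps native columns.
#' @param floor_frac Intensity floor as a fraction of the map maximum
#'   (default 0.02).
#' @param baseline,mode,irf_fwhm_ps Passed to [isolate_beats()].
#' @param taper,pad_factor Passed to [fft_spectrum()].
#' @return An object of class `fft_eke`: list with `freq_cm1`,
#'   `eke_cm1` (bin centers), `magnitude` (frequency x bin matrix, NA
#'   columns where masked), `mask` (logical, TRUE = analyzed) and
#'   `resolution_cm1`.
#' @export
fft_vs_eke <- function(map, bin_cm1 = 50, floor_frac = 0.02,
                       baseline = "auto", mode = "ratio",
                       irf_fwhm_ps = 0,
                       taper = "hann", pad_factor = 8L) {
  stopifnot(inherits(map, "trpes_map"))
  if (length(map$eke_cm1) == 0L || all(map$intensity == 0))
    stop("empty map")
  eke <- map$eke_cm1
  grp <- if (is.null(bin_cm1)) seq_along(eke) else
    floor((eke - eke[1]) / bin_cm1)
  idx <- split(seq_along(eke), grp)
  centers <- vapply(idx, function(i) mean(eke[i]), numeric(1))
  cols <- lapply(idx, function(i) rowSums(map$intensity[, i, drop = FALSE]))
  # robust column strength: time-averaged intensity (a noise-only column
  # can reach a large instantaneous max but averages to ~zero)
  strength <- vapply(cols, function(yy) mean(abs(yy)), numeric(1))
  mask <- strength >= floor_frac * max(strength)
  spec1 <- NULL
  mags <- vector("list", length(cols))
  for (j in seq_along(cols)) {
    if (!mask[j]) next
    tr <- transient(map$t_ps, cols[[j]])
    sp <- tryCatch({
      iso <- isolate_beats(tr, baseline = baseline, mode = mode,
                           irf_fwhm_ps = irf_fwhm_ps)
      fft_spectrum(iso, taper = taper, pad_factor = pad_factor)
    }, error = function(e) NULL)
    if (is.null(sp)) {      # unnormalizable column: mask it
      mask[j] <- FALSE
      next
    }
    if (is.null(spec1)) spec1 <- sp
    mags[[j]] <- sp$magnitude
  }
  if (is.null(spec1)) stop("all eKE columns below the intensity floor")
  magmat <- matrix(NA_real_, nrow = length(spec1$freq_cm1),
                   ncol = length(cols))
  for (j in seq_along(cols)) if (mask[j]) magmat[, j] <- mags[[j]]
  structure(list(freq_cm1 = spec1$freq_cm1, eke_cm1 = unname(centers),
                 magnitude = magmat, mask = unname(mask),
                 resolution_cm1 = spec1$resolution_cm1,
                 params = list(bin_cm1 = bin_cm1, floor_frac = floor_frac,
                               baseline = baseline, mode = mode,
                               taper = taper, pad_factor = pad_factor)),
            class = "fft_eke")
}

#' @export
print.fft_eke <- function(x, ...) {
  cat(sprintf("<fft_eke> %d eKE bins (%d analyzed), freq 0-%.0f cm^-1\n",
              length(x$eke_cm1), sum(x$mask), max(x$freq_cm1)))
  invisible(x)
}

#' Sliding-window beat spectrogram, FFT(delay)
#'
#' Computes tapered-window FFT magnitude spectra as a function of the
#' window center delay, revealing beat dampening and revivals.  The
#' window is Gaussian with the given FWHM; within each window the
#' (window-weighted) mean is subtracted before transforming.  With
#' `normalization = "global"` magnitudes are comparable across windows
#' (a stationary tone gives a constant band); `"per-window-max"`
#' rescales every window to unit maximum, which emphasises weak late
#' structure at the cost of absolute scale.
#'
#' @param tr A [transient()].
#' @param window_fwhm_ps Gaussian window FWHM in ps (default 2.5).
#' @param step_ps Window-center step in ps (default 0.1).
#' @param pad_factor FFT zero-padding factor (default 8).
#' @param taper Window shape; only `"gaussian"` is implemented.
#' @param normalization `"global"` (default) or `"per-window-max"`.
#' @return An object of class `spectrogram`: `window_center_ps`,
#'   `freq_cm1`, `magnitude` (window x frequency matrix),
#'   `window_fwhm_ps`, `step_ps`, `resolution_cm1` (nominal,
#'   `1/(c * window FWHM)`).
#' @export
fft_vs_time <- function(tr, window_fwhm_ps = 2.5, step_ps = 0.1,
                        pad_factor = 8L, taper = "gaussian",
                        normalization = c("global", "per-window-max")) {
  stopifnot(inherits(tr, "transient"))
  normalization <- match.arg(normalization)
  if (taper != "gaussian") stop("only the Gaussian window is implemented")
  keep <- tr$t_ps >= 0
  t <- tr$t_ps[keep]
  y <- tr$y[keep]
  n <- length(t)
  span <- t[n] - t[1]
  if (window_fwhm_ps > span) stop("window longer than record")
  dt <- t_step(tr)
  centers <- seq(t[1], t[n], by = step_ps)
  nfft <- 2^ceiling(log2(n * max(1L, as.integer(pad_factor))))
  nh <- nfft %/% 2L
  freq_cm1 <- (0:nh) / (nfft * dt) / .c_cm_ps
  mag <- matrix(0, nrow = length(centers), ncol = nh + 1L)
  for (k in seq_along(centers)) {
    w <- gauss_peak1(t, centers[k], window_fwhm_ps)
    sw <- sum(w)
    yw <- (y - sum(w * y) / sw) * w
    ft <- stats::fft(c(yw, rep(0, nfft - n)))
    mag[k, ] <- 2 * Mod(ft[1:(nh + 1L)]) / sw
  }
  if (normalization == "per-window-max") {
    mx <- apply(mag, 1, max)
    mx[mx == 0] <- 1
    mag <- mag / mx
  }
  structure(list(window_center_ps = centers, freq_cm1 = freq_cm1,
                 magnitude = mag, window_fwhm_ps = window_fwhm_ps,
                 step_ps = step_ps,
                 resolution_cm1 = 1 / (.c_cm_ps * window_fwhm_ps),
                 normalization = normalization),
            class = "spectrogram")
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("<spectrogram> %d windows (FWHM %.2f ps, step %.2f ps), freq 0-%.0f cm^-1\n",
              length(x$window_center_ps), x$window_fwhm_ps, x$step_ps,
              max(x$freq_cm1)))
  invisible(x)
}

#' Band-integrated spectrogram magnitude
#'
#' @param sg A [fft_vs_time()] spectrogram.
#' @param freq_cm1 Band center in cm^-1.
#' @param band_halfwidth_cm1 Half-width of the band in cm^-1.
#' @return A data.frame with columns `window_center_ps`, `magnitude`
#'   (mean magnitude over the band).
#' @export
band_magnitude <- function(sg, freq_cm1, band_halfwidth_cm1) {
  stopifnot(inherits(sg, "spectrogram"))
  idx <- which(sg$freq_cm1 >= freq_cm1 - band_halfwidth_cm1 &
                 sg$freq_cm1 <= freq_cm1 + band_halfwidth_cm1)
  if (!length(idx) || freq_cm1 - band_halfwidth_cm1 < 0 ||
      freq_cm1 + band_halfwidth_cm1 > max(sg$freq_cm1))
    stop("band outside spectrogram frequency range")
  data.frame(window_center_ps = sg$window_center_ps,
             magnitude = rowMeans(sg$magnitude[, idx, drop = FALSE]))
}

#' Detect beat revivals in a spectrogram band
#'
#' Integrates the spectrogram magnitude over a frequency band and
#' returns the delays of local maxima occurring after the first local
#' minimum (i.e. after the initial dampening), subject to a prominence
#' threshold.  A monotone or stationary band yields no revivals.
#'
#' @param sg A [fft_vs_time()] spectrogram.
#' @param freq_cm1,band_halfwidth_cm1 Band definition in cm^-1.
#' @param prominence_frac Prominence threshold as a fraction of the
#'   band maximum (default 0.1).
#' @return Numeric vector of revival times in ps (possibly empty).
#' @export
detect_revival <- function(sg, freq_cm1, band_halfwidth_cm1,
                           prominence_frac = 0.1) {
  bm <- band_magnitude(sg, freq_cm1, band_halfwidth_cm1)
  b <- bm$magnitude
  n <- length(b)
  if (n < 3L) return(numeric(0))
  is_min <- c(FALSE, b[2:(n - 1L)] < b[1:(n - 2L)] &
                b[2:(n - 1L)] <= b[3:n], FALSE)
  if (!any(is_min)) return(numeric(0))
  first_min <- which(is_min)[1]
  is_max <- c(FALSE, b[2:(n - 1L)] > b[1:(n - 2L)] &
                b[2:(n - 1L)] >= b[3:n], FALSE)
  cand <- which(is_max)
  cand <- cand[cand > first_min]
  if (!length(cand)) return(numeric(0))
  prom <- vapply(cand, function(i) peak_prominence(b, i), numeric(1))
  bm$window_center_ps[cand[prom >= prominence_frac * max(b)]]
}
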