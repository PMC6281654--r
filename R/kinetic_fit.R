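#' Kinetic model for a beat-modulated transient
#'
#' Describes a transient as a Gaussian-IRF-convolved, step-gated sum of
#' exponential decays modulated by damped cosine beats:
#' \deqn{S(t) = G_{irf} \ast \left[H(t)\,\Sigma_j A_j e^{-t/\tau_j}
#'   \left(1 + \Sigma_k B_k e^{-t/\tau^d_k}
#'   \cos(2\pi c \tilde\nu_k t + \phi_k)\right)\right] + y_0.}
#' Beats sharing a `group` id share one dampening lifetime (the
#' "overall beat decay lifetime"); `beats_mode = "additive"` instead
#' adds the damped cosines to the decay rather than modulating it.
#'
#' @param decays data.frame with columns `amplitude` and `lifetime_ps`
#'   (one row per exponential component).
#' @param beats NULL or data.frame with columns `amplitude` (relative
#'   modulation depth), `freq_cm1`, `phase_rad`, `damp_ps` (dampening
#'   lifetime; `Inf` for undamped) and optional `group` (integer id;
#'   default all 1, i.e. one shared dampening lifetime).
#' @param irf_fwhm_ps Gaussian IRF FWHM in ps (default 0.1).
#' @param offset Constant baseline offset (default 0).
#' @param beats_mode `"multiplicative"` (default) or `"additive"`.
#' @return An object of class `beat_fit_model`.
#' @seealso [model_eval()], [fit_transient()], [init_from_fft()]
#' @export
beat_fit_model <- function(decays, beats = NULL, irf_fwhm_ps = 0.1,
                           offset = 0,
                           beats_mode = c("multiplicative", "additive")) {
  beats_mode <- match.arg(beats_mode)
  decays <- as.data.frame(decays)
  stopifnot(all(c("amplitude", "lifetime_ps") %in% names(decays)),
            nrow(decays) >= 1L)
  if (any(decays$lifetime_ps <= 0)) stop("decay lifetimes must be > 0")
  if (!is.null(beats) && nrow(as.data.frame(beats)) > 0L) {
    beats <- as.data.frame(beats)
    need <- c("amplitude", "freq_cm1", "phase_rad", "damp_ps")
    stopifnot(all(need %in% names(beats)))
    if (is.null(beats$group)) beats$group <- 1L
    if (any(beats$freq_cm1 <= 0)) stop("beat frequencies must be > 0")
    if (any(beats$damp_ps <= 0)) stop("beat dampening lifetimes must be > 0")
    # within a group, damp_ps must agree; take the first
    for (g in unique(beats$group))
      beats$damp_ps[beats$group == g] <- beats$damp_ps[beats$group == g][1]
  } else beats <- NULL
  if (irf_fwhm_ps < 0) stop("'irf_fwhm_ps' must be >= 0")
  structure(list(decays = decays, beats = beats,
                 irf_fwhm_ps = irf_fwhm_ps, offset = offset,
                 beats_mode = beats_mode),
            class = "beat_fit_model")
}

#' @export
print.beat_fit_model <- function(x, ...) {
  cat(sprintf("<beat_fit_model> %d decay(s), %d beat(s), IRF %.3g ps, %s beats\n",
              nrow(x$decays), if (is.null(x$beats)) 0L else nrow(x$beats),
              x$irf_fwhm_ps, x$beats_mode))
  invisible(x)
}

#' Evaluate a kinetic beat model on a delay grid
#'
#' The step-gated model is evaluated on an oversampled grid extended
#' beyond the data range, convolved numerically with the Gaussian IRF,
#' and interpolated back onto `t_ps`.
#'
#' @param model A [beat_fit_model()].
#' @param t_ps Uniform, increasing delay grid in ps.
#' @param oversample Oversampling factor for the convolution grid;
#'   `NULL` (default) picks the smallest factor that resolves the IRF
#'   (grid step below sigma/3).
#' @return A [transient()].
#' @export
model_eval <- function(model, t_ps, oversample = NULL) {
  stopifnot(inherits(model, "beat_fit_model"))
  if (length(t_ps) < 2L) stop("'t_ps' must have at least two points")
  dt <- t_ps[2] - t_ps[1]
  sigma <- fwhm_to_sigma(model$irf_fwhm_ps)
  if (is.null(oversample))
    oversample <- if (sigma > 0) max(1, ceiling(3 * dt / sigma)) else 1L
  dtf <- dt / max(1L, as.integer(oversample))
  pad <- if (sigma > 0) 5 * sigma else 0
  tf <- seq(min(t_ps) - pad, max(t_ps) + pad + dtf / 2, by = dtf)
  step <- as.numeric(tf >= 0)
  dec <- rep(0, length(tf))
  for (j in seq_len(nrow(model$decays)))
    dec <- dec + model$decays$amplitude[j] *
      exp(-pmax(tf, 0) / model$decays$lifetime_ps[j])
  bsum <- rep(0, length(tf))
  if (!is.null(model$beats)) {
    for (k in seq_len(nrow(model$beats))) {
      b <- model$beats[k, ]
      bsum <- bsum + b$amplitude * exp(-pmax(tf, 0) / b$damp_ps) *
        cos(2 * pi * .c_cm_ps * b$freq_cm1 * tf + b$phase_rad)
    }
  }
  raw <- if (model$beats_mode == "multiplicative")
    step * dec * (1 + bsum) else step * (dec + bsum)
  if (sigma > 0) {
    half <- ceiling(4 * sigma / dtf)
    kern <- exp(-0.5 * ((-half:half) * dtf / sigma)^2)
    kern <- kern / sum(kern)
    raw_pad <- c(rep(raw[1], half), raw, rep(raw[length(raw)], half))
    raw <- stats::convolve(raw_pad, rev(kern), type = "filter")
  }
  yhat <- stats::approx(tf, raw, xout = t_ps, rule = 2)$y + model$offset
  transient(t_ps, yhat, meta = list(kind = "model_eval"))
}

# flatten a model into a named parameter vector and back ------------------

model_to_par <- function(model) {
  p <- c(offset = model$offset)
  nd <- nrow(model$decays)
  for (j in seq_len(nd)) {
    p[paste0("A", j)] <- model$decays$amplitude[j]
    p[paste0("tau", j)] <- model$decays$lifetime_ps[j]
  }
  if (!is.null(model$beats)) {
    for (k in seq_len(nrow(model$beats))) {
      p[paste0("B", k)] <- model$beats$amplitude[k]
      p[paste0("nu", k)] <- model$beats$freq_cm1[k]
      p[paste0("phi", k)] <- model$beats$phase_rad[k]
    }
    for (g in unique(model$beats$group))
      p[paste0("taud", g)] <- model$beats$damp_ps[model$beats$group == g][1]
  }
  p["irf"] <- model$irf_fwhm_ps
  p
}

par_to_model <- function(p, template) {
  m <- template
  m$offset <- p[["offset"]]
  for (j in seq_len(nrow(m$decays))) {
    m$decays$amplitude[j] <- p[[paste0("A", j)]]
    m$decays$lifetime_ps[j] <- p[[paste0("tau", j)]]
  }
  if (!is.null(m$beats)) {
    for (k in seq_len(nrow(m$beats))) {
      m$beats$amplitude[k] <- p[[paste0("B", k)]]
      m$beats$freq_cm1[k] <- p[[paste0("nu", k)]]
      m$beats$phase_rad[k] <- p[[paste0("phi", k)]]
    }
    for (g in unique(m$beats$group))
      m$beats$damp_ps[m$beats$group == g] <- p[[paste0("taud", g)]]
  }
  m$irf_fwhm_ps <- p[["irf"]]
  m
}

default_bounds <- function(p) {
  lower <- rep(-Inf, length(p))
  upper <- rep(Inf, length(p))
  names(lower) <- names(upper) <- names(p)
  lower[grep("^tau", names(p))] <- 1e-3
  lower[grep("^nu", names(p))] <- 1
  lower["irf"] <- 0
  list(lower = lower, upper = upper)
}

#' Seed a kinetic model from the FFT of a transient
#'
#' Fits an exponential baseline for the decay component, isolates the
#' beats, and seeds one beat component (phase 0) per FFT peak found by
#' [find_beat_peaks()], with amplitudes taken from the isolated-FFT
#' magnitudes and a shared dampening lifetime seeded at a third of the
#' record length.
#'
#' @param tr A [transient()].
#' @param max_beats Maximum number of beat components (default 4).
#' @param prominence_frac Peak threshold passed to [find_beat_peaks()]
#'   (default 0.1).
#' @param irf_fwhm_ps IRF FWHM for the seeded model (default 0.1 ps).
#' @param shared_damp If TRUE (default) all beats share one dampening
#'   lifetime (group 1); otherwise one group per beat.
#' @param max_freq_cm1 Seed no beats above this frequency (default
#'   250 cm^-1: with the ~0.1 ps instrument response, faster beats are
#'   attenuated below detectability, so peaks up there are noise).
#' @return A [beat_fit_model()]; beat-free transients yield a model
#'   with zero beat components.
#' @export
init_from_fft <- function(tr, max_beats = 4L, prominence_frac = 0.1,
                          irf_fwhm_ps = 0.1, shared_damp = TRUE,
                          max_freq_cm1 = 250) {
  stopifnot(inherits(tr, "transient"))
  # work beyond the instrument-response rise: it carries no decay or
  # beat information and any rise-model mismatch would leak broadly
  # into the untapered seeding spectrum
  keep <- tr$t_ps >= 2 * irf_fwhm_ps
  if (sum(keep) < 16L) keep <- tr$t_ps >= 0
  t <- tr$t_ps[keep]
  y <- tr$y[keep]
  tr <- transient(t, y)
  span <- max(t) - min(t)
  # log-linear envelope seed for the decay; offset seeded at zero so the
  # multiplicative beats ride the full population envelope (an offset
  # absorbing most of the signal would decouple the beats from it)
  pos <- y > max(y) * 1e-3 & t > 2 * irf_fwhm_ps
  if (sum(pos) >= 8L) {
    lf <- stats::lm.fit(cbind(1, t[pos]), log(y[pos]))
    tau0 <- -1 / min(lf$coefficients[2], -1 / (100 * span))
    a0 <- exp(lf$coefficients[1])
  } else {
    tau0 <- span / 3
    a0 <- max(y)
  }
  decays <- data.frame(amplitude = a0, lifetime_ps = tau0)
  offset <- 0
  iso <- isolate_beats(tr, baseline = "exp", mode = "ratio",
                       irf_fwhm_ps = irf_fwhm_ps)
  # rect taper for seeding: damped beats concentrate at early delays,
  # which a centered taper would suppress
  sp_seed <- fft_spectrum(iso, taper = "rect")
  # slow baseline-misfit residuals live below ~3 resolution elements;
  # do not seed beats there
  pk <- find_beat_peaks(sp_seed, prominence_frac = prominence_frac,
                        min_freq_cm1 = 3 * sp_seed$resolution_cm1,
                        max_freq_cm1 = max_freq_cm1)
  pk <- pk[pk$magnitude > 1e-6, , drop = FALSE]  # modulation depth floor
  beats <- NULL
  if (nrow(pk) > 0L) {
    # greedy selection by magnitude, skipping anything within three
    # resolution elements of an accepted peak (rejects taper sidelobes)
    pk <- pk[order(-pk$magnitude), , drop = FALSE]
    keep <- integer(0)
    for (i in seq_len(nrow(pk))) {
      if (length(keep) >= max_beats) break
      if (all(abs(pk$freq_cm1[keep] - pk$freq_cm1[i]) >
              3 * sp_seed$resolution_cm1))
        keep <- c(keep, i)
    }
    pk <- pk[keep, , drop = FALSE]
    pk <- pk[order(pk$freq_cm1), , drop = FALSE]
    beats <- data.frame(amplitude = pk$magnitude,
                        freq_cm1 = pk$freq_cm1,
                        phase_rad = 0,
                        damp_ps = span / 3,
                        group = if (shared_damp) 1L else seq_len(nrow(pk)))
  }
  beat_fit_model(decays, beats, irf_fwhm_ps = irf_fwhm_ps,
                 offset = offset)
}

#' Fit a kinetic beat model to a transient
#'
#' Weighted nonlinear least squares (Levenberg-Marquardt via
#' \pkg{minpack.lm}) with optional multistart: `multistart - 1`
#' restarts from randomly jittered initial values (seeded RNG) are run
#' and the lowest-deviance solution kept.  Standard errors come from
#' the scaled parameter covariance at the optimum.  The IRF FWHM is
#' held fixed by default; name parameters in `fix` to hold others
#' fixed (names as in the flattened parameter vector: `offset`, `A1`,
#' `tau1`, `B1`, `nu1`, `phi1`, `taud1`, `irf`, ...).
#'
#' @param tr A [transient()].
#' @param model Starting [beat_fit_model()]; `NULL` uses
#'   [init_from_fft()].
#' @param fix Character vector of parameter names to hold fixed
#'   (default `"irf"`).
#' @param weights Optional per-point standard deviations (residuals are
#'   divided by these); default uniform.
#' @param multistart Number of starts (default 8).
#' @param seed RNG seed for the multistart jitter (default 1).
#' @param maxiter Maximum LM iterations per start (default 200).
#' @return An object of class `beat_fit_result`: `parameters`
#'   (data.frame with `name`, `value`, `std_error`, `fixed`), the
#'   updated `model`, `fitted` and `residuals` vectors, `rss`,
#'   `redchi2`, `aicc`, `converged` (honest flag), `info`, `message`,
#'   `seed` and `n_starts`.
#' @export
fit_transient <- function(tr, model = NULL, fix = "irf", weights = NULL,
                          multistart = 8L, seed = 1L, maxiter = 200L) {
  stopifnot(inherits(tr, "transient"))
  if (is.null(model)) model <- init_from_fft(tr)
  keep <- tr$t_ps >= 0
  t <- tr$t_ps[keep]
  y <- tr$y[keep]
  if (is.null(weights)) weights <- rep(1, length(y))
  else weights <- rep_len(weights, length(y))
  p_all <- model_to_par(model)
  fix <- intersect(fix, names(p_all))
  free <- setdiff(names(p_all), fix)
  n_free <- length(free)
  if (length(y) < 5L * n_free)
    stop(sprintf("need at least 5 data points per free parameter (%d points, %d free)",
                 length(y), n_free))
  bounds <- default_bounds(p_all)
  # dampening slower than ~10 records is indistinguishable from none;
  # bounding keeps it identifiable instead of drifting to infinity
  bounds$upper[grep("^taud", names(p_all))] <-
    10 * (max(t) - min(t))
  resid_fn <- function(pf) {
    p <- p_all
    p[free] <- pf
    m <- par_to_model(p, model)
    (y - model_eval(m, t)$y) / weights
  }
  jitter_start <- function(p0, scale = 0.25) {
    p <- p0
    pos <- grepl("^(tau|nu|A|B)", names(p)) & p > 0
    p[pos] <- p[pos] * exp(stats::rnorm(sum(pos), 0, scale))
    phis <- grep("^phi", names(p))
    p[phis] <- p[phis] + stats::runif(length(phis), -pi / 2, pi / 2)
    pmin(pmax(p, bounds$lower[free] + 1e-6), bounds$upper[free])
  }
  set.seed(seed)
  best <- NULL
  for (s in seq_len(max(1L, as.integer(multistart)))) {
    start <- if (s == 1L) p_all[free] else jitter_start(p_all[free])
    fit <- try(minpack.lm::nls.lm(
      par = start, fn = resid_fn,
      lower = bounds$lower[free], upper = bounds$upper[free],
      control = minpack.lm::nls.lm.control(maxiter = maxiter)),
      silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("all fit starts failed")
  p_best <- p_all
  p_best[free] <- best$par
  m_best <- par_to_model(p_best, model)
  fitted <- model_eval(m_best, t)$y
  res <- y - fitted
  n <- length(y)
  rss <- sum((res / weights)^2)
  se_free <- tryCatch({
    sm <- summary(best)
    se <- sm$coefficients[, "Std. Error"]
    se[match(free, rownames(sm$coefficients))]
  }, error = function(e) rep(NA_real_, n_free))
  se <- stats::setNames(rep(NA_real_, length(p_all)), names(p_all))
  se[free] <- se_free
  converged <- !is.null(best$info) && best$info %in% 1:4
  structure(list(
    parameters = data.frame(name = names(p_all),
                            value = unname(p_best),
                            std_error = unname(se),
                            fixed = names(p_all) %in% fix,
                            row.names = NULL),
    model = m_best,
    t_ps = t, fitted = fitted, residuals = res,
    rss = rss,
    redchi2 = rss / max(n - n_free, 1),
    aicc = aicc_from_rss(rss, n, n_free),
    converged = converged, info = best$info,
    message = best$message,
    seed = seed, n_starts = as.integer(multistart)),
    class = "beat_fit_result")
}

#' @export
print.beat_fit_result <- function(x, ...) {
  cat(sprintf("<beat_fit_result> %s (info %s), red.chi2 %.4g, AICc %.4g\n",
              if (x$converged) "converged" else "NOT converged",
              x$info, x$redchi2, x$aicc))
  print(x$parameters, ...)
  invisible(x)
}

#' Extract a fitted parameter and its standard error
#'
#' @param fit A [fit_transient()] result.
#' @param name Parameter name (e.g. `"taud1"` for the shared beat
#'   dampening lifetime).
#' @return Named numeric vector `c(value, std_error)`.
#' @export
fit_parameter <- function(fit, name) {
  stopifnot(inherits(fit, "beat_fit_result"))
  i <- match(name, fit$parameters$name)
  if (is.na(i)) stop("no such parameter: ", name)
  c(value = fit$parameters$value[i],
    std_error = fit$parameters$std_error[i])
}
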