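#' 1-D pump-probe transient
#'
#' Intensity versus pump-probe delay on a uniform grid.
#'
#' @param t_ps Delay grid in ps; strictly increasing, uniform to within
#'   1e-9 ps.
#' @param y Intensity (arbitrary units), same length as `t_ps`.
#' @param meta Named list of provenance metadata (pump/probe identifiers,
#'   integrated eKE range, generator parameters, ...).
#' @return An object of class `transient`.
#' @export
transient <- function(t_ps, y, meta = list()) {
  if (length(t_ps) != length(y)) stop("'t_ps' and 'y' lengths differ")
  if (length(t_ps) < 2L) stop("a transient needs at least two samples")
  dt <- diff(t_ps)
  if (any(dt <= 0)) stop("'t_ps' must be strictly increasing")
  if (max(dt) - min(dt) > 1e-9)
    stop("'t_ps' must be uniform to within 1e-9 ps")
  structure(list(t_ps = as.numeric(t_ps), y = as.numeric(y),
                 meta = meta),
            class = "transient")
}

#' @export
print.transient <- function(x, ...) {
  cat(sprintf("<transient> %d samples, %.4g - %.4g ps (step %.4g ps)\n",
              length(x$t_ps), min(x$t_ps), max(x$t_ps), x$t_ps[2] - x$t_ps[1]))
  invisible(x)
}

t_step <- function(tr) tr$t_ps[2] - tr$t_ps[1]

#' Survival probability of a freely evolving wavepacket
#'
#' Computes the phase-augmented time-autocorrelation survival
#' probability
#' \deqn{P(\Delta t) = \left|\sum_n a_n^2
#'   e^{-i(2\pi c E_n \Delta t + \phi_n)}\right|^2,}
#' with `c` the speed of light in cm/ps.  With all phases zero this is
#' the textbook modulus-squared autocorrelation `|<Psi(t)|Psi(0)>|^2`
#' (so `P(0) = 1` exactly); non-zero per-level phases shift the beat
#' components between pairs of levels by the phase difference, which is
#' how a vibrational-mode-dependent ionization phase enters the model.
#' Oscillations ("quantum beats") occur at every pairwise level gap
#' `|E_n - E_m|` with amplitude `2 a_n^2 a_m^2`.
#'
#' @param wp A [wavepacket()].
#' @param t_ps Delay grid in ps (uniform, increasing).  Default
#'   `seq(0, 12.5, by = 0.005)`.
#' @return A [transient()] with `y = P(t)` in `[0, 1]`.
#' @examples
#' wp <- wavepacket(c(0, 179))            # equal amplitudes
#' tr <- survival_probability(wp)         # (1 + cos(2 pi c 179 t))/2
#' @export
survival_probability <- function(wp, t_ps = seq(0, 12.5, by = 0.005)) {
  stopifnot(inherits(wp, "wavepacket"))
  if (length(wp$energies_cm1) == 0L) stop("empty wavepacket")
  p <- wp$amplitudes^2
  omega <- 2 * pi * .c_cm_ps * wp$energies_cm1   # rad/ps
  # correlator C(t) = sum_n p_n exp(-i (omega_n t + phi_n))
  ph <- outer(omega, t_ps) + wp$phases_rad       # n x t
  ct <- colSums(p * exp(-1i * ph))
  transient(t_ps, Mod(ct)^2,
            meta = list(kind = "survival_probability",
                        n_levels = length(p),
                        energies_cm1 = wp$energies_cm1))
}

#' Add a phase to every level matching a mode label
#'
#' Returns a copy of the wavepacket in which `phase_rad` has been added
#' to the phase of every level whose `mode_label` contains the pattern
#' `mode_label` (regular-expression match, so `"nu179"` hits all members
#' of the 179 cm^-1 progression).  The survival probability is invariant
#' under a global phase; a phase applied to a subset shifts only the
#' beats between that subset and the rest.
#'
#' @param wp A [wavepacket()].
#' @param mode_label Pattern matched against the per-level labels.
#' @param phase_rad Phase to add, in radians.
#' @param on_missing `"warn"` (default) returns an unchanged copy with a
#'   warning when nothing matches; `"error"` stops.
#' @return A [wavepacket()].
#' @export
apply_mode_phase <- function(wp, mode_label, phase_rad,
                             on_missing = c("warn", "error")) {
  stopifnot(inherits(wp, "wavepacket"))
  on_missing <- match.arg(on_missing)
  hit <- !is.na(wp$mode_label) & grepl(mode_label, wp$mode_label)
  if (!any(hit)) {
    msg <- sprintf("no level matches mode label '%s'", mode_label)
    if (on_missing == "error") stop(msg)
    warning(msg)
    return(wp)
  }
  ph <- wp$phases_rad
  ph[hit] <- ph[hit] + phase_rad
  wavepacket(wp$energies_cm1, wp$amplitudes, ph, wp$mode_label,
             normalize = FALSE)
}

#' Smooth a transient with a Gaussian instrument response
#'
#' Discrete convolution with a unit-area Gaussian kernel of the given
#' temporal FWHM, emulating the pump-probe cross-correlation.  Edges are
#' handled by reflection, so a constant transient is returned unchanged;
#' `irf_fwhm_ps = 0` is the identity.  A cosine beat at wavenumber `nu`
#' is attenuated by `exp(-(pi c nu w)^2 / (4 log 2))` for FWHM `w`,
#' which is why beats much faster than the instrument response vanish
#' from smoothed transients.
#'
#' @param tr A [transient()].
#' @param irf_fwhm_ps Gaussian FWHM in ps (>= 0).  The grid spacing must
#'   be finer than `irf_fwhm_ps / 3`.
#' @return A [transient()] on the same grid.
#' @export
smooth_with_irf <- function(tr, irf_fwhm_ps) {
  stopifnot(inherits(tr, "transient"))
  if (irf_fwhm_ps < 0) stop("'irf_fwhm_ps' must be >= 0")
  if (irf_fwhm_ps == 0) return(tr)
  dt <- t_step(tr)
  if (dt >= irf_fwhm_ps / 3)
    stop(sprintf("grid too coarse for IRF smoothing: step %.4g ps, need < FWHM/3 = %.4g ps",
                 dt, irf_fwhm_ps / 3))
  sigma <- fwhm_to_sigma(irf_fwhm_ps)
  half <- ceiling(4 * sigma / dt)
  kern <- exp(-0.5 * ((-half:half) * dt / sigma)^2)
  kern <- kern / sum(kern)
  y <- tr$y
  n <- length(y)
  # reflect edges
  pad <- c(y[pmin(half + 1L, n):2L], y, y[(n - 1L):pmax(n - half, 1L)])
  if (half + 1L > n || half >= n)
    stop("IRF kernel longer than the transient")
  sm <- stats::convolve(pad, rev(kern), type = "filter")
  meta <- tr$meta
  meta$irf_fwhm_ps <- irf_fwhm_ps
  transient(tr$t_ps, sm, meta)
}
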