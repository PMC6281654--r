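#' Vibronic stick spectrum
#'
#' A stick spectrum is an ordered list of vibronic levels, each with an
#' energy relative to the excited-state origin, a relative intensity
#' (e.g. from a laser-induced-fluorescence excitation spectrum), an
#' optional mode-assignment label and an initial phase offset.  Levels
#' closer together than `merge_tol_cm1` are merged (intensities summed,
#' energy set to the intensity-weighted mean, label and phase taken from
#' the stronger stick) -- a hygiene step for digitized spectra.
#'
#' @param energy_cm1 Level energies relative to the origin (cm^-1, >= 0).
#' @param intensity Relative intensities (>= 0).
#' @param mode_label Optional assignment strings (recycled if length 1).
#' @param phase_rad Initial phase offsets in radians (default 0).
#' @param origin_cm1 Absolute origin energy in cm^-1 (optional metadata).
#' @param merge_tol_cm1 Levels closer than this are merged (default 0.5).
#' @return An object of class `stick_spectrum`: a list with elements
#'   `levels` (data.frame with columns `energy_cm1`, `intensity`,
#'   `mode_label`, `phase_rad`, energies strictly increasing) and
#'   `origin_cm1`.
#' @seealso [build_wavepacket()], [read_stick_spectrum()]
#' @export
stick_spectrum <- function(energy_cm1, intensity,
                           mode_label = NA_character_,
                           phase_rad = 0,
                           origin_cm1 = NA_real_,
                           merge_tol_cm1 = 0.5) {
  n <- length(energy_cm1)
  if (n == 0L) stop("a stick spectrum needs at least one level")
  if (length(intensity) != n)
    stop("'energy_cm1' and 'intensity' must have the same length")
  mode_label <- rep_len(as.character(mode_label), n)
  phase_rad <- rep_len(as.numeric(phase_rad), n)
  if (any(!is.finite(energy_cm1)) || any(energy_cm1 < 0))
    stop("level energies must be finite and >= 0 (relative to the origin)")
  if (any(!is.finite(intensity)) || any(intensity < 0))
    stop("intensities must be finite and >= 0")
  if (any(!is.finite(phase_rad)))
    stop("phases must be finite")

  ord <- order(energy_cm1)
  lv <- data.frame(energy_cm1 = as.numeric(energy_cm1[ord]),
                   intensity = as.numeric(intensity[ord]),
                   mode_label = mode_label[ord],
                   phase_rad = phase_rad[ord],
                   stringsAsFactors = FALSE)

  # merge near-coincident sticks
  if (nrow(lv) > 1L && merge_tol_cm1 > 0) {
    grp <- cumsum(c(TRUE, diff(lv$energy_cm1) >= merge_tol_cm1))
    if (max(grp) < nrow(lv)) {
      lv <- do.call(rbind, lapply(split(lv, grp), function(g) {
        if (nrow(g) == 1L) return(g)
        w <- g$intensity
        if (sum(w) == 0) w <- rep(1, nrow(g))
        k <- which.max(g$intensity)
        data.frame(energy_cm1 = sum(g$energy_cm1 * w) / sum(w),
                   intensity = sum(g$intensity),
                   mode_label = g$mode_label[k],
                   phase_rad = g$phase_rad[k],
                   stringsAsFactors = FALSE)
      }))
      rownames(lv) <- NULL
    }
  }
  structure(list(levels = lv, origin_cm1 = origin_cm1),
            class = "stick_spectrum")
}

#' @export
print.stick_spectrum <- function(x, ...) {
  cat(sprintf("<stick_spectrum> %d levels, origin %s cm^-1\n",
              nrow(x$levels),
              if (is.na(x$origin_cm1)) "unset" else format(x$origin_cm1)))
  print(x$levels, ...)
  invisible(x)
}

#' Spectral profile of the pump laser pulse
#'
#' The pump envelope is a unit-peak Gaussian in energy, characterized by
#' its center (relative to the excited-state origin) and spectral FWHM.
#' The center may be given directly in cm^-1 or as a vacuum wavelength
#' in nm together with the absolute origin energy.
#'
#' @param fwhm_cm1 Spectral full width at half maximum in cm^-1 (> 0).
#' @param center_cm1 Center relative to the origin, in cm^-1.
#' @param center_nm Alternatively, vacuum wavelength in nm (requires
#'   `origin_cm1`).
#' @param origin_cm1 Absolute origin energy in cm^-1, used to convert
#'   `center_nm`.
#' @return An object of class `pump_pulse` with elements `center_cm1`
#'   and `fwhm_cm1`.
#' @export
pump_pulse <- function(fwhm_cm1, center_cm1 = NULL, center_nm = NULL,
                       origin_cm1 = NULL) {
  if (!is.numeric(fwhm_cm1) || length(fwhm_cm1) != 1L || fwhm_cm1 <= 0)
    stop("'fwhm_cm1' must be a single positive number")
  if (is.null(center_cm1) == is.null(center_nm))
    stop("give exactly one of 'center_cm1' or 'center_nm'")
  if (!is.null(center_nm)) {
    if (is.null(origin_cm1))
      stop("'origin_cm1' is required to convert 'center_nm'")
    center_cm1 <- wavelength_to_relative_energy(center_nm, origin_cm1)
  }
  structure(list(center_cm1 = as.numeric(center_cm1),
                 fwhm_cm1 = as.numeric(fwhm_cm1)),
            class = "pump_pulse")
}

#' @export
print.pump_pulse <- function(x, ...) {
  cat(sprintf("<pump_pulse> center %+.1f cm^-1 (rel. origin), FWHM %.1f cm^-1\n",
              x$center_cm1, x$fwhm_cm1))
  invisible(x)
}

#' Vibronic wavepacket
#'
#' A coherent superposition of vibronic eigenstates: level energies
#' `E_n` (cm^-1, strictly increasing), real non-negative amplitudes
#' `a_n` normalized so that `sum(a_n^2) == 1`, and per-level phases
#' `phi_n`.  Usually constructed with [build_wavepacket()]; the direct
#' constructor is useful for idealized model wavepackets (e.g. equal
#' amplitudes over a set of levels).
#'
#' @param energies_cm1 Level energies (cm^-1), strictly increasing.
#' @param amplitudes Real non-negative amplitudes; normalized to unit
#'   summed square unless `normalize = FALSE`.
#' @param phases_rad Phases in radians (default 0).
#' @param mode_label Optional per-level assignment labels.
#' @param normalize Normalize amplitudes (default TRUE).  With
#'   `normalize = FALSE` the amplitudes must already satisfy
#'   `sum(a^2) == 1` to within 1e-12.
#' @return An object of class `wavepacket`.
#' @export
wavepacket <- function(energies_cm1, amplitudes = NULL, phases_rad = 0,
                       mode_label = NA_character_, normalize = TRUE) {
  n <- length(energies_cm1)
  if (n == 0L) stop("empty wavepacket")
  if (is.null(amplitudes)) amplitudes <- rep(1 / sqrt(n), n)
  if (length(amplitudes) != n)
    stop("'energies_cm1' and 'amplitudes' must have the same length")
  phases_rad <- rep_len(as.numeric(phases_rad), n)
  mode_label <- rep_len(as.character(mode_label), n)
  if (any(diff(energies_cm1) <= 0))
    stop("energies must be strictly increasing")
  if (any(amplitudes < 0) || any(!is.finite(amplitudes)))
    stop("amplitudes must be finite and >= 0")
  if (normalize) {
    s <- sqrt(sum(amplitudes^2))
    if (s == 0) stop("all amplitudes are zero")
    amplitudes <- amplitudes / s
  } else if (abs(sum(amplitudes^2) - 1) > 1e-12) {
    stop("amplitudes are not normalized (sum a^2 != 1 within 1e-12)")
  }
  structure(list(energies_cm1 = as.numeric(energies_cm1),
                 amplitudes = as.numeric(amplitudes),
                 phases_rad = phases_rad,
                 mode_label = mode_label),
            class = "wavepacket")
}

#' @export
print.wavepacket <- function(x, ...) {
  cat(sprintf("<wavepacket> %d levels\n", length(x$energies_cm1)))
  print(data.frame(energy_cm1 = x$energies_cm1,
                   amplitude = x$amplitudes,
                   population = x$amplitudes^2,
                   phase_rad = x$phases_rad,
                   mode_label = x$mode_label), ...)
  invisible(x)
}

#' Build the photoexcited wavepacket from a stick spectrum and pump pulse
#'
#' Each level acquires an amplitude proportional to the transition
#' amplitude times the pump field envelope at its energy:
#' `a_n ~ sqrt(I_n) * g(E_n)` with `g` the unit-peak Gaussian pump
#' profile (the default, `weighting = "sqrt"`, treats the stick
#' intensity as a squared transition moment; `weighting = "linear"`
#' uses `a_n ~ I_n * g(E_n)` for sensitivity checks).  Amplitudes are
#' normalized so the populations `a_n^2` sum to one; levels whose
#' normalized population falls below `floor` are dropped (and the
#' remainder renormalized).  Phases and mode labels are carried over
#' from the spectrum.
#'
#' @param spectrum A [stick_spectrum()].
#' @param pump A [pump_pulse()].
#' @param weighting `"sqrt"` (default) or `"linear"`, see Details.
#' @param floor Population floor below which levels are dropped
#'   (default 1e-6).
#' @return A [wavepacket()].
#' @examples
#' sp <- stick_spectrum(c(0, 179, 358), c(1, 1, 1))
#' build_wavepacket(sp, pump_pulse(500, center_cm1 = 100))
#' @export
build_wavepacket <- function(spectrum, pump,
                             weighting = c("sqrt", "linear"),
                             floor = 1e-6) {
  stopifnot(inherits(spectrum, "stick_spectrum"), inherits(pump, "pump_pulse"))
  weighting <- match.arg(weighting)
  lv <- spectrum$levels
  g <- gauss_peak1(lv$energy_cm1, pump$center_cm1, pump$fwhm_cm1)
  a <- switch(weighting,
              sqrt = sqrt(lv$intensity) * g,
              linear = lv$intensity * g)
  p <- a^2
  if (sum(p) <= 0)
    stop("pump does not overlap spectrum: all pump weights are zero")
  p <- p / sum(p)
  keep <- p >= floor
  if (!any(keep))
    stop("pump does not overlap spectrum: all weights below floor")
  wavepacket(lv$energy_cm1[keep], sqrt(p[keep]),
             phases_rad = lv$phase_rad[keep],
             mode_label = lv$mode_label[keep])
}

#' Approximate LIF level list for methyl anthranilate
#'
#' The dominant S1 vibronic levels of methyl anthranilate, as reported
#' in the main-text discussion of its LIF excitation spectrum: the
#' origin, the v = 1..3 members of the 179 cm^-1 ester-bend progression,
#' the prominent satellite at 366 cm^-1, the v = 1 level of the
#' 421 cm^-1 mode and the cluster of peaks near 600 cm^-1.  Relative
#' intensities are approximate (the full line list with exact weights is
#' part of the original study's data deposition, not reproduced here);
#' this list is adequate for reproducing the beat-frequency structure
#' (gaps ~55, ~63, ~116 and 179 cm^-1) but the intensities should be
#' treated as best-effort defaults.
#'
#' @param origin_cm1 Absolute S1 origin energy (default 28851 cm^-1).
#' @return A [stick_spectrum()].
#' @export
ma_lif_spectrum <- function(origin_cm1 = 28851) {
  stick_spectrum(
    energy_cm1 = c(0, 179, 358, 366, 421, 537, 600),
    intensity = c(1.00, 0.80, 0.55, 0.40, 0.65, 0.35, 0.30),
    mode_label = c("origin", "nu179_v1", "nu179_v2", "sat366",
                   "nu421_v1", "nu179_v3", "sat600"),
    origin_cm1 = origin_cm1)
}
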