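#' Set of harmonic vibrational modes
#'
#' @param frequencies_cm1 Harmonic frequencies in cm^-1 (all > 0); may
#'   be empty (a bare origin).  Degenerate modes are represented by
#'   listing a frequency more than once.
#' @param label Provenance string (e.g. `"S1,eq"`).
#' @return An object of class `mode_set`.
#' @export
mode_set <- function(frequencies_cm1 = numeric(0), label = "") {
  if (any(!is.finite(frequencies_cm1)) || any(frequencies_cm1 <= 0))
    stop("all frequencies must be finite and > 0")
  structure(list(frequencies_cm1 = as.numeric(frequencies_cm1),
                 label = as.character(label)),
            class = "mode_set")
}

#' @export
print.mode_set <- function(x, ...) {
  cat(sprintf("<mode_set> %d modes%s\n", length(x$frequencies_cm1),
              if (nzchar(x$label)) paste0(" (", x$label, ")") else ""))
  invisible(x)
}

#' Beyer-Swinehart direct count of harmonic vibrational states
#'
#' The classic fold: a count array over energy bins starts with a
#' single state (the zero-point level) in bin 0; folding in each mode
#' of frequency `f` adds `counts[i - round(f/bin)]` to `counts[i]` for
#' increasing `i`, which enumerates every harmonic quantum-number
#' combination exactly (for frequencies commensurate with the bin
#' width).  The cumulative sum of the counts is the total number of
#' states `N(E)` at or below each energy.
#'
#' @param modes A [mode_set()].
#' @param e_max_cm1 Maximum energy in cm^-1 (> 0).
#' @param bin_cm1 Bin width in cm^-1 (>= 1, default 1).  Frequencies
#'   are rounded to the nearest bin; a frequency smaller than the bin
#'   width is rejected (it would alias into the zero bin).
#' @return An object of class `state_counts`: `energy_cm1` (bin left
#'   edges, starting at 0), `counts` (states per bin), `cumulative`
#'   (`N(E)`), `bin_cm1`, `modes`.
#' @examples
#' sc <- beyer_swinehart_counts(mode_set(c(100, 200)), 400)
#' n_states(sc, 400) # 9
#' @export
beyer_swinehart_counts <- function(modes, e_max_cm1, bin_cm1 = 1) {
  stopifnot(inherits(modes, "mode_set"))
  if (e_max_cm1 <= 0) stop("'e_max_cm1' must be > 0")
  if (bin_cm1 < 1) stop("'bin_cm1' must be >= 1")
  nb <- floor(e_max_cm1 / bin_cm1) + 1L
  counts <- numeric(nb)
  counts[1L] <- 1
  for (f in modes$frequencies_cm1) {
    r <- round(f / bin_cm1)
    if (r < 1L)
      stop(sprintf("mode at %.3g cm^-1 is smaller than the bin width %.3g cm^-1",
                   f, bin_cm1))
    if (r < nb)
      for (i in seq.int(r + 1L, nb))
        counts[i] <- counts[i] + counts[i - r]
  }
  structure(list(energy_cm1 = (seq_len(nb) - 1L) * bin_cm1,
                 counts = counts,
                 cumulative = cumsum(counts),
                 bin_cm1 = bin_cm1,
                 modes = modes),
            class = "state_counts")
}

#' @export
print.state_counts <- function(x, ...) {
  cat(sprintf("<state_counts> %d modes, 0-%.0f cm^-1 in %.0f cm^-1 bins, N(max) = %s\n",
              length(x$modes$frequencies_cm1), max(x$energy_cm1),
              x$bin_cm1, format(x$cumulative[length(x$cumulative)])))
  invisible(x)
}

#' Total number of states at or below an energy
#'
#' @param counts A [beyer_swinehart_counts()] result.
#' @param e_cm1 Energy in cm^-1.
#' @return `N(E)`, the cumulative state count.
#' @export
n_states <- function(counts, e_cm1) {
  stopifnot(inherits(counts, "state_counts"))
  if (e_cm1 < 0 || e_cm1 > max(counts$energy_cm1) + counts$bin_cm1)
    stop("'e_cm1' outside the counted range")
  i <- findInterval(e_cm1, counts$energy_cm1)
  counts$cumulative[max(i, 1L)]
}

#' Vibrational density of states
#'
#' Windowed average of the state counts per cm^-1, centered on the
#' requested energy.  Windows extending past the counted range are
#' truncated with a warning.
#'
#' @param counts A [beyer_swinehart_counts()] result.
#' @param at_energy_cm1 Center energy in cm^-1 (inside the counted
#'   range).
#' @param smooth_window_cm1 Averaging window width in cm^-1
#'   (default 100).
#' @return Density of states in states per cm^-1.
#' @export
density_of_states <- function(counts, at_energy_cm1,
                              smooth_window_cm1 = 100) {
  stopifnot(inherits(counts, "state_counts"))
  e <- counts$energy_cm1
  if (at_energy_cm1 < min(e) || at_energy_cm1 > max(e))
    stop("'at_energy_cm1' outside the counted range")
  lo <- at_energy_cm1 - smooth_window_cm1 / 2
  hi <- at_energy_cm1 + smooth_window_cm1 / 2
  if (lo < min(e) || hi > max(e)) {
    warning("smoothing window truncated at the edge of the counted range")
    lo <- max(lo, min(e))
    hi <- min(hi, max(e) + counts$bin_cm1)
  }
  sel <- e >= lo & e < hi
  width <- sum(sel) * counts$bin_cm1
  sum(counts$counts[sel]) / width
}

#' Synthetic stand-in S1 harmonic frequencies for methyl anthranilate
#'
#' A plausible set of 54 harmonic vibrational frequencies (3N - 6 for
#' the 20-atom molecule) for the S1 state of methyl anthranilate,
#' assembled from typical values for substituted aromatic esters: the
#' two experimentally known LIF-active modes (179 and 421 cm^-1) plus
#' torsions, ring and substituent bends, ring stretches (including five
#' modes between 1400 and 1500 cm^-1), CH, NH2 and carbonyl stretches.
#' This is a synthetic stand-in for the computed S1,eq frequency list
#' (which belongs to the original study's data deposition and is not
#' redistributed here): it has the right size and spectral layout for
#' realistic Beyer-Swinehart state counts, but individual values other
#' than 179 and 421 cm^-1 are not from any calculation on this
#' molecule.
#'
#' @return A [mode_set()] labelled `"S1,eq (synthetic stand-in)"`.
#' @export
ma_s1_modes_synthetic <- function() {
  mode_set(c(45, 78, 110, 152, 179, 224, 262, 305, 340, 379,
             421, 465, 508, 556, 601, 648, 700, 752, 800, 838,
             876, 915, 952, 980, 1005, 1030, 1058, 1085, 1110, 1140,
             1165, 1190, 1230, 1260, 1295, 1320, 1350, 1410, 1432, 1455,
             1470, 1488, 1520, 1580, 1610, 1705, 2950, 2990, 3010, 3030,
             3060, 3080, 3420, 3540),
           label = "S1,eq (synthetic stand-in)")
}
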