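Package: beatmap
Title: Quantum-Beat Analysis and Vibronic Wavepacket Simulation for
    Time-Resolved Photoelectron Spectroscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing vibrational quantum beats in pump-probe
    time-resolved photoelectron spectroscopy (TR-PES) of jet-cooled
    molecules, developed around the photophysics of the sunscreen
    precursor methyl anthranilate.  Simulates the survival probability
    of a vibronic wavepacket prepared by a spectrally broad pump pulse
    from a stick spectrum (e.g. LIF-derived level positions and
    intensities), with optional mode-dependent phases and instrument
    response smoothing; extracts beat frequencies from 1-D transients
    and 2-D delay-by-electron-kinetic-energy maps via tapered FFT
    spectra, FFT(eKE) maps and sliding-window FFT spectrograms with
    revival detection; fits transients with IRF-convolved exponential
    decays modulated by damped sinusoids; counts harmonic vibrational
    states by the Beyer-Swinehart direct-count algorithm; and generates
    synthetic stick spectra and TR-PES maps with common-final-state
    interference so the whole pipeline is testable without measured data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
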