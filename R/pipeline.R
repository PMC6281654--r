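#' Run an analysis pipeline from a configuration
#'
#' Drives the package end-to-end from a declarative configuration (a
#' YAML file or an equivalent named list).  Subcommands:
#' \describe{
#'   \item{simulate}{stick spectrum + pump -> IRF-smoothed survival
#'     probability transient (`transient.csv`).}
#'   \item{analyze}{transient or TR-PES map -> FFT spectrum
#'     (`fft.csv`), peak list (`peaks.csv`), spectrogram
#'     (`spectrogram.csv`), optional revival times (`revivals.csv`) and,
#'     for maps, FFT(eKE) (`fft_eke.csv`).}
#'   \item{fit}{transient -> kinetic beat fit (`fit.json`,
#'     `residuals.csv`).}
#'   \item{dos}{mode list -> Beyer-Swinehart `N(E)` and density of
#'     states (`dos.json`).}
#'   \item{synth}{scenario fixtures via [make_fixture_suite()].}
#' }
#' Every run writes `provenance.json` (config echo, seed, package
#' version).  Unknown configuration keys fail fast, by name.
#'
#' @param config Path to a YAML config file, or a named list.  Must
#'   contain `subcommand`; remaining keys depend on the subcommand (see
#'   the package vignette).
#' @param out_dir Output directory (default `config$out_dir`, or
#'   `"beatmap_out"`); created if needed.
#' @param seed Integer RNG seed; overrides `config$rng_seed`.
#' @return Invisibly, a named list of output file paths.
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file '", config, "' not found")
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config) || is.null(config$subcommand))
    stop("config must be a named list (or YAML file) with a 'subcommand' key")
  known <- c("subcommand", "out_dir", "rng_seed", "input", "spectrum",
             "pump", "mode_phases", "t_max_ps", "t_step_ps", "irf_fwhm_ps",
             "taper", "pad_factor", "baseline", "mode", "window_fwhm_ps",
             "step_ps", "prominence_frac", "revival_bands", "bin_cm1",
             "floor_frac", "max_beats", "shared_damp", "multistart",
             "modes", "at_cm1", "window_cm1", "e_max_cm1", "bin_width_cm1",
             "scenario", "noise_sigma", "eke_range", "weighting")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("invalid config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(out_dir)) out_dir <- config$out_dir %||% "beatmap_out"
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (is.null(seed)) seed <- config$rng_seed %||% 1L
  seed <- as.integer(seed)

  cfg_get <- function(key, default = NULL) config[[key]] %||% default
  outputs <- list()

  parse_spectrum <- function() {
    sp <- cfg_get("spectrum")
    if (is.null(sp)) stop("config key 'spectrum' is required")
    if (is.character(sp)) read_stick_spectrum(sp)
    else stick_spectrum(as.numeric(sp$energy_cm1),
                        as.numeric(sp$intensity),
                        mode_label = sp$mode_label %||% NA_character_,
                        phase_rad = sp$phase_rad %||% 0,
                        origin_cm1 = sp$origin_cm1 %||% NA_real_)
  }
  parse_pump <- function() {
    p <- cfg_get("pump")
    if (is.null(p) || is.null(p$fwhm_cm1))
      stop("config key 'pump' with 'fwhm_cm1' is required")
    pump_pulse(p$fwhm_cm1, center_cm1 = p$center_cm1,
               center_nm = p$center_nm, origin_cm1 = p$origin_cm1)
  }

  sub <- config$subcommand
  if (sub == "simulate") {
    sp <- parse_spectrum()
    pm <- parse_pump()
    wp <- build_wavepacket(sp, pm,
                           weighting = cfg_get("weighting", "sqrt"))
    for (mp in cfg_get("mode_phases", list()))
      wp <- apply_mode_phase(wp, mp$label, mp$phase_rad)
    tg <- seq(0, cfg_get("t_max_ps", 12.5), by = cfg_get("t_step_ps", 0.005))
    tr <- survival_probability(wp, tg)
    irf <- cfg_get("irf_fwhm_ps", 0.1)
    if (irf > 0) tr <- smooth_with_irf(tr, irf)
    outputs$transient <- file.path(out_dir, "transient.csv")
    write_transient(tr, outputs$transient)
  } else if (sub == "analyze") {
    input <- cfg_get("input")
    if (is.null(input)) stop("config key 'input' is required")
    is_map <- tryCatch({
      read_trpes_map(input); TRUE
    }, error = function(e) FALSE)
    taper <- cfg_get("taper", "hann")
    padf <- cfg_get("pad_factor", 8L)
    if (is_map) {
      map <- read_trpes_map(input)
      fe <- fft_vs_eke(map, bin_cm1 = cfg_get("bin_cm1", 50),
                       floor_frac = cfg_get("floor_frac", 0.02),
                       baseline = cfg_get("baseline", "auto"),
                       mode = cfg_get("mode", "ratio"),
                       taper = taper, pad_factor = padf)
      outputs$fft_eke <- file.path(out_dir, "fft_eke.csv")
      grid <- expand.grid(freq_cm1 = fe$freq_cm1, eke_cm1 = fe$eke_cm1)
      writeLines(c("freq_cm1,eke_cm1,magnitude",
                   paste(fmt_num(grid$freq_cm1), fmt_num(grid$eke_cm1),
                         fmt_num(as.vector(fe$magnitude)), sep = ",")),
                 outputs$fft_eke)
      tr <- integrate_eke(map, cfg_get("eke_range"))
    } else {
      tr <- read_transient(input)
    }
    iso <- isolate_beats(tr, baseline = cfg_get("baseline", "auto"),
                         mode = cfg_get("mode", "ratio"),
                         irf_fwhm_ps = cfg_get("irf_fwhm_ps", 0))
    sp <- fft_spectrum(iso, taper = taper, pad_factor = padf)
    outputs$fft <- file.path(out_dir, "fft.csv")
    write_fft_spectrum(sp, outputs$fft)
    pk <- find_beat_peaks(sp, prominence_frac = cfg_get("prominence_frac", 0.05))
    outputs$peaks <- file.path(out_dir, "peaks.csv")
    utils::write.csv(pk, outputs$peaks, row.names = FALSE)
    sg <- fft_vs_time(iso, window_fwhm_ps = cfg_get("window_fwhm_ps", 2.5),
                      step_ps = cfg_get("step_ps", 0.1),
                      pad_factor = padf)
    outputs$spectrogram <- file.path(out_dir, "spectrogram.csv")
    write_spectrogram(sg, outputs$spectrogram)
    bands <- cfg_get("revival_bands", list())
    if (length(bands)) {
      rv <- do.call(rbind, lapply(bands, function(b) {
        times <- detect_revival(sg, b$freq_cm1, b$halfwidth_cm1)
        if (!length(times)) return(NULL)
        data.frame(band_cm1 = b$freq_cm1, revival_ps = times)
      }))
      outputs$revivals <- file.path(out_dir, "revivals.csv")
      utils::write.csv(rv %||% data.frame(band_cm1 = numeric(0),
                                          revival_ps = numeric(0)),
                       outputs$revivals, row.names = FALSE)
    }
  } else if (sub == "fit") {
    input <- cfg_get("input")
    if (is.null(input)) stop("config key 'input' is required")
    tr <- read_transient(input)
    model <- init_from_fft(tr, max_beats = cfg_get("max_beats", 4L),
                           irf_fwhm_ps = cfg_get("irf_fwhm_ps", 0.1),
                           shared_damp = cfg_get("shared_damp", TRUE))
    fit <- fit_transient(tr, model,
                         multistart = cfg_get("multistart", 8L),
                         seed = seed)
    outputs$fit <- file.path(out_dir, "fit.json")
    jsonlite::write_json(list(parameters = fit$parameters,
                              redchi2 = fit$redchi2, aicc = fit$aicc,
                              converged = fit$converged, seed = fit$seed),
                         outputs$fit, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
    outputs$residuals <- file.path(out_dir, "residuals.csv")
    writeLines(c("t_ps,residual",
                 paste(fmt_num(fit$t_ps), fmt_num(fit$residuals), sep = ",")),
               outputs$residuals)
  } else if (sub == "dos") {
    modes <- cfg_get("modes")
    if (is.null(modes)) stop("config key 'modes' is required")
    ms <- if (is.character(modes)) read_mode_set(modes)
    else mode_set(as.numeric(modes))
    at <- cfg_get("at_cm1", 1400)
    win <- cfg_get("window_cm1", 100)
    emax <- cfg_get("e_max_cm1", at + win)
    sc <- beyer_swinehart_counts(ms, emax, cfg_get("bin_width_cm1", 1))
    outputs$dos <- file.path(out_dir, "dos.json")
    jsonlite::write_json(list(at_cm1 = at, window_cm1 = win,
                              n_states = n_states(sc, at),
                              density_per_cm1 =
                                density_of_states(sc, at, win)),
                         outputs$dos, auto_unbox = TRUE, digits = NA)
  } else if (sub == "synth") {
    files <- make_fixture_suite(out_dir, seed = seed)
    outputs$fixtures <- files
  } else {
    stop("unknown subcommand: '", sub, "'")
  }

  prov <- file.path(out_dir, "provenance.json")
  jsonlite::write_json(list(subcommand = sub, config = config,
                            seed = seed,
                            package_version =
                              as.character(utils::packageVersion("beatmap"))),
                       prov, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  outputs$provenance <- prov
  invisible(outputs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
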