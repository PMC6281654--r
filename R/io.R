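# Delimited-text I/O.  All writers emit comma-separated values at full
# double precision with '#'-prefixed header lines carrying provenance;
# readers autodetect comma vs tab and round-trip the numeric payload
# bit-identically.

fmt_num <- function(x) sprintf("%.17g", x)

meta_header <- function(meta) {
  keep <- Filter(function(v) is.atomic(v) && length(v) <= 8, meta)
  vapply(names(keep), function(k)
    sprintf("# %s: %s", k, paste(format(keep[[k]]), collapse = " ")),
    character(1))
}

detect_sep <- function(line) if (grepl("\t", line)) "\t" else ","

read_delim_file <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^#", lines)
  body_idx <- setdiff(seq_along(lines), meta_lines)
  body_idx <- body_idx[nzchar(trimws(lines[body_idx]))]
  if (length(body_idx) < 2L) stop("'", path, "' contains no data rows")
  sep <- detect_sep(lines[body_idx[1]])
  df <- utils::read.table(text = lines[body_idx], sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "")
  meta <- list()
  for (ml in lines[meta_lines]) {
    m <- regmatches(ml, regexec("^#\\s*([^:]+):\\s*(.*)$", ml))[[1]]
    if (length(m) == 3L) meta[[trimws(m[2])]] <- trimws(m[3])
  }
  # report the first non-numeric cell with its file line number
  num_cols <- setdiff(names(df), c("mode_label"))
  for (cn in num_cols) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- which(is.na(v) & !is.na(df[[cn]]) & df[[cn]] != "NA")
    if (length(bad))
      stop(sprintf("'%s': non-numeric value '%s' in column '%s' at line %d",
                   path, df[[cn]][bad[1]], cn, body_idx[bad[1] + 1L]))
    df[[cn]] <- v
  }
  list(data = df, meta = meta)
}

#' Write / read a 1-D transient
#'
#' Two-column delimited text (`t_ps`, `y`) with scalar metadata echoed
#' as `# key: value` header lines.
#'
#' @param tr A [transient()].
#' @param path File path.
#' @return `write_transient` returns `path` invisibly; `read_transient`
#'   returns a [transient()] (header metadata as character strings in
#'   `meta`).
#' @export
write_transient <- function(tr, path) {
  stopifnot(inherits(tr, "transient"))
  lines <- c(meta_header(tr$meta), "t_ps,y",
             paste(fmt_num(tr$t_ps), fmt_num(tr$y), sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_transient
#' @export
read_transient <- function(path) {
  x <- read_delim_file(path)
  if (!all(c("t_ps", "y") %in% names(x$data)))
    stop("'", path, "' is not a transient file (need columns t_ps, y)")
  transient(x$data$t_ps, x$data$y, meta = x$meta)
}

#' Write / read a stick spectrum
#'
#' Columns `energy_cm1`, `intensity`, `mode_label`, `phase_rad`.
#'
#' @param spectrum A [stick_spectrum()].
#' @param path File path.
#' @param merge_tol_cm1 Merge tolerance applied on read (default 0.5).
#' @return `write_stick_spectrum` returns `path` invisibly;
#'   `read_stick_spectrum` returns a [stick_spectrum()].
#' @export
write_stick_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "stick_spectrum"))
  lv <- spectrum$levels
  hdr <- if (!is.na(spectrum$origin_cm1))
    sprintf("# origin_cm1: %s", fmt_num(spectrum$origin_cm1)) else character(0)
  lines <- c(hdr, "energy_cm1,intensity,mode_label,phase_rad",
             paste(fmt_num(lv$energy_cm1), fmt_num(lv$intensity),
                   lv$mode_label, fmt_num(lv$phase_rad), sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_stick_spectrum
#' @export
read_stick_spectrum <- function(path, merge_tol_cm1 = 0.5) {
  x <- read_delim_file(path)
  d <- x$data
  if (!all(c("energy_cm1", "intensity") %in% names(d)))
    stop("'", path, "' is not a stick spectrum (need energy_cm1, intensity)")
  stick_spectrum(d$energy_cm1, d$intensity,
                 mode_label = if (is.null(d$mode_label)) NA_character_
                 else d$mode_label,
                 phase_rad = if (is.null(d$phase_rad)) 0 else d$phase_rad,
                 origin_cm1 = if (is.null(x$meta$origin_cm1)) NA_real_
                 else as.numeric(x$meta$origin_cm1),
                 merge_tol_cm1 = merge_tol_cm1)
}

#' Write / read a TR-PES map (long format)
#'
#' Columns `t_ps`, `eke_cm1`, `intensity`, one row per grid point.
#'
#' @param map A [trpes_map()].
#' @param path File path.
#' @return `write_trpes_map` returns `path` invisibly; `read_trpes_map`
#'   returns a [trpes_map()].
#' @export
write_trpes_map <- function(map, path) {
  stopifnot(inherits(map, "trpes_map"))
  grid <- expand.grid(t_ps = map$t_ps, eke_cm1 = map$eke_cm1)
  lines <- c(meta_header(map$meta), "t_ps,eke_cm1,intensity",
             paste(fmt_num(grid$t_ps), fmt_num(grid$eke_cm1),
                   fmt_num(as.vector(map$intensity)), sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_trpes_map
#' @export
read_trpes_map <- function(path) {
  x <- read_delim_file(path)
  d <- x$data
  if (!all(c("t_ps", "eke_cm1", "intensity") %in% names(d)))
    stop("'", path, "' is not a TR-PES map (need t_ps, eke_cm1, intensity)")
  t_ps <- sort(unique(d$t_ps))
  eke <- sort(unique(d$eke_cm1))
  if (nrow(d) != length(t_ps) * length(eke))
    stop("'", path, "' is not a complete rectangular grid")
  ord <- order(d$eke_cm1, d$t_ps)
  intensity <- matrix(d$intensity[ord], nrow = length(t_ps),
                      ncol = length(eke))
  trpes_map(t_ps, eke, intensity, meta = x$meta)
}

#' Write an FFT spectrum or spectrogram as delimited text
#'
#' @param spec An [fft_spectrum()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_fft_spectrum <- function(spec, path) {
  stopifnot(inherits(spec, "fft_spectrum"))
  hdr <- c(sprintf("# resolution_cm1: %s", fmt_num(spec$resolution_cm1)),
           sprintf("# taper: %s", spec$taper),
           sprintf("# pad_factor: %d", spec$pad_factor))
  lines <- c(hdr, "freq_cm1,magnitude",
             paste(fmt_num(spec$freq_cm1), fmt_num(spec$magnitude),
                   sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_fft_spectrum
#' @param sg A [fft_vs_time()] spectrogram (long format output:
#'   `window_center_ps`, `freq_cm1`, `magnitude`).
#' @export
write_spectrogram <- function(sg, path) {
  stopifnot(inherits(sg, "spectrogram"))
  grid <- expand.grid(window_center_ps = sg$window_center_ps,
                      freq_cm1 = sg$freq_cm1)
  hdr <- c(sprintf("# window_fwhm_ps: %s", fmt_num(sg$window_fwhm_ps)),
           sprintf("# step_ps: %s", fmt_num(sg$step_ps)),
           sprintf("# normalization: %s", sg$normalization))
  lines <- c(hdr, "window_center_ps,freq_cm1,magnitude",
             paste(fmt_num(grid$window_center_ps), fmt_num(grid$freq_cm1),
                   fmt_num(as.vector(sg$magnitude)), sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read a mode set from a one-column text file
#'
#' One harmonic frequency (cm^-1) per line; `#` comments and blank
#' lines ignored.
#'
#' @param path File path.
#' @param label Provenance label (default: the file name).
#' @return A [mode_set()].
#' @export
read_mode_set <- function(path, label = basename(path)) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  vals <- suppressWarnings(as.numeric(trimws(lines[keep])))
  bad <- which(is.na(vals))
  if (length(bad))
    stop(sprintf("'%s': non-numeric frequency '%s' at line %d",
                 path, trimws(lines[keep[bad[1]]]), keep[bad[1]]))
  mode_set(vals, label = label)
}

#' Loader stub for the archived study deposition
#'
#' The original study's raw TR-PES transients, LIF line list and
#' computed frequency sets are archived in an external data deposition
#' whose internal layout is described only in its accompanying notes.
#' This loader checks a local copy for recognizable content and
#' otherwise fails with a clear message; it makes no attempt to guess
#' an undocumented layout.
#'
#' @param dir Directory containing a local copy of the deposition.
#' @return A list of loaded objects (transients as [transient()], mode
#'   lists as [mode_set()]), keyed by file name.
#' @export
load_deposition <- function(dir) {
  if (!dir.exists(dir)) stop("deposition directory '", dir, "' does not exist")
  files <- list.files(dir, pattern = "\\.(csv|txt|tsv|dat)$",
                      full.names = TRUE, recursive = TRUE)
  if (!length(files))
    stop("no delimited text files found under '", dir, "'; ",
         "the deposition layout is unknown -- place transients as ",
         "t_ps,y files and frequency lists as one-column text")
  out <- list()
  for (f in files) {
    obj <- tryCatch(read_transient(f), error = function(e)
      tryCatch(read_mode_set(f), error = function(e2) NULL))
    if (!is.null(obj)) out[[basename(f)]] <- obj
  }
  if (!length(out))
    stop("no files under '", dir, "' match the expected layouts ",
         "(transient t_ps,y or one-column frequency list)")
  out
}
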