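#' Read and write waveforms and parameter sets as plain text
#'
#' Waveform files are delimited text (comma or tab, autodetected) with two
#' columns `time,value` and an optional header; the cycle duration and
#' notch time come either from arguments or from a JSON sidecar
#' `{"T": ..., "T0": ...}` next to the file (same path with extension
#' `.json`). Standard-form waveforms are written as one `value` column plus
#' a sidecar `{"notch_fraction": ...}`. Parameter tables are JSON arrays of
#' records with explicit hatted field names.
#'
#' @param path File to read or write.
#' @param cycle_duration,notch_time Timing metadata (seconds); looked up in
#'   the sidecar when `NULL`.
#' @param sidecar Path of the JSON sidecar; defaults to `path` with a
#'   `.json` extension.
#' @return `read_waveform()`: a [raw_waveform()]; `read_scaled_waveform()`:
#'   a [scaled_waveform()]; writers return `path` invisibly.
#' @export
read_waveform <- function(path, cycle_duration = NULL, notch_time = NULL,
                          sidecar = NULL) {
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  header <- grepl("[A-Za-z]", first)
  df <- utils::read.table(path, sep = sep, header = header)
  if (ncol(df) < 2) stop_invalid("Waveform files need two columns: time, value.")
  names(df)[1:2] <- c("time", "value")
  if (is.null(cycle_duration) || is.null(notch_time)) {
    if (is.null(sidecar)) sidecar <- paste0(sub("\\.[^.]+$", "", path), ".json")
    if (!file.exists(sidecar)) {
      stop_invalid("Provide `cycle_duration` and `notch_time` or a JSON sidecar.")
    }
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (is.null(cycle_duration)) cycle_duration <- meta$T
    if (is.null(notch_time)) notch_time <- meta$T0
  }
  raw_waveform(df$time, df$value, cycle_duration, notch_time)
}

#' @param w The waveform to write.
#' @rdname read_waveform
#' @export
write_scaled_waveform <- function(w, path) {
  utils::write.table(data.frame(value = w$value), path, sep = ",",
                     row.names = FALSE, col.names = TRUE)
  jsonlite::write_json(list(notch_fraction = notch_fraction_of(w)),
                       paste0(sub("\\.[^.]+$", "", path), ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname read_waveform
#' @export
read_scaled_waveform <- function(path, sidecar = NULL) {
  df <- utils::read.table(path, sep = ",", header = TRUE)
  if (is.null(sidecar)) sidecar <- paste0(sub("\\.[^.]+$", "", path), ".json")
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  as_scaled_waveform(df$value, notch_fraction = meta$notch_fraction)
}

#' @param params A scaled parameter tibble (see [if_params()]).
#' @rdname read_waveform
#' @export
write_if_params <- function(params, path) {
  jsonlite::write_json(as_tibble(params), path, auto_unbox = FALSE,
                       digits = NA, dataframe = "rows")
  invisible(path)
}

#' @rdname read_waveform
#' @export
read_if_params <- function(path) {
  as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Write and reload a synthetic dataset as plain text
#'
#' The container is a directory with `waveforms.csv` (`n x 500` matrix of
#' values, no header), `params.json` (ground-truth records), and
#' `manifest.json` (seed, mode, ranges, filters, and an MD5 content hash of
#' the two data files).
#'
#' @param data An `if_dataset` from [generate_dataset()].
#' @param dir Directory to write to / read from.
#' @return `write_dataset()` returns `dir` invisibly; `read_dataset()` an
#'   `if_dataset`.
#' @export
write_dataset <- function(data, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wf <- file.path(dir, "waveforms.csv")
  pf <- file.path(dir, "params.json")
  utils::write.table(data$waveforms, wf, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  write_if_params(data$params, pf)
  manifest <- list(
    n = nrow(data$waveforms),
    n_samples = ncol(data$waveforms),
    seed = data$seed, mode = data$mode, noise_sd = data$noise_sd,
    preset = data$ranges$preset,
    intervals = data$ranges$intervals,
    rd_ratio_max = data$ranges$rd_ratio_max,
    value_band = data$ranges$value_band,
    content_md5 = unname(tools::md5sum(c(wf, pf)))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  waves <- as.matrix(utils::read.table(file.path(dir, "waveforms.csv"),
                                       sep = ","))
  dimnames(waves) <- NULL
  params <- read_if_params(file.path(dir, "params.json"))
  ranges <- parameter_ranges(manifest$preset,
                             rd_ratio_max = manifest$rd_ratio_max,
                             value_band = manifest$value_band)
  ranges$intervals <- as_tibble(manifest$intervals)
  structure(
    list(waveforms = waves, params = params, seed = manifest$seed,
         mode = manifest$mode, ranges = ranges,
         noise_sd = manifest$noise_sd),
    class = "if_dataset"
  )
}
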