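#' Write a spectrogram to disk
#'
#' Two on-disk forms are supported. `"csv"`: a self-contained text matrix
#' whose header row carries the column times, whose first column carries the
#' row velocities, and whose values are printed with 17 significant digits so
#' the round trip is bit-exact. `"bin"`: raw little-endian float64 values in
#' column-major order, with a JSON sidecar (`<path>.json`) carrying the axes
#' and acquisition metadata.
#'
#' @param sp [new_spectrogram()] object.
#' @param path Output path.
#' @param format `"csv"` or `"bin"`.
#' @return `path`, invisibly.
#' @export
write_spectrogram <- function(sp, path, format = c("csv", "bin")) {
  stopifnot(inherits(sp, "tcd_spectrogram"))
  format <- match.arg(format)
  if (format == "csv") {
    header <- paste(c("velocity_cm_s", num17(sp$times)), collapse = ",")
    body <- paste(num17(sp$velocities),
                  apply(sp$intensity, 1, function(r) {
                    paste(num17(r), collapse = ",")
                  }),
                  sep = ",")
    writeLines(c(header, body), path)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    # payload: dims, velocity axis, time axis, then the column-major matrix;
    # everything float64 so the round trip is bit-exact
    writeBin(as.double(dim(sp$intensity)), con, size = 8, endian = "little")
    writeBin(sp$velocities, con, size = 8, endian = "little")
    writeBin(sp$times, con, size = 8, endian = "little")
    writeBin(as.vector(sp$intensity), con, size = 8, endian = "little")
    jsonlite::write_json(
      list(container = "tcd_spectrogram_matrix", dtype = "float64",
           byte_order = "little", storage_order = "column-major",
           layout = c("n_rows", "n_cols", "velocities", "times", "intensity"),
           n_rows = nrow(sp$intensity), n_cols = ncol(sp$intensity),
           acquisition = unclass(sp$acquisition)),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

num17 <- function(x) sprintf("%.17g", x)

#' Read a spectrogram written by [write_spectrogram()]
#'
#' @param path Input path.
#' @param format `"csv"` or `"bin"`.
#' @return A [new_spectrogram()] object.
#' @export
read_spectrogram <- function(path, format = c("csv", "bin")) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- utils::read.csv(path, check.names = FALSE)
    if (names(df)[1] != "velocity_cm_s") {
      abort("malformed spectrogram CSV: missing velocity column")
    }
    times <- as.numeric(names(df)[-1])
    if (anyNA(times)) abort("malformed spectrogram CSV: bad time header")
    velocities <- df[[1]]
    intensity <- as.matrix(df[, -1, drop = FALSE])
    dimnames(intensity) <- NULL
    new_spectrogram(intensity, times, velocities)
  } else {
    meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
    if (!identical(meta$container, "tcd_spectrogram_matrix")) {
      abort("not a tcd spectrogram container")
    }
    con <- file(path, "rb")
    on.exit(close(con))
    dims <- readBin(con, "double", n = 2, size = 8, endian = "little")
    if (!isTRUE(all.equal(dims, c(meta$n_rows, meta$n_cols)))) {
      abort("binary container dimensions disagree with the sidecar")
    }
    velocities <- readBin(con, "double", n = dims[1], size = 8,
                          endian = "little")
    times <- readBin(con, "double", n = dims[2], size = 8, endian = "little")
    vals <- readBin(con, "double", n = dims[1] * dims[2], size = 8,
                    endian = "little")
    acq <- do.call(acquisition_params, meta$acquisition)
    new_spectrogram(matrix(vals, nrow = dims[1]), times, velocities, acq)
  }
}

#' Write an IQ signal (two-column CSV plus JSON sidecar)
#'
#' @param iq [iq_signal()] object.
#' @param path Output path; metadata goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_iq <- function(iq, path) {
  stopifnot(inherits(iq, "tcd_iq"))
  writeLines(c("re,im",
               paste(num17(Re(iq$samples)), num17(Im(iq$samples)),
                     sep = ",")),
             path)
  jsonlite::write_json(
    list(container = "tcd_iq", sampling_rate = iq$sampling_rate,
         acquisition = unclass(iq$acquisition)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an IQ signal written by [write_iq()]
#'
#' @param path Input path (sidecar `<path>.json` must exist).
#' @return An [iq_signal()] object.
#' @export
read_iq <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!identical(meta$container, "tcd_iq")) abort("not a tcd IQ container")
  df <- utils::read.csv(path)
  if (!all(c("re", "im") %in% names(df))) {
    abort("malformed IQ CSV: need columns re, im")
  }
  acq <- do.call(acquisition_params, meta$acquisition)
  if (!isTRUE(all.equal(meta$sampling_rate, acq$echo_sampling_rate))) {
    abort("IQ metadata mismatch: sampling_rate differs from acquisition")
  }
  iq_signal(complex(real = df$re, imaginary = df$im), meta$sampling_rate, acq)
}

#' Load a spectrogram or IQ signal by declared format
#'
#' @param path Input path.
#' @param format One of `"csv"`, `"bin"` (spectrogram) or `"iq"`.
#' @return A `tcd_spectrogram` or `tcd_iq`.
#' @export
load_input <- function(path, format) {
  if (!file.exists(path)) abort(sprintf("input file not found: %s", path))
  switch(format,
         csv = read_spectrogram(path, "csv"),
         bin = read_spectrogram(path, "bin"),
         iq = read_iq(path),
         abort(sprintf("unknown format '%s' (supported: csv, bin, iq)",
                       format)))
}

#' Save an envelope trace as CSV
#'
#' Columns `time_s`, `velocity_cm_s`, `sqi_pct`, `artifact_flag`,
#' `segment_id`, `gamma_selected`; numeric fields are printed with 12
#' significant digits. Provenance (tool version, optional seed and config
#' hash) is embedded as `#` header comments.
#'
#' @param trace [estimate_envelope()] result or its `trace` tibble.
#' @param path Output path.
#' @param provenance Named character vector of extra header fields.
#' @return `path`, invisibly.
#' @export
save_envelope <- function(trace, path, provenance = character(0)) {
  if (inherits(trace, "tcd_envelope")) trace <- trace$trace
  if (nrow(trace) > 0 &&
      (any(trace$sqi_pct < 0) || any(trace$sqi_pct > 100))) {
    abort("sqi_pct outside [0, 100]")
  }
  hdr <- c(sprintf("# tcdenv envelope %s",
                   as.character(utils::packageVersion("tcdenv"))),
           sprintf("# %s: %s", names(provenance), provenance))
  cols <- c("time_s", "velocity_cm_s", "sqi_pct", "artifact_flag",
            "segment_id", "gamma_selected")
  lines <- c(hdr, paste(cols, collapse = ","))
  if (nrow(trace) > 0) {
    lines <- c(lines, paste(
      sprintf("%.12g", trace$time_s), sprintf("%.12g", trace$velocity_cm_s),
      sprintf("%.12g", trace$sqi_pct), as.integer(trace$artifact_flag),
      trace$segment_id, sprintf("%.12g", trace$gamma_selected), sep = ","))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read an envelope CSV written by [save_envelope()]
#'
#' Also accepts any CSV with at least `time_s` and `velocity_cm_s` columns
#' (e.g. reference traces), `#` comments ignored.
#'
#' @param path Input path.
#' @return A tibble.
#' @export
read_envelope <- function(path) {
  if (!file.exists(path)) abort(sprintf("envelope file not found: %s", path))
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("time_s", "velocity_cm_s") %in% names(df))) {
    abort("malformed envelope CSV: need time_s and velocity_cm_s")
  }
  if ("artifact_flag" %in% names(df)) {
    df$artifact_flag <- as.logical(df$artifact_flag)
  }
  tibble::as_tibble(df)
}

#' Serialize / load a run configuration (YAML)
#'
#' All module configurations plus a provenance block (input file, seed, tool
#' version, config hash). Numbers are written in full precision so the round
#' trip is exact.
#'
#' @param cfg Named list of configuration objects or plain lists.
#' @param path YAML path.
#' @return `path` invisibly (`save_run_config`) or the restored list
#'   (`load_run_config`).
#' @export
save_run_config <- function(cfg, path) {
  plain <- rapply(cfg, function(x) x, how = "replace")
  plain <- lapply(plain, function(x) if (is.list(x)) unclass(x) else x)
  yaml::write_yaml(plain, path, precision = 17)
  invisible(path)
}

#' @rdname save_run_config
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  yaml::read_yaml(path)
}

#' Short provenance hash of a configuration
#'
#' A small non-cryptographic digest of the JSON serialization, embedded into
#' output files so any run can be traced back to its configuration.
#'
#' @param cfg Any serializable object.
#' @return An 8-hex-digit string.
#' @export
config_hash <- function(cfg) {
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA, force = TRUE)
  h <- 0
  for (b in utf8ToInt(as.character(s))) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
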