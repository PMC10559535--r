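#' Write one acquisition to disk
#'
#' The acquisition dialect is a CSV with header `time,s00,...,s31`, one data
#' row per sample (15000 at the standard 125 Hz / 120 s acquisition) and
#' voltages in volts, plus a JSON sidecar of the same basename carrying
#' provenance (`patient_id`, `container`, `acquisition`, `label`), the
#' sampling rate and the socket-to-sensor-model map.
#'
#' @param voltages numeric matrix, samples x 32 sockets.
#' @param path CSV output path; the sidecar is written next to it as
#'   `<path without .csv>.json`.
#' @param provenance list with `patient_id`, `container`, `acquisition`, and
#'   optionally `label` (0 = benign hyperplasia, 1 = prostate cancer).
#' @param sample_rate samples per second.
#' @param socket_map character vector of 32 sensor model ids, socket 0 first.
#' @return `path`, invisibly.
#' @export
write_acquisition <- function(voltages, path, provenance,
                              sample_rate = 125,
                              socket_map = default_socket_map()) {
  stopifnot(is.matrix(voltages), ncol(voltages) == 32L,
            length(socket_map) == 32L)
  n <- nrow(voltages)
  dt <- data.table::as.data.table(voltages)
  data.table::setnames(dt, sprintf("s%02d", 0:31))
  dt <- cbind(data.table::data.table(time = (seq_len(n) - 1L) / sample_rate), dt)
  data.table::fwrite(dt, path)
  sidecar <- list(provenance = provenance, sample_rate = sample_rate,
                  n_samples = n, socket_map = as.list(socket_map))
  jsonlite::write_json(sidecar, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

sidecar_path <- function(path) sub("\\.csv$", ".json", path)

#' Default socket-to-model map of the 32-socket array
#'
#' Sockets cycle through the four sensor models: socket `s` carries the model
#' with ordinal `s %% 4`, giving eight sensors of each model.
#' @return character vector of 32 model ids.
#' @export
default_socket_map <- function() {
  enose_sensor_models()[(0:31 %% 4L) + 1L]
}

#' Read and validate one acquisition
#'
#' Validates the shape bit-exactly: the header must be exactly
#' `time,s00,...,s31` and the row count must equal the sidecar's `n_samples`
#' (15000 for the standard acquisition). Any mismatch raises a typed
#' `enose_schema_error`.
#'
#' @param path acquisition CSV path (sidecar JSON expected next to it).
#' @param expected_samples required sample count (default 15000); `NULL`
#'   accepts any length.
#' @return list of 32 [response_curve()] objects plus a `meta` attribute with
#'   the sidecar contents.
#' @export
read_acquisition <- function(path, expected_samples = 15000L) {
  if (!file.exists(path)) schema_error("acquisition file not found: ", path)
  sc_path <- sidecar_path(path)
  if (!file.exists(sc_path)) schema_error("missing sidecar JSON: ", sc_path)
  meta <- jsonlite::read_json(sc_path)
  dt <- data.table::fread(path)
  expected_names <- c("time", sprintf("s%02d", 0:31))
  if (!identical(names(dt), expected_names)) {
    schema_error("bad acquisition header in ", path)
  }
  if (!is.null(expected_samples) && nrow(dt) != expected_samples) {
    schema_error("expected ", expected_samples, " samples, found ", nrow(dt),
                 " in ", path)
  }
  if (!is.null(meta$n_samples) && nrow(dt) != meta$n_samples) {
    schema_error("sample count disagrees with sidecar in ", path)
  }
  socket_map <- unlist(meta$socket_map)
  if (length(socket_map) != 32L) schema_error("sidecar socket_map must have 32 entries")
  prov <- meta$provenance
  rate <- if (is.null(meta$sample_rate)) 125 else meta$sample_rate
  curves <- lapply(0:31, function(s) {
    response_curve(dt[[sprintf("s%02d", s)]], sample_rate = rate,
                   socket_index = s, model_id = socket_map[s + 1L],
                   provenance = prov)
  })
  attr(curves, "meta") <- meta
  curves
}
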