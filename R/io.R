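# Native epochs container: a flat little-endian float64 array store plus a
# JSON sidecar of metadata. Inspectable and language-neutral.

#' Write epochs to the native container
#'
#' Writes `<path>.dat` (the trials x electrodes x samples array as flat
#' little-endian float64 in R's column-major order) and `<path>.json`
#' (dimensions, time axis, sampling rate, labels, electrode names, per-trial
#' metadata and an optional provenance hash).
#'
#' @param epochs an `eeg_epochs`.
#' @param path base path (extensions are appended).
#' @param config_hash optional provenance hash stored in the sidecar.
#' @return the base path, invisibly.
#' @export
write_epochs <- function(epochs, path, config_hash = NULL) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  con <- file(paste0(path, ".dat"), "wb")
  writeBin(as.vector(epochs$data), con, size = 8, endian = "little")
  close(con)
  meta <- list(format = "ctfem-epochs-v1",
               dims = dim(epochs$data),
               times_ms = epochs$times,
               sfreq = epochs$sfreq,
               labels = epochs$labels,
               electrodes = epochs$electrodes,
               meta = epochs$meta,
               config_hash = config_hash)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", dataframe = "columns")
  invisible(path)
}

#' Read epochs
#'
#' Reads the native container written by [write_epochs()]. EEGLAB
#' `.set`/`.fdt` import is not supported in this build (`.set` is a MATLAB
#' binary container); convert such data to the native container first.
#'
#' @param path base path (as passed to [write_epochs()]).
#' @param format `"native"` (default) or `"eeglab_set"` (unsupported).
#' @return an `eeg_epochs`.
#' @export
read_epochs <- function(path, format = c("native", "eeglab_set")) {
  format <- match.arg(format)
  if (format == "eeglab_set")
    stopf(paste0("EEGLAB .set import is not supported in this build; ",
                 "export your data to the native container instead"))
  json_path <- paste0(path, ".json")
  dat_path <- paste0(path, ".dat")
  if (!file.exists(json_path)) stopf("sidecar not found: %s", json_path)
  if (!file.exists(dat_path)) stopf("array store not found: %s", dat_path)
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  for (field in c("dims", "times_ms", "sfreq", "labels", "electrodes"))
    if (is.null(meta[[field]]))
      stopf("epochs sidecar is missing required field '%s'", field)
  dims <- as.integer(meta$dims)
  if (length(dims) != 3L) stopf("field 'dims' must have 3 entries")
  n_values <- prod(dims)
  con <- file(dat_path, "rb")
  values <- readBin(con, "double", n = n_values + 1, size = 8,
                    endian = "little")
  close(con)
  if (length(values) != n_values)
    stopf("array store has %d values but dims imply %d", length(values),
          n_values)
  md <- if (!is.null(meta$meta)) as.data.frame(meta$meta) else NULL
  epochs <- eeg_epochs(array(values, dim = dims), meta$times_ms, meta$sfreq,
                       meta$labels, meta$electrodes, meta = md)
  attr(epochs, "config_hash") <- meta$config_hash
  epochs
}
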