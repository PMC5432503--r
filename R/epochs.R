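# The epoched-data container used throughout the package.

#' Epoched EEG container
#'
#' Bundles a trials x electrodes x samples array (microvolts) with its time
#' axis (milliseconds, uniform, containing 0), sampling rate, per-trial
#' position labels and per-trial metadata. This is the object every analysis
#' stage consumes and returns.
#'
#' @param data numeric array `n_trials x n_electrodes x n_samples`, in uV.
#' @param times numeric vector of sample times in ms; strictly increasing,
#'   uniformly spaced, and containing 0.
#' @param sfreq sampling rate in Hz.
#' @param labels integer vector of per-trial position labels in `1..k`.
#' @param electrodes character vector of electrode names (length = dim 2).
#' @param montage optional `eeg_montage` carrying coordinates/adjacency.
#' @param meta optional per-trial data.frame (a `keep` flag is added if
#'   absent).
#' @return an object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(data, times, sfreq, labels, electrodes,
                       montage = NULL, meta = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stopf("data must be a 3-d array (trials x electrodes x samples)")
  d <- dim(data)
  if (length(times) != d[3])
    stopf("times has length %d but data has %d samples", length(times), d[3])
  dt <- diff(times)
  if (length(dt) && (any(dt <= 0) || max(abs(dt - dt[1])) > 1e-6))
    stopf("times must be strictly increasing and uniformly spaced")
  if (min(abs(times)) > 1e-9)
    stopf("times must contain the sample at 0 ms")
  if (length(labels) != d[1])
    stopf("labels has length %d but data has %d trials", length(labels), d[1])
  labels <- as.integer(labels)
  if (any(is.na(labels)) || any(labels < 1L))
    stopf("labels must be positive integers (1..k)")
  if (length(electrodes) != d[2])
    stopf("electrodes has length %d but data has %d channels",
          length(electrodes), d[2])
  if (anyDuplicated(electrodes))
    stopf("duplicate electrode names")
  if (is.null(meta)) meta <- data.frame(trial = seq_len(d[1]))
  if (nrow(meta) != d[1]) stopf("meta must have one row per trial")
  if (is.null(meta$keep)) meta$keep <- TRUE
  dimnames(data) <- list(NULL, electrodes, NULL)
  structure(list(data = data, times = as.numeric(times), sfreq = sfreq,
                 labels = labels, electrodes = as.character(electrodes),
                 montage = montage, meta = meta),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(paste0("<eeg_epochs> %d trials x %d electrodes x %d samples ",
                     "(%g Hz, %g..%g ms), %d position labels\n"),
              d[1], d[2], d[3], x$sfreq, min(x$times), max(x$times),
              length(unique(x$labels))))
  invisible(x)
}

#' @export
dim.eeg_epochs <- function(x) dim(x$data)

#' Epoch dimensions
#'
#' @param epochs an `eeg_epochs`.
#' @return trial, electrode or sample count.
#' @export
n_trials <- function(epochs) dim(epochs$data)[1]

#' @rdname n_trials
#' @export
n_electrodes <- function(epochs) dim(epochs$data)[2]

#' @rdname n_trials
#' @export
n_samples <- function(epochs) dim(epochs$data)[3]

electrode_index <- function(epochs, name) {
  idx <- match(name, epochs$electrodes)
  if (anyNA(idx))
    stopf("electrode(s) not found: %s",
          paste(name[is.na(idx)], collapse = ", "))
  idx
}

sample_index <- function(epochs, window) {
  if (length(window) != 2L || window[1] >= window[2])
    stopf("window must be an increasing (start, end) ms pair")
  tol <- 1e-6
  if (window[1] < min(epochs$times) - tol || window[2] > max(epochs$times) + tol)
    stopf("window [%g, %g] ms lies outside the epoch [%g, %g] ms",
          window[1], window[2], min(epochs$times), max(epochs$times))
  which(epochs$times >= window[1] - tol & epochs$times <= window[2] + tol)
}

#' Subset trials of an epochs object
#'
#' Keeps data, labels and metadata consistent; used by trial rejection.
#'
#' @param epochs an `eeg_epochs`.
#' @param keep logical or integer trial selector.
#' @return an `eeg_epochs` with the selected trials.
#' @export
subset_trials <- function(epochs, keep) {
  eeg_epochs(epochs$data[keep, , , drop = FALSE], epochs$times, epochs$sfreq,
             epochs$labels[keep], epochs$electrodes, epochs$montage,
             epochs$meta[keep, , drop = FALSE])
}

# uniform time axis for an epoch window at a given rate, guaranteed to
# contain the 0 ms sample
make_times <- function(window, sfreq) {
  step <- 1000 / sfreq
  (ceiling(window[1] / step):floor(window[2] / step)) * step
}
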