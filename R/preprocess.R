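# Epoch-level preprocessing: re-referencing, high-pass filtering, baseline
# correction, downsampling, HEOG derivation and the sliding-window step
# detector for ocular artifacts.

#' Re-reference to the average of a set of electrodes
#'
#' Subtracts, per trial and sample, the mean of the reference electrodes from
#' every channel (e.g. offline re-referencing to the average of both
#' earlobes).
#'
#' @param epochs an `eeg_epochs`.
#' @param ref_electrodes character vector of reference electrode names.
#' @return the re-referenced `eeg_epochs`.
#' @export
rereference <- function(epochs, ref_electrodes) {
  ri <- electrode_index(epochs, ref_electrodes)
  ref <- epochs$data[, ri, , drop = FALSE]
  refmean <- apply(ref, c(1, 3), mean)           # trials x samples
  m <- n_electrodes(epochs)
  epochs$data <- epochs$data -
    aperm(array(refmean, c(dim(refmean), m)), c(1, 3, 2))
  epochs
}

#' FIR high-pass filter length
#'
#' Length (in samples, odd) of the Hamming-windowed sinc FIR filter for a
#' given transition bandwidth, using the standard 3.3/transition rule for a
#' Hamming window. At 500 Hz and a 0.1 Hz transition band this gives a 33 s
#' filter.
#'
#' @param transition transition bandwidth, Hz.
#' @param sfreq sampling rate, Hz.
#' @return odd integer filter length in samples.
#' @export
fir_filter_length <- function(transition, sfreq) {
  n <- ceiling(3.3 / transition * sfreq)
  if (n %% 2 == 0) n <- n + 1
  as.integer(n)
}

# zero-phase FIR filtering of a vector via reflection padding + convolution
fir_zero_phase <- function(x, h) {
  nh <- length(h)
  half <- (nh - 1) / 2
  # reflect the signal at both ends to limit edge transients
  pre <- rev(2 * x[1] - x[seq_len(min(half, length(x) - 1)) + 1])
  post <- rev(2 * x[length(x)] - x[length(x) - seq_len(min(half, length(x) - 1))])
  xp <- c(pre, x, post)
  y <- stats::filter(xp, h, method = "convolution", sides = 2)
  y <- as.numeric(y)
  start <- length(pre) + 1
  y[start:(start + length(x) - 1)]
}

#' Zero-phase Hamming-windowed sinc FIR high-pass filter
#'
#' Designs a linear-phase high-pass FIR with a Hamming window and applies it
#' with zero phase (symmetric convolution with edge reflection), removing DC
#' and slow drifts. The -6 dB cutoff sits at `cutoff - transition/2` (so a
#' 0.1 Hz passband edge with a 0.1 Hz transition band has its half-amplitude
#' point at 0.05 Hz).
#'
#' @param x an `eeg_epochs`, or a numeric vector/matrix of continuous data
#'   (matrix: channels in columns).
#' @param cutoff passband edge, Hz.
#' @param sfreq sampling rate (taken from the epochs object when given one).
#' @param transition transition bandwidth in Hz; default equal to `cutoff`.
#' @param max_length optional cap on the filter length in samples; for short
#'   epochs the kernel is clamped (with a warning) to the data length.
#' @return the filtered object, same type as the input.
#' @export
highpass <- function(x, cutoff, sfreq = NULL, transition = cutoff,
                     max_length = NULL) {
  if (inherits(x, "eeg_epochs")) {
    sfreq <- x$sfreq
    len <- n_samples(x)
  } else {
    if (is.null(sfreq)) stopf("sfreq is required for raw numeric input")
    len <- if (is.matrix(x)) nrow(x) else length(x)
  }
  if (cutoff >= sfreq / 2) stopf("cutoff must be below the Nyquist frequency")
  n <- fir_filter_length(transition, sfreq)
  if (!is.null(max_length)) n <- min(n, max_length)
  if (n > len) {
    n <- if (len %% 2 == 0) len - 1 else len
    warning(sprintf("filter length clamped to data length (%d samples)", n))
  }
  fc <- cutoff - transition / 2                 # -6 dB point
  if (fc <= 0) stopf("transition band too wide for this cutoff")
  # spectral inversion of a unit-DC-gain windowed-sinc lowpass: the
  # resulting highpass has exactly zero DC response
  lp <- as.numeric(signal::fir1(n - 1, fc / (sfreq / 2), type = "low",
                                window = signal::hamming(n)))
  lp <- lp / sum(lp)
  h <- -lp
  h[(n + 1) / 2] <- h[(n + 1) / 2] + 1
  if (inherits(x, "eeg_epochs")) {
    d <- x$data
    for (i in seq_len(dim(d)[1]))
      for (j in seq_len(dim(d)[2]))
        d[i, j, ] <- fir_zero_phase(d[i, j, ], h)
    x$data <- d
    x
  } else if (is.matrix(x)) {
    apply(x, 2, fir_zero_phase, h = h)
  } else {
    fir_zero_phase(x, h)
  }
}

#' Baseline correction
#'
#' Subtracts, per trial and electrode, the mean over the baseline window
#' (e.g. -200..-100 ms or -100..0 ms pre-stimulus).
#'
#' @param epochs an `eeg_epochs`.
#' @param window (start, end) ms pair inside the epoch.
#' @return the corrected `eeg_epochs`.
#' @export
baseline_correct <- function(epochs, window) {
  idx <- sample_index(epochs, window)
  bl <- apply(epochs$data[, , idx, drop = FALSE], c(1, 2), mean)
  epochs$data <- epochs$data -
    array(bl, dim = c(dim(bl), n_samples(epochs)))
  epochs
}

#' Downsample epochs by an integer factor
#'
#' Decimates the time axis so that the sample at 0 ms is preserved. Only
#' downsampling by an integer factor is supported (e.g. 500 -> 250 Hz).
#'
#' @param epochs an `eeg_epochs`.
#' @param target_sfreq target rate, Hz; must divide the current rate.
#' @return the decimated `eeg_epochs`; trials and labels are unchanged.
#' @export
downsample <- function(epochs, target_sfreq) {
  if (target_sfreq > epochs$sfreq)
    stopf("upsampling (%g -> %g Hz) is not supported",
          epochs$sfreq, target_sfreq)
  factor <- epochs$sfreq / target_sfreq
  if (abs(factor - round(factor)) > 1e-9)
    stopf("target rate %g Hz does not divide the current rate %g Hz",
          target_sfreq, epochs$sfreq)
  factor <- as.integer(round(factor))
  if (factor == 1L) return(epochs)
  i0 <- which.min(abs(epochs$times))
  keep <- which((seq_along(epochs$times) - i0) %% factor == 0)
  eeg_epochs(epochs$data[, , keep, drop = FALSE], epochs$times[keep],
             target_sfreq, epochs$labels, epochs$electrodes, epochs$montage,
             epochs$meta)
}

#' Horizontal EOG from canthus electrodes
#'
#' Returns the left-minus-right difference per trial and sample, the
#' conventional HEOG derivation from electrodes at the outer canthi.
#'
#' @param epochs an `eeg_epochs`.
#' @param left,right electrode names.
#' @return a trials x samples numeric matrix.
#' @export
compute_heog <- function(epochs, left = "HEOGL", right = "HEOGR") {
  li <- electrode_index(epochs, left)
  ri <- electrode_index(epochs, right)
  epochs$data[, li, ] - epochs$data[, ri, ]
}

#' Sliding-window step detector for eye movements
#'
#' Implements the step algorithm: a window of `window` ms slides in steps of
#' `step` ms across `interval`; a trial is flagged when the absolute
#' difference between the mean of the second and the first half of any window
#' placement exceeds `threshold` uV. Defaults are a 100 ms window, 50 ms
#' steps, the 0-500 ms post-stimulus interval and a 25 uV threshold, the
#' standard saccade-scale criterion.
#'
#' @param heog trials x samples numeric matrix (from [compute_heog()]).
#' @param times sample times in ms (length = `ncol(heog)`).
#' @param window sliding window length, ms.
#' @param step window step, ms.
#' @param interval (start, end) ms pair searched.
#' @param threshold flag threshold, uV.
#' @return logical vector, one flag per trial.
#' @export
detect_step_artifacts <- function(heog, times, window = 100, step = 50,
                                  interval = c(0, 500), threshold = 25) {
  if (is.null(dim(heog))) heog <- matrix(heog, nrow = 1)
  if (ncol(heog) != length(times))
    stopf("heog has %d samples but times has length %d", ncol(heog),
          length(times))
  tol <- 1e-6
  if (interval[1] < min(times) - tol || interval[2] > max(times) + tol)
    stopf("search interval outside the epoch")
  if (window > diff(interval))
    stopf("window (%g ms) longer than the search interval (%g ms)",
          window, diff(interval))
  onsets <- seq(interval[1], interval[2] - window, by = step)
  flagged <- rep(FALSE, nrow(heog))
  for (on in onsets) {
    first <- times >= on - tol & times < on + window / 2 - tol
    second <- times >= on + window / 2 - tol & times < on + window - tol
    if (!any(first) || !any(second)) next
    d <- abs(rowMeans(heog[, second, drop = FALSE]) -
             rowMeans(heog[, first, drop = FALSE]))
    flagged <- flagged | (d > threshold)
  }
  flagged
}

#' Drop trials flagged as artifacts
#'
#' Removes flagged trials (they are dropped, not zeroed) and records the
#' decision in the metadata of the returned object via attribute
#' `rejected` (the original trial indices removed).
#'
#' @param epochs an `eeg_epochs`.
#' @param flags logical per-trial rejection flags.
#' @return the subsetted `eeg_epochs`.
#' @export
reject_trials <- function(epochs, flags) {
  stopifnot(length(flags) == n_trials(epochs))
  out <- subset_trials(epochs, !flags)
  attr(out, "rejected") <- which(flags)
  out
}

#' Hook for externally cleaned data
#'
#' Independent-component blink removal is not re-implemented here; this hook
#' accepts a cleaned data array (or a per-trial keep mask) produced by an
#' external tool and splices it into the epochs container after validation.
#'
#' @param epochs an `eeg_epochs`.
#' @param cleaned_data optional replacement data array of identical dimension.
#' @param keep_mask optional logical per-trial mask applied after replacement.
#' @return the updated `eeg_epochs`.
#' @export
apply_external_cleaning <- function(epochs, cleaned_data = NULL,
                                    keep_mask = NULL) {
  if (!is.null(cleaned_data)) {
    if (!identical(dim(cleaned_data), dim(epochs$data)))
      stopf("cleaned_data dimensions do not match the epochs")
    epochs$data <- cleaned_data
  }
  if (!is.null(keep_mask)) epochs <- reject_trials(epochs, !keep_mask)
  epochs
}
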