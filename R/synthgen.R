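# Synthetic epoched EEG with a known position-tuned generative model.
#
# Generative model, per trial with position label p:
#   data(t) = W_true %*% c_true(p) * s(t) + noise
# where W_true (electrodes x channels) holds one smooth scalp bump per
# position channel, c_true(p) is a wrapped Gaussian over the k position
# channels peaking at channel p, and s(t) is a raised-cosine envelope rising
# at signal_onset and peaking at signal_peak. Noise is white Gaussian by
# default, optionally spatially correlated over the montage.

#' Simulation configuration
#'
#' Captures the study design being emulated: an eight-position circular
#' search display (positions numbered clockwise from the upper right, none on
#' the horizontal or vertical midline) recorded from 27 electrodes, or a
#' four-position midline display recorded from 23 electrodes. Defaults follow
#' the eight-position design: 96 trials per position (768 total), 250 Hz,
#' -100..1000 ms epochs, a position-tuned signal rising at 180 ms and peaking
#' at 265 ms. See the package vignette for the rationale behind the signal
#' amplitude / noise level.
#'
#' @param n_positions number of target positions k (>= 2).
#' @param position_angles angles in degrees on the stimulus circle, clockwise
#'   from the top; strictly increasing modulo 360. Defaults to the
#'   eight off-midline positions (22.5, 67.5, ...).
#' @param n_trials_per_position trials per position label.
#' @param n_electrodes electrode count; must match the montage used.
#' @param sfreq sampling rate, Hz.
#' @param epoch_window (start, end) ms pair containing 0.
#' @param true_tuning_width sigma (in channel units) of the circular Gaussian
#'   tuning profile over position channels.
#' @param signal_onset,signal_peak,signal_offset envelope timing, ms.
#' @param signal_amplitude peak signal amplitude, uV.
#' @param noise_sd additive noise standard deviation, uV.
#' @param noise_mode `"white"` or `"correlated"` (spatial covariance decaying
#'   with montage distance; stress-tests covariance-based patterns).
#' @param noise_corr_scale spatial decay length for correlated noise,
#'   head-radius units.
#' @param spatial_width width of the scalp bump of each position channel,
#'   head-radius units.
#' @param heog if `TRUE`, two extra ocular channels `HEOGL`/`HEOGR` (noise
#'   only) are appended for artifact-detection fixtures.
#' @param seed integer RNG seed.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_positions = 8L,
                       position_angles = NULL,
                       n_trials_per_position = 96L,
                       n_electrodes = 27L,
                       sfreq = 250,
                       epoch_window = c(-100, 1000),
                       true_tuning_width = 1.2,
                       signal_onset = 180,
                       signal_peak = 265,
                       signal_offset = 600,
                       signal_amplitude = 2,
                       noise_sd = 4,
                       noise_mode = c("white", "correlated"),
                       noise_corr_scale = 0.5,
                       spatial_width = 0.6,
                       heog = FALSE,
                       seed = 1L) {
  noise_mode <- match.arg(noise_mode)
  if (!is_count(n_positions, min = 2)) stopf("n_positions must be >= 2")
  k <- as.integer(n_positions)
  if (is.null(position_angles)) {
    position_angles <- if (k == 8L) 22.5 + 45 * (seq_len(k) - 1)
                       else if (k == 4L) c(0, 90, 180, 270)
                       else 360 * (seq_len(k) - 1) / k
  }
  if (length(position_angles) != k)
    stopf("position_angles must have length n_positions")
  if (any(diff(position_angles %% 360) <= 0))
    stopf("position_angles must be strictly increasing modulo 360")
  if (!(epoch_window[1] < 0 && epoch_window[2] > 0))
    stopf("epoch_window must contain 0 (start < 0 < end)")
  if (true_tuning_width <= 0) stopf("true_tuning_width must be > 0")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  if (!(signal_onset < signal_peak && signal_peak < signal_offset))
    stopf("need signal_onset < signal_peak < signal_offset")
  structure(list(n_positions = k, position_angles = position_angles,
                 n_trials_per_position = as.integer(n_trials_per_position),
                 n_electrodes = as.integer(n_electrodes), sfreq = sfreq,
                 epoch_window = epoch_window,
                 true_tuning_width = true_tuning_width,
                 signal_onset = signal_onset, signal_peak = signal_peak,
                 signal_offset = signal_offset,
                 signal_amplitude = signal_amplitude, noise_sd = noise_sd,
                 noise_mode = noise_mode, noise_corr_scale = noise_corr_scale,
                 spatial_width = spatial_width, heog = heog,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Default configuration for the four-position midline design
#'
#' Convenience wrapper: 4 positions on the horizontal/vertical midline
#' (right, bottom, left, top at 90/180/270/0 degrees), 23 electrodes,
#' -200..400 ms epochs at 250 Hz.
#'
#' @param ... overrides passed to [sim_config()].
#' @return a `sim_config`.
#' @export
sim_config_exp1 <- function(...) {
  defaults <- list(n_positions = 4L, position_angles = c(0, 90, 180, 270),
                   n_electrodes = 23L, epoch_window = c(-200, 400),
                   n_trials_per_position = 96L)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

# raised-cosine envelope: 0 before onset, half-cosine rise onset->peak,
# half-cosine fall peak->offset, 0 after; unit peak
signal_envelope <- function(times, onset, peak, offset) {
  s <- numeric(length(times))
  rise <- times >= onset & times <= peak
  fall <- times > peak & times <= offset
  s[rise] <- 0.5 - 0.5 * cos(pi * (times[rise] - onset) / (peak - onset))
  s[fall] <- 0.5 + 0.5 * cos(pi * (times[fall] - peak) / (offset - peak))
  s
}

# scalp centre of the spatial bump for a stimulus at `angle` degrees
# (clockwise from top). The bump sits over posterior cortex contralateral to
# the stimulated hemifield and shifts with elevation, mimicking a coarse
# retinotopic gradient.
bump_center <- function(angle) {
  a <- angle * pi / 180
  c(x = -0.6 * sin(a), y = -0.6 + 0.25 * cos(a))
}

# true forward matrix: one smooth 2-D Gaussian bump per position channel
make_true_weights <- function(montage, angles, spatial_width, amplitude) {
  W <- sapply(angles, function(ang) {
    ctr <- bump_center(ang)
    d2 <- (montage$coords[, "x"] - ctr["x"])^2 +
          (montage$coords[, "y"] - ctr["y"])^2
    amplitude * exp(-d2 / (2 * spatial_width^2))
  })
  rownames(W) <- montage$names
  colnames(W) <- paste0("ch", seq_along(angles))
  W
}

# true channel tuning profile matrix: column p = c_true(p), wrapped Gaussian
# over channel distance, peak 1 at channel p
make_true_profile <- function(k, sigma) {
  idx <- seq_len(k)
  sapply(idx, function(p) wrapped_gaussian(circ_dist_channels(idx, p, k), sigma))
}

#' Simulate epoched EEG with known ground truth
#'
#' Draws balanced per-position trials from the generative model described in
#' the vignette: a smooth scalp bump per position channel, a wrapped-Gaussian
#' tuning profile across channels, a raised-cosine time envelope, plus
#' additive Gaussian noise. Identical configurations (including `seed`)
#' produce identical data.
#'
#' @param config a [sim_config()].
#' @param montage an `eeg_montage` whose electrode count matches
#'   `config$n_electrodes`.
#' @return a list with components `epochs` (an `eeg_epochs`; trial order is
#'   randomised as in an experiment) and `truth` (class `sim_truth`: the
#'   true weights `W_true`, tuning profile matrix `C_true`, envelope
#'   `s`, and the per-trial noiseless means generator `topography(angle)`).
#' @export
simulate_epochs <- function(config, montage) {
  stopifnot(inherits(config, "sim_config"), inherits(montage, "eeg_montage"))
  if (length(montage$names) != config$n_electrodes)
    stopf("montage has %d electrodes but config expects %d",
          length(montage$names), config$n_electrodes)
  k <- config$n_positions
  times <- make_times(config$epoch_window, config$sfreq)
  Tn <- length(times)
  n <- k * config$n_trials_per_position

  W <- make_true_weights(montage, config$position_angles,
                         config$spatial_width, config$signal_amplitude)
  C <- make_true_profile(k, config$true_tuning_width)
  s <- signal_envelope(times, config$signal_onset, config$signal_peak,
                       config$signal_offset)

  set.seed(config$seed)
  labels <- sample(rep(seq_len(k), config$n_trials_per_position))

  electrodes <- montage$names
  m <- length(electrodes)
  if (config$heog) {
    electrodes <- c(electrodes, "HEOGL", "HEOGR")
  }
  data <- array(0, dim = c(n, length(electrodes), Tn))
  # condition-mean topography time courses, m x T per position
  mean_tc <- lapply(seq_len(k), function(p) (W %*% C[, p]) %*% t(s))
  for (i in seq_len(n)) data[i, 1:m, ] <- mean_tc[[labels[i]]]
  if (config$noise_sd > 0) {
    noise <- array(stats::rnorm(n * length(electrodes) * Tn,
                                sd = config$noise_sd),
                   dim = c(n, length(electrodes), Tn))
    if (config$noise_mode == "correlated") {
      d <- as.matrix(stats::dist(montage$coords))
      S <- exp(-d / config$noise_corr_scale)
      L <- chol(S + diag(1e-8, m))
      for (i in seq_len(n))
        noise[i, 1:m, ] <- t(L) %*% noise[i, 1:m, ]
    }
    data <- data + noise
  }
  epochs <- eeg_epochs(data, times, config$sfreq, labels, electrodes,
                       montage = montage,
                       meta = data.frame(trial = seq_len(n),
                                         position = labels,
                                         angle = config$position_angles[labels]))
  # continuous extension of the channel tuning profile: distance from each
  # sampled position channel in channel units (one channel = 360/k degrees)
  channel_profile <- function(angle) {
    d <- circ_dist_deg(config$position_angles, angle) / (360 / k)
    wrapped_gaussian(d, config$true_tuning_width)
  }
  truth <- structure(
    list(W_true = W, C_true = C, envelope = s, times = times,
         config = config,
         channel_profile = channel_profile,
         # peak topography of a held-out position simulated with the same
         # generative model: the tuning profile evaluated at the continuous
         # angle, mixed through W_true
         topography = function(angle) drop(W %*% channel_profile(angle)),
         # stricter physical alternative: move the cortical bump itself to
         # the new angle (a pattern outside the span of the sampled ones)
         bump_topography = function(angle) {
           ctr <- bump_center(angle)
           d2 <- (montage$coords[, "x"] - ctr["x"])^2 +
                 (montage$coords[, "y"] - ctr["y"])^2
           config$signal_amplitude * exp(-d2 / (2 * config$spatial_width^2))
         }),
    class = "sim_truth")
  list(epochs = epochs, truth = truth)
}

#' Inject a step artifact into an ocular channel
#'
#' Adds a step of `amplitude` uV to one trial's designated HEOG channel from
#' `onset` ms to the end of the epoch; all other trials are untouched. Used
#' as a fixture for [detect_step_artifacts()].
#'
#' @param epochs an `eeg_epochs`.
#' @param trial trial index.
#' @param onset step onset in ms (inside the epoch).
#' @param amplitude step height, uV.
#' @param channel channel receiving the step (default `"HEOGL"`).
#' @return the modified `eeg_epochs`.
#' @export
inject_step_artifact <- function(epochs, trial, onset, amplitude,
                                 channel = "HEOGL") {
  if (!is_count(trial) || trial > n_trials(epochs))
    stopf("trial index %s out of range (1..%d)", toString(trial),
          n_trials(epochs))
  if (onset < min(epochs$times) || onset > max(epochs$times))
    stopf("onset %g ms outside the epoch window", onset)
  ci <- electrode_index(epochs, channel)
  idx <- epochs$times >= onset
  epochs$data[trial, ci, idx] <- epochs$data[trial, ci, idx] + amplitude
  epochs
}
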