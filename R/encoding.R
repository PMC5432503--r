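# Forward encoding model (FEM): delta-basis weight estimation, inversion to
# channel responses, canonical channel tuning functions (CTFs) over time,
# tuning statistics, and reconstruction of scalp topographies for positions
# that were never presented.

#' Basis set over position channels
#'
#' The delta basis is the identity: channel response 1 for the labelled
#' position and 0 elsewhere, imposing no shape assumption on the CTF. A
#' custom k x k basis (e.g. a Gaussian basis) is accepted and stored
#' verbatim.
#'
#' @param k number of position channels.
#' @param matrix optional custom k x k basis (columns = positions).
#' @return an object of class `basis_set` with `matrix` and `kind`.
#' @export
basis_set <- function(k, matrix = NULL) {
  if (is.null(matrix)) {
    structure(list(matrix = diag(k), kind = "delta", k = k),
              class = "basis_set")
  } else {
    if (!all(dim(matrix) == c(k, k))) stopf("custom basis must be k x k")
    structure(list(matrix = matrix, kind = "custom", k = k),
              class = "basis_set")
  }
}

#' Build the design matrix C1 from labels and a basis set
#'
#' Column j of the k x n design matrix is the basis column of trial j's
#' label, i.e. for the delta basis a 1 at the labelled position channel and
#' 0 elsewhere.
#'
#' @param labels per-trial position labels in `1..k`.
#' @param basis a [basis_set()].
#' @return k x n numeric matrix.
#' @export
build_design <- function(labels, basis) {
  stopifnot(inherits(basis, "basis_set"))
  labels <- as.integer(labels)
  if (any(labels < 1L | labels > basis$k))
    stopf("label(s) out of range 1..%d: %s", basis$k,
          toString(unique(labels[labels < 1L | labels > basis$k])))
  basis$matrix[, labels, drop = FALSE]
}

#' Estimate encoding weights W by OLS
#'
#' Regresses the design matrix C1 onto the electrode data B1:
#' `W = B1 C1' (C1 C1')^-1`, giving each electrode a regression weight per
#' position channel. With the delta basis, column p of W equals the mean
#' topography of the training trials labelled p.
#'
#' @param B1 electrodes x trials training data matrix.
#' @param C1 k x trials design matrix (from [build_design()]).
#' @return an object of class `encoding_model` with the m x k weight matrix
#'   `W`.
#' @export
estimate_weights <- function(B1, C1) {
  B1 <- as.matrix(B1); C1 <- as.matrix(C1)
  if (ncol(B1) != ncol(C1))
    stopf("B1 has %d trials but C1 has %d", ncol(B1), ncol(C1))
  G <- tcrossprod(C1)                      # k x k
  if (rcond(G) < 1e-12) {
    present <- rowSums(abs(C1)) > 0
    stopf("design matrix is rank deficient%s",
          if (any(!present))
            sprintf(" (no trials for channel(s) %s)",
                    toString(which(!present)))
          else "")
  }
  W <- B1 %*% t(C1) %*% solve(G)
  structure(list(W = W, k = nrow(C1), m = nrow(B1)),
            class = "encoding_model")
}

#' @export
print.encoding_model <- function(x, ...) {
  cat(sprintf("<encoding_model> W: %d electrodes x %d channels\n", x$m, x$k))
  invisible(x)
}

#' Invert an encoding model to estimate channel responses
#'
#' Regresses the weights onto held-out data: `C2 = (W'W)^-1 W' B2`, the OLS
#' estimate of the channel responses that generated each test trial.
#'
#' @param model an `encoding_model` (or bare m x k weight matrix).
#' @param B2 electrodes x trials test data matrix.
#' @return k x n2 matrix of estimated channel responses.
#' @export
invert_model <- function(model, B2) {
  W <- if (inherits(model, "encoding_model")) model$W else as.matrix(model)
  B2 <- as.matrix(B2)
  if (nrow(B2) != nrow(W))
    stopf("B2 has %d electrodes but W has %d", nrow(B2), nrow(W))
  # SVD-based least squares: the normal equations would square the
  # condition number of W, which is substantial for realistic montages
  sv <- svd(W)
  if (min(sv$d) < 1e-10 * max(sv$d))
    stopf("weight matrix is rank deficient (condition number %.3g)",
          max(sv$d) / max(min(sv$d), .Machine$double.xmin))
  sv$v %*% ((t(sv$u) %*% B2) / sv$d)
}

#' Align per-condition channel responses to a common center
#'
#' Circularly shifts condition p's mean channel-response vector by
#' `center - p` so that every condition's own channel lands on the center
#' channel, then averages across conditions to form the empirical canonical
#' CTF. The display variant appends the wrap-around (most distant) channel
#' so plots are symmetric.
#'
#' @param cond_means k x k matrix: column p = mean channel response vector
#'   of condition p (rows = channels).
#' @param center center channel (default 4).
#' @param display if `TRUE`, append the wrap-around channel (k+1 values).
#' @return an object of class `ctf`: the canonical per-channel `response`,
#'   the aligned per-condition matrix `aligned` (channels x conditions),
#'   `center` and `k`.
#' @export
canonical_ctf <- function(cond_means, center = 4L, display = FALSE) {
  cond_means <- as.matrix(cond_means)
  k <- nrow(cond_means)
  if (ncol(cond_means) != k)
    stopf("cond_means must be k x k (channels x conditions)")
  if (!is_count(center) || center > k) stopf("center must be in 1..%d", k)
  aligned <- sapply(seq_len(k), function(p)
    circshift(cond_means[, p], center - p))
  out <- structure(list(response = rowMeans(aligned), aligned = aligned,
                        center = as.integer(center), k = k),
                   class = "ctf")
  if (display) out$display <- ctf_display(out)
  out
}

# display variant: prepend the wrap-around (most distant) channel so the
# plotted CTF is symmetric about the center (k + 1 values, even k only)
ctf_display <- function(ctf) {
  if (ctf$k %% 2 != 0)
    stopf("display variant is defined for an even channel count")
  far <- 1 + ((ctf$center - 1 + ctf$k %/% 2) %% ctf$k)
  stats::setNames(c(ctf$response[far], ctf$response),
                  c(-(ctf$k %/% 2), seq_len(ctf$k) - ctf$center))
}

#' @export
print.ctf <- function(x, ...) {
  cat(sprintf("<ctf> %d channels centred at %d; response: %s\n", x$k,
              x$center, paste(sprintf("%.3f", x$response), collapse = " ")))
  invisible(x)
}

#' Fit the forward encoding model over time
#'
#' The central fitting function: for every requested time sample and fold,
#' estimates delta-basis weights on the training folds, inverts the model on
#' the held-out fold, accumulates single-trial channel responses until every
#' trial has been tested once, averages them per condition, aligns the
#' per-condition responses to a common center and averages across conditions
#' — yielding the canonical CTF as a function of time, along with the
#' fold-averaged weight matrices used for topography reconstruction.
#'
#' @param epochs a preprocessed `eeg_epochs`.
#' @param labels per-trial position labels (default `epochs$labels`).
#' @param folds a [assign_folds()] result (default: 10 seeded folds).
#' @param basis a [basis_set()] (default: delta basis).
#' @param center center channel for alignment (default 4).
#' @param samples optional sample-index subset (default: all).
#' @return an object of class `fem`: `ctf` (channels x samples canonical
#'   CTF), `cond_means` (channels x conditions x samples), `W` (electrodes x
#'   channels x samples, averaged over folds), `times`, `center`,
#'   `electrodes`, and fold bookkeeping.
#' @export
fem <- function(epochs, labels = epochs$labels, folds = NULL, basis = NULL,
                center = 4L, samples = NULL) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  labels <- as.integer(labels)
  k <- max(labels)
  if (is.null(basis)) basis <- basis_set(k)
  if (basis$k != k) stopf("basis has %d channels but labels imply %d",
                          basis$k, k)
  if (!is_count(center) || center > k) stopf("center must be in 1..%d", k)
  if (is.null(folds)) folds <- assign_folds(labels, K = 10L, seed = 1L)
  if (length(folds$fold) != length(labels))
    stopf("fold assignment does not match the trial count")
  if (is.null(samples)) samples <- seq_len(n_samples(epochs))
  m <- n_electrodes(epochs)
  Tn <- length(samples)
  K <- folds$K
  ctf_mat <- matrix(NA_real_, k, Tn)
  cond_means <- array(NA_real_, dim = c(k, k, Tn))
  Wbar <- array(0, dim = c(m, k, Tn),
                dimnames = list(epochs$electrodes, NULL, NULL))
  C1_full <- build_design(labels, basis)
  for (si in seq_len(Tn)) {
    X <- t(epochs$data[, , samples[si], drop = TRUE])   # electrodes x trials
    C2 <- matrix(NA_real_, k, length(labels))
    for (f in seq_len(K)) {
      tr <- folds$fold != f
      mod <- estimate_weights(X[, tr, drop = FALSE],
                              C1_full[, tr, drop = FALSE])
      C2[, !tr] <- invert_model(mod, X[, !tr, drop = FALSE])
      Wbar[, , si] <- Wbar[, , si] + mod$W / K
    }
    cm <- sapply(seq_len(k), function(p)
      rowMeans(C2[, labels == p, drop = FALSE]))
    cond_means[, , si] <- cm
    ctf_mat[, si] <- canonical_ctf(cm, center = center)$response
  }
  structure(list(ctf = ctf_mat, cond_means = cond_means, W = Wbar,
                 times = epochs$times[samples], sample_index = samples,
                 center = as.integer(center), k = k,
                 electrodes = epochs$electrodes, folds = folds,
                 basis = basis),
            class = "fem")
}

#' @rdname fem
#' @export
ctf_timecourse <- fem

#' @export
print.fem <- function(x, ...) {
  cat(sprintf(paste0("<fem> %d position channels x %d electrodes, %d time ",
                     "samples (%g..%g ms), %s basis, centred at channel ",
                     "%d\n"),
              x$k, length(x$electrodes), length(x$times), min(x$times),
              max(x$times), x$basis$kind, x$center))
  invisible(x)
}

#' @export
summary.fem <- function(object, ...) {
  # tuning strength: center minus most-distant channel of the canonical CTF
  far <- 1 + ((object$center - 1 + object$k %/% 2) %% object$k)
  tuning <- object$ctf[object$center, ] - object$ctf[far, ]
  pk <- find_peak(tuning, object$times)
  out <- list(k = object$k, center = object$center,
              peak_tuning = unname(pk["value"]),
              peak_latency_ms = unname(pk["latency_ms"]))
  class(out) <- "summary.fem"
  out
}

#' @export
print.summary.fem <- function(x, ...) {
  cat(sprintf(paste0("Forward encoding model: %d channels, center %d\n  ",
                     "peak center-minus-edge tuning %.3f at %g ms\n"),
              x$k, x$center, x$peak_tuning, x$peak_latency_ms))
  invisible(x)
}

#' @export
plot.fem <- function(x, ...) {
  graphics::image(x$times, seq_len(x$k), t(x$ctf),
                  xlab = "time (ms)", ylab = "channel (aligned)",
                  main = "canonical CTF over time", ...)
  invisible(x)
}

#' Fold- and window-averaged encoding weights
#'
#' @param object a `fem`.
#' @param window optional (start, end) ms pair; weights are averaged over
#'   the samples inside it (e.g. 260-270 ms). Default: all samples.
#' @param ... unused.
#' @return m x k weight matrix.
#' @export
coef.fem <- function(object, window = NULL, ...) {
  idx <- if (is.null(window)) seq_along(object$times)
         else which(object$times >= window[1] & object$times <= window[2])
  if (!length(idx)) stopf("window contains no fitted samples")
  W <- apply(object$W[, , idx, drop = FALSE], c(1, 2), mean)
  rownames(W) <- object$electrodes
  W
}

#' Window-averaged canonical CTF
#'
#' @param object a `fem`.
#' @param window optional (start, end) ms pair.
#' @return a `ctf` object averaged over the window.
#' @export
ctf_window <- function(object, window = NULL) {
  stopifnot(inherits(object, "fem"))
  idx <- if (is.null(window)) seq_along(object$times)
         else which(object$times >= window[1] & object$times <= window[2])
  if (!length(idx)) stopf("window contains no fitted samples")
  cm <- apply(object$cond_means[, , idx, drop = FALSE], c(1, 2), mean)
  canonical_ctf(cm, center = object$center)
}

#' Center-versus-edge tuning statistic across subjects
#'
#' Per time sample, a paired two-sided t statistic comparing the center
#' channel response with the most distant (boundary) channel response across
#' subjects; feed the per-subject differences into
#' [cluster_permutation_time()] for multiple-comparison correction.
#'
#' @param ctf_subjects subjects x channels x samples array of aligned CTFs.
#' @param center center channel (default 4).
#' @return a list with per-sample `t`, `p`, the subjects x samples
#'   difference matrix `diff`, and `df`.
#' @export
ctf_tuning_stat <- function(ctf_subjects, center = 4L) {
  d <- dim(ctf_subjects)
  if (is.null(d) || length(d) != 3L)
    stopf("ctf_subjects must be subjects x channels x samples")
  if (d[1] < 2) stopf("need at least 2 subjects")
  k <- d[2]
  far <- 1 + ((center - 1 + k %/% 2) %% k)
  diff <- ctf_subjects[, center, ] - ctf_subjects[, far, ]
  if (is.null(dim(diff))) diff <- matrix(diff, nrow = d[1])
  tt <- ttest_series(diff, 0)
  list(t = tt$t, p = tt$p, diff = diff, df = d[1] - 1)
}

#' Hypothetical channel response for an arbitrary position
#'
#' Constructs the channel-response vector for any position on the stimulus
#' circle from a canonical CTF: the CTF is first made line-symmetric about
#' its center (averaged with its mirror image), then circularly re-centered
#' on each of the two neighbouring position channels; the result is their
#' weighted average. Midpoint tags map to equal-weight neighbour pairs:
#' top = (8, 1), right = (2, 3), bottom = (4, 5), left = (6, 7).
#'
#' @param ctf a `ctf` object (or bare k-vector plus `center`).
#' @param position one of `"top"`, `"right"`, `"bottom"`, `"left"`, or a
#'   numeric angle in degrees (clockwise from top).
#' @param center center channel if `ctf` is a bare vector.
#' @param angles position-channel angles (degrees, clockwise from top);
#'   default the eight off-midline positions 22.5 + 45 (j - 1).
#' @return numeric k-vector of hypothetical channel responses.
#' @export
interpolate_channel_response <- function(ctf, position, center = NULL,
                                         angles = NULL) {
  if (inherits(ctf, "ctf")) {
    v <- ctf$response; center <- ctf$center; k <- ctf$k
  } else {
    v <- as.numeric(ctf); k <- length(v)
    if (is.null(center)) stopf("center is required for a bare CTF vector")
  }
  if (is.null(angles)) angles <- 22.5 + 45 * (seq_len(k) - 1)
  if (length(angles) != k) stopf("angles must have one entry per channel")
  # line-symmetrized CTF: average of the aligned CTF and its mirror about
  # the center channel (channel center + d <-> center - d)
  mirror <- v[1 + ((2 * (center - 1) - (seq_len(k) - 1)) %% k)]
  sym <- (v + mirror) / 2
  hypo <- function(p) circshift(sym, p - center)
  if (is.character(position)) {
    tags <- list(top = c(8L, 1L), right = c(2L, 3L), bottom = c(4L, 5L),
                 left = c(6L, 7L))
    if (k != 8L && position %in% names(tags))
      stopf("midpoint tags assume the 8-position layout")
    if (!position %in% names(tags))
      stopf("unknown position tag '%s'", position)
    pr <- tags[[position]]
    (hypo(pr[1]) + hypo(pr[2])) / 2
  } else {
    a <- as.numeric(position) %% 360
    # neighbours on the circle and inverse-distance weights
    d <- circ_dist_deg(a, angles %% 360)
    ord <- order(d)
    n1 <- ord[1]; n2 <- ord[2]
    if (d[n1] < 1e-9) return(hypo(n1))
    w1 <- d[n2] / (d[n1] + d[n2]); w2 <- 1 - w1
    w1 * hypo(n1) + w2 * hypo(n2)
  }
}

#' Reconstruct a scalp topography from channel responses
#'
#' Multiplies a channel-response vector with the encoding weights:
#' `pattern = W c`. With a delta response at position p this returns column
#' p of W (the condition-mean topography); with interpolated responses it
#' predicts the topography of a position that was never presented.
#'
#' @param model an `encoding_model`, `fem` (uses [coef.fem()] with
#'   `window`), or bare m x k weight matrix.
#' @param response numeric k-vector of channel responses.
#' @param window passed to [coef.fem()] when `model` is a `fem`.
#' @return an `activation_pattern` (unnormalized).
#' @export
reconstruct_topography <- function(model, response, window = NULL) {
  W <- if (inherits(model, "fem")) coef(model, window = window)
       else if (inherits(model, "encoding_model")) model$W
       else as.matrix(model)
  response <- as.numeric(response)
  if (ncol(W) != length(response))
    stopf("response has %d channels but W has %d columns",
          length(response), ncol(W))
  values <- drop(W %*% response)
  names(values) <- rownames(W)
  structure(list(values = values, normalized = FALSE, contrast = NULL,
                 window = window),
            class = "activation_pattern")
}

#' Predict method for forward encoding models
#'
#' `predict(fem, position = "top")` reconstructs the scalp topography for an
#' arbitrary (possibly never-presented) position; with `newdata` (electrodes
#' x trials), estimates channel responses for new data by model inversion.
#'
#' @param object a `fem`.
#' @param position position tag or angle passed to
#'   [interpolate_channel_response()].
#' @param newdata optional electrodes x trials matrix.
#' @param window (start, end) ms window over which weights/CTF are averaged.
#' @param ... unused.
#' @return an `activation_pattern` (for `position`) or a k x n matrix of
#'   channel responses (for `newdata`).
#' @export
predict.fem <- function(object, position = NULL, newdata = NULL,
                        window = NULL, ...) {
  if (!is.null(newdata)) {
    W <- coef(object, window = window)
    return(invert_model(W, newdata))
  }
  if (is.null(position)) stopf("supply either position or newdata")
  resp <- interpolate_channel_response(ctf_window(object, window), position)
  reconstruct_topography(object, resp, window = window)
}

#' Contrast two activation patterns and normalize
#'
#' Elementwise difference of two patterns (e.g. constructed left minus
#' right) followed by spatial normalization to Z-scores.
#'
#' @param pattern_a,pattern_b `activation_pattern`s (or numeric vectors)
#'   over the same electrode set.
#' @return a normalized `activation_pattern`.
#' @export
contrast_and_normalize <- function(pattern_a, pattern_b) {
  va <- if (inherits(pattern_a, "activation_pattern")) pattern_a$values
        else pattern_a
  vb <- if (inherits(pattern_b, "activation_pattern")) pattern_b$values
        else pattern_b
  if (length(va) != length(vb)) stopf("patterns have different electrode sets")
  if (!is.null(names(va)) && !is.null(names(vb)) &&
      !identical(names(va), names(vb)))
    stopf("patterns have different electrode sets")
  spatial_normalize(structure(list(values = va - vb, normalized = FALSE,
                                   contrast = NULL, window = NULL),
                              class = "activation_pattern"))
}

#' Compare two groups of activation patterns
#'
#' Pearson correlation across electrodes between the two group-mean
#' patterns, plus a per-electrode unpaired t test with cluster-based
#' permutation correction over the electrode adjacency graph. Electrodes not
#' shared by both groups must be dropped by the caller first.
#'
#' @param group_a,group_b subjects x electrodes matrices (same electrode
#'   columns).
#' @param adjacency electrode adjacency matrix (e.g. `montage$adjacency`).
#' @param cluster_alpha per-electrode two-sided threshold (default 0.05).
#' @param n_perm permutations (default 1000).
#' @param seed RNG seed.
#' @return a list with `correlation` (of the group means) and `clusters`
#'   (a `cluster_result` from [cluster_permutation_topo()]).
#' @export
compare_patterns <- function(group_a, group_b, adjacency,
                             cluster_alpha = 0.05, n_perm = 1000,
                             seed = 1L) {
  group_a <- as.matrix(group_a); group_b <- as.matrix(group_b)
  if (ncol(group_a) != ncol(group_b))
    stopf("groups have different electrode counts")
  if (nrow(group_a) < 2 || nrow(group_b) < 2)
    stopf("need at least 2 subjects per group")
  r <- stats::cor(colMeans(group_a), colMeans(group_b))
  cl <- cluster_permutation_topo(group_a, group_b, adjacency,
                                 cluster_alpha = cluster_alpha,
                                 n_perm = n_perm, seed = seed)
  list(correlation = r, clusters = cl)
}

#' Export a CTF time course / weight map as CSV
#'
#' @param x a `fem`.
#' @param ctf_path CSV of the canonical CTF
#'   (`time_ms, channel_offset, response`).
#' @param weights_path optional CSV of window-averaged weights
#'   (`electrode, channel, weight`).
#' @param window window for the weight average.
#' @param config_hash optional provenance hash (comment line).
#' @export
write_fem <- function(x, ctf_path, weights_path = NULL, window = NULL,
                      config_hash = NULL) {
  offs <- seq_len(x$k) - x$center
  df <- data.frame(time_ms = rep(x$times, each = x$k),
                   channel_offset = rep(offs, length(x$times)),
                   response = as.vector(x$ctf))
  con <- file(ctf_path, "w")
  if (!is.null(config_hash))
    writeLines(sprintf("# config_hash: %s", config_hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  close(con)
  if (!is.null(weights_path)) {
    W <- coef(x, window = window)
    dfw <- data.frame(electrode = rep(rownames(W), ncol(W)),
                      channel = rep(seq_len(ncol(W)), each = nrow(W)),
                      weight = as.vector(W))
    con <- file(weights_path, "w")
    if (!is.null(config_hash))
      writeLines(sprintf("# config_hash: %s", config_hash), con)
    utils::write.csv(dfw, con, row.names = FALSE)
    close(con)
  }
  invisible(ctf_path)
}
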