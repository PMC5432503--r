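# Backward decoding model: per-timepoint k-fold linear-discriminant
# classification, class-balanced accuracy time courses, covariance-based
# (Haufe) activation patterns, spatial normalization, display smoothing and
# peak finding.

#' Stratified fold assignment
#'
#' Randomly assigns trials to `K` cross-validation folds, stratified by
#' class: within each class trials are shuffled and dealt round-robin, so
#' folds are equally sized (within one trial) and every class appears in
#' every training split. Seeded for reproducibility; the randomisation also
#' destroys any information carried by trial acquisition order.
#'
#' @param labels per-trial class labels.
#' @param K number of folds (default 10).
#' @param seed integer RNG seed.
#' @return an object of class `fold_assignment`: integer fold index per
#'   trial plus `K` and `seed`.
#' @export
assign_folds <- function(labels, K = 10L, seed = 1L) {
  counts <- table(labels)
  if (any(counts < K))
    stopf("class(es) %s have fewer than K=%d trials",
          paste(names(counts)[counts < K], collapse = ", "), K)
  set.seed(seed)
  fold <- integer(length(labels))
  offset <- 0L
  for (cl in names(counts)) {
    idx <- sample(which(labels == cl))
    # rotate the dealing start per class so fold sizes stay balanced overall
    fold[idx] <- ((seq_along(idx) - 1L + offset) %% K) + 1L
    offset <- (offset + length(idx)) %% K
  }
  structure(list(fold = fold, K = as.integer(K), seed = as.integer(seed)),
            class = "fold_assignment")
}

# Ledoit-Wolf-style shrinkage of a covariance estimate toward the scaled
# identity. X must already be centred (per class for a pooled estimate).
# Returns the shrunk covariance and the intensity used.
shrink_covariance <- function(Xc, n_obs = nrow(Xc)) {
  m <- ncol(Xc)
  S <- crossprod(Xc) / n_obs
  mu <- mean(diag(S))
  D <- S - diag(mu, m)
  d2 <- sum(D^2)
  if (d2 < .Machine$double.eps) {
    lambda <- 1
  } else {
    # average squared distance of per-observation outer products from S
    x2 <- rowSums(Xc^2)
    b2 <- (sum(x2^2) / n_obs - sum(S^2)) / n_obs
    b2 <- min(max(b2, 0), d2)
    lambda <- b2 / d2
  }
  sigma <- lambda * diag(mu, m) + (1 - lambda) * S
  # degenerate case (e.g. noise-free data): keep the solve well defined
  if (mu <= 0 || rcond(sigma) < 1e-12)
    sigma <- sigma + diag(max(mu, 1) * 1e-10, m)
  list(sigma = sigma, lambda = lambda)
}

#' Train a linear discriminant classifier at one time sample
#'
#' Classic LDA: class means plus a pooled covariance estimated from
#' class-centred training data, shrunk toward the scaled identity with an
#' automatically selected (Ledoit-Wolf) intensity so that rank-deficient or
#' ill-conditioned covariances (few trials, many electrodes) remain
#' invertible. Discriminant scores assume equal class priors; assignment is
#' the argmax of the score, ties broken by the lowest class index.
#'
#' @param train_data trials x electrodes numeric matrix at one time sample.
#' @param labels per-trial class labels (>= 2 classes present).
#' @param shrinkage `"auto"` (Ledoit-Wolf), a number in \[0, 1\], or 0 for
#'   the unshrunk pooled covariance.
#' @return an object of class `lda_classifier` with electrode x class
#'   `weights`, per-class `intercepts`, the (shrunk) `pooled_covariance`,
#'   `class_levels` and the shrinkage intensity `lambda`.
#' @export
train_lda <- function(train_data, labels, shrinkage = "auto") {
  X <- as.matrix(train_data)
  labels <- as.factor(labels)
  lev <- levels(droplevels(labels))
  if (length(lev) < 2) stopf("need at least 2 classes to train a classifier")
  m <- ncol(X)
  M <- t(sapply(lev, function(cl) colMeans(X[labels == cl, , drop = FALSE])))
  Xc <- X - M[as.character(labels), , drop = FALSE]
  if (identical(shrinkage, "auto")) {
    sc <- shrink_covariance(Xc)
  } else {
    lambda <- as.numeric(shrinkage)
    S <- crossprod(Xc) / nrow(Xc)
    sc <- list(sigma = lambda * diag(mean(diag(S)), m) + (1 - lambda) * S,
               lambda = lambda)
    if (lambda == 0 && rcond(sc$sigma) < 1e-12) {
      warning("singular pooled covariance; falling back to auto shrinkage")
      sc <- shrink_covariance(Xc)
    }
  }
  A <- solve(sc$sigma, t(M))                    # electrodes x classes
  intercepts <- -0.5 * colSums(t(M) * A)        # equal priors
  dimnames(A) <- list(colnames(X), lev)
  structure(list(weights = A, intercepts = intercepts,
                 pooled_covariance = sc$sigma, lambda = sc$lambda,
                 class_levels = lev),
            class = "lda_classifier")
}

#' @export
print.lda_classifier <- function(x, ...) {
  cat(sprintf("<lda_classifier> %d classes x %d features, shrinkage %.3f\n",
              length(x$class_levels), nrow(x$weights), x$lambda))
  invisible(x)
}

#' @export
predict.lda_classifier <- function(object, newdata, ...) {
  scores <- as.matrix(newdata) %*% object$weights +
    matrix(object$intercepts, nrow(as.matrix(newdata)),
           length(object$intercepts), byrow = TRUE)
  object$class_levels[max.col(scores, ties.method = "first")]
}

#' Per-timepoint k-fold backward decoding
#'
#' For every time sample (or a subset), trains an LDA classifier on K-1
#' folds and tests on the held-out fold, repeating until every trial has been
#' tested once. Accuracy is the proportion of correct class assignments,
#' computed first per class (condition), then averaged across classes, then
#' across folds — so unequal class counts in a test fold cannot bias the
#' aggregate.
#'
#' @param epochs a preprocessed `eeg_epochs`.
#' @param labels per-trial class labels; defaults to `epochs$labels`.
#' @param folds a [assign_folds()] result (defaults to 10 seeded folds).
#' @param samples optional integer vector of sample indices to decode
#'   (default: all).
#' @param electrodes optional electrode subset used as features.
#' @param shrinkage passed to [train_lda()].
#' @return an object of class `bdm`: accuracy array `samples x folds x
#'   classes`, per-sample `aggregate`, `chance`, `times`, class levels and
#'   fold bookkeeping.
#' @export
bdm <- function(epochs, labels = epochs$labels, folds = NULL, samples = NULL,
                electrodes = NULL, shrinkage = "auto") {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (length(labels) != n_trials(epochs))
    stopf("labels must have one entry per trial")
  if (is.null(folds)) folds <- assign_folds(labels, K = 10L, seed = 1L)
  if (length(folds$fold) != length(labels))
    stopf("fold assignment does not match the trial count")
  ei <- if (is.null(electrodes)) seq_len(n_electrodes(epochs))
        else electrode_index(epochs, electrodes)
  if (is.null(samples)) samples <- seq_len(n_samples(epochs))
  labels <- as.factor(labels)
  lev <- levels(labels)
  k <- length(lev)
  K <- folds$K
  acc <- array(NA_real_, dim = c(length(samples), K, k),
               dimnames = list(NULL, NULL, lev))
  for (si in seq_along(samples)) {
    X <- epochs$data[, ei, samples[si], drop = TRUE]
    if (is.null(dim(X))) X <- matrix(X, ncol = length(ei))
    for (f in seq_len(K)) {
      tr <- folds$fold != f
      te <- !tr
      clf <- train_lda(X[tr, , drop = FALSE], labels[tr],
                       shrinkage = shrinkage)
      pred <- predict(clf, X[te, , drop = FALSE])
      truth <- as.character(labels[te])
      for (ci in seq_len(k))
        acc[si, f, ci] <- mean(pred[truth == lev[ci]] == lev[ci])
    }
  }
  aggregate <- apply(apply(acc, c(1, 2), mean, na.rm = TRUE), 1, mean)
  structure(list(accuracy = acc, aggregate = aggregate, chance = 1 / k,
                 times = epochs$times[samples], sample_index = samples,
                 class_levels = lev, folds = folds,
                 n_features = length(ei)),
            class = "bdm")
}

#' @rdname bdm
#' @export
decode_timecourse <- bdm

#' @export
print.bdm <- function(x, ...) {
  pk <- find_peak(x$aggregate, x$times)
  cat(sprintf(paste0("<bdm> %d-class decoding, %d features, %d folds, ",
                     "%d samples\n  chance %.3f, mean accuracy %.3f, ",
                     "peak %.3f at %g ms\n"),
              length(x$class_levels), x$n_features, x$folds$K,
              length(x$aggregate), x$chance, mean(x$aggregate),
              pk["value"], pk["latency_ms"]))
  invisible(x)
}

#' @export
summary.bdm <- function(object, ...) {
  pk <- find_peak(object$aggregate, object$times)
  out <- list(n_classes = length(object$class_levels),
              chance = object$chance,
              mean_accuracy = mean(object$aggregate),
              peak_latency_ms = unname(pk["latency_ms"]),
              peak_accuracy = unname(pk["value"]),
              n_features = object$n_features, K = object$folds$K)
  class(out) <- "summary.bdm"
  out
}

#' @export
print.summary.bdm <- function(x, ...) {
  cat(sprintf(paste0("Backward decoding: %d classes (chance %.3f), ",
                     "%d features, %d folds\n  mean accuracy %.3f; peak ",
                     "%.3f at %g ms\n"),
              x$n_classes, x$chance, x$n_features, x$K, x$mean_accuracy,
              x$peak_accuracy, x$peak_latency_ms))
  invisible(x)
}

#' @export
plot.bdm <- function(x, smooth = TRUE, ...) {
  y <- if (smooth && length(x$aggregate) > 8)
    smooth_for_display(x$aggregate, x$times) else x$aggregate
  graphics::plot(x$times, x$aggregate, type = "l", col = "grey70",
                 xlab = "time (ms)", ylab = "classification accuracy", ...)
  if (smooth && length(x$aggregate) > 8)
    graphics::lines(x$times, y, col = "black", lwd = 2)
  graphics::abline(h = x$chance, lty = 2)
  invisible(x)
}

#' Haufe activation pattern from classifier weights
#'
#' Multiplies an extraction (weight) vector with the data covariance matrix,
#' turning backward-model weights into an activation pattern interpretable
#' as neural sources: for a two-class LDA this returns (up to scale) the
#' mass-univariate difference between the two conditions.
#'
#' @param classifier an `lda_classifier`.
#' @param data trials x electrodes matrix the covariance is computed from
#'   (the training data of the same fold, by convention).
#' @param contrast either a pair of class levels/indices (pairwise contrast,
#'   default the first two classes) or a single class for a
#'   class-versus-rest contrast.
#' @return an object of class `activation_pattern`: per-electrode `values`,
#'   `normalized` flag, and the contrast used.
#' @export
haufe_pattern <- function(classifier, data, contrast = NULL) {
  data <- as.matrix(data)
  if (ncol(data) != nrow(classifier$weights))
    stopf("data has %d electrodes but the classifier expects %d",
          ncol(data), nrow(classifier$weights))
  lev <- classifier$class_levels
  if (is.null(contrast)) contrast <- lev[1:2]
  contrast <- as.character(contrast)
  if (!all(contrast %in% lev)) {
    ix <- suppressWarnings(as.integer(contrast))
    if (all(!is.na(ix)) && all(ix >= 1 & ix <= length(lev)))
      contrast <- lev[ix]
    else stopf("unknown contrast class(es): %s", toString(contrast))
  }
  W <- classifier$weights
  w <- if (length(contrast) == 2L) W[, contrast[1]] - W[, contrast[2]]
       else W[, contrast] - rowMeans(W[, setdiff(lev, contrast), drop = FALSE])
  n <- nrow(data)
  Xc <- scale(data, center = TRUE, scale = FALSE)
  sigma <- crossprod(Xc) / (n - 1)
  values <- drop(sigma %*% w)
  names(values) <- rownames(W)
  structure(list(values = values, normalized = FALSE,
                 contrast = contrast, window = NULL),
            class = "activation_pattern")
}

#' @export
print.activation_pattern <- function(x, ...) {
  cat(sprintf("<activation_pattern> %d electrodes%s%s\n", length(x$values),
              if (x$normalized) ", spatially normalized" else "",
              if (!is.null(x$contrast))
                paste0(", contrast ", paste(x$contrast, collapse = " vs "))
              else ""))
  invisible(x)
}

#' Spatial normalization of an activation pattern
#'
#' Subtracts the mean across electrodes and divides by the standard
#' deviation across electrodes (population convention, divide-by-n), so that
#' patterns from different recordings can be compared as Z-scores.
#'
#' @param pattern an `activation_pattern` or bare numeric vector.
#' @return the normalized pattern (mean 0, population SD 1), with the
#'   `normalized` flag set.
#' @export
spatial_normalize <- function(pattern) {
  v <- if (inherits(pattern, "activation_pattern")) pattern$values
       else pattern
  if (length(v) < 2) stopf("need at least 2 electrodes to normalize")
  s <- sd_pop(v)
  if (s < .Machine$double.eps * max(1, abs(mean(v))))
    stopf("zero spread across electrodes; cannot normalize a constant pattern")
  z <- (v - mean(v)) / s
  if (inherits(pattern, "activation_pattern")) {
    pattern$values <- z
    pattern$normalized <- TRUE
    pattern
  } else {
    structure(list(values = z, normalized = TRUE, contrast = NULL,
                   window = NULL),
              class = "activation_pattern")
  }
}

#' Display smoothing of an accuracy time course
#'
#' For presentation only: resamples the series to `target_rate` on a grid
#' anchored at the peak sample (so the peak value is retained exactly and
#' not diluted), then interpolates a spline through the retained points back
#' onto the original time axis. Statistics must always use the raw series.
#'
#' @param series numeric per-sample values.
#' @param times sample times, ms.
#' @param sfreq original sampling rate, Hz (inferred from `times` if NULL).
#' @param target_rate display rate, Hz (default 32).
#' @return numeric vector on the original time axis with attributes
#'   `retained` (indices of the anchor grid) and `display_only = TRUE`.
#' @export
smooth_for_display <- function(series, times, sfreq = NULL,
                               target_rate = 32) {
  if (!length(series)) stopf("empty series")
  if (length(series) != length(times)) stopf("series/times length mismatch")
  if (is.null(sfreq)) sfreq <- 1000 / mean(diff(times))
  step <- max(1L, as.integer(round(sfreq / target_rate)))
  peak <- which.max(series)
  idx <- sort(unique(c(seq(peak, 1L, by = -step),
                       seq(peak, length(series), by = step))))
  if (length(idx) < 4) return(structure(series, retained = idx,
                                        display_only = TRUE))
  sm <- stats::spline(times[idx], series[idx], xout = times,
                      method = "natural")$y
  structure(sm, retained = idx, display_only = TRUE)
}

#' Peak latency and value of a time course
#'
#' @param series numeric per-sample values.
#' @param times sample times, ms.
#' @param window optional (start, end) ms pair restricting the search.
#' @return named numeric vector `c(latency_ms, value)`; on ties the earliest
#'   sample wins.
#' @export
find_peak <- function(series, times, window = NULL) {
  stopifnot(length(series) == length(times))
  keep <- if (is.null(window)) seq_along(series)
          else which(times >= window[1] & times <= window[2])
  if (!length(keep)) stopf("peak search window contains no samples")
  i <- keep[which.max(series[keep])]     # which.max returns the first max
  c(latency_ms = times[i], value = series[i])
}

#' Export a decoding result as CSV and JSON summary
#'
#' @param x a `bdm`.
#' @param csv_path per-sample/fold/class accuracy CSV
#'   (`time_ms, accuracy, fold, class`).
#' @param json_path optional JSON summary (peak latency/value, chance).
#' @param config_hash optional provenance hash embedded in both outputs.
#' @export
write_bdm <- function(x, csv_path, json_path = NULL, config_hash = NULL) {
  d <- dim(x$accuracy)
  df <- data.frame(
    time_ms = rep(x$times, times = d[2] * d[3]),
    accuracy = as.vector(x$accuracy),
    fold = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    class = rep(x$class_levels, each = d[1] * d[2]))
  con <- file(csv_path, "w")
  if (!is.null(config_hash))
    writeLines(sprintf("# config_hash: %s", config_hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  close(con)
  if (!is.null(json_path)) {
    pk <- find_peak(x$aggregate, x$times)
    jsonlite::write_json(
      list(peak_latency_ms = unname(pk["latency_ms"]),
           peak_accuracy = unname(pk["value"]), chance = x$chance,
           n_classes = length(x$class_levels), K = x$folds$K,
           config_hash = config_hash),
      json_path, auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(csv_path)
}
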