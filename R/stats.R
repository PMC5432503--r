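# Sample-wise t tests with cluster-based permutation correction over
# contiguous time samples and over electrode neighbourhoods
# (max-sum-of-t statistic, sign-flip or group-exchange permutation).

#' One-sample t test per time sample
#'
#' Two-sided one-sample t against `null_value` at every column of a
#' subjects x samples matrix. Zero-variance samples yield infinite t (with a
#' warning); their parametric p is set to 0 when the mean differs from the
#' null and 1 otherwise.
#'
#' @param values subjects x samples numeric matrix.
#' @param null_value scalar null hypothesis value (default 0).
#' @return a list with per-sample `t`, two-sided `p`, and `df`.
#' @export
ttest_series <- function(values, null_value = 0) {
  values <- as.matrix(values)
  S <- nrow(values)
  if (S < 2) stopf("need at least 2 subjects")
  x <- values - null_value
  m <- colMeans(x)
  v <- (colSums(x^2) - S * m^2) / (S - 1)
  v[v < 0] <- 0
  se <- sqrt(v / S)
  t <- m / se
  if (any(!is.finite(t))) {
    warning("zero-variance sample(s): t is infinite/undefined")
    t[se == 0 & m != 0] <- sign(m[se == 0 & m != 0]) * Inf
    t[se == 0 & m == 0] <- 0
  }
  p <- 2 * stats::pt(-abs(t), df = S - 1)
  p[is.infinite(t)] <- 0
  list(t = t, p = p, df = S - 1)
}

# contiguous clusters of supra-threshold same-sign samples;
# returns list of (from, to, mass, sign)
time_clusters <- function(t, sig) {
  code <- integer(length(t))
  code[sig & t > 0] <- 1L
  code[sig & t < 0] <- -1L
  r <- rle(code)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values != 0L)
  lapply(keep, function(i) {
    idx <- starts[i]:ends[i]
    list(from = starts[i], to = ends[i], mass = sum(t[idx]),
         sign = r$values[i])
  })
}

max_cluster_mass_time <- function(t, sig) {
  cl <- time_clusters(t, sig)
  if (!length(cl)) 0 else max(abs(vapply(cl, `[[`, 0, "mass")))
}

# fast sign-flip t statistics: flipping signs leaves sum(x^2) unchanged,
# so only the mean must be recomputed per permutation
flip_t_matrix <- function(x, signs) {
  S <- nrow(x)
  M <- (signs %*% x) / S                        # perms x samples
  ss <- matrix(colSums(x^2), nrow(M), ncol(M), byrow = TRUE)
  v <- (ss - S * M^2) / (S - 1)
  v[v < 0] <- 0
  M / sqrt(v / S)
}

new_cluster_result <- function(clusters, n_permutations, cluster_alpha,
                               seed, type) {
  structure(list(clusters = clusters, n_permutations = n_permutations,
                 cluster_alpha = cluster_alpha, seed = seed, type = type),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %s, %d cluster(s), %s permutations\n",
              x$type, length(x$clusters),
              if (is.na(x$n_permutations)) "exhaustive"
              else as.character(x$n_permutations)))
  for (cl in x$clusters) {
    where <- if (!is.null(cl$from))
      sprintf("samples %d..%d", cl$from, cl$to)
    else sprintf("electrodes {%s}", paste(cl$members, collapse = ","))
    cat(sprintf("  %s: mass %.2f (%s), p = %.4g\n", where, cl$mass,
                if (cl$sign > 0) "+" else "-", cl$p))
  }
  invisible(x)
}

#' Cluster-based permutation test over contiguous time samples
#'
#' One-sample test across subjects at every time sample; contiguous runs of
#' samples with two-sided p below `cluster_alpha` and a common sign form
#' clusters whose mass is the sum of their t values. The null distribution
#' is the maximum absolute cluster mass over random subject-level sign flips
#' of `values - null_value`; each observed cluster's p-value is the
#' proportion of permutations whose maximum mass reaches its absolute mass,
#' using the (b + 1) / (n_perm + 1) convention. With
#' `method = "exhaustive"`, all 2^S sign-flip patterns are enumerated and
#' p-values are exact proportions over the full enumeration.
#'
#' @param values subjects x samples numeric matrix.
#' @param null_value scalar subtracted before testing (e.g. chance level).
#' @param cluster_alpha sample-level two-sided threshold (default 0.05).
#' @param n_perm number of random permutations (default 1000).
#' @param seed RNG seed.
#' @param method `"montecarlo"` (default) or `"exhaustive"` (feasible for
#'   small subject counts).
#' @return a `cluster_result`; each cluster has `from`, `to` (sample
#'   indices), `mass`, `sign` and `p`.
#' @export
cluster_permutation_time <- function(values, null_value = 0,
                                     cluster_alpha = 0.05, n_perm = 1000,
                                     seed = 1L,
                                     method = c("montecarlo", "exhaustive")) {
  method <- match.arg(method)
  values <- as.matrix(values)
  S <- nrow(values)
  if (S < 2) stopf("need at least 2 subjects")
  if (method == "montecarlo" && n_perm < 1) stopf("n_perm must be >= 1")
  x <- values - null_value
  tcrit <- stats::qt(1 - cluster_alpha / 2, df = S - 1)
  obs <- ttest_series(x, 0)
  obs_cl <- time_clusters(obs$t, abs(obs$t) > tcrit)
  if (method == "exhaustive") {
    if (S > 20) stopf("exhaustive enumeration is limited to <= 20 subjects")
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), S)))
    denom <- nrow(signs)
    n_used <- NA_integer_
  } else {
    set.seed(seed)
    signs <- matrix(sample(c(-1, 1), n_perm * S, replace = TRUE), n_perm, S)
    denom <- n_perm + 1
    n_used <- n_perm
  }
  tmat <- flip_t_matrix(x, signs)
  maxmass <- apply(tmat, 1, function(tt)
    max_cluster_mass_time(tt, abs(tt) > tcrit))
  clusters <- lapply(obs_cl, function(cl) {
    b <- sum(maxmass >= abs(cl$mass) - 1e-12)
    cl$p <- if (method == "exhaustive") b / denom else (b + 1) / denom
    cl
  })
  new_cluster_result(clusters, n_used, cluster_alpha, seed, "time")
}

# connected components of a set of electrodes under an adjacency matrix
connected_components <- function(members, adjacency) {
  comps <- list()
  left <- members
  while (length(left)) {
    queue <- left[1]
    comp <- integer(0)
    while (length(queue)) {
      e <- queue[1]; queue <- queue[-1]
      if (e %in% comp) next
      comp <- c(comp, e)
      nb <- intersect(which(adjacency[e, ]), left)
      queue <- c(queue, setdiff(nb, comp))
    }
    comps[[length(comps) + 1]] <- sort(comp)
    left <- setdiff(left, comp)
  }
  comps
}

topo_clusters <- function(t, sig, adjacency) {
  out <- list()
  for (sgn in c(1, -1)) {
    members <- which(sig & sign(t) == sgn)
    if (!length(members)) next
    for (comp in connected_components(members, adjacency))
      out[[length(out) + 1]] <- list(members = comp, mass = sum(t[comp]),
                                     sign = sgn)
  }
  out
}

max_cluster_mass_topo <- function(t, sig, adjacency) {
  cl <- topo_clusters(t, sig, adjacency)
  if (!length(cl)) 0 else max(abs(vapply(cl, `[[`, 0, "mass")))
}

# unpaired two-sample t per column (equal-variance, classic)
ttest2_columns <- function(a, b) {
  na <- nrow(a); nb <- nrow(b)
  ma <- colMeans(a); mb <- colMeans(b)
  va <- (colSums(a^2) - na * ma^2) / (na - 1)
  vb <- (colSums(b^2) - nb * mb^2) / (nb - 1)
  sp <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  (ma - mb) / sqrt(sp * (1 / na + 1 / nb))
}

#' Cluster-based permutation test over electrode neighbourhoods
#'
#' Per-electrode t statistics (one-sample against `values_b` when it is a
#' scalar, unpaired two-sample when it is a second subjects x electrodes
#' matrix); supra-threshold electrodes with a common sign are grouped into
#' connected components of the adjacency graph, and each component's
#' summed-t mass is compared against the permutation distribution of the
#' maximum absolute mass (subject sign flips for one-sample, group-label
#' exchange for two-sample).
#'
#' @param values_a subjects x electrodes matrix.
#' @param values_b scalar null value, or a second subjects x electrodes
#'   matrix.
#' @param adjacency symmetric logical adjacency matrix covering all
#'   electrodes; every electrode must have at least one neighbour.
#' @param cluster_alpha per-electrode two-sided threshold.
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return a `cluster_result`; each cluster lists its electrode `members`,
#'   `mass`, `sign` and `p`.
#' @export
cluster_permutation_topo <- function(values_a, values_b = 0, adjacency,
                                     cluster_alpha = 0.05, n_perm = 1000,
                                     seed = 1L) {
  a <- as.matrix(values_a)
  m <- ncol(a)
  if (!is.matrix(adjacency) || nrow(adjacency) != m || ncol(adjacency) != m)
    stopf("adjacency must be an %d x %d matrix covering all electrodes", m, m)
  adjacency <- adjacency | t(adjacency)
  diag(adjacency) <- FALSE
  if (any(rowSums(adjacency) == 0))
    stopf("electrode(s) %s have no neighbours in the adjacency graph",
          toString(which(rowSums(adjacency) == 0)))
  two_sample <- is.matrix(values_b) || length(values_b) > 1
  if (n_perm < 1) stopf("n_perm must be >= 1")
  set.seed(seed)
  if (two_sample) {
    b <- as.matrix(values_b)
    if (ncol(b) != m) stopf("groups have different electrode counts")
    if (nrow(a) < 2 || nrow(b) < 2) stopf("need >= 2 subjects per group")
    tobs <- ttest2_columns(a, b)
    df <- nrow(a) + nrow(b) - 2
    tcrit <- stats::qt(1 - cluster_alpha / 2, df)
    pooled <- rbind(a, b)
    na <- nrow(a)
    maxmass <- replicate(n_perm, {
      idx <- sample(nrow(pooled))
      tp <- ttest2_columns(pooled[idx[seq_len(na)], , drop = FALSE],
                           pooled[idx[-seq_len(na)], , drop = FALSE])
      max_cluster_mass_topo(tp, abs(tp) > tcrit, adjacency)
    })
  } else {
    if (nrow(a) < 2) stopf("need at least 2 subjects")
    x <- a - values_b
    tt <- ttest_series(x, 0)
    tobs <- tt$t
    tcrit <- stats::qt(1 - cluster_alpha / 2, tt$df)
    signs <- matrix(sample(c(-1, 1), n_perm * nrow(x), replace = TRUE),
                    n_perm, nrow(x))
    tmat <- flip_t_matrix(x, signs)
    maxmass <- apply(tmat, 1, function(tp)
      max_cluster_mass_topo(tp, abs(tp) > tcrit, adjacency))
  }
  obs_cl <- topo_clusters(tobs, abs(tobs) > tcrit, adjacency)
  clusters <- lapply(obs_cl, function(cl) {
    cl$p <- (sum(maxmass >= abs(cl$mass) - 1e-12) + 1) / (n_perm + 1)
    cl
  })
  new_cluster_result(clusters, n_perm, cluster_alpha, seed,
                     if (two_sample) "topo/two-sample" else "topo/one-sample")
}

#' Export a cluster result as JSON
#'
#' @param x a `cluster_result`.
#' @param path JSON file path.
#' @param config_hash optional provenance hash.
#' @export
write_cluster_result <- function(x, path, config_hash = NULL) {
  jsonlite::write_json(
    list(type = x$type, n_permutations = x$n_permutations,
         cluster_alpha = x$cluster_alpha, seed = x$seed,
         config_hash = config_hash,
         clusters = lapply(x$clusters, function(cl)
           list(from = cl$from, to = cl$to, members = cl$members,
                mass = cl$mass, sign = cl$sign, p = cl$p))),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
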