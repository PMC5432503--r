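test_that("design matrices place basis columns at the labelled positions", {
  b <- basis_set(8)
  expect_identical(b$kind, "delta")
  expect_equal(b$matrix, diag(8))
  C1 <- build_design(c(1L, 3L), b)
  expect_equal(C1[, 1], c(1, rep(0, 7)))
  expect_equal(C1[, 2], c(0, 0, 1, rep(0, 5)))
  # row sums equal per-class trial counts
  labels <- rep(1:8, times = 3:10)
  expect_equal(unname(rowSums(build_design(labels, b))), as.numeric(3:10))
  # a custom basis is stored verbatim and used as given
  G <- outer(1:4, 1:4, function(i, j)
    exp(-pmin(abs(i - j), 4 - abs(i - j))^2 / 2))
  bg <- basis_set(4, G)
  expect_identical(bg$kind, "custom")
  expect_equal(build_design(c(2L, 4L), bg), G[, c(2, 4)])
  expect_error(build_design(c(1L, 9L), b), "out of range")
})

test_that("delta-basis weights equal per-class training means exactly", {
  set.seed(31)
  m <- 12; k <- 5
  labels <- rep(1:k, times = c(7, 9, 4, 11, 6))
  B1 <- matrix(rnorm(m * length(labels)), m)
  mod <- estimate_weights(B1, build_design(labels, basis_set(k)))
  for (p in 1:k)
    expect_equal(mod$W[, p], rowMeans(B1[, labels == p, drop = FALSE]),
                 tolerance = 1e-12)
  # linearity: doubling B1 doubles W
  mod2 <- estimate_weights(2 * B1, build_design(labels, basis_set(k)))
  expect_equal(mod2$W, 2 * mod$W, tolerance = 1e-12)
  # single trial per class reproduces B1 exactly via W C1
  lab1 <- 1:k
  B1s <- matrix(rnorm(m * k), m)
  C1s <- build_design(lab1, basis_set(k))
  mods <- estimate_weights(B1s, C1s)
  expect_equal(mods$W %*% C1s, B1s, tolerance = 1e-12)
  # a missing class makes the delta design rank deficient
  expect_error(estimate_weights(B1[, labels != 3], build_design(
    labels[labels != 3], basis_set(k))), "rank deficient")
})

test_that("model inversion round-trips noise-free channel responses", {
  set.seed(32)
  m <- 20; k <- 8; n2 <- 30
  W <- matrix(rnorm(m * k), m)
  Ctrue <- matrix(runif(k * n2), k)
  C2 <- invert_model(structure(list(W = W, k = k, m = m),
                               class = "encoding_model"),
                     W %*% Ctrue)
  expect_equal(C2, Ctrue, tolerance = 1e-10)
  # data orthogonal to the column space of W maps to ~0
  qrW <- qr(W)
  ortho <- qr.resid(qrW, matrix(rnorm(m * 5), m))
  expect_lt(max(abs(invert_model(W, ortho))), 1e-10)
  expect_error(invert_model(W[, c(1:7, 1)] * 0 + W[, c(1:7, 1)],
                            matrix(0, m, 2)), "rank deficient")
  expect_error(invert_model(W, matrix(0, m + 1, 2)), "electrodes")
})

test_that("full estimate/invert pipeline recovers the identity noise-free", {
  # the closed form: with delta-basis training on noise-free data, the
  # per-condition mean channel responses are exactly the identity
  s <- small_sim(seed = 33, noise_sd = 0, n_trials_per_position = 12L)$sim
  ep <- s$epochs
  peak_i <- which.min(abs(ep$times - 265))
  ff <- fem(ep, folds = assign_folds(ep$labels, 10, seed = 2),
            samples = peak_i)
  # exact up to the conditioning of the condition-topography matrix
  # (kappa ~ 1e6 for the realistic overlapping-bump montage)
  expect_equal(unname(ff$cond_means[, , 1]), diag(8), tolerance = 1e-6)
  # hence the canonical CTF is a delta at the center channel
  expect_equal(unname(ff$ctf[, 1]), as.numeric(diag(8)[, 4]),
               tolerance = 1e-6)
})

test_that("CTF alignment shifts conditions to a common center", {
  k <- 8
  bump <- c(0.2, 0.5, 1, 0.5, 0.2, 0.1, 0.05, 0.1)
  # condition p shows the same bump centred at its own channel
  cm <- sapply(1:k, function(p) ctfem:::circshift(bump, p - 3))
  ctf <- canonical_ctf(cm, center = 4)
  expect_equal(ctf$response, ctfem:::circshift(bump, 1))
  # every aligned condition equals the common bump re-centered at 4
  expect_true(all(apply(ctf$aligned, 2, function(col)
    isTRUE(all.equal(col, ctfem:::circshift(bump, 1))))))
  # equivariance: shifting all responses and labels together is a no-op
  cm_shift <- sapply(1:k, function(p)
    ctfem:::circshift(cm[, 1 + ((p - 2) %% k)], 1))
  expect_equal(canonical_ctf(cm_shift, center = 4)$response, ctf$response)
  # alignment conserves the total (sum over channels) response
  expect_equal(sum(ctf$response), mean(colSums(cm)))
  # display variant appends the wrap-around channel
  disp <- ctfem:::ctf_display(ctf)
  expect_length(disp, k + 1)
  expect_equal(unname(disp[1]), unname(disp[k + 1]))
  expect_error(canonical_ctf(cm, center = 9), "center")
})

test_that("the graded CTF emerges at the default noise level", {
  s <- small_sim(seed = 34, n_trials_per_position = 96L)$sim
  ep <- s$epochs
  ff <- fem(ep, folds = assign_folds(ep$labels, 10, seed = 2),
            samples = which(ep$times >= 255 & ep$times <= 280))
  resp <- ctf_window(ff)$response
  # graded: response falls off with channel distance from the center
  expect_identical(which.max(resp), 4L)
  d0 <- resp[4]
  d1 <- mean(resp[c(3, 5)])
  d2 <- mean(resp[c(2, 6)])
  dfar <- max(mean(resp[c(1, 7)]), resp[8])
  expect_true(d0 > d1 && d1 > d2 && d2 > dfar)
  expect_gt(d0, 2 * dfar)
  # a seeded rerun reproduces the time course exactly
  ff2 <- fem(ep, folds = assign_folds(ep$labels, 10, seed = 2),
             samples = ff$sample_index)
  expect_identical(ff2$ctf, ff$ctf)
  # pre-stimulus samples carry no tuning: center ~ edge
  ffb <- fem(ep, folds = assign_folds(ep$labels, 10, seed = 2),
             samples = which(ep$times < 0))
  base <- ctf_window(ffb)$response
  expect_lt(abs(base[4] - base[8]), 3 * stats::sd(base))
})

test_that("center-versus-edge tuning statistic behaves at the extremes", {
  k <- 8
  arr <- array(0, c(3, k, 5))
  # center identical to edge -> t = 0 everywhere
  arr[, 4, ] <- 1; arr[, 8, ] <- 1
  arr <- arr + array(rnorm(3 * k * 5, sd = 1e-8), c(3, k, 5))
  st0 <- ctf_tuning_stat(arr, center = 4)
  expect_lt(max(abs(st0$t)), 10)       # only numeric noise
  # constant positive difference with zero variance -> infinite t, flagged
  arr2 <- array(0, c(3, k, 2))
  arr2[, 4, ] <- 2
  expect_warning(st2 <- ctf_tuning_stat(arr2, center = 4), "zero-variance")
  expect_true(all(is.infinite(st2$t)))
  expect_true(all(st2$p == 0))
  expect_error(ctf_tuning_stat(arr[1, , , drop = FALSE]), "2 subjects")
})

test_that("tuned subjects yield a significant positive cluster over time", {
  set.seed(35)
  S <- 8; k <- 8; Tn <- 30
  arr <- array(rnorm(S * k * Tn, sd = 0.3), c(S, k, Tn))
  sigwin <- 10:20
  arr[, 4, sigwin] <- arr[, 4, sigwin] + 1    # center channel boost
  st <- ctf_tuning_stat(arr, center = 4)
  res <- cluster_permutation_time(st$diff, 0, n_perm = 300, seed = 7)
  ps <- vapply(res$clusters, `[[`, 0, "p")
  sgn <- vapply(res$clusters, `[[`, 0, "sign")
  expect_true(any(ps < 0.05 & sgn > 0))
  best <- res$clusters[[which.min(ps)]]
  expect_true(best$from >= min(sigwin) - 2 && best$to <= max(sigwin) + 2)
})

test_that("hypothetical responses interpolate the symmetrized CTF", {
  k <- 8
  resp <- c(0.1, 0.35, 0.7, 1, 0.7, 0.35, 0.1, 0.02)
  ctf <- structure(list(response = resp, center = 4L, k = k), class = "ctf")
  # already symmetric about the center: hypothetical response for a sampled
  # position is the CTF re-centered there
  sym <- (resp + resp[c(7:1, 8)]) / 2   # mirror about channel 4
  h8 <- interpolate_channel_response(ctf, 337.5)
  expect_equal(h8, ctfem:::circshift(sym, 8 - 4))
  # midpoint tags average the two neighbouring re-centered responses
  top <- interpolate_channel_response(ctf, "top")
  expect_equal(top, (ctfem:::circshift(sym, 4) +
                       ctfem:::circshift(sym, -3)) / 2)
  expect_equal(interpolate_channel_response(ctf, 0), top)
  # all four tags equal their angle equivalents
  for (pair in list(c("right", 90), c("bottom", 180), c("left", 270)))
    expect_equal(interpolate_channel_response(ctf, pair[[1]]),
                 interpolate_channel_response(ctf, as.numeric(pair[[2]])))
  expect_error(interpolate_channel_response(ctf, "middle"), "unknown")
})

test_that("topography reconstruction is linear and exact for delta input", {
  set.seed(36)
  m <- 15; k <- 8
  W <- matrix(rnorm(m * k), m, dimnames = list(paste0("E", 1:m), NULL))
  mod <- structure(list(W = W, k = k, m = m), class = "encoding_model")
  e3 <- as.numeric(1:k == 3)
  expect_equal(unname(reconstruct_topography(mod, e3)$values), W[, 3],
               ignore_attr = TRUE)
  c1 <- runif(k); c2 <- runif(k)
  expect_equal(reconstruct_topography(mod, 2 * c1 + 3 * c2)$values,
               2 * reconstruct_topography(mod, c1)$values +
                 3 * reconstruct_topography(mod, c2)$values)
  expect_error(reconstruct_topography(mod, c1[1:5]), "channels")
})

test_that("pattern contrasts normalize and flip sign on swap", {
  a <- c(E1 = 1, E2 = 3, E3 = 2)
  b <- c(E1 = 0, E2 = 1, E3 = 4)
  d <- contrast_and_normalize(a, b)
  expect_equal(mean(d$values), 0)
  expect_equal(sqrt(mean(d$values^2)), 1)
  expect_equal(contrast_and_normalize(b, a)$values, -d$values)
  expect_error(contrast_and_normalize(a, a), "zero spread")
  expect_error(contrast_and_normalize(a, b[1:2]), "different electrode")
})

test_that("group pattern comparison separates shared from distinct maps", {
  mont <- make_montage("exp2_27")
  m <- length(mont$names)
  base <- sin(seq_len(m))               # smooth-ish shared map
  set.seed(37)
  ga <- t(replicate(6, base + rnorm(m, sd = 0.3)))
  gb_same <- t(replicate(6, base + rnorm(m, sd = 0.3)))
  same <- compare_patterns(ga, gb_same, mont$adjacency, n_perm = 200,
                           seed = 3)
  expect_gt(same$correlation, 0.9)
  expect_false(any(vapply(same$clusters$clusters, `[[`, 0, "p") < 0.05))
  # identical groups: r = 1; negated groups: r = -1
  expect_equal(compare_patterns(ga, ga, mont$adjacency, n_perm = 50,
                                seed = 1)$correlation, 1)
  expect_equal(compare_patterns(ga, -ga, mont$adjacency, n_perm = 50,
                                seed = 1)$correlation, -1)
  gb_diff <- t(replicate(6, -2 * base + rnorm(m, sd = 0.3)))
  diff <- compare_patterns(ga, gb_diff, mont$adjacency, n_perm = 200,
                           seed = 3)
  expect_true(any(vapply(diff$clusters$clusters, `[[`, 0, "p") < 0.05))
  expect_error(compare_patterns(ga[1, , drop = FALSE], gb_same,
                                mont$adjacency), "2 subjects")
})

test_that("fem objects expose coef/predict/summary methods coherently", {
  s <- small_sim(seed = 38, n_trials_per_position = 20L)$sim
  ep <- s$epochs
  ff <- fem(ep, folds = assign_folds(ep$labels, 10, seed = 4),
            samples = which(ep$times >= 240 & ep$times <= 290))
  W <- coef(ff, window = c(260, 270))
  expect_identical(dim(W), c(27L, 8L))
  expect_identical(rownames(W), ep$electrodes)
  top <- predict(ff, position = "top", window = c(260, 270))
  expect_s3_class(top, "activation_pattern")
  expect_length(top$values, 27)
  # predict on new data inverts the window-averaged weights
  B2 <- t(ep$data[1:5, , which.min(abs(ep$times - 265))])
  C2 <- predict(ff, newdata = B2, window = c(260, 270))
  expect_identical(dim(C2), c(8L, 5L))
  sm <- summary(ff)
  expect_s3_class(sm, "summary.fem")
  expect_true(is.finite(sm$peak_tuning))
})
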