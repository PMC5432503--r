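test_that("stratified folds partition trials with every class in each fold", {
  labels <- rep(1:8, each = 10)          # 80 trials, 8 classes, K = 10
  fa <- assign_folds(labels, K = 10, seed = 3)
  expect_true(all(table(fa$fold) == 8))
  for (f in 1:10)
    expect_setequal(unique(labels[fa$fold == f]), 1:8)
  # same seed -> identical; different seed -> different
  expect_identical(assign_folds(labels, 10, seed = 3)$fold, fa$fold)
  expect_false(identical(assign_folds(labels, 10, seed = 4)$fold, fa$fold))
  # union of test folds covers all trials exactly once (it is a partition)
  expect_identical(sort(unlist(lapply(1:10, function(f)
    which(fa$fold == f)))), seq_along(labels))
  expect_error(assign_folds(rep(1:2, c(5, 50)), K = 10),
               "fewer than K")
})

test_that("LDA matches the closed form and MASS::lda on clean data", {
  set.seed(5)
  n <- 400
  mu <- c(2, -1, 0.5)
  X <- rbind(matrix(rnorm(n * 3), n, 3),
             matrix(rnorm(n * 3), n, 3) + matrix(mu, n, 3, byrow = TRUE))
  y <- rep(c("a", "b"), each = n)
  clf <- train_lda(X, y, shrinkage = 0)
  # identity-covariance data: discriminant direction ~ class-mean difference
  w <- clf$weights[, "a"] - clf$weights[, "b"]
  md <- colMeans(X[y == "a", ]) - colMeans(X[y == "b", ])
  expect_gt(abs(cor(w, md)), 0.99)
  # cross-check decisions against MASS::lda (equal priors, no shrinkage)
  ml <- MASS::lda(X, grouping = y, prior = c(0.5, 0.5))
  expect_gt(mean(predict(clf, X) ==
                   as.character(predict(ml, X)$class)), 0.995)
  # permuting electrodes permutes weights identically
  perm <- c(3, 1, 2)
  clf_p <- train_lda(X[, perm], y, shrinkage = 0)
  expect_equal(unname(clf_p$weights), unname(clf$weights[perm, ]),
               tolerance = 1e-10)
})

test_that("shrinkage keeps rank-deficient problems finite", {
  set.seed(6)
  X <- matrix(rnorm(60 * 4), 60, 4)
  X <- cbind(X, X[, 4])                  # duplicated electrode
  y <- rep(1:2, each = 30)
  clf <- train_lda(X, y)                 # auto shrinkage
  expect_true(all(is.finite(clf$weights)))
  expect_gt(clf$lambda, 0)
  expect_warning(train_lda(X, y, shrinkage = 0), "singular")
  expect_error(train_lda(X, rep(1, 60)), "at least 2 classes")
})

test_that("noise-free separable classes decode perfectly in the signal window", {
  s <- small_sim(seed = 31, noise_sd = 0, n_trials_per_position = 20L)$sim
  ep <- s$epochs
  two <- ep$labels %in% c(1L, 5L)        # opposite positions
  ep2 <- subset_trials(ep, two)
  folds <- assign_folds(ep2$labels, K = 10, seed = 1)
  peak_i <- which.min(abs(ep2$times - 265))
  fit <- bdm(ep2, folds = folds, samples = peak_i)
  expect_equal(unname(fit$aggregate), 1)
  expect_equal(fit$chance, 0.5)
})

test_that("aggregate accuracy is the unweighted mean over classes", {
  # deliberately imbalanced test fold: class accuracy must be macro-averaged
  set.seed(8)
  n1 <- 90; n2 <- 10
  X <- rbind(matrix(rnorm(n1, mean = 3), ncol = 1),
             matrix(rnorm(n2, mean = -3), ncol = 1))
  X <- cbind(X, 0)
  labels <- rep(c(1L, 2L), c(n1, n2))
  times <- c(0, 4)
  ep <- eeg_epochs(array(rep(X, 2), c(100, 2, 2)), times, 250, labels,
                   c("E1", "E2"))
  folds <- structure(list(fold = rep(1:2, 50), K = 2L, seed = 0L),
                     class = "fold_assignment")
  fit <- bdm(ep, folds = folds, samples = 1L)
  acc <- fit$accuracy[1, , ]             # folds x classes
  expect_equal(unname(fit$aggregate), mean(rowMeans(acc)))
  # and per-class accuracies are proportions within each class
  expect_true(all(acc >= 0 & acc <= 1))
})

test_that("chance level is recovered under label permutation", {
  s <- small_sim(seed = 17, n_trials_per_position = 30L)$sim$epochs
  set.seed(99)
  perm <- sample(s$labels)
  folds <- assign_folds(perm, K = 10, seed = 2)
  fit <- bdm(s, labels = perm, folds = folds,
             samples = seq(1, n_samples(s), by = 5))
  n_test <- n_trials(s)
  ci <- qnorm(0.995) * sqrt(0.125 * 0.875 / n_test)
  expect_lt(abs(mean(fit$aggregate) - 0.125), ci)
})

test_that("zeroing the test fold never changes the trained classifier", {
  s <- small_sim(seed = 23, n_trials_per_position = 10L)$sim$epochs
  folds <- assign_folds(s$labels, K = 10, seed = 5)
  peak_i <- which.min(abs(s$times - 265))
  X <- s$data[, , peak_i]
  te <- folds$fold == 1
  clf1 <- train_lda(X[!te, ], s$labels[!te])
  X2 <- X; X2[te, ] <- 0
  clf2 <- train_lda(X2[!te, ], s$labels[!te])
  expect_identical(clf1$weights, clf2$weights)
})

test_that("Haufe patterns recover the mass-univariate class difference", {
  set.seed(12)
  n <- 300
  m <- 10
  d <- rnorm(m)                            # true pattern
  y <- rep(c(1, -1), each = n / 2)
  X <- outer(y, d / 2) + matrix(rnorm(n * m, sd = 0.01), n, m)
  clf <- train_lda(X, rep(c("a", "b"), each = n / 2))
  pat <- haufe_pattern(clf, X)
  oracle <- colMeans(X[1:(n / 2), ]) - colMeans(X[(n / 2 + 1):n, ])
  cosine <- sum(pat$values * oracle) /
    sqrt(sum(pat$values^2) * sum(oracle^2))
  expect_gt(cosine, 0.99)
  # identity covariance -> pattern proportional to the weight contrast
  set.seed(13)
  Xw <- matrix(rnorm(4000 * m), 4000, m)
  yw <- rep(c("a", "b"), each = 2000)
  clfw <- train_lda(Xw, yw, shrinkage = 0)
  patw <- haufe_pattern(clfw, Xw)
  ww <- clfw$weights[, "a"] - clfw$weights[, "b"]
  expect_gt(abs(cor(patw$values, ww)), 0.99)
  # scaling the data: covariance x4, refit weights ~ /2, direction stable
  clf2 <- train_lda(2 * X, rep(c("a", "b"), each = n / 2))
  pat2 <- haufe_pattern(clf2, 2 * X)
  expect_gt(abs(cor(pat2$values, pat$values)), 0.999)
  cov_ratio <- stats::cov(2 * X)[1, 1] / stats::cov(X)[1, 1]
  expect_equal(cov_ratio, 4, tolerance = 1e-12)
  expect_error(haufe_pattern(clf, X[, 1:3]), "expects")
})

test_that("spatial normalization matches the population-SD arithmetic", {
  out <- spatial_normalize(c(1, 2, 3))
  expect_equal(unname(out$values),
               c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_true(out$normalized)
  expect_equal(mean(out$values), 0)
  expect_equal(sqrt(mean(out$values^2)), 1)
  # idempotent, and invariant to affine transforms of the input
  expect_equal(spatial_normalize(out)$values, out$values)
  expect_equal(spatial_normalize(5 * c(1, 2, 3) - 7)$values, out$values)
  expect_error(spatial_normalize(rep(2, 5)), "zero spread")
})

test_that("display smoothing anchors the grid at the peak", {
  times <- make_times(c(-100, 600), 250)
  bump <- exp(-(times - 250)^2 / (2 * 60^2)) * 0.3 + 0.125
  sm <- smooth_for_display(bump, times, sfreq = 250, target_rate = 32)
  pk <- which.max(bump)
  expect_true(pk %in% attr(sm, "retained"))
  expect_equal(sm[pk], bump[pk], tolerance = 1e-9)   # peak not diluted
  expect_true(attr(sm, "display_only"))
  # constant series is unchanged
  const <- rep(0.2, length(times))
  expect_equal(as.numeric(smooth_for_display(const, times, 250)), const)
  # argmax moves by at most one display-grid step on noisy bumps
  step <- round(250 / 32)
  set.seed(3)
  for (i in 1:20) {
    y <- exp(-(times - sample(seq(100, 400, 50), 1))^2 / (2 * 50^2)) +
      rnorm(length(times), sd = 0.05)
    ym <- smooth_for_display(y, times, 250)
    expect_lte(abs(which.max(ym) - which.max(y)), step)
  }
})

test_that("peak finding respects windows and breaks ties early", {
  times <- make_times(c(-100, 600), 250)
  y <- exp(-(times - 250)^2 / (2 * 40^2))
  pk <- find_peak(y, times)
  expect_equal(unname(pk["latency_ms"]), 248, tolerance = 4)
  # two equal maxima -> the earlier latency wins
  y2 <- rep(0, length(times)); y2[c(20, 60)] <- 1
  expect_equal(unname(find_peak(y2, times)["latency_ms"]), times[20])
  # window restriction
  expect_equal(unname(find_peak(y, times, c(-100, 0))["latency_ms"]),
               times[which.max(y[times <= 0])])
  expect_error(find_peak(y, times, c(700, 800)), "no samples")
})

test_that("decoding results export to CSV and JSON", {
  s <- small_sim(seed = 41, n_trials_per_position = 10L)$sim$epochs
  fit <- bdm(s, folds = assign_folds(s$labels, 10, seed = 1), samples = 1:2)
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_bdm(fit, csv, js, config_hash = "abc123")
  df <- read.csv(csv, comment.char = "#")
  expect_identical(names(df), c("time_ms", "accuracy", "fold", "class"))
  expect_equal(nrow(df), 2 * 10 * 8)
  expect_equal(mean(df$accuracy[df$time_ms == df$time_ms[1]]),
               mean(fit$accuracy[1, , ]))
  j <- jsonlite::read_json(js)
  expect_equal(j$chance, 0.125)
  expect_identical(j$config_hash, "abc123")
})
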