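# Shared fixtures: everything is generated in code at test time.

# small, fast eight-position simulation (short epoch, fewer trials)
small_sim <- function(seed = 1L, noise_sd = 4, n_trials_per_position = 40L,
                      heog = FALSE, ...) {
  cfg <- sim_config(n_trials_per_position = n_trials_per_position,
                    epoch_window = c(-100, 500), noise_sd = noise_sd,
                    heog = heog, seed = seed, ...)
  list(config = cfg,
       sim = simulate_epochs(cfg, make_montage("exp2_27")))
}

# tiny hand-built epochs object: values fully controlled by the caller
toy_epochs <- function(data, sfreq = 250, labels = NULL,
                       electrodes = NULL) {
  d <- dim(data)
  times <- seq(0, by = 1000 / sfreq, length.out = d[3])
  eeg_epochs(data, times, sfreq,
             labels %||% rep(1L, d[1]),
             electrodes %||% paste0("E", seq_len(d[2])))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# least-squares circular-Gaussian fit to a CTF (baseline + amplitude +
# width), the conventional parameterisation for tuning-width summaries
fit_ctf_width <- function(resp, center = 4) {
  k <- length(resp)
  d <- pmin(abs(seq_len(k) - center), k - abs(seq_len(k) - center))
  obj <- function(par)
    sum((par[1] + par[2] * exp(-d^2 / (2 * par[3]^2)) - resp)^2)
  o <- stats::optim(c(min(resp), diff(range(resp)), 1.5), obj,
                    method = "L-BFGS-B", lower = c(-Inf, 1e-6, 0.2),
                    upper = c(Inf, Inf, 4))
  o$par[3]
}

# independent brute-force oracle for the time-cluster permutation test:
# plain loops, stats::t.test, exhaustive sign enumeration
oracle_cluster_time <- function(x, cluster_alpha = 0.05) {
  S <- nrow(x)
  tvec <- function(m) apply(m, 2, function(col) stats::t.test(col)$statistic)
  pvec <- function(m) apply(m, 2, function(col) stats::t.test(col)$p.value)
  clusters_of <- function(t, sig) {
    out <- list()
    i <- 1
    while (i <= length(t)) {
      if (sig[i]) {
        j <- i
        while (j < length(t) && sig[j + 1] && sign(t[j + 1]) == sign(t[i]))
          j <- j + 1
        out[[length(out) + 1]] <- list(from = i, to = j,
                                       mass = sum(t[i:j]))
        i <- j + 1
      } else i <- i + 1
    }
    out
  }
  tobs <- tvec(x)
  sig <- pvec(x) < cluster_alpha
  obs <- clusters_of(tobs, sig)
  grid <- as.matrix(expand.grid(rep(list(c(-1, 1)), S)))
  maxmass <- apply(grid, 1, function(sg) {
    xf <- x * sg
    tf <- tvec(xf)
    cl <- clusters_of(tf, pvec(xf) < cluster_alpha)
    if (!length(cl)) 0 else max(abs(vapply(cl, `[[`, 0, "mass")))
  })
  lapply(obs, function(cl) {
    cl$p <- mean(maxmass >= abs(cl$mass) - 1e-12)
    cl
  })
}
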