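# Run configuration, logging and the end-to-end pipeline commands backing
# the command-line wrapper (inst/cli/ctf.R).

#' Run configuration
#'
#' Validates and normalises a configuration list (typically read from YAML)
#' for [run_pipeline()]. Unspecified fields fall back to the generator /
#' analysis defaults.
#'
#' @param config a named list (or path to a YAML file) with optional blocks
#'   `paths` (input, out_dir), `design` (n_positions, montage,
#'   epoch_window, baseline_window), `decoding` (K, seed, shrinkage),
#'   `encoding` (basis, center, window), `stats` (cluster_alpha, n_perm,
#'   seed) and `simulate` (overrides for [sim_config()]).
#' @return an object of class `run_config` with a stable `hash` computed
#'   from the canonical JSON serialisation of its contents.
#' @export
run_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  defaults <- list(
    paths = list(input = "epochs", out_dir = "."),
    design = list(n_positions = 8L, montage = "exp2_27",
                  epoch_window = c(-100, 1000),
                  baseline_window = c(-100, 0)),
    decoding = list(K = 10L, seed = 1L, shrinkage = "auto"),
    encoding = list(basis = "delta", center = 4L, window = c(260, 270)),
    stats = list(cluster_alpha = 0.05, n_perm = 1000L, seed = 1L),
    simulate = list())
  cfg <- utils::modifyList(defaults, config)
  if (!cfg$design$montage %in% c("exp1_23", "exp2_27", "ring_n"))
    stopf("unknown montage '%s' in config", cfg$design$montage)
  for (s in c(cfg$decoding$seed, cfg$stats$seed))
    if (!is_count(s, min = 0)) stopf("seeds must be non-negative integers")
  ew <- cfg$design$epoch_window
  bw <- cfg$design$baseline_window
  if (bw[1] < ew[1] || bw[2] > ew[2])
    stopf("baseline window must lie inside the epoch window")
  enc <- cfg$encoding$window
  if (enc[1] < ew[1] || enc[2] > ew[2])
    stopf("encoding analysis window must lie inside the epoch window")
  cfg$hash <- config_hash(cfg)
  structure(cfg, class = "run_config")
}

# stable hash of the canonical JSON serialisation of the config contents;
# file-system paths are excluded so the hash identifies the analysis, not
# where its artifacts happen to live
config_hash <- function(cfg) {
  cfg$hash <- NULL
  cfg$paths <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  keys <- function(x) {
    if (!is.list(x) || !length(x)) return(x)
    nm <- names(x)
    if (is.null(nm)) lapply(x, keys) else lapply(x[order(nm)], keys)
  }
  jsonlite::write_json(keys(unclass(cfg)), tmp, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(tmp))
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("<run_config> %s montage, K=%d, hash %s\n",
              x$design$montage, x$decoding$K, substr(x$hash, 1, 8)))
  invisible(x)
}

pipeline_log <- function(out_dir, command, cfg, messages) {
  lines <- c(sprintf("[%s] ctfem %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                     command),
             sprintf("config_hash: %s", cfg$hash),
             sprintf("package_version: %s",
                     as.character(utils::packageVersion("ctfem"))),
             sprintf("seeds: decoding=%d stats=%d", cfg$decoding$seed,
                     cfg$stats$seed),
             messages)
  cat(paste0(lines, "\n"), file = file.path(out_dir, "run.log"),
      append = TRUE)
}

read_hash_comment <- function(path) {
  first <- readLines(path, n = 1)
  if (startsWith(first, "# config_hash: "))
    sub("# config_hash: ", "", first) else NA_character_
}

#' Run one pipeline command
#'
#' Executes one stage of the end-to-end pipeline against the configured
#' paths. Every artifact embeds the configuration hash; `report` refuses to
#' mix artifacts produced under different hashes. Outputs are deterministic
#' given the configured seeds; on failure, partially written outputs of the
#' failing stage are removed.
#'
#' Commands: `simulate` (write synthetic epochs + montage CSV),
#' `preprocess` (baseline correction and, when ocular channels are present,
#' step-artifact rejection), `decode` (per-timepoint k-fold LDA; accuracy
#' CSV + JSON summary), `encode` (forward encoding model; CTF and weight
#' CSVs), `reconstruct` (topographies for top/bottom/left/right from the
#' encode artifacts), `stats` (cluster permutation test of the decoding
#' aggregate against chance, across folds), `report` (collect artifacts
#' into report.txt).
#'
#' @param config a [run_config()] (or list / YAML path coerced to one).
#' @param command one of `"simulate"`, `"preprocess"`, `"decode"`,
#'   `"encode"`, `"reconstruct"`, `"stats"`, `"report"`.
#' @param out_dir output directory (default from the config).
#' @return invisibly, a character vector of the files written.
#' @export
run_pipeline <- function(config,
                         command = c("simulate", "preprocess", "decode",
                                     "encode", "reconstruct", "stats",
                                     "report"),
                         out_dir = NULL) {
  command <- match.arg(command)
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  if (is.null(out_dir)) out_dir <- cfg$paths$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  cleanup <- function() if (length(written)) unlink(written)
  ok <- FALSE
  on.exit(if (!ok) cleanup())
  epochs_path <- function() file.path(out_dir, cfg$paths$input)

  if (command == "simulate") {
    sim <- do.call(sim_config, cfg$simulate)
    montage <- make_montage(cfg$design$montage,
                            n = cfg$simulate$n_electrodes)
    out <- simulate_epochs(sim, montage)
    write_epochs(out$epochs, epochs_path(), config_hash = cfg$hash)
    mpath <- file.path(out_dir, "montage.csv")
    write_montage(montage, mpath)
    written <- c(paste0(epochs_path(), c(".dat", ".json")), mpath)
    pipeline_log(out_dir, command, cfg,
                 sprintf("simulated %d trials (seed %d)",
                         n_trials(out$epochs), sim$seed))
  } else if (command == "preprocess") {
    ep <- read_epochs(epochs_path())
    ep <- baseline_correct(ep, cfg$design$baseline_window)
    msg <- "baseline corrected"
    if (all(c("HEOGL", "HEOGR") %in% ep$electrodes)) {
      flags <- detect_step_artifacts(compute_heog(ep), ep$times)
      ep <- reject_trials(ep, flags)
      msg <- c(msg, sprintf("rejected trials: %s",
                            if (any(flags)) toString(which(flags)) else
                              "none"))
    }
    out_path <- file.path(out_dir, paste0(cfg$paths$input, "_clean"))
    write_epochs(ep, out_path, config_hash = cfg$hash)
    written <- paste0(out_path, c(".dat", ".json"))
    pipeline_log(out_dir, command, cfg, msg)
  } else if (command == "decode") {
    ep <- read_clean_or_raw(epochs_path())
    folds <- assign_folds(ep$labels, K = cfg$decoding$K,
                          seed = cfg$decoding$seed)
    fit <- bdm(ep, folds = folds, shrinkage = cfg$decoding$shrinkage)
    csv <- file.path(out_dir, "accuracy.csv")
    js <- file.path(out_dir, "decoding_summary.json")
    write_bdm(fit, csv, js, config_hash = cfg$hash)
    written <- c(csv, js)
    pipeline_log(out_dir, command, cfg,
                 sprintf("decoded %d classes, mean accuracy %.3f",
                         length(fit$class_levels), mean(fit$aggregate)))
  } else if (command == "encode") {
    ep <- read_clean_or_raw(epochs_path())
    folds <- assign_folds(ep$labels, K = cfg$decoding$K,
                          seed = cfg$decoding$seed)
    fit <- fem(ep, folds = folds, center = cfg$encoding$center)
    ctf_csv <- file.path(out_dir, "ctf.csv")
    w_csv <- file.path(out_dir, "weights.csv")
    write_fem(fit, ctf_csv, w_csv, window = cfg$encoding$window,
              config_hash = cfg$hash)
    meta <- file.path(out_dir, "encoding_meta.json")
    jsonlite::write_json(list(window_ms = cfg$encoding$window,
                              center = cfg$encoding$center,
                              K = cfg$decoding$K,
                              fold_policy = "weights averaged across folds",
                              config_hash = cfg$hash),
                         meta, auto_unbox = TRUE, digits = NA)
    written <- c(ctf_csv, w_csv, meta)
    pipeline_log(out_dir, command, cfg, "encoding model fitted")
  } else if (command == "reconstruct") {
    w_csv <- file.path(out_dir, "weights.csv")
    ctf_csv <- file.path(out_dir, "ctf.csv")
    for (f in c(w_csv, ctf_csv))
      if (!file.exists(f))
        stopf("missing artifact %s; run the encode command first", f)
    h <- c(read_hash_comment(w_csv), read_hash_comment(ctf_csv))
    if (length(unique(stats::na.omit(h))) > 1)
      stopf("artifacts were produced under different config hashes")
    Wdf <- utils::read.csv(w_csv, comment.char = "#")
    W <- stats::xtabs(weight ~ electrode + channel, data = Wdf)
    W <- matrix(W, nrow(W), dimnames = dimnames(W))
    ctfdf <- utils::read.csv(ctf_csv, comment.char = "#")
    win <- cfg$encoding$window
    ctfw <- ctfdf[ctfdf$time_ms >= win[1] & ctfdf$time_ms <= win[2], ]
    resp <- tapply(ctfw$response, ctfw$channel_offset, mean)
    k <- length(resp)
    center <- cfg$encoding$center
    v <- as.numeric(resp)[order(as.numeric(names(resp)))]
    ctf_obj <- structure(list(response = v, center = center, k = k),
                         class = "ctf")
    rows <- lapply(c("top", "right", "bottom", "left"), function(tag) {
      resp_tag <- interpolate_channel_response(ctf_obj, tag)
      pat <- reconstruct_topography(W, resp_tag)
      data.frame(position = tag, electrode = names(pat$values),
                 value = unname(pat$values))
    })
    out_csv <- file.path(out_dir, "reconstructed_patterns.csv")
    con <- file(out_csv, "w")
    writeLines(sprintf("# config_hash: %s", cfg$hash), con)
    utils::write.csv(do.call(rbind, rows), con, row.names = FALSE)
    close(con)
    written <- out_csv
    pipeline_log(out_dir, command, cfg,
                 "reconstructed top/right/bottom/left patterns")
  } else if (command == "stats") {
    csv <- file.path(out_dir, "accuracy.csv")
    if (!file.exists(csv))
      stopf("missing artifact %s; run the decode command first", csv)
    acc <- utils::read.csv(csv, comment.char = "#")
    # fold-wise accuracy series (folds as exchangeable units) vs chance
    agg <- tapply(acc$accuracy,
                  list(acc$fold, acc$time_ms), mean)
    chance <- 1 / length(unique(acc$class))
    res <- cluster_permutation_time(agg, chance,
                                    cluster_alpha = cfg$stats$cluster_alpha,
                                    n_perm = cfg$stats$n_perm,
                                    seed = cfg$stats$seed)
    out_json <- file.path(out_dir, "clusters.json")
    write_cluster_result(res, out_json, config_hash = cfg$hash)
    written <- out_json
    pipeline_log(out_dir, command, cfg,
                 sprintf("%d cluster(s) found", length(res$clusters)))
  } else if (command == "report") {
    hashes <- character(0)
    arts <- c("accuracy.csv", "ctf.csv", "weights.csv",
              "reconstructed_patterns.csv")
    lines <- c("ctfem pipeline report", sprintf("config_hash: %s", cfg$hash))
    for (a in arts) {
      f <- file.path(out_dir, a)
      if (!file.exists(f)) next
      h <- read_hash_comment(f)
      if (!is.na(h)) hashes <- c(hashes, h)
      lines <- c(lines, sprintf("artifact: %s", a))
    }
    for (j in c("decoding_summary.json", "encoding_meta.json",
                "clusters.json")) {
      f <- file.path(out_dir, j)
      if (!file.exists(f)) next
      h <- jsonlite::read_json(f)$config_hash
      if (!is.null(h)) hashes <- c(hashes, h)
      lines <- c(lines, sprintf("artifact: %s", j))
    }
    if (length(unique(hashes)) > 1)
      stopf("artifacts in %s mix different config hashes: %s", out_dir,
            toString(unique(substr(hashes, 1, 8))))
    if (length(hashes) && unique(hashes) != cfg$hash)
      stopf("artifacts were produced under a different config hash")
    rpt <- file.path(out_dir, "report.txt")
    writeLines(lines, rpt)
    written <- rpt
    pipeline_log(out_dir, command, cfg, "report written")
  }
  ok <- TRUE
  invisible(written)
}

# prefer the preprocessed container when present
read_clean_or_raw <- function(base) {
  clean <- paste0(base, "_clean")
  if (file.exists(paste0(clean, ".json"))) read_epochs(clean)
  else read_epochs(base)
}
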