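#' Pipeline configuration
#'
#' Assembles every stage's parameters with the standard defaults (128 Hz
#' working rate, 1 s epochs, db4 6-level wavelet packets, fuzzy entropy
#' m = 2 / r = 0.25, ReliefF m_iter = 80 / k_nn = 10, KNN K = 10 with
#' 5-fold stratified cross-validation), so a bare run reproduces the
#' canonical procedure.
#'
#' Exactly one data source must be given: `input` (recordings on disk) or
#' `synth` (generator settings). `input` is a list with `format`
#' (`"delimited"` or `"edf"`), `fs` (delimited only), and either
#' `recordings` -- a list of `list(path, state, subject)` entries with
#' `state` `"JX"` or `"ZD"` -- or `dir`, a directory containing a
#' `manifest.json` written by [write_synth_dataset()].
#'
#' @param input Input description (see above), or `NULL`.
#' @param synth Named list of [synth_spec()] arguments, or `NULL`.
#' @param feature_set One of `"Theta_Std"`, `"Alpha_Std"`, `"Beta1_Std"`,
#'   `"Beta2_Std"`, `"FE"`, or a fusion such as `"Theta_Std+FE"`.
#' @param target_fs Working sampling rate in Hz (default 128).
#' @param epoch_length_s Epoch length in seconds (default 1).
#' @param wpd,fe,relieff,eval Named lists of overrides for [wpd_config()],
#'   [fe_params()], [relieff_params()], [eval_params()].
#' @param output_dir Directory for report files, or `NULL` to skip writing.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(input = NULL, synth = NULL,
                            feature_set = "Theta_Std+FE",
                            target_fs = 128, epoch_length_s = 1,
                            wpd = list(), fe = list(),
                            relieff = list(), eval = list(),
                            output_dir = NULL) {
  if (is.null(input) == is.null(synth)) {
    abort_config("exactly one of 'input' or 'synth' must be given")
  }
  parse_feature_set(feature_set)  # validates the name
  cfg <- list(input = input, synth = synth, feature_set = feature_set,
              target_fs = target_fs, epoch_length_s = epoch_length_s,
              wpd = wpd, fe = fe, relieff = relieff, eval = eval,
              output_dir = output_dir)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys are the arguments of [pipeline_config()].
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort_config("config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) abort_config("unknown config keys: %s", paste(unknown, collapse = ", "))
  do.call(pipeline_config, raw)
}

SINGLE_FEATURES <- c("Theta_Std", "Alpha_Std", "Beta1_Std", "Beta2_Std", "FE")

parse_feature_set <- function(feature_set) {
  parts <- strsplit(feature_set, "+", fixed = TRUE)[[1]]
  if (length(parts) < 1L || length(parts) > 2L || !all(parts %in% SINGLE_FEATURES) ||
      anyDuplicated(parts)) {
    abort_config("unknown feature set '%s' (use one or a '+' fusion of: %s)",
                 feature_set, paste(SINGLE_FEATURES, collapse = ", "))
  }
  parts
}

#' Extract a named feature set from epochs
#'
#' Resolves a feature-set name to its extractor(s): subband standard
#' deviations via [subband_std_features()], fuzzy entropy via
#' [fe_features()], with `"A+B"` fused via [fuse()].
#'
#' @param epochs An `eeg_epochs` object.
#' @param feature_set Feature-set name (see [pipeline_config()]).
#' @param wpd_cfg A [wpd_config()].
#' @param fe_p A [fe_params()].
#' @return A [feature_matrix()].
#' @export
extract_feature_set <- function(epochs, feature_set, wpd_cfg = wpd_config(),
                                fe_p = fe_params()) {
  parts <- parse_feature_set(feature_set)
  one <- function(name) {
    if (name == "FE") return(fe_features(epochs, fe_p))
    band <- sub("_Std$", "", name)
    cfg1 <- wpd_config(levels = wpd_cfg$levels, wavelet = wpd_cfg$wavelet,
                       bands = wpd_cfg$bands[band])
    subband_std_features(epochs, cfg1)[[name]]
  }
  if (length(parts) == 1L) one(parts) else fuse(one(parts[1]), one(parts[2]))
}

# Load (or generate), resample, and epoch all recordings into one labeled set.
assemble_epochs <- function(cfg, log) {
  pairs <- if (!is.null(cfg$synth)) {
    ds <- synth_generate(do.call(synth_spec, cfg$synth))
    log("synth: %d subjects x 2 states x %d channels x %d s @ %g Hz (informative: %s)",
        ds$spec$n_subjects, ds$spec$n_channels, ds$spec$seconds_per_state,
        ds$spec$fs, paste(ds$ground_truth, collapse = ","))
    unlist(lapply(ds$recordings, function(p) {
      list(list(rec = p$JX, state = "JX"), list(rec = p$ZD, state = "ZD"))
    }), recursive = FALSE)
  } else {
    inp <- cfg$input
    if (!is.null(inp$dir)) {
      man_path <- file.path(inp$dir, "manifest.json")
      if (!file.exists(man_path)) abort_config("no manifest.json in %s", inp$dir)
      man <- jsonlite::read_json(man_path, simplifyVector = FALSE)
      inp$format <- man$format
      inp$fs <- man$fs
      inp$recordings <- lapply(man$files, function(f) {
        list(path = file.path(inp$dir, f$path), state = f$state, subject = f$subject)
      })
    }
    if (is.null(inp$recordings) || !length(inp$recordings)) {
      abort_config("input has no recordings")
    }
    lapply(inp$recordings, function(entry) {
      if (!entry$state %in% c("JX", "ZD")) {
        abort_config("state must be JX or ZD (got '%s')", entry$state)
      }
      rec <- load_recording(entry$path, format = inp$format, fs = inp$fs,
                            subject_id = entry$subject %||% basename(entry$path))
      log("load: %s (%s) %d ch x %d samples @ %g Hz", entry$path, entry$state,
          nrow(rec$data), ncol(rec$data), rec$fs)
      list(rec = rec, state = entry$state)
    })
  }
  sets <- lapply(pairs, function(p) {
    rec <- resample_recording(p$rec, cfg$target_fs)
    epoch_recording(rec, label = if (p$state == "ZD") 1L else 0L,
                    epoch_length_s = cfg$epoch_length_s)
  })
  epochs <- bind_epochs(sets)
  log("epochs: %d x %d channels x %d samples @ %g Hz (%d JX, %d ZD)",
      dim(epochs$epochs)[1], dim(epochs$epochs)[2], dim(epochs$epochs)[3],
      epochs$fs, sum(epochs$labels == 0L), sum(epochs$labels == 1L))
  epochs
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full channel-selection pipeline
#'
#' Load (or generate) recordings, resample to the working rate, cut into
#' labeled epochs, extract the configured feature set, rank channels with
#' ReliefF, and evaluate weight-ordered subsets with cross-validated KNN.
#' If `output_dir` is set, writes `ranking.tsv`, `accuracy_by_size.tsv`,
#' `optimal_subset.json`, `result.json` (machine-readable result including
#' the config hash and seeds), and `log.txt`.
#'
#' @param cfg A [pipeline_config()].
#' @return The `selection_result`, invisibly, with attribute `"files"`
#'   listing any report files written.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  log_lines <- character(0)
  log <- function(fmt, ...) log_lines[[length(log_lines) + 1L]] <<- sprintf(fmt, ...)
  stage <- "configuration"
  result <- tryCatch({
    p <- do.call(relieff_params, cfg$relieff)
    ep <- do.call(eval_params, cfg$eval)
    wpd_cfg <- do.call(wpd_config, cfg$wpd)
    fe_p <- do.call(fe_params, cfg$fe)
    stage <- "input"
    epochs <- assemble_epochs(cfg, log)
    stage <- "feature extraction"
    fm <- extract_feature_set(epochs, cfg$feature_set, wpd_cfg, fe_p)
    log("features: %s -> %d x %d matrix", cfg$feature_set,
        nrow(fm$values), ncol(fm$values))
    stage <- "channel selection"
    res <- relieff_sfs(fm, p, ep)
    log("selection: optimal %d channels (%s), accuracy %.4f",
        res$optimal_size, paste(res$optimal_channels, collapse = ","),
        res$accuracy_by_size[res$optimal_size])
    res
  }, eegchansel_error = function(e) {
    stop(errorCondition(sprintf("pipeline stage '%s' failed: %s", stage,
                                conditionMessage(e)),
                        class = class(e)))
  })
  if (result$optimal_size == length(result$accuracy_by_size)) {
    warning("maximum accuracy only attained with the full channel set")
  }
  files <- character(0)
  if (!is.null(cfg$output_dir)) {
    files <- write_pipeline_report(cfg, result, log_lines, cfg$output_dir)
  }
  invisible(structure(result, files = files))
}

write_pipeline_report <- function(cfg, result, log_lines, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  # hash identifies the analysis, not where its outputs land
  cfg_hash <- digest::digest(unclass(cfg)[setdiff(names(cfg), "output_dir")])
  provenance <- list(config_hash = cfg_hash,
                     seeds = list(relieff = do.call(relieff_params, cfg$relieff)$seed,
                                  eval = do.call(eval_params, cfg$eval)$seed,
                                  synth = if (!is.null(cfg$synth))
                                    do.call(synth_spec, cfg$synth)$seed))
  paths <- c(ranking = file.path(dir, "ranking.tsv"),
             accuracy = file.path(dir, "accuracy_by_size.tsv"),
             optimal = file.path(dir, "optimal_subset.json"),
             result = file.path(dir, "result.json"),
             log = file.path(dir, "log.txt"))
  rk <- ranking_table(result$ranking)
  rk$config_hash <- cfg_hash
  utils::write.table(rk, paths["ranking"], sep = "\t", quote = FALSE, row.names = FALSE)
  at <- accuracy_table(result)
  at$config_hash <- cfg_hash
  utils::write.table(at, paths["accuracy"], sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(feature_set = cfg$feature_set, optimal_size = result$optimal_size,
         optimal_channels = result$optimal_channels,
         optimal_channel_numbers = result$ranking$order[seq_len(result$optimal_size)],
         accuracy = result$accuracy_by_size[result$optimal_size],
         provenance = provenance),
    paths["optimal"], auto_unbox = TRUE, pretty = TRUE, digits = NA)
  jsonlite::write_json(
    list(config = unclass(cfg)[setdiff(names(cfg), "output_dir")],
         provenance = provenance,
         ranking = list(order = result$ranking$order,
                        weights = result$ranking$weights,
                        channels = result$ranking$channels),
         accuracy_by_size = result$accuracy_by_size,
         optimal_size = result$optimal_size,
         optimal_channels = result$optimal_channels),
    paths["result"], auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(c(sprintf("config_hash: %s", cfg_hash), log_lines), paths["log"])
  paths
}

#' Compare feature sets
#'
#' Runs the selection once per feature set on the same data (loaded and
#' epoched once) and tabulates each set's optimal subset size and accuracy.
#'
#' @param cfg A [pipeline_config()]; its own `feature_set` is ignored.
#' @param feature_sets Non-empty character vector of feature-set names.
#' @return data.frame with columns `feature`, `n_channels`, `accuracy`;
#'   also written to `comparison.tsv` under `cfg$output_dir` if set.
#' @export
compare_features <- function(cfg, feature_sets) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (length(feature_sets) < 1L) abort_config("feature_sets must be non-empty")
  for (fsname in feature_sets) parse_feature_set(fsname)
  p <- do.call(relieff_params, cfg$relieff)
  ep <- do.call(eval_params, cfg$eval)
  wpd_cfg <- do.call(wpd_config, cfg$wpd)
  fe_p <- do.call(fe_params, cfg$fe)
  epochs <- assemble_epochs(cfg, function(...) invisible(NULL))
  rows <- lapply(feature_sets, function(fsname) {
    fm <- extract_feature_set(epochs, fsname, wpd_cfg, fe_p)
    res <- relieff_sfs(fm, p, ep)
    data.frame(feature = fsname, n_channels = res$optimal_size,
               accuracy = res$accuracy_by_size[res$optimal_size])
  })
  out <- do.call(rbind, rows)
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(out, file.path(cfg$output_dir, "comparison.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' Plot accuracy against subset size
#'
#' @param x A `selection_result`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.selection_result <- function(x, ...) {
  graphics::plot(seq_along(x$accuracy_by_size), 100 * x$accuracy_by_size,
                 type = "b", pch = 16, xlab = "Number of channels",
                 ylab = "Accuracy (%)", ...)
  graphics::abline(v = x$optimal_size, lty = 2)
  invisible(x)
}
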