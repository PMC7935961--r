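# End-to-end orchestration: phantom (or files) -> features -> train ->
# predict -> binarize -> objects -> distances / co-localization ->
# segmentation evaluation -> group statistics, driven by one config, with
# per-stage seeds derived deterministically from a single global seed.

#' Build a validated pipeline configuration
#'
#' Exactly one input mode must be set: `phantom` (a [phantom_spec()] or a
#' list of its arguments; ground truth then feeds annotation sampling and
#' evaluation) or `channels` (named list of volume file paths plus `fmt` and
#' `spacing_um`, with annotation CSV paths per classified channel).
#'
#' @param input list, either `list(phantom = ...)` or
#'   `list(channels = ..., fmt = "tiff", spacing_um = c(z, y, x),
#'   annotation_paths = list(...))`.
#' @param classify list: `channels` to classify (default `"cancer"`),
#'   `n_per_class` annotation sample size (phantom mode, default 200),
#'   `n_trees` (default 100), `target_class` (default `"signal"`),
#'   `threshold` (default 0.5), `mode` (`"threshold"`/`"argmax"`).
#' @param objects list: `connectivity` (default 26), `min_voxels` (default 1).
#' @param analysis list: `distance_pairs` (each
#'   `list(source =, target =, mode = "to_mask"|"to_centroids")`),
#'   `within_thresholds_um` (default 10), `bands_um` (list of c(lo, hi)),
#'   `colocalization` (`list(source =, target =, threshold_um = 20)`),
#'   `density` (`list(pair_index = 1)` to fit a density curve to a pair).
#' @param evaluation list: `enabled` (phantom mode; Dice/Jaccard/overlap of
#'   the predicted mask against the truth signal mask).
#' @param compare list or NULL: `list(a_channel =, b_channel =, measure =
#'   "volume_um3", n_boot = 5000)` for the estimation-statistics stage.
#' @param out_dir output directory (created if missing).
#' @param seed global seed; per-stage seeds are derived from it by hashing
#'   the stage name.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input, classify = list(), objects = list(),
                            analysis = list(), evaluation = list(),
                            compare = NULL, out_dir = tempfile("tmeprof_run_"),
                            seed = 1L) {
  has_phantom <- !is.null(input$phantom)
  has_files <- !is.null(input$channels)
  if (has_phantom == has_files)
    stop("exactly one input mode must be set: input$phantom or input$channels")
  # shallow merge keeping defaults for unset keys (unlike modifyList, this
  # preserves unnamed list values such as distance_pairs entries)
  merge_defaults <- function(defaults, given) {
    for (nm in names(given)) defaults[nm] <- list(given[[nm]])
    defaults
  }
  cfg <- list(
    input = input,
    classify = merge_defaults(
      list(channels = "cancer", n_per_class = 200L, n_trees = 100L,
           target_class = "signal", threshold = 0.5, mode = "threshold",
           feature_config = NULL), classify),
    objects = merge_defaults(
      list(connectivity = 26L, min_voxels = 1L), objects),
    analysis = merge_defaults(
      list(distance_pairs = list(), within_thresholds_um = 10,
           bands_um = list(), colocalization = NULL, density = NULL),
      analysis),
    evaluation = merge_defaults(list(enabled = has_phantom), evaluation),
    compare = compare,
    out_dir = out_dir,
    seed = as.integer(seed))
  if (any(cfg$analysis$within_thresholds_um < 0))
    stop("distance thresholds must be non-negative")
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with the argument structure of [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$input$phantom) && !inherits(y$input$phantom, "phantom_spec"))
    y$input$phantom <- do.call(phantom_spec, y$input$phantom)
  do.call(pipeline_config, y)
}

# deterministic per-stage seed below 2^31, derived from the stage name
stage_seed <- function(global_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(global_seed) * 7919 + h * 104729) %% 2147483647)
}

#' Run the full profiling pipeline from a configuration
#'
#' Executes the requested stages in dependency order, writes every artifact
#' under the configured output directory, and returns (and writes) a run
#' manifest with the config echo, per-file MD5 checksums, and the seeds used.
#' Re-running with the same config and seed reproduces all numeric outputs
#' bit-identically.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress per-stage progress messages.
#' @return A list of class `run_manifest`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- list()
  outputs <- character()
  phantom_mode <- !is.null(config$input$phantom)

  ## ---- stage: input -------------------------------------------------------
  truth <- NULL
  if (phantom_mode) {
    spec <- config$input$phantom
    if (!inherits(spec, "phantom_spec")) spec <- do.call(phantom_spec, spec)
    seeds$simulate <- stage_seed(config$seed, "simulate")
    ph <- generate_phantom(spec, seed = seeds$simulate)
    channels <- ph$channels
    truth <- ph$truth
    say("simulate: phantom %s with %d catalogued object(s)",
        paste(spec$shape, collapse = "x"), nrow(truth$catalog))
  } else {
    fls <- config$input$channels
    channels <- channel_stack(lapply(fls, function(p)
      read_volume(p, fmt = config$input$fmt,
                  spacing = config$input$spacing_um)))
    say("input: read %d channel(s)", length(channels))
  }

  ## validate analysis requests against available channels before computing
  known <- names(channels)
  for (pr in config$analysis$distance_pairs)
    for (ch in c(pr$source, pr$target))
      if (!ch %in% known)
        stop("analysis requests unknown channel '", ch, "'; available: ",
             paste(known, collapse = ", "))
  if (!is.null(config$analysis$colocalization))
    for (ch in c(config$analysis$colocalization$source,
                 config$analysis$colocalization$target))
      if (!ch %in% known)
        stop("co-localization requests unknown channel '", ch, "'")
  cl_channels <- intersect(config$classify$channels, known)
  if (length(cl_channels) < length(config$classify$channels))
    stop("classification requests unknown channel(s): ",
         paste(setdiff(config$classify$channels, known), collapse = ", "))

  ## channels needed downstream (classified lazily per request)
  needed <- unique(c(cl_channels,
                     unlist(lapply(config$analysis$distance_pairs,
                                   function(p) c(p$source, p$target))),
                     config$analysis$colocalization$source,
                     config$analysis$colocalization$target,
                     if (!is.null(config$compare))
                       c(config$compare$a_channel, config$compare$b_channel)))

  fcfg <- config$classify$feature_config
  if (is.null(fcfg)) fcfg <- default_feature_config()

  masks <- list()
  tables <- list()
  scores <- list()
  for (ch in needed) {
    if (ch %in% cl_channels) {
      ## ---- features / train / predict / binarize --------------------------
      say("features: channel '%s' (%d features)", ch,
          length(feature_names(fcfg)))
      fs <- compute_feature_stack(channels[[ch]], fcfg)
      seeds[[paste0("annotate_", ch)]] <-
        stage_seed(config$seed, paste0("annotate_", ch))
      ann <- if (phantom_mode)
        sample_annotations(truth, ch, config$classify$n_per_class,
                           seed = seeds[[paste0("annotate_", ch)]])
      else read_annotations(config$input$annotation_paths[[ch]],
                            dim(channels[[ch]]$data))
      ann_path <- file.path(out_dir, paste0("annotations_", ch, ".csv"))
      write_annotations(ann, ann_path)
      outputs <- c(outputs, ann_path)
      seeds[[paste0("train_", ch)]] <-
        stage_seed(config$seed, paste0("train_", ch))
      model <- train_pixel_classifier(fs, ann,
                                      n_trees = config$classify$n_trees,
                                      seed = seeds[[paste0("train_", ch)]])
      pm <- predict_probabilities(model, fs)
      rm(fs)
      pm_path <- file.path(out_dir, paste0("probabilities_", ch, ".h5"))
      if (file.exists(pm_path)) unlink(pm_path)
      rhdf5::h5createFile(pm_path)
      suppressMessages(rhdf5::h5write(pm$data, pm_path, "probabilities"))
      outputs <- c(outputs, pm_path)
      mask <- binarize_probability(pm, config$classify$target_class,
                                   config$classify$threshold,
                                   config$classify$mode)
      rm(pm)
      say("classify: channel '%s' -> %d foreground voxel(s)", ch,
          sum(mask$data))
      if (isTRUE(config$evaluation$enabled) && phantom_mode) {
        ref <- binary_mask(truth$labels[[ch]] ==
                             PHANTOM_CLASS_CODES[["signal"]],
                           channels[[ch]]$spacing)
        scores[[ch]] <- evaluate_segmentation(mask, ref)
      }
    } else {
      ## non-classified channels fall back to the truth signal mask
      ## (phantom mode) so distance targets do not require training each one
      if (!phantom_mode)
        stop("channel '", ch, "' is requested by the analysis but not ",
             "classified; add it to classify$channels")
      mask <- binary_mask(truth$labels[[ch]] ==
                           PHANTOM_CLASS_CODES[["signal"]],
                         channels[[ch]]$spacing,
                         provenance = list(source = "phantom_truth"))
    }
    mask_path <- file.path(out_dir, paste0("mask_", ch, ".tif"))
    write_volume(voxel_grid(array(as.numeric(mask$data) * 255,
                                  dim(mask$data)),
                            mask$spacing),
                 mask_path, fmt = "tiff", bits = 8L)
    outputs <- c(outputs, mask_path)
    masks[[ch]] <- mask

    ## ---- objects ---------------------------------------------------------
    lab <- label_components(mask, config$objects$connectivity)
    tab <- extract_objects(lab, config$objects$min_voxels)
    say("objects: channel '%s' -> %d object(s)", ch, nrow(tab))
    tab_path <- file.path(out_dir, paste0("objects_", ch, ".csv"))
    write_object_table(tab, tab_path)
    outputs <- c(outputs, tab_path)
    tables[[ch]] <- tab
  }

  ## ---- distances / spatial statistics ------------------------------------
  spatial <- list()
  dist_sets <- list()
  for (i in seq_along(config$analysis$distance_pairs)) {
    pr <- config$analysis$distance_pairs[[i]]
    mode <- if (is.null(pr$mode)) "to_mask" else pr$mode
    ds <- if (mode == "to_mask")
      min_distance_to_mask(tables[[pr$source]], masks[[pr$target]])
    else min_distance_between_objects(tables[[pr$source]],
                                      tables[[pr$target]])
    nm <- paste0(pr$source, "_to_", pr$target, "_", mode)
    ds_path <- file.path(out_dir, paste0("distances_", nm, ".csv"))
    write_distance_set(ds, ds_path)
    outputs <- c(outputs, ds_path)
    dist_sets[[nm]] <- ds
    entry <- list(pair = nm, n = nrow(ds))
    for (thr in config$analysis$within_thresholds_um)
      entry[[sprintf("fraction_within_%g_um", thr)]] <-
        fraction_within(ds, thr)
    for (bd in config$analysis$bands_um)
      entry[[sprintf("band_fraction_%g_%g_um", bd[1], bd[2])]] <-
        band_fraction(ds, bd[1], bd[2])
    ec <- ecdf_curve(ds)
    ec_path <- file.path(out_dir, paste0("ecdf_", nm, ".csv"))
    utils::write.csv(data.frame(x_um = ec$x, F = ec$F), ec_path,
                     row.names = FALSE)
    outputs <- c(outputs, ec_path)
    if (!is.null(config$analysis$density) &&
        identical(config$analysis$density$pair_index, i) && nrow(ds) >= 2 &&
        stats::sd(ds$distance_um) > 0) {
      dc <- density_curve(ds)
      dc_path <- file.path(out_dir, paste0("density_", nm, ".csv"))
      utils::write.csv(data.frame(x_um = dc$x, density = dc$density),
                       dc_path, row.names = FALSE)
      outputs <- c(outputs, dc_path)
      entry$density_modes_um <- dc$modes_um
      entry$density_bandwidth_um <- dc$bandwidth_um
    }
    spatial[[nm]] <- entry
  }
  if (!is.null(config$analysis$colocalization)) {
    cc <- config$analysis$colocalization
    thr <- if (is.null(cc$threshold_um)) 20 else cc$threshold_um
    co <- colocalization(tables[[cc$source]], tables[[cc$target]],
                         threshold_um = thr)
    spatial$colocalization <- list(
      source = cc$source, target = cc$target, threshold_um = thr,
      n_sources = co$n_sources, n_colocalized = co$n_colocalized,
      fraction = co$fraction)
    say("coloc: %d / %d %s object(s) within %g um of %s",
        co$n_colocalized, co$n_sources, cc$source, thr, cc$target)
  }

  ## ---- statistics --------------------------------------------------------
  stats_out <- list()
  if (!is.null(config$compare)) {
    cp <- config$compare
    av <- tables[[cp$a_channel]][[cp$measure %||% "volume_um3"]]
    bv <- tables[[cp$b_channel]][[cp$measure %||% "volume_um3"]]
    seeds$compare <- stage_seed(config$seed, "compare")
    est <- bootstrap_mean_difference(av, bv,
                                     n_boot = cp$n_boot %||% 5000L,
                                     seed = seeds$compare)
    wt <- welch_t_test(av, bv)
    stats_out$comparison <- list(
      a_channel = cp$a_channel, b_channel = cp$b_channel,
      measure = cp$measure %||% "volume_um3",
      mean_difference = est$mean_difference,
      ci_low = est$ci_low, ci_high = est$ci_high, level = est$level,
      n_boot = est$n_boot,
      welch_t = wt$t, welch_df = wt$df, welch_p = wt$p_value)
  }

  results <- list(
    summaries = lapply(names(tables), function(ch)
      unclass(summarize_objects(tables[[ch]], ch))),
    spatial = spatial,
    segmentation_scores = lapply(scores, function(s)
      list(dice = s$dice, jaccard = s$jaccard, overlap = s$overlap)),
    statistics = stats_out)
  res_path <- file.path(out_dir, "results.json")
  jsonlite::write_json(results, res_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  outputs <- c(outputs, res_path)

  manifest <- structure(list(
    package_version = as.character(utils::packageVersion("tmeprofiler")),
    seed = config$seed,
    stage_seeds = seeds,
    config = config,
    outputs = data.frame(path = outputs,
                         md5 = unname(tools::md5sum(outputs)),
                         stringsAsFactors = FALSE),
    results = results,
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    class = "run_manifest")
  man_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(
    manifest[setdiff(names(manifest), "config")], man_path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
  say("done: %d artifact(s) under %s", length(outputs), out_dir)
  manifest
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> seed %d, %d artifact(s)\n", x$seed,
              nrow(x$outputs)))
  invisible(x)
}
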