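# FNV-1a hash of the canonicalized config; names run directories so a rerun
# with the same config lands in the same place.
fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)   # keep in integer range
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Default pipeline configuration
#' @return named list of all config keys with their defaults.
#' @export
default_config <- function() {
  list(
    input_edf_dir = NULL,              # read EDFs instead of simulating
    n_per_group = 20,
    channels = default_channels(),
    fs = 1000,
    duration = 80,
    noise_sd = 0.5,
    n_segments = 4,
    bands = eeg_bands()$name,
    threshold = 0.71,
    sweep = NULL,                      # e.g. seq(0.11, 0.91, by = 0.1)
    multilayer_bands = c("alpha", "beta1", "beta2"),
    selector = "filter",
    k = 20,
    kinds = "elts",
    folds = 10,
    seed = 1,
    group_by_subject = FALSE,
    out_dir = "plvnet-runs"
  )
}

#' Validate a pipeline configuration
#'
#' Reads a YAML config file (or takes a list), applies defaults, and either
#' returns the fully populated config or stops with an exhaustive list of
#' every problem found (not just the first).
#'
#' @param config path to a YAML file, or a named list of overrides.
#' @param strict treat unknown keys as errors instead of warnings.
#' @return The validated `run_config` list.
#' @export
validate_config <- function(config = list(), strict = FALSE) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  stopifnot(is.list(config))
  defaults <- default_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    msg <- paste("unknown config key(s):", paste(unknown, collapse = ", "))
    if (strict) stop(msg) else warning(msg)
    config <- config[intersect(names(config), names(defaults))]
  }
  cfg <- defaults
  cfg[names(config)] <- config

  errs <- character()
  add <- function(m) errs <<- c(errs, m)
  if ("threshold" %in% names(config) && !is.null(cfg$sweep))
    add("threshold and sweep are mutually exclusive; set only one")
  if (!is.null(cfg$sweep)) {
    if (any(cfg$sweep <= 0 | cfg$sweep >= 1))
      add("sweep thresholds must lie in (0,1)")
  } else if (!(is.numeric(cfg$threshold) && cfg$threshold > 0 &&
               cfg$threshold < 1))
    add(paste0("threshold must lie in the open interval (0,1); got ",
               cfg$threshold))
  badb <- setdiff(c(cfg$bands, cfg$multilayer_bands), eeg_bands()$name)
  if (length(badb) > 0)
    add(paste0("undefined band(s): ", paste(unique(badb), collapse = ", ")))
  if (!all(cfg$multilayer_bands %in% cfg$bands))
    add("multilayer_bands must be a subset of bands")
  if (!(is.numeric(cfg$seed) && length(cfg$seed) == 1L))
    add("seed must be a single number")
  if (!(is.numeric(cfg$folds) && cfg$folds >= 2)) add("folds must be >= 2")
  if (!(is.numeric(cfg$k) && cfg$k >= 1)) add("k must be >= 1")
  if (!all(cfg$kinds %in% classifier_kinds()))
    add(paste0("unknown classifier kind(s): ",
               paste(setdiff(cfg$kinds, classifier_kinds()), collapse = ", ")))
  if (!(cfg$selector %in% c("filter", "ks", "chi2", "tree", "l2", "pca")))
    add(paste0("unknown selector: ", cfg$selector))
  if (is.null(cfg$input_edf_dir)) {
    if (!(is.numeric(cfg$n_per_group) && cfg$n_per_group >= 2))
      add("n_per_group must be >= 2")
    if (!(is.numeric(cfg$fs) && cfg$fs > 60))
      add("fs must exceed twice the highest band edge (60 Hz)")
  } else if (!dir.exists(cfg$input_edf_dir))
    add(paste0("input_edf_dir does not exist: ", cfg$input_edf_dir))
  if (length(errs) > 0)
    stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "))
  class(cfg) <- "run_config"
  cfg
}

#' Threshold-sweep harness
#'
#' Re-thresholds the stored PLV matrices at each sweep value, rebuilds the
#' feature conditions, and cross-validates, reporting accuracy as a function
#' of threshold together with the argmax.
#'
#' @param cc a [cohort_connectivity()] result.
#' @param thresholds sweep values (default 0.11 to 0.91 in steps of 0.1).
#' @param conditions which feature conditions to evaluate.
#' @param ... passed to [run_comparison()].
#' @return list with `results` (threshold x condition accuracy table) and
#'   `best` (per condition, the threshold with the highest mean accuracy).
#' @export
sweep_thresholds <- function(cc, thresholds = seq(0.11, 0.91, by = 0.1),
                             conditions = "alpha", ...) {
  rows <- list()
  for (th in thresholds) {
    tabs <- feature_tables(cc, threshold = th)[conditions]
    res <- run_comparison(tabs, ...)
    res$threshold <- th
    rows[[length(rows) + 1L]] <- res
  }
  results <- do.call(rbind, rows)
  best <- do.call(rbind, lapply(split(results, results$condition), function(d)
    data.frame(condition = d$condition[1],
               best_threshold = d$threshold[which.max(d$mean_accuracy)],
               best_accuracy = max(d$mean_accuracy))))
  rownames(best) <- NULL
  list(results = results, best = best)
}

write_tidy_metrics <- function(tabs, path) {
  rows <- list()
  for (cond in names(tabs)) {
    t <- tabs[[cond]]
    long <- utils::stack(as.data.frame(t$x))
    df <- data.frame(subject_id = rep(t$subject_id, ncol(t$x)),
                     group = rep(as.character(t$group), ncol(t$x)),
                     segment = rep(t$segment, ncol(t$x)),
                     network = cond, feature = long$ind, value = long$values,
                     stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- df
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
}

#' Run the full pipeline
#'
#' simulate (or read EDF) -> preprocess -> spectra -> PLV connectivity ->
#' binary networks -> node metrics -> feature tables -> cross-validated
#' classification, writing every stage's outputs plus a machine-readable
#' manifest and a structured log under a config-hash-named run directory.
#' Reruns with an identical config are identical (all randomness is seeded).
#'
#' @param config a config list, YAML path, or `run_config` from
#'   [validate_config()].
#' @return The run directory path, invisibly; its `manifest.json` lists
#'   every output file.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  hash <- fnv1a(paste(deparse(unclass(cfg)), collapse = "\n"))
  run_dir <- file.path(cfg$out_dir, paste0("run-", hash))
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(run_dir, "log.txt")
  cat("", file = log_path)
  files <- character()
  logln <- function(...) cat(paste0(..., "\n"), file = log_path, append = TRUE)
  emit <- function(name) files <<- c(files, name)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste("FAILED at stage:", name), file.path(run_dir, "FAILED"))
      stop("pipeline failed at stage '", name, "': ", conditionMessage(e),
           call. = FALSE)
    })
  }

  yaml::write_yaml(unclass(cfg)[!vapply(unclass(cfg), is.null, TRUE)],
                   file.path(run_dir, "config.yaml"))
  emit("config.yaml")

  cohort <- stage("cohort", {
    if (is.null(cfg$input_edf_dir)) {
      spec <- cohort_spec(n_per_group = cfg$n_per_group,
                          channels = cfg$channels, fs = cfg$fs,
                          duration = cfg$duration, noise_sd = cfg$noise_sd,
                          seed = cfg$seed)
      generate_cohort(spec)
    } else {
      paths <- list.files(cfg$input_edf_dir, pattern = "\\.edf$",
                          full.names = TRUE, ignore.case = TRUE)
      if (length(paths) == 0) stop("no EDF files in ", cfg$input_edf_dir)
      lapply(paths, read_edf, channels = cfg$channels)
    }
  })
  man <- data.frame(
    subject_id = vapply(cohort, function(r) r$subject_id, ""),
    group = vapply(cohort, function(r) r$group, ""),
    n_channels = vapply(cohort, function(r) nrow(r$data), 0L),
    n_samples = vapply(cohort, function(r) ncol(r$data), 0L),
    fs = vapply(cohort, function(r) r$fs, 0))
  utils::write.csv(man, file.path(run_dir, "cohort_manifest.csv"),
                   row.names = FALSE)
  emit("cohort_manifest.csv")
  logln("stage=cohort subjects=", length(cohort), " channels=",
        nrow(cohort[[1]]$data), " samples=", ncol(cohort[[1]]$data))

  cc <- stage("connectivity", cohort_connectivity(
    cohort, bands = eeg_bands(cfg$bands), n_segments = cfg$n_segments,
    multilayer_bands = cfg$multilayer_bands))
  seg_sum <- stats::aggregate(segment ~ subject_id + group,
                              data = cc$samples, FUN = length)
  names(seg_sum)[3] <- "n_segments"
  utils::write.csv(seg_sum, file.path(run_dir, "segments_summary.csv"),
                   row.names = FALSE)
  emit("segments_summary.csv")
  logln("stage=connectivity samples=", nrow(cc$samples), " bands=",
        paste(cc$bands$name, collapse = ","))

  stage("export_plv", {
    rows <- list()
    for (s in seq_len(nrow(cc$samples))) for (b in cc$bands$name) {
      v <- cc$plv[[s]][[b]]$values
      idx <- which(upper.tri(v), arr.ind = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = cc$samples$subject_id[s], group = cc$samples$group[s],
        segment = cc$samples$segment[s], band = b,
        node_i = rownames(v)[idx[, 1]], node_j = colnames(v)[idx[, 2]],
        plv = v[idx], stringsAsFactors = FALSE)
    }
    utils::write.csv(do.call(rbind, rows),
                     file.path(run_dir, "plv_matrices.csv"), row.names = FALSE)
  })
  emit("plv_matrices.csv")

  thresholds <- if (is.null(cfg$sweep)) cfg$threshold else cfg$sweep
  all_res <- list()
  for (th in thresholds) {
    tabs <- stage("features", feature_tables(cc, threshold = th))
    if (identical(th, thresholds[1])) {
      write_tidy_metrics(tabs, file.path(run_dir, "features.csv"))
      emit("features.csv")
      adj_rows <- list()
      for (s in seq_len(nrow(cc$samples))) for (b in cc$bands$name) {
        net <- binarize(cc$plv[[s]][[b]], th)
        idx <- which(upper.tri(net$adjacency) & net$adjacency > 0,
                     arr.ind = TRUE)
        if (nrow(idx) == 0) next
        adj_rows[[length(adj_rows) + 1L]] <- data.frame(
          subject_id = cc$samples$subject_id[s],
          segment = cc$samples$segment[s], band = b, threshold = th,
          node_i = net$node_labels[idx[, 1]],
          node_j = net$node_labels[idx[, 2]], stringsAsFactors = FALSE)
      }
      utils::write.csv(
        if (length(adj_rows)) do.call(rbind, adj_rows) else
          data.frame(subject_id = character(), segment = integer(),
                     band = character(), threshold = numeric(),
                     node_i = character(), node_j = character()),
        file.path(run_dir, "adjacency_edges.csv"), row.names = FALSE)
      emit("adjacency_edges.csv")
    }
    res <- stage("classify", run_comparison(
      tabs, kinds = cfg$kinds, selector = cfg$selector, k = cfg$k,
      k_folds = cfg$folds, seed = cfg$seed,
      group_by_subject = isTRUE(cfg$group_by_subject)))
    res$threshold <- th
    all_res[[length(all_res) + 1L]] <- res
    logln("stage=classify threshold=", th, " conditions=", length(tabs))
  }
  results <- do.call(rbind, all_res)
  utils::write.csv(results, file.path(run_dir, "cv_results.csv"),
                   row.names = FALSE)
  emit("cv_results.csv")
  jsonlite::write_json(results, file.path(run_dir, "cv_results.json"),
                       dataframe = "rows", digits = NA, auto_unbox = TRUE)
  emit("cv_results.json")

  manifest <- list(config_hash = hash, seed = cfg$seed, files = files)
  jsonlite::write_json(manifest, file.path(run_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  logln("stage=done files=", length(files))
  invisible(run_dir)
}
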