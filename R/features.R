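#' Construct a feature table
#'
#' Samples x features matrix plus sample labels; the classifier's input.
#' Feature labels must be unique, values complete, and the group label must
#' take exactly two values.
#'
#' @param x numeric matrix (samples x features) with column names.
#' @param subject_id,segment,group per-sample label vectors.
#' @param condition label describing which feature set this is.
#' @return A `feature_table`.
#' @export
feature_table <- function(x, subject_id, segment, group, condition = "features") {
  x <- as.matrix(x)
  if (anyNA(x) || !all(is.finite(x))) stop("feature table contains missing or non-finite values")
  if (is.null(colnames(x)) || anyDuplicated(colnames(x)))
    stop("feature labels must be present and unique")
  if (nrow(x) != length(subject_id) || nrow(x) != length(group) ||
      nrow(x) != length(segment))
    stop("sample label lengths do not match the feature matrix")
  group <- factor(group)
  if (nlevels(group) != 2)
    stop("group must have exactly 2 classes (got ",
         paste(levels(group), collapse = ", "), ")")
  structure(list(x = x, subject_id = as.character(subject_id),
                 segment = as.integer(segment), group = group,
                 condition = condition),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> '%s': %d samples x %d features (%s)\n",
              x$condition, nrow(x$x), ncol(x$x),
              paste(sprintf("%s n=%d", levels(x$group), table(x$group)),
                    collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.feature_table <- function(x, ...) {
  cbind(data.frame(subject_id = x$subject_id, segment = x$segment,
                   group = x$group, stringsAsFactors = FALSE),
        as.data.frame(x$x))
}

#' Write / read a feature table as CSV
#' @param table a `feature_table`.
#' @param path CSV path.
#' @return `path` (write) or a `feature_table` (read).
#' @export
write_feature_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @param condition condition label for the re-read table.
#' @export
read_feature_csv <- function(path, condition = "features") {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta <- c("subject_id", "segment", "group")
  feature_table(as.matrix(df[, setdiff(names(df), meta), drop = FALSE]),
                df$subject_id, df$segment, df$group, condition)
}

#' Spectral and connectivity summaries for a whole cohort
#'
#' Runs preprocessing, segmentation, Welch spectra, and per-band PLV
#' connectivity for every subject, retaining the per-sample PLV matrices so
#' that networks can be re-thresholded cheaply (e.g. for a threshold sweep).
#' One sample = one subject-segment.
#'
#' @param cohort list of [eeg_recording()] objects with group labels.
#' @param bands band table (default all five).
#' @param n_segments segments per subject (default 4).
#' @param multilayer_bands bands forming the multilayer/IMN layers.
#' @param preprocess_seconds retained window for [preprocess()]; default the
#'   full recording length.
#' @param welch_seconds,overlap_fraction Welch parameters.
#' @param edge_trim seconds trimmed per segment end in the PLV step.
#' @param do_preprocess set `FALSE` if the recordings are already
#'   preprocessed.
#' @return A `cohort_connectivity` object: sample metadata, per-sample
#'   band-power and band-ratio matrices, per-sample multilayer weights
#'   (the power-spectral ratios over `multilayer_bands`), and per-sample
#'   per-band PLV matrices.
#' @export
cohort_connectivity <- function(cohort, bands = eeg_bands(), n_segments = 4,
                                multilayer_bands = c("alpha", "beta1", "beta2"),
                                preprocess_seconds = NULL,
                                welch_seconds = 2, overlap_fraction = 0.5,
                                edge_trim = 1, do_preprocess = TRUE) {
  if (is.character(bands)) bands <- eeg_bands(bands)
  channels <- cohort[[1]]$channel_labels
  samples <- list(); power <- list(); ratio <- list(); wts <- list()
  plv_list <- list()
  for (rec in cohort) {
    r <- if (do_preprocess) {
      ws <- if (is.null(preprocess_seconds)) duration_s(rec) else preprocess_seconds
      preprocess(rec, window_seconds = ws)
    } else rec
    segs <- split_segments(r, n_segments)
    for (seg in segs) {
      prof <- welch_psd(seg, welch_seconds, overlap_fraction)
      pw <- vapply(seq_len(nrow(bands)), function(i)
        band_power(prof, bands[i, ], per_channel = TRUE),
        numeric(length(channels)))
      colnames(pw) <- bands$name               # channels x bands
      rt <- pw / rowSums(pw)                   # per-channel ratios, all bands
      w <- band_ratios(prof, multilayer_bands)
      cms <- lapply(seq_len(nrow(bands)), function(i)
        connectivity_matrix(seg, bands[i, ], edge_trim = edge_trim))
      names(cms) <- bands$name
      samples[[length(samples) + 1L]] <- data.frame(
        subject_id = rec$subject_id, group = rec$group,
        segment = seg$segment_index, stringsAsFactors = FALSE)
      power[[length(power) + 1L]] <- pw
      ratio[[length(ratio) + 1L]] <- rt
      wts[[length(wts) + 1L]] <- w
      plv_list[[length(plv_list) + 1L]] <- cms
    }
  }
  structure(list(samples = do.call(rbind, samples), power = power,
                 ratio = ratio, weights = wts, plv = plv_list,
                 bands = bands, channels = channels,
                 multilayer_bands = multilayer_bands),
            class = "cohort_connectivity")
}

#' @export
print.cohort_connectivity <- function(x, ...) {
  cat(sprintf("<cohort_connectivity> %d samples, %d channels, bands: %s\n",
              nrow(x$samples), length(x$channels),
              paste(x$bands$name, collapse = ", ")))
  invisible(x)
}

#' Build the per-condition feature tables
#'
#' Thresholds every stored PLV matrix into a binary network and assembles
#' the classification conditions: `PS` (per-channel band powers and band
#' ratios), one condition per band (8 nodes x 4 node metrics = 32 features),
#' `MN` (unweighted node-wise sums over the multilayer bands) and `IMN`
#' (sums weighted by each sample's power-spectral ratios).
#'
#' @param cc a [cohort_connectivity()] result.
#' @param threshold PLV binarization threshold (default 0.71).
#' @return Named list of `feature_table` objects:
#'   `PS`, one per band, `MN`, `IMN`.
#' @export
feature_tables <- function(cc, threshold = 0.71) {
  stopifnot(inherits(cc, "cohort_connectivity"))
  ns <- nrow(cc$samples)
  bands <- cc$bands$name
  chans <- cc$channels
  metrics <- c("degree", "clustering", "efficiency", "robustness")

  ps_names <- c(outer(chans, bands, function(ch, b) paste("power", b, ch, sep = "|")),
                outer(chans, bands, function(ch, b) paste("ratio", b, ch, sep = "|")))
  ps <- matrix(NA_real_, ns, length(ps_names), dimnames = list(NULL, ps_names))
  band_feats <- lapply(bands, function(b) {
    nm <- c(outer(chans, metrics, function(ch, m) paste(b, m, ch, sep = "|")))
    matrix(NA_real_, ns, length(nm), dimnames = list(NULL, nm))
  })
  names(band_feats) <- bands
  mn_names <- c(outer(chans, metrics, function(ch, m) paste("MN", m, ch, sep = "|")))
  imn_names <- sub("^MN", "IMN", mn_names)
  mn <- matrix(NA_real_, ns, length(mn_names), dimnames = list(NULL, mn_names))
  imn <- matrix(NA_real_, ns, length(imn_names), dimnames = list(NULL, imn_names))

  for (s in seq_len(ns)) {
    ps[s, ] <- c(as.numeric(cc$power[[s]]), as.numeric(cc$ratio[[s]]))
    layer_ms <- list()
    for (b in bands) {
      net <- binarize(cc$plv[[s]][[b]], threshold)
      ms <- node_metrics(net)
      band_feats[[b]][s, ] <- as.numeric(as.matrix(ms[, metrics]))
      layer_ms[[b]] <- ms
    }
    ml_layers <- layer_ms[cc$multilayer_bands]
    mn[s, ] <- as.numeric(as.matrix(
      multilayer_metrics(ml_layers)[, metrics]))
    imn[s, ] <- as.numeric(as.matrix(
      multilayer_metrics(ml_layers, weights = cc$weights[[s]])[, metrics]))
  }
  meta <- cc$samples
  mk <- function(m, cond) feature_table(m, meta$subject_id, meta$segment,
                                        meta$group, condition = cond)
  out <- c(list(PS = mk(ps, "PS")),
           stats::setNames(lapply(bands, function(b)
             mk(band_feats[[b]], b)), bands),
           list(MN = mk(mn, "MN"), IMN = mk(imn, "IMN")))
  out
}

#' One-call feature extraction
#'
#' [cohort_connectivity()] followed by [feature_tables()].
#'
#' @inheritParams cohort_connectivity
#' @inheritParams feature_tables
#' @param ... passed to [cohort_connectivity()].
#' @return Named list of `feature_table` objects.
#' @export
extract_features <- function(cohort, threshold = 0.71, ...) {
  feature_tables(cohort_connectivity(cohort, ...), threshold = threshold)
}
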