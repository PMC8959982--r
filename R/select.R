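#' Fit a feature selector on training data
#'
#' All selectors are fit on training samples only; apply the result to any
#' split with [apply_selector()]. Methods:
#' \describe{
#'   \item{filter}{top-`k` features by absolute two-sample (Welch) t
#'     statistic between the classes; zero-variance features score 0.}
#'   \item{ks}{features whose two-sample Kolmogorov--Smirnov p-value is
#'     below `alpha` (default 0.001). If no feature passes, the single
#'     smallest-p feature is kept so downstream models stay defined.}
#'   \item{chi2}{top-`k` by chi-square statistic between class and the
#'     feature discretized into quantile bins; requires non-negative
#'     features (shift first if needed).}
#'   \item{tree}{top-`k` by mean impurity (Gini) importance of a seeded
#'     random forest.}
#'   \item{l2}{top-`k` by absolute coefficient of an l2-regularized
#'     (ridge) linear model on standardized features.}
#'   \item{pca}{the first `k` principal components of the standardized
#'     training matrix (a transformation, not a subset).}
#' }
#'
#' @param x training feature matrix (samples x features).
#' @param y two-level factor of training labels.
#' @param method one of `"filter", "ks", "chi2", "tree", "l2", "pca"`.
#' @param k number of features/components to keep (ignored by `ks`).
#' @param alpha KS selection p-value cut (default 0.001).
#' @param bins quantile bins for `chi2` discretization.
#' @param seed RNG seed for the `tree` method.
#' @return A `feature_selector` to pass to [apply_selector()].
#' @export
fit_selector <- function(x, y, method = "filter", k = 20, alpha = 0.001,
                         bins = 5, seed = 1) {
  methods <- c("filter", "ks", "chi2", "tree", "l2", "pca")
  if (!(method %in% methods))
    stop("unknown selector '", method, "'; valid: ",
         paste(methods, collapse = ", "))
  y <- factor(y)
  stopifnot(nlevels(y) == 2, nrow(x) == length(y))
  if (method != "ks") {
    if (!(is.numeric(k) && k >= 1)) stop("k must be >= 1")
    if (k > ncol(x)) stop("k = ", k, " exceeds feature count ", ncol(x))
    k <- as.integer(k)
  }
  i1 <- y == levels(y)[1]

  if (method == "pca") {
    sds <- apply(x, 2L, stats::sd)
    keep <- which(sds > 1e-12)
    if (length(keep) == 0) stop("all features are constant; PCA undefined")
    pc <- stats::prcomp(x[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
    ncomp <- min(k, ncol(pc$rotation))
    return(structure(list(method = "pca", keep = keep,
                          center = pc$center, scale = pc$scale,
                          rotation = pc$rotation[, seq_len(ncomp), drop = FALSE],
                          selected = colnames(pc$rotation)[seq_len(ncomp)]),
                     class = "feature_selector"))
  }

  score <- switch(method,
    filter = apply(x, 2L, function(v) {
      s1 <- stats::sd(v[i1]); s2 <- stats::sd(v[!i1])
      d <- abs(mean(v[i1]) - mean(v[!i1]))
      if (s1 < 1e-12 && s2 < 1e-12)       # constant within both classes:
        return(if (d > 1e-12) Inf else 0) # either perfect split or useless
      d / sqrt(s1^2 / sum(i1) + s2^2 / sum(!i1))
    }),
    ks = apply(x, 2L, function(v) {
      if (stats::sd(v) < 1e-12) return(1)
      suppressWarnings(stats::ks.test(v[i1], v[!i1])$p.value)
    }),
    chi2 = {
      if (any(x < 0))
        stop("chi2 selection requires non-negative features; ",
             "shift the features first")
      apply(x, 2L, function(v) {
        if (stats::sd(v) < 1e-12) return(0)
        br <- unique(stats::quantile(v, probs = seq(0, 1, length.out = bins + 1)))
        if (length(br) < 3) br <- unique(c(min(v) - 1e-9, stats::median(v), max(v)))
        b <- cut(v, breaks = br, include.lowest = TRUE)
        suppressWarnings(as.numeric(stats::chisq.test(table(b, y))$statistic))
      })
    },
    tree = {
      old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
      set.seed(seed)
      fit <- randomForest::randomForest(x, y, ntree = 200)
      as.numeric(fit$importance[, "MeanDecreaseGini"])
    },
    l2 = {
      fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                            lambda = 0.1, standardize = TRUE)
      as.numeric(abs(stats::coef(fit)[-1, 1]))
    })

  keep <- if (method == "ks") {
    sel <- which(score < alpha)
    if (length(sel) == 0) which.min(score) else sel
  } else {
    order(score, decreasing = TRUE)[seq_len(k)]
  }
  keep <- sort(keep)
  structure(list(method = method, keep = keep,
                 selected = colnames(x)[keep], score = score),
            class = "feature_selector")
}

#' Apply a fitted selector to a feature matrix
#' @param sel a `feature_selector` from [fit_selector()].
#' @param x feature matrix with the same columns the selector was fit on.
#' @return The reduced (or, for PCA, projected) matrix.
#' @export
apply_selector <- function(sel, x) {
  stopifnot(inherits(sel, "feature_selector"))
  if (sel$method == "pca") {
    xs <- scale(x[, sel$keep, drop = FALSE], center = sel$center,
                scale = sel$scale)
    return(xs %*% sel$rotation)
  }
  x[, sel$keep, drop = FALSE]
}

#' Select features of a feature table (convenience wrapper)
#'
#' Fits the selector on the whole table and returns the reduced table. For
#' cross-validated work use [cross_validate()], which refits the selector
#' inside each training fold.
#'
#' @param table a `feature_table`.
#' @inheritParams fit_selector
#' @param ... passed to [fit_selector()].
#' @return The reduced/transformed `feature_table`.
#' @export
select_features <- function(table, method = "filter", k = 20, ...) {
  stopifnot(inherits(table, "feature_table"))
  sel <- fit_selector(table$x, table$group, method = method, k = k, ...)
  x2 <- apply_selector(sel, table$x)
  if (is.null(colnames(x2))) colnames(x2) <- sel$selected
  feature_table(x2, table$subject_id, table$segment, table$group,
                condition = paste0(table$condition, "[", method, "]"))
}
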