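#' Classifier kinds
#'
#' Baselines: `rf` (random forest), `svm` (RBF support vector machine on
#' standardized inputs), `knn` (k-nearest neighbours, k = 5), `bn` (Gaussian
#' naive Bayes). Boosted trees: `lgbm` (leaf-wise gradient-boosted trees) and
#' `gbst` (depth-wise gradient-boosted trees, log-loss objective). Ensembles
#' of the three tree models rf + lgbm + gbst: `elts` (soft voting: mean
#' predicted class probability) and `elth` (hard voting: majority label).
#'
#' @return character vector of valid kinds.
#' @export
classifier_kinds <- function() c("rf", "svm", "knn", "bn", "lgbm", "gbst",
                                 "elth", "elts")

#' Create a classifier handle
#'
#' @param kind one of [classifier_kinds()].
#' @param seed RNG seed used at fit time; with equal data and seed, fits and
#'   predictions are identical across runs.
#' @param params optional list overriding hyperparameters: `ntree` (rf, 500),
#'   `nrounds` (boosted models, 200), `eta` (0.1), `max_depth` (gbst, 3),
#'   `max_leaves` (lgbm, 31), `knn_k` (5), `svm_cost` (1).
#' @return A `plv_classifier` handle for [fit_classifier()].
#' @export
make_classifier <- function(kind, seed = 1, params = list()) {
  if (!(kind %in% classifier_kinds()))
    stop("unknown classifier kind '", kind, "'; valid kinds: ",
         paste(classifier_kinds(), collapse = ", "))
  defaults <- list(ntree = 500, nrounds = 200, eta = 0.1, max_depth = 3,
                   max_leaves = 31, knn_k = 5, svm_cost = 1)
  defaults[names(params)] <- params
  structure(list(kind = kind, seed = seed, params = defaults),
            class = "plv_classifier")
}

#' @export
print.plv_classifier <- function(x, ...) {
  cat(sprintf("<plv_classifier> kind=%s seed=%d\n", x$kind, x$seed))
  invisible(x)
}

# Standardization guardrails shared by distance/margin-based members.
std_fit <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2L, stats::sd)
  sdv[sdv < 1e-12] <- 1
  list(mu = mu, sd = sdv)
}
std_apply <- function(st, x) sweep(sweep(x, 2L, st$mu), 2L, st$sd, "/")

fit_xgb <- function(x, y, pos, p, leafwise, seed) {
  dtrain <- xgboost::xgb.DMatrix(x, label = as.numeric(y == pos))
  par <- list(objective = "binary:logistic", eta = p$eta, nthread = 1,
              eval_metric = "logloss")
  if (leafwise) {
    par$tree_method <- "hist"; par$grow_policy <- "lossguide"
    par$max_leaves <- p$max_leaves; par$max_depth <- 0
  } else {
    par$max_depth <- p$max_depth
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  xgboost::xgb.train(params = par, data = dtrain, nrounds = p$nrounds,
                     verbose = 0)
}

#' Fit a classifier
#'
#' @param clf a `plv_classifier` from [make_classifier()].
#' @param x training feature matrix.
#' @param y two-level factor; the second level is treated as the positive
#'   class whose probability [predict_prob()] reports.
#' @return A fitted model object for [predict_prob()] / [predict_label()].
#' @export
fit_classifier <- function(clf, x, y) {
  stopifnot(inherits(clf, "plv_classifier"))
  y <- factor(y)
  if (nlevels(y) != 2)
    stop("classifier requires exactly 2 classes in the training labels")
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  pos <- levels(y)[2]
  p <- clf$params
  # constant features carry no information and derail some fitters; when
  # nothing varies at all, fall back to the majority-class predictor
  keep <- which(apply(x, 2L, stats::sd) > 1e-12)
  if (length(keep) == 0) {
    return(structure(list(kind = "majority",
                          model = list(prob = mean(y == pos)),
                          levels = levels(y), features = colnames(x),
                          seed = clf$seed, keep = integer()),
                     class = "plv_fit"))
  }
  all_features <- colnames(x)
  x <- x[, keep, drop = FALSE]
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(clf$seed)
  model <- switch(clf$kind,
    rf = randomForest::randomForest(x, y, ntree = p$ntree),
    svm = {
      st <- std_fit(x)
      list(st = st,
           fit = e1071::svm(std_apply(st, x), y, kernel = "radial",
                            cost = p$svm_cost, probability = TRUE,
                            scale = FALSE))
    },
    knn = {
      st <- std_fit(x)
      list(st = st, train = std_apply(st, x), cl = y, k = p$knn_k)
    },
    bn = {
      keep <- which(apply(x, 2L, function(v)
        any(tapply(v, y, stats::sd) > 1e-12)))
      if (length(keep) == 0) keep <- 1L
      list(keep = keep,
           fit = e1071::naiveBayes(as.data.frame(x[, keep, drop = FALSE]), y))
    },
    lgbm = fit_xgb(x, y, pos, p, leafwise = TRUE, seed = clf$seed),
    gbst = fit_xgb(x, y, pos, p, leafwise = FALSE, seed = clf$seed),
    elth = ,
    elts = {
      members <- c("rf", "lgbm", "gbst")
      lapply(stats::setNames(seq_along(members), members), function(i)
        fit_classifier(make_classifier(members[i], seed = clf$seed + i,
                                       params = p), x, y))
    })
  structure(list(kind = clf$kind, model = model, levels = levels(y),
                 features = all_features, seed = clf$seed, keep = keep),
            class = "plv_fit")
}

#' Predicted probability of the positive (second-level) class
#' @param fit a `plv_fit` from [fit_classifier()].
#' @param x feature matrix to predict on.
#' @return numeric vector of probabilities. For `elts` this is exactly the
#'   mean of the three members' probabilities; for `elth` the fraction of
#'   members voting positive.
#' @export
predict_prob <- function(fit, x) {
  stopifnot(inherits(fit, "plv_fit"))
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- fit$features
  if (fit$kind == "majority")
    return(rep(fit$model$prob, nrow(x)))
  x <- x[, fit$keep, drop = FALSE]
  pos <- fit$levels[2]
  m <- fit$model
  switch(fit$kind,
    rf = as.numeric(stats::predict(m, x, type = "prob")[, pos]),
    svm = {
      pr <- stats::predict(m$fit, std_apply(m$st, x), probability = TRUE)
      as.numeric(attr(pr, "probabilities")[, pos])
    },
    knn = {
      old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
      set.seed(fit$seed)
      pr <- class::knn(m$train, std_apply(m$st, x), m$cl, k = m$k, prob = TRUE)
      pwin <- attr(pr, "prob")
      ifelse(pr == pos, pwin, 1 - pwin)
    },
    bn = as.numeric(stats::predict(
      m$fit, as.data.frame(x[, m$keep, drop = FALSE]), type = "raw")[, pos]),
    lgbm = ,
    gbst = as.numeric(stats::predict(m, xgboost::xgb.DMatrix(x))),
    elts = {
      probs <- vapply(m, predict_prob, numeric(nrow(x)), x = x)
      if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1L)
      rowMeans(probs)
    },
    elth = {
      labs <- vapply(m, function(f) predict_label(f, x) == pos,
                     logical(nrow(x)))
      if (is.null(dim(labs))) labs <- matrix(labs, nrow = 1L)
      rowMeans(labs)
    })
}

#' Predicted class labels
#'
#' Soft-voting and probabilistic kinds predict the positive class when its
#' probability exceeds 0.5 (exact ties go to the positive class,
#' deterministically); `elth` takes the majority of the three members'
#' labels.
#'
#' @inheritParams predict_prob
#' @return factor of predicted labels.
#' @export
predict_label <- function(fit, x) {
  pr <- predict_prob(fit, x)
  factor(ifelse(pr >= 0.5, fit$levels[2], fit$levels[1]),
         levels = fit$levels)
}

#' Stratified fold assignment
#'
#' Shuffles each class (or each subject, when grouping) with the seed and
#' deals round-robin, so fold test sets are disjoint, cover all samples, and
#' keep the class balance.
#'
#' @param y class factor, one entry per sample.
#' @param k_folds number of folds.
#' @param seed RNG seed.
#' @param subject optional subject ids; when given, all samples of a subject
#'   land in the same fold (grouped folds prevent identity leakage).
#' @return integer fold assignment (1..k_folds) per sample.
#' @export
make_folds <- function(y, k_folds = 10, seed = 1, subject = NULL) {
  y <- factor(y)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  fold <- integer(length(y))
  if (is.null(subject)) {
    for (lev in levels(y)) {
      idx <- sample(which(y == lev))
      fold[idx] <- rep_len(seq_len(k_folds), length(idx))
    }
  } else {
    subj <- unique(subject)
    sgrp <- y[match(subj, subject)]
    sfold <- integer(length(subj))
    for (lev in levels(sgrp)) {
      idx <- sample(which(sgrp == lev))
      sfold[idx] <- rep_len(seq_len(k_folds), length(idx))
    }
    fold <- sfold[match(subject, subj)]
  }
  fold
}

#' Cross-validated classification of a feature table
#'
#' Stratified k-fold cross-validation without repeated sampling: fold test
#' sets partition the samples. Feature selection is refit inside each
#' training fold (no information from the test fold reaches the selector or
#' the model), and every source of randomness derives from `seed`.
#'
#' @param table a `feature_table`.
#' @param kind classifier kind (see [classifier_kinds()]).
#' @param selector selection method passed to [fit_selector()], or `NULL`
#'   for no selection.
#' @param k features kept by the selector.
#' @param k_folds folds (default 10).
#' @param seed RNG seed.
#' @param group_by_subject use subject-grouped folds (default `FALSE`:
#'   sample = subject-segment, matching a segment-level design).
#' @param params hyperparameter overrides for [make_classifier()].
#' @param ... further arguments to [fit_selector()].
#' @return A `cv_result`: list with `fold_accuracy`, `mean_accuracy`,
#'   `selected` (per-fold selected feature names), `kind`, `selector`,
#'   `seed`, `folds` (the assignment), `n`.
#' @export
cross_validate <- function(table, kind = "elts", selector = "filter", k = 20,
                           k_folds = 10, seed = 1, group_by_subject = FALSE,
                           params = list(), ...) {
  stopifnot(inherits(table, "feature_table"))
  y <- table$group
  if (min(table(y)) < k_folds)
    stop("need at least k_folds = ", k_folds, " samples per class")
  fold <- make_folds(y, k_folds, seed,
                     subject = if (group_by_subject) table$subject_id)
  acc <- numeric(k_folds)
  selected <- vector("list", k_folds)
  for (f in seq_len(k_folds)) {
    tr <- fold != f; te <- !tr
    if (nlevels(droplevels(y[tr])) < 2)
      stop("a class is absent from the training set of fold ", f)
    xtr <- table$x[tr, , drop = FALSE]; ytr <- y[tr]
    xte <- table$x[te, , drop = FALSE]
    if (!is.null(selector)) {
      sel <- fit_selector(xtr, ytr, method = selector,
                          k = min(k, ncol(xtr)), seed = seed + f, ...)
      xtr <- apply_selector(sel, xtr)
      xte <- apply_selector(sel, xte)
      selected[[f]] <- sel$selected
    } else selected[[f]] <- colnames(xtr)
    clf <- make_classifier(kind, seed = seed * 1000L + f, params = params)
    fit <- fit_classifier(clf, xtr, ytr)
    pred <- predict_label(fit, xte)
    acc[f] <- mean(pred == y[te])
  }
  structure(list(fold_accuracy = acc, mean_accuracy = mean(acc),
                 selected = selected, kind = kind, selector = selector,
                 seed = seed, folds = fold, n = length(y),
                 condition = table$condition),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "<cv_result> %s | %s-%s: mean accuracy %.4f over %d folds (n = %d)\n",
    x$condition, if (is.null(x$selector)) "none" else x$selector, x$kind,
    x$mean_accuracy, length(x$fold_accuracy), x$n))
  invisible(x)
}

#' Compare feature conditions and classifiers
#'
#' Runs [cross_validate()] for every (condition, classifier) pair and emits
#' a tidy results table — the design of the power-spectrum vs single-band vs
#' multilayer comparison.
#'
#' @param tables named list of `feature_table`s (the conditions).
#' @param kinds classifier kinds to run (default `"elts"`).
#' @param selector,k,k_folds,seed,group_by_subject,params,... as in
#'   [cross_validate()].
#' @return data.frame with columns `condition`, `classifier`,
#'   `mean_accuracy`, `sd_accuracy`, `n_folds`, `n_samples`.
#' @export
run_comparison <- function(tables, kinds = "elts", selector = "filter",
                           k = 20, k_folds = 10, seed = 1,
                           group_by_subject = FALSE, params = list(), ...) {
  stopifnot(length(names(tables)) == length(tables))
  rows <- list()
  for (cond in names(tables)) for (kind in kinds) {
    cv <- cross_validate(tables[[cond]], kind = kind, selector = selector,
                         k = k, k_folds = k_folds, seed = seed,
                         group_by_subject = group_by_subject,
                         params = params, ...)
    rows[[length(rows) + 1L]] <- data.frame(
      condition = cond, classifier = kind,
      mean_accuracy = cv$mean_accuracy,
      sd_accuracy = stats::sd(cv$fold_accuracy),
      n_folds = k_folds, n_samples = cv$n, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
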