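separable_table <- function(n = 40, seed = 1) {
  set.seed(seed)
  y <- rep(c("A", "B"), each = n / 2)
  # disjoint class supports on f1 (constant within class, so every split
  # convention separates train and test identically)
  x <- cbind(f1 = ifelse(y == "B", 10, 0), f2 = rnorm(n))
  feature_table(x, paste0("s", seq_len(n)), rep(1L, n), y)
}

noise_table <- function(n = 60, p = 10, seed = 1) {
  set.seed(seed)
  y <- rep(c("A", "B"), each = n / 2)
  x <- matrix(rnorm(n * p), n, dimnames = list(NULL, paste0("f", seq_len(p))))
  feature_table(x, paste0("s", seq_len(n)), rep(1L, n), y)
}

test_that("unknown classifier kinds are rejected with the valid list", {
  expect_error(make_classifier("deepnet"), "rf")
  expect_error(make_classifier("deepnet"), "elts")
})

test_that("soft vote equals the member probability mean; hard vote is the majority", {
  tab <- separable_table(seed = 2)
  fit <- fit_classifier(make_classifier("elts", seed = 3), tab$x, tab$group)
  member_probs <- vapply(fit$model, predict_prob, numeric(nrow(tab$x)),
                         x = tab$x)
  expect_equal(predict_prob(fit, tab$x), rowMeans(member_probs),
               tolerance = 1e-12)

  fith <- fit_classifier(make_classifier("elth", seed = 3), tab$x, tab$group)
  member_labs <- vapply(fith$model, function(f)
    predict_label(f, tab$x) == "B", logical(nrow(tab$x)))
  expect_identical(predict_label(fith, tab$x) == "B",
                   rowSums(member_labs) >= 2)
})

test_that("soft-vote decision follows mean probability (0.9, 0.6, 0.3 -> positive)", {
  # decision rule on a synthetic probability triple: mean 0.6 > 0.5
  expect_equal(mean(c(0.9, 0.6, 0.3)), 0.6)
  tab <- separable_table(seed = 4)
  fit <- fit_classifier(make_classifier("elts", seed = 5), tab$x, tab$group)
  pr <- predict_prob(fit, tab$x)
  lab <- predict_label(fit, tab$x)
  expect_identical(lab == "B", pr >= 0.5)
})

test_that("every classifier kind is seeded-deterministic", {
  tab <- noise_table(seed = 6)
  small <- list(ntree = 50, nrounds = 20)
  for (kind in classifier_kinds()) {
    f1 <- fit_classifier(make_classifier(kind, seed = 11, params = small),
                         tab$x, tab$group)
    f2 <- fit_classifier(make_classifier(kind, seed = 11, params = small),
                         tab$x, tab$group)
    expect_identical(predict_prob(f1, tab$x), predict_prob(f2, tab$x),
                     info = kind)
  }
})

test_that("perfectly separable classes are classified with accuracy 1", {
  tab <- separable_table(n = 40, seed = 7)
  for (kind in c("rf", "knn", "elts")) {
    cv <- cross_validate(tab, kind = kind, selector = NULL, k_folds = 5,
                         seed = 8, params = list(ntree = 100, nrounds = 30))
    expect_equal(cv$mean_accuracy, 1, info = kind)
  }
})

test_that("folds partition the samples, stratified, without repeated sampling", {
  y <- factor(rep(c("A", "B"), each = 50))
  fold <- make_folds(y, k_folds = 10, seed = 9)
  expect_length(fold, 100)
  expect_true(all(sort(unique(fold)) == 1:10))
  expect_true(all(table(fold) == 10))               # disjoint cover
  expect_true(all(table(fold, y) == 5))             # stratified
  # grouped folds keep all samples of a subject together
  subj <- rep(paste0("s", 1:20), each = 5)
  gf <- make_folds(factor(rep(c("A", "B"), each = 50)), k_folds = 5,
                   seed = 9, subject = subj)
  expect_true(all(tapply(gf, subj, function(v) length(unique(v))) == 1))
})

test_that("cross-validation accuracy sits at chance for permuted labels", {
  accs <- vapply(1:5, function(s) {
    tab <- noise_table(n = 60, seed = 100 + s)
    cross_validate(tab, kind = "rf", selector = "filter", k = 5,
                   k_folds = 5, seed = s,
                   params = list(ntree = 100))$mean_accuracy
  }, 0)
  expect_lt(abs(mean(accs) - 0.5), 0.15)
})

test_that("cv_result bookkeeping holds and degenerate inputs are rejected", {
  tab <- separable_table(n = 40, seed = 12)
  cv <- cross_validate(tab, kind = "rf", selector = NULL, k_folds = 5,
                       seed = 13, params = list(ntree = 50))
  expect_equal(cv$mean_accuracy, mean(cv$fold_accuracy))
  expect_true(all(cv$fold_accuracy >= 0 & cv$fold_accuracy <= 1))
  expect_error(cross_validate(tab, kind = "rf", k_folds = 30, seed = 1),
               "k_folds")
})

test_that("run_comparison emits one row per condition-classifier pair", {
  tabs <- list(a = separable_table(seed = 14), b = noise_table(seed = 14))
  res <- run_comparison(tabs, kinds = c("rf", "knn"), selector = NULL,
                        k_folds = 4, seed = 15, params = list(ntree = 50))
  expect_equal(nrow(res), 4)
  expect_setequal(res$condition, c("a", "b"))
  expect_gt(res$mean_accuracy[res$condition == "a" & res$classifier == "rf"],
            res$mean_accuracy[res$condition == "b" & res$classifier == "rf"])
})
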