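# Synthetic two-class table with one informative feature among noise.
planted_table <- function(n = 80, n_noise = 31, delta = 3, seed = 1) {
  set.seed(seed)
  y <- rep(c("A", "B"), each = n / 2)
  x <- cbind(planted = rnorm(n, mean = ifelse(y == "B", delta, 0)),
             matrix(rnorm(n * n_noise), n,
                    dimnames = list(NULL, paste0("noise", seq_len(n_noise)))))
  feature_table(x, subject_id = paste0("s", seq_len(n)),
                segment = rep(1L, n), group = y)
}

test_that("feature tables enforce completeness, unique labels, two classes", {
  x <- matrix(1:12, 4, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_s3_class(feature_table(x, paste0("s", 1:4), rep(1, 4),
                                c("A", "A", "B", "B")), "feature_table")
  xna <- x; xna[1] <- NA
  expect_error(feature_table(xna, paste0("s", 1:4), rep(1, 4),
                             c("A", "A", "B", "B")), "missing")
  xd <- x; colnames(xd) <- c("a", "a", "c")
  expect_error(feature_table(xd, paste0("s", 1:4), rep(1, 4),
                             c("A", "A", "B", "B")), "unique")
  expect_error(feature_table(x, paste0("s", 1:4), rep(1, 4),
                             c("A", "A", "A", "A")), "2 classes")
})

test_that("filter selection recovers a planted feature in >= 95% of runs", {
  hits <- vapply(1:100, function(s) {
    tab <- planted_table(seed = s)
    sel <- fit_selector(tab$x, tab$group, method = "filter", k = 5)
    "planted" %in% sel$selected
  }, NA)
  expect_gte(mean(hits), 0.95)
})

test_that("KS selection at p < 0.001 is calibrated on null features", {
  set.seed(21)
  n <- 60
  y <- rep(c("A", "B"), each = n / 2)
  x <- matrix(rnorm(n * 4000), n,
              dimnames = list(NULL, paste0("f", 1:4000)))
  sel <- fit_selector(x, y, method = "ks")
  # score holds the KS p-values; count genuine sub-threshold features
  rate <- mean(sel$score < 0.001)
  expect_lte(rate, 0.001 + 3 * sqrt(0.001 / 4000))
})

test_that("chi2 selection rejects negative features and works after shifting", {
  tab <- planted_table(seed = 3)
  expect_error(fit_selector(tab$x, tab$group, method = "chi2", k = 5),
               "non-negative")
  shifted <- tab$x - min(tab$x)
  sel <- fit_selector(shifted, tab$group, method = "chi2", k = 5)
  expect_length(sel$selected, 5)
  expect_true("planted" %in% sel$selected)
})

test_that("tree and l2 selectors return k features and find strong signal", {
  tab <- planted_table(seed = 4)
  for (m in c("tree", "l2")) {
    sel <- fit_selector(tab$x, tab$group, method = m, k = 5, seed = 9)
    expect_length(sel$selected, 5)
    expect_true("planted" %in% sel$selected)
  }
  # tree selection is seeded-deterministic
  s1 <- fit_selector(tab$x, tab$group, method = "tree", k = 5, seed = 9)
  s2 <- fit_selector(tab$x, tab$group, method = "tree", k = 5, seed = 9)
  expect_identical(s1$selected, s2$selected)
})

test_that("PCA with k = rank reconstructs a rank-2 matrix exactly", {
  set.seed(6)
  u <- matrix(rnorm(40 * 2), 40)
  v <- matrix(rnorm(2 * 10), 2)
  x <- u %*% v
  colnames(x) <- paste0("f", 1:10)
  y <- rep(c("A", "B"), 20)
  sel <- fit_selector(x, y, method = "pca", k = 2)
  z <- apply_selector(sel, x)
  expect_equal(ncol(z), 2)
  recon <- z %*% t(sel$rotation)
  recon <- sweep(sweep(recon, 2, sel$scale, "*"), 2, sel$center, "+")
  expect_lt(max(abs(recon - x[, sel$keep])), 1e-8)
})

test_that("selectors are fit on training data only (no test-label leakage)", {
  tab <- planted_table(seed = 7)
  tr <- 1:60; te <- 61:80
  # a selector fit on the training split is a pure function of (x_train,
  # y_train); altering the held-out rows cannot change it
  s1 <- fit_selector(tab$x[tr, ], tab$group[tr], method = "filter", k = 5)
  xalt <- tab$x; xalt[te, ] <- 999
  s3 <- fit_selector(xalt[tr, ], tab$group[tr], method = "filter", k = 5)
  expect_identical(s1$selected, s3$selected)
  cv1 <- cross_validate(tab, kind = "rf", selector = "filter", k = 5,
                        k_folds = 4, seed = 5, params = list(ntree = 50))
  cv2 <- cross_validate(tab, kind = "rf", selector = "filter", k = 5,
                        k_folds = 4, seed = 5, params = list(ntree = 50))
  expect_identical(cv1$selected, cv2$selected)
  expect_identical(cv1$fold_accuracy, cv2$fold_accuracy)
})

test_that("select_features wrapper reduces the table; invalid input rejected", {
  tab <- planted_table(seed = 8)
  red <- select_features(tab, method = "filter", k = 5)
  expect_equal(ncol(red$x), 5)
  expect_identical(red$group, tab$group)
  expect_error(fit_selector(tab$x, tab$group, method = "bogus"), "filter")
  expect_error(fit_selector(tab$x, tab$group, method = "filter", k = 0), "k")
  expect_error(fit_selector(tab$x, tab$group, method = "filter", k = 999),
               "exceeds")
})
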