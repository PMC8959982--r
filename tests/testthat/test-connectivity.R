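tone_seg <- function(freqs, fs = 500, dur = 10, phase = NULL) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  if (is.null(phase)) phase <- rep(0, length(freqs))
  x <- t(vapply(seq_along(freqs), function(i)
    cos(2 * pi * freqs[i] * t + phase[i]), t))
  plvnet:::new_segment(x, fs, 1L, "s", "g")
}

test_that("wavelet phase of a tone advances at the tone frequency", {
  fs <- 500
  seg <- tone_seg(10, fs = fs)
  ph <- instantaneous_phase(seg, "alpha")[1, ]
  mid <- (2 * fs):(8 * fs)
  increments <- diff(ph[mid])
  increments <- (increments + pi) %% (2 * pi) - pi  # unwrap
  expect_lt(max(abs(increments - 2 * pi * 10 / fs)), 1e-3)
})

test_that("identical channels give identical phase; a quarter-period delay gives pi/2", {
  fs <- 500
  seg <- tone_seg(c(10, 10), fs = fs)
  ph <- instantaneous_phase(seg, "alpha")
  expect_identical(ph[1, ], ph[2, ])

  lag <- tone_seg(c(10, 10), fs = fs, phase = c(0, -pi / 2))
  phl <- instantaneous_phase(lag, "alpha")
  mid <- (2 * fs):(8 * fs)
  d <- (phl[1, mid] - phl[2, mid] + pi) %% (2 * pi) - pi
  expect_lt(max(abs(d - pi / 2)), 0.02)

  low <- plvnet:::new_segment(seg$data, 50, 1L, "s", "g")
  expect_error(instantaneous_phase(low, "beta2"), "Nyquist")
})

test_that("PLV analytic cases hold", {
  th <- runif(1000, -pi, pi)
  expect_identical(plv(th, th), 1)
  expect_equal(plv(th + pi / 2, th), 1, tolerance = 1e-12)
  alt <- rep(c(0, pi), 500)
  expect_equal(plv(alt, numeric(1000)), 0, tolerance = 1e-12)
  expect_error(plv(th, th[-1]), "length")
  # invariance under a common phase shift
  th2 <- runif(1000, -pi, pi)
  expect_equal(plv(th, th2), plv(th + 1.234, th2 + 1.234), tolerance = 1e-12)
})

test_that("independent-phase null mean matches sqrt(pi)/(2 sqrt(n))", {
  set.seed(11)
  n <- 200
  draws <- vapply(1:1000, function(i)
    plv(runif(n, -pi, pi), runif(n, -pi, pi)), 0)
  expected <- sqrt(pi) / (2 * sqrt(n))
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - expected), 4 * se)
})

test_that("connectivity matrices are symmetric, unit-diagonal, in [0,1], equivariant", {
  spec <- tiny_spec(n_per_group = 2, duration = 12)
  rec <- generate_subject(spec, "HC", 1)
  seg <- split_segments(rec, 1)[[1]]
  cm <- connectivity_matrix(seg, "alpha")
  v <- cm$values
  expect_equal(dim(v), c(8, 8))
  expect_identical(v, t(v))
  expect_true(all(diag(v) == 1))
  expect_true(all(v >= 0 & v <= 1))

  perm <- c(3, 1, 2, 8, 5, 4, 7, 6)
  rec_p <- select_channels(rec, rec$channel_labels[perm])
  cm_p <- connectivity_matrix(split_segments(rec_p, 1)[[1]], "alpha")
  expect_equal(cm_p$values, v[perm, perm], tolerance = 1e-12)

  bad <- seg; bad$data[1, 1] <- NA
  expect_error(connectivity_matrix(bad, "alpha"), "non-finite")
})

test_that("binarization follows strict-greater thresholding and is monotone", {
  mk_cm <- function(vals) {
    v <- matrix(vals, 8, 8); v[lower.tri(v)] <- t(v)[lower.tri(v)]
    diag(v) <- 1
    rownames(v) <- colnames(v) <- default_channels()
    structure(list(values = v, band = eeg_bands("alpha"),
                   subject_id = "s", group = "g", segment_index = 1L),
              class = "connectivity_matrix")
  }
  all9 <- mk_cm(0.9)
  k8 <- binarize(all9, 0.71)
  expect_equal(sum(k8$adjacency) / 2, 28)       # complete graph K8
  expect_true(all(diag(k8$adjacency) == 0))
  empty <- binarize(all9, 0.91)
  expect_equal(sum(empty$adjacency), 0)

  set.seed(12)
  mixed_vals <- matrix(sample(c(0.5, 0.8), 64, replace = TRUE), 8, 8)
  mixed <- mk_cm(mixed_vals)
  net <- binarize(mixed, 0.71)
  expect_identical(unname(net$adjacency[upper.tri(net$adjacency)]),
                   as.integer(mixed$values[upper.tri(mixed$values)] == 0.8))
  # ties at exactly the threshold are excluded
  expect_equal(sum(binarize(mk_cm(0.71), 0.71)$adjacency), 0)

  # raising the threshold never adds an edge
  rnd <- mk_cm(runif(64))
  ths <- seq(0.11, 0.91, by = 0.1)
  edges <- vapply(ths, function(th) sum(binarize(rnd, th)$adjacency), 0)
  expect_true(all(diff(edges) <= 0))
  expect_error(binarize(rnd, 1.2), "\\(0, 1\\)")
})

test_that("sparsity bound evaluates to 2 ln(N)/N and flags densities", {
  k8 <- binary_network(matrix(1, 8, 8) - diag(8))
  d <- sparsity_bounds(k8, n_rewire = 10)
  expect_equal(d$lower_bound, 2 * log(8) / 8, tolerance = 1e-12)
  expect_equal(d$lower_bound, 0.5199, tolerance = 1e-4)
  expect_equal(d$density, 1)
  expect_true(d$density_ok)

  empty <- binary_network(matrix(0, 8, 8))
  de <- sparsity_bounds(empty, n_rewire = 10)
  expect_false(de$density_ok)
  expect_true(is.na(de$sigma))
})

test_that("a ring lattice with shortcuts is small-world (sigma > 1)", {
  n <- 20
  a <- matrix(0L, n, n)
  for (i in seq_len(n)) for (s in 1:2) {
    j <- ((i - 1 + s) %% n) + 1
    a[i, j] <- a[j, i] <- 1L
  }
  for (p in list(c(1, 10), c(5, 15), c(3, 12))) a[p[1], p[2]] <- a[p[2], p[1]] <- 1L
  net <- binary_network(a)
  d <- sparsity_bounds(net, n_rewire = 100, seed = 3)

  # independent brute force for C and L on this deterministic graph
  deg <- rowSums(a)
  tri <- vapply(seq_len(n), function(i) {
    nbr <- which(a[i, ] > 0)
    sum(a[nbr, nbr]) / 2
  }, 0)
  c_hand <- mean(ifelse(deg < 2, 0, tri / (deg * (deg - 1) / 2)))
  dist <- ifelse(a > 0, 1, Inf); diag(dist) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (dist[i, k] + dist[k, j] < dist[i, j]) dist[i, j] <- dist[i, k] + dist[k, j]
  l_hand <- mean(dist[upper.tri(dist)])
  expect_equal(d$clustering, c_hand, tolerance = 1e-12)
  expect_equal(d$path_length, l_hand, tolerance = 1e-12)
  expect_gt(d$sigma, 1)
  expect_false(d$disconnected)
})

test_that("matrix and edge-list exports round-trip", {
  spec <- tiny_spec(n_per_group = 2, duration = 8)
  seg <- split_segments(generate_subject(spec, "HC", 1), 1)[[1]]
  cm <- connectivity_matrix(seg, "alpha")
  p1 <- withr::local_tempfile(fileext = ".csv")
  write_matrix_csv(cm, p1)
  back <- as.matrix(utils::read.csv(p1, row.names = 1))
  expect_equal(unname(back), unname(cm$values), tolerance = 1e-6)
  net <- binarize(cm, 0.31)
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_edgelist_tsv(net, p2, weights = cm)
  el <- utils::read.delim(p2)
  expect_equal(nrow(el), sum(net$adjacency) / 2)
  expect_true(all(el$weight > 0.31))
})
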