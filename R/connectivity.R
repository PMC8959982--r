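#' Instantaneous phase via complex Morlet wavelet
#'
#' Convolves each channel with a complex Morlet wavelet centered at the
#' band's midpoint frequency (7-cycle width) and returns the argument of the
#' complex coefficient, in (-pi, pi]. One wavelet per band matches the single
#' per-channel phase series entering the PLV.
#'
#' @param seg an `eeg_segment`.
#' @param band band name or [band_def()] row.
#' @param n_cycles wavelet width in cycles (default 7).
#' @return channels x samples matrix of phases.
#' @export
instantaneous_phase <- function(seg, band, n_cycles = 7) {
  band <- resolve_band(band)
  if (seg$fs <= 2 * band$hi)
    stop("band ", band$name, " (hi = ", band$hi,
         " Hz) violates Nyquist at fs = ", seg$fs, " Hz")
  f0 <- band_center(band)
  t(apply(seg$data, 1L, morlet_phase, fs = seg$fs, f0 = f0,
          n_cycles = n_cycles))
}

# Complex Morlet convolution of one channel ("same" alignment via FFT).
morlet_phase <- function(x, fs, f0, n_cycles = 7) {
  sigma_t <- n_cycles / (2 * pi * f0)
  tk <- seq(-4 * sigma_t, 4 * sigma_t, by = 1 / fs)
  kern <- exp(2i * pi * f0 * tk) * exp(-tk^2 / (2 * sigma_t^2))
  n <- length(x); nk <- length(kern)
  m <- stats::nextn(n + nk - 1L)  # pad to a fast FFT length
  conv <- stats::fft(stats::fft(c(x, rep(0, m - n))) *
                     stats::fft(c(kern, rep(0, m - nk))), inverse = TRUE) / m
  half <- (nk - 1L) %/% 2L
  Arg(conv[(half + 1L):(half + n)])
}

#' Phase-locking value of two phase series
#'
#' `PLV = |<exp(i (theta_x - theta_y))>|`: the modulus of the time-averaged
#' unit phasor of the phase difference. 1 means perfect phase locking, 0 no
#' consistent phase relation; symmetric in its arguments and invariant under
#' a common phase shift.
#'
#' @param phase_x,phase_y equal-length numeric phase vectors (radians).
#' @return scalar in `[0, 1]`.
#' @export
plv <- function(phase_x, phase_y) {
  if (length(phase_x) != length(phase_y))
    stop("phase series have different lengths (", length(phase_x), " vs ",
         length(phase_y), ")")
  if (length(phase_x) < 2) stop("need at least 2 phase samples")
  Mod(mean(exp(1i * (phase_x - phase_y))))
}

#' Pairwise PLV connectivity matrix for one band
#'
#' Wavelet phases are computed per channel and `edge_trim` seconds are
#' discarded at each end of the segment before averaging phasors, so wavelet
#' edge effects do not bias the PLV.
#'
#' @param seg an `eeg_segment`.
#' @param band band name or [band_def()] row.
#' @param edge_trim seconds discarded at each end (default 1).
#' @param n_cycles wavelet width in cycles.
#' @return A `connectivity_matrix`: symmetric channels x channels matrix in
#'   `[0, 1]` with unit diagonal, carrying band and provenance tags.
#' @export
connectivity_matrix <- function(seg, band, edge_trim = 1, n_cycles = 7) {
  if (nrow(seg$data) < 2) stop("need >= 2 channels")
  if (!all(is.finite(seg$data))) stop("segment contains non-finite data")
  band <- resolve_band(band)
  ph <- instantaneous_phase(seg, band, n_cycles = n_cycles)
  trim <- round(edge_trim * seg$fs)
  if (ncol(ph) <= 2 * trim + 1)
    stop("segment too short for edge_trim = ", edge_trim, " s")
  if (trim > 0) ph <- ph[, (trim + 1L):(ncol(ph) - trim), drop = FALSE]
  nc <- nrow(ph)
  z <- exp(1i * ph)
  # PLV(i,j) = |mean_t z_i conj(z_j)|, all pairs at once
  m <- (z %*% Conj(t(z))) / ncol(z)
  v <- Mod(m)
  diag(v) <- 1
  v[v > 1] <- 1
  dimnames(v) <- list(rownames(seg$data), rownames(seg$data))
  structure(list(values = v, band = band, subject_id = seg$subject_id,
                 group = seg$group, segment_index = seg$segment_index),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %s band, subject %s segment %s\n",
              x$band$name, x$subject_id, x$segment_index))
  print(round(x$values, 3))
  invisible(x)
}

#' Threshold a connectivity matrix into a binary network
#'
#' Edge `(i, j)` is present iff `PLV(i, j) > threshold` (strictly greater;
#' ties at the threshold are excluded). The diagonal is forced to zero.
#'
#' @param cm a `connectivity_matrix`.
#' @param threshold scalar in (0, 1); default 0.71.
#' @return A `binary_network` with fields `adjacency`, `threshold`, `band`,
#'   `node_labels`.
#' @export
binarize <- function(cm, threshold = 0.71) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  if (!(is.numeric(threshold) && length(threshold) == 1L &&
        threshold > 0 && threshold < 1))
    stop("threshold must lie in the open interval (0, 1); got ", threshold)
  adj <- (cm$values > threshold) * 1L
  diag(adj) <- 0L
  adj <- pmax(adj, t(adj))  # values are symmetric; keep adjacency exactly so
  structure(list(adjacency = adj, threshold = threshold, band = cm$band,
                 node_labels = rownames(cm$values),
                 subject_id = cm$subject_id, group = cm$group,
                 segment_index = cm$segment_index),
            class = "binary_network")
}

#' Construct a binary network directly from an adjacency matrix
#'
#' Mainly for simulation and testing of the graph-metric layer.
#'
#' @param adjacency symmetric 0/1 matrix with zero diagonal.
#' @param node_labels optional labels (default V1..Vn).
#' @param band optional band tag.
#' @param threshold threshold tag carried for provenance.
#' @return A `binary_network`.
#' @export
binary_network <- function(adjacency, node_labels = NULL, band = NULL,
                           threshold = NA_real_) {
  adjacency <- as.matrix(adjacency)
  if (!isTRUE(all.equal(adjacency, t(adjacency))))
    stop("adjacency must be symmetric")
  if (any(diag(adjacency) != 0)) stop("adjacency diagonal must be zero")
  if (!all(adjacency %in% c(0, 1))) stop("adjacency entries must be 0/1")
  if (is.null(node_labels))
    node_labels <- if (!is.null(rownames(adjacency))) rownames(adjacency)
      else paste0("V", seq_len(nrow(adjacency)))
  dimnames(adjacency) <- list(node_labels, node_labels)
  structure(list(adjacency = adjacency, threshold = threshold, band = band,
                 node_labels = node_labels, subject_id = NA_character_,
                 group = NA_character_, segment_index = NA_integer_),
            class = "binary_network")
}

#' @export
print.binary_network <- function(x, ...) {
  cat(sprintf("<binary_network> %d nodes, %d edges (threshold %s%s)\n",
              nrow(x$adjacency), sum(x$adjacency) / 2,
              format(x$threshold),
              if (is.null(x$band)) "" else paste0(", ", x$band$name, " band")))
  invisible(x)
}

#' Sparsity and small-world diagnostics for a binary network
#'
#' Reports the edge density against the random-graph full-connectivity lower
#' bound `2 ln(N) / N`, and the small-world coefficient
#' `sigma = (C / C_rand) / (L / L_rand)` against degree-preserving rewired
#' null graphs. For a sensible binary brain network the density should not
#' fall below the bound and sigma should exceed 1.
#'
#' @param net a `binary_network` with `N >= 3` nodes.
#' @param n_rewire number of rewired null graphs (default 100).
#' @param seed RNG seed for the rewiring null.
#' @return list with `n_nodes`, `density`, `lower_bound`, `density_ok`,
#'   `sigma`, `sigma_ok`, `clustering`, `path_length`, `disconnected`
#'   (TRUE when sigma was computed on the largest connected component).
#' @export
sparsity_bounds <- function(net, n_rewire = 100, seed = 1) {
  stopifnot(inherits(net, "binary_network"))
  a <- net$adjacency
  n <- nrow(a)
  if (n < 3) stop("need N >= 3 nodes")
  m <- sum(a) / 2
  density <- m / (n * (n - 1) / 2)
  bound <- 2 * log(n) / n
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
  comp <- igraph::components(g)
  disconnected <- comp$no > 1
  if (disconnected) {
    keep <- which(comp$membership == which.max(comp$csize))
    g <- igraph::induced_subgraph(g, keep)
  }
  sigma <- NA_real_
  cc <- NA_real_; pl <- NA_real_
  if (igraph::gorder(g) >= 3 && igraph::gsize(g) >= 2) {
    cc <- mean(igraph::transitivity(g, type = "localundirected", isolates = "zero"))
    pl <- igraph::mean_distance(g, directed = FALSE)
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    nulls <- vapply(seq_len(n_rewire), function(k) {
      gr <- igraph::rewire(g, igraph::keeping_degseq(niter = 10 * igraph::gsize(g)))
      c(mean(igraph::transitivity(gr, type = "localundirected",
                                  isolates = "zero")),
        igraph::mean_distance(gr, directed = FALSE))
    }, c(0, 0))
    c_rand <- mean(nulls[1, ]); l_rand <- mean(nulls[2, ])
    if (is.finite(c_rand) && c_rand > 0 && is.finite(l_rand) && l_rand > 0 &&
        pl > 0)
      sigma <- (cc / c_rand) / (pl / l_rand)
  }
  list(n_nodes = n, density = density, lower_bound = bound,
       density_ok = density >= bound, sigma = sigma,
       sigma_ok = is.finite(sigma) && sigma > 1,
       clustering = cc, path_length = pl, disconnected = disconnected)
}

#' Write a connectivity matrix (or adjacency) as square CSV
#' @param x a `connectivity_matrix` or `binary_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(x, path) {
  m <- if (inherits(x, "connectivity_matrix")) x$values else x$adjacency
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}

#' Write a binary network as an edge-list TSV (node_i, node_j, weight)
#' @param net a `binary_network`.
#' @param path output path.
#' @param weights optional `connectivity_matrix` supplying edge weights;
#'   defaults to 1.
#' @return `path`, invisibly.
#' @export
write_edgelist_tsv <- function(net, path, weights = NULL) {
  a <- net$adjacency
  idx <- which(upper.tri(a) & a > 0, arr.ind = TRUE)
  w <- if (is.null(weights)) rep(1, nrow(idx)) else weights$values[idx]
  df <- data.frame(node_i = net$node_labels[idx[, 1]],
                   node_j = net$node_labels[idx[, 2]], weight = w)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
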