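#' Node degree
#' @param net a `binary_network`.
#' @return named integer vector: number of edges at each node.
#' @export
node_degree <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  stats::setNames(as.integer(rowSums(net$adjacency)), net$node_labels)
}

#' Local clustering coefficient
#'
#' Closed triangles at node `i` divided by `d_i (d_i - 1) / 2`, the number of
#' possible neighbour pairs; defined as 0 for nodes with degree < 2.
#'
#' @param net a `binary_network`.
#' @return named numeric vector in `[0, 1]`.
#' @export
node_clustering <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  a <- net$adjacency
  d <- rowSums(a)
  tri <- diag(a %*% a %*% a) / 2          # closed triangles at each node
  poss <- d * (d - 1) / 2
  out <- ifelse(d < 2, 0, tri / pmax(poss, 1))
  stats::setNames(as.numeric(out), net$node_labels)
}

#' Local efficiency
#'
#' For node `i`, the mean of `1 / l_{j,k}` over ordered pairs of `i`'s
#' neighbours, with shortest paths `l_{j,k}` computed within the subgraph
#' induced by those neighbours; disconnected pairs contribute 0, and nodes
#' with fewer than 2 neighbours score 0. A fault-tolerance proxy: how well
#' `i`'s neighbourhood communicates when `i` is removed.
#'
#' @param net a `binary_network`.
#' @return named numeric vector in `[0, 1]`.
#' @export
node_local_efficiency <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  a <- net$adjacency
  n <- nrow(a)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nbr <- which(a[i, ] > 0)
    k <- length(nbr)
    if (k < 2) next
    sub <- a[nbr, nbr, drop = FALSE]
    g <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected")
    dm <- igraph::distances(g)
    inv <- 1 / dm
    diag(inv) <- 0
    inv[!is.finite(inv)] <- 0
    out[i] <- sum(inv) / (k * (k - 1))
  }
  stats::setNames(out, net$node_labels)
}

#' Connectivity robustness
#'
#' `R_i = d_avg / (N - 1)` where `d_avg` is the mean degree of the graph
#' after deleting node `i` (degrees counted within the reduced graph) and
#' `N` is the original node count: how much connectivity the network retains
#' when node `i` is attacked.
#'
#' @param net a `binary_network` with `N >= 2`.
#' @return named numeric vector in `[0, 1]`.
#' @export
node_robustness <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  a <- net$adjacency
  n <- nrow(a)
  if (n < 2) stop("need N >= 2 nodes")
  out <- vapply(seq_len(n), function(i) {
    sub <- a[-i, -i, drop = FALSE]
    mean(rowSums(sub)) / (n - 1)
  }, 0)
  stats::setNames(out, net$node_labels)
}

#' All four node metrics of one network
#'
#' @param net a `binary_network`.
#' @param provenance label recorded in the result (defaults to the band name).
#' @return A `node_metric_set`: data.frame with columns `node`, `degree`,
#'   `clustering`, `efficiency`, `robustness` and a `provenance` attribute.
#' @export
node_metrics <- function(net, provenance = NULL) {
  if (is.null(provenance))
    provenance <- if (!is.null(net$band)) net$band$name else "network"
  out <- data.frame(
    node = net$node_labels,
    degree = as.numeric(node_degree(net)),
    clustering = node_clustering(net),
    efficiency = node_local_efficiency(net),
    robustness = node_robustness(net),
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "provenance") <- provenance
  class(out) <- c("node_metric_set", "data.frame")
  out
}

#' Multilayer aggregation of node metrics
#'
#' Plain multilayer attributes are the node-wise sums of each metric across
#' band layers; the improved multilayer network weights layer `a` by that
#' sample's power-spectral ratio of band `a`, so the weights form a convex
#' combination per sample.
#'
#' @param layers list of `node_metric_set` objects sharing node labels.
#' @param weights optional numeric vector, one weight per layer (the
#'   power-spectral ratios for the improved multilayer network); `NULL`
#'   means unit weights (plain multilayer).
#' @param provenance label for the result (default "MN" or "IMN").
#' @return A `node_metric_set` of the aggregated metrics.
#' @export
multilayer_metrics <- function(layers, weights = NULL, provenance = NULL) {
  stopifnot(length(layers) >= 1)
  nodes <- layers[[1]]$node
  for (l in layers)
    if (!identical(l$node, nodes))
      stop("layers have mismatched node labels")
  if (is.null(weights)) {
    weights <- rep(1, length(layers))
    if (is.null(provenance)) provenance <- "MN"
  } else {
    if (length(weights) != length(layers))
      stop("got ", length(weights), " weights for ", length(layers), " layers")
    if (is.null(provenance)) provenance <- "IMN"
  }
  cols <- c("degree", "clustering", "efficiency", "robustness")
  acc <- matrix(0, length(nodes), length(cols), dimnames = list(NULL, cols))
  for (k in seq_along(layers))
    acc <- acc + weights[k] * as.matrix(layers[[k]][, cols])
  out <- data.frame(node = nodes, acc, stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "provenance") <- provenance
  attr(out, "weights") <- weights
  class(out) <- c("node_metric_set", "data.frame")
  out
}

#' Brute-force metric oracle (testing only)
#'
#' Recomputes all four node metrics by exhaustive enumeration: triangle
#' counting by looping over neighbour pairs, Floyd--Warshall all-pairs
#' shortest paths for local efficiency, and explicit node deletion for
#' robustness. Deliberately naive and refused for `N > 12`.
#'
#' @param net a `binary_network` with at most 12 nodes.
#' @return A `node_metric_set`.
#' @export
metric_oracle <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  a <- net$adjacency
  n <- nrow(a)
  if (n > 12) stop("metric_oracle is restricted to N <= 12 nodes")
  deg <- integer(n)
  for (i in seq_len(n)) for (j in seq_len(n)) deg[i] <- deg[i] + (a[i, j] > 0)

  clus <- numeric(n)
  for (i in seq_len(n)) {
    nbr <- which(a[i, ] > 0)
    if (length(nbr) < 2) next
    tri <- 0
    for (x in nbr) for (y in nbr) if (x < y && a[x, y] > 0) tri <- tri + 1
    clus[i] <- tri / (length(nbr) * (length(nbr) - 1) / 2)
  }

  floyd <- function(m) {
    nn <- nrow(m)
    d <- matrix(Inf, nn, nn)
    d[m > 0] <- 1
    diag(d) <- 0
    for (k in seq_len(nn)) for (i in seq_len(nn)) for (j in seq_len(nn))
      if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
    d
  }
  eff <- numeric(n)
  for (i in seq_len(n)) {
    nbr <- which(a[i, ] > 0)
    k <- length(nbr)
    if (k < 2) next
    d <- floyd(a[nbr, nbr, drop = FALSE])
    s <- 0
    for (x in seq_len(k)) for (y in seq_len(k))
      if (x != y && is.finite(d[x, y])) s <- s + 1 / d[x, y]
    eff[i] <- s / (k * (k - 1))
  }

  rob <- numeric(n)
  for (i in seq_len(n)) {
    sub <- a[-i, -i, drop = FALSE]
    degs <- numeric(nrow(sub))
    for (x in seq_len(nrow(sub))) for (y in seq_len(ncol(sub)))
      degs[x] <- degs[x] + (sub[x, y] > 0)
    rob[i] <- mean(degs) / (n - 1)
  }

  out <- data.frame(node = net$node_labels, degree = as.numeric(deg),
                    clustering = clus, efficiency = eff, robustness = rob,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "provenance") <- "oracle"
  class(out) <- c("node_metric_set", "data.frame")
  out
}
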