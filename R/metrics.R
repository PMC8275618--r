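#' Newman-Girvan modularity of a partition
#'
#' `Q = sum_i (e_ii - a_i^2)` over communities, where `e_ii` is the fraction
#' of edges inside community `i` and `a_i` the fraction of edge endpoints in
#' `i`; unweighted, undirected.
#'
#' @param graph Simple undirected graph with at least one edge.
#' @param partition Partition tibble (`unit_id`, `community`), named vector,
#'   or plain membership vector in vertex order.
#' @return Modularity in `(-1, 1]`.
#' @export
modularity_q <- function(graph, partition) {
  gd <- graph_data(graph)
  q_memb(align_membership(partition, gd), gd)
}

# Align two partitions into a pair of integer label vectors over common units.
pair_memberships <- function(labels_a, labels_b) {
  if (is.data.frame(labels_a) && is.data.frame(labels_b)) {
    joined <- dplyr::inner_join(
      dplyr::select(labels_a, "unit_id", a = "community"),
      dplyr::select(labels_b, "unit_id", b = "community"),
      by = "unit_id")
    if (nrow(joined) != nrow(labels_a) || nrow(joined) != nrow(labels_b)) {
      abort("partitions cover different unit sets")
    }
    list(a = as.integer(joined$a), b = as.integer(joined$b))
  } else {
    a <- if (is.data.frame(labels_a)) labels_a$community else labels_a
    b <- if (is.data.frame(labels_b)) labels_b$community else labels_b
    if (length(a) != length(b)) abort("partitions must have equal length")
    list(a = as.integer(as.factor(a)), b = as.integer(as.factor(b)))
  }
}

#' Normalized mutual information between two partitions
#'
#' Mutual information of the label contingency table, normalized by default by
#' the arithmetic mean of the two label entropies (`variant = "mean"`); the
#' max-entropy normalization is available with `variant = "max"`. Symmetric
#' and invariant to label permutation. When one partition has zero entropy the
#' value is 1 if both partitions are the identical single-block partition and
#' 0 otherwise.
#'
#' @param labels_a,labels_b Partitions (tibbles with `unit_id`/`community`, or
#'   label vectors of equal length).
#' @param variant Normalization: `"mean"` (default) or `"max"`.
#' @return NMI in `[0, 1]`.
#' @export
nmi <- function(labels_a, labels_b, variant = c("mean", "max")) {
  variant <- match.arg(variant)
  p <- pair_memberships(labels_a, labels_b)
  n <- length(p$a)
  tab <- table(p$a, p$b)
  pij <- tab / n
  pi_ <- rowSums(pij)
  p_j <- colSums(pij)
  h_a <- -sum(pi_[pi_ > 0] * log(pi_[pi_ > 0]))
  h_b <- -sum(p_j[p_j > 0] * log(p_j[p_j > 0]))
  if (h_a == 0 || h_b == 0) {
    same <- length(unique(p$a)) == 1 && length(unique(p$b)) == 1
    return(if (same) 1 else 0)
  }
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer(pi_, p_j)[nz]))
  denom <- switch(variant, mean = (h_a + h_b) / 2, max = max(h_a, h_b))
  mi / denom
}

#' Adjusted Rand index between two partitions
#'
#' Pair-counting agreement with expected-index correction:
#' `ARI = (Index - E[Index]) / (MaxIndex - E[Index])`.
#'
#' @inheritParams nmi
#' @return ARI in `[-1, 1]`; 1 for identical partitions.
#' @export
ari <- function(labels_a, labels_b) {
  p <- pair_memberships(labels_a, labels_b)
  tab <- table(p$a, p$b)
  n <- length(p$a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  total <- comb2(n)
  expected <- sum_a * sum_b / total
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)   # both trivial partitions
  (sum_ij - expected) / (max_index - expected)
}

#' Degree distribution of a unit network
#'
#' @param graph An igraph object (isolated nodes allowed).
#' @return A tibble `degree`, `n_nodes`; counts sum to the node count.
#' @export
degree_distribution_tbl <- function(graph) {
  deg <- igraph::degree(graph)
  tibble::tibble(degree = as.integer(names(table(deg))),
                 n_nodes = as.integer(table(deg))) |>
    dplyr::arrange(.data$degree)
}

#' Per-node centrality table
#'
#' Degree centrality is reported as the raw degree (with the normalized
#' variant alongside); betweenness is non-normalized shortest-path vertex
#' betweenness with fractional counting over tied shortest paths, each
#' unordered pair counted once.
#'
#' @param graph An igraph object.
#' @return A tibble `unit_id`, `degree`, `degree_centrality_norm`,
#'   `betweenness`, sorted by decreasing degree.
#' @export
node_centrality <- function(graph) {
  n <- igraph::vcount(graph)
  deg <- igraph::degree(graph)
  btw <- igraph::betweenness(graph, directed = FALSE, normalized = FALSE)
  tibble::tibble(
    unit_id = igraph::V(graph)$name %||% as.character(seq_len(n)),
    degree = as.integer(deg),
    degree_centrality_norm = deg / (n - 1),
    betweenness = as.numeric(btw)
  ) |>
    dplyr::arrange(dplyr::desc(.data$degree), .data$unit_id)
}

#' Per-edge betweenness table
#'
#' Non-normalized shortest-path edge betweenness with fractional counting over
#' ties.
#'
#' @param graph An igraph object.
#' @return A tibble `from`, `to`, `betweenness`, sorted by decreasing value.
#' @export
edge_betweenness_tbl <- function(graph) {
  eb <- igraph::edge_betweenness(graph, directed = FALSE)
  el <- igraph::as_edgelist(graph)
  tibble::tibble(from = pmin(el[, 1], el[, 2]), to = pmax(el[, 1], el[, 2]),
                 betweenness = as.numeric(eb)) |>
    dplyr::arrange(dplyr::desc(.data$betweenness), .data$from, .data$to)
}

#' Full metric report for a graph and partition
#'
#' Bundles the scalar partition-quality metrics (modularity and, when a
#' reference partition is supplied, NMI and ARI against it) with the per-node
#' centrality table.
#'
#' @param graph The unit network.
#' @param partition Partition to score.
#' @param reference Optional reference partition (e.g. growth groups) for
#'   NMI/ARI.
#' @return A list of class `qicd_metrics`: `scalars` (one-row tibble) and
#'   `nodes` (per-node tibble).
#' @export
metric_report <- function(graph, partition, reference = NULL) {
  gd <- graph_data(graph)
  scalars <- tibble::tibble(
    dataset = gd$graph_name,
    q = modularity_q(graph, partition),
    nmi = if (!is.null(reference)) nmi(partition, reference) else NA_real_,
    ari = if (!is.null(reference)) ari(partition, reference) else NA_real_
  )
  structure(list(scalars = scalars, nodes = node_centrality(graph)),
            class = "qicd_metrics")
}
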