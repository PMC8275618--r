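#' Girvan-Newman divisive community detection (native implementation)
#'
#' Repeatedly removes the edge of maximum edge betweenness (recomputed after
#' every removal; ties broken by the lexicographically smallest edge id) and
#' records the partition into connected components together with its
#' modularity on the original graph after each removal. The returned partition
#' is the global modularity maximum along this dendrogram; if `target_k` is
#' given, the first partition reaching that many communities is also reported.
#'
#' @param graph Simple undirected graph with at least one edge.
#' @param target_k Optional community count at which to also cut the
#'   dendrogram (e.g. 4 to reproduce a fixed-size subgroup discovery).
#' @return An object of class `qicd_gn`: `partition` (max-Q cut), `modularity`,
#'   `dendrogram` (tibble: step, removed_from, removed_to, n_communities, q)
#'   and, when requested, `partition_at_k` / `modularity_at_k`.
#' @export
girvan_newman <- function(graph, target_k = NULL) {
  gd <- graph_data(graph)
  work <- graph
  memb <- canonical_membership(igraph::components(work)$membership)
  q0 <- q_memb(memb, gd)
  steps <- list(tibble::tibble(step = 0L, removed_from = NA_character_,
                               removed_to = NA_character_,
                               n_communities = max(memb), q = q0))
  best_q <- q0
  best_memb <- memb
  at_k <- NULL
  q_at_k <- NA_real_
  if (!is.null(target_k) && max(memb) >= target_k) {
    at_k <- memb
    q_at_k <- q0
  }
  step <- 0L
  while (igraph::ecount(work) > 0L) {
    step <- step + 1L
    eb <- igraph::edge_betweenness(work, directed = FALSE)
    el <- igraph::as_edgelist(work)
    # lexicographic edge id: endpoints sorted within the edge
    ids <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), sep = "|")
    cand <- which(eb >= max(eb) - 1e-12)
    pick <- cand[order(ids[cand])][1]
    removed <- sort(c(el[pick, 1], el[pick, 2]))
    work <- igraph::delete_edges(work, pick)
    comp <- igraph::components(work)$membership
    memb <- canonical_membership(comp[match(gd$names, igraph::V(work)$name)])
    q <- q_memb(memb, gd)
    steps[[step + 1L]] <- tibble::tibble(step = step, removed_from = removed[1],
                                         removed_to = removed[2],
                                         n_communities = max(memb), q = q)
    if (q > best_q) {
      best_q <- q
      best_memb <- memb
    }
    if (!is.null(target_k) && is.null(at_k) && max(memb) >= target_k) {
      at_k <- memb
      q_at_k <- q
    }
  }
  out <- list(
    algorithm = "girvan_newman",
    graph_name = gd$graph_name,
    partition = partition_tbl(gd$names, best_memb),
    modularity = best_q,
    n_communities = max(best_memb),
    dendrogram = purrr::list_rbind(steps)
  )
  if (!is.null(target_k)) {
    out$partition_at_k <- if (!is.null(at_k)) partition_tbl(gd$names, at_k) else NULL
    out$modularity_at_k <- q_at_k
  }
  structure(out, class = "qicd_gn")
}

#' @export
print.qicd_gn <- function(x, ...) {
  cat(sprintf("<qicd_gn> Girvan-Newman on '%s': %d communities at max Q = %.4f\n",
              x$graph_name, x$n_communities, x$modularity))
  invisible(x)
}

#' Tidy the Girvan-Newman dendrogram
#'
#' @param x A `qicd_gn` object.
#' @param ... Unused.
#' @return The removal-by-removal dendrogram tibble.
#' @method tidy qicd_gn
#' @export
tidy.qicd_gn <- function(x, ...) x$dendrogram

#' One-row summary of a Girvan-Newman fit
#'
#' @param x A `qicd_gn` object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance qicd_gn
#' @export
glance.qicd_gn <- function(x, ...) {
  tibble::tibble(algorithm = "girvan_newman", graph = x$graph_name,
                 modularity = x$modularity, n_communities = x$n_communities)
}

#' Run the standard community-detection comparison suite
#'
#' Runs six standard algorithms — label propagation, Louvain, fast greedy
#' (CNM), leading eigenvector, walktrap, and fast Girvan-Newman (edge
#' betweenness) — delegating to igraph, plus this package's native
#' Girvan-Newman, and reports every partition's modularity as computed by
#' [modularity_q()] (this package's own implementation, for comparability).
#' A backend that fails on the given graph is skipped with a warning, never
#' silently.
#'
#' @param graph The unit network.
#' @param seed Seed for the stochastic baselines (label propagation, walktrap).
#' @return A tibble: `dataset`, `algorithm`, `q`, `n_communities`.
#' @export
run_standard_suite <- function(graph, seed = 1L) {
  gd <- graph_data(graph)
  backends <- list(
    lprop = function(g) igraph::cluster_label_prop(g),
    louvain = function(g) igraph::cluster_louvain(g),
    cnm = function(g) igraph::cluster_fast_greedy(g),
    n_eigen = function(g) igraph::cluster_leading_eigen(g),
    walktrap = function(g) igraph::cluster_walktrap(g),
    gn_fast = function(g) igraph::cluster_edge_betweenness(g)
  )
  rows <- purrr::imap(backends, function(fn, name) {
    set.seed(seed)
    res <- tryCatch(fn(graph), error = function(e) {
      warn(sprintf("baseline '%s' unavailable on this graph: %s", name,
                   conditionMessage(e)))
      NULL
    })
    if (is.null(res)) return(NULL)
    memb <- canonical_membership(igraph::membership(res))
    tibble::tibble(dataset = gd$graph_name, algorithm = name,
                   q = q_memb(memb, gd), n_communities = max(memb))
  })
  gn <- girvan_newman(graph)
  rows$girvan_newman <- tibble::tibble(dataset = gd$graph_name,
                                       algorithm = "girvan_newman",
                                       q = gn$modularity,
                                       n_communities = gn$n_communities)
  purrr::list_rbind(purrr::compact(rows))
}
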