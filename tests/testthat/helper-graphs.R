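# Small named graphs used across the suite.

named_graph <- function(edges, nodes = NULL, name = "test") {
  tbl <- tibble::tibble(from = edges[c(TRUE, FALSE)], to = edges[c(FALSE, TRUE)])
  nodes <- nodes %||% sort(unique(c(tbl$from, tbl$to)))
  g <- igraph::graph_from_data_frame(tbl, directed = FALSE, vertices = nodes)
  igraph::graph_attr(g, "name") <- name
  g
}

# Two triangles {A,B,C} and {D,E,F} joined by the bridge C-D (7 edges).
two_triangles_bridge <- function() {
  named_graph(c("A","B", "A","C", "B","C", "C","D", "D","E", "D","F", "E","F"),
              name = "two_triangles")
}

# k cliques of the given sizes, consecutive cliques joined by one bridge edge.
planted_cliques <- function(sizes, bridges = TRUE) {
  labels <- rep(seq_along(sizes), times = sizes)
  ids <- sprintf("n%02d", seq_len(sum(sizes)))
  edges <- character(0)
  offset <- 0L
  for (s in sizes) {
    members <- ids[(offset + 1):(offset + s)]
    if (s >= 2) {
      idx <- utils::combn(s, 2)
      edges <- c(edges, rbind(members[idx[1, ]], members[idx[2, ]]))
    }
    offset <- offset + s
  }
  if (bridges && length(sizes) > 1) {
    starts <- cumsum(c(1, head(sizes, -1)))
    for (i in seq_len(length(sizes) - 1)) {
      edges <- c(edges, ids[starts[i]], ids[starts[i + 1]])
    }
  }
  g <- named_graph(edges, nodes = ids, name = "planted")
  list(graph = g,
       truth = tibble::tibble(unit_id = ids, community = labels))
}

# Random connected-ish small graph with reproducible structure.
random_small_graph <- function(n, p = 0.5, seed = 1) {
  set.seed(seed)
  repeat {
    A <- matrix(runif(n * n) < p, n, n)
    A[lower.tri(A, diag = TRUE)] <- FALSE
    el <- which(A, arr.ind = TRUE)
    if (nrow(el) >= 1) break
  }
  ids <- LETTERS[seq_len(n)]
  named_graph(as.vector(t(cbind(ids[el[, 1]], ids[el[, 2]]))),
              nodes = ids, name = "random")
}

# Distinct reproducible seeds for repeated-run tests.
derive_seed_for_test <- function(r) 1000L + 17L * r
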