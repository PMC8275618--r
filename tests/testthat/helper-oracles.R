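# Independent oracles: brute-force / closed-form references computed without
# the package's own code paths.

# All set partitions of n elements as restricted-growth strings.
all_partitions <- function(n) {
  out <- list()
  recurse <- function(prefix, k) {
    i <- length(prefix) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible(NULL))
    }
    for (lab in seq_len(k + 1L)) {
      recurse(c(prefix, lab), max(k, lab))
    }
  }
  recurse(integer(0), 0L)
  out
}

# Direct-summation modularity: Q = (1/2m) sum_ij (A_ij - k_i k_j / 2m) d(c_i,c_j).
q_direct <- function(graph, memb) {
  A <- as.matrix(igraph::as_adjacency_matrix(graph))
  k <- rowSums(A)
  m <- sum(A) / 2
  same <- outer(memb, memb, "==")
  sum((A - outer(k, k) / (2 * m)) * same) / (2 * m)
}

# Exhaustive maximum-modularity partition of a small graph.
max_modularity_exhaustive <- function(graph) {
  parts <- all_partitions(igraph::vcount(graph))
  qs <- vapply(parts, function(p) q_direct(graph, p), numeric(1))
  list(q = max(qs), partition = parts[[which.max(qs)]])
}

# Brute-force betweenness by explicit enumeration of all shortest paths,
# fractional counting over ties, each unordered pair counted once.
brute_betweenness <- function(graph) {
  n <- igraph::vcount(graph)
  A <- as.matrix(igraph::as_adjacency_matrix(graph))
  nbs <- lapply(seq_len(n), function(i) which(A[i, ] > 0))
  bfs_dist <- function(s) {
    d <- rep(Inf, n)
    d[s] <- 0
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) {
        for (w in nbs[[v]]) {
          if (is.infinite(d[w])) {
            d[w] <- d[v] + 1
            nxt <- c(nxt, w)
          }
        }
      }
      frontier <- unique(nxt)
    }
    d
  }
  enumerate_paths <- function(s, t, d) {
    # all shortest s->t paths, walking backwards along distance levels
    paths <- list()
    walk <- function(path) {
      v <- path[length(path)]
      if (v == t) {
        paths[[length(paths) + 1L]] <<- path
        return(invisible(NULL))
      }
      for (w in nbs[[v]]) {
        if (d[w] == d[v] + 1 && d[w] <= d[t]) walk(c(path, w))
      }
    }
    walk(s)
    paths
  }
  vb <- setNames(rep(0, n), igraph::V(graph)$name)
  eb <- list()
  ekey <- function(a, b) paste(sort(c(a, b)), collapse = "|")
  for (s in seq_len(n - 1)) {
    d <- bfs_dist(s)
    for (t in (s + 1):n) {
      if (is.infinite(d[t])) next
      paths <- enumerate_paths(s, t, d)
      np <- length(paths)
      for (p in paths) {
        if (length(p) > 2) {
          for (v in p[-c(1, length(p))]) vb[v] <- vb[v] + 1 / np
        }
        for (i in seq_len(length(p) - 1)) {
          key <- ekey(igraph::V(graph)$name[p[i]], igraph::V(graph)$name[p[i + 1]])
          eb[[key]] <- (eb[[key]] %||% 0) + 1 / np
        }
      }
    }
  }
  list(vertex = vb, edge = unlist(eb))
}

# Closed-form Pearson correlation from the sum formulas.
pearson_closed_form <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# Two-tailed correlation p-value by numerical integration of the t-density.
p_value_by_integration <- function(r, n) {
  df <- n - 2
  t_stat <- abs(r) * sqrt(df) / sqrt(1 - r^2)
  dens <- function(x) {
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  }
  2 * stats::integrate(dens, t_stat, Inf, rel.tol = 1e-10)$value
}
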