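# Internal helpers shared across modules.

# Deterministic per-run seed derivation: a master seed and a counter give a
# reproducible stream of seeds below 2^31, so sweeps are replayable run by run.
derive_seed <- function(master, counter) {
  as.integer((as.double(master) %% 2147483647) * 100003 %% 2147483647 +
               as.double(counter) * 7919) %% 2147483629L
}

# Split n items into g groups as evenly as possible (first groups get the extra).
split_sizes <- function(n, g) {
  sizes <- rep(n %/% g, g)
  extra <- n %% g
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  as.integer(sizes)
}

# Relabel an integer membership vector to contiguous ids 1..k in order of first
# appearance (the lexicographically smallest equivalent labeling).
canonical_membership <- function(memb) {
  as.integer(match(memb, unique(memb)))
}

# Extract the flat data all detection algorithms consume from an igraph object.
graph_data <- function(graph) {
  stopifnot(igraph::is_igraph(graph))
  n <- igraph::vcount(graph)
  m <- igraph::ecount(graph)
  if (n < 2L || m < 1L) {
    abort("graph must have at least 2 nodes and 1 edge (modularity is undefined otherwise)",
          class = "qicd_degenerate_graph")
  }
  el <- igraph::as_edgelist(graph, names = FALSE)
  nms <- igraph::V(graph)$name %||% as.character(seq_len(n))
  nb <- lapply(igraph::as_adj_list(graph, mode = "all"), as.integer)
  list(
    n = n, m = m,
    ea = as.integer(el[, 1]), eb = as.integer(el[, 2]),
    deg = as.integer(igraph::degree(graph)),
    nb = nb,
    names = nms,
    graph_name = igraph::graph_attr(graph, "name") %||% "graph"
  )
}

# Fast Newman-Girvan modularity of a membership vector against precomputed
# graph data: Q = (internal edges)/m - sum_c (d_c / 2m)^2.
q_memb <- function(memb, gd) {
  k <- max(memb)
  internal <- sum(memb[gd$ea] == memb[gd$eb])
  d_c <- tabulate(rep.int(memb, gd$deg), nbins = k)
  internal / gd$m - sum((d_c / (2 * gd$m))^2)
}

# Align a partition (tibble with unit_id/community, or a named/plain vector)
# to the vertex order of precomputed graph data; returns an integer membership.
align_membership <- function(partition, gd) {
  if (is.data.frame(partition)) {
    if (!all(c("unit_id", "community") %in% names(partition))) {
      abort("partition data frame must have columns 'unit_id' and 'community'")
    }
    idx <- match(gd$names, partition$unit_id)
    if (anyNA(idx)) {
      abort(paste0("partition is missing units: ",
                   paste(gd$names[is.na(idx)], collapse = ", ")))
    }
    memb <- as.integer(partition$community[idx])
  } else if (!is.null(names(partition))) {
    idx <- match(gd$names, names(partition))
    if (anyNA(idx)) abort("named partition vector is missing some graph vertices")
    memb <- as.integer(partition[idx])
  } else {
    if (length(partition) != gd$n) {
      abort("unnamed partition vector must have one entry per graph vertex")
    }
    memb <- as.integer(partition)
  }
  if (anyNA(memb)) abort("partition contains missing community ids")
  canonical_membership(memb)
}

# Partition tibble from unit names + membership vector.
partition_tbl <- function(unit_ids, memb) {
  tibble::tibble(unit_id = unit_ids, community = canonical_membership(memb))
}

# Connected components of the locus graph {i -- to[i]} via union-find.
locus_components <- function(to) {
  n <- length(to)
  parent <- seq_len(n)
  find_root <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (i in seq_len(n)) {
    if (is.na(to[i]) || to[i] == i) next
    ra <- find_root(i)
    rb <- find_root(to[i])
    if (ra != rb) parent[ra] <- rb
  }
  roots <- vapply(seq_len(n), find_root, integer(1))
  canonical_membership(roots)
}

# Greedy single-node relabeling refinement: repeatedly move nodes to the
# neighboring community that most increases Q, until a full pass finds nothing.
refine_greedy <- function(memb, gd, max_passes = 50L) {
  best_q <- q_memb(memb, gd)
  for (pass in seq_len(max_passes)) {
    moved <- FALSE
    for (v in seq_len(gd$n)) {
      cands <- unique(c(memb[gd$nb[[v]]], memb[v]))
      cands <- cands[cands != memb[v]]
      if (!length(cands)) next
      for (lab in cands) {
        trial <- memb
        trial[v] <- lab
        qt <- q_memb(canonical_membership(trial), gd)
        if (qt > best_q + 1e-12) {
          memb <- canonical_membership(trial)
          best_q <- qt
          moved <- TRUE
        }
      }
    }
    if (!moved) break
  }
  list(membership = canonical_membership(memb), q = best_q)
}

# Stable hash of an R object for provenance headers (rlang's xxHash).
config_hash <- function(x) rlang::hash(x)
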