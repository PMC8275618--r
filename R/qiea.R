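# Binary and real-coded quantum-inspired evolutionary community detection.

# One QIEA bipartition of the node set `nodes` inside the fixed global
# membership `memb`. A population of qubit chromosomes (one gene per node,
# alpha2^2 = probability of siding with the new community) is collapsed,
# evaluated on *global* modularity, and rotated toward the best observation;
# each gene re-initializes to the balanced superposition with probability mu.
# Returns the best 0/1 split vector observed.
binqiea_bipartition <- function(nodes, gd, memb, config) {
  k <- length(nodes)
  newlab <- max(memb) + 1L
  pop <- config$population_size
  a2sq <- matrix(0.5, nrow = k, ncol = pop)   # P(collapse to 1) per gene
  fitness_of <- function(bits) {
    cand <- memb
    cand[nodes[bits == 1L]] <- newlab
    q_memb(cand, gd)
  }
  best_bits <- NULL
  best_fit <- -Inf
  stale <- 0L
  for (gen in seq_len(config$generations)) {
    bits <- matrix(as.integer(matrix(runif(k * pop), k, pop) < a2sq), k, pop)
    fits <- vapply(seq_len(pop), function(j) fitness_of(bits[, j]), numeric(1))
    gen_best <- which.max(fits)
    if (fits[gen_best] > best_fit) {
      best_fit <- fits[gen_best]
      best_bits <- bits[, gen_best]
      stale <- 0L
    } else {
      stale <- stale + 1L
    }
    # rotate every chromosome toward the best-so-far observation
    for (j in seq_len(pop)) {
      differ <- bits[, j] != best_bits
      if (any(differ)) {
        t_cur <- asin(sqrt(pmin(1, a2sq[differ, j])))
        toward_best <- fits[j] <= best_fit   # best dominates: pull toward it
        if (toward_best) {
          delta <- ifelse(best_bits[differ] == 1L, config$theta1, -config$theta1)
        } else {
          delta <- ifelse(bits[differ, j] == 1L, config$theta2, -config$theta2)
        }
        t_new <- pmin(pi / 2, pmax(0, t_cur + delta))
        a2sq[differ, j] <- sin(t_new)^2
      }
    }
    # mixing parameter: per-gene random re-initialization
    if (config$mu > 0) {
      reset <- matrix(runif(k * pop) < config$mu, k, pop)
      a2sq[reset] <- 0.5
    }
    if (stale >= config$patience) break
  }
  # local-search polish: single-bit flips accepted while fitness improves
  repeat {
    improved <- FALSE
    for (i in seq_len(k)) {
      flipped <- best_bits
      flipped[i] <- 1L - flipped[i]
      f <- fitness_of(flipped)
      if (f > best_fit + 1e-12) {
        best_bits <- flipped
        best_fit <- f
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  best_bits
}

#' Binary quantum-inspired evolutionary community detection (binQIEA)
#'
#' A population of qubit chromosomes (one gene per node, encoding the side of
#' a bipartition) is evolved by measurement collapse, modularity evaluation,
#' and rotation toward the best observation, with per-gene random
#' re-initialization at rate `mu`. The bipartition routine is wrapped in
#' hierarchical bi-partitioning: each community is recursively split while the
#' split increases global modularity. A greedy single-node relabeling polish
#' is applied to the final solution when `config$refine` is `TRUE`.
#'
#' @param graph The unit network (simple, undirected, at least one edge).
#' @param config A [qicd_config()].
#' @return A `qicd_fit`: partition, modularity, improvement trace, config.
#' @export
run_binqiea <- function(graph, config = qicd_config()) {
  gd <- graph_data(graph)
  set.seed(config$seed)
  res <- hier_bipartition_memb(gd, config, binqiea_bipartition)
  memb <- res$membership
  q <- res$q
  trace <- res$trace
  if (config$refine) {
    ref <- refine_greedy(memb, gd)
    memb <- ref$membership
    q <- ref$q
    trace <- c(trace, q)
  }
  new_qicd_fit("binqiea", gd, memb, q, trace, config)
}

# --- numQIEA ----------------------------------------------------------------

# Real-coded chromosomes over a locus-based adjacency encoding: node i's gene
# is a probability vector (squared amplitudes) over its neighbors; observation
# picks one neighbor per node and the partition is the connected components of
# the resulting locus graph, so the community count is dynamic.

numqiea_observe <- function(probs, gd) {
  vapply(seq_len(gd$n), function(i) {
    d <- length(gd$nb[[i]])
    if (d == 0L) return(i)                       # isolated node points to itself
    if (d == 1L) return(gd$nb[[i]][1])
    gd$nb[[i]][sample.int(d, 1, prob = probs[[i]])]
  }, integer(1))
}

# Rotate node i's amplitude vector toward the target neighbor choice.
numqiea_rotate <- function(p, target_idx, theta) {
  amp <- sqrt(p)
  t_cur <- asin(min(1, amp[target_idx]))
  t_new <- min(pi / 2 - 1e-8, t_cur + theta)
  rest <- sum(p[-target_idx])
  p_new <- p
  p_new[target_idx] <- sin(t_new)^2
  if (rest > 0) {
    p_new[-target_idx] <- p[-target_idx] * (1 - p_new[target_idx]) / rest
  }
  p_new / sum(p_new)
}

#' Real-coded quantum-inspired evolutionary community detection (numQIEA)
#'
#' Chromosomes hold per-node amplitude vectors over the node's neighbors
#' (generalized qubits); observing a chromosome selects one neighbor per node
#' and the decoded partition is the connected components of the locus graph,
#' so the number of communities emerges dynamically. Amplitudes rotate toward
#' the best-so-far observation; each node's amplitude vector re-initializes to
#' uniform with probability `mu` per generation. Acceptance and elitism follow
#' the same modularity-guided rule as [run_binqiea()].
#'
#' @inheritParams run_binqiea
#' @return A `qicd_fit`.
#' @export
run_numqiea <- function(graph, config = qicd_config()) {
  gd <- graph_data(graph)
  set.seed(config$seed)
  pop <- config$population_size
  uniform_probs <- lapply(gd$nb, function(nb) {
    d <- length(nb)
    if (d == 0L) numeric(0) else rep(1 / d, d)
  })
  chroms <- rep(list(uniform_probs), pop)
  best_to <- NULL
  best_fit <- -Inf
  best_memb <- NULL
  trace <- numeric(0)
  stale <- 0L
  for (gen in seq_len(config$generations)) {
    improved <- FALSE
    for (j in seq_len(pop)) {
      to <- numqiea_observe(chroms[[j]], gd)
      memb <- locus_components(to)
      fit <- q_memb(memb, gd)
      if (fit > best_fit) {
        best_fit <- fit
        best_to <- to
        best_memb <- memb
        improved <- TRUE
      }
    }
    trace <- c(trace, best_fit)
    stale <- if (improved) 0L else stale + 1L
    for (j in seq_len(pop)) {
      for (i in seq_len(gd$n)) {
        d <- length(gd$nb[[i]])
        if (d < 2L) next
        if (runif(1) < config$mu) {
          chroms[[j]][[i]] <- rep(1 / d, d)
        } else {
          tgt <- match(best_to[i], gd$nb[[i]])
          if (!is.na(tgt)) {
            chroms[[j]][[i]] <- numqiea_rotate(chroms[[j]][[i]], tgt, config$theta1)
          }
        }
      }
    }
    if (stale >= config$patience) break
  }
  q <- best_fit
  memb <- best_memb
  if (config$refine) {
    ref <- refine_greedy(memb, gd)
    memb <- ref$membership
    q <- ref$q
    trace <- c(trace, q)
  }
  new_qicd_fit("numqiea", gd, memb, q, trace, config)
}

#' Decode a locus (neighbor-pointer) vector into a partition
#'
#' Each node points at one neighbor (or itself); communities are the connected
#' components of the resulting locus graph.
#'
#' @param to Integer vector: `to[i]` is the node index node `i` points at.
#' @param graph The unit network supplying vertex names.
#' @return A partition tibble.
#' @export
decode_locus <- function(to, graph) {
  gd <- graph_data(graph)
  stopifnot(length(to) == gd$n)
  partition_tbl(gd$names, locus_components(as.integer(to)))
}
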