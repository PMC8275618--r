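#' Qubit chromosomes
#'
#' A qubit gene is an amplitude pair `(alpha1, alpha2)` with
#' `alpha1^2 + alpha2^2 = 1`; `alpha1^2` is the probability of the gene
#' collapsing to 0 under measurement. A chromosome is a matrix with one row
#' per gene and columns `alpha1`, `alpha2`.
#'
#' @param n Number of genes.
#' @param alpha1,alpha2 Optional amplitude vectors (recycled); default is the
#'   balanced superposition `1/sqrt(2)` for both.
#' @return A numeric matrix of class `qubit_chromosome`.
#' @export
qubit_chromosome <- function(n, alpha1 = 1 / sqrt(2), alpha2 = 1 / sqrt(2)) {
  chrom <- cbind(alpha1 = rep_len(alpha1, n), alpha2 = rep_len(alpha2, n))
  check_normalized(chrom)
  structure(chrom, class = c("qubit_chromosome", class(chrom)))
}

check_normalized <- function(chrom, tol = 1e-9) {
  norms <- chrom[, 1]^2 + chrom[, 2]^2
  if (any(abs(norms - 1) > tol)) {
    abort("qubit genes must satisfy alpha1^2 + alpha2^2 = 1",
          class = "qicd_unnormalized_gene")
  }
  invisible(chrom)
}

#' Measure (collapse) a qubit chromosome to a classical bit vector
#'
#' Each gene independently collapses to 1 with probability `alpha2^2`.
#'
#' @param chromosome A [qubit_chromosome()].
#' @return Integer vector of 0/1, one per gene.
#' @export
collapse_chromosome <- function(chromosome) {
  check_normalized(chromosome)
  as.integer(runif(nrow(chromosome)) < chromosome[, 2]^2)
}

#' Rotate a qubit chromosome toward a target bit vector
#'
#' Implements the standard QIEA rotation-gate lookup keyed on the collapsed
#' bit, the target (best-so-far) bit and their fitness comparison: where the
#' bits agree the angle is zero; where they differ the gene rotates toward the
#' target bit by `theta1` when the target's fitness is at least the collapsed
#' solution's, and back toward its own bit by `theta2` otherwise. Rotation is
#' orthogonal, so normalization is preserved exactly; amplitudes are kept in
#' the first quadrant (angle clamped to `[0, pi/2]`).
#'
#' @param chromosome A [qubit_chromosome()].
#' @param collapsed The chromosome's collapsed bit vector.
#' @param target The guiding (best) bit vector.
#' @param theta1,theta2 Rotation magnitudes in radians.
#' @param target_better Logical: is the target's fitness >= the collapsed
#'   solution's? (default `TRUE`).
#' @return The rotated `qubit_chromosome`.
#' @export
rotate_chromosome <- function(chromosome, collapsed, target,
                              theta1 = 0.01 * pi, theta2 = 0.025 * pi,
                              target_better = TRUE) {
  check_normalized(chromosome)
  t <- atan2(chromosome[, 2], chromosome[, 1])   # current angle; alpha2 = sin t
  delta <- numeric(nrow(chromosome))
  differ <- collapsed != target
  if (isTRUE(target_better)) {
    # move toward the target bit: +theta grows alpha2 (toward 1)
    delta[differ] <- ifelse(target[differ] == 1L, theta1, -theta1)
  } else {
    delta[differ] <- ifelse(collapsed[differ] == 1L, theta2, -theta2)
  }
  t_new <- pmin(pi / 2, pmax(0, t + delta))
  out <- cbind(alpha1 = cos(t_new), alpha2 = sin(t_new))
  structure(out, class = c("qubit_chromosome", class(out)))
}

#' Single-node mutation with modularity-based acceptance
#'
#' Resamples one randomly chosen node's community label uniformly from the
#' partition's existing community ids; the mutant replaces the input only if
#' its modularity is strictly greater, otherwise the input is returned
#' unchanged (hill-climbing acceptance).
#'
#' @param partition Partition tibble (`unit_id`, `community`).
#' @param graph The unit network the partition lives on.
#' @return A partition tibble (possibly identical to the input).
#' @export
mutate_and_accept <- function(partition, graph) {
  gd <- graph_data(graph)
  memb <- align_membership(partition, gd)
  q0 <- q_memb(memb, gd)
  v <- sample.int(gd$n, 1)
  labs <- seq_len(max(memb))
  trial <- memb
  trial[v] <- sample(labs, 1)
  trial <- canonical_membership(trial)
  if (q_memb(trial, gd) > q0) {
    partition_tbl(gd$names, trial)
  } else {
    partition_tbl(gd$names, memb)
  }
}

#' Hierarchical bi-partitioning driven by a split routine
#'
#' Starting from one community holding every node, each current community is
#' recursively offered to `bipartition_fn`; a proposed split is kept only when
#' it strictly increases global modularity. Recursion stops at
#' `config$max_depth` levels or when no split improves Q.
#'
#' @param graph The unit network.
#' @param config A [qicd_config()]; `max_depth` bounds the recursion and
#'   `seed` fixes the random stream.
#' @param bipartition_fn Function `(nodes, gd, memb, config) -> 0/1 vector`
#'   proposing a two-way split of the node indices `nodes` (internal callers
#'   pass [qicd_config()]-driven QIEA routines).
#' @return List with `partition` (tibble) and `modularity`.
#' @export
hierarchical_bipartition <- function(graph, config, bipartition_fn) {
  gd <- graph_data(graph)
  set.seed(config$seed)
  res <- hier_bipartition_memb(gd, config, bipartition_fn)
  list(partition = partition_tbl(gd$names, res$membership),
       modularity = res$q, trace = res$trace)
}

# Membership-level engine behind hierarchical_bipartition(); assumes the RNG
# is already seeded.
hier_bipartition_memb <- function(gd, config, bipartition_fn) {
  memb <- rep(1L, gd$n)
  best_q <- q_memb(memb, gd)
  trace <- best_q
  queue <- list(list(comm = 1L, depth = 1L))
  next_label <- 2L
  while (length(queue)) {
    task <- queue[[1]]
    queue <- queue[-1]
    if (task$depth > config$max_depth) next
    nodes <- which(memb == task$comm)
    if (length(nodes) < 2L) next
    bits <- bipartition_fn(nodes, gd, memb, config)
    if (all(bits == bits[1])) next
    cand <- memb
    cand[nodes[bits == 1L]] <- next_label
    q_new <- q_memb(cand, gd)
    if (q_new > best_q + 1e-12) {
      memb <- cand
      best_q <- q_new
      trace <- c(trace, best_q)
      queue <- c(queue, list(list(comm = task$comm, depth = task$depth + 1L),
                             list(comm = next_label, depth = task$depth + 1L)))
      next_label <- next_label + 1L
    }
  }
  list(membership = canonical_membership(memb), q = best_q, trace = trace)
}
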