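# Quantum-behaved discrete multi-objective particle swarm community detection.

# Per-community objectives for the optional bi-criteria mode.
partition_objectives <- function(memb, gd) {
  memb <- canonical_membership(memb)
  k <- max(memb)
  internal <- sum(memb[gd$ea] == memb[gd$eb])
  sizes <- tabulate(memb, nbins = k)
  possible <- sizes * (sizes - 1) / 2
  dens <- ifelse(possible > 0,
                 tabulate(memb[gd$ea][memb[gd$ea] == memb[gd$eb]], nbins = k) / possible,
                 1)
  c(intra_density = mean(dens),
    inter_fraction = 1 - internal / gd$m)
}

#' Quantum-behaved discrete particle swarm community detection (QDMPSO)
#'
#' Particles are community label vectors. Each dimension updates by sampling
#' around a discrete local attractor — the personal-best label with
#' probability `alpha_coef`, else the global-best label — and, where the
#' particle still disagrees with its attractor, performs a delta-well quantum
#' jump (adopting the label of a random neighbor) with probability
#' proportional to the contraction-expansion coefficient, which decreases
#' linearly from `beta_coef` to `beta_coef / 2`. With probability `mu` a
#' dimension explores a uniformly random label. The global best is elitist, so
#' its modularity trace is non-decreasing.
#'
#' With `objectives = "bicriteria"` every evaluated particle is also scored on
#' (mean intra-community edge density, inter-community link fraction); the
#' first non-dominated front is extracted by fast non-dominated sorting and
#' the returned solution is its maximum-modularity member.
#'
#' @inheritParams run_binqiea
#' @param objectives `"modularity"` (default) or `"bicriteria"`.
#' @return A `qicd_fit`; in bi-criteria mode the first front is attached as
#'   attribute `"front"`.
#' @export
run_qdmpso <- function(graph, config = qicd_config(),
                       objectives = c("modularity", "bicriteria")) {
  objectives <- match.arg(objectives)
  gd <- graph_data(graph)
  set.seed(config$seed)
  n <- gd$n
  pop <- config$population_size
  # initial positions: each node adopts itself or a random neighbor's id
  X <- vapply(seq_len(pop), function(j) {
    vapply(seq_len(n), function(i) {
      cands <- c(i, gd$nb[[i]])
      cands[sample.int(length(cands), 1)]
    }, integer(1))
  }, integer(n))
  X <- matrix(X, nrow = n)
  fit <- apply(X, 2, function(x) q_memb(canonical_membership(x), gd))
  pbest <- X
  pfit <- fit
  gidx <- which.max(pfit)
  gbest <- pbest[, gidx]
  gfit <- pfit[gidx]
  trace <- gfit
  archive <- list()
  stale <- 0L
  gens <- max(2L, config$generations)
  for (gen in seq_len(gens)) {
    beta_t <- config$beta_coef * (1 - 0.5 * (gen - 1) / (gens - 1))
    improved <- FALSE
    for (j in seq_len(pop)) {
      follow_p <- runif(n) < config$alpha_coef
      attract <- ifelse(follow_p, pbest[, j], gbest)
      x <- attract
      # delta-well jump only where the particle had not yet collapsed onto its
      # attractor (zero well width => stationary fixed point)
      disagree <- X[, j] != attract
      jump <- disagree & (runif(n) < 0.25 * beta_t)
      if (any(jump)) {
        x[jump] <- vapply(which(jump), function(i) {
          nbs <- gd$nb[[i]]
          if (!length(nbs)) return(x[i])
          x[nbs[sample.int(length(nbs), 1)]]
        }, numeric(1))
      }
      if (config$mu > 0) {
        explore <- runif(n) < config$mu
        if (any(explore)) x[explore] <- sample.int(n, sum(explore), replace = TRUE)
      }
      x <- as.integer(x)
      f <- q_memb(canonical_membership(x), gd)
      X[, j] <- x
      if (objectives == "bicriteria") {
        archive[[length(archive) + 1L]] <-
          c(partition_objectives(x, gd), q = f, gen = gen, particle = j)
      }
      if (f > pfit[j]) {
        pbest[, j] <- x
        pfit[j] <- f
      }
      if (f > gfit) {
        gfit <- f
        gbest <- x
        improved <- TRUE
      }
    }
    trace <- c(trace, gfit)
    stale <- if (improved) 0L else stale + 1L
    if (stale >= config$patience) break
  }
  memb <- canonical_membership(gbest)
  q <- gfit
  if (config$refine) {
    ref <- refine_greedy(memb, gd)
    memb <- ref$membership
    q <- ref$q
    trace <- c(trace, q)
  }
  fit_obj <- new_qicd_fit("qdmpso", gd, memb, q, trace, config)
  if (objectives == "bicriteria" && length(archive)) {
    obj_tbl <- tibble::as_tibble(do.call(rbind, archive))
    # maximize intra density, minimize inter fraction
    ranks <- pareto_fronts(cbind(-obj_tbl$intra_density, obj_tbl$inter_fraction))
    front <- obj_tbl[ranks == 1L, ]
    attr(fit_obj, "front") <- front
  }
  fit_obj
}

#' Run a named detection algorithm
#'
#' @param graph The unit network.
#' @param algorithm `"binqiea"`, `"numqiea"`, or `"qdmpso"`.
#' @param config A [qicd_config()].
#' @return A `qicd_fit`.
#' @export
detect_communities <- function(graph,
                               algorithm = c("binqiea", "numqiea", "qdmpso"),
                               config = qicd_config()) {
  algorithm <- match.arg(algorithm)
  switch(algorithm,
         binqiea = run_binqiea(graph, config),
         numqiea = run_numqiea(graph, config),
         qdmpso = run_qdmpso(graph, config))
}
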