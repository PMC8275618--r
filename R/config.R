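#' Configuration for the quantum-inspired detection algorithms
#'
#' @param population_size Chromosomes / particles per generation (>= 2).
#' @param generations Maximum generations per evolutionary loop.
#' @param mu Mixing parameter in `[0, 0.5]`: the per-gene probability of random
#'   re-initialization (exploration) per generation. This is the knob the
#'   sweep harness varies.
#' @param theta1,theta2 QIEA rotation angles (radians). Defaults `0.01*pi` and
#'   `0.025*pi` are common magnitudes for the rotation-gate lookup.
#' @param alpha_coef QDMPSO attractor weight: probability a dimension follows
#'   the personal best rather than the global best.
#' @param beta_coef QDMPSO contraction-expansion scale at generation 1; it
#'   decreases linearly to `beta_coef / 2` across generations.
#' @param runs Independent restarts used by the sweep harness (default 40).
#' @param seed Master seed; per-run seeds are derived by a counter scheme.
#' @param max_depth Maximum hierarchical bipartition depth (default 4).
#' @param patience Early-stopping: stop a loop after this many generations
#'   without improvement of the best solution.
#' @param refine Apply a greedy single-node relabeling polish to each run's
#'   final partition (default `TRUE`).
#' @return A list of class `qicd_config`.
#' @export
qicd_config <- function(population_size = 20L, generations = 100L, mu = 0.1,
                        theta1 = 0.01 * pi, theta2 = 0.025 * pi,
                        alpha_coef = 0.75, beta_coef = 1.0,
                        runs = 40L, seed = 1L, max_depth = 4L,
                        patience = 15L, refine = TRUE) {
  if (population_size < 2L) abort("population_size must be >= 2")
  if (mu < 0 || mu > 0.5) abort("mu must lie in [0, 0.5]")
  if (runs < 1L) abort("runs must be >= 1")
  structure(
    list(population_size = as.integer(population_size),
         generations = as.integer(generations), mu = as.double(mu),
         theta1 = as.double(theta1), theta2 = as.double(theta2),
         alpha_coef = as.double(alpha_coef), beta_coef = as.double(beta_coef),
         runs = as.integer(runs), seed = as.integer(seed),
         max_depth = as.integer(max_depth), patience = as.integer(patience),
         refine = isTRUE(refine)),
    class = "qicd_config"
  )
}

# Assemble the common fit object returned by all detection algorithms.
new_qicd_fit <- function(algorithm, gd, memb, q, trace, config) {
  structure(
    list(
      algorithm = algorithm,
      graph_name = gd$graph_name,
      partition = partition_tbl(gd$names, memb),
      modularity = q,
      n_communities = max(canonical_membership(memb)),
      trace = tibble::tibble(step = seq_along(trace), best_q = trace),
      config = config,
      seed = config$seed
    ),
    class = "qicd_fit"
  )
}

#' @export
print.qicd_fit <- function(x, ...) {
  cat(sprintf("<qicd_fit> %s on '%s': %d communities, Q = %.4f (seed %d)\n",
              x$algorithm, x$graph_name, x$n_communities, x$modularity, x$seed))
  invisible(x)
}

#' Tidy a community-detection fit into its membership table
#'
#' @param x A `qicd_fit` object.
#' @param ... Unused.
#' @return A tibble `unit_id`, `community`.
#' @method tidy qicd_fit
#' @export
tidy.qicd_fit <- function(x, ...) x$partition

#' One-row summary of a community-detection fit
#'
#' @param x A `qicd_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: algorithm, graph, Q, community count, seed.
#' @method glance qicd_fit
#' @export
glance.qicd_fit <- function(x, ...) {
  tibble::tibble(algorithm = x$algorithm, graph = x$graph_name,
                 modularity = x$modularity, n_communities = x$n_communities,
                 seed = x$seed)
}
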