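# Fast non-dominated sorting, crowding distance, and the NSGA-II parameter
# tuner used for the rotation-angle / attractor-coefficient search.

#' Fast non-dominated sorting
#'
#' Sorts points in objective space (all objectives minimized) into Pareto
#' fronts: front 1 is the non-dominated set, front 2 is non-dominated once
#' front 1 is removed, and so on.
#'
#' @param obj Numeric matrix, one row per point, one column per objective
#'   (smaller is better for every column).
#' @return Integer vector of front ranks (1 = non-dominated).
#' @export
pareto_fronts <- function(obj) {
  obj <- as.matrix(obj)
  n <- nrow(obj)
  if (n == 0L) return(integer(0))
  dominates <- function(i, j) {
    all(obj[i, ] <= obj[j, ]) && any(obj[i, ] < obj[j, ])
  }
  rank <- integer(n)
  remaining <- seq_len(n)
  front <- 0L
  while (length(remaining)) {
    front <- front + 1L
    nd <- remaining[vapply(remaining, function(i) {
      !any(vapply(remaining, function(j) j != i && dominates(j, i), logical(1)))
    }, logical(1))]
    rank[nd] <- front
    remaining <- setdiff(remaining, nd)
  }
  rank
}

# Crowding distance within one front (all objectives minimized).
crowding_distance <- function(obj) {
  obj <- as.matrix(obj)
  n <- nrow(obj)
  if (n <= 2L) return(rep(Inf, n))
  dist <- numeric(n)
  for (k in seq_len(ncol(obj))) {
    ord <- order(obj[, k])
    rng <- obj[ord[n], k] - obj[ord[1], k]
    dist[ord[c(1, n)]] <- Inf
    if (rng > 0) {
      for (i in 2:(n - 1)) {
        dist[ord[i]] <- dist[ord[i]] + (obj[ord[i + 1], k] - obj[ord[i - 1], k]) / rng
      }
    }
  }
  dist
}

#' Tune algorithm parameters with a small NSGA-II
#'
#' Searches over the rotation angles and swarm coefficients
#' `(theta1, theta2, alpha_coef, beta_coef)` with two objectives evaluated
#' over repeated runs: maximize the mean modularity and minimize its standard
#' deviation. The default configuration is seeded into the initial population,
#' so the tuned result can never evaluate worse than the default on the same
#' evaluation protocol. Returns the knee-point configuration of the final
#' non-dominated front (closest to the normalized ideal point).
#'
#' @param graph The unit network to tune on.
#' @param algorithm `"binqiea"`, `"numqiea"`, or `"qdmpso"`.
#' @param search_space Named list of `c(lower, upper)` ranges for any of
#'   `theta1`, `theta2`, `alpha_coef`, `beta_coef`.
#' @param budget NSGA-II generations (default 3).
#' @param population Configurations per generation (default 8).
#' @param base_config Template [qicd_config()] supplying every other field;
#'   `runs` here sets how many evaluation runs score each candidate.
#' @return The tuned `qicd_config`, with attributes `"front"` (tibble of the
#'   final non-dominated front) and `"evaluations"` (all scored candidates).
#' @export
tune_parameters <- function(graph, algorithm = c("binqiea", "numqiea", "qdmpso"),
                            search_space = list(theta1 = c(0.001 * pi, 0.05 * pi),
                                                theta2 = c(0.001 * pi, 0.1 * pi),
                                                alpha_coef = c(0.5, 0.95),
                                                beta_coef = c(0.5, 1.5)),
                            budget = 3L, population = 8L,
                            base_config = qicd_config(generations = 30L,
                                                      runs = 5L, patience = 8L)) {
  algorithm <- match.arg(algorithm)
  par_names <- names(search_space)
  stopifnot(all(par_names %in% c("theta1", "theta2", "alpha_coef", "beta_coef")))
  set.seed(base_config$seed)

  clamp <- function(x, rng) pmin(rng[2], pmax(rng[1], x))
  random_candidate <- function() {
    vapply(par_names, function(p) runif(1, search_space[[p]][1], search_space[[p]][2]),
           numeric(1))
  }
  as_config <- function(params) {
    cfg <- base_config
    for (p in par_names) cfg[[p]] <- unname(params[[p]])
    cfg
  }
  evaluate <- function(params, eval_id) {
    cfg <- as_config(params)
    qs <- vapply(seq_len(base_config$runs), function(r) {
      cfg$seed <- derive_seed(base_config$seed, eval_id * 1000L + r)
      detect_communities(graph, algorithm, cfg)$modularity
    }, numeric(1))
    c(mean_q = mean(qs), sd_q = if (length(qs) > 1) sd(qs) else 0)
  }

  # initial population: default config + random draws
  default_params <- setNames(
    vapply(par_names, function(p) base_config[[p]], numeric(1)), par_names)
  pop_params <- c(list(default_params),
                  lapply(seq_len(max(population - 1L, 1L)), function(i) random_candidate()))
  eval_counter <- 0L
  score <- function(plist) {
    t(vapply(plist, function(pp) {
      eval_counter <<- eval_counter + 1L
      evaluate(pp, eval_counter)
    }, numeric(2)))
  }
  scores <- score(pop_params)
  history <- list()
  record <- function(params_list, sc) {
    tibble::tibble(
      !!!setNames(lapply(par_names, function(p)
        vapply(params_list, `[[`, numeric(1), p)), par_names),
      mean_q = sc[, "mean_q"], sd_q = sc[, "sd_q"])
  }
  history[[1]] <- record(pop_params, scores)

  for (gen in seq_len(budget)) {
    # objectives minimized: (-mean_q, sd_q)
    obj <- cbind(-scores[, "mean_q"], scores[, "sd_q"])
    ranks <- pareto_fronts(obj)
    crowd <- numeric(nrow(obj))
    for (f in unique(ranks)) crowd[ranks == f] <- crowding_distance(obj[ranks == f, , drop = FALSE])
    tournament <- function() {
      ij <- sample.int(length(pop_params), 2)
      i <- ij[1]; j <- ij[2]
      if (ranks[i] < ranks[j] || (ranks[i] == ranks[j] && crowd[i] > crowd[j])) i else j
    }
    offspring <- lapply(seq_along(pop_params), function(o) {
      a <- pop_params[[tournament()]]
      b <- pop_params[[tournament()]]
      w <- runif(length(par_names))
      child <- w * a + (1 - w) * b               # blend crossover
      for (idx in seq_along(par_names)) {        # gaussian mutation, 20% rate
        if (runif(1) < 0.2) {
          rng <- search_space[[par_names[idx]]]
          child[idx] <- clamp(child[idx] + rnorm(1, 0, 0.1 * diff(rng)), rng)
        }
      }
      setNames(child, par_names)
    })
    off_scores <- score(offspring)
    history[[gen + 1]] <- record(offspring, off_scores)
    # elitist environmental selection over parents + offspring
    all_params <- c(pop_params, offspring)
    all_scores <- rbind(scores, off_scores)
    obj_all <- cbind(-all_scores[, "mean_q"], all_scores[, "sd_q"])
    ranks_all <- pareto_fronts(obj_all)
    crowd_all <- numeric(nrow(obj_all))
    for (f in unique(ranks_all)) {
      crowd_all[ranks_all == f] <- crowding_distance(obj_all[ranks_all == f, , drop = FALSE])
    }
    keep <- order(ranks_all, -crowd_all)[seq_along(pop_params)]
    pop_params <- all_params[keep]
    scores <- all_scores[keep, , drop = FALSE]
  }

  obj <- cbind(-scores[, "mean_q"], scores[, "sd_q"])
  ranks <- pareto_fronts(obj)
  front_idx <- which(ranks == 1L)
  front_obj <- obj[front_idx, , drop = FALSE]
  # knee point: closest to the ideal corner after min-max normalization
  norm <- apply(front_obj, 2, function(col) {
    rng <- diff(range(col))
    if (rng == 0) rep(0, length(col)) else (col - min(col)) / rng
  })
  norm <- matrix(norm, nrow = length(front_idx))
  knee <- front_idx[which.min(rowSums(norm^2))]

  tuned <- as_config(pop_params[[knee]])
  attr(tuned, "front") <- record(pop_params[front_idx], scores[front_idx, , drop = FALSE])
  attr(tuned, "evaluations") <- purrr::list_rbind(history)
  tuned
}
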