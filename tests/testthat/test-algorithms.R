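small_cfg <- function(seed = 1, runs = 1) {
  qicd_config(population_size = 12, generations = 40, patience = 8,
              runs = runs, seed = seed)
}

test_that("all three algorithms recover the planted two-clique split", {
  p <- planted_cliques(c(4, 4))
  for (alg in c("binqiea", "numqiea", "qdmpso")) {
    hits <- vapply(1:40, function(r) {
      fit <- detect_communities(p$graph, alg, small_cfg(seed = derive_seed_for_test(r)))
      nmi(fit$partition, p$truth) == 1
    }, logical(1))
    expect_gte(mean(hits), 0.95)
  }
})

test_that("best-of-40 modularity equals the exhaustive maximum on small graphs", {
  graphs <- list(two_triangles_bridge(), random_small_graph(7, 0.45, seed = 13))
  for (g in graphs) {
    oracle <- max_modularity_exhaustive(g)
    for (alg in c("binqiea", "numqiea", "qdmpso")) {
      best <- max(vapply(1:40, function(r) {
        detect_communities(g, alg, small_cfg(seed = derive_seed_for_test(100 + r)))$modularity
      }, numeric(1)))
      expect_equal(best, oracle$q, tolerance = 1e-10)
    }
  }
})

test_that("fixed seeds fix the full output bit for bit", {
  g <- planted_cliques(c(4, 3, 4))$graph
  for (alg in c("binqiea", "numqiea", "qdmpso")) {
    a <- detect_communities(g, alg, small_cfg(seed = 31))
    b <- detect_communities(g, alg, small_cfg(seed = 31))
    expect_identical(a$partition, b$partition)
    expect_identical(a$modularity, b$modularity)
    expect_identical(a$trace, b$trace)
  }
})

test_that("degenerate graphs are rejected", {
  empty <- igraph::make_empty_graph(3, directed = FALSE)
  for (alg in c("binqiea", "numqiea", "qdmpso")) {
    expect_error(detect_communities(empty, alg, small_cfg()),
                 class = "qicd_degenerate_graph")
  }
  expect_error(girvan_newman(empty), class = "qicd_degenerate_graph")
})

test_that("best-so-far modularity traces are monotone non-decreasing", {
  g <- planted_cliques(c(5, 4, 4))$graph
  for (alg in c("binqiea", "numqiea", "qdmpso")) {
    fit <- detect_communities(g, alg, small_cfg(seed = 17))
    expect_true(all(diff(fit$trace$best_q) >= -1e-12))
    expect_equal(fit$modularity, max(fit$trace$best_q))
  }
})

test_that("locus decoding yields the components of the pointer graph", {
  p <- planted_cliques(c(4, 4), bridges = FALSE)
  gd_names <- igraph::V(p$graph)$name
  # every node points at a within-clique neighbour -> the two cliques
  to <- c(2L, 3L, 4L, 1L, 6L, 7L, 8L, 5L)
  part <- decode_locus(to, p$graph)
  expect_equal(nmi(part, p$truth), 1)
  expect_lte(length(unique(part$community)), length(gd_names))
})

test_that("the mixing-parameter sweep emits the full tidy grid", {
  g <- planted_cliques(c(4, 4))$graph
  sw <- sweep_mixing_parameter(g, "qdmpso",
                               config = small_cfg(seed = 3, runs = 2))
  expect_equal(nrow(sw), 11)
  expect_equal(sw$mu, seq(0, 0.5, by = 0.05))
  runs <- attr(sw, "runs")
  expect_equal(nrow(runs), 22)
  expect_true(all(c("dataset", "algorithm", "mu", "run", "seed", "q",
                    "n_communities") %in% names(runs)))
  sw1 <- sweep_mixing_parameter(g, "qdmpso", mu_grid = c(0, 0.2),
                                config = small_cfg(seed = 3, runs = 1))
  expect_equal(sw1$mean_q, sw1$max_q)
})

test_that("NSGA-II tuning returns a mutually non-dominated front containing
           a config at least as good as the default", {
  g <- planted_cliques(c(4, 4, 4))$graph
  base <- qicd_config(population_size = 10, generations = 20, patience = 6,
                      runs = 3, seed = 19)
  tuned <- tune_parameters(g, "binqiea", budget = 2, population = 4,
                           base_config = base)
  expect_s3_class(tuned, "qicd_config")
  front <- attr(tuned, "front")
  evals <- attr(tuned, "evaluations")
  # pairwise non-domination on the front (maximize mean_q, minimize sd_q)
  if (nrow(front) > 1) {
    for (i in seq_len(nrow(front))) {
      for (j in seq_len(nrow(front))) {
        if (i == j) next
        dominates <- front$mean_q[j] >= front$mean_q[i] &&
          front$sd_q[j] <= front$sd_q[i] &&
          (front$mean_q[j] > front$mean_q[i] || front$sd_q[j] < front$sd_q[i])
        expect_false(dominates)
      }
    }
  }
  # the default config is evaluated first; tuning cannot end below it
  expect_gte(max(front$mean_q), evals$mean_q[1] - 1e-9)
})

test_that("a one-generation, two-candidate tuning budget degrades gracefully", {
  g <- planted_cliques(c(4, 4))$graph
  base <- qicd_config(population_size = 8, generations = 15, patience = 5,
                      runs = 2, seed = 23)
  tuned <- tune_parameters(g, "qdmpso", budget = 1, population = 2,
                           base_config = base)
  expect_s3_class(tuned, "qicd_config")
  expect_gte(nrow(attr(tuned, "front")), 1)
})

test_that("pareto front ranking matches the domination definition", {
  obj <- rbind(c(0, 0), c(1, 1), c(0, 2), c(2, 0), c(3, 3))
  ranks <- pareto_fronts(obj)
  expect_equal(ranks[1], 1L)             # dominates everything
  expect_equal(ranks[5], max(ranks))     # dominated by everything
  expect_true(all(ranks[c(3, 4)] == 2L)) # tied second front
})
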