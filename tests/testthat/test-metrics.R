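test_that("modularity reproduces hand-computed reference values", {
  g <- two_triangles_bridge()
  one <- tibble::tibble(unit_id = igraph::V(g)$name, community = 1L)
  expect_equal(modularity_q(g, one), 0)
  triangles <- tibble::tibble(unit_id = c("A", "B", "C", "D", "E", "F"),
                              community = c(1L, 1L, 1L, 2L, 2L, 2L))
  expect_equal(modularity_q(g, triangles), 5 / 14, tolerance = 1e-12)
  tri <- named_graph(c("A","B", "B","C", "A","C"), name = "triangle")
  singletons <- tibble::tibble(unit_id = c("A", "B", "C"), community = 1:3)
  expect_equal(modularity_q(tri, singletons), -1 / 3, tolerance = 1e-12)
  expect_error(modularity_q(igraph::make_empty_graph(3), c(1, 2, 3)),
               class = "qicd_degenerate_graph")
})

test_that("modularity agrees with direct summation and igraph on random graphs", {
  set.seed(99)
  for (i in 1:30) {
    g <- random_small_graph(sample(4:10, 1), p = runif(1, 0.3, 0.8),
                            seed = 100 + i)
    n <- igraph::vcount(g)
    memb <- sample.int(3, n, replace = TRUE)
    part <- tibble::tibble(unit_id = igraph::V(g)$name, community = memb)
    expect_equal(modularity_q(g, part), q_direct(g, memb), tolerance = 1e-12)
    expect_equal(modularity_q(g, part), igraph::modularity(g, memb),
                 tolerance = 1e-12)
  }
})

test_that("NMI matches its frozen reference cases", {
  expect_equal(nmi(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(nmi(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)   # pure relabeling
  expect_equal(nmi(c(1, 1, 2, 2), c(1, 2, 1, 2)), 0)   # uniform contingency
  # zero-entropy convention
  expect_equal(nmi(c(1, 1, 1), c(1, 1, 1)), 1)
  expect_equal(nmi(c(1, 1, 1), c(1, 2, 3)), 0)
  # max-entropy variant is bounded by the mean variant
  a <- c(1, 1, 2, 2, 3, 3)
  b <- c(1, 1, 1, 2, 2, 2)
  expect_lte(nmi(a, b, variant = "max"), nmi(a, b, variant = "mean"))
})

test_that("ARI matches the pair-counting formula on reference cases", {
  expect_equal(ari(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(ari(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
  expect_equal(ari(c(1, 1, 1, 1), c(1, 1, 1, 1)), 1)
})

test_that("NMI and ARI are symmetric and label-permutation invariant", {
  skip_if_not_installed("mclust")
  set.seed(55)
  for (i in 1:25) {
    n <- sample(6:14, 1)
    a <- sample.int(4, n, replace = TRUE)
    b <- sample.int(3, n, replace = TRUE)
    perm <- sample.int(4)
    a_perm <- perm[a]
    expect_equal(nmi(a, b), nmi(b, a), tolerance = 1e-12)
    expect_equal(ari(a, b), ari(b, a), tolerance = 1e-12)
    expect_equal(nmi(a_perm, b), nmi(a, b), tolerance = 1e-12)
    expect_equal(ari(a_perm, b), ari(a, b), tolerance = 1e-12)
    # independent cross-check of the ARI pair-counting formula
    expect_equal(ari(a, b), mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
})

test_that("degree distribution counts nodes exactly", {
  star <- named_graph(c("H","A", "H","B", "H","C", "H","D"), name = "star")
  dd <- degree_distribution_tbl(star)
  expect_equal(dd$n_nodes[dd$degree == 4], 1)
  expect_equal(dd$n_nodes[dd$degree == 1], 4)
  expect_equal(sum(dd$n_nodes), 5)
  empty <- igraph::make_empty_graph(3, directed = FALSE)
  dd0 <- degree_distribution_tbl(empty)
  expect_equal(dd0, tibble::tibble(degree = 0L, n_nodes = 3L))
  # handshake lemma on the fixture
  fx <- tiger_fixture()
  g <- build_network(fx$counts, fx$attributes, "reserves")
  dd2 <- degree_distribution_tbl(g)
  expect_equal(sum(dd2$n_nodes), igraph::vcount(g))
  expect_equal(sum(dd2$degree * dd2$n_nodes), 2 * igraph::ecount(g))
})

test_that("degree centrality is the raw degree", {
  k4 <- named_graph(as.vector(utils::combn(LETTERS[1:4], 2)), name = "K4")
  expect_equal(node_centrality(k4)$degree, rep(3L, 4))
  path <- named_graph(c("A","B", "B","C"), name = "path")
  nc <- node_centrality(path)
  expect_equal(setNames(nc$degree, nc$unit_id)[c("A", "B", "C")],
               c(A = 1L, B = 2L, C = 1L))
})

test_that("betweenness matches hand-derived values and the brute-force oracle", {
  path <- named_graph(c("A","B", "B","C"), name = "path")
  nc <- node_centrality(path)
  expect_equal(nc$betweenness[nc$unit_id == "B"], 1)
  g <- two_triangles_bridge()
  eb <- edge_betweenness_tbl(g)
  expect_equal(eb$betweenness[eb$from == "C" & eb$to == "D"], 9)
  c4 <- named_graph(c("A","B", "B","C", "C","D", "D","A"), name = "C4")
  expect_equal(node_centrality(c4)$betweenness, rep(0.5, 4))
  # oracle equality on random graphs of up to 7 nodes
  for (seed in c(3, 8, 15)) {
    rg <- random_small_graph(7, 0.5, seed = seed)
    bb <- brute_betweenness(rg)
    nc <- node_centrality(rg)
    expect_equal(setNames(nc$betweenness, nc$unit_id)[names(bb$vertex)],
                 bb$vertex, tolerance = 1e-9)
    eb <- edge_betweenness_tbl(rg)
    keys <- paste(eb$from, eb$to, sep = "|")
    expect_equal(setNames(eb$betweenness, keys)[names(bb$edge)], bb$edge,
                 tolerance = 1e-9)
  }
})

test_that("metric_report bundles scalars and per-node tables", {
  g <- two_triangles_bridge()
  part <- tibble::tibble(unit_id = igraph::V(g)$name,
                         community = c(1L, 1L, 1L, 2L, 2L, 2L))
  rep <- metric_report(g, part, reference = part)
  expect_equal(rep$scalars$q, 5 / 14, tolerance = 1e-12)
  expect_equal(rep$scalars$nmi, 1)
  expect_equal(rep$scalars$ari, 1)
  expect_equal(nrow(rep$nodes), 6)
})
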