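test_that("percentage increase follows its definition", {
  expect_equal(percentage_increase(100, 150), 50)
  expect_equal(percentage_increase(200, 200), 0)
  expect_equal(percentage_increase(80, 60), -25)
  expect_error(percentage_increase(0, 10), class = "qicd_undefined_growth")
})

test_that("quantile growth grouping matches a sort-and-split oracle", {
  growths <- c(-10, 0, 5, 10, 20, 40, 60, 100)
  counts <- tibble::tibble(unit_id = sprintf("u%02d", 1:8),
                           count_t0 = 100L,
                           count_t1 = as.integer(100 + growths))
  groups <- assign_growth_groups(counts, n_groups = 4)
  # sorted split: two units per group in growth order
  expected <- rep(1:4, each = 2)[rank(growths)]
  expect_equal(groups$community, expected)
  expect_equal(groups$pct_increase, growths)
})

test_that("degenerate grouping and explicit boundaries behave as specified", {
  counts <- tibble::tibble(unit_id = letters[1:6], count_t0 = 100L,
                           count_t1 = 120L)
  expect_error(assign_growth_groups(counts, 4), class = "qicd_degenerate_grouping")
  counts2 <- tibble::tibble(unit_id = c("a", "b", "c", "d"),
                            count_t0 = 100L,
                            count_t1 = c(70L, 110L, 130L, 180L))
  g <- assign_growth_groups(counts2, boundaries = c(0, 25, 50))
  # half-open bins [-Inf,0), [0,25), [25,50), [50,Inf): growth 30 -> 3rd bin
  expect_equal(g$community, c(1L, 2L, 3L, 4L))
})

test_that("intra-links wire each growth subgroup as a clique", {
  groups <- tibble::tibble(unit_id = c("A", "B", "C", "D", "E"),
                           community = c(1L, 1L, 1L, 2L, 2L))
  edges <- build_intra_links(groups)
  expect_equal(nrow(edges), 4)
  expect_setequal(paste(edges$from, edges$to),
                  c("A B", "A C", "B C", "D E"))
  singletons <- tibble::tibble(unit_id = c("A", "B"), community = 1:2)
  expect_equal(nrow(build_intra_links(singletons)), 0)
  one_group <- tibble::tibble(unit_id = sprintf("s%02d", 1:18), community = 1L)
  expect_equal(nrow(build_intra_links(one_group)), 18 * 17 / 2)
})

test_that("inter-links wire landscape and reserve classes as specified", {
  attrs <- tibble::tibble(
    unit_id = sprintf("u%02d", 1:18),
    landscape_class = rep(1:4, times = c(5, 5, 4, 4)),
    reserve_count = c(rep(5L, 10), rep(1L, 8)))
  expect_equal(nrow(build_inter_links(attrs, "landscape")), 10 + 10 + 6 + 6)
  expect_equal(nrow(build_inter_links(attrs, "reserves")), 45 + 28)
  all_low <- dplyr::mutate(attrs, reserve_count = 0L)
  expect_equal(nrow(build_inter_links(all_low, "reserves")), 18 * 17 / 2)
})

test_that("network edge set is the deduplicated union of intra and inter links", {
  counts <- tibble::tibble(unit_id = as.character(1:6), count_t0 = 100L,
                           count_t1 = c(90L, 95L, 100L, 150L, 160L, 170L))
  attrs <- tibble::tibble(unit_id = as.character(1:6),
                          landscape_class = c(1L, 2L, 3L, 1L, 2L, 3L),
                          reserve_count = 0L)
  g <- build_network(counts, attrs, "landscape", n_groups = 2)
  # growth groups {1,2,3 | 4,5,6} give 6 clique edges; landscape pairs
  # {1,4},{2,5},{3,6} give 3 more; no overlap
  expect_equal(igraph::ecount(g), 9)
  expect_equal(igraph::vcount(g), 6)
  # identical grouping attributes collapse onto the intra-links alone
  attrs2 <- tibble::tibble(unit_id = as.character(1:6),
                           landscape_class = c(1L, 1L, 1L, 2L, 2L, 2L),
                           reserve_count = 0L)
  g2 <- build_network(counts, attrs2, "landscape", n_groups = 2)
  expect_equal(igraph::ecount(g2), 6)
  expect_error(build_network(counts, attrs[1:5, ], "landscape"),
               class = "qicd_unit_mismatch")
})

test_that("union size is bounded and degree respects the two-rule bound", {
  fx <- tiger_fixture()
  groups <- assign_growth_groups(fx$counts)
  intra <- build_intra_links(groups)
  inter <- build_inter_links(fx$attributes, "reserves")
  g <- build_network(fx$counts, fx$attributes, "reserves")
  expect_lte(igraph::ecount(g), nrow(intra) + nrow(inter))
  # per-node degree bound: (growth group size - 1) + (attribute class size - 1)
  cls <- ifelse(fx$attributes$reserve_count >= 3, 1L, 2L)
  cls_sizes <- table(cls)[as.character(cls)]
  grp_sizes <- table(groups$community)[as.character(groups$community)]
  bound <- setNames(as.integer(grp_sizes - 1) + as.integer(cls_sizes - 1),
                    groups$unit_id)
  deg <- igraph::degree(g)
  expect_true(all(deg <= bound[names(deg)]))
})

test_that("fixture networks have 18 nodes and deterministic construction", {
  fx <- tiger_fixture()
  gl1 <- build_network(fx$counts, fx$attributes, "landscape")
  gl2 <- build_network(fx$counts, fx$attributes, "landscape")
  gr <- build_network(fx$counts, fx$attributes, "reserves")
  expect_equal(igraph::vcount(gl1), 18)
  expect_equal(igraph::vcount(gr), 18)
  expect_identical(igraph::as_edgelist(gl1), igraph::as_edgelist(gl2))
})

test_that("edge lists round-trip through TSV and GraphML export works", {
  g <- two_triangles_bridge()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(g, path)
  g2 <- read_edge_list(path)
  expect_equal(igraph::vcount(g2), igraph::vcount(g))
  expect_equal(igraph::ecount(g2), igraph::ecount(g))
  gml <- withr::local_tempfile(fileext = ".graphml")
  export_graphml(g, gml)
  expect_true(file.exists(gml))
})

test_that("alternative wiring rules produce ring and star subgroup graphs", {
  groups <- tibble::tibble(unit_id = LETTERS[1:5], community = 1L)
  expect_equal(nrow(build_intra_links(groups, rule = "ring")), 5)
  expect_equal(nrow(build_intra_links(groups, rule = "star")), 4)
  expect_equal(nrow(build_intra_links(groups, rule = "clique")), 10)
})
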