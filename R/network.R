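#' Percentage increase between two census counts
#'
#' @param count_a Baseline count (must be positive).
#' @param count_b Later count.
#' @return `100 * (count_b - count_a) / count_a`, vectorized.
#' @export
percentage_increase <- function(count_a, count_b) {
  if (any(count_a <= 0)) {
    abort("baseline count must be positive: percentage growth is undefined at 0",
          class = "qicd_undefined_growth")
  }
  100 * (count_b - count_a) / count_a
}

#' Bin units into growth subgroups by percentage population increase
#'
#' The default binning is an equal-count quantile split on the t0 -> t1
#' percentage increase, ties broken by `unit_id` (lexicographic) for
#' reproducibility; explicit `boundaries` override with half-open bins
#' `[-Inf, b1), [b1, b2), ..., [bk, Inf)`. Group 1 is the slowest-growing.
#'
#' @param counts Species-count table with `unit_id`, `count_t0`, `count_t1`.
#' @param n_groups Number of groups (default 4); ignored when `boundaries` given.
#' @param boundaries Optional strictly increasing numeric cut points (percent).
#' @return A tibble `unit_id`, `pct_increase`, `community` (1-based group id).
#' @export
assign_growth_groups <- function(counts, n_groups = 4L, boundaries = NULL) {
  stopifnot(all(c("unit_id", "count_t0", "count_t1") %in% names(counts)))
  growth <- percentage_increase(counts$count_t0, counts$count_t1)
  if (!is.null(boundaries)) {
    if (is.unsorted(boundaries, strictly = TRUE)) {
      abort("boundaries must be strictly increasing")
    }
    group <- findInterval(growth, boundaries) + 1L
  } else {
    if (n_groups < 1L) abort("n_groups must be at least 1")
    if (length(unique(growth)) < n_groups) {
      abort("fewer distinct growth values than groups: degenerate grouping",
            class = "qicd_degenerate_grouping")
    }
    ord <- order(growth, counts$unit_id)
    sizes <- split_sizes(nrow(counts), n_groups)
    group <- integer(nrow(counts))
    group[ord] <- rep(seq_len(n_groups), times = sizes)
  }
  tibble::tibble(
    unit_id = counts$unit_id,
    pct_increase = growth,
    community = as.integer(group)
  )
}

# Wire the members of one subgroup according to the pluggable link rule.
wire_group <- function(members, rule = c("clique", "ring", "star")) {
  rule <- match.arg(rule)
  members <- sort(members)
  k <- length(members)
  if (k < 2L) return(tibble::tibble(from = character(), to = character()))
  pairs <- switch(rule,
    clique = {
      idx <- utils::combn(k, 2)
      tibble::tibble(from = members[idx[1, ]], to = members[idx[2, ]])
    },
    ring = {
      if (k == 2L) {
        tibble::tibble(from = members[1], to = members[2])
      } else {
        nxt <- c(seq_len(k)[-1], 1L)
        tibble::tibble(from = pmin(members, members[nxt]),
                       to = pmax(members, members[nxt]))
      }
    },
    star = tibble::tibble(from = members[1], to = members[-1])
  )
  pairs
}

# Normalize an edge tibble: lexicographic within row, sorted rows, no dups.
normalize_edges <- function(edges) {
  if (!nrow(edges)) return(tibble::tibble(from = character(), to = character()))
  edges |>
    dplyr::transmute(from = pmin(.data$from, .data$to),
                     to = pmax(.data$from, .data$to)) |>
    dplyr::filter(.data$from != .data$to) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$from, .data$to)
}

#' Intra-links: wire each growth subgroup
#'
#' @param groups A partition tibble (`unit_id`, `community`), e.g. from
#'   [assign_growth_groups()].
#' @param rule Wiring rule within each subgroup: `"clique"` (default),
#'   `"ring"`, or `"star"`.
#' @return An edge tibble (`from`, `to`), lexicographically normalized.
#' @export
build_intra_links <- function(groups, rule = "clique") {
  edges <- groups |>
    dplyr::group_by(.data$community) |>
    dplyr::group_map(~ wire_group(.x$unit_id, rule)) |>
    purrr::list_rbind()
  normalize_edges(edges)
}

#' Inter-links: wire landscape classes or reserve-count classes
#'
#' `mode = "landscape"` wires each landscape class; `mode = "reserves"`
#' bifurcates units into \{reserve_count >= threshold\} versus the rest and
#' wires each of the two classes.
#'
#' @param attrs Unit-attribute table.
#' @param mode `"landscape"` or `"reserves"`.
#' @param reserve_threshold Threshold for the reserve split (default 3).
#' @param rule Wiring rule, as in [build_intra_links()].
#' @return An edge tibble (`from`, `to`).
#' @export
build_inter_links <- function(attrs, mode = c("landscape", "reserves"),
                              reserve_threshold = 3L, rule = "clique") {
  mode <- match.arg(mode)
  cls <- switch(mode,
    landscape = attrs$landscape_class,
    reserves = ifelse(attrs$reserve_count >= reserve_threshold, 1L, 2L)
  )
  edges <- tibble::tibble(unit_id = attrs$unit_id, community = as.integer(cls)) |>
    build_intra_links(rule = rule)
  edges
}

#' Build a benchmark unit network
#'
#' The edge set is the union of growth-subgroup intra-links and attribute
#' inter-links, with duplicates collapsed; the result is a simple, undirected,
#' unweighted igraph whose vertex names are the unit ids.
#'
#' @param counts Species-count table.
#' @param attrs Unit-attribute table (same units).
#' @param mode `"landscape"` or `"reserves"` (selects the inter-link rule).
#' @param n_groups,boundaries Passed to [assign_growth_groups()].
#' @param reserve_threshold Passed to [build_inter_links()].
#' @param rule Wiring rule for both link families.
#' @return An igraph object with a `name` graph attribute set to `mode`.
#' @export
build_network <- function(counts, attrs, mode = c("landscape", "reserves"),
                          n_groups = 4L, boundaries = NULL,
                          reserve_threshold = 3L, rule = "clique") {
  mode <- match.arg(mode)
  if (!setequal(counts$unit_id, attrs$unit_id)) {
    abort("unit mismatch between count and attribute tables",
          class = "qicd_unit_mismatch")
  }
  groups <- assign_growth_groups(counts, n_groups = n_groups, boundaries = boundaries)
  intra <- build_intra_links(groups, rule = rule)
  inter <- build_inter_links(attrs, mode = mode,
                             reserve_threshold = reserve_threshold, rule = rule)
  edges <- normalize_edges(dplyr::bind_rows(intra, inter))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = sort(counts$unit_id))
  igraph::graph_attr(g, "name") <- mode
  g
}

#' Write / read an edge list as two-column TSV
#'
#' Rows are lexicographically ordered within and across rows; a `#` provenance
#' header records the graph name and edge count.
#'
#' @param graph An igraph object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  el <- igraph::as_edgelist(graph)
  edges <- normalize_edges(tibble::tibble(from = el[, 1], to = el[, 2]))
  header <- sprintf("# qicd edge list | graph=%s | edges=%d",
                    igraph::graph_attr(graph, "name") %||% "graph", nrow(edges))
  writeLines(c(header, paste(edges$from, edges$to, sep = "\t")), path)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  edges <- readr::read_tsv(path, comment = "#", col_names = c("from", "to"),
                           show_col_types = FALSE)
  nodes <- sort(unique(c(edges$from, edges$to)))
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
}

#' Export a unit network as GraphML
#'
#' @param graph An igraph object.
#' @param path Output path (.graphml).
#' @return `path`, invisibly.
#' @export
export_graphml <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}
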