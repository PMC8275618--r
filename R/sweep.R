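#' Sweep the mixing parameter over repeated runs
#'
#' For each value of the mixing parameter mu the chosen algorithm is restarted
#' `config$runs` times with per-run seeds derived from the master seed by a
#' counter scheme, and the per-mu mean, maximum and standard deviation of
#' modularity are recorded.
#'
#' @param graph The unit network.
#' @param algorithm `"binqiea"`, `"numqiea"`, or `"qdmpso"`.
#' @param mu_grid Mixing-parameter grid; default `seq(0, 0.5, by = 0.05)`
#'   (11 points).
#' @param config A [qicd_config()]; `runs` and `seed` drive the restarts.
#' @return A tibble of class `qicd_sweep` with one row per mu
#'   (`dataset`, `algorithm`, `mu`, `mean_q`, `max_q`, `sd_q`,
#'   `mean_communities`) and the per-run results attached as attribute
#'   `"runs"` (columns `dataset`, `algorithm`, `mu`, `run`, `seed`, `q`,
#'   `n_communities`).
#' @export
sweep_mixing_parameter <- function(graph,
                                   algorithm = c("binqiea", "numqiea", "qdmpso"),
                                   mu_grid = seq(0, 0.5, by = 0.05),
                                   config = qicd_config()) {
  algorithm <- match.arg(algorithm)
  gd <- graph_data(graph)
  per_run <- purrr::map(seq_along(mu_grid), function(i_mu) {
    purrr::map(seq_len(config$runs), function(r) {
      cfg <- config
      cfg$mu <- mu_grid[i_mu]
      cfg$seed <- derive_seed(config$seed, (i_mu - 1L) * config$runs + r)
      fit <- detect_communities(graph, algorithm, cfg)
      tibble::tibble(dataset = gd$graph_name, algorithm = algorithm,
                     mu = mu_grid[i_mu], run = r, seed = cfg$seed,
                     q = fit$modularity, n_communities = fit$n_communities)
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()

  summary <- per_run |>
    dplyr::group_by(.data$dataset, .data$algorithm, .data$mu) |>
    dplyr::summarise(mean_q = mean(.data$q), max_q = max(.data$q),
                     sd_q = if (dplyr::n() > 1) sd(.data$q) else 0,
                     mean_communities = mean(.data$n_communities),
                     .groups = "drop")
  attr(summary, "runs") <- per_run
  class(summary) <- c("qicd_sweep", class(summary))
  summary
}
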