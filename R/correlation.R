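#' Aggregate a per-unit driver series by community
#'
#' @param attrs Unit-attribute table (one row per unit).
#' @param partition Partition tibble (`unit_id`, `community`).
#' @param var Name of the driver column in `attrs`.
#' @param statistic `"mean"` (anomalies, percentage increases) or `"sum"`
#'   (counts).
#' @return A tibble `community`, `value`, ordered by community id.
#' @export
aggregate_by_community <- function(attrs, partition, var,
                                   statistic = c("mean", "sum")) {
  statistic <- match.arg(statistic)
  if (!var %in% names(attrs)) {
    abort(sprintf("driver column '%s' not found in attribute table", var),
          class = "qicd_missing_column")
  }
  fn <- switch(statistic, mean = mean, sum = sum)
  dplyr::inner_join(dplyr::select(attrs, "unit_id", value = dplyr::all_of(var)),
                    dplyr::select(partition, "unit_id", "community"),
                    by = "unit_id") |>
    dplyr::group_by(.data$community) |>
    dplyr::summarise(value = fn(.data$value), .groups = "drop") |>
    dplyr::arrange(.data$community)
}

#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors of equal length (at least 3), each with nonzero
#'   variance.
#' @return Pearson's r.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 3) abort("need at least 3 observations for a correlation")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("correlation undefined: zero variance", class = "qicd_zero_variance")
  }
  as.numeric(cor(x, y))
}

#' Two-tailed p-value for a Pearson correlation
#'
#' Uses the exact small-sample t transform `t = r * sqrt(n - 2) / sqrt(1 -
#' r^2)` against the t-distribution with `n - 2` degrees of freedom.
#'
#' @param r Pearson correlation, `|r| < 1`.
#' @param n Number of paired observations (>= 3).
#' @return Two-tailed p-value in `(0, 1]`.
#' @export
pearson_p_value <- function(r, n) {
  if (n < 3) abort("need n >= 3 for a p-value")
  if (abs(r) >= 1) abort("|r| must be < 1 for the t transform")
  t_stat <- r * sqrt(n - 2) / sqrt(1 - r^2)
  2 * pt(-abs(t_stat), df = n - 2)
}

# Internal: one correlation row from two per-community aggregate vectors.
correlation_row <- function(dataset, variable, pair, agg_x, agg_y, statistic) {
  r <- pearson_r(agg_x$value, agg_y$value)
  n <- nrow(agg_x)
  tibble::tibble(dataset = dataset, variable = variable, pair = pair,
                 statistic = statistic, r = r, p = pearson_p_value(r, n), n = n)
}

#' Correlate community-aggregated drivers across timestamps or intervals
#'
#' For the landscape dataset, each climate anomaly (temperature,
#' precipitation) is aggregated per community at the three census timestamps
#' and the three timestamp pairs (I2-I1, I3-I1, I3-I2) are correlated. For the
#' reserves dataset, the per-interval reserve additions (summed per community)
#' and the average percentage increase in reserve core area (mean per
#' community) are correlated between interval 1 (2010-2014) and interval 2
#' (2014-2018). Every result carries the number of communities `n`, because
#' with as few as 4 aggregate points any r is fragile.
#'
#' @param attrs Unit-attribute table.
#' @param partition Partition tibble (communities from a detection run).
#' @param dataset_mode `"landscape"` or `"reserves"`.
#' @return A tibble of class `qicd_correlation`: `dataset`, `variable`,
#'   `pair`, `statistic`, `r`, `p`, `n`, with the per-community aggregate
#'   vectors attached as attribute `"aggregates"`.
#' @export
correlate_drivers <- function(attrs, partition,
                              dataset_mode = c("landscape", "reserves")) {
  dataset_mode <- match.arg(dataset_mode)
  k <- length(unique(partition$community))
  if (k < 3) {
    abort("need at least 3 communities to correlate community aggregates",
          class = "qicd_too_few_communities")
  }
  aggs <- list()
  rows <- list()
  if (dataset_mode == "landscape") {
    for (var in c("temp_anomaly", "precip_anomaly")) {
      cols <- paste0(var, c("_t0", "_t1", "_t2"))
      missing <- setdiff(cols, names(attrs))
      if (length(missing)) {
        abort(sprintf("attribute table lacks columns: %s",
                      paste(missing, collapse = ", ")),
              class = "qicd_missing_column")
      }
      a <- lapply(cols, function(cl) aggregate_by_community(attrs, partition, cl, "mean"))
      names(a) <- c("I1", "I2", "I3")
      aggs[[var]] <- a
      rows[[length(rows) + 1L]] <- correlation_row("landscape", var, "I2I1",
                                                   a$I2, a$I1, "mean")
      rows[[length(rows) + 1L]] <- correlation_row("landscape", var, "I3I1",
                                                   a$I3, a$I1, "mean")
      rows[[length(rows) + 1L]] <- correlation_row("landscape", var, "I3I2",
                                                   a$I3, a$I2, "mean")
    }
  } else {
    specs <- list(
      list(var = "reserve_count",
           cols = c("reserve_count_interval_1", "reserve_count_interval_2"),
           stat = "sum"),
      list(var = "core_area_pct_increase",
           cols = c("core_area_interval_1", "core_area_interval_2"),
           stat = "mean"))
    for (sp in specs) {
      missing <- setdiff(sp$cols, names(attrs))
      if (length(missing)) {
        abort(sprintf("attribute table lacks columns: %s",
                      paste(missing, collapse = ", ")),
              class = "qicd_missing_column")
      }
      a <- lapply(sp$cols, function(cl)
        aggregate_by_community(attrs, partition, cl, sp$stat))
      names(a) <- c("I1", "I2")
      aggs[[sp$var]] <- a
      rows[[length(rows) + 1L]] <- correlation_row("reserves", sp$var, "I2I1",
                                                   a$I2, a$I1, sp$stat)
    }
  }
  out <- purrr::list_rbind(rows)
  attr(out, "aggregates") <- aggs
  class(out) <- c("qicd_correlation", class(out))
  out
}
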