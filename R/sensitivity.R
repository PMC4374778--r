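#' Reciprocal-overlap threshold sweep
#'
#' Recomputes the inherited CNV rate over a grid of RO thresholds and
#' averages it across families, per source. Because matching is monotone in
#' the threshold, each curve is non-increasing; how steeply it falls
#' measures how imprecise a caller's breakpoints are (calls with exact
#' breakpoints survive any threshold).
#'
#' @param calls A call tibble covering all pedigree members.
#' @param pedigree A quartet pedigree tibble.
#' @param thresholds Strictly increasing grid of RO thresholds in `(0, 1]`.
#' @return A tibble of class `cnv_sweep` with columns `source`,
#'   `threshold`, `rate` (mean across families).
#' @export
ro_sweep <- function(calls, pedigree, thresholds = seq(0.1, 0.9, by = 0.1)) {
  if (length(thresholds) < 2) abort("`thresholds` must contain at least 2 values.")
  if (any(diff(thresholds) <= 0)) {
    abort("`thresholds` must be strictly increasing (no duplicates).")
  }
  purrr::walk(thresholds, check_threshold)
  curve <- purrr::map_dfr(thresholds, function(t) {
    rates <- inherited_rate(calls, pedigree, t)
    dplyr::summarise(
      dplyr::group_by(rates, .data$source),
      threshold = t, rate = mean(.data$rate, na.rm = TRUE), .groups = "drop"
    )
  })
  curve <- dplyr::arrange(curve, .data$source, .data$threshold)
  class(curve) <- c("cnv_sweep", class(curve))
  curve
}

#' Mean slope of a sweep curve
#'
#' The mean of the successive finite differences
#' `(rate[i+1] - rate[i]) / (t[i+1] - t[i])`, per source. On a uniform
#' threshold grid this equals the endpoint slope
#' `(rate_last - rate_first) / (t_last - t_first)`. More negative slopes
#' indicate poorer breakpoint resolution.
#'
#' @param curve A sweep tibble from [ro_sweep()] (or any tibble with
#'   `threshold` and `rate` columns, optionally grouped by `source`).
#' @return A tibble with one row per source and a `mean_slope` column.
#' @export
mean_slope <- function(curve) {
  if (!all(c("threshold", "rate") %in% names(curve))) {
    abort("`curve` must have `threshold` and `rate` columns.")
  }
  if (!"source" %in% names(curve)) curve$source <- NA_character_
  out <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(curve), .data$source),
    mean_slope = {
      if (dplyr::n() < 2) abort("mean_slope() needs at least 2 sweep points.")
      o <- order(.data$threshold)
      mean(diff(.data$rate[o]) / diff(.data$threshold[o]))
    },
    .groups = "drop"
  )
  out
}

#' @rdname ro_sweep
#' @param x A `cnv_sweep` object.
#' @param ... Ignored.
#' @method autoplot cnv_sweep
#' @export
autoplot.cnv_sweep <- function(x, ...) {
  ggplot2::ggplot(
    tibble::as_tibble(x),
    ggplot2::aes(x = .data$threshold, y = .data$rate, colour = .data$source)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = "reciprocal-overlap threshold",
      y = "inherited CNV rate (mean across families)",
      colour = "caller"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname ro_sweep
#' @method glance cnv_sweep
#' @export
glance.cnv_sweep <- function(x, ...) {
  mean_slope(x)
}
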