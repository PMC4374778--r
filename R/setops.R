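#' Pairwise union / intersection of two callers
#'
#' Builds match components per sample from exactly two sources and emits
#' one call per kept component, spanning the component's extremes. The
#' union keeps every component (a call seen by either tool); the
#' intersection keeps only components containing both sources (a call
#' corroborated by both tools). The emitted call set is a normal call
#' table and can feed every downstream metric.
#'
#' @param calls A call tibble restricted (or restrictable) to two sources.
#' @param sources Character vector of the two source names to combine.
#' @param op `"union"` or `"intersection"`.
#' @param threshold RO threshold in `(0, 1]`.
#' @return A call tibble with `source` set to
#'   `"<a>.<op>.<b>"`.
#' @export
pairwise_setop <- function(calls, sources, op = c("union", "intersection"),
                           threshold = 0.7) {
  op <- match.arg(op)
  calls <- check_calls(calls)
  check_threshold(threshold)
  if (length(sources) != 2) abort("`sources` must name exactly two callers.")
  missing_src <- setdiff(sources, unique(calls$source))
  if (length(missing_src) > 0) {
    abort(sprintf("source \"%s\" not present in `calls`.", missing_src[1]))
  }
  sub <- calls[calls$source %in% sources, , drop = FALSE]
  comp <- summarize_components(match_components(sub, threshold))
  if (op == "intersection") {
    comp <- comp[comp$n_sources == 2, , drop = FALSE]
  }
  out <- tibble::tibble(
    chrom = comp$chrom, start = comp$start, end = comp$end,
    status = comp$status, sample_id = comp$sample_id,
    source = paste(sources[1], op, sources[2], sep = "."),
    score = NA_real_
  )
  sort_calls(out)
}

#' Inherited rate of a combined (union/intersection) call set
#'
#' Applies [pairwise_setop()] per sample and scores the combined call set
#' with the per-family inherited CNV rate. Also reports the mean per-sample
#' call count of the combined set — the discovery/consistency trade-off:
#' intersections are typically more consistent but smaller.
#'
#' @inheritParams pairwise_setop
#' @param pedigree A quartet pedigree tibble.
#' @return A tibble with one row per family (`source`, `family_id`, `n1`,
#'   `n2`, `shared`, `rate`) plus a constant `mean_calls` column (mean
#'   per-sample call count of the combined set).
#' @export
combined_inherited_rate <- function(calls, sources, op, pedigree,
                                    threshold = 0.7) {
  pedigree <- check_pedigree(pedigree)
  combined <- pairwise_setop(calls, sources, op, threshold)
  rates <- inherited_rate(combined, pedigree, threshold)
  n_samples <- dplyr::n_distinct(
    calls$sample_id[calls$source %in% sources]
  )
  rates$mean_calls <- nrow(combined) / n_samples
  rates
}
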