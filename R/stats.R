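#' Descriptive call-set statistics
#'
#' Per (sample, source) call set: number of calls, mean call size, mean
#' distance between adjacent calls, and the fraction of the genome covered
#' by the union of the call intervals. These are the standard summary
#' statistics used to characterize caller behaviour (fragmentation, size
#' over-estimation, excess call counts).
#'
#' Adjacent distance is the gap `start_next - end_prev` between consecutive
#' calls on the same chromosome, pooled across chromosomes; negative gaps
#' (overlaps between calls of opposite status) are clamped to 0. With fewer
#' than two calls on every chromosome the mean distance is reported as `NA`.
#'
#' @param calls A call tibble (ideally already normalized with
#'   [merge_adjacent()]).
#' @param context A [genome_context()]; every chromosome carrying a call
#'   must have a length.
#' @param by_status If `TRUE`, adjacent distances are computed within
#'   gain/loss groups instead of across all calls on a chromosome.
#' @return A tibble with one row per (sample, source) group and columns
#'   `n_calls`, `mean_size`, `mean_adjacent_distance`, `genome_coverage`.
#' @export
callset_stats <- function(calls, context, by_status = FALSE) {
  calls <- check_calls(calls)
  if (!inherits(context, "genome_context")) {
    abort("`context` must be a genome_context object.")
  }
  missing_chrom <- setdiff(unique(calls$chrom), names(context$chrom_lengths))
  if (length(missing_chrom) > 0) {
    abort(sprintf(
      "no chromosome length for \"%s\" in `context`.", missing_chrom[1]
    ))
  }
  genome_size <- sum(context$chrom_lengths)
  groups <- dplyr::group_by(
    calls, dplyr::across(dplyr::any_of(c("sample_id", "source")))
  )
  dplyr::summarise(
    groups,
    n_calls = dplyr::n(),
    mean_size = mean(.data$end - .data$start),
    mean_adjacent_distance = mean_gap(
      .data$chrom, .data$start, .data$end,
      if (by_status) .data$status else NULL
    ),
    genome_coverage = union_width(.data$chrom, .data$start, .data$end) / genome_size,
    .groups = "drop"
  )
}

# Mean clamped gap between consecutive calls per chromosome (optionally per
# status), pooled; NA when no chromosome has two calls.
mean_gap <- function(chrom, start, end, status = NULL) {
  key <- if (is.null(status)) chrom else paste(chrom, status)
  gaps <- unlist(lapply(split(seq_along(start), key), function(i) {
    if (length(i) < 2) return(numeric(0))
    o <- i[order(start[i], end[i])]
    pmax(0, start[o][-1] - end[o][-length(o)])
  }), use.names = FALSE)
  if (length(gaps) == 0) return(NA_real_)
  mean(gaps)
}

# Total number of bases covered by the union of the intervals.
union_width <- function(chrom, start, end) {
  sum(unlist(lapply(split(seq_along(start), chrom), function(i) {
    o <- i[order(start[i], end[i])]
    s <- start[o]; e <- cummax(end[o])
    new_run <- c(TRUE, s[-1] >= e[-length(e)])
    run <- cumsum(new_run)
    run_start <- tapply(s, run, min)
    run_end <- tapply(e, run, max)
    sum(run_end - run_start)
  }), use.names = FALSE))
}
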