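#' Merge adjacent same-status calls
#'
#' Callers without a statistical test for inter-call gaps fragment single
#' biological CNVs into runs of nearby calls. Within each
#' (sample, source, chromosome, status) group, consecutive calls separated
#' by a gap smaller than `max_gap` — including overlapping calls, whose gap
#' is negative — are replaced by one call spanning the group's extremes.
#' The operation is idempotent and independent of input order; calls of
#' opposite status are never merged, even when they overlap.
#'
#' @param calls A call tibble.
#' @param max_gap Gap threshold in bp; calls with `start_next - end_prev <
#'   max_gap` are merged. The conventional default is 5 kb.
#' @return A merged, sorted call tibble. Scores are dropped from merged
#'   calls (set to `NA`); singleton calls keep theirs.
#' @export
merge_adjacent <- function(calls, max_gap = 5000) {
  calls <- check_calls(calls)
  if (max_gap < 0) abort("`max_gap` must be >= 0.")
  if (nrow(calls) == 0) return(calls)
  has_score <- "score" %in% names(calls)
  clustered <- cluster_gaps(calls, max_gap)
  out <- dplyr::summarise(
    dplyr::group_by(
      clustered,
      dplyr::across(dplyr::any_of(c("sample_id", "source"))),
      .data$chrom, .data$status, .data$.cluster
    ),
    start = min(.data$start),
    end = max(.data$end),
    score = if (has_score) ifelse(dplyr::n() == 1, .data$score[1], NA_real_) else NA_real_,
    .groups = "drop"
  )
  out <- dplyr::select(out, -".cluster")
  if (!has_score) out$score <- NULL
  sort_calls(out)
}

# Assign each call to a merge cluster within its (ids, chrom, status) group:
# sorted by start, a call opens a new cluster when its start is at least
# max_gap beyond the running maximum end of the current cluster.
cluster_gaps <- function(calls, max_gap) {
  grouped <- dplyr::group_by(
    calls,
    dplyr::across(dplyr::any_of(c("sample_id", "source"))),
    .data$chrom, .data$status
  )
  grouped <- dplyr::arrange(grouped, .data$start, .data$end, .by_group = TRUE)
  out <- dplyr::mutate(
    grouped,
    .cluster = {
      prev_max_end <- dplyr::lag(cummax(.data$end))
      cumsum(is.na(prev_max_end) | (.data$start - prev_max_end >= max_gap))
    }
  )
  dplyr::ungroup(out)
}

#' Fraction of calls affected by adjacent-call merging
#'
#' The fraction of input calls that participate in at least one merge event
#' at the given gap threshold, i.e. that end up in a merge cluster of two or
#' more calls. High values are symptomatic of call fragmentation.
#'
#' @inheritParams merge_adjacent
#' @return A fraction in `[0, 1]`; 0 for an empty call set.
#' @export
merged_fraction <- function(calls, max_gap = 5000) {
  calls <- check_calls(calls)
  if (nrow(calls) == 0) return(0)
  clustered <- cluster_gaps(calls, max_gap)
  sizes <- dplyr::add_count(
    clustered,
    dplyr::across(dplyr::any_of(c("sample_id", "source"))),
    .data$chrom, .data$status, .data$.cluster,
    name = ".cluster_size"
  )
  mean(sizes$.cluster_size >= 2)
}
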