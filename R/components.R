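#' Cross-caller match components
#'
#' Builds, per (sample, chromosome, status), the graph whose vertices are
#' all calls from all sources and whose edges are RO matches at the working
#' threshold, and returns its connected components. RO matching is not
#' transitive; the connected-component closure is the only symmetric
#' completion that never splits a matched pair, and it is independent of
#' call order and source labels. Components are the unit counted in
#' multi-caller agreement (Venn) tables.
#'
#' @param calls A call tibble, typically several sources for one or more
#'   samples.
#' @param threshold RO threshold in `(0, 1]`.
#' @return `calls` with an integer `.component` column; component ids are
#'   unique across the whole table.
#' @export
match_components <- function(calls, threshold = 0.7) {
  calls <- check_calls(calls)
  check_threshold(threshold)
  if (nrow(calls) == 0) {
    calls$.component <- integer(0)
    return(calls)
  }
  calls$.row <- seq_len(nrow(calls))
  key <- paste(calls$sample_id, calls$chrom, calls$status, sep = "\r")
  comp <- integer(nrow(calls))
  offset <- 0L
  for (idx in split(seq_len(nrow(calls)), key)) {
    n <- length(idx)
    s <- calls$start[idx]; e <- calls$end[idx]
    ov <- pmax(0, outer(e, e, pmin) - outer(s, s, pmax))
    minro <- ov / outer(e - s, e - s, pmax)
    adj <- minro >= threshold
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                             diag = FALSE)
    membership <- igraph::components(g)$membership
    comp[idx] <- membership + offset
    offset <- offset + max(membership)
  }
  calls$.component <- comp
  calls$.row <- NULL
  calls
}

#' Summarize match components
#'
#' One row per component of a [match_components()] result: the spanning
#' interval over its member calls, the shared status, and the set of
#' contributing sources (sorted, `"+"`-joined — the Venn cell the component
#' falls into).
#'
#' @param components A call tibble carrying a `.component` column.
#' @return A tibble with columns `sample_id`, `.component`, `chrom`,
#'   `start`, `end`, `status`, `n_calls`, `n_sources`, `sources`.
#' @export
summarize_components <- function(components) {
  if (!".component" %in% names(components)) {
    abort("`components` must come from match_components() (missing .component).")
  }
  dplyr::summarise(
    dplyr::group_by(components, .data$sample_id, .data$.component),
    chrom = .data$chrom[1],
    start = min(.data$start),
    end = max(.data$end),
    status = .data$status[1],
    n_calls = dplyr::n(),
    n_sources = dplyr::n_distinct(.data$source),
    sources = paste(sort(unique(.data$source)), collapse = "+"),
    .groups = "drop"
  )
}
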