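#' Multi-caller agreement (Venn) counts
#'
#' Counts, per sample, the match components falling in each Venn cell
#' (cell = the sorted set of sources contributing to a component) and
#' averages the counts over samples. With `filter = "inherited"` each
#' per-source call set is first reduced to its Mendelian-consistent subset
#' ([inherited_calls()] per source and family), restricting the table to
#' the twin samples.
#'
#' @param calls A call tibble with several sources.
#' @param threshold RO threshold in `(0, 1]`.
#' @param filter `"raw"` (all calls) or `"inherited"` (Mendelian-filtered;
#'   requires `pedigree`).
#' @param pedigree A quartet pedigree tibble, required for
#'   `filter = "inherited"`.
#' @return A tibble with columns `sources` (the Venn cell) and `mean_n`
#'   (mean component count per sample).
#' @export
venn_counts <- function(calls, threshold = 0.7,
                        filter = c("raw", "inherited"), pedigree = NULL) {
  calls <- check_calls(calls)
  check_threshold(threshold)
  filter <- match.arg(filter)
  if (filter == "inherited") {
    if (is.null(pedigree)) abort("filter = \"inherited\" requires a `pedigree`.")
    pedigree <- check_pedigree(pedigree)
    calls <- mendelian_subset(calls, pedigree, threshold)
    samples <- c(rbind(pedigree$twin1, pedigree$twin2))
  } else {
    samples <- unique(calls$sample_id)
  }
  per_sample_venn(calls, samples, threshold)
}

# Inherited subsets for every family, stacked (twin samples only).
mendelian_subset <- function(calls, pedigree, threshold) {
  purrr::map_dfr(seq_len(nrow(pedigree)), function(i) {
    q <- pedigree[i, , drop = FALSE]
    fam_calls <- calls[calls$sample_id %in%
                         c(q$twin1, q$twin2, q$parent1, q$parent2), ,
                       drop = FALSE]
    inherited_calls(fam_calls, q, threshold)
  })
}

per_sample_venn <- function(calls, samples, threshold) {
  per_sample <- purrr::map_dfr(samples, function(s) {
    cs <- calls[calls$sample_id == s, , drop = FALSE]
    comp <- summarize_components(match_components(cs, threshold))
    if (nrow(comp) == 0) {
      return(tibble::tibble(sample_id = s, sources = character(), n = integer()))
    }
    dplyr::count(dplyr::mutate(comp, sample_id = s), .data$sample_id,
                 .data$sources)
  })
  if (nrow(per_sample) == 0) {
    return(tibble::tibble(sources = character(), mean_n = numeric()))
  }
  full <- tidyr::complete(
    per_sample,
    sample_id = samples, sources = unique(per_sample$sources),
    fill = list(n = 0L)
  )
  dplyr::summarise(dplyr::group_by(full, .data$sources),
                   mean_n = mean(.data$n), .groups = "drop")
}

#' Venn table before/after Mendelian filtering
#'
#' Cell-wise comparison of the agreement table computed on the raw calls and
#' after Mendelian filtering, both over the twin samples, with the per-cell
#' loss ratio `1 - filtered / raw`. Cells dominated by one caller's false
#' positives lose most of their mass under the filter.
#'
#' @inheritParams venn_counts
#' @return A tibble with columns `sources`, `mean_n_raw`,
#'   `mean_n_inherited`, `loss_ratio` (`NA` for cells empty before
#'   filtering).
#' @export
venn_table <- function(calls, pedigree, threshold = 0.7) {
  pedigree <- check_pedigree(pedigree)
  calls <- check_calls(calls)
  twins <- c(rbind(pedigree$twin1, pedigree$twin2))
  raw <- venn_counts(calls[calls$sample_id %in% twins, , drop = FALSE],
                     threshold, "raw")
  inh <- venn_counts(calls, threshold, "inherited", pedigree)
  out <- dplyr::full_join(
    dplyr::rename(raw, mean_n_raw = "mean_n"),
    dplyr::rename(inh, mean_n_inherited = "mean_n"),
    by = "sources"
  )
  out <- tidyr::replace_na(out, list(mean_n_raw = 0, mean_n_inherited = 0))
  dplyr::mutate(
    out,
    loss_ratio = ifelse(.data$mean_n_raw > 0,
                        1 - .data$mean_n_inherited / .data$mean_n_raw,
                        NA_real_)
  )
}
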