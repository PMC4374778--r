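#' Calls of one set validated by another
#'
#' Returns the subset of `a` for which at least one call in `b` matches
#' under [ro_match()] at the given threshold (same chromosome, same status,
#' both overlap fractions at or above the threshold). Matching multiplicity
#' is many-to-one: a single call in `b` may validate several calls in `a`,
#' which keeps the operation robust to call fragmentation.
#'
#' @param a,b Call tibbles (single sample and source each).
#' @param threshold RO threshold in `(0, 1]`.
#' @return The matched rows of `a`, in their original order.
#' @export
shared_calls <- function(a, b, threshold = 0.7) {
  a <- check_calls(a, "a")
  b <- check_calls(b, "b")
  check_threshold(threshold)
  a[best_min_ro(a, b) >= threshold, , drop = FALSE]
}

#' Mendelian-consistent (inherited) calls of a twin quartet
#'
#' A twin call is considered inherited when it is matched in the co-twin's
#' call set and in the union of the two parents' call sets ("both twins and
#' at least one parent"). Computed per source when the call table carries
#' several callers.
#'
#' @param calls A call tibble containing the four quartet members (matched
#'   by `sample_id`).
#' @param quartet A one-row pedigree tibble (`family_id`, `twin1`, `twin2`,
#'   `parent1`, `parent2`).
#' @param threshold RO threshold in `(0, 1]`.
#' @return The inherited subset of the two twins' calls (rows of `calls`).
#' @export
inherited_calls <- function(calls, quartet, threshold = 0.7) {
  calls <- check_calls(calls)
  check_threshold(threshold)
  quartet <- check_pedigree(quartet)
  if (nrow(quartet) != 1) abort("`quartet` must be a single pedigree row.")
  by_source <- split(calls, factor(calls$source, exclude = NULL))
  out <- lapply(by_source, function(cs) {
    t1 <- cs[cs$sample_id == quartet$twin1, , drop = FALSE]
    t2 <- cs[cs$sample_id == quartet$twin2, , drop = FALSE]
    parents <- cs[cs$sample_id %in% c(quartet$parent1, quartet$parent2), ,
                  drop = FALSE]
    i1 <- t1[best_min_ro(t1, t2) >= threshold &
               best_min_ro(t1, parents) >= threshold, , drop = FALSE]
    i2 <- t2[best_min_ro(t2, t1) >= threshold &
               best_min_ro(t2, parents) >= threshold, , drop = FALSE]
    dplyr::bind_rows(i1, i2)
  })
  dplyr::bind_rows(out)
}

#' Inherited CNV rate per family
#'
#' The fraction of twin calls validated by both twins and at least one
#' parent: with `I1`, `I2` the inherited subsets of the two twins' call
#' sets of sizes `N1`, `N2`, the rate is `(|I1| + |I2|) / (N1 + N2)`. When
#' both twins validate symmetrically this reduces to the familiar
#' `2 * shared / (N1 + N2)` with `shared = (|I1| + |I2|) / 2`.
#'
#' @param calls A call tibble covering all pedigree members (per source).
#' @param pedigree A quartet pedigree tibble.
#' @param threshold RO threshold in `(0, 1]`.
#' @return A tibble with one row per (source, family): `n1`, `n2`, `shared`,
#'   `rate`. The rate is `NA` when a family's twins have no calls.
#' @export
inherited_rate <- function(calls, pedigree, threshold = 0.7) {
  calls <- check_calls(calls)
  pedigree <- check_pedigree(pedigree)
  check_threshold(threshold)
  sources <- unique(calls$source)
  by_source <- split(calls, factor(calls$source, levels = sources,
                                   exclude = NULL))
  empty <- calls[0, , drop = FALSE]
  purrr::map_dfr(seq_along(by_source), function(si) {
    cs <- by_source[[si]]
    by_sample <- split(cs, cs$sample_id)
    purrr::map_dfr(seq_len(nrow(pedigree)), function(i) {
      q <- pedigree[i, , drop = FALSE]
      t1 <- by_sample[[q$twin1]] %||% empty
      t2 <- by_sample[[q$twin2]] %||% empty
      parents <- dplyr::bind_rows(by_sample[[q$parent1]],
                                  by_sample[[q$parent2]])
      i1 <- sum(best_min_ro(t1, t2) >= threshold &
                  best_min_ro(t1, parents) >= threshold)
      i2 <- sum(best_min_ro(t2, t1) >= threshold &
                  best_min_ro(t2, parents) >= threshold)
      n1 <- nrow(t1)
      n2 <- nrow(t2)
      tibble::tibble(
        source = sources[si], family_id = q$family_id,
        n1 = n1, n2 = n2,
        shared = (i1 + i2) / 2,
        rate = if (n1 + n2 > 0) (i1 + i2) / (n1 + n2) else NA_real_
      )
    })
  })
}

#' Pairwise CNV sharing rate
#'
#' The symmetric sharing rate between two samples' call sets:
#' `(|shared_calls(a, b)| + |shared_calls(b, a)|) / (|a| + |b|)`.
#'
#' @inheritParams shared_calls
#' @return A fraction in `[0, 1]`, or `NA` when both sets are empty.
#' @export
pair_sharing_rate <- function(a, b, threshold = 0.7) {
  a <- check_calls(a, "a")
  b <- check_calls(b, "b")
  check_threshold(threshold)
  n <- nrow(a) + nrow(b)
  if (n == 0) return(NA_real_)
  (sum(best_min_ro(a, b) >= threshold) + sum(best_min_ro(b, a) >= threshold)) / n
}
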