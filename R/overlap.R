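#' Reciprocal overlap between CNV calls
#'
#' For two intervals A and B on the same chromosome with `o` overlapping
#' bases, the reciprocal overlap (RO) is the tuple
#' `(o / size(A), o / size(B))`. Calls on different chromosomes have RO
#' `(0, 0)`. `reciprocal_overlap()` is vectorized over rows: `a` and `b`
#' must have the same number of rows (or one of them a single row, which is
#' recycled).
#'
#' @param a,b Call tibbles with columns `chrom`, `start`, `end` (and
#'   `status` for [ro_match()]).
#' @return A tibble with columns `r_a` and `r_b`, both in `[0, 1]`.
#' @export
#' @examples
#' a <- tibble::tibble(chrom = "1", start = 100, end = 200, status = "gain")
#' b <- tibble::tibble(chrom = "1", start = 150, end = 250, status = "gain")
#' reciprocal_overlap(a, b) # (0.5, 0.5)
reciprocal_overlap <- function(a, b) {
  a <- check_calls(a, "a")
  b <- check_calls(b, "b")
  n <- recycle_n(nrow(a), nrow(b))
  ia <- rep_len(seq_len(max(nrow(a), 1L)), n)
  ib <- rep_len(seq_len(max(nrow(b), 1L)), n)
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(tibble::tibble(r_a = numeric(), r_b = numeric()))
  }
  ov <- pmax(0, pmin(a$end[ia], b$end[ib]) - pmax(a$start[ia], b$start[ib]))
  ov[a$chrom[ia] != b$chrom[ib]] <- 0
  tibble::tibble(
    r_a = ov / (a$end[ia] - a$start[ia]),
    r_b = ov / (b$end[ib] - b$start[ib])
  )
}

recycle_n <- function(na, nb) {
  if (na == nb) return(na)
  if (na == 1L) return(nb)
  if (nb == 1L) return(na)
  abort("`a` and `b` must have the same number of rows (or one row).")
}

#' RO-threshold matching of two calls
#'
#' Two calls match at threshold `t` when they lie on the same chromosome,
#' carry the same gain/loss status, and both reciprocal-overlap fractions
#' are at least `t` — equivalently, overlap divided by the larger call size
#' is at least `t`. Matching is symmetric and monotone in the threshold.
#'
#' @inheritParams reciprocal_overlap
#' @param threshold RO threshold in `(0, 1]`; 0.70 is the conventional
#'   default for CNV concordance work.
#' @return A logical vector, one element per compared pair.
#' @export
ro_match <- function(a, b, threshold = 0.7) {
  check_threshold(threshold)
  ro <- reciprocal_overlap(a, b)
  n <- nrow(ro)
  if (n == 0) return(logical(0))
  ia <- rep_len(seq_len(nrow(a)), n)
  ib <- rep_len(seq_len(nrow(b)), n)
  same_status <- a$status[ia] == b$status[ib]
  same_status & pmin(ro$r_a, ro$r_b) >= threshold
}

# For each call in `a`, the best (largest) min-RO fraction achieved against
# any same-chromosome, same-status call in `b`. min(r_a, r_b) equals
# overlap / max(size_a, size_b), which is what is computed here.
best_min_ro <- function(a, b) {
  out <- numeric(nrow(a))
  if (nrow(a) == 0 || nrow(b) == 0) return(out)
  key_a <- paste(a$chrom, a$status)
  key_b <- paste(b$chrom, b$status)
  for (k in intersect(unique(key_a), unique(key_b))) {
    ia <- which(key_a == k)
    ib <- which(key_b == k)
    ov <- pmax(
      0,
      outer(a$end[ia], b$end[ib], pmin) - outer(a$start[ia], b$start[ib], pmax)
    )
    denom <- outer(a$end[ia] - a$start[ia], b$end[ib] - b$start[ib], pmax)
    out[ia] <- apply(ov / denom, 1, max)
  }
  out
}
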