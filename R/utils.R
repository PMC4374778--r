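# Internal validators shared across the package.

# Validate (and lightly normalize) a CNV call table. Returns the tibble with
# the canonical columns present; errors on violated invariants.
check_calls <- function(calls, arg = "calls") {
  if (!is.data.frame(calls)) {
    abort(sprintf("`%s` must be a data frame of CNV calls.", arg))
  }
  needed <- c("chrom", "start", "end", "status")
  missing <- setdiff(needed, names(calls))
  if (length(missing) > 0) {
    abort(sprintf(
      "`%s` is missing required column(s): %s.",
      arg, paste(missing, collapse = ", ")
    ))
  }
  calls <- tibble::as_tibble(calls)
  if (!"sample_id" %in% names(calls)) calls$sample_id <- NA_character_
  if (!"source" %in% names(calls)) calls$source <- NA_character_
  if (nrow(calls) == 0) {
    return(calls)
  }
  if (!is.numeric(calls$start) || !is.numeric(calls$end)) {
    abort(sprintf("`%s`: start/end must be numeric (0-based half-open).", arg))
  }
  bad <- which(calls$end <= calls$start)
  if (length(bad) > 0) {
    abort(sprintf(
      "`%s`: end must be greater than start (first offending row: %d).",
      arg, bad[1]
    ))
  }
  bad_status <- which(!calls$status %in% STATUS_LEVELS)
  if (length(bad_status) > 0) {
    abort(sprintf(
      "`%s`: status must be one of {gain, loss} (first offending row: %d has \"%s\").",
      arg, bad_status[1], calls$status[bad_status[1]]
    ))
  }
  calls
}

check_threshold <- function(threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      is.na(threshold) || threshold <= 0 || threshold > 1) {
    abort("`threshold` must be a single number in (0, 1].")
  }
  invisible(threshold)
}

check_pedigree <- function(pedigree) {
  if (!is.data.frame(pedigree)) abort("`pedigree` must be a data frame.")
  needed <- c("family_id", "twin1", "twin2", "parent1", "parent2")
  missing <- setdiff(needed, names(pedigree))
  if (length(missing) > 0) {
    abort(sprintf(
      "`pedigree` is missing required column(s): %s.",
      paste(missing, collapse = ", ")
    ))
  }
  members <- c(t(as.matrix(pedigree[, c("twin1", "twin2", "parent1", "parent2")])))
  per_row_dup <- apply(
    pedigree[, c("twin1", "twin2", "parent1", "parent2")], 1,
    function(x) anyDuplicated(x) > 0
  )
  if (any(per_row_dup)) {
    abort(sprintf(
      "`pedigree`: the four members of family \"%s\" are not distinct.",
      pedigree$family_id[which(per_row_dup)[1]]
    ))
  }
  dup <- members[duplicated(members)]
  if (length(dup) > 0) {
    abort(sprintf(
      "`pedigree`: sample \"%s\" appears in more than one family.", dup[1]
    ))
  }
  if (anyDuplicated(pedigree$family_id) > 0) {
    abort("`pedigree`: family_id values must be unique.")
  }
  tibble::as_tibble(pedigree)
}

# Canonical call ordering used throughout: (chrom, start, end).
sort_calls <- function(calls) {
  dplyr::arrange(calls, .data$chrom, .data$start, .data$end)
}

# Group columns present among sample_id/source; lets interval operations work
# both on single call sets and on stacked multi-sample tables.
id_cols <- function(calls) {
  intersect(c("sample_id", "source"), names(calls))
}
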