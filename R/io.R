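#' Read a BED-like CNV call file
#'
#' Reads a tab-separated CNV call file with at least four columns
#' (chrom, start, end, status). A header line is detected automatically
#' (a non-numeric second field on the first line). Coordinates are 0-based
#' half-open internally; files using 1-based inclusive starts can be
#' converted on the fly with `one_based = TRUE`. Status strings are matched
#' case-insensitively, with `dup`/`duplication` mapped to `gain` and
#' `del`/`deletion` mapped to `loss`. A numeric fifth column, when present,
#' is read as a per-call score.
#'
#' @param path Path to a tab-separated call file.
#' @param sample_id,source Optional identifiers attached to every call;
#'   callers typically emit one file per sample per tool.
#' @param one_based If `TRUE`, input starts are 1-based inclusive and are
#'   shifted to the 0-based half-open convention on read.
#' @param strip_chr If `TRUE` (default), a leading `"chr"` prefix is removed
#'   from chromosome names so that mixed dialects compare equal.
#'
#' @return A tibble of calls with columns `chrom`, `start`, `end`, `status`,
#'   `sample_id`, `source`, `score`, sorted by (chrom, start, end).
#' @export
#' @examples
#' tf <- tempfile(fileext = ".bed")
#' writeLines(c("1\t1000\t5000\tgain", "1\t8000\t9000\tdel"), tf)
#' read_cnv_calls(tf, sample_id = "S1", source = "toolA")
read_cnv_calls <- function(path, sample_id = NULL, source = NULL,
                           one_based = FALSE, strip_chr = TRUE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  offset <- 0L
  if (length(lines) > 0) {
    first <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    if (length(first) >= 2 && is.na(suppressWarnings(as.numeric(first[2])))) {
      lines <- lines[-1]
      offset <- 1L
    }
  }
  if (length(lines) == 0) {
    return(empty_calls(sample_id, source))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 4)) {
    abort(sprintf(
      "%s: line %d has %d field(s); at least 4 (chrom, start, end, status) are required.",
      path, which(nf < 4)[1] + offset, nf[which(nf < 4)[1]]
    ))
  }
  chrom <- vapply(fields, `[`, character(1), 1)
  start_raw <- vapply(fields, `[`, character(1), 2)
  end_raw <- vapply(fields, `[`, character(1), 3)
  status_raw <- vapply(fields, `[`, character(1), 4)
  score_raw <- vapply(fields, function(x) if (length(x) >= 5) x[5] else NA_character_,
                      character(1))

  start <- suppressWarnings(as.numeric(start_raw))
  end <- suppressWarnings(as.numeric(end_raw))
  bad <- which(is.na(start) | is.na(end) | start != floor(start) | end != floor(end))
  if (length(bad) > 0) {
    abort(sprintf(
      "%s: line %d has a malformed coordinate (\"%s\", \"%s\").",
      path, bad[1] + offset, start_raw[bad[1]], end_raw[bad[1]]
    ))
  }
  if (one_based) start <- start - 1
  bad <- which(end <= start)
  if (length(bad) > 0) {
    abort(sprintf(
      "%s: line %d has end <= start (%s >= %s is required).",
      path, bad[1] + offset, end_raw[bad[1]], start_raw[bad[1]]
    ))
  }
  status <- normalize_status(status_raw)
  bad <- which(is.na(status))
  if (length(bad) > 0) {
    abort(sprintf(
      "%s: line %d has unknown status \"%s\" (expected gain/loss/dup/del).",
      path, bad[1] + offset, status_raw[bad[1]]
    ))
  }
  if (strip_chr) chrom <- sub("^chr", "", chrom)
  calls <- tibble::tibble(
    chrom = chrom, start = start, end = end, status = status,
    sample_id = sample_id %||% NA_character_,
    source = source %||% NA_character_,
    score = suppressWarnings(as.numeric(score_raw))
  )
  sort_calls(calls)
}

empty_calls <- function(sample_id = NULL, source = NULL) {
  tibble::tibble(
    chrom = character(), start = numeric(), end = numeric(),
    status = character(),
    sample_id = if (is.null(sample_id)) character() else character(),
    source = character(), score = numeric()
  )
}

normalize_status <- function(x) {
  x <- tolower(trimws(x))
  out <- rep(NA_character_, length(x))
  out[x %in% c("gain", "dup", "duplication")] <- "gain"
  out[x %in% c("loss", "del", "deletion")] <- "loss"
  out
}

#' Write a CNV call table as BED-like TSV
#'
#' Writes `chrom`, `start`, `end`, `status` (0-based half-open) plus a fifth
#' `score` column when any score is present. The output round-trips through
#' [read_cnv_calls()] exactly. An empty call set produces a header-only file.
#'
#' @param calls A call tibble (see [read_cnv_calls()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cnv_calls <- function(calls, path) {
  calls <- check_calls(calls)
  has_score <- "score" %in% names(calls) && any(!is.na(calls$score))
  calls <- sort_calls(calls)
  header <- c("chrom", "start", "end", "status", if (has_score) "score")
  body <- character(0)
  if (nrow(calls) > 0) {
    cols <- list(
      calls$chrom,
      sprintf("%.0f", calls$start),
      sprintf("%.0f", calls$end),
      calls$status
    )
    if (has_score) {
      sc <- ifelse(is.na(calls$score), ".", format(calls$score, trim = TRUE))
      cols <- c(cols, list(sc))
    }
    body <- do.call(paste, c(cols, sep = "\t"))
  }
  writeLines(c(paste(header, collapse = "\t"), body), path)
  invisible(path)
}

#' Read a twin-quartet pedigree file
#'
#' A quartet pedigree is a TSV with header columns `family_id`, `twin1`,
#' `twin2`, `parent1`, `parent2` — one monozygotic twin pair plus both
#' parents per row. Sample identifiers must be distinct within a family and
#' unique across families.
#'
#' @param path Path to the pedigree TSV.
#' @return A tibble with one row per quartet.
#' @export
read_pedigree <- function(path) {
  ped <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  check_pedigree(ped)
}

#' @rdname read_pedigree
#' @param pedigree A pedigree tibble.
#' @export
write_pedigree <- function(pedigree, path) {
  pedigree <- check_pedigree(pedigree)
  utils::write.table(pedigree, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a UCSC-style cytoband table and extract centromeres
#'
#' `read_cytoband()` reads the five-column cytoband TSV (chrom, start, end,
#' band, stain; no header). `centromeres_from_cytoband()` reduces it to one
#' centromere interval per chromosome, defined as the span of the rows with
#' Giemsa stain `"acen"`.
#'
#' @param path Path to a cytoband TSV.
#' @param strip_chr Remove a leading `"chr"` prefix from chromosome names.
#' @return A tibble (`chrom`, `start`, `end`, `band`, `stain`), or for
#'   `centromeres_from_cytoband()` one row per chromosome with the
#'   centromere interval.
#' @export
read_cytoband <- function(path, strip_chr = TRUE) {
  cb <- utils::read.delim(
    path, header = FALSE, sep = "\t",
    col.names = c("chrom", "start", "end", "band", "stain"),
    colClasses = c("character", "numeric", "numeric", "character", "character")
  )
  if (strip_chr) cb$chrom <- sub("^chr", "", cb$chrom)
  tibble::as_tibble(cb)
}

#' @rdname read_cytoband
#' @param cytoband A cytoband tibble as returned by `read_cytoband()`.
#' @export
centromeres_from_cytoband <- function(cytoband) {
  acen <- dplyr::filter(cytoband, .data$stain == "acen")
  if (nrow(acen) == 0) abort("cytoband table contains no rows with stain \"acen\".")
  dplyr::summarise(
    dplyr::group_by(acen, .data$chrom),
    start = min(.data$start), end = max(.data$end), .groups = "drop"
  )
}

#' Assemble a genome context
#'
#' Bundles the per-chromosome information needed by call-set statistics and
#' sequence-feature annotation: chromosome lengths, optional centromere
#' intervals, and optional nucleotide sequence.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#' @param centromere Optional tibble (`chrom`, `start`, `end`) of centromere
#'   intervals, e.g. from [centromeres_from_cytoband()].
#' @param sequence Optional named character vector (or `Biostrings`
#'   `DNAStringSet`) of chromosome sequences, used for GC content.
#' @return A list of class `genome_context`.
#' @export
genome_context <- function(chrom_lengths, centromere = NULL, sequence = NULL) {
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths)))) {
    abort("`chrom_lengths` must be a named vector (names are chromosomes).")
  }
  if (any(chrom_lengths <= 0)) abort("chromosome lengths must be positive.")
  if (!is.null(centromere)) {
    centromere <- tibble::as_tibble(centromere)
    bad <- setdiff(centromere$chrom, names(chrom_lengths))
    if (length(bad) > 0) {
      abort(sprintf("centromere table references unknown chromosome \"%s\".", bad[1]))
    }
    lens <- chrom_lengths[centromere$chrom]
    if (any(centromere$start < 0) || any(centromere$end > lens)) {
      abort("centromere intervals must lie within [0, chrom_length].")
    }
  }
  if (!is.null(sequence) && inherits(sequence, "DNAStringSet")) {
    sequence <- setNames(as.character(sequence), names(sequence))
  }
  structure(
    list(chrom_lengths = chrom_lengths, centromere = centromere,
         sequence = sequence),
    class = "genome_context"
  )
}

#' @rdname genome_context
#' @param path Path to an (uncompressed or gzipped) FASTA file; requires the
#'   Biostrings package.
#' @param cytoband_path Optional cytoband TSV used for centromeres.
#' @param strip_chr Remove a leading `"chr"` prefix from sequence names.
#' @export
genome_context_from_fasta <- function(path, cytoband_path = NULL,
                                      strip_chr = TRUE) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("genome_context_from_fasta() requires the Biostrings package.")
  }
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (strip_chr) names(seqs) <- sub("^chr", "", names(seqs))
  centromere <- NULL
  if (!is.null(cytoband_path)) {
    centromere <- centromeres_from_cytoband(read_cytoband(cytoband_path, strip_chr))
  }
  genome_context(
    chrom_lengths = setNames(Biostrings::width(seqs), names(seqs)),
    centromere = centromere,
    sequence = setNames(as.character(seqs), names(seqs))
  )
}
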