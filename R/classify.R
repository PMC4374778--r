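#' Build the familial-relationship pair table
#'
#' Assembles the observations for the familial relationship classification
#' test: one twin-twin pair per family, two child-parent pairs per family
#' (twin1 vs each parent — the twins are genetically identical, so which
#' twin is used is immaterial), and `n_unrelated` random cross-family pairs,
#' and computes the pairwise sharing rate for each. With the default nine
#' families this yields the classic 9 + 18 + 9 = 36 observations.
#'
#' @param calls A call tibble covering all pedigree members; computed per
#'   source when several callers are present.
#' @param pedigree A quartet pedigree tibble.
#' @param threshold RO threshold for sharing-rate computation.
#' @param n_unrelated Number of random unrelated pairs (default: one per
#'   family). Unrelated pairs never draw two members of the same family.
#' @param seed Optional integer seed making the unrelated-pair draw
#'   reproducible; the same pairs are used for every source.
#' @param pc_twin Which twin anchors the child-parent pairs (`"twin1"` or
#'   `"twin2"`).
#' @return A tibble with columns `source`, `sample_a`, `sample_b`,
#'   `true_label` (factor: twin, parent_child, unrelated), `sharing_rate`.
#' @export
build_pair_table <- function(calls, pedigree, threshold = 0.7,
                             n_unrelated = nrow(pedigree), seed = NULL,
                             pc_twin = c("twin1", "twin2")) {
  calls <- check_calls(calls)
  pedigree <- check_pedigree(pedigree)
  check_threshold(threshold)
  pc_twin <- match.arg(pc_twin)
  if (n_unrelated > 0 && nrow(pedigree) < 2) {
    abort("unrelated pairs require at least two families.")
  }

  pairs <- dplyr::bind_rows(
    tibble::tibble(sample_a = pedigree$twin1, sample_b = pedigree$twin2,
                   true_label = "twin"),
    tibble::tibble(sample_a = pedigree[[pc_twin]], sample_b = pedigree$parent1,
                   true_label = "parent_child"),
    tibble::tibble(sample_a = pedigree[[pc_twin]], sample_b = pedigree$parent2,
                   true_label = "parent_child")
  )
  if (n_unrelated > 0) {
    members <- tidyr::pivot_longer(
      pedigree, dplyr::all_of(c("twin1", "twin2", "parent1", "parent2")),
      names_to = "role", values_to = "sample_id"
    )[, c("family_id", "sample_id")]
    cross <- tidyr::expand_grid(a = seq_len(nrow(members)), b = seq_len(nrow(members)))
    cross <- cross[cross$a < cross$b &
                     members$family_id[cross$a] != members$family_id[cross$b], ]
    if (n_unrelated > nrow(cross)) {
      abort("`n_unrelated` exceeds the number of available cross-family pairs.")
    }
    draw <- function() cross[sample.int(nrow(cross), n_unrelated), ]
    picked <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
    pairs <- dplyr::bind_rows(pairs, tibble::tibble(
      sample_a = members$sample_id[picked$a],
      sample_b = members$sample_id[picked$b],
      true_label = "unrelated"
    ))
  }
  pairs$true_label <- factor(pairs$true_label, levels = REL_LEVELS)

  by_source <- split(calls, factor(calls$source, exclude = NULL))
  purrr::imap_dfr(by_source, function(cs, src) {
    rates <- purrr::map2_dbl(pairs$sample_a, pairs$sample_b, function(x, y) {
      pair_sharing_rate(
        cs[cs$sample_id == x, , drop = FALSE],
        cs[cs$sample_id == y, , drop = FALSE],
        threshold
      )
    })
    dplyr::bind_cols(tibble::tibble(source = src), pairs,
                     tibble::tibble(sharing_rate = rates))
  })
}

#' Cluster pairwise sharing rates into relationship classes
#'
#' Runs k-means (k = 3, multiple restarts) on the one-dimensional sharing
#' rates and labels the clusters by the rank of their mean rate: highest
#' mean = twin, middle = parent-child, lowest = unrelated. When the rates
#' contain fewer than `k` distinct values the clustering is degenerate: all
#' observations are assigned to one class and flagged.
#'
#' @param pairs A pair table from [build_pair_table()] (one or several
#'   sources).
#' @param k Number of clusters (3 relationship classes).
#' @param seed Optional seed for the k-means restarts.
#' @param nstart Number of random restarts; the solution with the lowest
#'   within-cluster sum of squares is kept.
#' @return `pairs` with columns `pred_label` (factor over the same levels)
#'   and `degenerate` (logical, constant per source) appended.
#' @export
kmeans_relationship <- function(pairs, k = 3, seed = NULL, nstart = 10) {
  if (!all(c("sharing_rate") %in% names(pairs))) {
    abort("`pairs` must contain a `sharing_rate` column.")
  }
  if (!"source" %in% names(pairs)) pairs$source <- NA_character_
  run <- function(df) {
    if (nrow(df) < k) abort("fewer observations than clusters.")
    x <- df$sharing_rate
    if (length(unique(x)) < k) {
      warn("fewer distinct sharing rates than clusters; degenerate clustering.")
      df$pred_label <- factor(REL_LEVELS[1], levels = REL_LEVELS)
      df$degenerate <- TRUE
      return(df)
    }
    km <- kmeans(x, centers = k, nstart = nstart)
    # highest-mean cluster -> twin, lowest -> unrelated
    rank_by_mean <- rank(-km$centers[, 1], ties.method = "first")
    df$pred_label <- factor(REL_LEVELS[rank_by_mean[km$cluster]],
                            levels = REL_LEVELS)
    df$degenerate <- FALSE
    df
  }
  by_source <- split(pairs, factor(pairs$source, exclude = NULL))
  wrapped <- function() purrr::map_dfr(by_source, run)
  out <- if (is.null(seed)) wrapped() else withr::with_seed(seed, wrapped())
  tibble::as_tibble(out)
}

#' Support-weighted F1 score
#'
#' Per-class F1 = 2PR / (P + R) from per-class precision and recall,
#' averaged with weights proportional to the true-class support. A class
#' with no predicted and no true members contributes F1 = 0.
#'
#' @param truth,predicted Equal-length vectors (or factors) of class labels.
#' @return A single number in `[0, 1]`.
#' @export
weighted_f1 <- function(truth, predicted) {
  if (length(truth) == 0 || length(truth) != length(predicted)) {
    abort("`truth` and `predicted` must be non-empty and of equal length.")
  }
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  classes <- union(unique(truth), unique(predicted))
  f1s <- vapply(classes, function(cl) {
    tp <- sum(truth == cl & predicted == cl)
    fp <- sum(truth != cl & predicted == cl)
    fn <- sum(truth == cl & predicted != cl)
    if (tp == 0) return(0)
    p <- tp / (tp + fp)
    r <- tp / (tp + fn)
    2 * p * r / (p + r)
  }, numeric(1))
  support <- vapply(classes, function(cl) sum(truth == cl), numeric(1))
  sum(f1s * support) / sum(support)
}

#' Familial relationship classification test
#'
#' End-to-end wrapper: builds the pair table, clusters the sharing rates,
#' and scores each caller with the support-weighted F1 against the true
#' relationship labels. An F1 of 1 means the caller's sharing rates
#' perfectly separate twins, parent-child pairs and unrelated pairs; low
#' values indicate unspecific (random or systematically biased) calls.
#'
#' @inheritParams build_pair_table
#' @return A tibble with one row per source: `f1`, `degenerate`.
#' @export
relationship_f1 <- function(calls, pedigree, threshold = 0.7,
                            n_unrelated = nrow(pedigree), seed = NULL) {
  pairs <- build_pair_table(calls, pedigree, threshold, n_unrelated, seed)
  pred <- kmeans_relationship(pairs, seed = seed)
  dplyr::summarise(
    dplyr::group_by(pred, .data$source),
    f1 = weighted_f1(.data$true_label, .data$pred_label),
    degenerate = any(.data$degenerate),
    .groups = "drop"
  )
}
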