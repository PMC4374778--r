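#' Virtual-caller error profile
#'
#' Describes how a simulated caller corrupts a sample's true CNV genome:
#' false positives (a Poisson count of spurious calls per sample), false
#' negatives (a per-CNV miss probability), Gaussian breakpoint jitter,
#' call fragmentation (a true CNV emitted as two fragments separated by a
#' sub-5-kb gap, so gap-threshold merging can heal it), and multiplicative
#' size distortion (read-depth callers tend to over-estimate CNV size).
#'
#' @param name Caller name (the `source` on emitted calls).
#' @param fp_rate Expected false calls per sample (Poisson mean, >= 0).
#' @param fn_prob Per-true-CNV miss probability in `[0, 1]`.
#' @param jitter_sd Breakpoint Gaussian noise SD in bp (>= 0).
#' @param frag_prob Probability that a detected CNV is emitted as two
#'   fragments, in `[0, 1]`.
#' @param size_bias Multiplicative size distortion (1 = unbiased).
#' @return A one-row tibble.
#' @export
caller_profile <- function(name, fp_rate = 0, fn_prob = 0, jitter_sd = 0,
                           frag_prob = 0, size_bias = 1) {
  stopifnot(
    fp_rate >= 0, fn_prob >= 0, fn_prob <= 1,
    jitter_sd >= 0, frag_prob >= 0, frag_prob <= 1, size_bias > 0
  )
  tibble::tibble(
    name = name, fp_rate = fp_rate, fn_prob = fn_prob,
    jitter_sd = jitter_sd, frag_prob = frag_prob, size_bias = size_bias
  )
}

#' Default virtual-caller panel
#'
#' Four archetypal error profiles spanning the behaviours real CNV callers
#' exhibit: a precise low-noise caller, a read-depth caller with broad
#' breakpoints and size over-estimation, a false-positive-prone caller,
#' and a heavily fragmenting caller.
#'
#' @return A tibble of four [caller_profile()] rows.
#' @export
default_caller_profiles <- function() {
  dplyr::bind_rows(
    caller_profile("precise", fp_rate = 5, fn_prob = 0.05,
                   jitter_sd = 50, frag_prob = 0.02),
    caller_profile("rd_broad", fp_rate = 10, fn_prob = 0.10,
                   jitter_sd = 300, frag_prob = 0.05, size_bias = 1.3),
    caller_profile("fp_prone", fp_rate = 60, fn_prob = 0.25,
                   jitter_sd = 150, frag_prob = 0.05, size_bias = 0.9),
    caller_profile("frag_prone", fp_rate = 40, fn_prob = 0.20,
                   jitter_sd = 400, frag_prob = 0.5)
  )
}

#' Simulation configuration
#'
#' Study-design and genetics parameters for the synthetic twin-quartet
#' simulator: number of families, per-parent CNV burden, log-normal CNV
#' size distribution, gain/loss mix, genome layout, Mendelian transmission
#' probability, a shared population CNV pool (so unrelated individuals
#' share some CNVs, as in real cohorts), and the virtual-caller panel.
#'
#' @param n_families Number of twin quartets (default 9, the classic
#'   quartet-study design).
#' @param n_cnvs_per_parent Private CNVs placed per parent genome.
#' @param cnv_size_log_mean,cnv_size_log_sd Log-normal size parameters
#'   (bp); defaults give a median of ~8 kb.
#' @param gain_fraction Probability a simulated CNV is a gain.
#' @param chrom_lengths Named vector of chromosome lengths (default: five
#'   20-Mb chromosomes, a desk-scale stand-in genome).
#' @param transmission_prob Probability a parental CNV is transmitted to
#'   the child (0.5 for an unlinked heterozygous variant).
#' @param pool_size Number of CNVs in the shared population pool.
#' @param carrier_freq Probability a parent carries each pool CNV.
#' @param profiles Virtual-caller panel ([default_caller_profiles()]).
#' @param seed Integer seed fixing the entire study.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(n_families = 9,
                              n_cnvs_per_parent = 80,
                              cnv_size_log_mean = log(8000),
                              cnv_size_log_sd = 0.7,
                              gain_fraction = 0.5,
                              chrom_lengths = setNames(rep(2e7, 5),
                                                       as.character(1:5)),
                              transmission_prob = 0.5,
                              pool_size = 40,
                              carrier_freq = 0.3,
                              profiles = default_caller_profiles(),
                              seed = 1) {
  stopifnot(
    n_families >= 1, n_cnvs_per_parent >= 0,
    gain_fraction >= 0, gain_fraction <= 1,
    transmission_prob >= 0, transmission_prob <= 1,
    pool_size >= 0, carrier_freq >= 0, carrier_freq <= 1,
    all(chrom_lengths > 0), !is.null(names(chrom_lengths))
  )
  structure(
    list(
      n_families = n_families, n_cnvs_per_parent = n_cnvs_per_parent,
      cnv_size_log_mean = cnv_size_log_mean,
      cnv_size_log_sd = cnv_size_log_sd,
      gain_fraction = gain_fraction, chrom_lengths = chrom_lengths,
      transmission_prob = transmission_prob, pool_size = pool_size,
      carrier_freq = carrier_freq, profiles = profiles, seed = seed
    ),
    class = "sim_config"
  )
}

# Place n non-overlapping CNVs, avoiding `existing` intervals, by rejection
# sampling (bounded retries).
place_cnvs <- function(n, config, existing = NULL, id_prefix = "cnv") {
  if (n == 0) {
    return(tibble::tibble(cnv_id = character(), chrom = character(),
                          start = numeric(), end = numeric(),
                          status = character()))
  }
  lens <- config$chrom_lengths
  # per-chromosome occupied intervals, kept as plain vectors for speed
  occ_s <- occ_e <- setNames(vector("list", length(lens)), names(lens))
  for (ch in names(lens)) occ_s[[ch]] <- occ_e[[ch]] <- numeric(0)
  if (!is.null(existing) && nrow(existing) > 0) {
    for (ch in unique(existing$chrom)) {
      sel <- existing$chrom == ch
      occ_s[[ch]] <- existing$start[sel]
      occ_e[[ch]] <- existing$end[sel]
    }
  }
  chrom_out <- character(n); start_out <- end_out <- numeric(n)
  placed <- 0L
  attempts <- 0L
  max_attempts <- 200L * n
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      abort("genome too small to place the requested non-overlapping CNVs.")
    }
    size <- max(50, round(rlnorm(1, config$cnv_size_log_mean,
                                 config$cnv_size_log_sd)))
    chrom <- sample(names(lens), 1, prob = lens)
    if (size >= lens[[chrom]]) next
    start <- floor(runif(1, 0, lens[[chrom]] - size))
    end <- start + size
    if (any(start < occ_e[[chrom]] & occ_s[[chrom]] < end)) next
    occ_s[[chrom]] <- c(occ_s[[chrom]], start)
    occ_e[[chrom]] <- c(occ_e[[chrom]], end)
    placed <- placed + 1L
    chrom_out[placed] <- chrom
    start_out[placed] <- start
    end_out[placed] <- end
  }
  tibble::tibble(
    cnv_id = paste0(id_prefix, "_", seq_len(n)),
    chrom = chrom_out, start = start_out, end = end_out,
    status = ifelse(runif(n) < config$gain_fraction, "gain", "loss")
  )
}

# Greedy pass keeping only CNVs that do not overlap an already-kept CNV.
keep_nonoverlapping <- function(genome) {
  if (nrow(genome) <= 1) return(genome)
  genome <- genome[order(genome$chrom, genome$start, genome$end), ]
  keep <- logical(nrow(genome))
  last_end <- list()
  for (i in seq_len(nrow(genome))) {
    ch <- genome$chrom[i]
    prev <- last_end[[ch]] %||% -Inf
    if (genome$start[i] >= prev) {
      keep[i] <- TRUE
      last_end[[ch]] <- genome$end[i]
    }
  }
  genome[keep, , drop = FALSE]
}

#' Simulate the true genomes of a twin-quartet cohort
#'
#' Each parent receives private non-overlapping CNVs plus draws from a
#' shared population pool; each parental CNV transmits to the child with
#' `transmission_prob`; the second twin's true genome is an exact copy of
#' the first (monozygotic twins). De novo CNVs are not simulated.
#'
#' @param config A [simulation_config()].
#' @return A list with `genomes` (tibble: `sample_id`, `family_id`, `role`,
#'   `cnv_id`, `chrom`, `start`, `end`, `status`) and `pedigree`.
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_truth_impl(config))
}

simulate_truth_impl <- function(config) {
  pool <- place_cnvs(config$pool_size, config, id_prefix = "pool")
  fams <- paste0("F", seq_len(config$n_families))
  pedigree <- tibble::tibble(
    family_id = fams,
    twin1 = paste0(fams, "_t1"), twin2 = paste0(fams, "_t2"),
    parent1 = paste0(fams, "_p1"), parent2 = paste0(fams, "_p2")
  )
  genomes <- purrr::map_dfr(seq_len(config$n_families), function(i) {
    fam <- fams[i]
    parent_genome <- function(who) {
      carried <- pool[runif(nrow(pool)) < config$carrier_freq, , drop = FALSE]
      private <- place_cnvs(config$n_cnvs_per_parent, config,
                            existing = carried,
                            id_prefix = paste0(fam, "_", who))
      dplyr::bind_rows(carried, private)
    }
    p1 <- parent_genome("p1")
    p2 <- parent_genome("p2")
    transmit <- function(g) g[runif(nrow(g)) < config$transmission_prob, ,
                              drop = FALSE]
    child <- dplyr::bind_rows(transmit(p1), transmit(p2))
    child <- child[!duplicated(child$cnv_id), , drop = FALSE]
    child <- keep_nonoverlapping(child)
    dplyr::bind_rows(
      dplyr::mutate(child, sample_id = pedigree$twin1[i], role = "twin1"),
      dplyr::mutate(child, sample_id = pedigree$twin2[i], role = "twin2"),
      dplyr::mutate(p1, sample_id = pedigree$parent1[i], role = "parent1"),
      dplyr::mutate(p2, sample_id = pedigree$parent2[i], role = "parent2")
    ) |>
      dplyr::mutate(family_id = fam)
  })
  genomes <- genomes[, c("sample_id", "family_id", "role", "cnv_id",
                         "chrom", "start", "end", "status")]
  list(genomes = tibble::as_tibble(genomes), pedigree = pedigree)
}

#' Observe true genomes through a virtual caller
#'
#' Applies one [caller_profile()] to a table of true genomes: each true CNV
#' is missed with `fn_prob`; survivors get breakpoints jittered with
#' Gaussian noise and sizes scaled by `size_bias`; with `frag_prob` a
#' survivor is split into two fragments separated by a gap below 5 kb;
#' finally `Poisson(fp_rate)` false calls per sample are placed uniformly
#' with the configured size distribution. Every emitted call carries its
#' ground truth (`true_cnv_id`, `is_fp`, `fragment`).
#'
#' @param genomes A true-genome tibble from [simulate_truth()] (one or many
#'   samples).
#' @param profile A one-row [caller_profile()] tibble.
#' @param config The [simulation_config()] (for genome layout and FP size
#'   distribution).
#' @param seed Optional integer seed.
#' @return A call tibble with truth columns appended.
#' @export
observe_calls <- function(genomes, profile, config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"), nrow(profile) == 1)
  run <- function() observe_impl(genomes, profile, config)
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

observe_impl <- function(genomes, profile, config) {
  lens <- config$chrom_lengths
  g <- genomes
  n <- nrow(g)
  detected <- if (n > 0) runif(n) >= profile$fn_prob else logical(0)
  g <- g[detected, , drop = FALSE]
  n <- nrow(g)
  s <- g$start
  e <- g$end
  if (n > 0 && profile$jitter_sd > 0) {
    s <- s + round(rnorm(n, 0, profile$jitter_sd))
    e <- e + round(rnorm(n, 0, profile$jitter_sd))
  }
  if (n > 0 && profile$size_bias != 1) {
    centre <- (s + e) / 2
    half <- (e - s) * profile$size_bias / 2
    s <- round(centre - half)
    e <- round(centre + half)
  }
  if (n > 0) {
    s <- pmax(0, s)
    e <- pmin(lens[g$chrom], pmax(e, s + 1))
    s <- pmin(s, e - 1)
  }

  frag_draw <- if (n > 0) runif(n) < profile$frag_prob else logical(0)
  L <- e - s
  do_frag <- frag_draw & L >= 3000
  whole <- tibble::tibble(
    chrom = g$chrom[!do_frag], start = s[!do_frag], end = e[!do_frag],
    status = g$status[!do_frag], sample_id = g$sample_id[!do_frag],
    true_cnv_id = g$cnv_id[!do_frag], is_fp = FALSE, fragment = FALSE
  )
  frags <- NULL
  if (any(do_frag)) {
    fi <- which(do_frag)
    k <- length(fi)
    gap <- round(runif(k, 200, pmin(4500, L[fi] - 1000)))
    x <- s[fi] + round((L[fi] - gap) * runif(k, 0.3, 0.7))
    x <- pmax(s[fi] + 1, pmin(x, s[fi] + L[fi] - gap - 1))
    frags <- tibble::tibble(
      chrom = rep(g$chrom[fi], 2),
      start = c(s[fi], x + gap), end = c(x, e[fi]),
      status = rep(g$status[fi], 2), sample_id = rep(g$sample_id[fi], 2),
      true_cnv_id = rep(g$cnv_id[fi], 2), is_fp = FALSE, fragment = TRUE
    )
  }

  samples <- unique(genomes$sample_id)
  fp <- purrr::map_dfr(samples, function(smp) {
    n_fp <- rpois(1, profile$fp_rate)
    if (n_fp == 0) return(NULL)
    size <- pmax(50, round(rlnorm(n_fp, config$cnv_size_log_mean,
                                  config$cnv_size_log_sd)))
    chrom <- sample(names(lens), n_fp, replace = TRUE, prob = lens)
    size <- pmin(size, lens[chrom] - 1)
    start <- floor(runif(n_fp, 0, lens[chrom] - size))
    tibble::tibble(
      chrom = chrom, start = start, end = start + size,
      status = ifelse(runif(n_fp) < config$gain_fraction, "gain", "loss"),
      sample_id = smp, true_cnv_id = NA_character_, is_fp = TRUE,
      fragment = FALSE
    )
  })
  out <- dplyr::bind_rows(whole, frags, fp)
  if (nrow(out) == 0) {
    out <- tibble::tibble(
      chrom = character(), start = numeric(), end = numeric(),
      status = character(), sample_id = character(),
      true_cnv_id = character(), is_fp = logical(), fragment = logical()
    )
  }
  out$source <- rep(profile$name, nrow(out))
  out$score <- rep(NA_real_, nrow(out))
  sort_calls(out[, c("chrom", "start", "end", "status", "sample_id",
                     "source", "score", "true_cnv_id", "is_fp", "fragment")])
}

#' Simulate a complete synthetic quartet study
#'
#' Generates the true genomes of `n_families` twin quartets and observes
#' every sample through every virtual caller in the panel. The result
#' feeds every downstream metric and is fully reproducible from the seed.
#'
#' @param config A [simulation_config()].
#' @return A list of class `cnv_study`: `calls` (all sources stacked, with
#'   truth columns), `pedigree`, `genomes` (true genomes), `config`.
#' @export
simulate_study <- function(config = simulation_config()) {
  stopifnot(inherits(config, "sim_config"))
  truth <- simulate_truth(config)
  calls <- purrr::map_dfr(seq_len(nrow(config$profiles)), function(i) {
    observe_calls(truth$genomes, config$profiles[i, , drop = FALSE], config,
                  seed = config$seed + i)
  })
  structure(
    list(calls = calls, pedigree = truth$pedigree, genomes = truth$genomes,
         config = config),
    class = "cnv_study"
  )
}

#' @export
print.cnv_study <- function(x, ...) {
  cat(sprintf(
    "Synthetic quartet study: %d families, %d samples, %d caller(s), %d calls\n",
    nrow(x$pedigree), dplyr::n_distinct(x$genomes$sample_id),
    nrow(x$config$profiles), nrow(x$calls)
  ))
  invisible(x)
}
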