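# Brute-force reference implementations used as independent oracles.
# These deliberately avoid the package's vectorized/graph code paths.

# Plain union-find over n elements with an edge list (2-column matrix).
uf_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) {
    root <- i
    while (parent[root] != root) root <- parent[root]
    root
  }
  if (length(edges) > 0) {
    for (k in seq_len(nrow(edges))) {
      ri <- find(edges[k, 1]); rj <- find(edges[k, 2])
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# Scalar reciprocal overlap, written from the definition.
oracle_ro <- function(a, b) {
  if (a$chrom != b$chrom) return(c(0, 0))
  ov <- max(0, min(a$end, b$end) - max(a$start, b$start))
  c(ov / (a$end - a$start), ov / (b$end - b$start))
}

oracle_match <- function(a, b, t) {
  ro <- oracle_ro(a, b)
  a$chrom == b$chrom && a$status == b$status && min(ro) >= t
}

# All-pairs RO scan: rows of `a` with at least one match in `b`.
oracle_shared_idx <- function(a, b, t) {
  which(vapply(seq_len(nrow(a)), function(i) {
    any(vapply(seq_len(nrow(b)), function(j) {
      oracle_match(a[i, ], b[j, ], t)
    }, logical(1)))
  }, logical(1)))
}

# Union-find over the "gap < max_gap" adjacency graph, then min/max spans.
oracle_merge <- function(calls, max_gap) {
  if (nrow(calls) == 0) return(calls)
  key <- paste(calls$sample_id, calls$source, calls$chrom, calls$status,
               sep = "\r")
  pieces <- lapply(split(seq_len(nrow(calls)), key), function(idx) {
    n <- length(idx)
    edges <- NULL
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i < j) {
          gap <- max(calls$start[idx[i]], calls$start[idx[j]]) -
            min(calls$end[idx[i]], calls$end[idx[j]])
          if (gap < max_gap) edges <- rbind(edges, c(i, j))
        }
      }
    }
    comp <- uf_components(n, edges)
    do.call(rbind, lapply(unique(comp), function(cc) {
      rows <- idx[comp == cc]
      data.frame(
        sample_id = calls$sample_id[rows[1]], source = calls$source[rows[1]],
        chrom = calls$chrom[rows[1]], status = calls$status[rows[1]],
        start = min(calls$start[rows]), end = max(calls$end[rows]),
        stringsAsFactors = FALSE
      )
    }))
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$chrom, out$start, out$end), ]
  rownames(out) <- NULL
  out
}

# Per-base bitmap coverage.
oracle_coverage <- function(calls, chrom_lengths) {
  covered <- 0
  for (ch in names(chrom_lengths)) {
    bitmap <- logical(chrom_lengths[[ch]])
    sel <- which(calls$chrom == ch)
    for (i in sel) {
      bitmap[(calls$start[i] + 1):calls$end[i]] <- TRUE
    }
    covered <- covered + sum(bitmap)
  }
  covered / sum(chrom_lengths)
}

# All-pairs RO edge list + union-find component construction.
oracle_components <- function(calls, t) {
  n <- nrow(calls)
  edges <- NULL
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j &&
          calls$sample_id[i] == calls$sample_id[j] &&
          oracle_match(calls[i, ], calls[j, ], t)) {
        edges <- rbind(edges, c(i, j))
      }
    }
  }
  uf_components(n, edges)
}

# Weighted F1 from an explicit confusion matrix.
oracle_weighted_f1 <- function(truth, predicted) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  classes <- union(unique(truth), unique(predicted))
  cm <- table(factor(truth, classes), factor(predicted, classes))
  total <- 0
  for (cl in classes) {
    tp <- cm[cl, cl]
    p <- if (sum(cm[, cl]) > 0) tp / sum(cm[, cl]) else 0
    r <- if (sum(cm[cl, ]) > 0) tp / sum(cm[cl, ]) else 0
    f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
    total <- total + f1 * sum(cm[cl, ])
  }
  total / length(truth)
}

# Random call-set generator for property tests.
rand_calls <- function(n, chroms = c("1", "2"), max_pos = 10000,
                       max_size = 2000, sample_id = "S", source = "T") {
  start <- floor(runif(n, 0, max_pos))
  size <- floor(runif(n, 1, max_size))
  tibble::tibble(
    chrom = sample(chroms, n, replace = TRUE),
    start = start, end = start + size,
    status = sample(c("gain", "loss"), n, replace = TRUE),
    sample_id = sample_id, source = source
  )
}

sort_by_coords <- function(calls) {
  out <- calls[order(calls$chrom, calls$start, calls$end), ]
  rownames(out) <- NULL
  out
}

# A small deterministic quartet pedigree.
toy_pedigree <- function(n = 2) {
  fams <- paste0("F", seq_len(n))
  tibble::tibble(
    family_id = fams,
    twin1 = paste0(fams, "_t1"), twin2 = paste0(fams, "_t2"),
    parent1 = paste0(fams, "_p1"), parent2 = paste0(fams, "_p2")
  )
}

# Zero-noise caller panel.
noiseless_profiles <- function(names = c("toolA", "toolB")) {
  do.call(rbind, lapply(names, caller_profile))
}

# Small fast study configuration for tests.
test_config <- function(..., seed = 1) {
  defaults <- list(
    n_families = 3, n_cnvs_per_parent = 25, pool_size = 10,
    chrom_lengths = setNames(rep(5e6, 2), c("1", "2")),
    profiles = noiseless_profiles(), seed = seed
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_config, args)
}

# Synthetic feature rows for the association stage (beta_gc on the logit).
sim_feature_rows <- function(n, beta_gc = 0, seed = 1) {
  withr::with_seed(seed, {
    gc <- runif(n, 0.3, 0.7)
    size <- rlnorm(n, log(5000), 0.5)
    dt <- runif(n, 0, 5e5)
    dc <- runif(n, 0, 5e5)
    eta <- 0.3 + beta_gc * (gc - 0.5)
    y <- runif(n) < stats::plogis(eta)
    tibble::tibble(size_bp = size, gc = gc, dist_telomere = dt,
                   dist_centromere = dc, concordant = y)
  })
}
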