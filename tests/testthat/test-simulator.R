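test_that("truth simulation obeys transmission extremes and determinism", {
  cfg1 <- test_config(seed = 10, transmission_prob = 1, pool_size = 0)
  truth <- simulate_truth(cfg1)
  g <- truth$genomes
  for (i in seq_len(nrow(truth$pedigree))) {
    fam <- truth$pedigree[i, ]
    child_ids <- sort(g$cnv_id[g$sample_id == fam$twin1])
    parent_ids <- sort(g$cnv_id[g$sample_id %in% c(fam$parent1, fam$parent2)])
    # full transmission: child carries every parental CNV (minus rare
    # overlap collisions resolved by the non-overlap rule)
    expect_true(all(child_ids %in% parent_ids))
    expect_gte(length(child_ids), 0.9 * length(unique(parent_ids)))
    # monozygotic twins: identical true genomes
    t1 <- g[g$sample_id == fam$twin1, c("cnv_id", "chrom", "start", "end")]
    t2 <- g[g$sample_id == fam$twin2, c("cnv_id", "chrom", "start", "end")]
    expect_equal(t1[order(t1$cnv_id), ], t2[order(t2$cnv_id), ],
                 ignore_attr = TRUE)
  }

  cfg0 <- test_config(seed = 10, transmission_prob = 0, pool_size = 0)
  g0 <- simulate_truth(cfg0)$genomes
  expect_equal(sum(g0$role %in% c("twin1", "twin2")), 0)

  # determinism: same config twice -> identical genomes
  expect_equal(simulate_truth(cfg1)$genomes, truth$genomes)
})

test_that("true genomes are non-overlapping within a sample", {
  g <- simulate_truth(test_config(seed = 44))$genomes
  by_sample <- split(g, g$sample_id)
  for (gs in by_sample) {
    for (ch in unique(gs$chrom)) {
      sub <- gs[gs$chrom == ch, ]
      sub <- sub[order(sub$start), ]
      if (nrow(sub) > 1) {
        expect_true(all(sub$start[-1] >= sub$end[-nrow(sub)]))
      }
    }
  }
})

test_that("transmission frequency sits in the binomial confidence band", {
  # many parental CNVs, transmission_prob = 0.5
  cfg <- simulation_config(
    n_families = 10, n_cnvs_per_parent = 100, pool_size = 0,
    chrom_lengths = setNames(rep(2e7, 2), c("1", "2")),
    profiles = caller_profile("x"), seed = 99
  )
  truth <- simulate_truth(cfg)
  g <- truth$genomes
  n_parental <- sum(g$role %in% c("parent1", "parent2"))
  n_transmitted <- sum(g$role == "twin1")
  ci <- qbinom(c(0.005, 0.995), n_parental, 0.5)
  expect_gte(n_transmitted, ci[1])
  expect_lte(n_transmitted, ci[2])
})

test_that("observation error model behaves at its extremes", {
  cfg <- test_config(seed = 12)
  truth <- simulate_truth(cfg)
  one <- truth$genomes[truth$genomes$sample_id == "F1_p1", ]

  clean <- observe_calls(one, caller_profile("zero"), cfg, seed = 1)
  expect_equal(nrow(clean), nrow(one))
  expect_equal(sort(clean$start), sort(one$start))
  expect_false(any(clean$is_fp))

  gone <- observe_calls(one, caller_profile("blind", fn_prob = 1), cfg, seed = 1)
  expect_equal(nrow(gone), 0)

  # truth-table conservation: emitted = surviving true (split or not) + FPs
  noisy_prof <- caller_profile("noisy", fp_rate = 20, fn_prob = 0.3,
                               frag_prob = 0.5)
  noisy <- observe_calls(one, noisy_prof, cfg, seed = 2)
  n_true_calls <- sum(!noisy$is_fp)
  n_surviving <- length(unique(noisy$true_cnv_id[!noisy$is_fp]))
  n_frag <- sum(noisy$fragment)
  expect_equal(n_true_calls, n_surviving + n_frag / 2)
  expect_true(all(is.na(noisy$true_cnv_id[noisy$is_fp])))
})

test_that("fragmentation heals under 5 kb merging", {
  cfg <- simulation_config(
    n_families = 1, n_cnvs_per_parent = 40, pool_size = 0,
    cnv_size_log_mean = log(20000), cnv_size_log_sd = 0.3,
    chrom_lengths = c(`1` = 5e7),
    profiles = caller_profile("frag", frag_prob = 1), seed = 7
  )
  truth <- simulate_truth(cfg)
  one <- truth$genomes[truth$genomes$sample_id == "F1_p1", ]
  frag <- observe_calls(one, cfg$profiles, cfg, seed = 3)
  expect_gt(nrow(frag), nrow(one)) # splits happened
  healed <- merge_adjacent(frag, max_gap = 5000)
  expect_equal(nrow(healed), nrow(one))
})

test_that("a full study is reproducible and consistent with its truth", {
  cfg <- test_config(seed = 101)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_equal(s1$calls, s2$calls)
  expect_equal(nrow(s1$pedigree), 3)
  expect_equal(dplyr::n_distinct(s1$calls$source), 2)
  expect_equal(dplyr::n_distinct(s1$calls$sample_id), 12)

  # zero noise: truth-derived labels match the Mendelian filter at t = 0.99
  for (i in seq_len(nrow(s1$pedigree))) {
    fam <- s1$pedigree[i, ]
    fam_calls <- s1$calls[s1$calls$sample_id %in%
                            c(fam$twin1, fam$twin2, fam$parent1, fam$parent2) &
                            s1$calls$source == "toolA", ]
    inh <- inherited_calls(fam_calls, fam, threshold = 0.99)
    twins <- fam_calls[fam_calls$sample_id %in% c(fam$twin1, fam$twin2), ]
    # every (noise-free) twin call is truly inherited, and all are recovered
    expect_equal(nrow(inh), nrow(twins))
  }
})
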