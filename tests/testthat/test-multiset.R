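two_source <- function(a, b, sample_id = "S") {
  dplyr::bind_rows(
    dplyr::mutate(a, sample_id = sample_id, source = "A"),
    dplyr::mutate(b, sample_id = sample_id, source = "B")
  )
}

spaced_set <- function(n = 5, chrom = "1") {
  start <- seq(0, by = 100000, length.out = n)
  tibble::tibble(chrom = chrom, start = start, end = start + 5000,
                 status = rep(c("gain", "loss"), length.out = n))
}

test_that("match components join identical sets and keep disjoint ones apart", {
  a <- spaced_set()
  comp <- match_components(two_source(a, a), 0.7)
  sm <- summarize_components(comp)
  expect_equal(nrow(sm), 5)
  expect_true(all(sm$sources == "A+B"))

  b <- dplyr::mutate(a, start = start + 50000, end = end + 50000)
  sm2 <- summarize_components(match_components(two_source(a, b), 0.7))
  expect_equal(nrow(sm2), 10)
  expect_true(all(sm2$n_sources == 1))
})

test_that("non-transitive RO chains collapse into one component", {
  # A≈B and B≈C at t=0.5 but A and C do not match directly
  chain <- tibble::tibble(
    chrom = "1",
    start = c(0, 500, 1000), end = c(1000, 1500, 2000),
    status = "gain", sample_id = "S",
    source = c("A", "B", "C")
  )
  expect_false(ro_match(chain[1, ], chain[3, ], 0.5))
  sm <- summarize_components(match_components(chain, 0.5))
  expect_equal(nrow(sm), 1)
  expect_equal(sm$sources, "A+B+C")
  expect_equal(sm$start, 0)
  expect_equal(sm$end, 2000)
})

test_that("components partition calls and match the union-find oracle", {
  withr::local_seed(55)
  for (rep in 1:20) {
    calls <- dplyr::bind_rows(
      rand_calls(15, max_pos = 15000, max_size = 3000, source = "A"),
      rand_calls(15, max_pos = 15000, max_size = 3000, source = "B"),
      rand_calls(10, max_pos = 15000, max_size = 3000, source = "C")
    )
    t <- sample(c(0.3, 0.5, 0.7), 1)
    comp <- match_components(calls, t)
    expect_equal(nrow(comp), nrow(calls)) # partition: every call exactly once
    want <- oracle_components(calls, t)
    # same partition up to component relabelling
    canon <- function(ids, keys) {
      sort(vapply(split(keys, ids),
                  function(x) paste(sort(x), collapse = "|"), character(1)))
    }
    keys <- paste(calls$chrom, calls$start, calls$end, calls$status,
                  calls$source)
    expect_equal(unname(canon(comp$.component, keys)),
                 unname(canon(want, keys)))
    # invariance under row shuffling
    perm <- sample(nrow(calls))
    comp2 <- match_components(calls[perm, ], t)
    keys2 <- paste(comp2$chrom, comp2$start, comp2$end, comp2$status,
                   comp2$source)
    expect_equal(unname(canon(comp2$.component, keys2)),
                 unname(canon(comp$.component, keys)))
  }
})

test_that("venn counts per cell behave on simple and noise-free input", {
  a <- spaced_set()
  solo <- dplyr::mutate(a, sample_id = "S", source = "onlytool")
  vc <- venn_counts(solo, 0.7)
  expect_equal(vc$sources, "onlytool")
  expect_equal(vc$mean_n, 5)

  study <- simulate_study(test_config(seed = 41))
  vt <- venn_table(study$calls, study$pedigree, 0.7)
  expect_equal(vt$sources, "toolA+toolB")
  expect_equal(vt$loss_ratio, 0)

  expect_error(venn_counts(study$calls, 0.7, "inherited"), "pedigree")
})

test_that("pairwise set operations obey count inequalities and identities", {
  a <- spaced_set()
  both <- two_source(a, a)
  u <- pairwise_setop(both, c("A", "B"), "union", 0.7)
  i <- pairwise_setop(both, c("A", "B"), "intersection", 0.7)
  expect_equal(nrow(u), 5)
  expect_equal(nrow(i), 5)
  expect_equal(u$start, i$start)

  b <- dplyr::mutate(a, start = start + 50000, end = end + 50000)
  disj <- two_source(a, b)
  expect_equal(nrow(pairwise_setop(disj, c("A", "B"), "intersection")), 0)
  expect_equal(nrow(pairwise_setop(disj, c("A", "B"), "union")), 10)

  expect_error(pairwise_setop(both, c("A", "Z"), "union"), "\"Z\"")
  expect_error(pairwise_setop(both, c("A", "B"), "difference"))

  withr::local_seed(66)
  for (rep in 1:10) {
    x <- rand_calls(20, max_pos = 30000, source = "A")
    y <- rand_calls(20, max_pos = 30000, source = "B")
    calls <- dplyr::bind_rows(x, y)
    nu <- nrow(pairwise_setop(calls, c("A", "B"), "union", 0.5))
    ni <- nrow(pairwise_setop(calls, c("A", "B"), "intersection", 0.5))
    sm <- summarize_components(match_components(calls, 0.5))
    expect_equal(nu, nrow(sm))
    expect_equal(ni, sum(sm$n_sources == 2))
    expect_lte(ni, nu)
  }
})

test_that("combined inherited rates: identity, and intersection beats union under FP load", {
  study <- simulate_study(test_config(seed = 51))
  own <- inherited_rate(study$calls[study$calls$source == "toolA", ],
                        study$pedigree)
  self_union <- combined_inherited_rate(
    dplyr::bind_rows(
      study$calls[study$calls$source == "toolA", ],
      dplyr::mutate(study$calls[study$calls$source == "toolA", ],
                    source = "copy")
    ),
    c("toolA", "copy"), "union", study$pedigree
  )
  expect_equal(self_union$rate, own$rate)

  # caller B = caller A plus pure false positives
  cfg <- simulation_config(
    n_families = 3, n_cnvs_per_parent = 25, pool_size = 0,
    chrom_lengths = setNames(rep(5e6, 2), c("1", "2")),
    profiles = dplyr::bind_rows(
      caller_profile("clean"),
      caller_profile("fppy", fp_rate = 30)
    ),
    seed = 61
  )
  study2 <- simulate_study(cfg)
  ir <- function(op) mean(combined_inherited_rate(
    study2$calls, c("clean", "fppy"), op, study2$pedigree
  )$rate)
  expect_gt(ir("intersection"), ir("union"))
})
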