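# Build a quartet call table from explicit per-member call sets.
quartet_calls <- function(t1, t2, p1, p2, source = "T", fam = toy_pedigree(1)) {
  dplyr::bind_rows(
    dplyr::mutate(t1, sample_id = fam$twin1),
    dplyr::mutate(t2, sample_id = fam$twin2),
    dplyr::mutate(p1, sample_id = fam$parent1),
    dplyr::mutate(p2, sample_id = fam$parent2)
  ) |> dplyr::mutate(source = source)
}

base_set <- function(n = 6, seed = 1) {
  withr::with_seed(seed, {
    start <- seq(0, by = 50000, length.out = n) + floor(runif(n, 0, 1000))
    tibble::tibble(
      chrom = "1", start = start, end = start + 5000,
      status = sample(c("gain", "loss"), n, replace = TRUE)
    )
  })
}

test_that("shared_calls matches the all-pairs RO scan oracle", {
  a <- base_set(8)
  expect_equal(nrow(shared_calls(dplyr::mutate(a, sample_id = "x", source = "T"),
                                 a, 0.7)), 8)
  b <- dplyr::mutate(a, chrom = "2")
  expect_equal(nrow(shared_calls(a, b, 0.7)), 0)

  withr::local_seed(17)
  for (rep in 1:10) {
    orig <- rand_calls(25, max_pos = 50000, max_size = 3000)
    jit <- orig
    jit$start <- jit$start + round(rnorm(25, 0, 400))
    jit$end <- pmax(jit$start + 1, jit$end + round(rnorm(25, 0, 400)))
    got <- shared_calls(jit, orig, 0.5)
    want <- oracle_shared_idx(jit, orig, 0.5)
    expect_equal(nrow(got), length(want))
    expect_equal(got$start, jit$start[want])
    expect_equal(got$end, jit$end[want])
  }
})

test_that("inherited_calls applies the both-twins-plus-parent filter", {
  fam <- toy_pedigree(1)
  a <- base_set(6)
  all_same <- quartet_calls(a, a, a, a, fam = fam)
  inh <- inherited_calls(all_same, fam)
  expect_equal(nrow(inh), 12) # both twins' full sets

  # a twin-only call absent from both parents is excluded
  extra <- tibble::tibble(chrom = "2", start = 100, end = 6000, status = "gain")
  with_extra <- quartet_calls(dplyr::bind_rows(a, extra),
                              dplyr::bind_rows(a, extra), a, a, fam = fam)
  inh2 <- inherited_calls(with_extra, fam)
  expect_equal(nrow(inh2), 12)
  expect_false(any(inh2$chrom == "2"))

  # a call in twin1 and one parent but not twin2 is excluded too
  with_one_twin <- quartet_calls(dplyr::bind_rows(a, extra), a,
                                 dplyr::bind_rows(a, extra), a, fam = fam)
  expect_equal(nrow(inherited_calls(with_one_twin, fam)), 12)
})

test_that("inherited_rate is (I1+I2)/(N1+N2) and handles empty twins", {
  fam <- toy_pedigree(1)
  a <- base_set(2, seed = 5)
  b <- base_set(2, seed = 9) # disjoint from a with high probability
  # twin1: calls a1,a2; twin2: a1,b2 -> each twin validates 1 call via parents
  t1 <- a
  t2 <- dplyr::bind_rows(a[1, ], b[2, ])
  calls <- quartet_calls(t1, t2, a[1, ], b[1, ], fam = fam)
  res <- inherited_rate(calls, fam)
  expect_equal(res$n1, 2)
  expect_equal(res$n2, 2)
  expect_equal(res$rate, 0.5)
  expect_equal(res$shared, 1)

  empty <- quartet_calls(a[0, ], a[0, ], a, a, fam = fam)
  expect_true(is.na(inherited_rate(empty, fam)$rate))
})

test_that("noise-free quartets have inherited rate 1 at every threshold", {
  cfg <- test_config(seed = 31)
  study <- simulate_study(cfg)
  for (t in c(0.1, 0.5, 0.9, 1)) {
    rates <- inherited_rate(study$calls, study$pedigree, t)
    expect_true(all(rates$rate == 1))
  }
})

test_that("inherited_rate is non-increasing in the threshold", {
  cfg <- test_config(seed = 77,
                     profiles = caller_profile("jit", jitter_sd = 500))
  study <- simulate_study(cfg)
  rates <- vapply(
    seq(0.1, 0.9, by = 0.2),
    function(t) mean(inherited_rate(study$calls, study$pedigree, t)$rate),
    numeric(1)
  )
  expect_true(all(diff(rates) <= 1e-12))
})

test_that("pair sharing rate is symmetric and ranks relationships", {
  a <- dplyr::mutate(base_set(10), sample_id = "A", source = "T")
  expect_equal(pair_sharing_rate(a, a), 1)
  b <- dplyr::mutate(a, chrom = "9")
  expect_equal(pair_sharing_rate(a, b), 0)
  sub <- a[1:5, ]
  expect_equal(pair_sharing_rate(sub, a), 10 / 15)
  expect_equal(pair_sharing_rate(a, sub), 10 / 15)
  expect_true(is.na(pair_sharing_rate(a[0, ], a[0, ])))

  # twins >= parent-child >= unrelated under default genetics
  study <- simulate_study(test_config(seed = 13))
  one_source <- study$calls[study$calls$source == "toolA", ]
  ped <- study$pedigree
  gets <- function(s) one_source[one_source$sample_id == s, ]
  tw <- mean(purrr::map2_dbl(ped$twin1, ped$twin2,
                             ~ pair_sharing_rate(gets(.x), gets(.y))))
  pc <- mean(purrr::map2_dbl(ped$twin1, ped$parent1,
                             ~ pair_sharing_rate(gets(.x), gets(.y))))
  un <- pair_sharing_rate(gets(ped$twin1[1]), gets(ped$parent1[2]))
  expect_gt(tw, pc)
  expect_gt(pc, un)
})
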