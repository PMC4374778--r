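# cnvquartet

Family-aware benchmarking of copy-number variant (CNV) call sets using
monozygotic twin quartets.

CNV callers applied to whole-genome sequencing disagree heavily, and cohorts
rarely have an external truth set. A quartet of two monozygotic twins plus
both parents provides an internal one: the twins share a genome, and every
germline CNV in a child must be present in at least one parent. `cnvquartet`
turns that constraint into quantitative quality metrics for one or several
callers, and ships a synthetic quartet simulator (with per-caller error
profiles and full ground truth) so the whole framework is testable without
cohort data.

## What it computes

Calls are `gain`/`loss` intervals (0-based half-open) in plain tibbles.
Two calls **match** at reciprocal-overlap (RO) threshold *t* (default 0.70)
when they share chromosome and status and, with *o* overlapping bases,
`min(o/|A|, o/|B|) >= t`. Same-status calls separated by less than 5 kb are
merged first to undo caller fragmentation.

* **Inherited CNV rate** per quartet — with twin call sets of sizes N1, N2
  and inherited subsets I1, I2 (matched in the co-twin and in the union of
  the parents), `rate = (|I1|+|I2|)/(N1+N2)`, the symmetric form of
  `2·shared/(N1+N2)`.
* **Familial relationship classification** — pairwise sharing rates for
  twin, child–parent and random unrelated pairs, clustered by k-means
  (k = 3) and scored with support-weighted `F1 = 2PR/(P+R)` against the true
  labels.
* **Multi-caller agreement** — connected components of the RO match graph
  across callers give Venn-cell counts before/after Mendelian filtering
  (loss ratio `1 − B/A`) and pairwise union/intersection call sets, each
  scoreable by the inherited rate.
* **Breakpoint resolution** — the inherited rate swept over an RO-threshold
  grid; the curve's mean slope separates precise from sloppy breakpoints.
* **Sequence-feature association** — multivariate logistic regression of
  call concordance on size, GC content, telomere distance and centromere
  distance, with Wald tests at the Bonferroni-corrected level
  `alpha/4 = 0.01/4 = 0.0025`.

## Worked example

Simulate three quartets seen by a clean caller and a noisy one, then score
both:

```r
library(cnvquartet)
library(dplyr)

study <- simulate_study(simulation_config(
  n_families = 3, n_cnvs_per_parent = 20, pool_size = 10,
  chrom_lengths = c(`1` = 5e6, `2` = 5e6),
  profiles = bind_rows(
    caller_profile("clean"),
    caller_profile("noisy", fp_rate = 15, fn_prob = 0.2, jitter_sd = 300)
  ),
  seed = 7
))

calls <- merge_adjacent(study$calls)

inherited_rate(calls, study$pedigree) |>
  group_by(source) |>
  summarise(rate = mean(rate))
#> # A tibble: 2 × 2
#>   source  rate
#>   <chr>  <dbl>
#> 1 clean  0.985
#> 2 noisy  0.343

relationship_f1(calls, study$pedigree, seed = 7)
#> # A tibble: 2 × 3
#>   source    f1 degenerate
#>   <chr>  <dbl> <lgl>
#> 1 clean  1     FALSE
#> 2 noisy  0.919 FALSE

mean_slope(ro_sweep(calls, study$pedigree))
#> # A tibble: 2 × 2
#>   source mean_slope
#>   <chr>       <dbl>
#> 1 clean     -0.0189
#> 2 noisy     -0.228
```

The clean caller validates ~98% of twin calls within the family, separates
twin / child–parent / unrelated pairs perfectly (F1 = 1), and its sweep
curve is nearly flat; the noisy caller's false positives and 300-bp
breakpoint jitter drag the inherited rate to 0.34 and steepen the slope to
−0.23. `autoplot()` on the sweep curve and `plot_sharing()` /
`plot_venn()` draw the standard figures; `tidy()`/`glance()` extract the
association fit.

A thin command-line front end wraps the same functions
(`inst/cli/cnvquartet.R`; subcommands `simulate`, `normalize`, `stats`,
`inherited`, `classify`, `venn`, `setop`, `sweep`, `features`).

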