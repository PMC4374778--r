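---
title: "Evaluating CNV call sets with monozygotic twin quartets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating CNV call sets with monozygotic twin quartets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(cnvquartet)
library(dplyr)
```

## The problem

Copy-number variant (CNV) callers applied to whole-genome sequencing data
disagree with each other far more than SNV callers do, and no gold-standard
truth set exists for a newly sequenced cohort. Families offer an internal
control: monozygotic twins carry (essentially) identical genomes, and every
germline CNV in a child must also be present in at least one parent. A cohort
of twin quartets — two monozygotic twins plus both parents — therefore lets us
score a caller without external truth: a twin call corroborated by the
co-twin *and* by a parent is very likely real; a call that fails this
Mendelian filter is likely an artifact.

`cnvquartet` implements this family-aware evaluation framework as a set of
pipeable, tibble-in/tibble-out functions, together with a synthetic quartet
simulator so every metric can be exercised — and its statistical behaviour
verified — without access to cohort sequencing data.

## Call representation and matching

Calls are rows of a tibble (`chrom`, `start`, `end`, `status`, `sample_id`,
`source`), 0-based half-open, with copy number reduced to `gain`/`loss`.
Two calls are compared by **reciprocal overlap (RO)**: with $o$ overlapping
bases, the tuple $(o/|A|,\ o/|B|)$. Calls *match* at threshold $t$ when they
share chromosome and status and $\min(o/|A|, o/|B|) \ge t$. The working
default is $t = 0.70$. Two numerical choices are worth stating:

* the comparison is inclusive ($\ge$), so exact copies match at $t = 1$ and
  there is no floating-point knife edge;
* status must agree — a gain never validates a loss, even at identical
  coordinates.

Because callers fragment single biological CNVs into runs of nearby calls,
call sets are first **normalized** with `merge_adjacent()`: same-status calls
on one chromosome separated by a gap strictly below 5 kb (including
overlapping calls, whose gap is negative) are replaced by their span. The
operation is idempotent and order-independent; opposite-status calls are
never merged, even when they overlap, since collapsing them would discard
signal. `merged_fraction()` reports how much of a call set is touched by this
healing — a direct fragmentation diagnostic.

## Mendelian-consistency metrics

For a quartet with twin call sets of sizes $N_1, N_2$, the **inherited CNV
rate** is

$$\mathrm{rate} = \frac{|I_1| + |I_2|}{N_1 + N_2},$$

where $I_k$ is the subset of twin $k$'s calls matched in the co-twin and in
the union of the two parents' call sets. When the twins validate
symmetrically this is the familiar $2 \times \mathrm{shared}/(N_1+N_2)$ with
$\mathrm{shared} = (|I_1|+|I_2|)/2$; we report both tallies because the two
twins' observed call counts generally differ. Matching multiplicity is
many-to-one (any counterpart validates a call): no assignment procedure is
enforced, because fragmentation makes one-to-one matching brittle and the
symmetric counting compensates.

The **familial relationship classification test** asks whether a caller's
output even distinguishes relatedness: per family we form one twin pair and
two child–parent pairs (twin 1 against each parent — the twins are
genetically identical, so the anchor choice is immaterial and configurable),
plus randomly drawn cross-family "unrelated" pairs, compute each pair's
symmetric sharing rate, cluster the 1-D rates with k-means ($k = 3$, 10
seeded restarts), label clusters by the rank of their mean (highest = twin,
lowest = unrelated), and score against the true labels with support-weighted
F1. Unspecific call sets collapse the three bands and drive F1 down. If the
rates contain fewer than three distinct values the clustering is degenerate;
we flag it and assign a single class rather than failing.

## Multi-caller agreement

RO matching is not transitive, so "the same CNV seen by several tools" needs
a closure rule. We use connected components of the match graph per
(sample, chromosome, status): it is the only symmetric completion that never
splits a matched pair, and it is independent of input order and source
labels. A component's source subset indexes its Venn cell; `venn_table()`
compares cell counts before and after Mendelian filtering
(loss ratio $1 - B/A$), and `pairwise_setop()` emits union or intersection
call sets (one call per kept component, spanning its members) that feed
straight back into the inherited-rate machinery via
`combined_inherited_rate()`. Intersections are expected to be more
consistent but smaller — the discovery/consistency trade-off the mean call
count column makes visible. A component containing several calls from one
tool counts once in its cell.

## Breakpoint resolution

Tightening the RO threshold penalizes imprecise breakpoints: `ro_sweep()`
recomputes the family-averaged inherited rate over a grid (default 0.1–0.9,
step 0.1; the grid is configurable) and `mean_slope()` summarizes each curve
by the mean of successive finite differences — on a uniform grid this equals
the endpoint slope, which is why only the uniform case is exposed by
default. Exact-breakpoint callers give flat curves (slope near 0) even when
contaminated by false positives; jittered breakpoints give steadily more
negative slopes.

## Sequence-feature association

For a chosen call set (typically a two-tool intersection),
`label_concordance()` marks each twin call concordant/discordant by the
Mendelian filter, `annotate_features()` adds call size, GC content of the
spanned reference sequence (ambiguous bases excluded from the denominator),
distance to the nearer chromosome end (a telomere proxy — explicit telomere
coordinates are rarely available, so chromosome ends stand in), and distance
to the centromere (0 inside it, from a user-supplied cytoband table).
`concordance_association()` then fits a multivariate logistic regression
(IRLS, tolerance $10^{-8}$, max 100 iterations) with Wald z-tests and a
Bonferroni-corrected per-feature threshold $\alpha / 4 = 0.01/4 = 0.0025$.
Features are standardized internally for conditioning — the reported
estimates are transformed back to the original scale, and the p-values are
provably unaffected. Perfect separation is detected and flagged rather than
silently reported; collinear designs error with the offending features
named.

## The simulator

`simulate_study()` generates the whole study: per parent, private
non-overlapping CNVs (log-normal sizes, uniform placement, gain/loss mix)
plus draws from a shared population pool; each parental CNV transmits to the
child with probability 0.5; twin 2's genome is an exact copy of twin 1's.
De novo CNVs are not simulated (they are a negligible fraction of the CNV
burden), and true CNVs never overlap within a genome — a documented
simplification (real genomes can nest CNVs). The population pool exists so
unrelated individuals share *some* CNVs: without it the unrelated cluster of
the classification test sits exactly at 0 and the test is trivially easy.
The default carrier frequency (0.3 over a 40-CNV pool) keeps unrelated
sharing well below child–parent sharing.

Observation noise is a per-caller profile: Poisson false positives, per-CNV
false-negative probability, Gaussian breakpoint jitter, fragmentation into
two sub-calls with a sub-5-kb internal gap (so 5-kb merging can heal it), and
multiplicative size bias (read-depth callers over-call size). The default
four-caller panel spans these archetypes: `precise` (low noise),
`rd_broad` (strong jitter, size bias 1.3), `fp_prone` (60 FPs/sample),
`frag_prone` (fragmentation probability 0.5). Every emitted call carries its
ground truth (`true_cnv_id`, `is_fp`, `fragment`), and a config seed fixes
the entire study.

Default study design: 9 families (36 samples), 80 private CNVs per parent on
a five-chromosome 100-Mb stand-in genome. The genome is a length-scaled
stand-in, not a human reference: densities (CNVs per Mb) are higher than
real cohorts so that desk-scale runs still have enough calls for stable
rates. What passing tests on this simulator show is that the *metrics* are
computed correctly and respond to error modes in the right direction — not
that any particular real caller will achieve a given score: real data adds
mapping artifacts, reference biases and correlated errors between callers
that the simulator deliberately leaves out (caller errors are independent
here except through the shared truth).

```{r example}
study <- simulate_study(simulation_config(
  n_families = 3, n_cnvs_per_parent = 20, pool_size = 10,
  chrom_lengths = c(`1` = 5e6, `2` = 5e6),
  profiles = dplyr::bind_rows(
    caller_profile("clean"),
    caller_profile("noisy", fp_rate = 15, fn_prob = 0.2, jitter_sd = 300)
  ),
  seed = 7
))

calls <- merge_adjacent(study$calls)
inherited_rate(calls, study$pedigree) |>
  group_by(source) |>
  summarise(rate = mean(rate))
```

## Verification strategy and problem sizes

The test suite checks every interval primitive against an independent
brute-force oracle (all-pairs RO scans, union-find over explicit edge lists,
per-base coverage bitmaps, confusion-matrix F1 arithmetic, direct likelihood
maximization for the logistic fit) on hundreds of randomized small
instances, and checks the statistical machinery at the scales where its
expectations are known: zero-noise studies must hit every ideal value
exactly (rate 1, F1 1, loss ratios 0, flat sweep); a 1000-family study with
miss probability $\beta$ and Poisson false-positive load $F$ must match the
closed-form rate $\sum 2T(1-\beta)^3 / \sum 2(T(1-\beta)+F)$ within
Monte-Carlo error; directional claims (intersection > union under
contamination, steeper sweep slopes under jitter) are checked over 100
seeded replicates; and the association stage's type-I error is verified
against its Bonferroni-corrected level over 500 null replicates of
$n = 2000$. Test and acceptance runs use deliberately small genomes
(2–3 chromosomes of 5–10 Mb) and reduced CNV counts; these sizes are stated
here as the package's chosen verification scale.

## Known limitations

* Chromosome names are compared as strings after optional `chr`-prefix
  stripping; cross-assembly coordinate lifting is out of scope.
* Sex chromosomes receive no special treatment: calls on them are included
  in every metric (an autosome-only analysis is a simple `filter()` away).
* The Venn loss ratio can leave $[0,1]$ in pathological cases where
  filtering *splits* a component across cells; this mirrors the definition
  $1 - B/A$ applied cell-wise and is left as-is.
* Only pairwise union/intersection call sets are emitted; components support
  more tools, but higher-order combinations are not exposed.
* The simulator draws caller errors independently; correlated artifacts
  (e.g. two read-depth callers failing on the same GC-extreme region) are
  not modelled, so multi-caller agreement on simulated data is optimistic.
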