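---
title: "Methods: SNV calling and haplotype-ratio copy number in copy-number-variable capture data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SNV calling and haplotype-ratio copy number}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the models and procedures it
implements, the assumptions behind them, the parameters that matter, and
the choices made where the design was genuinely open.

## Setting and assumptions

The pipeline targets deep (tens to hundreds of reads per site), long-read
(~300–350 bp) capture resequencing of genomic regions whose copy number
varies between individuals. Reads are assumed to be already mapped:
`capvar` consumes alignments (SAM/BAM or a 6-column TSV dialect) or
per-site pileups and never remaps. Three assumptions shape everything
downstream:

1. **Errors are site-independent substitutions at a single pooled rate.**
   Indels and complex events are out of scope (the calling rule ignores
   them), and the error process is summarized by one global per-site
   mismatch probability `p` covering sequencing *and* mapping error. No
   position-, motif- or flow-cycle-specific structure is modelled.
2. **Depth is informative but unmodelled.** The binomial filter
   conditions on the observed local depth `n`; capture efficiency,
   GC bias and the saturation of capture arrays at high copy number are
   not modelled mechanistically (the generator exposes a scalar
   `saturation` factor instead).
3. **Copies of a multi-copy locus co-capture and co-map.** A site in a
   6-copy cluster shows a mixture of 6 haploid alleles at roughly equal
   read proportions; a variant on `k` of `c` copies has expected VAF
   `100·k/c` percent.

## Candidate calling

At each pileup column the most-supported non-reference base is nominated
iff it has at least `min_each_strand` (default 3) quality-passing reads
in each orientation, or at least `min_single_strand` (default 5)
quality-passing reads with all evidence in a single orientation. Depth
`n` counts every spanning read; the quality gate (Phred ≥ 20) applies
only to variant *support*, which keeps `n` consistent with the `n` used
by the error model. VAF is computed from all variant-supporting reads
over depth, and calls under `min_vaf = 10`% are suppressed, emulating the
reporting floor of the mapper whose behaviour the rule reproduces.

Two open points were decided as follows:

- whether the one-orientation clause also demands Q20 is not determined
  by the rule's published phrasing; the quality gate is applied
  uniformly to both clauses;
- multi-allelic columns emit the single best-supported alternate, ties
  broken by higher total support then alphabetical base order.
  Multi-allelic sites are vanishingly rare at these error rates.

## The binomial error model

Control sites — positions independently known to be homozygous for a
variant allele in a 2-copy region — should show only the expected allele;
every other read is an error of sequencing or mapping. Pooling mismatch
and total read counts over all control sites gives the estimate `p̂`
(`estimate_error_rate()`). Pooling (rather than per-site rates) is
deliberate: individual control sites see ~50 reads, far too few to
estimate a per-site rate, and the filter only needs a calibrated global
tail. If no mismatch is observed, `p̂` is floored at `10⁻⁴` (with a
warning) so the tail test stays defined.

A candidate with depth `n` and `d` variant-supporting reads is scored by
the inclusive upper binomial tail

$$P = \sum_{k=d}^{n} \binom{n}{k} p^k (1-p)^{n-k},$$

the posterior probability of `d` *identical* deviations arising from
error alone. `d` counts reads supporting the specific alternate, not all
mismatches — errors must be identical to mimic a variant. Calls with
`P > threshold` (default `10⁻³`) are discarded. The tail is evaluated
through the survival function (`pbinom(d - 1, n, p, lower.tail =
FALSE)`), which is numerically stable far beyond depth 10⁴; the suite
verifies agreement with direct pmf summation to 10⁻¹² relative tolerance
for all `n ≤ 200` and checks monotonicity in `d` and `p`.

`simulate_vaf_distribution()` exposes the model's predictive side: for a
genotype `k` of `c`, the variant-read probability is perturbed to
`q(1-p) + (1-q)·p/3` (the true allele is misread away with probability
`p`; each other base is misread *toward* the variant with `p/3`,
errors being uniform over the three alternatives), and VAFs are drawn
over an empirical depth distribution for comparison with observed VAF
histograms.

## Masking and VAF classification

Mask intervals (BED, 0-based half-open — a call whose 0-based coordinate
equals an interval end is outside it) mark calls `masked`; masking is
applied before the error filter and is never undone. Both filters are
idempotent, and the funnel raw → masked → filtered → passed is logged by
the pipeline.

VAF bands for 2 copies are homref `[10,25)`, het `[25,75]`, homvar
`(75,100]` — 75% belongs to het. For 6 copies the six `k_of_6` classes
use `[10,25) [25,43) [43,59) [59,76) [76,93) [93,100]`: the printed
integer shorthand ranges (10–24, 25–42, …) are closed into half-open
intervals on the percent scale, reading the integer gaps as notation
rather than holes. For any other copy number (our generalization; only 2
and 6 are conventionally defined) band boundaries sit at midpoints
between consecutive expected VAFs `100·k/cn`, with the lowest bound
floored at the 10% reporting floor; the suite checks that the bands
partition `[10, 100]` for every copy number 2–12.

## Haplotyping and copy number

**Window selection.** Haplotyping candidate regions are maximal runs of
SNVs in which every 1-kb window anchored at an SNV holds at least
`min_density` (default 9) SNVs; runs are split where consecutive SNVs are
more than 1 kb apart. Within a window, combinations are greedy
consecutive runs of 2–7 SNVs spanning at most `max_span` bases (default
250, comfortably inside a 330-base read).

**Tallying.** A read contributes to a combination only if it spans all
its positions with unambiguous (non-N), Q20+ bases — one low-quality base
excludes the read entirely, since a partial tuple cannot be assigned to a
haplotype. Tuples with fewer than 5 reads are dropped (sequencing errors
at any single combination position produce spurious tuples at roughly
`p/3` per position, so a handful of reads is not evidence of a real
haplotype), and a combination is callable only if the surviving total
reaches `min_total` — 5 reads per expected copy, i.e. 10 for a 2-copy and
30 for a 6-copy locus.

**Integer ratio.** Copy number estimation needs the small-integer ratio
underlying the observed read counts. The search formalizes what is
usually done by eye: candidate totals `T` are tried smallest first; for
each `T` counts are apportioned to integer copies by largest remainder
(assignments giving a haplotype zero copies are invalid); the first
assignment whose chi-square goodness of fit against expected counts
`Σcounts·c_i/T` is not rejected at `alpha` (default 0.05) wins. Smallest-
total-first embodies parsimony: expected proportions are invariant under
scaling `c → 2c`, so the data alone can never distinguish a copy number
from its multiples, and the smallest consistent total is the only
principled choice. Two consequences are documented rather than hidden:

- *Two-haplotype loci are fundamentally scale-ambiguous* (1:1 fits 2, 4,
  6 … copies). `cn_from_ratio()` takes an explicit `haploid_scale` for
  them (as published tables resolve such rows with external knowledge,
  e.g. a "3n" annotation meaning scale 2 on a 1:2 ratio) and flags the
  estimate ambiguous when the scale was left at its default.
- *The estimator is conservative at low read counts.* With ~50 reads per
  combination the chi-square cannot always reject a coarser apportionment
  (2:1:1 may be accepted where the truth is 3:2:1), biasing estimates
  downward by about one copy; published per-locus estimates around a
  6-copy truth spread over 4–8 for the same reason. The package's 6-copy
  recovery test therefore runs at per-combination totals of roughly
  150–300 reads (a 30-kb 6-copy region at per-copy depth 55, ≥ 20
  scale-unambiguous loci), where the mean recovered copy number is stable
  near 6; at the 50-read floor the same test design recovers means
  nearer 5.
- `alpha` is configurable because no single parsimony rule reproduces
  every published eyeballed ratio; rows irreproducible under any single
  rule are excluded from exact regression tests.

Aggregation reports count, mean, min, max and SD of the diploid copy
numbers, plus the pooled two-haplotype read ratio (summing counts across
loci before dividing, in tally order — pooling damps sampling noise and
should sit near 1 at a true 2-copy locus).

## Evaluation conventions

Concordance tables assign every truth site to exactly one called
category; sites under `min_depth` (default 6 — "covered by more than 5
sequences") are *not covered*, and truth-homozygous-reference sites
without a call are the *no-call* category (with a 10% VAF floor, silence
is itself the homozygous-reference signal). **Sensitivity** is concordant
calls over the truth-class total; **specificity** follows the published
concordance-table arithmetic — concordant calls over all calls of that
class at truth-annotated sites — which is a precision-like measure, *not*
the textbook true-negative rate; we keep the field's convention and name
it explicitly in the documentation. Percentages and densities are
rounded half-up to one decimal (integer percent for the multi-copy
extrapolation), matching how such tables are printed.

The multi-copy sensitivity extrapolation corrects an observed 2-copy SNV
count by the single-copy sensitivity, scales by the haploid copy
multiple, and reports the observed multi-copy count over that
expectation.

## The synthetic data generator

The generator is first-class, tested code, and defines the conditions
under which the pipeline's statistical claims are verified. It emulates:

- per-region capture depth proportional to copy number
  (`target_depth_per_copy`, default 25 reads/copy; scalar `saturation`
  damps the scaling to mimic array saturation at high copy number — the
  factor is free, not fitted, as no quantitative saturation curve is
  available);
- read lengths normal with mean 330 bases and SD 40, truncated below at
  50 and at the region end (average published lengths fall between 300
  and 350 bases);
- i.i.d. substitution errors at `per_site_error` (default 0.023, the
  calibrated rate for this technology), uniform over the three
  non-template bases — no transition/transversion skew, since the error
  model itself pools all mismatches;
- per-base qualities drawn around Q30 (SD 6, clipped to 2–40), giving a
  realistic ~5% sub-Q20 fraction; quality is independent of the error
  process;
- planted SNVs as a Poisson process at the configured density, each
  assigned to a uniform 1..c of the c copies on a random copy subset —
  this induces the multi-copy haplotype structure the phasing stage
  recovers; dense haplotyping windows (default 16 SNVs/kb over
  `htcr_fraction` of the region) emulate observed high-density stretches
  (at least 9 SNVs/kb);
- a known-SNP resource: each planted SNV is flagged known with
  probability `known_fraction` (default 0.9, the ballpark share of
  already-catalogued variants in such regions).

It does **not** emulate homopolymer indel errors (the dominant 454 error
mode — irrelevant here because indels are discarded upstream of this
analysis), flowgram-derived quality structure, capture-probe
hybridization kinetics, paired ends, or mapping ambiguity between
paralogs (paralog confusion is handled by masking, not simulated).
Passing tests on this generator therefore demonstrate the *arithmetic
and statistical* correctness of the pipeline under its own error model —
not robustness to mapping artifacts or systematic error clustering in
real paralogous regions.

Determinism: one integer seed makes all outputs byte-identical;
module-specific streams are derived from it, and the RNG state of the
calling session is restored afterwards.

## Numerical and convention choices

- Coordinates: 0-based half-open internally for intervals (BED on disk),
  1-based positions in all variant tables.
- Rounding: half away from zero at reporting only (`round_half_up()`);
  internal values keep full precision.
- The binomial tail via the survival function in log space (through
  `pbinom`), never naive summation.
- Chi-square acceptance uses `k − 1` degrees of freedom for `k`
  haplotypes; exact-fit assignments have statistic 0 and are always
  accepted.
- Degenerate inputs: zero-depth control sets, empty depth distributions,
  `d > n`, zero haplotype counts, non-positive effective lengths and
  duplicate truth positions raise errors; absence of a call or a tally
  is a normal `NULL`/zero-row outcome, not an error.

## Problem sizes used by the test suite

Unit tests run on kilobase-scale regions at depth ~50. The statistical
acceptance checks use: 10⁵ sites of pure error at depth 50 for the
false-positive calibration (the post-filter false-positive count must
stay within the binomial model's `10⁻³` prediction plus 3 Poisson SDs);
~500 planted heterozygous SNVs at depth 50 for the 2-copy
recall/precision regime (both ≥ 0.94); and the 6-copy design described
above for copy-number recovery (mean within ±1 of 6). These sizes are
the package's chosen validation conditions and complete in a few minutes
on one CPU.

## Known limitations

- The error model is global; real 454 error clusters at homopolymers and
  specific motifs, so the false-positive calibration on synthetic data is
  optimistic for real alignments.
- Two-haplotype loci (and any all-equal ratio) cannot determine their own
  scale; external copy-number knowledge must be supplied.
- The smallest-total ratio search is conservative at low coverage
  (downward copy-number bias) and `alpha` trades parsimony against
  resolution.
- Specificity follows the concordance-table (precision-like) convention;
  users wanting the textbook definition must compute it from the same
  table themselves.
- Statistical phasing across non-overlapping reads (EM/HMM haplotype
  assembly) is deliberately out of scope: only direct read-backed tuples
  are used.
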