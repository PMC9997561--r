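---
title: "Coverage-based sex-region discovery from ddRAD-seq: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coverage-based sex-region discovery from ddRAD-seq: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddradscan)
```

## The problem

In many fish the sex chromosomes are homomorphic: karyotypes show no
heteromorphic pair, yet sex is genetically determined, often by a small,
recently diverged male-specific (Y-linked) region. Such regions are
invisible to assembly-level comparisons but leave a clean signature in
reduced-representation sequencing: loci inside a male-specific region
receive reads from males only, and X-linked duplications double the
female mapping rate. `ddradscan` implements that coverage logic as a
tested pipeline: in-silico prediction of ddRAD loci, filtered and
normalized per-locus read counts, per-locus permutation tests with FDR
control, and region calling — plus windowed π/d~xy~/F~ST~ for the
population-genetic context, and generators that produce data with the
exact structure the pipeline assumes.

## In-silico double digestion

A ddRAD library contains the fragments between cut sites of two
enzymes. The digest module scans the top strand for each recognition
motif (IUPAC codes in the motif are expanded; `N` in the genome never
matches; both defaults, NsiI `ATGCAT` and MspI `CCGG`, are palindromic,
so a top-strand scan is a full scan), converts each site to its cut
position (`site start + cut offset`: NsiI +5, MspI +1), pools and sorts
cuts per chromosome, and emits the intervals between consecutive cuts.

Two conventions are deliberate and exposed as flags rather than
hard-coded, because digestion-prediction tools differ on both:

* **Boundaries** default to cut positions (the physical digestion
  product), not recognition-site edges (`boundaries = "site_edge"`).
* **Ends rule** defaults to keeping only fragments flanked by the two
  *different* enzymes, because only those ligate both adapters and get
  sequenced; `ends_rule = "any"` restores same-enzyme fragments.

Size selection keeps lengths in `[0, 613]` bp by default — only the
maximum is a property of the targeted library design; no minimum is
imposed. Coordinates are 0-based half-open throughout. Sites are never
called across `N` runs (an `N` matches nothing); fragments *containing*
internal `N`s are kept, since the covered-fraction filter downstream
handles unmappable interiors empirically.

## Counting and filtering

For each sample, an alignment counts toward a fragment when its
reference interval overlaps the fragment by at least one base and its
mapping quality is at least 30; unmapped, secondary, supplementary and
duplicate-marked records are excluded. The per-sample library size is
the total number of retained high-quality mappings genome-wide (not
only within fragments), and normalization is counts per million of
that total — a scale choice only, since the permutation test is
invariant to common scaling. One alignment can overlap two adjacent
fragments, so fragment counts are not a partition of the library.

Two filters follow. A sample–fragment pair is *masked* when less than
half of the fragment is covered by retained alignments — with ~300 bp
of paired read per locus and a 613 bp maximum, a genuine locus present
in a sample should cover at least half. A fragment is dropped when
fewer than 50 samples survive that mask. Both sexes are pooled in that
count, deliberately: a male-specific fragment has zero surviving
females and ~64 surviving males, and pooling is what lets it reach the
test at all. The default 50 is 90% of the smaller sex group rounded
down (`min_samples_default()` computes it for other designs).

Masked pairs enter the test as zero counts rather than being removed:
a region absent from females *is* a zero-coverage observation, not
missing data. `drop_masked = TRUE` provides the alternative reading
(permute surviving samples only), under which sex-specific fragments
become untestable and get `NA` p-values.

## The permutation test and the p-value floor

Per fragment the statistic is `|mean(M) − mean(F)|` of normalized
counts — the simplest two-sided contrast of mapping rates; no
distributional model is imposed on counts. Sex labels are shuffled
uniformly `n_reps` times (default 100,000) in compiled code, with each
fragment's RNG stream derived deterministically from
`(seed, fragment index)`, so results are reproducible and independent
of evaluation order. Ties with the observed statistic count as
exceedances.

Two estimators are provided. `add_one`, `(b+1)/(B+1)`, is the default:
it is a valid p-value (never anti-conservative, never zero).
`plug_in`, `b/B`, is unbiased but can return zero. The difference
matters at scale: `add_one` has a floor of `1/(B+1)`, and under
Benjamini–Hochberg at level α over m tests, a test at rank k needs
p ≤ αk/m. `bh_feasibility()` reports the consequence: with
B = 100,000, m = 200,543 and α = 0.05, the smallest attainable
adjusted p at rank 25 is `200543/(100001 × 25) ≈ 0.080 > 0.05`, and at
least 41 tests would have to sit exactly at the floor before any could
be declared significant. A scan of that scale reporting 25 discoveries
is therefore only reachable with the plug-in estimator (or more
replicates); the scan prints this diagnostic rather than silently
switching estimators.

Significance is strict (`adjusted p < 0.05`) with a flag for `<=`;
contiguity for region merging means consecutive in the chromosome's
fragment ordering, and a region's pattern is the majority pattern of
its members.

Pattern labels are heuristics on survivor counts and means:
`male_specific` requires zero surviving females and positive male
mean; `female_elevated` requires both sexes positive and a
female/male ratio within 2 ± 0.5 (`ratio_tol = 0.25` on the doubling
factor). The ratio window is generous because normalized means at
56–64 samples have a few percent sampling error; at very low depth the
classification degrades before the test does.

## Windowed population statistics

π, d~xy~ and Hudson's F~ST~ are computed from per-site allele counts
with pairwise deletion: a missing allele removes only the pairs it
would have participated in. Every window value is a **ratio of sums**
of per-site numerators and denominators over the fixed 1-based grid
`[1, 10000], [10001, 20000], …` — never a mean of per-site ratios,
which is biased when per-site denominators vary (the test suite pins
this distinction on a crafted two-site window). Sites with fewer than
two called alleles (per relevant population) contribute nothing;
windows with zero denominators report `NA` with their components, so
downstream aggregation can re-sum rather than average. For Hudson's
F~ST~ the per-site numerator is `(p₁−p₂)² − p₁q₁/(n₁−1) − p₂q₂/(n₂−1)`
and the denominator `p₁q₂ + p₂q₁`; sites monomorphic in both
populations contribute zeros to both sums, and negative estimates are
preserved. These are the standard missing-data-aware definitions for
windowed statistics from genotype matrices; only biallelic SNPs are
accepted (multiallelic sites are dropped with a count at VCF load, and
half-called genotypes become missing).

One consequence worth stating: the denominators count only the sites
present in the matrix. With a variants-only VCF, π is per *variant*
site; per-bp diversity over a region requires invariant sites to be
included as rows.

## The generators: what they emulate, and what they do not

`simulate_genome()` plants NsiI/MspI sites at Poisson spacing (defaults
0.4/kb and 2/kb — a 6-cutter/4-cutter density ratio on a ~50% GC
background) in random sequence, then mutates away any accidental motif,
including motifs created at planting junctions, so the planted map is
provably the complete site map and the expected fragment list is exact
ground truth.

`simulate_count_table()` emulates ddRAD depth structure: log-normal
per-sample library factors (CV 0.2), gamma per-fragment relative
abundances (shape 4, mean 1), negative-binomial counts (dispersion
size 5) around a 20× baseline, defaults of 64 males and 56 females
allocated to three river populations (39/38/43 at n = 120). Planted
`male_specific` fragments have exactly zero female counts;
`female_doubled` doubles the female mean. Covered fractions are binary
(1 where count > 0) with optional sub-threshold noise — the filter
consumes only the fraction, so base-level coverage simulation would add
nothing the filter can see.

`simulate_genotypes()` draws ancestral frequencies Uniform(0.05, 0.95),
population frequencies Balding–Nichols at the target F~ST~, binomial
diploid genotypes and i.i.d. missingness. Under this model the Hudson
ratio-of-sums estimator targets the Balding–Nichols parameter exactly,
which is what the recovery tests exploit.

None of the generators model mapping artifacts, GC or fragment-length
depth bias, linkage disequilibrium, partial digestion, or related
individuals. Passing tests therefore demonstrate correctness of the
computations and calibration under the assumed sampling models — not
robustness of the method to real-data pathologies such as paralogous
mapping, which remain the analyst's responsibility.

## Numerical and design choices

* Permutation exceedance uses a relative epsilon (`1e-12` × value
  scale) so float round-off cannot turn a tie into a non-exceedance.
* Coincident cut positions from the two enzymes (possible only for
  overlapping motifs) are collapsed with a warning; zero-length
  fragments cannot result.
* BH adjustment is the standard step-up (via `p.adjust`) after
  validating inputs; `NA` p-values (untestable fragments under
  `drop_masked`) are excluded from the adjustment and from m.
* Genotype presence means both alleles called; site positions must be
  strictly increasing within a chromosome.
* Window bounds are reported on the nominal grid; the last window of a
  chromosome is not truncated to sequence length because the genotype
  matrix does not carry chromosome lengths.
* All generator and scan functions take integer seeds and are
  deterministic given them; derived per-fragment seeds stay below
  2³¹ − 1.

## Problem sizes used in validation

The test suite and `scripts/acceptance.R` validate at desk scale,
chosen so the full suite runs in minutes: 100 random 5–50 kb sequences
for digestion-oracle equivalence; exhaustive enumeration at n = 3 + 3
for permutation exactness; 2,000 null fragments at 60 M/56 F and 2,000
replicates for calibration; 20 seeds × (20 male-specific + 20
female-doubled among 2,000 fragments at 20×) for recovery, FDR and
pattern accuracy; 10,000 Balding–Nichols sites at n = 50/50 × 10 seeds
for F~ST~ recovery (±0.02). The feasibility bound is evaluated
analytically at the full scale (m = 200,543, B = 100,000) because it
costs nothing to do so.

## Limitations

* The scan detects *coverage* differences only; a sex-determining
  locus with ordinary coverage but divergent sequence will not be
  found, and no attempt is made to classify XY vs ZW systems beyond
  the direction of the pattern labels.
* The counting unit is the individual primary alignment; if proper
  read pairs should count once, collapse them upstream.
* With `add_one` at default replicates, very large fragment sets are
  FDR-infeasible by construction (see the floor discussion); the scan
  reports the bound and leaves the estimator choice explicit.
* π/d~xy~ comparability across datasets depends on including invariant
  sites consistently.
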