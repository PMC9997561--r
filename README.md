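# ddradscan

Coverage-based discovery of sex-linked genomic regions from
double-digest RAD sequencing (ddRAD-seq), plus missing-data-aware
windowed population statistics — for geneticists working on species
whose sex chromosomes are homomorphic and invisible to karyotyping,
where the only footprint of a nascent Y (or W) is a local difference in
read depth between the sexes.

## What it computes

A ddRAD library sequences only the genomic fragments that lie between
the cut sites of two restriction enzymes (here NsiI, `ATGCAT`, and
MspI, `CCGG`) and pass size selection. If a region is present only in
males, female reads simply never map to it; if it is duplicated on the
X, female depth doubles. `ddradscan` turns that logic into a pipeline:

1. **Digest** — in-silico double digestion of an assembly: all motif
   sites are located, cut positions (`site + cut offset`) pooled, and
   every fragment flanked by cuts from *different* enzymes and at most
   613 bp long becomes a locus.
2. **Count** — per sample, alignments with `mapq >= 30` (primary,
   non-duplicate) are counted per fragment; a sample–fragment pair is
   masked when less than half the fragment is covered, and a fragment
   is dropped when fewer than 50 samples survive; counts are scaled to
   counts per million high-quality mappings.
3. **Scan** — per fragment, a two-sample Monte Carlo test: sex labels
   are permuted (default 100,000 replicates) and the statistic
   `|mean(M) − mean(F)|` recomputed; p-values are BH-adjusted and
   fragments with adjusted p < 0.05 are merged, when contiguous, into
   candidate sex regions classified as `male_specific`,
   `female_elevated`, etc.
4. **Popgen** — over a genotype matrix, nucleotide diversity π,
   divergence d<sub>xy</sub> and Hudson's F<sub>ST</sub> in 10 kb
   windows, each as a ratio of summed per-site numerators and
   denominators with pairwise deletion of missing alleles:
   π = Σ c(n−c) / Σ C(n,2), d<sub>xy</sub> = Σ[c₁(n₂−c₂)+c₂(n₁−c₁)] /
   Σ n₁n₂, and Hudson's
   F<sub>ST</sub> = Σ[(p₁−p₂)² − p₁q₁/(n₁−1) − p₂q₂/(n₂−1)] /
   Σ[p₁q₂ + p₂q₁].

A synthetic-data module (`simulate_genome()`,
`simulate_count_table()`, `simulate_genotypes()`) generates genomes
with planted restriction maps, negative-binomial count tables with
planted male-specific / female-doubled fragments, and Balding–Nichols
structured genotypes, so every stage runs and is validated without any
external data.

## Worked example

The numbered drivers under `analysis/` run the whole workflow on
synthetic data (about a minute in total):

```sh
Rscript analysis/01_simulate_data.R
Rscript analysis/02_digest_fragments.R
Rscript analysis/03_sex_scan.R
Rscript analysis/04_popgen_windows.R
```

Stage 3 prints:

```
filters: 2131 pairs masked, 0 fragments dropped, 2000 kept
<sex_scan> 2000 fragments tested, 41 significant (BH < 0.05), 3 region(s)
  n_reps=10000 estimator=add_one seed=271
recovered 40/40 planted fragments; 1 false discoveries
patterns among discoveries: female_elevated=20, male_specific=20, other=1
```

All 20 planted male-specific and all 20 female-doubled fragments are
recovered at BH 0.05 with a single false discovery, and every planted
fragment's coverage pattern is labelled correctly. Stage 4 prints the
windowed statistics for the three simulated river populations:

```
fst: Halda:Jamuna=0.1012  Halda:Padma=0.1004  Jamuna:Padma=0.0995
```

recovering the Balding–Nichols simulation target F<sub>ST</sub> = 0.1
for every pair. (Here π and d<sub>xy</sub> are per *variant* site;
per-bp values require invariant sites in the input, see the vignette.)

A one-call version of the same workflow, with a machine-readable
manifest of outputs and parameters, is

```r
library(ddradscan)
run_pipeline(pipeline_config(seed = 42), "results/pipeline")
```

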