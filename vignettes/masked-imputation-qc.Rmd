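---
title: "Masked data analysis for genotype imputation quality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Masked data analysis for genotype imputation quality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplomask)
```

## The procedure and its assumptions

Masked data analysis estimates the error of genotype imputation without any
external truth set: genotypes that *are* observed are deliberately hidden,
the imputer fills them back in, and the refilled values are compared with
the originals. `haplomask` organizes this as four composable steps — mask,
impute, count, select — around a single in-memory representation, the
`haplotype_panel` (a samples × variants × 2 array of allele codes with
per-variant metadata, read from fastPHASE `.inp` or VCF).

The approach rests on two assumptions worth keeping in mind:

* **Missingness is exchangeable.** Masked cells are drawn uniformly at
  random per locus, so the estimated error describes *randomly* missing
  genotypes. If the real missingness in your data is informative (e.g.
  concentrated in low-MAF assays), the masked estimate is optimistic for
  those cells.
* **The truth panel is correct.** Discordance charges every disagreement to
  the imputer; genotyping errors in the original panel inflate it.

### Masks

A mask set holds `n` pairwise-disjoint sets of genotype cells. In
`genotype` mode each mask hides exactly `m = round(p·N)` cells at every
locus (rounding half away from zero; `N` = samples). Disjointness — a cell
appears in at most one mask, and never in a cell already missing in the
source — makes the set a partition-like family, a generalized
cross-validation in which the number of folds is free. It also makes every
mask exactly recoverable later by diffing missingness between a masked file
and the truth, which is how `estimate_quality()` works when only the files
survive. The price of disjointness is a capacity constraint,
`n·m + missing(column) ≤ N` per column, enforced with an error naming the
tightest column. In `snp` mode whole variant columns are hidden
(`round(p·L)` per mask, drawn without replacement across the set),
emulating the reconstruction of entirely untyped markers.

With pre-existing missingness the *overall* missing fraction of a masked
file exceeds `p` — by construction, since masks avoid the already-missing
cells; the mask-set summary and the manifest record both.

One seeded generator drives the whole set, with a fixed draw order (columns
outer, masks inner), so a `(panel, p, n, mode, seed)` tuple reproduces the
identical mask set on any platform with the same RNG (the generator name is
written into the manifest header). The TSV manifest — one row per masked
cell, keyed by sample id and variant position — is written alongside the
masked files so that mask generation, imputation and scoring can run in
separate processes or on separate machines.

### Discordance

A masked cell counts as wrong when its imputed unordered allele pair
differs from the truth in one or both alleles; phase is deliberately
ignored, because masked inputs lose phase and the quantity of interest is
genotype reconstruction. The statistic per imputed file is
`discordance = n_wrong / n_masked`. Cells the imputer left missing count as
wrong (with a warning reporting how many): silently dropping them would
bias the estimate downward, and an imputer's job is to fill everything.
Cells missing in the *original* panel are never evaluated — there is no
truth there.

Panels are aligned before comparison: by sample id when both sides carry
real ids, and by variant `(chrom, pos)` when both sides have coordinates
(position alone when one side came from `.inp`, which stores no
chromosome); otherwise strictly by index with a length check. Misalignments
are errors, not warnings.

### The error curve and parameter selection

Sweeping a model parameter (the haplotype-cluster count K of a
cluster-model imputer, or its EM cycle count) produces discordance records
labelled by parameter value; `summarize_curve()` reduces them to median and
sample standard deviation (n−1 denominator) per value, the conventional
"median (SD) of n imputations" summary. Two selection rules are exposed
because real curves come in two shapes:

* `min` — for curves with a clear interior minimum, the bias–variance
  signature typical when a single homogeneous population is imputed.
* `elbow` (default) — for monotonically decreasing, asymptotic curves,
  typical for pooled heterogeneous populations where the minimum lies past
  the affordable range of K. Both axes are min-max normalized to [0, 1]; a
  chord joins the first and last points, and the selected parameter is the
  point of maximum perpendicular distance *below* the chord (the convex
  side of a decreasing curve). Ties take the smallest parameter; an exactly
  collinear curve returns the smallest parameter with a "no elbow" warning,
  since claiming a bend there would be fiction.

Normalization makes the choice invariant to rescaling either axis — a
property the tests assert — at the cost of depending on the endpoints of
the sweep; extending the swept range can legitimately move the elbow.
`elbow` needs at least three points.

### Population-genetic utilities

The Reynolds distance between two populations is computed exactly as the
ratio of locus-summed components:

$$\Theta = \frac{\sum_{j}\sum_{i}\left(p_{ij}-q_{ij}\right)^2}
                {2\sum_{j}\left(1-\sum_{i} p_{ij} q_{ij}\right)}$$

with frequencies estimated as observed allele counts over genotyped
chromosomes. Loci without any genotyped sample in a population are flagged
absent and dropped pairwise (per population pair, to keep the most loci per
pair). A zero denominator — both populations fixed for the same allele at
every usable locus — yields Θ = 0, the correct limit for identical
populations. The exact Hardy–Weinberg test enumerates the conditional
distribution of the heterozygote count given the allele counts and sums the
probabilities of configurations no likelier than the observed one, the
standard exact test that Plink applies by default.

Variant filters run in a fixed, reported order — MAF, HWE, call rate,
positional duplicates, id pattern — because the filters interact and the
removal counts depend on the order; the per-filter report makes the
pipeline auditable. The duplicate filter removes *all* members of a
duplicated-position group by default (the conservative reading;
`dedup_keep = "first"` gives the other).

## Built-in imputers and the external adapter

The two built-in imputers are deliberately naive. `major_allele` fills with
the modal observed genotype of the locus (lexicographic tie-break);
`freq_sample` draws both alleles from the locus's observed allele
frequencies (seeded). Neither uses linkage disequilibrium, so neither is
competitive — that is the point: on Hardy–Weinberg data their expected
discordance has a closed form (for the modal-homozygote fill at major-allele
frequency *f*, 1 − f²; for frequency sampling, 1 − Σ_g P(g)²), which turns
them into analytic oracles for the whole counting machinery, and into
honest floors that any real imputer should beat.

External imputers are driven through a shell template containing `{input}`
and `{output}` exactly once each. The adapter renders and executes the
template per masked file, captures each run's output to a log, checks exit
status and output existence, and returns outputs in input order; it never
parses imputer output itself (reading is `read_panel()`'s job). Since such
imputers are typically single-threaded, `workers > 1` runs several
single-CPU processes concurrently, each writing to its own path.

## The simulator: what it emulates, and what it does not

Two generators make the toolkit self-contained:

* `simulate_populations()` implements the Balding–Nichols divergence model:
  an ancestral allele frequency per locus (uniform on (0.05, 0.5) by
  default, the ascertained-SNP range of a genotyping array), and a
  per-population frequency drawn from a Beta with that mean and shape
  parameters `p(1−F)/F`, `(1−p)(1−F)/F` (`F = 0` is a point mass).
  Genotypes are Hardy–Weinberg within populations. The generator returns
  its true frequencies, so frequency estimation and Reynolds distances can
  be checked against truth; `F` pairs of 0.01 and 0.15 reproduce the
  continental-scale regimes of human reference panels (closely related
  European samples vs an African outgroup).
* `simulate_mosaic_panel()` produces the haplotype-cluster structure that
  cluster-model imputers assume: a small founder pool (8 by default), each
  sampled haplotype copying one founder with per-locus template switches
  (0.02) and copy errors (0.005). The founder paths are attached to the
  returned panel so switch counts are auditable.

What the simulator does **not** emulate: coalescent genealogies,
recombination-map-shaped LD decay, allele-frequency ascertainment bias,
genotyping error, or relatedness between samples. Passing tests on these
panels therefore demonstrate that the *accounting* — masking, counting,
selection, distances — is correct, not that any particular imputer will
reach a particular accuracy on real data; real-data discordances must be
measured on real panels.

Defaults are fixed once in `sim_config()` (60 diploids, 500 loci, F = 0.05,
5% missingness) to resemble a single-population SNP-array chromosome panel
at workable desk scale.

## Numerical and design choices

* **Rounding**: per-column mask counts use round-half-away-from-zero;
  the rule is recorded in the manifest so external reimplementations can
  match counts exactly.
* **Missingness is genotype-level**: a half-missing VCF genotype (`0/.`)
  is stored fully missing, because the discordance criterion operates on
  whole genotypes.
* **Phase flag**: a VCF panel is phased only if *every* genotype uses `|`;
  mixed separators downgrade to unphased with a warning. Phase affects only
  output formatting — comparison is unordered.
* **Multiallelic variants** are carried in panels and VCF, and recoded to
  digits 0–9 on `.inp` export (a one-character-per-site format); more than
  ten alleles at a locus cannot be expressed there and raise an error.
* **HWE p-values** are computed from log-factorials with a
  `(1 + 1e-12)` slack when summing "no likelier than observed"
  configurations, guarding against ties lost to floating point.
* **Elbow tie-break**: first index at the maximum distance, i.e. the
  smallest parameter — the cheaper model, on the principle that ties should
  not buy complexity.
* **Θ division by zero** returns 0 (with a warning if the numerator is
  nonzero, which indicates inconsistent input).
* **Degenerate loci**: an all-missing locus has no modal genotype; built-in
  imputers fill it homozygous for the first-listed allele and say so.

## Problem sizes used in the checks

The shipped test-and-verification suite exercises: 200 randomized panels
for format round-trips; a 100 × 1000 panel for the mask-set contract
(p = 0.1, n = 5 — ten cells per column per mask, fifty per column across the
set); 100 randomized panel/mask/imputation triples against a brute-force
recount; Balding–Nichols pairs of 500 diploids × 2000 loci at F = 0.01 and
0.15 for Reynolds recovery (within three bootstrap standard errors of
generator truth); full enumeration of every HWE table with ≤ 40–50
genotypes; 1000 random monotone curves against exhaustive chord-distance
search; and the complete simulate–mask–impute–score–select workflow on a
50 × 300 mosaic panel. These sizes were chosen as the smallest at which the
stochastic checks have comfortable power.

## Known limitations

* `.inp` parsing follows the two fastPHASE dialects (with and without id
  lines), auto-detected from the line count; exotic header extensions
  (subpopulation labels) are not supported.
* VCF handling is GT-only; INFO/QUAL fields are not preserved through a
  read–write cycle.
* The discordance denominator counts genotypes, not alleles; per-allele
  error rates and per-SNP correlation metrics (r², INFO) are different
  statistics and out of scope.
* Masking is uniform at random; stratified (e.g. MAF-stratified) masking is
  not implemented.
* The elbow is endpoint-dependent by construction; report the swept range
  alongside the selected parameter.
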