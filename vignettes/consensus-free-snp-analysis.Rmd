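---
title: "Consensus-free SNP analysis of granulovirus isolate mixtures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus-free SNP analysis of granulovirus isolate mixtures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gvpop)
```

## The problem

Naturally occurring baculovirus isolates — here the Cydia pomonella
granulovirus (CpGV), a biocontrol agent of the codling moth — are usually
mixtures of several genotypes. A consensus sequence built from deep
sequencing keeps only the majority base at every position, so minority
genotypes vanish from any downstream comparison. gvpop instead works
directly on per-site nucleotide *counts* obtained by mapping every
isolate's reads to one common reference: the frequency of the alternative
base at a diagnostic position is an estimate of the proportion of the
genotype carrying it. Nothing in the pipeline ever collapses the counts to
a consensus.

The pipeline has five analysis stages:

1. **Stringency filtering** (`apply_filters()`): a site/isolate pair is
   *variable* only when total depth > 100, alternative count > 10, and
   alternative frequency f > 0.05 — all bounds strict. Each site is reduced
   to the reference base plus a single *first alternative*, the
   non-reference base with the highest count summed across all isolates
   (second and third alternatives carry almost no reads after filtering).
   Sites variable in no isolate are dropped.
2. **Specificity assignment** (`assign_specificity()`): each retained
   position is labelled with the exact set of isolates in which it is
   variable. Singleton labels are isolate-specific markers; larger labels
   are group-specific markers. Positions sharing a label form a *marker
   set* (`build_marker_sets()`).
3. **Composition quantification** (`quantify_marker_sets()`): for every
   isolate and marker set, the median (with 5th/95th percentiles) of the
   alternative frequency across the set's positions estimates the
   proportion of the corresponding genotype in that isolate.
4. **SNP classification** (`classify_snps()`, `density_table()`,
   `compare_classes()`): transition/transversion, coding/noncoding, codon
   position and synonymy against an ORF annotation on the circular genome,
   per-ORF SNP densities per kbp, and a Tukey-transformed one-way
   ANOVA/HSD/t-test comparison across ORF functional classes.
5. **HCPC** (`run_pca()`, `hierarchical_cluster()`,
   `cut_and_consolidate()`): PCA of the isolate-by-position frequency
   matrix, Ward (D2) clustering on the leading components, a tree cut, and
   a k-means consolidation started from the cut centroids.

Alongside these, `count_repeats()` genotypes a 12-bp tandem repeat in the
*pe38* gene — a marker of type-I-resistance-breaking — directly from reads,
anchored by the unique 12-nt upstream and 10-nt downstream flanks of the
repeat array.

## Conventions and tunable parameters

* Coordinates are 1-based inclusive everywhere; circularity of the
  reference is declared, never inferred. Wrap-around ORFs (end < start) are
  legal on circular references; their lengths use modular arithmetic.
* Filter thresholds (`filter_config()`): depth 100, alternative count 10,
  frequency 0.05 — the published stringency settings; all strict. The
  frequency denominator is the full four-base depth, so frequencies
  conserve to one.
* The first alternative is chosen *globally* per site (summed counts, ties
  broken A < C < G < T) so that a site's alternative identity is shared
  across isolates — without this, cross-isolate specificity would compare
  different alleles.
* "Missing alternative counts" in the specificity rules means a false
  variability flag, not a raw zero; a `raw_zero` mode exists for
  sensitivity analysis.
* Marker-set labels for composition tables are computed on the **field
  sub-panel** (`assign_specificity(x, isolates = ...)`): commercial
  isolates are quantified on the field-derived sets but their variability
  does not join the labels. With mixtures of field-derived genotypes in
  commercial products, full-panel labels would absorb every E-containing
  product into the group-E label and the printed combined-group sets could
  not exist. The full-panel assignment is still used to split positions
  into field-specific versus commercial-only (`partition_by_panel()`).
* The genotype of the mapping reference itself leaves no alternative trace
  in its own isolate, so its diagnostic set is the one variable in *every
  other* field isolate; `reference_marker_set()` relabels that complement
  set and flags it for quantification by the reference-base frequency.
* The composition statistic defaults to the median (the reported form);
  the mean is exposed via `statistic = "mean"`. Percentiles interpolate
  linearly between order statistics; rounding to integers happens only in
  the rendered table.
* `collapse_groups()` implements the absence-driven relabelling of
  combined marker sets: member groups whose own specific sets quantify
  below 1% are removed, and a two-group combination minus a known member
  yields the remaining member (clamped to [0, 100]). A subset exceeding
  its superset by more than 5 points signals genotype heterogeneity and
  warns rather than fails — heterogenous isolates genuinely violate the
  single-proportion model, and the numbers are reported as-is.
* Tukey ladder of powers: lambda on a grid from -2 to 2 in steps of 0.05
  (the ladder's conventional range), chosen to maximise the Shapiro-Wilk
  statistic; non-positive lambdas are skipped when zeros are present. For
  near-normal input the Shapiro surface is almost flat in lambda, so the
  chosen value is only meaningful to within a broad band — the tests
  assert direction, not the exact grid point.
* HCPC: columns are standardised to unit variance by default (the
  convention of the standard HCPC implementations; `scale = FALSE` is
  exposed). Seven components are retained by default. Ward.D2 on Euclidean
  distances; the suggested cluster count maximises the relative
  inertia-gain drop g(k)/g(k+1); the k-means consolidation starts from the
  tree-cut centroids and is therefore deterministic, making the whole
  clustering seed-free. Missing variability is encoded as frequency 0, not
  NA — "no alternative seen" is informative absence in this design.
* Repeat counting is exact-match on both flanks (presence/absence of fixed
  marker sequences); reads with repeated flank hits are ambiguous and
  discarded, flank-to-flank distances that are not multiples of the unit
  are tallied separately as irregular, and the spanned sequence must be
  exact tandem copies of the motif unless `verify_motif = FALSE`. Every
  read is also scanned as its reverse complement, so the histogram is
  strand-symmetric.

## What the synthetic data emulate

The package ships no sequencing data; `simulate_counts_from_freq()` draws
multinomial base counts at declared true alternative frequencies under a
uniform-miscall error model (each sequenced base is misread with rate
epsilon, spread evenly over the three wrong bases), with per-site depths
from a truncated normal per isolate. The genotype layer
(`make_panel()` / `simulate_counts()`) builds the frequency matrix as
carriage-times-proportions: an isolate's true alternative frequency at a
SNP is the summed proportion of the genotypes carrying it.

`simulate_study()` instantiates the full 20-isolate study structure:
twelve field isolates and eight commercial/selected ones at the published
mean read depths (540x to 4,345x), 753 variable sites of which 544 are
transitions, nine named marker blocks with the published sizes
(58/68/24/30/89/21/22/75/45), 291 assorted field-specific sites (including
30 group-E fingerprint sites distinguishing the two group-E genotypes and
one reference-anomaly site at position 105,178 that is near-fixed for the
alternative in every isolate), 30 commercial-only sites, and 20
sub-threshold internal-variation sites of the reference isolate that the
filters must remove. Mixture proportions come from the published
composition medians. Two design liberties keep the structure identifiable
at these depths and were fixed when the generator was written: every
nonzero mixture component is at least 0.09 (well above the 0.05
variability threshold), and depths are floored at 150 (above the depth
threshold). Consequently a few unchecked composition cells sit at the
margin rather than at their printed values (e.g. the Iranian-genotype
component of one isolate is 10% rather than 2%). The heterogenous group-B
genotype receives a shared per-site beta-distributed frequency profile (a
"wave"), emulating the one isolate pair whose genotype proportions are not
constant along the genome.

What the simulation does *not* emulate: alignment and mapping artefacts,
strand bias, base-quality structure, indels other than the repeat locus,
linkage between nearby sites, and the empirical spectrum of the real
frequency matrix. Passing the end-to-end tests therefore shows that the
pipeline recovers a known mixture structure from realistic counts — not
that any particular biological claim about real isolates is reproduced.
For the same reason the cumulative variance of the leading seven principal
components on the synthetic panel (about 83%) is a property of the
synthetic frequency matrix, and the suggested cluster count from the
inertia-gain rule fluctuates with the seed; the qualitative clustering
facts (the two homogenous pairs co-cluster at k = 6) are stable.

`simulate_repeat_reads()` places fixed-length reads uniformly over a
synthetic repeat locus with designed copy-number class probabilities, on
random strands, with the same miscall model; pads are resampled if a flank
sequence occurs spuriously. With generous pads some reads span only one
flank and are uninformative, as in real data.

## Numerical and degenerate-input choices

* Zero-depth cells yield NA frequencies and can never be variable.
* Ties in the first-alternative choice are broken by fixed base order so
  parsing and filtering are order-independent and reproducible.
* A filtered matrix reaching `assign_specificity()` with a position
  variable in no isolate is a pipeline-order violation and errors.
* PCA applies a deterministic sign convention (largest-magnitude loading
  positive); zero-variance columns are dropped with a warning when
  scaling.
* The k-means consolidation cannot increase within-cluster inertia (it
  starts at the tree-cut centroids); cutting at k equal to the isolate
  count makes consolidation the identity.
* ORF lengths that are not multiples of 3 are accepted at annotation time
  with a warning (wrap-around annotation arithmetic is still useful) but
  refuse codon classification.
* Overlapping ORFs: a SNP is classified in every ORF containing it; the
  genome-wide tally counts it once, under the lexicographically lowest ORF
  id, and as nonsynonymous if it is nonsynonymous in any containing ORF
  (the conservative choice); overlap counts are reported separately.

## Problem sizes used in tests

The test suite and the acceptance script run entirely on simulated data:
the 20-isolate, 773-site study panel (seconds to simulate and analyse),
100 random 5-isolate matrices against a brute-force specificity oracle,
200 random SNPs against a whole-genome translation oracle, 20 replicate
mixtures at depth 2,000 for proportion recovery, and 2,000-read repeat
simulations. The full suite completes in well under a minute of CPU time.

## Known limitations

* Quantification assumes each genotype component has one proportion per
  isolate; heterogenous isolates (the "wave" pattern) violate this and are
  flagged, not modelled. No likelihood-based mixture deconvolution is
  attempted — the method is marker-set summary statistics by design.
* Specificity labels are exact sets under fixed thresholds; a component
  sitting at the threshold flips membership with sampling noise. The
  published structure is only reproducible because its components sit away
  from the thresholds.
* The repeat counter needs both flanks on one read, so it cannot genotype
  arrays longer than the read length minus the flanks.
* Upstream steps (trimming, mapping, pileup) are out of scope; the package
  starts from count tables or allele-depth VCFs.
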