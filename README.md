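# gvpop

Consensus-free SNP analysis of granulovirus isolate mixtures.

Baculovirus isolates — such as those of the Cydia pomonella granulovirus
(CpGV), sprayed worldwide as a biocontrol agent of the codling moth — are
usually *mixtures* of genotypes. A consensus sequence keeps only the
majority base at each position and silently erases the minority genotypes.
gvpop analyses deep-sequencing data of many isolates mapped to one common
reference entirely at the level of per-site nucleotide counts:

* **Filtering.** A site/isolate pair is variable iff depth > 100,
  alternative count > 10 and alternative frequency ƒ > 0.05 (all strict);
  each site keeps the reference base and the single *first alternative*.
* **Specificity.** Every variable position is labelled with the exact set
  of isolates in which it is variable; positions sharing a label form a
  *marker set* (isolate-specific or group-specific).
* **Composition.** The median of ƒ over a genotype's marker set in an
  isolate estimates that genotype's proportion there:
  ƒ<sub>a</sub>, ƒ<sub>b</sub> and a shared ƒ<sub>a+b</sub> ≈ 1 form the
  typical signature of a two-genotype mixture. Combined-group sets can be
  collapsed when member groups are demonstrably absent (B = BE − E).
* **SNP classes.** Transition/transversion, coding/noncoding, codon
  position and synonymy on the circular genome (wrap-around ORFs
  supported), SNP density per kbp per ORF, Tukey-transformed
  ANOVA/Tukey-HSD/t-test across ORF functional classes.
* **pe38 repeats.** Copy number of a 12-bp tandem repeat counted directly
  from reads that carry both unique flanks of the repeat array — the
  marker of type-I-resistance-breaking isolates.
* **HCPC.** PCA of the isolate × position frequency matrix, Ward.D2
  clustering on the leading 7 components, tree cut, deterministic k-means
  consolidation.

A synthetic-data module (`make_panel()`, `simulate_counts()`,
`simulate_repeat_reads()`, `simulate_study()`) generates references,
genotype panels, mixed-isolate count matrices and repeat-region reads with
known ground truth, including a full 20-isolate panel that encodes the
published study structure (depths, marker-set sizes, mixture
proportions). Standard formats are supported throughout: count-table TSV,
multi-sample VCF with allele depths, FASTA, GFF3, FASTQ, Newick.

## Worked example

```r
library(gvpop)

study    <- simulate_study(seed = 1)          # synthetic 20-isolate panel
filtered <- apply_filters(study$matrix)       # stringency filters
filtered
#> filtered_snp_matrix: 753 variable sites x 20 isolates (depth > 100, alt > 10, f > 0.05)

field <- panel_subset(study$panel, "field")
sets  <- build_marker_sets(assign_specificity(filtered, field))
rs    <- reference_marker_set(sets, field, "M")   # the reference genotype set
q     <- quantify_marker_sets(filtered, c(list(M = rs), sets["E2"]))
composition_table(q)[c("M", "V003", "KS1", "KS2", "E2", "V15"), ]
#>      M             E2
#> M    100 (100-100) 0 (0-0)
#> V003 100 (100-100) 0 (0-0)
#> KS1  69 (67-71)    0 (0-0)
#> KS2  86 (83-87)    0 (0-0)
#> E2   18 (7-34)     85 (63-94)
#> V15  9 (8-10)      42 (40-43)
```

Reading the table: each cell is "median (5th–95th percentile)" of the
marker-set frequency, in per cent — the estimated proportion of that
genotype in that isolate. The reference-derived isolates M and V003 are
pure reference genotype (100); KS1 is a 69:31 mixture of the reference
genotype and a group-E genotype; the commercial product V15 contains 42%
of the group-B genotype; E2's wide percentile band (63–94) flags its
genotype heterogeneity.

```r
fm  <- freq_matrix(filtered)
hc  <- hierarchical_cluster(run_pca(fm), n_components = 7)
res <- cut_and_consolidate(hc, k = 6)
split(names(res$assignment), res$assignment)   # M+V003 and WW+S co-cluster
```

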