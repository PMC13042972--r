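# editomeKit

Tools for building and genetically dissecting an A-to-I RNA editome from
RNA-seq alone — no matched DNA required. The package covers the full
analysis arc used in multi-tissue editome studies:

* **Site discovery without genotypes.** Per-sample mismatch pileups are
  passed through a fixed filter cascade (read-start trimming, homopolymer
  exclusion, known-SNP removal, a genome self-similarity mask for
  alignment artifacts, region-stratified support thresholds, and a
  per-tissue recurrence filter), then strand-corrected against the gene
  annotation. The editing level at a site is the ratio of edited reads to
  total covering reads.
* **Self-similarity masking.** The genome is tiled into 76 bp windows
  every 19 bp and re-aligned to itself by exact k-mer seeding plus
  ungapped extension; windows hitting another locus with aligned length
  ≥ 61 bp and identity ≥ 94% mark both loci as artifact-prone. Mismatches
  at such loci (outside annotated repeats) are discarded.
* **Editome characterization.** Site-by-sample matrices live in an
  `EditingExperiment` (a `RangedSummarizedExperiment`); tissue specificity
  uses Shannon entropy (< 0.4 bits with a tissue-mean range > 10%);
  co-editing modules come from soft-power correlation networks
  (|r|^4 adjacency, average-linkage clustering, minimum module size 30).
* **cis-edQTL mapping.** Editing levels are logit-transformed, residualized
  on permutation-selected principal components, inverse-normal transformed,
  and regressed on SNP dosages within ±1 Mb; per-site significance uses a
  permutation minimum-p null with a Beta tail approximation, followed by
  Benjamini-Hochberg FDR at 5% and forward-backward stepwise selection of
  conditionally independent signals.
* **Allele-specific editing (ASED).** For heterozygous carriers of a
  nearby SNP, the two alleles form matched pairs across replicate
  individuals; a shared-overdispersion beta-binomial likelihood-ratio test
  detects allelic imbalance in editing.
* **Trait integration.** Squared GWAS Z-score enrichment of lead edQTL
  SNPs against MAF- and LD-score-matched controls, greedy LD clumping
  (r² 0.4 / 250 kb), Wakefield approximate-Bayes-factor colocalization
  (posteriors PP0-PP4, shared-variant calls at PP4 > 0.9), and
  average-information REML heritability partitioning over SNP categories.
* **Cross-species conservation.** UCSC chain-file parsing and block-wise
  coordinate lifting (minimum match fraction 0.5 for intervals),
  conservation-score filtering (phastCons-style, score > 0.5), catalog
  overlap, and permutation enrichment.
* **A seeded synthetic-data generator** (`simulateEditome()`) that emits
  every input layer — genome FASTA, repeat/duplication/homopolymer
  annotation, GTF, genotypes, pileups, allelic counts, GWAS summaries —
  with planted ground truth, so every stage is testable end to end.

The intended users are statistical-genomics practitioners who want a
transparent, fully scriptable re-implementation of this pipeline at desk
scale, with every filter and test specified in code.

## Worked example

Simulate a small three-tissue study, build the self-similarity mask, run
the filter cascade, and map one planted edQTL:

```r
library(editomeKit)
library(data.table)

cfg <- simConfig(seed = 7, genome_length = 40000, n_chromosomes = 1,
                 n_genes = 15, n_edit_sites = 300, n_artifact_sites = 60,
                 n_snp_leak_sites = 60, n_snps = 600, n_edqtl = 40,
                 n_duplicated_segments = 4, samples_per_tissue = 30)
sim  <- simulateEditome(cfg)
mask <- buildSimilarityMask(sim$genome$genome)
mask
#> SimilarityMask: 7 intervals, 3344 bp masked

cascade <- runFilterCascade(sim$pileups, sim$genome$genome,
                            sim$genome$repeats, mask,
                            sim$truth$snps[, .(chrom, pos, ref, alt)],
                            sim$genome$gtf, c(T1 = 30, T2 = 30, T3 = 30))
cascade$steps
#>            called     read_position       homopolymer         known_snp
#>             33435             33123             32814             30173
#>        similarity region_stratified          presence
#>             25122             22490               741
```

The per-sample candidate count drops at each filter; the presence filter
(≥ 20 samples and ≥ 10% of a tissue) collapses the table to 741
site-tissue records. The strand-corrected catalog is dominated by
canonical A-to-G substitutions:

```r
mutationSpectrum(cascade$sites)[1:3]
#>    substitution     n   fraction
#> 1:          A>G   227 0.82545455
#> 2:          C>G     9 0.03272727
#> 3:          G>T     8 0.02909091
```

Against the planted truth this catalog has sensitivity 0.917 and
precision 1.000. Editing levels go into an `EditingExperiment`:

```r
ee <- buildEditingExperiment(sim$pileups, cascade$sites)
ee
#> EditingExperiment: 275 sites x 90 samples (3 tissues)
summary(unname(sampleOverallLevel(ee)))
#>  Min. 1st Qu. Median  Mean 3rd Qu.  Max.
#> 0.281   0.293  0.299 0.298   0.304 0.312
```

A cis scan at one planted edQTL site recovers the causal variant:

```r
#> site ED00001: planted causal rs00173 (slope -1.22); lead rs00173,
#> slope -1.66 (SD units), empirical p 0.0031
```

The lead SNP is the planted causal variant; its slope is on the
standardized (inverse-normal) phenotype scale, and the empirical p comes
from the Beta-approximated 1,000-permutation null.

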