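---
title: "Methods: detection and genetic mapping of A-to-I RNA editing"
author: "editomeKit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detection and genetic mapping of A-to-I RNA editing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models, the filtering rules, the
numerical choices and the deliberate design decisions behind editomeKit.
It is the companion to the README's worked example: nothing here states
an empirical result that the test-suite or `scripts/acceptance.R` does
not itself compute.

## The problem

Adenosine-to-inosine (A-to-I) editing is read by sequencers as an A-to-G
mismatch against the reference genome. Calling editing sites from RNA-seq
without matched DNA means separating genuine editing from three noise
classes: sequencing errors, genomic variants leaking into the RNA
mismatch stream, and alignment artifacts at self-similar loci. The
package implements a cascade of filters targeting each class, then
quantifies editing, maps its cis genetic regulation (edQTLs), verifies
regulation through allele-specific editing, connects edQTLs to complex
traits, and assesses cross-species conservation.

## Site discovery

### The observation layer

The unit of observation is a pileup record: per site and sample, the
counts of A/C/G/T reads, mean base and mapping quality, and the number of
mismatching reads whose mismatch lies in the first 6 bases of the read.
Alignment and pileup generation themselves are out of scope; the package
consumes the site-level table (TSV) and the synthetic generator produces
it directly.

### Filter cascade

The order is fixed and re-running any filter on its own output is a
no-op:

1. **Candidate calling** — the highest-count non-reference base per
   (site, sample), ties broken alphabetically; thresholds
   `min_edited = 2`, `min_coverage = 10`, `minBQ = 25`, `minMQ = 20`. The
   quality thresholds are conventional values for editing callers; they
   are configurable because the acceptance surface here is recovery of
   synthetic truth, not any fixed count.
2. **Read-start trimming** — support from mismatches in the first 6 read
   bases is subtracted (read starts are enriched for artifacts);
   candidates falling below `min_edited` are dropped. Only the first 6
   bases are trimmed, not both read ends.
3. **Homopolymer filter** — candidates inside or within ±1 bp of a
   reference run of ≥ 5 identical bases are removed. The ±1 bp adjacency
   reads "in homopolymer runs" inclusively; indel-induced misalignment
   affects the run boundary as well as the run itself.
4. **Known-SNP filter** — candidates at panel positions are removed.
   Removal is allele-aware by default (only when the candidate's alt
   matches the panel alt); a positional mode is available since panels
   often omit allele detail.
5. **Similarity filter** — candidates outside annotated repeats that fall
   in the self-similarity mask (below) are removed. Repeat candidates are
   exempt: the repeat-region editing signal is real and dense, and the
   mask would otherwise swallow it.
6. **Region-stratified support** — non-repeat candidates face stricter
   thresholds (edited ≥ 3, level ≥ 0.1) than repeat candidates
   (edited ≥ 2, level ≥ 0.05). The exact "more stringent" values are not
   fixed by convention anywhere; these defaults are explicit and
   configurable.
7. **Presence filter** — a site is kept in a tissue iff called in ≥ 20
   samples *and* ≥ 10% of that tissue's samples. The calibration helper
   (`calibratePresenceThreshold()`) reports, over a grid of recurrence
   thresholds, the retained-site count and the strand-corrected A-to-G
   share. On synthetic data the share rises while recurrence removes
   sporadic errors and then plateaus; on the plateau only binomial
   sampling jitter among true sites remains, so monotonicity is asserted
   up to 0.5 percentage points.

Strand correction happens after the presence filter and before spectrum
computation: sites in minus-strand genes have their substitution
complemented (T-to-C becomes A-to-G); sites in no gene, or overlapping
genes on both strands, keep their type and carry an ambiguity flag.

### Self-similarity mask

The genome is tiled into 76 bp windows every 19 bp (no partial tail
window), mirroring a read-length re-mapping simulation. Each window is
re-aligned to the whole genome by exact k-mer seeding (k = 16, seeds
every 8 bp within the window, both strands) followed by ungapped X-drop
extension (match +1, mismatch −2, drop 8), confined to the window's
columns. A non-source hit with extended aligned length ≥ 61 bp and
identity ≥ 94% masks **both** the window and the hit interval — the
symmetric choice, since self-similarity is a property of the pair.
Gapped alignment is deliberately omitted: the decision rule is pure
length + identity, and an ungapped extender is deterministic and exactly
testable against a brute-force all-diagonals oracle (the test-suite does
this on 20 seeded genomes, requiring agreement up to one window length at
interval boundaries).

## Editome characterization

* **Editing level** = edited reads / covering reads; the per-sample
  overall level is the ratio of totals (coverage-weighted), not the mean
  of ratios.
* **Tissue specificity** — sites eligible when covered by ≥ 50 reads in
  ≥ 30 samples; the tissue-mean profile is normalized to a probability
  vector and its Shannon entropy computed in bits (base 2; the threshold
  0.4 is stated without a base anywhere, so bits are chosen and the
  threshold is configurable). A site is tissue-specific when entropy
  < 0.4 bits and the tissue-mean range exceeds 10 percentage points.
  Entropy on the normalized rather than raw means is this package's
  choice; both options move together for unimodal profiles.
* **Co-editing modules** — preprocessing drops sites missing in ≥ 4
  tissues, tissues missing ≥ 50% of sites, sites with coefficient of
  variation < 0.8 and sites observed in < 10 tissues; adjacency is
  |Pearson r|^4, clustered by average linkage on 1 − adjacency with a
  fixed cut height (0.9); clusters below 30 sites merge into "grey".
  The topological-overlap transform is omitted — plain adjacency
  clustering is the declared simplification, validated by planted-block
  recovery (adjusted Rand index ≥ 0.8 at within-block r = 0.9) rather
  than by equivalence to any external network package. Hub sites are
  members correlating with the module eigen-profile at ≥ 0.8 (a kME rule;
  no standard definition exists for hub counts); module-tissue
  correlation is the Pearson r between the eigen-profile and the tissue
  indicator.
* **Annotation** — region classes use the fixed precedence
  exonic > UTR3/UTR5 > intronic > up/downstream (±1 kb) > intergenic
  across transcripts; coding consequences come from codon substitution on
  the annotated frame, `unknown` when the transcript has no CDS.

## cis-edQTL mapping

Per tissue and site with ≥ 30 covered samples:

1. **Transformation** — pseudo-count logit
   `log(((k+0.5)/(n+1)) / (1 − (k+0.5)/(n+1)))` (which also handles the
   0 and 1 boundaries), OLS residualization on covariate PCs, then a
   rank-based inverse-normal transform with Blom offset 3/8 and average
   ranks for ties, rescaled to unit sample variance so the phenotype is
   exactly N(0, 1)-calibrated in mean and SD.
2. **Covariate PCs** — the number of phenotype PCs is chosen by a
   seeded permutation (parallel-analysis) criterion: keep leading PCs
   whose explained-variance share exceeds the 95th percentile of a
   column-permutation null (100 permutations). This is an explicit,
   reproducible operationalization of an otherwise unspecified
   "empirical" PC significance rule.
3. **Scan** — simple linear regression on dosage for every SNP within
   ±1 Mb with MAF ≥ 0.05 (the common-variant cutoff is not fixed
   anywhere; 0.05 is the field default and configurable), two-sided
   t-test on the slope. The implementation is vectorized normal
   equations and is tested to 1e-10 against `lm()`.
4. **Permutations** — the phenotype is permuted (default 1,000 times),
   the minimum nominal p recorded per permutation, a Beta distribution
   fitted by maximum likelihood (Nelder-Mead on log shapes, moment
   starts) and the observed minimum p evaluated on its CDF. The direct
   rank p is also reported and used when the fit fails. Against a
   10,000-permutation direct estimate the Beta p agrees within ±0.02 for
   ≥ 90% of sites (and within ±0.05 always) — the residual difference is
   Monte-Carlo noise of both estimators.
5. **FDR** — Benjamini-Hochberg on the per-site empirical p, significant
   at q < 0.05. Applying BH to the beta-approximated empirical p (rather
   than nominal p) is the standard reading when both are mentioned.
6. **Independent signals** — forward stepwise selection conditioning on
   all previously selected SNPs, thresholded at the nominal p
   corresponding to the site's Beta null at 0.05, with a backward pass
   that drops signals losing conditional significance (avoiding
   order-of-entry artifacts). Collinear candidates are skipped.

Effect sizes on the inverse-normal scale are in SD units; the planted
logit-scale slopes are recovered without the INT step (plain
pseudo-count logit regression), which the acceptance suite verifies to
< 10% relative bias at n = 300.

Tissue sharing is the Spearman correlation of effects over (site, SNP)
pairs significant in at least one tissue of each pair; pairs with < 10
shared records are flagged low-confidence. Type-specific edQTLs are
those with maximum LD r² < 0.8 against every eQTL/sQTL SNP within ±1 Mb
(the comparison window is unbounded in principle; ±1 Mb covers cis LD).

## Allele-specific editing

Heterozygous individuals for a SNP near an editing site contribute a
matched pair of per-allele (edited, total) counts. Groups need ≥ 5
individuals (a minimal-replication default), both alleles covered. The
test models per-allele edited counts as beta-binomial with
allele-specific means and a **shared** overdispersion φ (parameterized
α = μ/φ, β = (1−μ)/φ, φ ≥ 1e-6 for stability), all fitted jointly by
maximum likelihood; H0 equates the means and the likelihood-ratio
statistic is referred to χ²(1). The published framework this
operationalizes is cited without equations in the literature, so the
implementation is validated by its statistical properties — type-I error
≤ 0.07 at α = 0.05 over 1,000 null groups and power ≥ 0.8 at a planted
1.5-logit allelic difference with 20 individuals at coverage 50 — rather
than by equation identity. A coverage-weighted paired t-test on
pseudo-count logits is the flagged fallback when the fit fails. BH
controls FDR at 5%.

## Trait integration

* **LD score** = 1 + Σ r² over same-chromosome SNPs within ±1 Mb (the
  window is a documented default; the definition is scale-free).
* **Matched controls** — per focal SNP, controls from the same
  chromosome with |ΔMAF| ≤ 0.02 and |ΔLD score| ≤ 0.1 SD, sampled
  without replacement where possible; a focal SNP may match itself (so
  degenerate pools behave as an exchangeability null) but never another
  focal SNP.
* **Z² enrichment** — ratio of the focal mean squared GWAS Z to the mean
  over re-drawn control sets; one-sided Wilcoxon rank-sum on the Z²
  values; empirical p = share of 1,000 control draws reaching the focal
  mean.
* **Clumping** — greedy: best remaining p, remove SNPs within 250 kb at
  r² ≥ 0.4; ties by position then identifier.
* **Colocalization** — Wakefield log-ABF `0.5(log(1−r) + r z²)` with
  `r = W/(W + se²)`; prior effect variances W = 0.2² for the quantitative
  QTL side and 0.15² for the GWAS side (the conventional defaults), and
  priors p1 = p2 = 1e-4, p12 = 1e-5. Hypothesis sums use log-sum-exp;
  H3 subtracts the same-SNP term in log space. Regions qualify when the
  minimum GWAS p is below 1e-5.
* **REML** — variance components for per-category GRMs (`ZZ'/M` over
  per-SNP standardized dosages — standardization only, no MAF-dependent
  weighting) by average-information REML with three initial EM steps,
  step-halving at the non-negativity boundary, and an EM fallback when
  the AI system is singular; non-convergence is flagged and the current
  estimate returned. Heritability enrichment of a category is its h²
  share divided by its SNP share.

## The synthetic generator

`simulateEditome()` emulates the data structure the pipeline assumes:

* a repeat-rich genome (35% PRE-like repeat cover; ~300 bp elements),
  duplicated segment pairs (12 pairs of 400 bp, identity 1 by default)
  placed outside repeats, planted homopolymer runs, and genes with
  exon/intron/UTR/CDS structure on both strands;
* 2,000 true editing sites inside genes (80% A-to-G on the annotated
  strand), baseline levels Beta(2, 5) truncated to [0.05, 0.9] with
  0.3-SD logit-scale tissue jitter, and a 5% single-tissue subset;
* 500 artifact sites confined to duplicated segments, 500 heterozygous
  genomic SNPs leaking as mismatches, and sporadic 1-2-read errors;
* 3,000 genotyped SNPs (MAF Uniform(0.05, 0.5)) with haplotype-block LD
  (blocks of 4, copy fidelity 0.98 giving within-block r² near 0.9);
  300 sites get cis effects of |slope| 0.5-1.5 logits;
* negative-binomial coverage (mean 50, dispersion 5 — a typical bulk
  RNA-seq depth at editing sites; no published coverage distribution
  exists to copy, so this default is configurable) and binomial edited
  reads; per-allele counts for heterozygous individuals are drawn
  directly as binomials per allele (read-level allele splitting is out
  of scope);
* a separate 2,000-individual GWAS cohort at the same SNP map, trait
  h² = 0.4 from 20 causal SNPs, half drawn from the planted edQTL SNPs.

Everything derives deterministically from one seed (per-stage child
seeds keep stages independently reproducible).

What passing tests on these data do **not** show: robustness to
alignment-level artifacts that vary along reads, to indel-driven
mispileups, to population structure in the cohort (genotypes are
exchangeable draws), or to the LD complexity of a real genome — the
100 kb per-chromosome scale makes a ±1 Mb cis window cover a whole
chromosome, which compresses LD relative to real data. Two analysis
choices in `scripts/acceptance.R` exist precisely because of this
compression: the Z²-enrichment control pool excludes SNPs in strong LD
(r² ≥ 0.8) with the focal set, and the colocalization region is chosen
so its GWAS lead is the planted shared variant (lead-SNP-centred loci),
since on a compressed genome a single ±1 Mb region otherwise contains
several unrelated causal variants and the single-causal-variant
assumption of the ABF model fails by construction.

## Problem sizes and run times

The default study conditions (three tissues × 60 samples, 2,000 true
sites) run the full generator + mask + cascade in about two minutes on
one CPU. The test-suite uses these conditions once (cached), 20 small
genomes for the mask oracle, 1,000-site calibration batches for the
edQTL and ASED properties, and 100 REML replicates at n = 500; the
acceptance script maps edQTLs for the planted-site set plus a 100-site
null background at 300 permutations. These sizes were chosen so each
property is measured with enough replication to be stable at the stated
thresholds while the whole suite remains a coffee-break run.

## Known limitations

* Ungapped self-alignment understates similarity for indel-diverged
  duplications; such loci reach the mask only if a 61 bp ungapped block
  survives.
* The beta-binomial LRT is slightly anticonservative for very small
  groups (the 0.07 type-I bound at n = 20 reflects this); the paired
  t fallback is more conservative.
* REML with a single GRM at n = 500 has an h² standard error around
  0.1; category enrichment at this scale is indicative, not sharp.
* Strand correction relies entirely on the gene annotation; sites in
  unannotated or bidirectionally transcribed regions keep their
  genomic-strand substitution and an ambiguity flag.
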