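test_that("simConfig validates counts and proportions", {
  expect_s3_class(simConfig(), "SimConfig")
  expect_error(simConfig(repeat_fraction = 1.2), "\\[0, 1\\]")
  expect_error(simConfig(n_snps = -1), ">= 0")
  expect_error(simConfig(genome_length = 5000), "10 kb")
  expect_length(simConfig(n_tissues = 4,
                          samples_per_tissue = 10)$samples_per_tissue, 4L)
})

test_that("genome simulation is seed-deterministic and honors config", {
  cfg <- simConfig(seed = 3L, genome_length = 20000L, n_chromosomes = 2L,
                   n_genes = 6L, n_duplicated_segments = 2L,
                   duplicated_length = 120L, duplicated_identity = 1.0)
  g1 <- simulateGenome(cfg)
  g2 <- simulateGenome(cfg)
  expect_identical(as.character(g1$genome), as.character(g2$genome))

  ## exact duplications: the two copies compare equal
  dup <- g1$duplications
  for (pr in unique(dup$pair)) {
    pair <- dup[dup$pair == pr]
    sq <- vapply(seq_along(pair), function(i)
      as.character(Biostrings::subseq(
        g1$genome[[as.character(GenomicRanges::seqnames(pair))[i]]],
        GenomicRanges::start(pair)[i], GenomicRanges::end(pair)[i])),
      character(1))
    expect_identical(sq[1], sq[2])
  }

  ## degenerate config: no repeats requested
  g0 <- simulateGenome(simConfig(seed = 3L, genome_length = 20000L,
                                 repeat_fraction = 0, n_genes = 6L,
                                 n_duplicated_segments = 2L))
  expect_length(g0$repeats, 0L)

  ## annotation intervals stay within chromosome bounds
  lens <- setNames(Biostrings::width(g1$genome), names(g1$genome))
  for (gr in list(g1$repeats, g1$duplications, g1$genes, g1$homopolymers)) {
    if (!length(gr)) next
    expect_true(all(GenomicRanges::start(gr) >= 1))
    expect_true(all(GenomicRanges::end(gr) <=
                    lens[as.character(GenomicRanges::seqnames(gr))]))
  }
})

test_that("infeasible packing raises an explicit error", {
  cfg <- simConfig(seed = 1L, genome_length = 10000L, n_chromosomes = 1L,
                   n_duplicated_segments = 30L, duplicated_length = 400L)
  expect_error(simulateGenome(cfg), "infeasible packing")
})

test_that("truth set honors composition targets and disjointness", {
  cfg <- simConfig(seed = 5L, genome_length = 60000L, n_chromosomes = 1L,
                   n_genes = 25L, n_edit_sites = 2000L,
                   a2g_fraction = 0.70, n_artifact_sites = 100L,
                   n_snp_leak_sites = 100L, n_snps = 600L, n_edqtl = 50L)
  g <- simulateGenome(cfg)
  tr <- simulateTruth(cfg, g)

  ## observed A-to-G share within 5 pp of the 70% target at n = 2000
  expect_lt(abs(mean(tr$true_sites$sub_tx == "A>G") - 0.70), 0.05)

  ## the three planted categories are disjoint
  k_true <- tr$true_sites[, paste(chrom, pos)]
  k_art <- tr$artifact_sites[, paste(chrom, pos)]
  k_leak <- tr$snp_leak_sites[, paste(chrom, pos)]
  expect_length(intersect(k_true, k_art), 0L)
  expect_length(intersect(k_true, k_leak), 0L)
  expect_length(intersect(k_art, k_leak), 0L)

  ## true sites avoid homopolymers and duplicated segments
  site_gr <- GenomicRanges::GRanges(
    tr$true_sites$chrom, IRanges::IRanges(tr$true_sites$pos, width = 1))
  expect_false(any(IRanges::overlapsAny(site_gr, g$homopolymers + 1L)))
  expect_false(any(IRanges::overlapsAny(site_gr, g$duplications)))

  ## every edQTL causal SNP lies within 1 Mb of its site
  m <- merge(tr$edqtl, tr$true_sites[, .(site_id, chrom, pos)],
             by = "site_id")
  m <- merge(m, tr$snps[, .(snp_id, snp_chrom = chrom, snp_pos = pos)],
             by = "snp_id")
  expect_true(all(m$chrom == m$snp_chrom & abs(m$pos - m$snp_pos) <= 1e6))

  ## tissue-specific subset near-zero outside its top tissue
  spec <- which(tr$true_sites$is_tissue_specific)
  if (length(spec)) {
    lev <- tr$tissue_levels[spec, , drop = FALSE]
    top <- tr$true_sites$top_tissue[spec]
    for (i in seq_along(spec)) {
      expect_lt(max(lev[i, colnames(lev) != top[i]]), 0.05)
      expect_gt(lev[i, top[i]], 0.1)
    }
  }

  ## zero tissue-specific fraction leaves the subset empty
  tr0 <- simulateTruth(simConfig(seed = 5L, genome_length = 60000L,
                                 n_chromosomes = 1L, n_genes = 25L,
                                 n_edit_sites = 200L, n_snps = 300L,
                                 tissue_specific_fraction = 0), g)
  expect_false(any(tr0$true_sites$is_tissue_specific))
})

test_that("genotypes have bounded MAF, LD blocks and seed determinism", {
  s <- getSmallSim()
  G <- s$genotypes
  f <- colMeans(G) / 2
  maf <- pmin(f, 1 - f)
  ## population MAF in [0.05, 0.5]; sample MAF gets slack for drift
  expect_true(all(maf <= 0.5 + 1e-9))
  expect_gt(mean(maf > 0.02), 0.97)

  ## adjacent block-copied SNPs are in strong LD
  bs <- s$cfg$ld_block_size
  r2 <- vapply(seq(1, 20 * bs, by = bs), function(j)
    suppressWarnings(cor(G[, j], G[, j + 1L]))^2, numeric(1))
  expect_gt(median(r2, na.rm = TRUE), 0.8)

  expect_identical(simulateGenotypes(s$cfg, s$truth),
                   simulateGenotypes(s$cfg, s$truth))
})

test_that("genotypes round-trip through VCF", {
  skip_if_not_installed("VariantAnnotation")
  s <- getSmallSim()
  idx <- 1:40
  G <- s$genotypes[, idx]
  f <- tempfile(fileext = ".vcf")
  writeGenotypesVcf(G, s$truth$snps[idx], f)
  rt <- readGenotypesVcf(f)
  expect_identical(unname(rt$genotypes[rownames(G), colnames(G)]),
                   unname(G))
  expect_equal(rt$snps[match(colnames(G), snp_id), pos],
               s$truth$snps[idx, pos])
})

test_that("pileups reproduce planted levels and conserve read counts", {
  s <- getSmallSim()
  pl <- s$pileups
  counts <- as.matrix(pl[, .(A, C, G, T)])
  expect_true(all(counts >= 0))
  refc <- counts[cbind(seq_len(nrow(pl)), match(pl$ref, c("A","C","G","T")))]
  expect_true(all(refc <= rowSums(counts)))

  ## high-coverage check of a planted level: pooled observed level close
  ## to the planted tissue mean
  ts <- s$truth$true_sites
  lev <- s$truth$tissue_levels
  non_qtl <- setdiff(ts$site_id, s$truth$edqtl$site_id)
  idx <- match(non_qtl[1:20], ts$site_id)
  for (i in idx) {
    sub <- pl[chrom == ts$chrom[i] & pos == ts$pos[i] & tissue == "T1"]
    cnt <- as.matrix(sub[, .(A, C, G, T)])
    obs <- sum(cnt[, match(ts$alt[i], c("A","C","G","T"))]) / sum(cnt)
    expect_lt(abs(obs - lev[i, "T1"]), 0.06)
  }

  ## het SNP-leak sites pool to ~50% in het carriers
  leak <- s$truth$snp_leak_sites[1:10]
  for (i in seq_len(nrow(leak))) {
    het <- rownames(s$genotypes)[s$genotypes[, leak$snp_id[i]] == 1L]
    if (length(het) < 5) next
    sub <- pl[chrom == leak$chrom[i] & pos == leak$pos[i] & sample %in% het]
    cnt <- as.matrix(sub[, .(A, C, G, T)])
    obs <- sum(cnt[, match(leak$alt[i], c("A","C","G","T"))]) / sum(cnt)
    expect_lt(abs(obs - 0.5), 0.08)
  }

  ## artifact mismatches emitted only inside duplicated segments
  art <- s$truth$artifact_sites
  art_gr <- GenomicRanges::GRanges(art$chrom,
                                   IRanges::IRanges(art$pos, width = 1))
  expect_true(all(IRanges::overlapsAny(art_gr, s$genome$duplications)))
})

test_that("GWAS summaries are calibrated under the null and powered for causals", {
  cfg0 <- simConfig(seed = 9L, genome_length = 40000L, n_chromosomes = 1L,
                    n_duplicated_segments = 4L,
                    n_genes = 15L, n_edit_sites = 100L, n_snps = 5000L,
                    n_gwas_causal = 0L, gwas_n = 1500L,
                    n_artifact_sites = 20L, n_snp_leak_sites = 20L,
                    n_edqtl = 10L)
  g0 <- simulateGenome(cfg0)
  tr0 <- simulateTruth(cfg0, g0)
  gw0 <- simulateGwas(tr0, cfg0)
  ## null: mean Z^2 within 0.1 of 1 at 5,000 SNPs
  expect_lt(abs(mean(gw0$z^2) - 1), 0.1)

  s <- getSmallSim()
  gw <- simulateGwas(s$truth, s$cfg)
  causal_z <- gw[snp %in% s$truth$gwas_causal, abs(z)]
  expect_gt(max(causal_z), 5)
  expect_identical(simulateGwas(s$truth, s$cfg), gw)
})
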