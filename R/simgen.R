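## Synthetic editome generator: produces every input the pipeline consumes
## (genome, annotation, genotypes, pileups, allelic counts, GWAS summaries)
## with planted ground truth, fully determined by a single seed.

#' Simulation configuration
#'
#' Builds and validates the configuration object that drives the synthetic
#' editome generator. Defaults define the standard study conditions used
#' throughout the test-suite: a repeat-rich two-chromosome genome, three
#' tissues of 60 samples each, 2,000 true A-to-I-dominated editing sites,
#' 500 alignment-artifact sites confined to duplicated segments and 500
#' genomic-SNP "leak" sites, with cis genetic effects on a subset of sites.
#'
#' @param seed Integer master seed; every derived stream is seeded from it.
#' @param genome_length Total genome length (bp), split over chromosomes.
#' @param n_chromosomes Number of chromosomes.
#' @param repeat_fraction Proportion of the genome covered by PRE-like
#'   short interspersed repeats.
#' @param n_duplicated_segments Number of duplicated segment pairs
#'   (alignment-artifact-prone regions).
#' @param duplicated_length Length of each duplicated segment (bp).
#' @param duplicated_identity Sequence identity between the two copies.
#' @param homopolymer_rate Planted homopolymer runs per kb.
#' @param n_genes Number of genes (strand assigned at random).
#' @param n_tissues,samples_per_tissue Tissue layout; `samples_per_tissue`
#'   is recycled to `n_tissues`.
#' @param n_edit_sites Number of true editing sites.
#' @param a2g_fraction Target fraction of true sites that are A-to-G on the
#'   annotated strand.
#' @param level_shape1,level_shape2 Beta parameters for per-site baseline
#'   editing levels (truncated to `[0.05, 0.9]`).
#' @param tissue_sd SD of per-tissue logit-scale jitter around the baseline.
#' @param tissue_specific_fraction Fraction of true sites edited in a single
#'   tissue only (near-zero elsewhere).
#' @param n_artifact_sites Artifact mismatch sites, placed inside duplicated
#'   segments.
#' @param n_snp_leak_sites Genomic SNPs emitted as RNA mismatches.
#' @param n_snps Genotyped SNP count.
#' @param maf_min,maf_max Uniform MAF bounds.
#' @param ld_block_size SNPs per copied haplotype block (creates LD).
#' @param ld_copy_fidelity Per-SNP probability that a block SNP copies the
#'   block haplotype (controls within-block r2).
#' @param n_edqtl Number of true sites given a cis genetic effect.
#' @param slope_min,slope_max Absolute cis effect (logit scale), sign random.
#' @param coverage_mean,coverage_dispersion Negative-binomial read coverage.
#' @param base_error_rate Per-base sequencing error probability.
#' @param n_error_sites Random positions receiving sporadic error mismatches.
#' @param gwas_n GWAS cohort size.
#' @param n_gwas_causal Causal SNPs behind the simulated trait.
#' @param causal_overlap_fraction Fraction of GWAS causal SNPs drawn from the
#'   planted edQTL SNPs.
#' @param gwas_h2 Trait heritability in the GWAS cohort.
#' @return A validated list of class `SimConfig`.
#' @export
simConfig <- function(seed = 1L,
                      genome_length = 200000L, n_chromosomes = 2L,
                      repeat_fraction = 0.35,
                      n_duplicated_segments = 12L, duplicated_length = 400L,
                      duplicated_identity = 1.0,
                      homopolymer_rate = 0.5, n_genes = 60L,
                      n_tissues = 3L, samples_per_tissue = 60L,
                      n_edit_sites = 2000L, a2g_fraction = 0.8,
                      level_shape1 = 2, level_shape2 = 5,
                      tissue_sd = 0.3, tissue_specific_fraction = 0.05,
                      n_artifact_sites = 500L, n_snp_leak_sites = 500L,
                      n_snps = 3000L, maf_min = 0.05, maf_max = 0.5,
                      ld_block_size = 4L, ld_copy_fidelity = 0.98,
                      n_edqtl = 300L, slope_min = 0.5, slope_max = 1.5,
                      coverage_mean = 50, coverage_dispersion = 5,
                      base_error_rate = 0.001, n_error_sites = 1000L,
                      gwas_n = 2000L, n_gwas_causal = 20L,
                      causal_overlap_fraction = 0.5, gwas_h2 = 0.4) {
  cfg <- as.list(environment())
  counts <- c("genome_length", "n_chromosomes", "n_duplicated_segments",
              "duplicated_length", "n_genes", "n_tissues", "n_edit_sites",
              "n_artifact_sites", "n_snp_leak_sites", "n_snps", "n_edqtl",
              "n_error_sites", "gwas_n", "n_gwas_causal", "ld_block_size")
  for (nm in counts)
    if (any(cfg[[nm]] < 0)) stop(sprintf("'%s' must be >= 0", nm))
  props <- c("repeat_fraction", "duplicated_identity", "a2g_fraction",
             "tissue_specific_fraction", "maf_min", "maf_max",
             "base_error_rate", "causal_overlap_fraction", "gwas_h2",
             "ld_copy_fidelity")
  for (nm in props)
    if (any(cfg[[nm]] < 0 | cfg[[nm]] > 1))
      stop(sprintf("'%s' must lie in [0, 1]", nm))
  if (genome_length < 10000) stop("genome_length must be >= 10 kb")
  cfg$samples_per_tissue <- rep_len(as.integer(samples_per_tissue),
                                    cfg$n_tissues)
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "SimConfig")
}

## non-overlapping interval placement by rejection sampling
.placeIntervals <- function(chrom_lens, n, len, occupied = NULL,
                            max_tries = 50000L) {
  if (n == 0L)
    return(GRanges())
  chroms <- names(chrom_lens)
  occ <- lapply(chroms, function(chr) {
    if (is.null(occupied) || !length(occupied))
      return(list(s = integer(0), e = integer(0)))
    sel <- as.character(seqnames(occupied)) == chr
    list(s = start(occupied)[sel], e = end(occupied)[sel])
  })
  names(occ) <- chroms
  probs <- chrom_lens / sum(chrom_lens)
  out_chr <- character(n); out_s <- integer(n)
  found <- 0L; tries <- 0L
  while (found < n && tries < max_tries) {
    tries <- tries + 1L
    chr <- chroms[sample.int(length(chroms), 1L, prob = probs)]
    if (chrom_lens[[chr]] < len) next
    s <- sample.int(chrom_lens[[chr]] - len + 1L, 1L)
    e <- s + len - 1L
    o <- occ[[chr]]
    if (length(o$s) && any(s <= o$e & e >= o$s)) next
    occ[[chr]] <- list(s = c(o$s, s), e = c(o$e, e))
    found <- found + 1L
    out_chr[found] <- chr; out_s[found] <- s
  }
  if (found < n)
    stop("infeasible packing: requested features exceed available genome")
  GRanges(out_chr, IRanges(out_s, width = len))
}

#' Simulate a genome with annotation layers
#'
#' Generates random chromosome sequences with planted homopolymer runs,
#' PRE-like repeat intervals, duplicated segment pairs (near-exact copies,
#' the substrate for alignment artifacts) and a gene annotation with
#' exon/intron/UTR/CDS structure on both strands. Duplicated segments are
#' placed outside repeat intervals so that artifact mismatches fall under
#' the non-repeat similarity filter downstream.
#'
#' @param config A [simConfig()] object.
#' @return A list with elements `genome` (named [Biostrings::DNAStringSet]),
#'   `repeats`, `duplications` (GRanges, with `pair` and `role` columns),
#'   `homopolymers` (all reference runs >= 5 bp), `genes` (gene-level
#'   GRanges) and `gtf` (feature-level GRanges with `type`, `gene_id`,
#'   `transcript_id`).
#' @export
simulateGenome <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(childSeed(config$seed, 1L))
  n_chr <- config$n_chromosomes
  chrom_lens <- rep(config$genome_length %/% n_chr, n_chr)
  names(chrom_lens) <- paste0("chr", seq_len(n_chr))

  seqs <- lapply(chrom_lens, function(L)
    sample(c("A", "C", "G", "T"), L, replace = TRUE))

  ## planted homopolymer runs (5-8 bp)
  n_homo <- round(config$homopolymer_rate * config$genome_length / 1000)
  if (n_homo > 0) {
    hp <- .placeIntervals(chrom_lens, n_homo, 8L)
    for (i in seq_along(hp)) {
      chr <- as.character(seqnames(hp))[i]
      run_len <- sample(5:8, 1L)
      s <- start(hp)[i]
      seqs[[chr]][s:(s + run_len - 1L)] <-
        sample(c("A", "C", "G", "T"), 1L)
    }
  }

  ## duplicated segment pairs: copy source onto target with configurable
  ## identity; both copies recorded
  n_dup <- config$n_duplicated_segments
  dup_len <- config$duplicated_length
  dup_all <- .placeIntervals(chrom_lens, 2L * n_dup, dup_len)
  duplications <- GRanges()
  if (n_dup > 0) {
    src <- dup_all[seq_len(n_dup)]
    tgt <- dup_all[n_dup + seq_len(n_dup)]
    for (i in seq_len(n_dup)) {
      schr <- as.character(seqnames(src))[i]
      tchr <- as.character(seqnames(tgt))[i]
      piece <- seqs[[schr]][start(src)[i]:end(src)[i]]
      mut <- runif(dup_len) > config$duplicated_identity
      if (any(mut))
        piece[mut] <- vapply(piece[mut], function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
      seqs[[tchr]][start(tgt)[i]:end(tgt)[i]] <- piece
    }
    duplications <- suppressWarnings(c(src, tgt))
    mcols(duplications)$pair <- rep(seq_len(n_dup), 2L)
    mcols(duplications)$role <- rep(c("source", "copy"), each = n_dup)
  }

  ## PRE-like repeats: ~300 bp intervals to the target genome fraction,
  ## kept clear of duplicated segments
  rep_target <- config$repeat_fraction * config$genome_length
  repeats <- GRanges()
  if (rep_target > 0) {
    n_rep <- ceiling(rep_target / 300)
    repeats <- .placeIntervals(chrom_lens, n_rep, 300L,
                               occupied = duplications)
  }

  ## genes: 3 exons, CDS spanning mid-exon1 to mid-exon3, UTRs at the ends
  gtf_rows <- list()
  gene_occ <- GRanges()
  for (g in seq_len(config$n_genes)) {
    w_ex <- sample(100:250, 3L, replace = TRUE)
    w_in <- sample(100:400, 2L, replace = TRUE)
    glen <- sum(w_ex, w_in)
    gr <- .placeIntervals(chrom_lens, 1L, glen,
                          occupied = suppressWarnings(c(gene_occ,
                                                        duplications)))
    gene_occ <- suppressWarnings(c(gene_occ, gr))
    chr <- as.character(seqnames(gr)); gs <- start(gr)
    strand_g <- sample(c("+", "-"), 1L)
    e1 <- c(gs, gs + w_ex[1] - 1L)
    e2 <- c(e1[2] + w_in[1] + 1L, e1[2] + w_in[1] + w_ex[2])
    e3 <- c(e2[2] + w_in[2] + 1L, e2[2] + w_in[2] + w_ex[3])
    cds_s <- e1[1] + w_ex[1] %/% 2L
    cds_e <- e3[1] + w_ex[3] %/% 2L
    cds_len <- (cds_e - cds_s + 1L) - w_in[1] - w_in[2]
    cds_e <- cds_e - (cds_len %% 3L)   # keep CDS in frame
    gid <- sprintf("G%04d", g); tid <- paste0(gid, ".1")
    add <- function(type, s, e) {
      if (e < s) return(NULL)
      data.frame(chrom = chr, start = s, end = e, strand = strand_g,
                 type = type, gene_id = gid, transcript_id = tid)
    }
    utr_left <- add(if (strand_g == "+") "five_prime_utr" else
                      "three_prime_utr", e1[1], cds_s - 1L)
    utr_right <- add(if (strand_g == "+") "three_prime_utr" else
                       "five_prime_utr", cds_e + 1L, e3[2])
    gtf_rows[[g]] <- do.call(rbind, Filter(Negate(is.null), list(
      add("gene", e1[1], e3[2]), add("transcript", e1[1], e3[2]),
      add("exon", e1[1], e1[2]), add("exon", e2[1], e2[2]),
      add("exon", e3[1], e3[2]),
      add("CDS", cds_s, e1[2]), add("CDS", e2[1], e2[2]),
      add("CDS", e3[1], cds_e),
      utr_left, utr_right)))
  }
  gtf_df <- do.call(rbind, gtf_rows)
  gtf <- GRanges(gtf_df$chrom, IRanges(gtf_df$start, gtf_df$end),
                 strand = gtf_df$strand, type = gtf_df$type,
                 gene_id = gtf_df$gene_id,
                 transcript_id = gtf_df$transcript_id)
  genes <- gtf[gtf$type == "gene"]

  genome <- Biostrings::DNAStringSet(vapply(seqs, paste0, character(1),
                                            collapse = ""))
  names(genome) <- names(chrom_lens)

  ## all reference homopolymer runs >= 5 bp, detected from the final sequence
  homopolymers <- suppressWarnings(do.call(c, lapply(names(seqs), function(chr) {
    r <- rle(seqs[[chr]])
    ends <- cumsum(r$lengths)
    keep <- r$lengths >= 5L
    if (!any(keep)) return(GRanges())
    GRanges(chr, IRanges(ends[keep] - r$lengths[keep] + 1L, ends[keep]))
  })))

  list(genome = genome, repeats = sort(repeats),
       duplications = sort(duplications), homopolymers = sort(homopolymers),
       genes = genes, gtf = gtf)
}

#' Simulate the planted truth set
#'
#' Chooses true editing sites (predominantly A-to-G on the annotated strand,
#' clear of homopolymer runs and duplicated segments), artifact sites
#' (inside duplicated segments), SNP-leak sites, the genotyped SNP map,
#' cis-edQTL assignments, the tissue-specific subset and the GWAS causal
#' set. The three planted site categories are disjoint by construction.
#'
#' @param config A [simConfig()].
#' @param genome Output of [simulateGenome()].
#' @return A list of class `TruthSet`; see fields in the source. Per-tissue
#'   mean levels are stored in `tissue_levels` (sites x tissues, linear
#'   scale).
#' @export
simulateTruth <- function(config, genome) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(childSeed(config$seed, 2L))
  chrom_lens <- setNames(Biostrings::width(genome$genome),
                         names(genome$genome))
  seq_chars <- lapply(names(genome$genome), function(chr)
    strsplit(as.character(genome$genome[[chr]]), "")[[1]])
  names(seq_chars) <- names(genome$genome)
  comp <- c(A = "T", C = "G", G = "C", T = "A")

  ## forbidden zone for true sites: homopolymers (+-1 bp) and duplications
  forbidden <- GenomicRanges::reduce(suppressWarnings(c(
    genome$homopolymers + 1L, genome$duplications)))

  gene_gr <- genome$genes
  pos_gr <- function(chr, pos) GRanges(chr, IRanges(pos, width = 1))

  ## candidate in-gene positions with transcript-strand base A (for A>G)
  pick_positions <- function(n, want_base_txs) {
    empty <- data.table::data.table(chrom = character(0), pos = integer(0),
                                    gene = character(0),
                                    gene_strand = character(0))
    if (n <= 0L) return(empty)
    out <- empty
    tries <- 0L
    while (nrow(out) < n && tries < 200L) {
      tries <- tries + 1L
      gi <- sample(length(gene_gr), 1L)
      chr <- as.character(seqnames(gene_gr))[gi]
      st <- as.character(strand(gene_gr))[gi]
      span <- start(gene_gr)[gi]:end(gene_gr)[gi]
      base <- seq_chars[[chr]][span]
      tx_base <- if (st == "+") base else comp[base]
      ok <- if (is.null(want_base_txs)) rep(TRUE, length(span)) else
        tx_base == want_base_txs
      cand <- span[ok]
      if (!length(cand)) next
      k <- min(length(cand), max(1L, n %/% 20L))
      take <- cand[sample.int(length(cand), k)]
      keep <- !ovAny(pos_gr(chr, take), forbidden)
      take <- take[keep]
      if (!length(take)) next
      out <- unique(rbind(out, data.table::data.table(
        chrom = chr, pos = take, gene = gene_gr$gene_id[gi],
        gene_strand = st)), by = c("chrom", "pos"))
    }
    if (nrow(out) < n)
      stop("n_edit_sites exceeds available positions")
    out[sample(nrow(out), n)]
  }

  n_a2g <- round(config$n_edit_sites * config$a2g_fraction)
  n_other <- config$n_edit_sites - n_a2g
  a2g <- pick_positions(n_a2g, "A")
  a2g[, sub_tx := "A>G"]
  other <- pick_positions(if (n_other > 0L) n_other + 50L else 0L, NULL)
  other <- other[!a2g, on = c("chrom", "pos")]
  if (nrow(other) < n_other)
    stop("n_edit_sites exceeds available positions")
  other <- other[seq_len(n_other)]
  other_ref <- mapply(function(chr, pos, st) {
    b <- seq_chars[[chr]][pos]; if (st == "+") b else comp[[b]]
  }, other$chrom, other$pos, other$gene_strand)
  other[, sub_tx := paste0(other_ref, ">", vapply(other_ref, function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1)))]
  true_sites <- rbind(a2g, other)

  ## genomic-strand ref/alt
  txs <- data.table::tstrsplit(true_sites$sub_tx, ">")
  plus <- true_sites$gene_strand == "+"
  true_sites[, ref := ifelse(plus, txs[[1]], comp[txs[[1]]])]
  true_sites[, alt := ifelse(plus, txs[[2]], comp[txs[[2]]])]
  true_sites[, in_repeat := ovAny(
    pos_gr(chrom, pos), genome$repeats)]

  ## per-tissue mean levels
  n_sites <- nrow(true_sites)
  n_tis <- config$n_tissues
  base_lev <- rbeta(n_sites, config$level_shape1, config$level_shape2)
  base_lev <- pmin(pmax(base_lev, 0.05), 0.9)
  lev <- invlogit(matrix(logit(base_lev), n_sites, n_tis) +
                  matrix(rnorm(n_sites * n_tis, 0, config$tissue_sd),
                         n_sites, n_tis))
  n_spec <- round(config$tissue_specific_fraction * n_sites)
  spec_idx <- if (n_spec > 0) sample(n_sites, n_spec) else integer(0)
  top_tissue <- rep(NA_integer_, n_sites)
  if (n_spec > 0) {
    top_tissue[spec_idx] <- sample(n_tis, n_spec, replace = TRUE)
    for (i in spec_idx) {
      lev[i, ] <- 0.01
      lev[i, top_tissue[i]] <- pmin(pmax(base_lev[i], 0.2), 0.9)
    }
  }
  colnames(lev) <- paste0("T", seq_len(n_tis))
  true_sites[, site_id := sprintf("ED%05d", .I)]
  true_sites[, is_tissue_specific := seq_len(.N) %in% spec_idx]
  top_lab <- ifelse(is.na(top_tissue), NA_character_,
                    paste0("T", top_tissue))
  true_sites[, top_tissue := top_lab]

  taken <- pos_gr(true_sites$chrom, true_sites$pos)

  ## artifact sites inside duplicated segments
  artifact <- data.table::data.table()
  if (config$n_artifact_sites > 0 && length(genome$duplications)) {
    dup <- genome$duplications
    di <- sample(length(dup), config$n_artifact_sites, replace = TRUE)
    apos <- start(dup)[di] + sample.int(width(dup)[1], # equal widths
                                        config$n_artifact_sites,
                                        replace = TRUE) - 1L
    artifact <- unique(data.table::data.table(
      chrom = as.character(seqnames(dup))[di], pos = apos),
      by = c("chrom", "pos"))
    artifact <- artifact[!true_sites, on = c("chrom", "pos")]
    artifact[, ref := mapply(function(c, p) seq_chars[[c]][p], chrom, pos)]
    artifact[, alt := vapply(ref, function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))]
    artifact[, level := runif(.N, 0.1, 0.4)]
  }

  ## SNP map; a subset doubles as leak sites
  snp_gr <- .placeIntervals(chrom_lens, config$n_snps, 1L,
                            occupied = suppressWarnings(
                              c(taken, pos_gr(artifact$chrom,
                                              artifact$pos))))
  snp_gr <- sort(snp_gr)
  snps <- data.table::data.table(
    snp_id = sprintf("rs%05d", seq_along(snp_gr)),
    chrom = as.character(seqnames(snp_gr)), pos = start(snp_gr))
  snps[, ref := mapply(function(c, p) seq_chars[[c]][p], chrom, pos)]
  snps[, alt := vapply(ref, function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))]
  snps[, maf := runif(.N, config$maf_min, config$maf_max)]

  leak_idx <- sample(nrow(snps), min(config$n_snp_leak_sites, nrow(snps)))
  snp_leak <- snps[leak_idx, .(snp_id, chrom, pos, ref, alt, maf)]

  ## cis-edQTL assignments: causal SNP on the site's chromosome within 1 Mb
  edqtl <- data.table::data.table()
  if (config$n_edqtl > 0) {
    cand_sites <- true_sites[is_tissue_specific == FALSE]
    es <- cand_sites[sample(.N, min(config$n_edqtl, .N))]
    rows <- lapply(seq_len(nrow(es)), function(i) {
      pool <- snps[chrom == es$chrom[i] & abs(pos - es$pos[i]) <= 1e6 &
                   !snp_id %in% snp_leak$snp_id]
      if (!nrow(pool)) return(NULL)
      s <- pool[sample(.N, 1L)]
      data.table::data.table(site_id = es$site_id[i], snp_id = s$snp_id,
                             slope = sample(c(-1, 1), 1L) *
                               runif(1L, config$slope_min, config$slope_max))
    })
    edqtl <- data.table::rbindlist(rows)
  }

  gwas_causal <- character(0)
  if (config$n_gwas_causal > 0) {
    n_from_edqtl <- round(config$n_gwas_causal * config$causal_overlap_fraction)
    n_from_edqtl <- min(n_from_edqtl, nrow(edqtl))
    from_ed <- if (n_from_edqtl > 0)
      sample(unique(edqtl$snp_id), n_from_edqtl) else character(0)
    rest_pool <- setdiff(snps$snp_id, c(from_ed, snp_leak$snp_id))
    n_rest <- config$n_gwas_causal - n_from_edqtl
    if (length(rest_pool) < n_rest)       # tiny maps: allow leak SNPs
      rest_pool <- setdiff(snps$snp_id, from_ed)
    gwas_causal <- c(from_ed, sample(rest_pool,
                                     min(n_rest, length(rest_pool))))
  }

  structure(list(true_sites = true_sites, tissue_levels = lev,
                 artifact_sites = artifact, snp_leak_sites = snp_leak,
                 snps = snps, edqtl = edqtl, gwas_causal = gwas_causal),
            class = "TruthSet")
}

## haplotype-block genotype simulator shared by study and GWAS cohorts
.simDosages <- function(snps, n_ind, block_size, fidelity) {
  m <- nrow(snps)
  block <- ceiling(seq_len(m) / block_size)
  ## restart blocks at chromosome boundaries
  block <- as.integer(factor(paste(snps$chrom, block)))
  hap <- function() {
    h <- matrix(0L, n_ind, m)
    for (b in unique(block)) {
      idx <- which(block == b)
      f <- mean(snps$maf[idx])
      core <- rbinom(n_ind, 1L, f)
      for (j in idx) {
        keep <- runif(n_ind) < fidelity
        h[, j] <- ifelse(keep, core, rbinom(n_ind, 1L, snps$maf[j]))
      }
    }
    h
  }
  hap() + hap()
}

#' Simulate genotype dosages
#'
#' Biallelic dosages (0/1/2) for the study cohort, with LD produced by
#' copying haplotype-block indicators across adjacent SNPs.
#'
#' @param config A [simConfig()].
#' @param truth A [simulateTruth()] result (provides the SNP map).
#' @param n_ind Number of individuals; defaults to the total study samples.
#' @param seed_offset Internal stream offset (GWAS cohort uses a different
#'   one).
#' @return Integer matrix, individuals x SNPs, columns named by SNP id.
#' @export
simulateGenotypes <- function(config, truth,
                              n_ind = sum(config$samples_per_tissue),
                              seed_offset = 3L) {
  stopifnot(inherits(config, "SimConfig"), inherits(truth, "TruthSet"))
  set.seed(childSeed(config$seed, seed_offset))
  G <- .simDosages(truth$snps, n_ind, config$ld_block_size,
                   config$ld_copy_fidelity)
  colnames(G) <- truth$snps$snp_id
  rownames(G) <- sprintf("S%03d", seq_len(n_ind))
  G
}

#' Simulate per-sample mismatch pileups and allelic counts
#'
#' Emits the observation layer the filter cascade consumes: for every
#' planted site and sample, negative-binomial coverage and binomial edited
#' reads at the site's (possibly genotype-shifted) editing level; artifact
#' mismatches only inside duplicated segments; heterozygous genomic SNPs as
#' ~50% mismatch sites; sporadic base errors at random positions. Per-allele
#' count tables are emitted for heterozygous individuals at planted edQTL
#' (site, SNP) pairs.
#'
#' @param truth A [simulateTruth()] result.
#' @param genotypes Study-cohort dosage matrix from [simulateGenotypes()].
#' @param config A [simConfig()].
#' @param genome A [simulateGenome()] result.
#' @return List with `pileups` (long data.table: sample, tissue, chrom, pos,
#'   ref, A, C, G, T, meanBQ, meanMQ, n_mismatch_in_first6) and
#'   `allelic_counts` (individual, tissue, snp_id, chrom, pos, allele,
#'   edited, total).
#' @export
simulatePileups <- function(truth, genotypes, config, genome) {
  stopifnot(inherits(config, "SimConfig"), inherits(truth, "TruthSet"))
  set.seed(childSeed(config$seed, 4L))
  n_tis <- config$n_tissues
  spt <- config$samples_per_tissue
  sample_ids <- rownames(genotypes)
  tissue_of <- rep(paste0("T", seq_len(n_tis)), times = spt)
  names(tissue_of) <- sample_ids
  cm <- config$coverage_mean; cd <- config$coverage_dispersion
  err <- config$base_error_rate

  ts <- truth$true_sites
  n_sites <- nrow(ts)
  n_samp <- length(sample_ids)

  ## site x sample expected levels (logit shift at edQTL sites)
  lev_mat <- truth$tissue_levels[, match(tissue_of, colnames(truth$tissue_levels)),
                                 drop = FALSE]
  eta <- logit(pmin(pmax(lev_mat, 1e-4), 1 - 1e-4))
  if (nrow(truth$edqtl)) {
    ridx <- match(truth$edqtl$site_id, ts$site_id)
    dos <- t(genotypes[, truth$edqtl$snp_id, drop = FALSE])  # qtl x samples
    eta[ridx, ] <- eta[ridx, ] + truth$edqtl$slope * dos
  }
  p_edit <- invlogit(eta)

  cov_mat <- matrix(rnbinom(n_sites * n_samp, size = cd, mu = cm),
                    n_sites, n_samp)
  ed_mat <- matrix(rbinom(n_sites * n_samp, cov_mat, p_edit),
                   n_sites, n_samp)

  mk_counts <- function(chrom, pos, ref, alt, cov, ed) {
    n <- length(cov)
    other_err <- rbinom(n, pmax(cov - ed, 0L), err)
    counts <- matrix(0L, n, 4L, dimnames = list(NULL, c("A", "C", "G", "T")))
    counts[cbind(seq_len(n), match(ref, colnames(counts)))] <-
      pmax(cov - ed - other_err, 0L)
    counts[cbind(seq_len(n), match(alt, colnames(counts)))] <-
      counts[cbind(seq_len(n), match(alt, colnames(counts)))] + ed
    if (any(other_err > 0)) {
      oi <- which(other_err > 0)
      ob <- vapply(oi, function(i)
        sample(setdiff(c("A", "C", "G", "T"), c(ref[i], alt[i])), 1L),
        character(1))
      counts[cbind(oi, match(ob, colnames(counts)))] <-
        counts[cbind(oi, match(ob, colnames(counts)))] + other_err[oi]
    }
    n_mm <- rowSums(counts) - counts[cbind(seq_len(n),
                                           match(ref, colnames(counts)))]
    data.table::data.table(
      chrom = chrom, pos = pos, ref = ref,
      A = counts[, "A"], C = counts[, "C"], G = counts[, "G"],
      T = counts[, "T"],
      meanBQ = pmin(40, pmax(20, round(rnorm(n, 35, 2), 1))),
      meanMQ = pmin(60, pmax(30, round(rnorm(n, 55, 3), 1))),
      n_mismatch_in_first6 = rbinom(n, n_mm, 6 / 76))
  }

  per_sample <- vector("list", n_samp)
  art <- truth$artifact_sites
  leak <- truth$snp_leak_sites
  for (j in seq_len(n_samp)) {
    blocks <- list(
      mk_counts(ts$chrom, ts$pos, ts$ref, ts$alt, cov_mat[, j], ed_mat[, j]))
    if (nrow(art)) {
      acov <- rnbinom(nrow(art), size = cd, mu = cm)
      aed <- rbinom(nrow(art), acov, art$level)
      blocks <- c(blocks, list(mk_counts(art$chrom, art$pos, art$ref,
                                         art$alt, acov, aed)))
    }
    if (nrow(leak)) {
      d <- genotypes[j, leak$snp_id]
      lcov <- rnbinom(nrow(leak), size = cd, mu = cm)
      lp <- c(err, 0.5, 1 - err)[d + 1L]
      led <- rbinom(nrow(leak), lcov, lp)
      blocks <- c(blocks, list(mk_counts(leak$chrom, leak$pos, leak$ref,
                                         leak$alt, lcov, led)))
    }
    dt <- data.table::rbindlist(blocks)
    dt[, sample := sample_ids[j]]
    dt[, tissue := tissue_of[j]]
    per_sample[[j]] <- dt
  }
  pileups <- data.table::rbindlist(per_sample)

  ## sporadic base errors at random clean positions, 1-3 samples each
  if (config$n_error_sites > 0) {
    chrom_lens <- setNames(Biostrings::width(genome$genome),
                           names(genome$genome))
    epos <- .placeIntervals(chrom_lens, config$n_error_sites, 1L)
    echr <- as.character(seqnames(epos)); ep <- start(epos)
    eref <- mapply(function(c, p)
      substr(as.character(genome$genome[[c]]), p, p), echr, ep)
    rows <- lapply(seq_along(ep), function(i) {
      sj <- sample(n_samp, sample(1:3, 1L))
      cov <- rnbinom(length(sj), size = cd, mu = cm)
      ed <- pmin(cov, 1L + rbinom(length(sj), 1L, 0.3))
      alt <- sample(setdiff(c("A", "C", "G", "T"), eref[i]), 1L)
      dt <- mk_counts(rep(echr[i], length(sj)), rep(ep[i], length(sj)),
                      rep(eref[i], length(sj)), rep(alt, length(sj)),
                      cov, ed)
      dt[, sample := sample_ids[sj]]
      dt[, tissue := tissue_of[sample_ids[sj]]]
      dt
    })
    pileups <- data.table::rbindlist(c(list(pileups), rows))
  }
  data.table::setkey(pileups, sample, chrom, pos)

  ## per-allele counts for het individuals at planted edQTL pairs
  allelic <- data.table::data.table()
  if (nrow(truth$edqtl)) {
    ed <- truth$edqtl
    ridx <- match(ed$site_id, ts$site_id)
    rows <- lapply(seq_len(nrow(ed)), function(k) {
      het <- which(genotypes[, ed$snp_id[k]] == 1L)
      if (!length(het)) return(NULL)
      tis <- tissue_of[sample_ids[het]]
      base <- logit(pmin(pmax(
        truth$tissue_levels[ridx[k], match(tis, colnames(truth$tissue_levels))],
        1e-4), 1 - 1e-4))
      tot_ref <- rnbinom(length(het), size = cd, mu = cm / 2)
      tot_alt <- rnbinom(length(het), size = cd, mu = cm / 2)
      data.table::data.table(
        individual = rep(sample_ids[het], 2L),
        tissue = rep(tis, 2L),
        snp_id = ed$snp_id[k],
        chrom = ts$chrom[ridx[k]], pos = ts$pos[ridx[k]],
        allele = rep(c("ref", "alt"), each = length(het)),
        edited = c(rbinom(length(het), tot_ref, invlogit(base)),
                   rbinom(length(het), tot_alt,
                          invlogit(base + ed$slope[k]))),
        total = c(tot_ref, tot_alt))
    })
    allelic <- data.table::rbindlist(Filter(Negate(is.null), rows))
  }

  list(pileups = pileups, allelic_counts = allelic)
}

#' Simulate GWAS summary statistics
#'
#' Simulates a quantitative trait in an independent cohort genotyped at the
#' same SNP map (same MAFs and haplotype-block LD process) and returns
#' per-SNP marginal regression summaries.
#'
#' @param truth A [simulateTruth()] result (`gwas_causal` defines the causal
#'   set).
#' @param config A [simConfig()].
#' @return data.table: snp, chrom, pos, beta, se, z, p, n, maf.
#' @export
simulateGwas <- function(truth, config) {
  stopifnot(inherits(config, "SimConfig"), inherits(truth, "TruthSet"))
  G <- simulateGenotypes(config, truth, n_ind = config$gwas_n,
                         seed_offset = 5L)
  set.seed(childSeed(config$seed, 6L))
  n <- nrow(G); m <- ncol(G)
  causal <- truth$gwas_causal
  y <- rnorm(n)
  if (length(causal)) {
    Xc <- scale(G[, causal, drop = FALSE])
    Xc[is.na(Xc)] <- 0
    b <- rnorm(length(causal))
    gviol <- drop(Xc %*% b)
    gviol <- gviol / sd(gviol) * sqrt(config$gwas_h2 / (1 - config$gwas_h2))
    y <- y + gviol
  }
  y <- as.numeric(scale(y))
  ## vectorized marginal OLS
  gm <- colMeans(G)
  gc <- sweep(G, 2L, gm)
  sxx <- colSums(gc^2)
  sxy <- drop(crossprod(gc, y - mean(y)))
  beta <- sxy / sxx
  syy <- sum((y - mean(y))^2)
  sigma2 <- pmax((syy - beta * sxy) / (n - 2), 1e-12)
  se <- sqrt(sigma2 / sxx)
  z <- beta / se
  data.table::data.table(
    snp = colnames(G), chrom = truth$snps$chrom, pos = truth$snps$pos,
    beta = beta, se = se, z = z,
    p = 2 * pt(-abs(z), df = n - 2), n = n,
    maf = pmin(gm / 2, 1 - gm / 2))
}

#' Run the full synthetic generator
#'
#' Convenience wrapper producing every pipeline input for one seed.
#'
#' @param config A [simConfig()].
#' @return List: `config`, `genome`, `truth`, `genotypes`, `pileups`,
#'   `allelic_counts`, `gwas`.
#' @export
simulateEditome <- function(config = simConfig()) {
  genome <- simulateGenome(config)
  truth <- simulateTruth(config, genome)
  genotypes <- simulateGenotypes(config, truth)
  pl <- simulatePileups(truth, genotypes, config, genome)
  gwas <- simulateGwas(truth, config)
  list(config = config, genome = genome, truth = truth,
       genotypes = genotypes, pileups = pl$pileups,
       allelic_counts = pl$allelic_counts, gwas = gwas)
}

#' Write simulated inputs to disk in standard formats
#'
#' FASTA genome, BED annotation layers, GTF genes, TSV pileups and GWAS
#' summaries, and (if VariantAnnotation is available) a VCF of genotypes.
#'
#' @param sim A [simulateEditome()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of written paths.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genome = file.path(dir, "genome.fa"),
    repeats = file.path(dir, "repeats.bed"),
    duplications = file.path(dir, "duplications.bed"),
    genes = file.path(dir, "genes.gtf"),
    pileups = file.path(dir, "pileups.tsv"),
    gwas = file.path(dir, "gwas.tsv"))
  Biostrings::writeXStringSet(sim$genome$genome, paths["genome"])
  rtracklayer::export(sim$genome$repeats, paths[["repeats"]], format = "BED")
  rtracklayer::export(sim$genome$duplications, paths[["duplications"]],
                      format = "BED")
  rtracklayer::export(sim$genome$gtf, paths[["genes"]], format = "GTF")
  data.table::fwrite(sim$pileups, paths[["pileups"]], sep = "\t")
  data.table::fwrite(sim$gwas, paths[["gwas"]], sep = "\t")
  invisible(paths)
}
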