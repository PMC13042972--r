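## Shared fixtures, computed lazily and cached for the whole test run.

library(data.table)

## full default-condition simulation plus similarity mask and cascade run
getDefaultRun <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- simConfig(seed = 20260924L)
    sim <- simulateEditome(cfg)
    mask <- buildSimilarityMask(sim$genome$genome)
    tissue_sizes <- setNames(cfg$samples_per_tissue,
                             paste0("T", seq_len(cfg$n_tissues)))
    cascade <- runFilterCascade(
      sim$pileups, sim$genome$genome, sim$genome$repeats, mask,
      sim$truth$snps[, .(chrom, pos, ref, alt)], sim$genome$gtf,
      tissue_sizes)
    cache <<- list(cfg = cfg, sim = sim, mask = mask, cascade = cascade,
                   tissue_sizes = tissue_sizes)
    cache
  }
})

## small genome for fast structural tests
getSmallSim <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- simConfig(seed = 11L, genome_length = 30000L,
                     n_chromosomes = 1L, n_genes = 12L,
                     n_edit_sites = 150L, n_artifact_sites = 30L,
                     n_snp_leak_sites = 30L, n_snps = 300L,
                     n_edqtl = 20L, n_error_sites = 50L,
                     n_duplicated_segments = 3L,
                     samples_per_tissue = 20L, gwas_n = 400L,
                     n_gwas_causal = 5L)
    genome <- simulateGenome(cfg)
    truth <- simulateTruth(cfg, genome)
    geno <- simulateGenotypes(cfg, truth)
    pil <- simulatePileups(truth, geno, cfg, genome)
    cache <<- list(cfg = cfg, genome = genome, truth = truth,
                   genotypes = geno, pileups = pil$pileups,
                   allelic = pil$allelic_counts)
    cache
  }
})

## random genome sequence as a DNAStringSet
randomGenome <- function(lens, seed = 1L) {
  set.seed(seed)
  g <- Biostrings::DNAStringSet(vapply(lens, function(L)
    paste0(sample(c("A", "C", "G", "T"), L, replace = TRUE),
           collapse = ""), character(1)))
  names(g) <- names(lens) %||% paste0("chr", seq_along(lens))
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## adjusted Rand index between two labelings
adjustedRand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  maxi <- (si + sj) / 2
  (sij - expected) / (maxi - expected)
}

## simulate counts for one ASED group
simAsedGroup <- function(n_ind = 20L, coverage = 50, mu = 0.3,
                         delta = 0, phi = 0.01) {
  rbb <- function(n, size, mu, phi) {
    a <- mu / phi; b <- (1 - mu) / phi
    rbinom(n, size, rbeta(n, a, b))
  }
  tot_r <- pmax(rpois(n_ind, coverage), 1L)
  tot_a <- pmax(rpois(n_ind, coverage), 1L)
  mu_a <- plogis(qlogis(mu) + delta)
  data.table::data.table(
    individual = rep(sprintf("I%02d", seq_len(n_ind)), 2L),
    allele = rep(c("ref", "alt"), each = n_ind),
    edited = c(rbb(n_ind, tot_r, mu, phi), rbb(n_ind, tot_a, mu_a, phi)),
    total = c(tot_r, tot_a))
}

## write a chain file from header fields and block rows
writeChainFile <- function(path, score, t_name, t_size, t_start, t_end,
                           q_name, q_size, q_strand, q_start, q_end,
                           blocks, id = 1L) {
  hdr <- paste("chain", score, t_name, t_size, "+", t_start, t_end,
               q_name, q_size, q_strand, q_start, q_end, id)
  rows <- apply(blocks, 1L, function(b)
    if (is.na(b[2])) as.character(b[1]) else paste(b[1], b[2], b[3]))
  writeLines(c(hdr, rows, ""), path)
  path
}
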