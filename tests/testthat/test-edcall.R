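## small pileup row constructor
plRow <- function(chrom = "chr1", pos = 100L, ref = "A", A = 0L, C = 0L,
                  G = 0L, T = 0L, meanBQ = 35, meanMQ = 55, first6 = 0L,
                  sample = "S1", tissue = "T1") {
  data.table::data.table(sample = sample, tissue = tissue, chrom = chrom,
                         pos = pos, ref = ref, A = A, C = C, G = G, T = T,
                         meanBQ = meanBQ, meanMQ = meanMQ,
                         n_mismatch_in_first6 = first6)
}

test_that("candidate calling applies ratio and threshold rules", {
  ## ref A with 9 ref and 3 G reads: candidate A>G at level 3/12
  cand <- callCandidates(plRow(A = 9L, G = 3L))
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$alt, "G")
  expect_equal(cand$level, 0.25)
  expect_equal(cand$coverage, 12L)

  ## all-reference rows emit nothing
  expect_equal(nrow(callCandidates(plRow(A = 30L))), 0L)

  ## alt support below min_edited emits nothing
  expect_equal(nrow(callCandidates(plRow(A = 20L, G = 1L))), 0L)

  ## low quality rows are dropped
  expect_equal(nrow(callCandidates(plRow(A = 9L, G = 3L, meanBQ = 20))), 0L)
  expect_equal(nrow(callCandidates(plRow(A = 9L, G = 3L, meanMQ = 10))), 0L)
  expect_equal(nrow(callCandidates(plRow(A = 5L, G = 3L),
                                   min_coverage = 10L)), 0L)

  ## multiple alts: highest count wins, ties broken alphabetically
  two <- callCandidates(plRow(A = 10L, C = 4L, G = 2L))
  expect_equal(two$alt, "C")
  tie <- callCandidates(plRow(A = 10L, C = 3L, G = 3L))
  expect_equal(tie$alt, "C")
})

test_that("read-start mismatch support is subtracted", {
  cand <- callCandidates(plRow(A = 10L, G = 8L, first6 = 3L))
  out <- filterReadPosition(cand)
  expect_equal(out$edited, 5L)
  ## support entirely in the first 6 bases: removed
  cand2 <- callCandidates(plRow(A = 10L, G = 2L, first6 = 2L))
  expect_equal(nrow(filterReadPosition(cand2)), 0L)
  ## no first-6 support: unchanged
  cand3 <- callCandidates(plRow(A = 10L, G = 4L))
  expect_equal(filterReadPosition(cand3)$edited, 4L)
})

test_that("homopolymer-adjacent candidates are removed", {
  ## run-free backbone with one planted run of 5 and one of 4
  seqv <- rep(c("C", "G", "T"), length.out = 120)
  seqv[51:55] <- "A"
  seqv[80:83] <- "A"                       # run of 4: below threshold
  seqv[79] <- "C"; seqv[84] <- "C"
  g <- Biostrings::DNAStringSet(paste0(seqv, collapse = ""))
  names(g) <- "chr1"
  cand <- data.table::rbindlist(list(
    callCandidates(plRow(pos = 56L, ref = "C", C = 9L, T = 3L)),  # adjacent
    callCandidates(plRow(pos = 53L, ref = "A", A = 9L, G = 3L)),  # inside
    callCandidates(plRow(pos = 84L, ref = "C", C = 9L, T = 3L)),  # run of 4
    callCandidates(plRow(pos = 20L, ref = "C", C = 9L, T = 3L))))
  out <- filterHomopolymer(cand, g)
  expect_setequal(out$pos, c(84L, 20L))
})

test_that("known-SNP filtering is allele-aware with a positional mode", {
  cand <- data.table::rbindlist(list(
    callCandidates(plRow(pos = 10L, A = 9L, G = 3L)),
    callCandidates(plRow(pos = 20L, A = 9L, G = 3L)),
    callCandidates(plRow(pos = 30L, A = 9L, G = 3L))))
  panel <- data.table::data.table(chrom = "chr1", pos = c(10L, 20L),
                                  ref = "A", alt = c("G", "T"))
  out <- filterKnownSnps(cand, panel)
  expect_setequal(out$pos, c(20L, 30L))      # different alt at 20: kept
  out_pos <- filterKnownSnps(cand, panel, allele_aware = FALSE)
  expect_setequal(out_pos$pos, 30L)
  ## empty panel is the identity
  expect_equal(nrow(filterKnownSnps(cand, panel[0])), 3L)
})

test_that("similarity filtering exempts repeat candidates", {
  cand <- data.table::rbindlist(list(
    callCandidates(plRow(pos = 100L, A = 9L, G = 3L)),   # masked, non-repeat
    callCandidates(plRow(pos = 200L, A = 9L, G = 3L)),   # masked, repeat
    callCandidates(plRow(pos = 300L, A = 9L, G = 3L))))  # unmasked
  mask <- SimilarityMask(GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(90, 190), c(110, 210))))
  repeats <- GenomicRanges::GRanges("chr1", IRanges::IRanges(195, 260))
  out <- filterSimilarity(cand, mask, repeats)
  expect_setequal(out$pos, c(200L, 300L))
  expect_equal(nrow(filterSimilarity(cand, SimilarityMask(), repeats)), 3L)
})

test_that("region-stratified thresholds are stricter outside repeats", {
  repeats <- GenomicRanges::GRanges("chr1", IRanges::IRanges(150, 250))
  cand <- data.table::rbindlist(list(
    callCandidates(plRow(pos = 100L, A = 30L, G = 2L)),   # non-repeat, 2 reads
    callCandidates(plRow(pos = 200L, A = 31L, G = 2L)),   # repeat, level .06
    callCandidates(plRow(pos = 110L, A = 24L, G = 4L))))  # non-repeat, ok
  out <- regionStratifiedFilter(cand, repeats)
  expect_setequal(out$pos, c(200L, 110L))
  ## equalized parameters reduce to one threshold
  eq <- regionStratifiedFilter(cand, repeats,
                               nonrepeat_min_edited = 2L,
                               nonrepeat_min_level = 0.05)
  expect_equal(nrow(eq), 3L)
})

test_that("presence filter requires both count and fraction", {
  mk <- function(n_samp, tissue, n_tissue) {
    data.table::rbindlist(lapply(seq_len(n_samp), function(i)
      callCandidates(plRow(A = 9L, G = 3L, sample = sprintf("S%03d", i),
                           tissue = tissue))))
  }
  ## 25 of 100: retained (25 >= 20, 25% >= 10%)
  out <- presenceFilter(mk(25L, "A"), c(A = 100L))
  expect_equal(nrow(out), 1L)
  ## 19 of 100: fails the count rule
  expect_equal(nrow(presenceFilter(mk(19L, "A"), c(A = 100L))), 0L)
  ## 25 of 300: fails the fraction rule
  expect_equal(nrow(presenceFilter(mk(25L, "A"), c(A = 300L))), 0L)
  expect_error(presenceFilter(mk(5L, "A"), c(A = 0L)), "0 samples")
})

test_that("strand correction complements minus-gene substitutions", {
  gtf <- GenomicRanges::GRanges(
    c("chr1", "chr1", "chr1"),
    IRanges::IRanges(c(100, 500, 890), c(300, 700, 1100)),
    strand = c("-", "+", "+"), type = "gene",
    gene_id = c("G1", "G2", "G3"), transcript_id = NA_character_)
  ## third gene overlaps a minus gene region to create ambiguity
  gtf2 <- c(gtf, GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(1000, 1200), strand = "-", type = "gene",
    gene_id = "G4", transcript_id = NA_character_))
  sites <- data.table::data.table(
    chrom = "chr1", pos = c(150L, 600L, 1050L, 2000L),
    ref = c("T", "A", "A", "T"), alt = c("C", "G", "G", "C"))
  out <- correctStrand(sites, gtf2)
  expect_equal(out$substitution,
               c("A>G", "A>G", "A>G", "T>C"))
  expect_equal(out$strand_ambiguous, c(FALSE, FALSE, TRUE, FALSE))
  expect_true(is.na(out$gene_strand[4]))
})

test_that("mutation spectrum fractions sum to one", {
  sites <- data.table::data.table(substitution = c("A>G", "A>G", "C>T",
                                                   "G>A"))
  sp <- mutationSpectrum(sites)
  expect_equal(sum(sp$fraction), 1)
  expect_equal(sp[substitution == "A>G", fraction], 0.5)
  expect_error(mutationSpectrum(sites[0]), "empty")
})

test_that("calibration curve is monotone and tracks A-to-G purity", {
  gtf <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 10000),
                                strand = "+", type = "gene",
                                gene_id = "G1",
                                transcript_id = NA_character_)
  ## recurrent A>G sites in many samples plus singleton artifacts
  rows <- list()
  for (i in 1:10) for (s in 1:12)
    rows[[length(rows) + 1L]] <- plRow(pos = 100L + i, A = 9L, G = 3L,
                                       sample = sprintf("S%02d", s))
  for (i in 1:30)
    rows[[length(rows) + 1L]] <- plRow(pos = 5000L + i, ref = "C",
                                       C = 9L, T = 3L, sample = "S01")
  cand <- callCandidates(data.table::rbindlist(rows))
  cal <- calibratePresenceThreshold(cand, c(1, 2, 5, 10), gtf)
  expect_true(all(diff(cal$n_retained) <= 0))
  expect_true(all(diff(cal$a2g_fraction) >= 0))
  expect_equal(cal$n_retained[1], 40L)       # threshold 1 keeps everything
  empty <- calibratePresenceThreshold(cand[0], c(1, 2), gtf)
  expect_equal(nrow(empty), 0L)
})

test_that("the cascade is idempotent on its own output", {
  s <- getSmallSim()
  runs <- findHomopolymers(s$genome$genome)
  cand <- callCandidates(s$pileups)
  cand <- filterReadPosition(cand)
  cand1 <- filterHomopolymer(cand, runs = runs)
  expect_identical(filterHomopolymer(cand1, runs = runs), cand1)
  panel <- s$truth$snps[, .(chrom, pos, ref, alt)]
  cand2 <- filterKnownSnps(cand1, panel)
  expect_identical(filterKnownSnps(cand2, panel), cand2)
})
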