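test_that("editing level and overall level follow the ratio definitions", {
  expect_equal(editingLevel(0, 10), 0)
  expect_equal(editingLevel(10, 10), 1)
  expect_equal(editingLevel(3, 12), 0.25)
  expect_error(editingLevel(1, 0), "coverage")

  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(10, 20),
                                                        width = 1),
                               substitution = "A>G")
  ee <- EditingExperiment(edited = matrix(c(2L, 8L, 1L, 1L), 2),
                          coverage = matrix(10L, 2, 2),
                          sites = gr, tissue = c("T1", "T1"))
  ## coverage-weighted: (2+8)/20 for sample 1
  expect_equal(unname(sampleOverallLevel(ee)[1]), 0.5)

  ## invariance to site order, equal to ratio of totals on random matrices
  set.seed(4)
  for (rep in 1:5) {
    cv <- matrix(sample(10:100, 40, replace = TRUE), 20)
    ed <- matrix(rbinom(40, as.vector(cv), 0.2), 20)
    gr2 <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(seq_len(20), width = 1),
                                  substitution = "A>G")
    e1 <- EditingExperiment(ed, cv, gr2, c("T1", "T2"))
    perm <- sample(20)
    e2 <- EditingExperiment(ed[perm, ], cv[perm, ], gr2[perm],
                            c("T1", "T2"))
    expect_equal(sampleOverallLevel(e1), sampleOverallLevel(e2))
    expect_equal(unname(sampleOverallLevel(e1)),
                 colSums(ed) / colSums(cv))
  }
})

test_that("EditingExperiment validity catches impossible counts", {
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(10, width = 1),
                               substitution = "A>G")
  expect_error(EditingExperiment(matrix(5L, 1, 1), matrix(3L, 1, 1),
                                 gr, "T1"), "exceed coverage")
})

test_that("Shannon entropy matches the closed form", {
  ## direct oracle on random probability vectors to 1e-12
  set.seed(10)
  for (rep in 1:20) {
    v <- runif(sample(2:8, 1))
    p <- v / sum(v)
    oracle <- -sum(p * log2(p))
    expect_equal(shannonEntropy(v), oracle, tolerance = 1e-12)
  }
  expect_equal(shannonEntropy(c(0.25, 0.25, 0.25, 0.25)), 2)
  expect_equal(shannonEntropy(c(0.4, 0, 0, 0)), 0)
  ## -sum p log2 p for (0.5, 0.3, 0.1, 0.1)
  expect_equal(shannonEntropy(c(0.5, 0.3, 0.1, 0.1)), 1.68547,
               tolerance = 1e-4)
  expect_true(is.na(shannonEntropy(c(0, 0))))
})

test_that("tissue specificity combines the entropy and range rules", {
  prof <- rbind(one = c(0.4, 0, 0, 0),
                flat = c(0.25, 0.25, 0.25, 0.25),
                weak = c(0.05, 0, 0, 0))
  colnames(prof) <- paste0("T", 1:4)
  ts <- tissueSpecificity(prof)
  expect_equal(ts$is_specific, c(TRUE, FALSE, FALSE))
  expect_equal(ts$entropy[1], 0)
  expect_equal(ts$entropy[2], 2)
  expect_equal(ts$top_tissue[1], "T1")
  ## all-missing profile: not specific, entropy undefined
  prof2 <- rbind(m = c(NA, NA, NA, NA))
  colnames(prof2) <- paste0("T", 1:4)
  ts2 <- tissueSpecificity(prof2)
  expect_false(ts2$is_specific)
  expect_true(is.na(ts2$entropy))
})

test_that("site annotation applies region precedence and codon logic", {
  ## gene on +: exon1 101-200 (CDS from 151), intron 201-300,
  ## exon2 301-400, intron 401-500, exon3 501-600 (CDS to 550)
  mkrow <- function(type, s, e, strand = "+", gid = "G1", tid = "G1.1")
    GenomicRanges::GRanges("chr1", IRanges::IRanges(s, e), strand = strand,
                           type = type, gene_id = gid,
                           transcript_id = tid)
  cds_len <- (200 - 151 + 1) + 100 + (550 - 501 + 1)  # 200, in frame ok
  expect_equal(cds_len %% 3, 2)  # adjust end to 548 for frame
  gtf <- c(mkrow("gene", 101, 600), mkrow("transcript", 101, 600),
           mkrow("exon", 101, 200), mkrow("exon", 301, 400),
           mkrow("exon", 501, 600),
           mkrow("CDS", 151, 200), mkrow("CDS", 301, 400),
           mkrow("CDS", 501, 548),
           mkrow("five_prime_utr", 101, 150),
           mkrow("three_prime_utr", 549, 600))
  ## genome with AAA at the first codon (151-153)
  seqv <- rep("C", 1000)
  seqv[151:153] <- "A"
  g <- Biostrings::DNAStringSet(paste0(seqv, collapse = ""))
  names(g) <- "chr1"
  repeats <- GenomicRanges::GRanges()

  sites <- data.table::data.table(
    chrom = "chr1",
    pos = c(250L, 152L, 130L, 560L, 700L, 5000L),
    ref = c("C", "A", "C", "C", "C", "C"),
    alt = c("T", "G", "T", "T", "T", "T"))
  ann <- annotateSites(sites, gtf, repeats, g)
  expect_equal(ann$region,
               c("intronic", "exonic", "UTR5", "UTR3", "downstream",
                 "intergenic"))
  ## codon AAA -> AGA is K -> R: nonsynonymous
  expect_equal(ann$consequence[2], "nonsynonymous")
  ## codon CCC -> CCT is P -> P at a third position: synonymous
  sites2 <- data.table::data.table(chrom = "chr1", pos = 156L, ref = "C",
                                   alt = "T")
  expect_equal(annotateSites(sites2, gtf, repeats, g)$consequence,
               "synonymous")
  ## exon of one transcript beats intron of another
  gtf2 <- c(gtf, mkrow("gene", 120, 800, gid = "G2", tid = "G2.1"),
            mkrow("exon", 240, 260, gid = "G2", tid = "G2.1"))
  ann2 <- annotateSites(sites[1], gtf2, repeats, g)
  expect_equal(ann2$region, "exonic")
  expect_equal(ann2$consequence, "unknown")
})

test_that("co-editing modules recover planted correlated blocks", {
  set.seed(77)
  n_tis <- 20
  block <- function(n_sites, seedv) {
    base <- rnorm(n_tis)
    t(vapply(seq_len(n_sites), function(i)
      0.35 + 0.12 * scale(base + rnorm(n_tis, 0, 0.33))[, 1],
      numeric(n_tis)))
  }
  m <- rbind(block(40), block(40))
  m <- pmin(pmax(m, 0.01), 0.99)
  ## separate the two blocks: regenerate second block from its own base
  rownames(m) <- paste0("s", seq_len(nrow(m)))
  colnames(m) <- paste0("T", seq_len(n_tis))
  truth_lab <- rep(c("b1", "b2"), each = 40)
  res <- coeditModules(m, cv_min = 0, min_tissues = 10, min_module = 30)
  keep <- names(res$membership)
  ari <- adjustedRand(truth_lab[match(keep, rownames(m))],
                      res$membership)
  expect_gte(ari, 0.8)
  expect_equal(length(setdiff(unique(res$membership), "grey")), 2L)

  ## fully independent sites collapse to grey
  noise <- matrix(runif(60 * n_tis), 60,
                  dimnames = list(paste0("n", 1:60),
                                  paste0("T", seq_len(n_tis))))
  res0 <- coeditModules(noise, cv_min = 0, min_tissues = 10,
                        min_module = 30)
  expect_true(all(res0$membership == "grey"))

  ## degenerate: too few sites after preprocessing
  expect_warning(coeditModules(noise[1:10, ], cv_min = 0,
                               min_tissues = 10), "minimum module size")
})

test_that("module-tissue correlation flags a tissue-loading block", {
  set.seed(99)
  n_tis <- 20
  loading <- c(rep(1, 1), rep(0, n_tis - 1))   # block high in tissue 1
  m <- t(vapply(1:40, function(i)
    0.2 + 0.5 * loading + rnorm(n_tis, 0, 0.03), numeric(n_tis)))
  m <- rbind(m, matrix(runif(40 * n_tis, 0.2, 0.25), 40))
  rownames(m) <- paste0("s", seq_len(nrow(m)))
  colnames(m) <- paste0("T", seq_len(n_tis))
  res <- coeditModules(m, cv_min = 0, min_tissues = 10, min_module = 30)
  mods <- res$modules
  expect_gte(nrow(mods), 1L)
  expect_equal(mods$top_tissue[1], "T1")
  expect_gt(mods$tissue_r[1], 0.8)
  expect_gt(mods$n_hubs[1], 0L)
})

test_that("scale-free fit distinguishes structured from degenerate input", {
  set.seed(5)
  n_tis <- 15
  ## hub-structured profiles give a decent fit at some power
  hub <- rnorm(n_tis)
  m <- t(vapply(1:120, function(i) {
    w <- rbeta(1, 0.4, 1.2)
    w * hub + rnorm(n_tis, 0, sqrt(1 - w^2))
  }, numeric(n_tis)))
  rownames(m) <- paste0("s", 1:120)
  fit <- softThresholdFit(m, powers = c(1, 4, 8))
  expect_true(any(fit$scale_free_R2 > 0.5, na.rm = TRUE))
  ## constant matrix: missing values, no crash
  cm <- matrix(0.3, 30, n_tis, dimnames = list(paste0("c", 1:30), NULL))
  fit0 <- softThresholdFit(cm, powers = c(1, 4))
  expect_true(all(is.na(fit0$scale_free_R2)))
})
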