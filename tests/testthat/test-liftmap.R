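test_that("chain parsing validates structure and block arithmetic", {
  f <- tempfile(fileext = ".chain")
  ## identity chain: one block of 1000
  writeChainFile(f, 1000, "chrA", 5000, 0, 1000, "chrB", 6000, "+", 0,
                 1000, matrix(c(1000, NA, NA), 1))
  ch <- parseChain(f)
  expect_length(ch, 1L)
  expect_equal(nrow(ch[[1]]$blocks), 1L)
  ## two-block chain with a 10 bp target (source) gap
  writeChainFile(f, 900, "chrA", 5000, 100, 310, "chrB", 6000, "+", 200,
                 400, rbind(c(100, 10, 0), c(100, NA, NA)))
  ch2 <- parseChain(f)[[1]]
  expect_equal(ch2$blocks$dt, c(10L, 0L))
  expect_equal(ch2$blocks$dq, c(0L, 0L))
  ## inconsistent arithmetic is rejected with the chain id
  writeChainFile(f, 900, "chrA", 5000, 100, 300, "chrB", 6000, "+", 200,
                 400, rbind(c(100, 10, 0), c(100, NA, NA)), id = "bad1")
  expect_error(parseChain(f), "bad1")
  ## truncated file
  writeLines(c("chain 1 chrA 5000 + 0 100 chrB 6000 + 0 100 1", "50 10 0"),
             f)
  expect_error(parseChain(f), "truncated")
})

test_that("position lifting walks blocks, strands and gaps correctly", {
  f <- tempfile(fileext = ".chain")
  writeChainFile(f, 1000, "chrA", 5000, 0, 2000, "chrB", 6000, "+", 0,
                 2000, matrix(c(2000, NA, NA), 1))
  ident <- parseChain(f)
  r <- liftPositions(data.table::data.table(chrom = "chrA", pos = 1234L),
                     ident)
  expect_equal(r$target_pos, 1234L)
  expect_equal(r$status, "mapped")

  ## 10 bp insertion in the target (dq) before the position:
  ## target = source + 10 after the gap
  writeChainFile(f, 1000, "chrA", 5000, 0, 300, "chrB", 6000, "+", 0,
                 310, rbind(c(100, 0, 10), c(200, NA, NA)))
  ins <- parseChain(f)
  r2 <- liftPositions(data.table::data.table(chrom = "chrA",
                                             pos = c(50L, 150L)), ins)
  expect_equal(r2$target_pos, c(50L, 160L))

  ## a source (dt) gap swallows positions: unmapped with reason
  writeChainFile(f, 1000, "chrA", 5000, 0, 310, "chrB", 6000, "+", 0,
                 300, rbind(c(100, 10, 0), c(200, NA, NA)))
  gap <- parseChain(f)
  r3 <- liftPositions(data.table::data.table(chrom = "chrA",
                                             pos = c(105L, 120L, 250L)),
                      gap)
  expect_equal(r3$status, c("unmapped", "mapped", "mapped"))
  expect_equal(r3$target_pos[2:3], c(110L, 240L))

  ## outside every chain
  r4 <- liftPositions(data.table::data.table(chrom = "chrZ", pos = 5L),
                      gap)
  expect_equal(r4$status, "no_chain")

  ## minus-strand target: coordinates flip within the q sequence
  writeChainFile(f, 1000, "chrA", 5000, 0, 100, "chrB", 400, "-", 0, 100,
                 matrix(c(100, NA, NA), 1))
  mins <- parseChain(f)
  r5 <- liftPositions(data.table::data.table(chrom = "chrA", pos = 1L),
                      mins)
  ## source base 0 maps to reverse-strand q 0 => plus-strand 399 (1-based 400)
  expect_equal(r5$target_pos, 400L)
  expect_equal(r5$target_strand, "-")
})

test_that("lifting round-trips through the inverted chain", {
  f <- tempfile(fileext = ".chain")
  writeChainFile(f, 1000, "chrA", 5000, 100, 450, "chrB", 6000, "+", 500,
                 880, rbind(c(100, 20, 40), c(80, 0, 10), c(150, NA, NA)))
  ch <- parseChain(f)
  inv <- list(invertChain(ch[[1]]))
  pos <- data.table::data.table(chrom = "chrA",
                                pos = c(150L, 205L, 260L, 330L, 400L))
  fwd <- liftPositions(pos, ch)
  mapped <- fwd[status == "mapped"]
  back <- liftPositions(
    data.table::data.table(chrom = mapped$target_chrom,
                           pos = mapped$target_pos), inv)
  expect_equal(back$target_pos, mapped$pos)
  expect_true(all(back$status == "mapped"))
})

test_that("lifting agrees with rtracklayer::liftOver on a toy chain", {
  skip_if_not_installed("rtracklayer")
  f <- tempfile(fileext = ".chain")
  writeChainFile(f, 1000, "chrA", 5000, 100, 450, "chrB", 6000, "+", 500,
                 880, rbind(c(100, 20, 40), c(80, 0, 10), c(150, NA, NA)))
  ch <- parseChain(f)
  pos <- data.table::data.table(chrom = "chrA", pos = c(150L, 260L, 400L))
  ours <- liftPositions(pos, ch)
  rt <- rtracklayer::import.chain(f)
  gr <- GenomicRanges::GRanges("chrA", IRanges::IRanges(pos$pos,
                                                        width = 1))
  lifted <- rtracklayer::liftOver(gr, rt)
  theirs <- vapply(seq_along(lifted), function(i)
    if (length(lifted[[i]])) GenomicRanges::start(lifted[[i]])[1]
    else NA_integer_, integer(1))
  expect_equal(ours$target_pos, theirs)
})

test_that("interval lifting enforces the matched fraction", {
  f <- tempfile(fileext = ".chain")
  ## 100 aligned, 100 source-gap, 100 aligned
  writeChainFile(f, 1000, "chrA", 5000, 0, 300, "chrB", 6000, "+", 0,
                 200, rbind(c(100, 100, 0), c(100, NA, NA)))
  ch <- parseChain(f)
  ## interval 1-200: half its bases aligned -> passes at min_match 0.5
  r <- liftIntervals(data.table::data.table(chrom = "chrA", start = 1L,
                                            end = 200L), ch)
  expect_equal(r$status, "mapped")
  expect_equal(r$matched_fraction, 0.5)
  ## stricter fraction fails
  r2 <- liftIntervals(data.table::data.table(chrom = "chrA", start = 1L,
                                             end = 200L), ch,
                      min_match = 0.6)
  expect_equal(r2$status, "unmapped")
  ## width-1 intervals ignore min_match
  r3 <- liftIntervals(data.table::data.table(chrom = "chrA", start = 50L,
                                             end = 50L), ch,
                      min_match = 0.99)
  expect_equal(r3$status, "mapped")
})

test_that("conservation filtering is strict and counts missing scores", {
  lifted <- data.table::data.table(
    chrom = "chrA", pos = 1:4,
    target_chrom = "chrB", target_pos = c(10L, 20L, 30L, 40L),
    target_strand = "+", status = "mapped")
  track <- GenomicRanges::GRanges(
    "chrB", IRanges::IRanges(c(10, 20, 30), width = 1),
    score = c(0.51, 0.5, 0.9))
  cf <- conservationFilter(lifted, track)
  expect_equal(cf$sites$target_pos, c(10L, 30L))   # 0.5 dropped (strict)
  expect_equal(cf$n_no_score, 1L)                  # pos 40 uncovered
})

test_that("catalog overlap is exact-position and strand-agnostic", {
  lifted <- data.table::data.table(target_chrom = "chrB",
                                   target_pos = c(100L, 101L))
  catalog <- GenomicRanges::GRanges("chrB", IRanges::IRanges(100, 100),
                                    strand = "-")
  oc <- overlapCatalog(lifted, catalog)
  expect_equal(oc$in_catalog, c(TRUE, FALSE))
  oc0 <- overlapCatalog(lifted, GenomicRanges::GRanges())
  expect_false(any(oc0$in_catalog))
})

test_that("permutation enrichment calibrates fold and p", {
  sizes <- c(chrB = 10000)
  set.seed(2)
  catalog <- GenomicRanges::GRanges(
    "chrB", IRanges::IRanges(sample.int(10000, 500), width = 1))
  ## catalog covering ~5%: observed constructed at twice the null mean
  null_rate <- sum(IRanges::width(GenomicRanges::reduce(catalog))) / 10000
  obs <- round(2 * null_rate * 200)
  pe <- permutationEnrichment(200, obs, sizes, catalog, n_perm = 400,
                              seed = 7)
  expect_lt(abs(pe$fold - 2), 0.35)
  expect_lt(pe$empirical_p, 0.05)
  ## saturated catalog: fold 1, p ~ 1
  full <- GenomicRanges::GRanges("chrB", IRanges::IRanges(1, 10000))
  pe2 <- permutationEnrichment(100, 100, sizes, full, n_perm = 100,
                               seed = 1)
  expect_equal(pe2$fold, 1)
  expect_gt(pe2$empirical_p, 0.9)
  ## seeded repeatability
  expect_identical(permutationEnrichment(50, 10, sizes, catalog,
                                         n_perm = 50, seed = 4),
                   permutationEnrichment(50, 10, sizes, catalog,
                                         n_perm = 50, seed = 4))
})

test_that("level correlation returns r and r squared", {
  x <- c(0.1, 0.5, 0.9, 0.3)
  expect_equal(levelCorrelation(x, x)$r2, 1)
  expect_equal(levelCorrelation(x, -x)$r, -1)
  set.seed(12)
  a <- rnorm(200)
  b <- 0.8 * a + rnorm(200, 0, sqrt(1 - 0.64))
  expect_lt(abs(levelCorrelation(a, b)$r - 0.8), 0.1)
  expect_error(levelCorrelation(1:2, 1:2), "3 paired")
})
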