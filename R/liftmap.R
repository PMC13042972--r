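## Cross-species conservation: UCSC chain-format parsing, block-wise
## coordinate lifting (strand-aware, with failure reasons), conservation-
## score filtering, catalog overlap, permutation enrichment and editing-
## level correlation at conserved sites.

#' Parse a UCSC chain file
#'
#' Parses chain headers and (size, dt, dq) block triples, validating the
#' block arithmetic against the declared interval ends.
#'
#' @param file Path to a chain-format text file.
#' @return List of chains; each chain is a list with `score`, `id`,
#'   `t`/`q` (name, size, strand, start, end; 0-based half-open) and
#'   `blocks` (data.table: size, dt, dq; last row has dt = dq = 0).
#' @export
parseChain <- function(file) {
  lines <- readLines(file)
  lines <- trimws(lines)
  chains <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(lines[i])) { i <- i + 1L; next }
    f <- strsplit(lines[i], "\\s+")[[1]]
    if (f[1] != "chain")
      stop(sprintf("expected 'chain' header at line %d", i))
    if (length(f) < 12L) stop("truncated chain header")
    hdr <- list(
      score = as.numeric(f[2]),
      t = list(name = f[3], size = as.integer(f[4]), strand = f[5],
               start = as.integer(f[6]), end = as.integer(f[7])),
      q = list(name = f[8], size = as.integer(f[9]), strand = f[10],
               start = as.integer(f[11]), end = as.integer(f[12])),
      id = if (length(f) >= 13L) f[13] else as.character(length(chains) + 1L))
    blocks <- list()
    i <- i + 1L
    repeat {
      if (i > length(lines)) stop("truncated chain file: missing final block")
      if (!nzchar(lines[i])) stop("truncated chain file: blank before final block")
      b <- as.integer(strsplit(lines[i], "\\s+")[[1]])
      if (length(b) == 1L) {
        blocks[[length(blocks) + 1L]] <- c(b, 0L, 0L)
        i <- i + 1L
        break
      } else if (length(b) == 3L) {
        blocks[[length(blocks) + 1L]] <- b
        i <- i + 1L
      } else stop(sprintf("malformed block line %d", i))
    }
    bl <- data.table::as.data.table(do.call(rbind, blocks))
    data.table::setnames(bl, c("size", "dt", "dq"))
    if (any(bl$size <= 0)) stop(sprintf("chain %s: non-positive block size",
                                        hdr$id))
    t_span <- sum(bl$size) + sum(bl$dt)
    q_span <- sum(bl$size) + sum(bl$dq)
    if (t_span != hdr$t$end - hdr$t$start ||
        q_span != hdr$q$end - hdr$q$start)
      stop(sprintf("chain %s: inconsistent block arithmetic", hdr$id))
    hdr$blocks <- bl
    chains[[length(chains) + 1L]] <- hdr
  }
  chains
}

## walk one chain; o is 0-based source (t) position; returns 0-based q
## position on the + strand of the q sequence, or NA if in a gap
.liftOne <- function(chain, o) {
  tcur <- chain$t$start; qcur <- chain$q$start
  bl <- chain$blocks
  for (r in seq_len(nrow(bl))) {
    sz <- bl$size[r]
    if (o < tcur) return(NA_integer_)
    if (o < tcur + sz) {
      qo <- qcur + (o - tcur)
      if (chain$q$strand == "-") qo <- chain$q$size - 1L - qo
      return(qo)
    }
    tcur <- tcur + sz + bl$dt[r]
    qcur <- qcur + sz + bl$dq[r]
  }
  NA_integer_
}

#' Lift positions through chain alignments
#'
#' Maps 1-based positions through aligned blocks (strand-aware); positions
#' falling in alignment gaps fail with reason "unmapped", positions outside
#' all chains with "no_chain". Where several chains overlap a position the
#' highest-scoring one wins.
#'
#' @param positions data.table/data.frame with chrom, pos (1-based), or a
#'   GRanges of width-1 sites.
#' @param chains [parseChain()] output.
#' @return data.table: chrom, pos, target_chrom, target_pos (1-based),
#'   target_strand, status ("mapped"/"unmapped"/"no_chain").
#' @export
liftPositions <- function(positions, chains) {
  if (is(positions, "GRanges"))
    positions <- data.table::data.table(
      chrom = as.character(seqnames(positions)), pos = start(positions))
  ps <- data.table::as.data.table(positions)
  out <- ps[, .(chrom, pos)]
  out[, `:=`(target_chrom = NA_character_, target_pos = NA_integer_,
             target_strand = NA_character_, status = "no_chain")]
  score <- vapply(chains, function(ch) ch$score, numeric(1))
  ord <- order(-score)
  for (i in seq_len(nrow(out))) {
    o <- out$pos[i] - 1L
    for (ci in ord) {
      ch <- chains[[ci]]
      if (ch$t$name != out$chrom[i] || o < ch$t$start || o >= ch$t$end)
        next
      qo <- .liftOne(ch, o)
      if (is.na(qo)) {
        out[i, status := "unmapped"]
      } else {
        out[i, `:=`(target_chrom = ch$q$name, target_pos = qo + 1L,
                    target_strand = ch$q$strand, status = "mapped")]
      }
      break   # highest-scoring covering chain decides
    }
  }
  out[]
}

#' Lift intervals through chain alignments
#'
#' An interval lifts when at least `min_match` of its bases fall inside
#' aligned blocks of the winning (highest-score covering) chain; the
#' target interval spans the mapped bases.
#'
#' @param intervals GRanges or data.table with chrom, start, end (1-based
#'   closed).
#' @param chains [parseChain()] output.
#' @param min_match Minimum matched base fraction (default 0.5); single
#'   positions (width 1) are exempt.
#' @return data.table with target coordinates, matched_fraction and
#'   status.
#' @export
liftIntervals <- function(intervals, chains, min_match = 0.5) {
  if (is(intervals, "GRanges"))
    intervals <- data.table::data.table(
      chrom = as.character(seqnames(intervals)),
      start = start(intervals), end = end(intervals))
  iv <- data.table::as.data.table(intervals)
  score <- vapply(chains, function(ch) ch$score, numeric(1))
  ord <- order(-score)
  rows <- lapply(seq_len(nrow(iv)), function(i) {
    res <- data.table::data.table(
      chrom = iv$chrom[i], start = iv$start[i], end = iv$end[i],
      target_chrom = NA_character_, target_start = NA_integer_,
      target_end = NA_integer_, target_strand = NA_character_,
      matched_fraction = 0, status = "no_chain")
    w <- iv$end[i] - iv$start[i] + 1L
    for (ci in ord) {
      ch <- chains[[ci]]
      if (ch$t$name != iv$chrom[i] || iv$end[i] - 1L < ch$t$start ||
          iv$start[i] - 1L >= ch$t$end) next
      qpos <- vapply(seq.int(iv$start[i], iv$end[i]) - 1L,
                     function(o) .liftOne(ch, o), integer(1))
      frac <- mean(!is.na(qpos))
      res$matched_fraction <- frac
      if (frac == 0 || (w > 1L && frac < min_match)) {
        res$status <- "unmapped"
      } else {
        res$target_chrom <- ch$q$name
        res$target_start <- min(qpos, na.rm = TRUE) + 1L
        res$target_end <- max(qpos, na.rm = TRUE) + 1L
        res$target_strand <- ch$q$strand
        res$status <- "mapped"
      }
      break
    }
    res
  })
  data.table::rbindlist(rows)
}

#' Invert a plus-strand chain
#'
#' Swaps source and target so that lifting can be round-tripped.
#'
#' @param chain One chain from [parseChain()].
#' @return The inverted chain.
#' @export
invertChain <- function(chain) {
  if (chain$q$strand != "+")
    stop("only plus-strand chains can be inverted")
  inv <- chain
  inv$t <- chain$q
  inv$q <- chain$t
  inv$blocks <- data.table::data.table(
    size = chain$blocks$size, dt = chain$blocks$dq, dq = chain$blocks$dt)
  inv
}

#' Filter lifted sites by conservation score
#'
#' Retains sites whose position has a conservation score strictly greater
#' than the threshold; sites without track coverage are dropped and
#' counted.
#'
#' @param lifted [liftPositions()] output (mapped rows used).
#' @param track GRanges with a `score` column (e.g.
#'   `rtracklayer::import(f, format = "bedGraph")`), in target
#'   coordinates.
#' @param threshold Strict lower bound (default 0.5).
#' @return List: `sites` (retained rows with `score`), `n_no_score`.
#' @export
conservationFilter <- function(lifted, track, threshold = 0.5) {
  lf <- data.table::as.data.table(lifted)[status == "mapped"]
  gr <- GRanges(lf$target_chrom, IRanges(lf$target_pos, width = 1L))
  hit <- ovFind(gr, track, select = "first")
  sc <- rep(NA_real_, length(gr))
  sc[!is.na(hit)] <- track$score[hit[!is.na(hit)]]
  lf[, score := sc]
  list(sites = lf[!is.na(score) & score > threshold][],
       n_no_score = sum(is.na(sc)))
}

#' Overlap lifted sites with a known editing catalog
#'
#' Exact-position, strand-agnostic membership against a catalog aggregated
#' across tissues.
#'
#' @param lifted data.table with target_chrom, target_pos (1-based).
#' @param catalog GRanges of known sites (width 1) or BED path.
#' @return Input with an `in_catalog` logical column.
#' @export
overlapCatalog <- function(lifted, catalog) {
  if (is.character(catalog))
    catalog <- rtracklayer::import(catalog, format = "BED")
  lf <- data.table::copy(data.table::as.data.table(lifted))
  gr <- GRanges(lf$target_chrom, IRanges(lf$target_pos, width = 1L))
  lf[, in_catalog := ovAny(gr, catalog,
                                          ignore.strand = TRUE)]
  lf[]
}

#' Permutation enrichment of catalog overlap
#'
#' Compares the observed overlap count to overlaps of randomly sampled
#' genomic positions: fold = observed / mean(null), empirical
#' p = (1 + #\{null >= observed\}) / (n_perm + 1).
#'
#' @param n_query Number of query positions (sampled per permutation).
#' @param observed_overlap Observed overlap count.
#' @param genome_sizes Named vector of chromosome lengths.
#' @param catalog GRanges of catalog sites.
#' @param n_perm Permutations (default 1000).
#' @param seed Seed.
#' @return data.table: fold, empirical_p, null_mean, saturated (flag for
#'   infinite fold).
#' @export
permutationEnrichment <- function(n_query, observed_overlap, genome_sizes,
                                  catalog, n_perm = 1000L, seed = 1L) {
  set.seed(seed)
  chroms <- names(genome_sizes)
  total <- n_perm * n_query
  chr <- sample(chroms, total, replace = TRUE, prob = genome_sizes)
  pos <- floor(runif(total) * genome_sizes[chr]) + 1L
  gr <- GRanges(chr, IRanges(pos, width = 1L))
  hit <- ovAny(gr, catalog, ignore.strand = TRUE)
  null_counts <- tabulate(rep(seq_len(n_perm), each = n_query)[hit],
                          nbins = n_perm)
  nm <- mean(null_counts)
  fold <- if (nm == 0) Inf else observed_overlap / nm
  data.table::data.table(
    fold = fold,
    empirical_p = (1 + sum(null_counts >= observed_overlap)) /
      (n_perm + 1),
    null_mean = nm, saturated = !is.finite(fold))
}

#' Editing-level correlation at conserved sites
#'
#' @param source_levels,target_levels Paired level vectors.
#' @return data.table: r, r2, n.
#' @export
levelCorrelation <- function(source_levels, target_levels) {
  ok <- complete.cases(source_levels, target_levels)
  if (sum(ok) < 3L) stop("need at least 3 paired levels")
  r <- cor(source_levels[ok], target_levels[ok])
  data.table::data.table(r = r, r2 = r^2, n = sum(ok))
}
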