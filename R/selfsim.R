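## Genome self-similarity scan: tile the genome into read-length windows,
## re-align each window to the whole genome by exact k-mer seeding plus
## ungapped extension, and mask regions hit at high length/identity. The
## mask flags alignment-artifact-prone loci for the mismatch filter cascade.

#' Tile a genome into sliding windows
#'
#' Pure sliding tiling: per chromosome of length L the window count is
#' `floor((L - window_length)/step) + 1` when `L >= window_length`, else 0;
#' no partial tail window is emitted.
#'
#' @param genome A named [Biostrings::DNAStringSet] (or list with element
#'   `genome`).
#' @param window_length Window size in bp (default 76).
#' @param step Step size in bp (default 19).
#' @return A [GenomicRanges::GRanges] of windows in genome order.
#' @export
tileWindows <- function(genome, window_length = 76L, step = 19L) {
  genome <- .asDNAStringSet(genome)
  stopifnot(window_length > 0L, step > 0L, step <= window_length)
  out <- lapply(names(genome), function(chr) {
    L <- Biostrings::width(genome[chr])
    if (L < window_length) return(GRanges())
    n <- (L - window_length) %/% step + 1L
    starts <- seq.int(1L, by = step, length.out = n)
    GRanges(chr, IRanges(starts, width = window_length))
  })
  suppressWarnings(do.call(c, out))
}

.asDNAStringSet <- function(genome) {
  if (is.list(genome) && !is.null(genome$genome)) genome <- genome$genome
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  stopifnot(is(genome, "DNAStringSet"), !is.null(names(genome)))
  genome
}

## k-mer position index over both the genome and its reverse complement
.kmerIndex <- function(seq_chars, k) {
  idx <- lapply(names(seq_chars), function(chr) {
    s <- seq_chars[[chr]]
    L <- length(s)
    if (L < k) return(NULL)
    starts <- seq_len(L - k + 1L)
    km <- substring(paste0(s, collapse = ""), starts, starts + k - 1L)
    data.table::data.table(kmer = km, chrom = chr, tpos = starts)
  })
  dt <- data.table::rbindlist(Filter(Negate(is.null), idx))
  data.table::setkey(dt, kmer)
  dt
}

.revcompChar <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rev(unname(comp[x]))
}

## ungapped X-drop extension of a seed match along one diagonal, confined
## to the window columns: match +1, mismatch -2; each side extends to its
## best-scoring endpoint and stops once the running score drops `xdrop`
## below the best. Endpoints always land on matching columns.
.extendSeed <- function(match_vec, seed_lo, seed_hi, xdrop = 8L) {
  n <- length(match_vec)
  hi <- seed_hi
  sc <- 0L; best <- 0L
  i <- seed_hi + 1L
  while (i <= n) {
    sc <- sc + (if (match_vec[i]) 1L else -2L)
    if (sc > best) { best <- sc; hi <- i }
    if (sc < best - xdrop) break
    i <- i + 1L
  }
  lo <- seed_lo
  sc <- 0L; best <- 0L
  i <- seed_lo - 1L
  while (i >= 1L) {
    sc <- sc + (if (match_vec[i]) 1L else -2L)
    if (sc > best) { best <- sc; lo <- i }
    if (sc < best - xdrop) break
    i <- i - 1L
  }
  if (hi < lo) return(NULL)
  c(lo, hi)
}

#' Align one window against the genome
#'
#' Exact k-mer seeding on both strands followed by ungapped extension along
#' the seed diagonal. Each hit reports the extended matched span
#' (`aligned_length`, capped at the window length), its identity
#' (matches / aligned columns) and whether it is the window's own locus.
#'
#' @param window A single-range GRanges (one tiling window).
#' @param genome DNAStringSet (or list with `genome`).
#' @param k Seed k-mer length (default 16).
#' @param index Optional precomputed k-mer index (internal reuse).
#' @param seq_chars Optional precomputed per-chromosome character vectors.
#' @return data.table: query chrom/start/end, target chrom/start/end,
#'   strand, aligned_length, identity, is_source_locus.
#' @export
alignWindow <- function(window, genome, k = 16L, index = NULL,
                        seq_chars = NULL) {
  genome <- .asDNAStringSet(genome)
  if (is.null(seq_chars)) {
    seq_chars <- lapply(names(genome), function(chr)
      strsplit(as.character(genome[[chr]]), "")[[1]])
    names(seq_chars) <- names(genome)
  }
  if (is.null(index)) index <- .kmerIndex(seq_chars, k)
  qchr <- as.character(seqnames(window))[1]
  qs <- start(window)[1]; qe <- end(window)[1]
  w <- qe - qs + 1L
  wseq <- seq_chars[[qchr]][qs:qe]
  hits <- list()
  for (strand_i in c("+", "-")) {
    qvec <- if (strand_i == "+") wseq else .revcompChar(wseq)
    offs <- unique(c(seq.int(1L, w - k + 1L, by = max(1L, k %/% 2L)),
                     w - k + 1L))
    seeds <- data.table::data.table(
      off = offs,
      kmer = substring(paste0(qvec, collapse = ""), offs, offs + k - 1L))
    m <- index[seeds, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
    if (!nrow(m)) next
    m[, diag := tpos - off + 1L]
    m <- unique(m, by = c("chrom", "diag"))
    for (r in seq_len(nrow(m))) {
      tchr <- m$chrom[r]; d <- m$diag[r]
      tlen <- length(seq_chars[[tchr]])
      ## window column j aligns to target position d + j - 1
      jlo <- max(1L, 1L - d + 1L)
      jhi <- min(w, tlen - d + 1L)
      if (jhi - jlo + 1L < k) next
      tvec <- seq_chars[[tchr]][(d + jlo - 1L):(d + jhi - 1L)]
      mv <- qvec[jlo:jhi] == tvec
      so <- m$off[r] - jlo + 1L
      span <- .extendSeed(mv, so, so + k - 1L)
      if (is.null(span)) next
      cols <- span[1]:span[2]
      alen <- length(cols)
      ident <- mean(mv[cols])
      ## aligned columns back to query coordinates (strand-aware)
      qcols <- (jlo:jhi)[cols]
      if (strand_i == "+") {
        q_lo <- qs + qcols[1] - 1L; q_hi <- qs + qcols[alen] - 1L
      } else {
        q_hi <- qe - qcols[1] + 1L; q_lo <- qe - qcols[alen] + 1L
      }
      t_lo <- d + jlo - 1L + cols[1] - 1L
      t_hi <- t_lo + alen - 1L
      hits[[length(hits) + 1L]] <- data.table::data.table(
        query_chrom = qchr, query_start = qs, query_end = qe,
        target_chrom = tchr, target_start = t_lo, target_end = t_hi,
        strand = strand_i, aligned_length = alen, identity = ident,
        is_source_locus = (strand_i == "+" && tchr == qchr && d == qs))
    }
  }
  if (!length(hits)) return(data.table::data.table())
  data.table::rbindlist(hits)
}

#' Build the genome self-similarity mask
#'
#' Runs the tiling and self-alignment over the whole genome and masks, for
#' every non-source hit passing the length/identity thresholds, both the
#' query window interval and the target hit interval (symmetric masking).
#'
#' @param genome DNAStringSet, FASTA path, or [simulateGenome()] output.
#' @param window_length,step Tiling parameters (defaults 76/19).
#' @param min_length Minimum extended aligned length (default 61 bp).
#' @param min_identity Minimum identity (default 0.94).
#' @param k Seed k-mer length.
#' @return A [SimilarityMask-class].
#' @export
buildSimilarityMask <- function(genome, window_length = 76L, step = 19L,
                                min_length = 61L, min_identity = 0.94,
                                k = 16L) {
  genome <- .asDNAStringSet(genome)
  seq_chars <- lapply(names(genome), function(chr)
    strsplit(as.character(genome[[chr]]), "")[[1]])
  names(seq_chars) <- names(genome)
  index <- .kmerIndex(seq_chars, k)
  windows <- tileWindows(genome, window_length, step)
  masked <- list()
  for (i in seq_along(windows)) {
    h <- alignWindow(windows[i], genome, k = k, index = index,
                     seq_chars = seq_chars)
    if (!nrow(h)) next
    h <- h[is_source_locus == FALSE & aligned_length >= min_length &
           identity >= min_identity]
    if (!nrow(h)) next
    masked[[length(masked) + 1L]] <- suppressWarnings(c(
      GRanges(h$query_chrom, IRanges(h$query_start, h$query_end)),
      GRanges(h$target_chrom, IRanges(h$target_start, h$target_end))))
  }
  if (!length(masked)) return(SimilarityMask())
  SimilarityMask(suppressWarnings(do.call(c, masked)))
}
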