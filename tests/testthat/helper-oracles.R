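## Independent brute-force oracles used by the acceptance suite.

## all-pairs ungapped self-alignment oracle: exact repeats >= min_len on
## both strands, found by scanning every diagonal of the genome against
## itself (and against its reverse complement)
bruteSelfRepeats <- function(g_chars, min_len = 61L) {
  L <- length(g_chars)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  runs_s <- integer(0); runs_e <- integer(0)
  add <- function(s, e) {
    runs_s <<- c(runs_s, s); runs_e <<- c(runs_e, e)
  }
  ## forward diagonals: g[i] vs g[i + d]
  for (d in seq_len(L - min_len)) {
    m <- g_chars[seq_len(L - d)] == g_chars[seq_len(L - d) + d]
    r <- rle(m)
    ends <- cumsum(r$lengths)
    for (k in which(r$values & r$lengths >= min_len)) {
      s <- ends[k] - r$lengths[k] + 1L; e <- ends[k]
      add(s, e); add(s + d, e + d)
    }
  }
  ## reverse-strand: g[i] vs comp(g[j]) along anti-diagonals, via the
  ## reverse complement h where h[i] = comp(g[L - i + 1])
  h <- unname(comp[rev(g_chars)])
  for (d in seq.int(-(L - min_len), L - min_len)) {
    i <- seq_len(L)
    j <- i + d
    ok <- j >= 1L & j <= L
    i <- i[ok]; j <- j[ok]
    if (length(i) < min_len) next
    m <- g_chars[i] == h[j]
    r <- rle(m)
    ends <- cumsum(r$lengths)
    for (k in which(r$values & r$lengths >= min_len)) {
      s <- i[ends[k] - r$lengths[k] + 1L]; e <- i[ends[k]]
      add(s, e)
      ## partner interval on the genome: h[j] = g[L - j + 1]
      js <- j[ends[k] - r$lengths[k] + 1L]; je <- j[ends[k]]
      add(L - je + 1L, L - js + 1L)
    }
  }
  if (!length(runs_s)) return(IRanges::IRanges())
  IRanges::reduce(IRanges::IRanges(runs_s, runs_e))
}

## every base of `a` lies within `b` dilated by `slack` bp
coversWithin <- function(a, b, slack) {
  if (!length(a)) return(TRUE)
  if (!length(b)) return(FALSE)
  length(IRanges::setdiff(IRanges::reduce(a),
                          IRanges::reduce(b + slack))) == 0L
}
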