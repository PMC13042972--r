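## Editing-site calling: turn per-sample mismatch pileups into a
## strand-corrected, high-confidence site catalog via a fixed filter
## cascade: call -> read-position -> homopolymer -> known-SNP ->
## similarity -> region-stratified -> presence.

BASES <- c("A", "C", "G", "T")
BASE_COMP <- c(A = "T", C = "G", G = "C", T = "A")

.candGRanges <- function(x) GRanges(x$chrom, IRanges(x$pos, width = 1L))

#' Call mismatch candidates from pileups
#'
#' One candidate per (site, sample): the highest-count non-reference base
#' (ties broken alphabetically), subject to minimum edited reads, coverage
#' and mean base/mapping quality. Reference-only rows emit nothing.
#'
#' @param pileups Long pileup data.table with columns sample, tissue, chrom,
#'   pos, ref, A, C, G, T, meanBQ, meanMQ, n_mismatch_in_first6.
#' @param min_bq,min_mq Minimum mean base/mapping quality (defaults 25/20).
#' @param min_coverage Minimum total reads (default 10).
#' @param min_edited Minimum edited (alt) reads (default 2).
#' @return Candidate data.table with columns sample, tissue, chrom, pos,
#'   ref, alt, edited, coverage, level, n_mismatch_in_first6.
#' @export
callCandidates <- function(pileups, min_bq = 25, min_mq = 20,
                           min_coverage = 10L, min_edited = 2L) {
  pl <- data.table::as.data.table(pileups)
  counts <- as.matrix(pl[, BASES, with = FALSE])
  coverage <- rowSums(counts)
  n_zero <- sum(coverage == 0)
  if (n_zero > 0)
    message(sprintf("callCandidates: skipped %d zero-coverage rows", n_zero))
  alt_counts <- counts
  alt_counts[cbind(seq_len(nrow(pl)), match(pl$ref, BASES))] <- -1L
  alt_j <- max.col(alt_counts, ties.method = "first")
  edited <- alt_counts[cbind(seq_len(nrow(pl)), alt_j)]
  out <- pl[, .(sample, tissue, chrom, pos, ref)]
  out[, `:=`(alt = BASES[alt_j], edited = as.integer(edited),
             coverage = as.integer(coverage),
             n_mismatch_in_first6 = pl$n_mismatch_in_first6)]
  out <- out[edited >= min_edited & coverage >= min_coverage &
             pl$meanBQ >= min_bq & pl$meanMQ >= min_mq]
  out[, level := edited / coverage]
  out[]
}

#' Drop read-start mismatch support
#'
#' Recomputes mismatch support excluding reads whose mismatch lies in the
#' first 6 bases of the read, then re-applies the minimum-edited threshold.
#'
#' @param candidates Candidate table from [callCandidates()].
#' @param min_edited Minimum remaining edited reads (default 2).
#' @export
filterReadPosition <- function(candidates, min_edited = 2L) {
  cand <- data.table::copy(data.table::as.data.table(candidates))
  drop <- pmin(cand$n_mismatch_in_first6, cand$edited)
  cand[, edited := as.integer(edited - drop)]
  cand[, level := edited / coverage]
  cand[edited >= min_edited][]
}

#' Find reference homopolymer runs
#'
#' @param genome DNAStringSet or [simulateGenome()] output.
#' @param min_run Minimum run length (default 5).
#' @return GRanges of runs of `>= min_run` identical bases.
#' @export
findHomopolymers <- function(genome, min_run = 5L) {
  genome <- .asDNAStringSet(genome)
  out <- lapply(names(genome), function(chr) {
    r <- rle(strsplit(as.character(genome[[chr]]), "")[[1]])
    ends <- cumsum(r$lengths)
    keep <- r$lengths >= min_run
    if (!any(keep)) return(GRanges())
    GRanges(chr, IRanges(ends[keep] - r$lengths[keep] + 1L, ends[keep]))
  })
  sort(suppressWarnings(do.call(c, out)))
}

#' Remove candidates in or adjacent to homopolymer runs
#'
#' A candidate is removed when its position lies within, or within 1 bp of,
#' a reference run of `>= run_length` identical bases.
#'
#' @param candidates Candidate table.
#' @param genome DNAStringSet (ignored when `runs` given).
#' @param run_length Minimum run length (default 5).
#' @param runs Optional precomputed homopolymer GRanges.
#' @export
filterHomopolymer <- function(candidates, genome = NULL, run_length = 5L,
                              runs = NULL) {
  cand <- data.table::as.data.table(candidates)
  if (is.null(runs)) runs <- findHomopolymers(genome, run_length)
  if (!length(runs)) return(cand)
  hit <- ovAny(.candGRanges(cand), runs + 1L)
  cand[!hit][]
}

#' Remove candidates at known genomic SNPs
#'
#' @param candidates Candidate table.
#' @param panel data.table/data.frame with chrom, pos, alt columns (e.g. a
#'   parsed VCF panel); may be a list of panels.
#' @param allele_aware If `TRUE` (default) remove only candidates whose alt
#'   allele matches the panel's; if `FALSE`, remove on position alone.
#' @export
filterKnownSnps <- function(candidates, panel, allele_aware = TRUE) {
  cand <- data.table::as.data.table(candidates)
  if (is.data.frame(panel)) panel <- list(panel)
  pan <- data.table::rbindlist(lapply(panel, function(p)
    data.table::as.data.table(p)[, .(chrom, pos, alt)]), use.names = TRUE)
  if (!nrow(pan)) return(cand)
  if (allele_aware)
    cand[!pan, on = c("chrom", "pos", "alt")][]
  else
    cand[!unique(pan[, .(chrom, pos)]), on = c("chrom", "pos")][]
}

#' Remove non-repeat candidates in the self-similarity mask
#'
#' Candidates outside repeat annotation that fall inside the similarity
#' mask are removed; candidates inside repeats are exempt.
#'
#' @param candidates Candidate table.
#' @param mask A [SimilarityMask-class].
#' @param repeats Repeat annotation GRanges.
#' @export
filterSimilarity <- function(candidates, mask, repeats) {
  cand <- data.table::as.data.table(candidates)
  if (!length(mask)) return(cand)
  gr <- .candGRanges(cand)
  in_rep <- if (length(repeats)) ovAny(gr, repeats)
            else rep(FALSE, nrow(cand))
  in_mask <- isMasked(gr, mask)
  cand[!(in_mask & !in_rep)][]
}

#' Region-stratified support thresholds
#'
#' Non-repeat candidates face stricter support thresholds than candidates
#' inside PRE-like repeats, reflecting the repeat-concentrated nature of
#' true A-to-I editing.
#'
#' @param candidates Candidate table.
#' @param repeats Repeat GRanges.
#' @param nonrepeat_min_edited,nonrepeat_min_level Defaults 3 / 0.10.
#' @param repeat_min_edited,repeat_min_level Defaults 2 / 0.05.
#' @export
regionStratifiedFilter <- function(candidates, repeats,
                                   nonrepeat_min_edited = 3L,
                                   nonrepeat_min_level = 0.10,
                                   repeat_min_edited = 2L,
                                   repeat_min_level = 0.05) {
  cand <- data.table::as.data.table(candidates)
  in_rep <- if (length(repeats))
    ovAny(.candGRanges(cand), repeats)
  else rep(FALSE, nrow(cand))
  keep <- ifelse(in_rep,
                 cand$edited >= repeat_min_edited &
                   cand$level >= repeat_min_level,
                 cand$edited >= nonrepeat_min_edited &
                   cand$level >= nonrepeat_min_level)
  out <- cand[keep]
  out[, in_repeat := in_rep[keep]]
  out[]
}

#' Per-tissue recurrence (presence) filter
#'
#' A site is retained in a tissue iff it is called in at least
#' `min_samples` samples and in at least `min_fraction` of that tissue's
#' samples.
#'
#' @param candidates Candidate table (after the upstream filters).
#' @param tissue_sizes Named vector: number of samples per tissue.
#' @param min_samples,min_fraction Defaults 20 / 0.10.
#' @return Per-tissue site table: tissue, chrom, pos, ref, alt,
#'   n_samples_present, n_tissue_samples.
#' @export
presenceFilter <- function(candidates, tissue_sizes, min_samples = 20L,
                           min_fraction = 0.10) {
  cand <- data.table::as.data.table(candidates)
  if (any(tissue_sizes <= 0)) stop("tissue with 0 samples")
  per <- cand[, .(n_samples_present = data.table::uniqueN(sample)),
              by = .(tissue, chrom, pos, ref, alt)]
  per[, n_tissue_samples := as.integer(tissue_sizes[tissue])]
  per[n_samples_present >= min_samples &
      n_samples_present / n_tissue_samples >= min_fraction][]
}

#' Strand-correct substitution types by gene annotation
#'
#' Sites overlapping a minus-strand gene have their substitution converted
#' to the reverse complement (e.g. T-to-C becomes A-to-G); plus-strand
#' sites are unchanged; sites in no gene or in genes on both strands keep
#' their original type and are flagged ambiguous.
#'
#' @param sites data.table with chrom, pos, ref, alt.
#' @param gtf Gene annotation GRanges (rows with `type == "gene"` used; a
#'   plain gene-level GRanges also works).
#' @return Input with added `substitution` (corrected, "X>Y"),
#'   `gene_strand` ("+", "-", "*" ambiguous, NA intergenic) and
#'   `strand_ambiguous` columns.
#' @export
correctStrand <- function(sites, gtf) {
  sites <- data.table::copy(data.table::as.data.table(sites))
  genes <- if (!is.null(gtf$type)) gtf[gtf$type == "gene"] else gtf
  gr <- .candGRanges(sites)
  ov <- ovFind(gr, genes, ignore.strand = TRUE)
  st <- data.table::data.table(
    i = S4Vectors::queryHits(ov),
    strand = as.character(strand(genes))[S4Vectors::subjectHits(ov)])
  st <- st[, .(n_strands = data.table::uniqueN(strand),
               strand = strand[1]), by = i]
  sites[, gene_strand := NA_character_]
  sites[st$i, gene_strand := ifelse(st$n_strands > 1L, "*", st$strand)]
  sites[, strand_ambiguous := !is.na(gene_strand) & gene_strand == "*"]
  minus <- !is.na(sites$gene_strand) & sites$gene_strand == "-"
  sites[, substitution := paste0(ref, ">", alt)]
  sites[minus, substitution := paste0(BASE_COMP[ref], ">", BASE_COMP[alt])]
  sites[]
}

#' Mismatch spectrum over the 12 substitution types
#'
#' @param sites Table with a `substitution` column (use [correctStrand()]
#'   first).
#' @return data.table: substitution, n, fraction (fractions sum to 1).
#' @export
mutationSpectrum <- function(sites) {
  sites <- data.table::as.data.table(sites)
  if (!nrow(sites)) stop("empty site catalog")
  sp <- sites[, .(n = .N), by = substitution]
  sp[, fraction := n / sum(n)]
  sp[order(-n)][]
}

#' Presence-threshold calibration curve
#'
#' For a grid of recurrence thresholds, reports how many sites survive and
#' what fraction of them are A-to-G after strand correction. The A-to-G
#' fraction plateauing at a high level guides the presence-threshold
#' choice.
#'
#' @param candidates Candidate table.
#' @param thresholds Integer vector of minimum sample counts.
#' @param gtf Gene annotation for strand correction.
#' @return data.table: threshold, n_retained, a2g_fraction.
#' @export
calibratePresenceThreshold <- function(candidates, thresholds, gtf) {
  cand <- data.table::as.data.table(candidates)
  if (!nrow(cand))
    return(data.table::data.table(threshold = integer(0),
                                  n_retained = integer(0),
                                  a2g_fraction = numeric(0)))
  per <- cand[, .(n_samples_present = data.table::uniqueN(sample)),
              by = .(chrom, pos, ref, alt)]
  per <- correctStrand(per, gtf)
  data.table::rbindlist(lapply(sort(thresholds), function(t) {
    keep <- per[n_samples_present >= t]
    data.table::data.table(
      threshold = as.integer(t), n_retained = nrow(keep),
      a2g_fraction = if (nrow(keep)) mean(keep$substitution == "A>G")
                     else NA_real_)
  }))
}

#' Run the full filter cascade
#'
#' Applies the fixed filter order (call, read-position, homopolymer,
#' known-SNP, similarity, region-stratified, presence) and strand-corrects
#' the resulting per-tissue catalog.
#'
#' @param pileups Pileup table (see [callCandidates()]).
#' @param genome DNAStringSet.
#' @param repeats,gtf Annotation GRanges.
#' @param mask A [SimilarityMask-class].
#' @param snp_panel Known-SNP panel (data.table chrom/pos/alt, or list).
#' @param tissue_sizes Named vector of samples per tissue.
#' @param params Optional list overriding filter defaults (names: min_bq,
#'   min_mq, min_coverage, min_edited, run_length, allele_aware,
#'   nonrepeat_min_edited, nonrepeat_min_level, repeat_min_edited,
#'   repeat_min_level, min_samples, min_fraction).
#' @return List: `catalog` (per-tissue strand-corrected site table),
#'   `sites` (unique sites across tissues), `candidates` (post-filter
#'   per-sample candidates), `steps` (rows surviving each stage).
#' @export
runFilterCascade <- function(pileups, genome, repeats, mask, snp_panel,
                             gtf, tissue_sizes, params = list()) {
  p <- utils::modifyList(list(
    min_bq = 25, min_mq = 20, min_coverage = 10L, min_edited = 2L,
    run_length = 5L, allele_aware = TRUE,
    nonrepeat_min_edited = 3L, nonrepeat_min_level = 0.10,
    repeat_min_edited = 2L, repeat_min_level = 0.05,
    min_samples = 20L, min_fraction = 0.10), params)
  steps <- integer(0)
  cand <- callCandidates(pileups, p$min_bq, p$min_mq, p$min_coverage,
                         p$min_edited)
  steps["called"] <- nrow(cand)
  cand <- filterReadPosition(cand, p$min_edited)
  steps["read_position"] <- nrow(cand)
  cand <- filterHomopolymer(cand, genome, p$run_length)
  steps["homopolymer"] <- nrow(cand)
  cand <- filterKnownSnps(cand, snp_panel, p$allele_aware)
  steps["known_snp"] <- nrow(cand)
  cand <- filterSimilarity(cand, mask, repeats)
  steps["similarity"] <- nrow(cand)
  cand <- regionStratifiedFilter(cand, repeats, p$nonrepeat_min_edited,
                                 p$nonrepeat_min_level, p$repeat_min_edited,
                                 p$repeat_min_level)
  steps["region_stratified"] <- nrow(cand)
  catalog <- presenceFilter(cand, tissue_sizes, p$min_samples,
                            p$min_fraction)
  steps["presence"] <- nrow(catalog)
  catalog <- correctStrand(catalog, gtf)
  in_rep <- if (length(repeats))
    ovAny(.candGRanges(catalog), repeats)
  else rep(FALSE, nrow(catalog))
  catalog[, in_repeat := in_rep]
  sites <- unique(catalog[, .(chrom, pos, ref, alt, substitution,
                              gene_strand, strand_ambiguous, in_repeat)],
                  by = c("chrom", "pos"))
  list(catalog = catalog, sites = sites, candidates = cand, steps = steps)
}
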