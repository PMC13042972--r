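## Editome quantification and characterization: editing-level matrices,
## per-sample overall editing activity, genomic annotation with coding
## consequences, tissue-specificity by Shannon entropy, and correlation-
## based co-editing modules.

#' Editing level of a site
#'
#' The ratio of reads supporting the edited base to total reads covering
#' the site.
#'
#' @param edited,coverage Read counts (vectorized).
#' @return `edited / coverage`.
#' @export
editingLevel <- function(edited, coverage) {
  if (any(coverage <= 0)) stop("coverage must be > 0")
  if (any(edited > coverage)) stop("edited cannot exceed coverage")
  edited / coverage
}

#' Build an EditingExperiment from pileups at catalog sites
#'
#' Extracts, for every catalog site and sample, the count of the site's
#' edited (alt) base and the total coverage from the pileup table.
#'
#' @param pileups Pileup table (see [callCandidates()]).
#' @param sites Site table with chrom, pos, ref, alt (and optionally
#'   substitution metadata), e.g. `runFilterCascade()$sites`.
#' @return An [EditingExperiment-class] (sites x samples).
#' @export
buildEditingExperiment <- function(pileups, sites) {
  pl <- data.table::as.data.table(pileups)
  st <- data.table::as.data.table(sites)
  st <- unique(st, by = c("chrom", "pos"))
  sub <- pl[st, on = c("chrom", "pos"), nomatch = NULL]
  counts <- as.matrix(sub[, BASES, with = FALSE])
  sub[, coverage := rowSums(counts)]
  sub[, edited := counts[cbind(seq_len(.N), match(alt, BASES))]]
  samples <- sort(unique(pl$sample))
  tissue <- pl[match(samples, sample), tissue]
  key <- paste(st$chrom, st$pos)
  ed <- matrix(0L, nrow(st), length(samples),
               dimnames = list(key, samples))
  cv <- ed
  ri <- match(paste(sub$chrom, sub$pos), key)
  ci <- match(sub$sample, samples)
  ed[cbind(ri, ci)] <- sub$edited
  cv[cbind(ri, ci)] <- sub$coverage
  gr <- GRanges(st$chrom, IRanges(st$pos, width = 1L))
  mcols(gr)$substitution <- if ("substitution" %in% names(st))
    st$substitution else paste0(st$ref, ">", st$alt)
  mcols(gr)$ref <- st$ref
  mcols(gr)$alt <- st$alt
  if ("in_repeat" %in% names(st)) mcols(gr)$in_repeat <- st$in_repeat
  names(gr) <- key
  EditingExperiment(ed, cv, gr, tissue)
}

#' Per-sample overall editing level
#'
#' Coverage-weighted overall activity: total edited reads divided by total
#' covering reads over all sites in a sample (not the mean of ratios).
#'
#' @param x An [EditingExperiment-class].
#' @return Named numeric vector, one value per sample.
#' @export
sampleOverallLevel <- function(x) {
  stopifnot(is(x, "EditingExperiment"))
  ed <- assay(x, "edited"); cv <- assay(x, "coverage")
  tot_cv <- colSums(cv)
  if (any(tot_cv == 0)) stop("sample with no covered sites")
  colSums(ed) / tot_cv
}

#' Tissue-mean editing profile
#'
#' @param x An [EditingExperiment-class].
#' @param min_coverage Sample-level observations require at least this
#'   coverage to contribute (default 1).
#' @return List: `mean` (sites x tissues mean level, NA where no sample
#'   covered) and `n` (contributing sample counts).
#' @export
tissueProfile <- function(x, min_coverage = 1L) {
  lev <- editingLevels(x)
  cv <- assay(x, "coverage")
  lev[cv < min_coverage] <- NA
  tis <- tissueLabels(x)
  tl <- sort(unique(tis))
  mean_m <- vapply(tl, function(t)
    rowMeans(lev[, tis == t, drop = FALSE], na.rm = TRUE),
    numeric(nrow(lev)))
  n_m <- vapply(tl, function(t)
    rowSums(!is.na(lev[, tis == t, drop = FALSE])), numeric(nrow(lev)))
  mean_m[is.nan(mean_m)] <- NA
  list(mean = mean_m, n = n_m)
}

#' Shannon entropy of a profile (bits)
#'
#' Normalizes a non-negative vector to sum 1 (dropping missing entries) and
#' returns `-sum(p * log2(p))`; zero entries contribute zero.
#'
#' @param x Non-negative numeric vector.
#' @return Entropy in bits; `NA` if the vector has no positive mass.
#' @export
shannonEntropy <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x) || sum(x) <= 0) return(NA_real_)
  p <- x / sum(x)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Eligibility for tissue-specificity analysis
#'
#' Sites covered by at least `min_reads` reads in at least `min_samples`
#' samples.
#'
#' @param x An [EditingExperiment-class].
#' @param min_reads,min_samples Defaults 50 / 30.
#' @return Logical vector over sites.
#' @export
eligibleSites <- function(x, min_reads = 50L, min_samples = 30L) {
  cv <- assay(x, "coverage")
  rowSums(cv >= min_reads) >= min_samples
}

#' Tissue-specific editing sites
#'
#' A site is tissue-specific when the Shannon entropy of its normalized
#' tissue-mean profile is below `entropy_max` and the range of tissue means
#' exceeds `range_min`.
#'
#' @param profile A sites x tissues mean-level matrix (see
#'   [tissueProfile()]).
#' @param range_min,entropy_max Defaults 0.10 / 0.4 (bits).
#' @return data.table: site, entropy, level_range, top_tissue, is_specific.
#' @export
tissueSpecificity <- function(profile, range_min = 0.10, entropy_max = 0.4) {
  stopifnot(is.matrix(profile))
  ent <- apply(profile, 1L, shannonEntropy)
  rng <- apply(profile, 1L, function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(NA_real_)
    max(v) - min(v)
  })
  top <- colnames(profile)[apply(profile, 1L, function(v)
    if (all(is.na(v))) NA_integer_ else which.max(replace(v, is.na(v), -Inf)))]
  data.table::data.table(
    site = rownames(profile) %||% as.character(seq_len(nrow(profile))),
    entropy = ent, level_range = rng, top_tissue = top,
    is_specific = !is.na(ent) & !is.na(rng) &
      ent < entropy_max & rng > range_min)
}

## module colour labels by decreasing size, WGCNA-style
.MODULE_COLORS <- c("turquoise", "blue", "brown", "yellow", "green", "red",
                    "black", "pink", "magenta", "purple", "greenyellow",
                    "tan", "salmon", "cyan", "midnightblue")

#' Detect co-editing modules
#'
#' Simplified correlation-network module detection on the site x tissue
#' mean-level matrix: preprocessing (missingness, CV and breadth filters),
#' soft-power adjacency `|r|^power`, average-linkage clustering of
#' `1 - adjacency` cut at a fixed height, small clusters merged into
#' "grey". Hub sites are members whose profile correlates with the module
#' eigen-profile at `>= hub_kme`; each module reports its best-matching
#' tissue indicator correlation.
#'
#' @param profile Sites x tissues matrix of tissue-mean levels.
#' @param missing_site_max Drop sites missing in at least this many tissues
#'   (default 4).
#' @param tissue_missing_max Drop tissues missing at least this fraction of
#'   sites (default 0.5).
#' @param cv_min Minimum coefficient of variation (default 0.8).
#' @param min_tissues Minimum tissues a site must be observed in
#'   (default 10).
#' @param power Soft-threshold power (default 4).
#' @param min_module Minimum module size (default 30).
#' @param cut_height Dendrogram cut height on 1 - adjacency (default 0.9).
#' @param hub_kme Hub membership threshold (default 0.8).
#' @return List: `membership` (named module label per retained site),
#'   `modules` (data.table: module, n_sites, n_hubs, top_tissue, tissue_r),
#'   `eigenprofiles` (tissues x modules), `hubs` (list of hub site names).
#' @export
coeditModules <- function(profile, missing_site_max = 4L,
                          tissue_missing_max = 0.5, cv_min = 0.8,
                          min_tissues = 10L, power = 4,
                          min_module = 30L, cut_height = 0.9,
                          hub_kme = 0.8) {
  stopifnot(is.matrix(profile))
  if (is.null(rownames(profile)))
    rownames(profile) <- paste0("site", seq_len(nrow(profile)))
  m <- profile
  m <- m[rowSums(is.na(m)) < missing_site_max, , drop = FALSE]
  m <- m[, colMeans(is.na(m)) < tissue_missing_max, drop = FALSE]
  cv <- apply(m, 1L, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2L || mean(v) == 0) return(NA_real_)
    sd(v) / mean(v)
  })
  m <- m[!is.na(cv) & cv >= cv_min, , drop = FALSE]
  m <- m[rowSums(!is.na(m)) >= min_tissues, , drop = FALSE]

  grey_out <- function(sites) list(
    membership = setNames(rep("grey", length(sites)), sites),
    modules = data.table::data.table(module = character(0),
                                     n_sites = integer(0),
                                     n_hubs = integer(0),
                                     top_tissue = character(0),
                                     tissue_r = numeric(0)),
    eigenprofiles = NULL, hubs = list())
  if (nrow(m) < min_module) {
    warning("fewer sites than the minimum module size after preprocessing")
    return(grey_out(rownames(m)))
  }
  a <- abs(cor(t(m), use = "pairwise.complete.obs"))^power
  a[is.na(a)] <- 0
  cl <- cutree(hclust(stats::as.dist(1 - a), method = "average"),
               h = cut_height)
  tab <- table(cl)
  big <- names(tab)[tab >= min_module]
  membership <- setNames(rep("grey", nrow(m)), rownames(m))
  ord <- big[order(-tab[big])]
  for (i in seq_along(ord))
    membership[cl == as.integer(ord[i])] <-
      .MODULE_COLORS[min(i, length(.MODULE_COLORS))]

  mods <- setdiff(unique(membership), "grey")
  eig <- NULL; hubs <- list(); rows <- list()
  for (mod in mods) {
    sub <- m[membership == mod, , drop = FALSE]
    subz <- t(scale(t(sub)))
    subz[is.na(subz)] <- 0
    pc <- prcomp(t(subz), center = FALSE, scale. = FALSE)
    e <- pc$x[, 1]
    if (cor(e, colMeans(subz)) < 0) e <- -e   # orient with mean profile
    kme <- apply(sub, 1L, function(v) suppressWarnings(
      cor(v, e, use = "pairwise.complete.obs")))
    hubs[[mod]] <- names(kme)[!is.na(kme) & kme >= hub_kme]
    tis_r <- vapply(seq_len(ncol(m)), function(j)
      suppressWarnings(cor(e, as.numeric(seq_len(ncol(m)) == j))),
      numeric(1))
    best <- which.max(tis_r)
    eig <- cbind(eig, e)
    rows[[mod]] <- data.table::data.table(
      module = mod, n_sites = nrow(sub), n_hubs = length(hubs[[mod]]),
      top_tissue = colnames(m)[best], tissue_r = tis_r[best])
  }
  if (!is.null(eig)) colnames(eig) <- mods
  list(membership = membership,
       modules = if (length(rows)) data.table::rbindlist(rows)
                 else grey_out(character(0))$modules,
       eigenprofiles = eig, hubs = hubs)
}

#' Scale-free topology fit across soft powers
#'
#' For each power, computes the adjacency connectivity distribution and the
#' R-squared of the log10 p(k) versus log10 k regression over connectivity
#' bins.
#'
#' @param profile Sites x tissues matrix.
#' @param powers Powers to evaluate (default 1:10).
#' @param n_bins Connectivity bins (default 10).
#' @return data.table: power, scale_free_R2 (NA where degenerate).
#' @export
softThresholdFit <- function(profile, powers = 1:10, n_bins = 10L) {
  stopifnot(is.matrix(profile))
  r <- abs(cor(t(profile), use = "pairwise.complete.obs"))
  r[is.na(r)] <- 0
  diag(r) <- 0
  data.table::rbindlist(lapply(powers, function(p) {
    k <- rowSums(r^p)
    if (sd(k) < 1e-12 || any(k <= 0))
      return(data.table::data.table(power = p, scale_free_R2 = NA_real_))
    br <- unique(quantile(k, seq(0, 1, length.out = n_bins + 1L)))
    if (length(br) < 3L)
      return(data.table::data.table(power = p, scale_free_R2 = NA_real_))
    bin <- cut(k, br, include.lowest = TRUE)
    pk <- tapply(k, bin, length) / length(k)
    mk <- tapply(k, bin, mean)
    ok <- !is.na(pk) & pk > 0 & mk > 0
    if (sum(ok) < 3L)
      return(data.table::data.table(power = p, scale_free_R2 = NA_real_))
    fit <- lm(log10(pk[ok]) ~ log10(mk[ok]))
    data.table::data.table(power = p,
                           scale_free_R2 = summary(fit)$r.squared)
  }))
}

#' Annotate sites by genomic region and coding consequence
#'
#' Region classes follow a fixed precedence across transcripts:
#' exonic (CDS) > UTR3/UTR5 > intronic > upstream/downstream (within
#' `flank` bp of a gene, strand-aware) > intergenic. CDS sites are
#' classified synonymous/nonsynonymous by codon substitution on the
#' annotated frame.
#'
#' @param sites Site table with chrom, pos, ref, alt.
#' @param gtf Feature-level annotation GRanges (type, gene_id,
#'   transcript_id).
#' @param repeats Repeat GRanges.
#' @param genome DNAStringSet (for codon lookup).
#' @param flank Up/downstream distance (default 1000).
#' @return Input with `region`, `consequence` (exonic sites only),
#'   `in_repeat` columns.
#' @export
annotateSites <- function(sites, gtf, repeats, genome, flank = 1000L) {
  sites <- data.table::copy(data.table::as.data.table(sites))
  genome <- .asDNAStringSet(genome)
  gr <- .candGRanges(sites)
  ov_type <- function(type) {
    f <- gtf[gtf$type == type]
    if (!length(f)) rep(FALSE, length(gr))
    else ovAny(gr, f, ignore.strand = TRUE)
  }
  in_cds <- ov_type("CDS")
  ## exons of transcripts with no CDS annotation count as exonic too
  ## (consequence "unknown")
  ex <- gtf[gtf$type == "exon"]
  cds_tx <- unique(gtf$transcript_id[gtf$type == "CDS"])
  ex_nocds <- ex[!(ex$transcript_id %in% cds_tx)]
  in_ex_nocds <- if (length(ex_nocds))
    ovAny(gr, ex_nocds, ignore.strand = TRUE)
  else rep(FALSE, length(gr))
  in_utr3 <- ov_type("three_prime_utr")
  in_utr5 <- ov_type("five_prime_utr")
  genes <- gtf[gtf$type == "gene"]
  in_gene <- ovAny(gr, genes, ignore.strand = TRUE)
  up <- GenomicRanges::flank(genes, flank, start = TRUE)
  dn <- GenomicRanges::flank(genes, flank, start = FALSE)
  in_up <- ovAny(gr, up, ignore.strand = TRUE)
  in_dn <- ovAny(gr, dn, ignore.strand = TRUE)
  region <- rep("intergenic", length(gr))
  region[in_dn] <- "downstream"
  region[in_up] <- "upstream"
  region[in_gene] <- "intronic"
  region[in_utr5] <- "UTR5"
  region[in_utr3] <- "UTR3"
  region[in_cds | in_ex_nocds] <- "exonic"
  sites[, region := region]
  sites[, consequence := NA_character_]
  exonic <- which(in_cds)
  if (length(exonic)) {
    cds <- gtf[gtf$type == "CDS"]
    gc_tab <- Biostrings::GENETIC_CODE
    for (i in exonic) {
      hit <- ovFind(gr[i], cds, ignore.strand = TRUE)
      if (!length(hit)) next
      tid <- cds$transcript_id[S4Vectors::subjectHits(hit)[1]]
      tx_cds <- cds[cds$transcript_id == tid]
      strand_t <- as.character(strand(tx_cds))[1]
      tx_cds <- if (strand_t == "+") sort(tx_cds) else
        rev(sort(tx_cds))
      ## CDS-relative position of the site
      pos <- sites$pos[i]
      offs <- 0L; cds_pos <- NA_integer_
      for (piece in seq_along(tx_cds)) {
        s <- start(tx_cds)[piece]; e <- end(tx_cds)[piece]
        if (pos >= s && pos <= e) {
          cds_pos <- offs + if (strand_t == "+") pos - s + 1L else e - pos + 1L
          break
        }
        offs <- offs + (e - s + 1L)
      }
      if (is.na(cds_pos)) next
      codon_i <- (cds_pos - 1L) %/% 3L
      codon_cds <- codon_i * 3L + 1:3
      ## map CDS coords back to genome
      g_pos <- integer(3)
      for (ci in 1:3) {
        target <- codon_cds[ci]; offs <- 0L
        for (piece in seq_along(tx_cds)) {
          w <- width(tx_cds)[piece]
          if (target <= offs + w) {
            g_pos[ci] <- if (strand_t == "+")
              start(tx_cds)[piece] + (target - offs) - 1L
            else end(tx_cds)[piece] - (target - offs) + 1L
            break
          }
          offs <- offs + w
        }
      }
      chr <- sites$chrom[i]
      base_at <- function(p) substr(as.character(genome[[chr]]), p, p)
      codon_ref <- vapply(g_pos, base_at, character(1))
      pos_in_codon <- which(g_pos == pos)
      codon_alt <- codon_ref
      codon_alt[pos_in_codon] <- sites$alt[i]
      if (strand_t == "-") {
        codon_ref <- BASE_COMP[codon_ref]
        codon_alt <- BASE_COMP[codon_alt]
      }
      aa_ref <- gc_tab[paste0(codon_ref, collapse = "")]
      aa_alt <- gc_tab[paste0(codon_alt, collapse = "")]
      if (is.na(aa_ref) || is.na(aa_alt))
        sites$consequence[i] <- "unknown"
      else
        sites$consequence[i] <- if (aa_ref == aa_alt) "synonymous"
                                else "nonsynonymous"
    }
  }
  sites[region == "exonic" & is.na(consequence), consequence := "unknown"]
  sites[, in_repeat := if (length(repeats))
    ovAny(gr, repeats) else FALSE]
  sites[]
}
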