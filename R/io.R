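## Readers/writers for the package's tabular interchange formats.

#' Write / read pileup tables
#'
#' Plain TSV with columns sample, tissue, chrom, pos, ref, A, C, G, T,
#' meanBQ, meanMQ, n_mismatch_in_first6.
#'
#' @param pileups Pileup data.table.
#' @param file Path.
#' @export
writePileupTsv <- function(pileups, file) {
  data.table::fwrite(data.table::as.data.table(pileups), file, sep = "\t")
  invisible(file)
}

#' @rdname writePileupTsv
#' @export
readPileupTsv <- function(file) {
  data.table::fread(file, sep = "\t")
}

#' Write genotype dosages as VCF
#'
#' @param genotypes Samples x SNPs dosage matrix.
#' @param snps data.table: snp_id, chrom, pos, ref, alt.
#' @param file Output path (".vcf").
#' @export
writeGenotypesVcf <- function(genotypes, snps, file) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("VariantAnnotation is required to write VCF")
  sn <- data.table::as.data.table(snps)
  ord <- match(colnames(genotypes), sn$snp_id)
  sn <- sn[ord]
  gt <- t(genotypes)  # snps x samples
  gt_str <- matrix(c("0/0", "0/1", "1/1")[gt + 1L], nrow(gt), ncol(gt))
  dimnames(gt_str) <- list(sn$snp_id, rownames(genotypes))
  rr <- GRanges(sn$chrom, IRanges(sn$pos, width = 1L))
  names(rr) <- sn$snp_id
  vcf <- VariantAnnotation::VCF(
    rowRanges = rr,
    colData = S4Vectors::DataFrame(Samples = seq_len(ncol(gt_str)),
                                   row.names = colnames(gt_str)),
    exptData = list(header = VariantAnnotation::VCFHeader(
      samples = colnames(gt_str),
      header = IRanges::DataFrameList(
        fileformat = S4Vectors::DataFrame(Value = "VCFv4.2",
                                          row.names = "fileformat"),
        FORMAT = S4Vectors::DataFrame(
          Number = "1", Type = "String", Description = "Genotype",
          row.names = "GT")))),
    fixed = S4Vectors::DataFrame(
      REF = Biostrings::DNAStringSet(sn$ref),
      ALT = Biostrings::DNAStringSetList(as.list(sn$alt)),
      QUAL = rep(NA_real_, nrow(sn)),
      FILTER = rep("PASS", nrow(sn))),
    geno = S4Vectors::SimpleList(GT = gt_str))
  VariantAnnotation::writeVcf(vcf, file)
  invisible(file)
}

#' Read genotype dosages from VCF
#'
#' @param file VCF path.
#' @return List: `genotypes` (samples x SNPs dosage matrix), `snps`
#'   (data.table: snp_id, chrom, pos, ref, alt).
#' @export
readGenotypesVcf <- function(file) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("VariantAnnotation is required to read VCF")
  vcf <- VariantAnnotation::readVcf(file)
  gt <- VariantAnnotation::geno(vcf)$GT
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  dos[gt %in% c("0/0", "0|0")] <- 0L
  dos[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  dos[gt %in% c("1/1", "1|1")] <- 2L
  rr <- SummarizedExperiment::rowRanges(vcf)
  snps <- data.table::data.table(
    snp_id = names(rr), chrom = as.character(seqnames(rr)),
    pos = start(rr),
    ref = as.character(rr$REF),
    alt = vapply(rr$ALT, function(a) as.character(a)[1], character(1)))
  list(genotypes = t(dos), snps = snps)
}

#' Read a known-SNP panel from VCF into a filter table
#'
#' @param file VCF path.
#' @return data.table: chrom, pos, ref, alt (one row per alt allele).
#' @export
readSnpPanelVcf <- function(file) {
  g <- readGenotypesVcf(file)
  g$snps[, .(chrom, pos, ref, alt)]
}
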