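## Allele-specific editing (ASED): paired comparison of editing levels on
## the two alleles of a nearby heterozygous SNP, across individuals sharing
## the het genotype, via a hierarchical beta-binomial likelihood-ratio test
## that accounts for per-individual estimation uncertainty.

#' Pair allele-specific counts
#'
#' Retains heterozygous individuals with non-zero coverage on both alleles
#' and (site, SNP) groups with at least `min_individuals` such individuals.
#'
#' @param allelic data.table: individual, snp_id, chrom, pos, allele
#'   ("ref"/"alt"), edited, total (and optionally tissue).
#' @param genotypes Samples x SNPs dosage matrix (rownames = individuals);
#'   rows with dosage != 1 are dropped.
#' @param min_individuals Minimum replicate individuals per group
#'   (default 5).
#' @return data.table of paired rows (two per individual), with a `group`
#'   key "chrom:pos:snp".
#' @export
pairAlleles <- function(allelic, genotypes, min_individuals = 5L) {
  al <- data.table::as.data.table(allelic)
  if (!is.null(genotypes)) {
    d <- genotypes[cbind(match(al$individual, rownames(genotypes)),
                         match(al$snp_id, colnames(genotypes)))]
    n_hom <- sum(d != 1L, na.rm = TRUE)
    if (n_hom > 0)
      message(sprintf("pairAlleles: dropped %d non-heterozygous rows",
                      n_hom))
    al <- al[!is.na(d) & d == 1L]
  }
  wide <- data.table::dcast(al, chrom + pos + snp_id + individual ~ allele,
                            value.var = "total", fun.aggregate = sum)
  ok <- wide[ref > 0 & alt > 0, .(chrom, pos, snp_id, individual)]
  al <- al[ok, on = c("chrom", "pos", "snp_id", "individual")]
  al[, group := paste(chrom, pos, snp_id, sep = ":")]
  n_ind <- al[, .(n = data.table::uniqueN(individual)), by = group]
  al[group %in% n_ind[n >= min_individuals, group]][]
}

## beta-binomial log-likelihood; mu in (0,1), phi > 0 overdispersion
## (alpha = mu/phi, beta = (1-mu)/phi; phi -> 0 approaches binomial)
.bbLogLik <- function(k, n, mu, phi) {
  a <- mu / phi; b <- (1 - mu) / phi
  sum(lchoose(n, k) + lbeta(k + a, n - k + b) - lbeta(a, b))
}

#' Paired beta-binomial test for one (site, SNP) group
#'
#' Models per-allele edited counts as beta-binomial with allele-specific
#' means and a shared overdispersion estimated jointly by maximum
#' likelihood; tests mean equality with a 1-df likelihood-ratio test.
#' `delta` is the logit-scale difference `logit(mu_alt) - logit(mu_ref)`.
#' When the fit fails, a coverage-weighted paired t test on pseudo-count
#' logit levels is used and flagged.
#'
#' @param group data.table for one group (columns allele, edited, total,
#'   individual).
#' @param phi_min Lower bound on overdispersion (default 1e-6).
#' @return One-row data.table: n_individuals, mu_ref, mu_alt, mean_ref,
#'   mean_alt, delta, p, method, degenerate.
#' @export
pairedAsedTest <- function(group, phi_min = 1e-6) {
  g <- data.table::as.data.table(group)
  kr <- g[allele == "ref", edited]; nr <- g[allele == "ref", total]
  ka <- g[allele == "alt", edited]; na_ <- g[allele == "alt", total]
  n_ind <- length(kr)
  mean_ref <- sum(kr) / sum(nr); mean_alt <- sum(ka) / sum(na_)
  out <- function(p, mu_r, mu_a, method, degen = FALSE)
    data.table::data.table(
      n_individuals = n_ind, mu_ref = mu_r, mu_alt = mu_a,
      mean_ref = mean_ref, mean_alt = mean_alt,
      delta = logit(pmin(pmax(mu_a, 1e-6), 1 - 1e-6)) -
              logit(pmin(pmax(mu_r, 1e-6), 1 - 1e-6)),
      p = p, method = method, degenerate = degen)
  all_zero <- all(kr == 0) && all(ka == 0)
  all_one <- all(kr == nr) && all(ka == na_)
  if (all_zero || all_one)
    return(out(1, mean_ref, mean_alt, "degenerate", TRUE))

  clamp <- function(m) pmin(pmax(m, 1e-4), 1 - 1e-4)
  nll1 <- function(par) {
    mu_r <- invlogit(par[1]); mu_a <- invlogit(par[2])
    phi <- max(exp(par[3]), phi_min)
    -(.bbLogLik(kr, nr, mu_r, phi) + .bbLogLik(ka, na_, mu_a, phi))
  }
  nll0 <- function(par) {
    mu <- invlogit(par[1]); phi <- max(exp(par[2]), phi_min)
    -(.bbLogLik(kr, nr, mu, phi) + .bbLogLik(ka, na_, mu, phi))
  }
  mu_all <- clamp((sum(kr) + sum(ka)) / (sum(nr) + sum(na_)))
  fit1 <- tryCatch(optim(c(logit(clamp(mean_ref)), logit(clamp(mean_alt)),
                           log(0.01)), nll1, method = "Nelder-Mead"),
                   error = function(e) NULL)
  fit0 <- tryCatch(optim(c(logit(mu_all), log(0.01)), nll0,
                         method = "Nelder-Mead"),
                   error = function(e) NULL)
  if (!is.null(fit1) && !is.null(fit0) &&
      is.finite(fit1$value) && is.finite(fit0$value)) {
    lrt <- max(2 * (fit0$value - fit1$value), 0)
    p <- stats::pchisq(lrt, df = 1L, lower.tail = FALSE)
    return(out(p, invlogit(fit1$par[1]), invlogit(fit1$par[2]),
               "betabinomial_lrt"))
  }
  ## fallback: coverage-weighted paired t on pseudo-count logits
  lr <- logit((kr + 0.5) / (nr + 1)); la <- logit((ka + 0.5) / (na_ + 1))
  d <- la - lr
  w <- 1 / (1 / (nr + 1) + 1 / (na_ + 1))
  mw <- sum(w * d) / sum(w)
  vw <- sum(w * (d - mw)^2) / sum(w) / (n_ind - 1)
  tv <- mw / sqrt(vw)
  p <- 2 * pt(-abs(tv), df = n_ind - 1)
  out(p, mean_ref, mean_alt, "weighted_t")
}

#' Run the ASED analysis across groups
#'
#' Pairs alleles, tests every (site, SNP) group, and controls FDR at 5%
#' (BH).
#'
#' @inheritParams pairAlleles
#' @param alpha FDR threshold (default 0.05).
#' @return data.table: chrom, pos, snp_id (and tissue when present in the
#'   input), test columns from [pairedAsedTest()], q, significant,
#'   direction.
#' @export
asedScan <- function(allelic, genotypes = NULL, min_individuals = 5L,
                     alpha = 0.05) {
  paired <- pairAlleles(allelic, genotypes, min_individuals)
  if (!nrow(paired)) return(data.table::data.table())
  by_cols <- intersect(c("chrom", "pos", "snp_id", "tissue"),
                       names(paired))
  res <- paired[, pairedAsedTest(.SD), by = by_cols]
  fc <- fdrControl(res$p, alpha)
  res[, q := fc$q]
  res[, significant := fc$significant]
  res[, direction := ifelse(delta > 0, "alt>ref", "ref>alt")]
  res[]
}

#' Report significant ASED results and tissue occurrence
#'
#' @param results Output of [asedScan()] (per-tissue results may be bound
#'   together with a `tissue` column).
#' @param alpha Significance threshold on q (default 0.05).
#' @return List: `table` (significant rows with per-allele editing ratios
#'   and direction), `occurrence` (per (site, SNP): n_tissues,
#'   single_tissue flag), `summary` (single-/multi-tissue counts and
#'   shares).
#' @export
asedReport <- function(results, alpha = 0.05) {
  res <- data.table::as.data.table(results)
  if (!nrow(res))
    return(list(table = res, occurrence = res,
                summary = data.table::data.table(single = 0L, multi = 0L,
                                                 single_share = NA_real_)))
  sig <- res[q < alpha]
  if (!"tissue" %in% names(sig)) sig[, tissue := "all"]
  occ <- sig[, .(n_tissues = data.table::uniqueN(tissue)),
             by = .(chrom, pos, snp_id)]
  occ[, single_tissue := n_tissues == 1L]
  n_single <- sum(occ$single_tissue); n_multi <- sum(!occ$single_tissue)
  summary <- data.table::data.table(
    single = n_single, multi = n_multi,
    single_share = if (nrow(occ))
      percentShare(n_single, nrow(occ)) else NA_real_)
  list(table = sig[], occurrence = occ[], summary = summary)
}
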