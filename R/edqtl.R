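## cis-edQTL mapping: covariate PCs, phenotype transformation, single-site
## cis scans, permutation-based empirical p-values with a Beta tail
## approximation, BH FDR, conditionally independent signals, LD utilities,
## type-specificity against other QTL sets, and cross-tissue sharing.

#' Select significant phenotype PCs by permutation
#'
#' Parallel-analysis-style criterion: principal components of the
#' sample-by-site level matrix are retained while their explained-variance
#' fraction exceeds the 95th percentile of a permutation null in which each
#' site's values are permuted independently across samples.
#'
#' @param levels Sites x samples matrix of editing levels (missing values
#'   are imputed to site means for the PCA).
#' @param n_perm Permutations (default 100).
#' @param alpha Significance level (default 0.05).
#' @param seed Seed for the permutation stream.
#' @return List: `pcs` (samples x k score matrix, possibly 0 columns),
#'   `n_significant`, `var_explained`, `null_quantile`.
#' @export
selectPCs <- function(levels, n_perm = 100L, alpha = 0.05, seed = 1L) {
  stopifnot(is.matrix(levels))
  if (ncol(levels) < 3L) stop("need at least 3 samples")
  m <- levels
  for (i in seq_len(nrow(m))) {
    mi <- is.na(m[i, ])
    if (any(mi)) m[i, mi] <- mean(m[i, ], na.rm = TRUE)
  }
  m <- m[apply(m, 1L, function(v) sd(v) > 0 && !anyNA(v)), , drop = FALSE]
  pca <- prcomp(t(m), center = TRUE, scale. = FALSE)
  ve <- pca$sdev^2 / sum(pca$sdev^2)
  set.seed(seed)
  k_max <- min(10L, length(ve))
  null_ve <- matrix(NA_real_, n_perm, k_max)
  for (b in seq_len(n_perm)) {
    mp <- t(apply(m, 1L, sample))
    pp <- prcomp(t(mp), center = TRUE, scale. = FALSE)
    vep <- pp$sdev^2 / sum(pp$sdev^2)
    null_ve[b, ] <- vep[seq_len(k_max)]
  }
  qn <- apply(null_ve, 2L, quantile, probs = 1 - alpha)
  sig <- 0L
  for (j in seq_len(k_max)) {
    if (ve[j] > qn[j]) sig <- j else break
  }
  list(pcs = pca$x[, seq_len(sig), drop = FALSE], n_significant = sig,
       var_explained = ve[seq_len(k_max)], null_quantile = qn)
}

#' Transform editing levels for association testing
#'
#' Pseudo-count logit `log(((k + 0.5)/(n + 1)) / (1 - (k + 0.5)/(n + 1)))`,
#' ordinary least-squares residualization on covariate PCs, then a
#' rank-based inverse-normal transform (average ranks for ties, Blom
#' offset 3/8) rescaled to unit sample variance.
#'
#' @param edited,coverage Per-sample counts at one site (coverage > 0).
#'   Alternatively pass `levels` directly.
#' @param pcs Optional samples x k covariate matrix.
#' @param levels Optional raw levels in `[0, 1]` (used when counts are not
#'   available; boundary values are shrunk by `eps`).
#' @param eps Boundary shrinkage for `levels` input (default 1e-3).
#' @return Numeric phenotype vector with mean 0 and SD 1.
#' @export
transformLevels <- function(edited = NULL, coverage = NULL, pcs = NULL,
                            levels = NULL, eps = 1e-3) {
  if (is.null(levels)) {
    stopifnot(!is.null(edited), !is.null(coverage), all(coverage > 0))
    p <- (edited + 0.5) / (coverage + 1)
  } else {
    p <- pmin(pmax(levels, eps), 1 - eps)
  }
  if (sd(p) == 0) stop("constant phenotype: untestable site")
  x <- logit(p)
  if (!is.null(pcs) && NCOL(pcs) > 0) {
    x <- residuals(lm(x ~ as.matrix(pcs)))
  }
  r <- rank(x, ties.method = "average")
  n <- length(x)
  z <- qnorm((r - 3 / 8) / (n + 1 - 3 / 4))
  z <- z - mean(z)
  z / sd(z)
}

#' Single-site cis scan
#'
#' Simple linear regression of the transformed phenotype on each SNP dosage
#' within the cis window, with a two-sided t test on the slope.
#'
#' @param phenotype Numeric vector (one value per sample).
#' @param genotypes Samples x SNPs dosage matrix (0/1/2).
#' @param snp_pos data.table/data.frame with snp_id, chrom, pos for the
#'   genotype columns (same order), or NULL to test all columns.
#' @param site_chrom,site_pos Site location defining the window.
#' @param window Cis window half-width (default 1 Mb).
#' @param maf_min Minimum minor allele frequency (default 0.05).
#' @return data.table: snp_id, pos, maf, slope, se, t, p. Zero rows when no
#'   SNP qualifies.
#' @export
cisScan <- function(phenotype, genotypes, snp_pos = NULL,
                    site_chrom = NULL, site_pos = NULL,
                    window = 1e6, maf_min = 0.05) {
  G <- as.matrix(genotypes)
  n <- length(phenotype)
  stopifnot(nrow(G) == n)
  ids <- colnames(G) %||% as.character(seq_len(ncol(G)))
  pos <- rep(NA_integer_, ncol(G))
  keep <- rep(TRUE, ncol(G))
  if (!is.null(snp_pos)) {
    sp <- data.table::as.data.table(snp_pos)
    pos <- sp$pos[match(ids, sp$snp_id)]
    keep <- sp$chrom[match(ids, sp$snp_id)] == site_chrom &
      abs(pos - site_pos) <= window
    keep[is.na(keep)] <- FALSE
  }
  f <- colMeans(G) / 2
  maf <- pmin(f, 1 - f)
  nclass <- apply(G, 2L, function(g) length(unique(g)))
  keep <- keep & maf >= maf_min & nclass >= 2L
  if (!any(keep))
    return(data.table::data.table(snp_id = character(0), pos = integer(0),
                                  maf = numeric(0), slope = numeric(0),
                                  se = numeric(0), t = numeric(0),
                                  p = numeric(0)))
  Gk <- G[, keep, drop = FALSE]
  gc <- sweep(Gk, 2L, colMeans(Gk))
  yc <- phenotype - mean(phenotype)
  sxx <- colSums(gc^2)
  sxy <- drop(crossprod(gc, yc))
  slope <- sxy / sxx
  syy <- sum(yc^2)
  sigma2 <- pmax((syy - slope * sxy) / (n - 2), 0)
  se <- sqrt(sigma2 / sxx)
  tval <- ifelse(se > 0, slope / se, sign(slope) * Inf)
  data.table::data.table(snp_id = ids[keep], pos = pos[keep],
                         maf = maf[keep], slope = slope, se = se, t = tval,
                         p = 2 * pt(-abs(tval), df = n - 2))
}

## Beta MLE on (0,1) sample; returns c(a, b) or NULL on failure
.fitBetaML <- function(x) {
  x <- pmin(pmax(x, 1e-300), 1 - 1e-12)
  mm_m <- mean(x); mm_v <- var(x)
  if (mm_v <= 0) return(NULL)
  c0 <- max(mm_m * (1 - mm_m) / mm_v - 1, 0.1)
  start <- log(c(max(mm_m * c0, 1e-3), max((1 - mm_m) * c0, 1e-3)))
  nll <- function(lp) -sum(dbeta(x, exp(lp[1]), exp(lp[2]), log = TRUE))
  fit <- tryCatch(optim(start, nll, method = "Nelder-Mead"),
                  error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$value)) return(NULL)
  exp(fit$par)
}

#' Permutation pass with Beta-approximated empirical p-value
#'
#' Permutes the phenotype, records the minimum nominal p per permutation,
#' fits a Beta distribution to the null minimum-p sample by maximum
#' likelihood, and evaluates the observed minimum p on its CDF. The direct
#' empirical rank p is also reported, and used as fallback when the Beta
#' fit fails.
#'
#' @inheritParams cisScan
#' @param n_perm Number of permutations (default 1000; below 100 a warning
#'   is issued).
#' @param seed Permutation seed.
#' @return List: lead (snp_id, slope, se, nominal_p), empirical_p, rank_p,
#'   beta_shape (a, b) or NULL, n_snps.
#' @export
permutationPass <- function(phenotype, genotypes, snp_pos = NULL,
                            site_chrom = NULL, site_pos = NULL,
                            window = 1e6, maf_min = 0.05,
                            n_perm = 1000L, seed = 1L) {
  if (n_perm < 100L) warning("n_perm < 100: empirical p will be unstable")
  scan <- cisScan(phenotype, genotypes, snp_pos, site_chrom, site_pos,
                  window, maf_min)
  if (!nrow(scan))
    return(list(lead = NULL, empirical_p = NA_real_, rank_p = NA_real_,
                beta_shape = NULL, n_snps = 0L))
  obs_min <- min(scan$p)
  lead <- scan[which.min(p)]
  ## null min-p by vectorized correlation across permutations
  G <- as.matrix(genotypes)[, scan$snp_id, drop = FALSE]
  n <- length(phenotype)
  Gs <- scale(G)
  set.seed(seed)
  Y <- vapply(seq_len(n_perm), function(b) sample(phenotype), numeric(n))
  Ys <- scale(Y)
  R <- crossprod(Gs, Ys) / (n - 1)
  R <- pmin(pmax(R, -1 + 1e-12), 1 - 1e-12)
  Tv <- abs(R) * sqrt((n - 2) / (1 - R^2))
  null_min_p <- 2 * pt(-apply(Tv, 2L, max), df = n - 2)
  rank_p <- (1 + sum(null_min_p <= obs_min)) / (n_perm + 1)
  shape <- .fitBetaML(null_min_p)
  emp_p <- if (!is.null(shape)) pbeta(obs_min, shape[1], shape[2])
           else rank_p
  list(lead = lead, empirical_p = emp_p, rank_p = rank_p,
       beta_shape = shape, n_snps = nrow(scan))
}

#' Benjamini-Hochberg FDR control
#'
#' @param p Vector of per-site empirical p-values.
#' @param alpha FDR threshold (default 0.05).
#' @return data.table: p, q, significant.
#' @export
fdrControl <- function(p, alpha = 0.05) {
  if (!length(p))
    return(data.table::data.table(p = numeric(0), q = numeric(0),
                                  significant = logical(0)))
  q <- p.adjust(p, method = "BH")
  data.table::data.table(p = p, q = q, significant = q < alpha)
}

#' Conditionally independent cis signals
#'
#' Forward stepwise selection of cis-SNPs conditioning on all previously
#' selected signals, thresholded on the site's Beta-approximated
#' permutation null, with a backward pass dropping signals that lose
#' conditional significance. Ranks follow selection order.
#'
#' @inheritParams cisScan
#' @param beta_shape Beta shape pair from [permutationPass()]; the
#'   conditional nominal-p threshold is `qbeta(alpha, a, b)`.
#' @param alpha Significance level on the empirical scale (default 0.05).
#' @param max_signals Safety cap (default 10).
#' @return data.table: rank, snp_id, slope, se, p (conditional on the other
#'   selected signals).
#' @export
conditionalSignals <- function(phenotype, genotypes, snp_pos = NULL,
                               site_chrom = NULL, site_pos = NULL,
                               window = 1e6, maf_min = 0.05,
                               beta_shape, alpha = 0.05,
                               max_signals = 10L) {
  scan <- cisScan(phenotype, genotypes, snp_pos, site_chrom, site_pos,
                  window, maf_min)
  empty <- data.table::data.table(rank = integer(0), snp_id = character(0),
                                  slope = numeric(0), se = numeric(0),
                                  p = numeric(0))
  if (!nrow(scan)) return(empty)
  p_thresh <- if (!is.null(beta_shape))
    qbeta(alpha, beta_shape[1], beta_shape[2]) else alpha / nrow(scan)
  G <- as.matrix(genotypes)[, scan$snp_id, drop = FALSE]
  n <- length(phenotype)
  selected <- character(0)

  cond_scan <- function(exclude) {
    X <- cbind(1, G[, selected, drop = FALSE])
    Q <- qr.Q(qr(X))
    ry <- phenotype - Q %*% crossprod(Q, phenotype)
    cand <- setdiff(colnames(G), c(selected, exclude))
    if (!length(cand)) return(NULL)
    Gc <- G[, cand, drop = FALSE]
    RG <- Gc - Q %*% crossprod(Q, Gc)
    sxx <- colSums(RG^2)
    ok <- sxx > 1e-8          # collinear with selected: skipped
    if (!any(ok)) return(NULL)
    RG <- RG[, ok, drop = FALSE]; sxx <- sxx[ok]; cand <- cand[ok]
    sxy <- drop(crossprod(RG, ry))
    slope <- sxy / sxx
    df <- n - ncol(X) - 1L
    sigma2 <- pmax((sum(ry^2) - slope * sxy) / df, 0)
    se <- sqrt(sigma2 / sxx)
    tv <- ifelse(se > 0, slope / se, sign(slope) * Inf)
    data.table::data.table(snp_id = cand, slope = slope, se = se,
                           p = 2 * pt(-abs(tv), df = df))
  }

  while (length(selected) < max_signals) {
    cs <- cond_scan(character(0))
    if (is.null(cs) || !nrow(cs)) break
    best <- cs[which.min(p)]
    if (best$p >= p_thresh) break
    selected <- c(selected, best$snp_id)
  }
  if (!length(selected)) return(empty)
  ## backward check: each signal conditional on all the others
  repeat {
    drop_one <- NULL
    for (s in selected) {
      others <- setdiff(selected, s)
      X <- cbind(1, G[, others, drop = FALSE])
      Q <- qr.Q(qr(X))
      ry <- phenotype - Q %*% crossprod(Q, phenotype)
      g <- G[, s] - Q %*% crossprod(Q, G[, s])
      sxx <- sum(g^2)
      if (sxx <= 1e-8) { drop_one <- s; break }
      slope <- sum(g * ry) / sxx
      df <- n - ncol(X) - 1L
      sigma2 <- max((sum(ry^2) - slope * sum(g * ry)) / df, 0)
      pv <- 2 * pt(-abs(slope / sqrt(sigma2 / sxx)), df = df)
      if (pv >= p_thresh) { drop_one <- s; break }
    }
    if (is.null(drop_one)) break
    selected <- setdiff(selected, drop_one)
    if (!length(selected)) return(empty)
  }
  ## final conditional estimates
  rows <- lapply(seq_along(selected), function(i) {
    s <- selected[i]
    others <- setdiff(selected, s)
    X <- cbind(1, G[, others, drop = FALSE])
    Q <- qr.Q(qr(X))
    ry <- phenotype - Q %*% crossprod(Q, phenotype)
    g <- G[, s] - Q %*% crossprod(Q, G[, s])
    sxx <- sum(g^2)
    slope <- sum(g * ry) / sxx
    df <- n - ncol(X) - 1L
    sigma2 <- max((sum(ry^2) - slope * sum(g * ry)) / df, 0)
    se <- sqrt(sigma2 / sxx)
    data.table::data.table(rank = i, snp_id = s, slope = slope, se = se,
                           p = 2 * pt(-abs(slope / se), df = df))
  })
  data.table::rbindlist(rows)
}

#' LD r-squared between two SNPs
#'
#' Squared Pearson correlation of dosages.
#'
#' @param a,b Dosage vectors over the same samples.
#' @return r2 in `[0, 1]`; `NA` (with attribute `monomorphic = TRUE`) when
#'   either SNP is monomorphic.
#' @export
ldR2 <- function(a, b) {
  if (sd(a) == 0 || sd(b) == 0) {
    out <- NA_real_
    attr(out, "monomorphic") <- TRUE
    return(out)
  }
  cor(a, b)^2
}

#' Type-specific edQTLs relative to other QTL sets
#'
#' An edQTL is type-specific when its maximum LD r2 against every eQTL and
#' sQTL SNP on the same chromosome within the comparison window is below
#' `r2_thresh`. When per-SNP eQTL nominal p-values are supplied, a second
#' pass reports the fraction of retained edQTLs whose eQTL p exceeds 0.05.
#'
#' @param edqtl_snps data.table: snp_id, chrom, pos.
#' @param other_snps data.table of eQTL/sQTL SNPs (snp_id, chrom, pos).
#' @param genotypes Samples x SNPs dosage matrix covering both sets.
#' @param r2_thresh LD threshold (default 0.8).
#' @param window Comparison window half-width (default 1 Mb).
#' @param eqtl_p Optional named vector of eQTL nominal p per edQTL snp_id.
#' @return List: `table` (edqtl_snps plus max_r2, type_specific),
#'   `fraction_type_specific`, `fraction_eqtl_p_gt_0.05` (NA when no p
#'   given).
#' @export
typeSpecificFilter <- function(edqtl_snps, other_snps, genotypes,
                               r2_thresh = 0.8, window = 1e6,
                               eqtl_p = NULL) {
  ed <- data.table::as.data.table(edqtl_snps)
  ot <- data.table::as.data.table(other_snps)
  G <- as.matrix(genotypes)
  max_r2 <- vapply(seq_len(nrow(ed)), function(i) {
    cand <- ot[chrom == ed$chrom[i] & abs(pos - ed$pos[i]) <= window &
               snp_id %in% colnames(G)]
    if (!nrow(cand)) return(0)
    r <- suppressWarnings(
      cor(G[, ed$snp_id[i]], G[, cand$snp_id, drop = FALSE]))
    max(r^2, na.rm = TRUE)
  }, numeric(1))
  out <- data.table::copy(ed)
  out[, max_r2 := max_r2]
  out[, type_specific := max_r2 < r2_thresh]
  frac_p <- NA_real_
  if (!is.null(eqtl_p)) {
    ret <- out[type_specific == TRUE]
    pv <- eqtl_p[ret$snp_id]
    if (length(pv)) frac_p <- mean(pv > 0.05, na.rm = TRUE)
  }
  list(table = out[],
       fraction_type_specific = mean(out$type_specific),
       fraction_eqtl_p_gt_0.05 = frac_p)
}

#' Positional density of QTL SNPs around anchors
#'
#' Counts QTL SNPs in equal bins of the `+-flank` window around anchor
#' positions (TSS, splice junctions or editing sites), normalized per
#' anchor. Bins are half-open; windows truncated at contig edges are
#' normalized by covered width.
#'
#' @param qtl_pos data.table: chrom, pos of QTL SNPs.
#' @param anchors data.table: chrom, pos of anchors; optionally
#'   `chrom_len`.
#' @param flank Half-window (default 1000).
#' @param bins Number of bins (default 40).
#' @return data.table: bin (1-based), bin_start (offset), density.
#' @export
positionalDensity <- function(qtl_pos, anchors, flank = 1000L, bins = 40L) {
  q <- data.table::as.data.table(qtl_pos)
  a <- data.table::as.data.table(anchors)
  width <- 2 * flank / bins
  counts <- numeric(bins)
  cover <- numeric(bins)
  for (i in seq_len(nrow(a))) {
    off <- q[chrom == a$chrom[i], pos] - a$pos[i]
    off <- off[off >= -flank & off < flank]
    if (length(off)) {
      b <- floor((off + flank) / width) + 1L
      tb <- table(b)
      counts[as.integer(names(tb))] <- counts[as.integer(names(tb))] + tb
    }
    ## covered fraction per bin (contig edges)
    lo <- a$pos[i] - flank
    len <- if ("chrom_len" %in% names(a)) a$chrom_len[i] else Inf
    bin_lo <- lo + (seq_len(bins) - 1L) * width
    bin_hi <- bin_lo + width
    cov_i <- pmax(0, pmin(bin_hi, len) - pmax(bin_lo, 1)) / width
    cover <- cover + pmin(cov_i, 1)
  }
  data.table::data.table(
    bin = seq_len(bins),
    bin_start = -flank + (seq_len(bins) - 1L) * width,
    density = ifelse(cover > 0, counts / cover, NA_real_))
}

#' Cross-tissue sharing of edQTL effects
#'
#' Spearman rank correlation of effect sizes over (site, SNP) pairs
#' significant in at least one tissue of each pair.
#'
#' @param effects Named list of per-tissue data.tables with columns
#'   site_id, snp_id, slope, significant (logical).
#' @param min_shared Pairs with fewer shared records are flagged
#'   low-confidence (default 10).
#' @return List: `rho` (tissue x tissue Spearman matrix, diagonal 1),
#'   `n_shared`, `low_confidence` (logical matrix).
#' @export
tissueSharing <- function(effects, min_shared = 10L) {
  tl <- names(effects)
  k <- length(tl)
  rho <- matrix(NA_real_, k, k, dimnames = list(tl, tl))
  ns <- matrix(0L, k, k, dimnames = list(tl, tl))
  diag(rho) <- 1
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j <= i) next
    a <- data.table::as.data.table(effects[[i]])
    b <- data.table::as.data.table(effects[[j]])
    keys <- rbind(a[significant == TRUE, .(site_id, snp_id)],
                  b[significant == TRUE, .(site_id, snp_id)])
    keys <- unique(keys)
    m <- a[keys, on = c("site_id", "snp_id"), nomatch = NULL][
      b, on = c("site_id", "snp_id"), nomatch = NULL]
    ns[i, j] <- ns[j, i] <- nrow(m)
    if (nrow(m) >= 3L)
      rho[i, j] <- rho[j, i] <- suppressWarnings(
        cor(m$slope, m$i.slope, method = "spearman"))
  }
  list(rho = rho, n_shared = ns, low_confidence = ns < min_shared)
}

#' Map cis-edQTLs across sites
#'
#' Orchestrates the per-site pipeline: transform levels, cis scan,
#' permutation pass, then BH FDR across sites.
#'
#' @param x An [EditingExperiment-class] (one tissue) or a list with
#'   `edited`/`coverage` matrices.
#' @param genotypes Samples x SNPs dosage matrix (rows matching samples).
#' @param snp_pos data.table: snp_id, chrom, pos.
#' @param pcs Optional covariate matrix (see [selectPCs()]).
#' @param window,maf_min,n_perm,seed Passed through.
#' @param min_samples Minimum covered samples per site (default 30).
#' @param alpha FDR threshold (default 0.05).
#' @return data.table: site, chrom, pos, lead snp_id, slope, se, nominal_p,
#'   empirical_p, q, significant, n_snps, plus `beta_shapes` attribute for
#'   downstream conditional analysis.
#' @export
mapEdqtl <- function(x, genotypes, snp_pos, pcs = NULL, window = 1e6,
                     maf_min = 0.05, n_perm = 1000L, seed = 1L,
                     min_samples = 30L, alpha = 0.05) {
  ed <- assay(x, "edited"); cv <- assay(x, "coverage")
  gr <- rowRanges(x)
  rows <- list(); shapes <- list()
  for (i in seq_len(nrow(ed))) {
    ok <- cv[i, ] > 0
    if (sum(ok) < min_samples) next
    y <- tryCatch(
      transformLevels(ed[i, ok], cv[i, ok],
                      pcs = if (is.null(pcs)) NULL
                            else pcs[ok, , drop = FALSE]),
      error = function(e) NULL)
    if (is.null(y)) next
    G <- genotypes[ok, , drop = FALSE]
    pp <- permutationPass(y, G, snp_pos,
                          site_chrom = as.character(seqnames(gr))[i],
                          site_pos = start(gr)[i], window = window,
                          maf_min = maf_min, n_perm = n_perm,
                          seed = childSeed(seed, i))
    if (is.null(pp$lead)) next
    site_key <- names(gr)[i] %||% as.character(i)
    shapes[[site_key]] <- pp$beta_shape
    rows[[length(rows) + 1L]] <- data.table::data.table(
      site = site_key, chrom = as.character(seqnames(gr))[i],
      pos = start(gr)[i], snp_id = pp$lead$snp_id,
      slope = pp$lead$slope, se = pp$lead$se, nominal_p = pp$lead$p,
      empirical_p = pp$empirical_p, rank_p = pp$rank_p,
      n_snps = pp$n_snps)
  }
  if (!length(rows)) return(data.table::data.table())
  out <- data.table::rbindlist(rows)
  fc <- fdrControl(out$empirical_p, alpha)
  out[, q := fc$q]
  out[, significant := fc$significant]
  data.table::setattr(out, "beta_shapes", shapes)
  out[]
}
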