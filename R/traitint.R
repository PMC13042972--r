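## Trait integration: connect edQTLs to complex traits via matched-control
## Z^2 enrichment, LD clumping, approximate-Bayes-factor colocalization,
## REML heritability partitioning over SNP categories, and hypergeometric
## gene-set enrichment.

#' LD scores
#'
#' For each SNP, `1 + sum of r2` against all other SNPs on the same
#' chromosome within the window.
#'
#' @param genotypes Samples x SNPs dosage matrix.
#' @param snp_pos data.table: snp_id, chrom, pos (matching columns).
#' @param window Half-window in bp (default 1 Mb).
#' @return Named numeric vector of LD scores (`NA` for monomorphic SNPs).
#' @export
ldScore <- function(genotypes, snp_pos, window = 1e6) {
  G <- as.matrix(genotypes)
  sp <- data.table::as.data.table(snp_pos)
  ord <- match(colnames(G), sp$snp_id)
  chrom <- sp$chrom[ord]; pos <- sp$pos[ord]
  out <- setNames(rep(NA_real_, ncol(G)), colnames(G))
  for (chr in unique(chrom)) {
    j <- which(chrom == chr)
    sds <- apply(G[, j, drop = FALSE], 2L, sd)
    poly <- sds > 0
    jj <- j[poly]
    if (!length(jj)) next
    r2 <- suppressWarnings(cor(G[, jj, drop = FALSE]))^2
    d <- abs(outer(pos[jj], pos[jj], "-"))
    r2[d > window] <- 0
    diag(r2) <- 0
    out[jj] <- 1 + rowSums(r2, na.rm = TRUE)
  }
  out
}

#' Match control SNPs to a focal set
#'
#' Samples, per focal SNP, one control from the pool on the same chromosome
#' with `|dMAF| <= maf_tol` and `|dLDscore| <= ld_tol_sd * SD(LD score)`,
#' without replacement where possible. Focal SNPs with an empty tolerance
#' window are flagged unmatched.
#'
#' @param focal Character vector of focal SNP ids.
#' @param pool data.table: snp_id, chrom, maf, ldscore (the candidate
#'   controls; may include the focal SNPs themselves).
#' @param maf_tol MAF tolerance (default 0.02).
#' @param ld_tol_sd LD-score tolerance in pool SDs (default 0.1).
#' @param seed Sampling seed.
#' @return List: `controls` (named character vector, NA where unmatched),
#'   `unmatched` (focal ids), `meta` (per-pair MAF/LD-score deltas).
#' @export
matchControls <- function(focal, pool, maf_tol = 0.02, ld_tol_sd = 0.1,
                          seed = 1L) {
  pool <- data.table::as.data.table(pool)
  if (!nrow(pool)) stop("empty control pool")
  set.seed(seed)
  ld_sd <- sd(pool$ldscore, na.rm = TRUE)
  ld_tol <- ld_tol_sd * ifelse(is.na(ld_sd) || ld_sd == 0, Inf, ld_sd)
  used <- character(0)
  controls <- setNames(rep(NA_character_, length(focal)), focal)
  meta <- list()
  for (f in focal) {
    fr <- pool[snp_id == f]
    if (!nrow(fr)) next
    cand <- pool[chrom == fr$chrom & abs(maf - fr$maf) <= maf_tol &
                 abs(ldscore - fr$ldscore) <= ld_tol]
    cand <- cand[!snp_id %in% used]
    if (!nrow(cand)) {
      cand <- pool[chrom == fr$chrom & abs(maf - fr$maf) <= maf_tol &
                   abs(ldscore - fr$ldscore) <= ld_tol]  # allow reuse
    }
    if (!nrow(cand)) next
    pick <- cand[sample.int(nrow(cand), 1L)]
    controls[f] <- pick$snp_id
    used <- c(used, pick$snp_id)
    meta[[f]] <- data.table::data.table(
      focal = f, control = pick$snp_id,
      d_maf = pick$maf - fr$maf, d_ldscore = pick$ldscore - fr$ldscore)
  }
  list(controls = controls,
       unmatched = names(controls)[is.na(controls)],
       meta = if (length(meta)) data.table::rbindlist(meta)
              else data.table::data.table())
}

#' GWAS Z-squared enrichment against matched controls
#'
#' Compares squared GWAS Z-scores of focal SNPs against repeatedly redrawn
#' matched control sets: reports the ratio of the focal mean Z2 to the mean
#' over control draws, a one-sided Wilcoxon rank-sum test (focal greater),
#' and the empirical p-value, i.e. the fraction of control draws whose mean
#' Z2 reaches the focal mean.
#'
#' @param focal Focal SNP ids (e.g. lead edQTL SNPs).
#' @param gwas data.table with snp and z columns.
#' @param pool Control pool (see [matchControls()]).
#' @param n_perm Control draws (default 1000).
#' @param seed Seed.
#' @param maf_tol,ld_tol_sd Matching tolerances.
#' @return data.table: ratio, wilcoxon_p, empirical_p, n_focal,
#'   n_unmatched, underpowered.
#' @export
z2Enrichment <- function(focal, gwas, pool, n_perm = 1000L, seed = 1L,
                         maf_tol = 0.02, ld_tol_sd = 0.1) {
  gwas <- data.table::as.data.table(gwas)
  pool <- data.table::as.data.table(pool)
  z2 <- setNames(gwas$z^2, gwas$snp)
  set.seed(seed)
  ld_sd <- sd(pool$ldscore, na.rm = TRUE)
  ld_tol <- ld_tol_sd * ifelse(is.na(ld_sd) || ld_sd == 0, Inf, ld_sd)
  ## per-focal candidate control lists, computed once; a focal SNP may
  ## match itself (degenerate pools) but never another focal SNP
  cand <- lapply(focal, function(f) {
    fr <- pool[snp_id == f]
    if (!nrow(fr)) return(character(0))
    ids <- pool[chrom == fr$chrom & abs(maf - fr$maf) <= maf_tol &
                abs(ldscore - fr$ldscore) <= ld_tol, snp_id]
    ids <- setdiff(ids, setdiff(focal, f))
    ids[ids %in% names(z2)]
  })
  names(cand) <- focal
  matched <- focal[lengths(cand) > 0 & focal %in% names(z2)]
  cand <- cand[matched]
  focal_z2 <- z2[matched]
  obs <- mean(focal_z2)
  null_means <- vapply(seq_len(n_perm), function(b) {
    draw <- vapply(cand, function(ids)
      ids[sample.int(length(ids), 1L)], character(1))
    mean(z2[draw])
  }, numeric(1))
  ctrl_all <- vapply(cand, function(ids)
    ids[sample.int(length(ids), 1L)], character(1))
  ratio <- obs / mean(null_means, na.rm = TRUE)
  wp <- if (length(ctrl_all) >= 3L)
    suppressWarnings(wilcox.test(focal_z2, z2[ctrl_all],
                                 alternative = "greater")$p.value)
  else NA_real_
  emp_p <- (1 + sum(null_means >= obs, na.rm = TRUE)) / (n_perm + 1)
  data.table::data.table(
    ratio = ratio, wilcoxon_p = wp, empirical_p = emp_p,
    n_focal = length(matched),
    n_unmatched = length(focal) - length(matched),
    underpowered = length(matched) < 10L)
}

#' Greedy LD clumping
#'
#' Repeatedly takes the best remaining p-value and removes all SNPs within
#' `kb` kilobases at `r2 >= r2_thresh`. Ties are broken by position, then
#' id.
#'
#' @param snps data.table: snp_id, chrom, pos, p.
#' @param genotypes Samples x SNPs dosage matrix covering the SNPs.
#' @param r2_thresh LD threshold (default 0.4).
#' @param kb Distance bound in kb (default 250).
#' @return data.table of clump index SNPs (subset of the input rows, with
#'   `clump` id).
#' @export
clump <- function(snps, genotypes, r2_thresh = 0.4, kb = 250) {
  s <- data.table::as.data.table(snps)
  G <- as.matrix(genotypes)
  s <- s[order(p, pos, snp_id)]
  out <- list()
  remaining <- s
  ci <- 0L
  while (nrow(remaining)) {
    ci <- ci + 1L
    lead <- remaining[1]
    out[[ci]] <- data.table::copy(lead)[, clump := ci]
    near <- remaining$chrom == lead$chrom &
      abs(remaining$pos - lead$pos) <= kb * 1000
    drop <- rep(FALSE, nrow(remaining))
    idx <- which(near)
    if (length(idx)) {
      r <- suppressWarnings(
        cor(G[, lead$snp_id], G[, remaining$snp_id[idx], drop = FALSE]))
      drop[idx] <- !is.na(r) & r^2 >= r2_thresh
    }
    drop[1] <- TRUE
    remaining <- remaining[!drop]
  }
  data.table::rbindlist(out)
}

## log(sum(exp(x))) stable
.logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Colocalization by approximate Bayes factors
#'
#' Wakefield log-ABF per SNP and study,
#' `0.5 * (log(1 - r) + r * z^2)` with `r = W / (W + se^2)`, combined into
#' posterior probabilities of the five hypotheses (no association; one
#' study only; two distinct causal variants; one shared causal variant)
#' under the standard single-causal-variant priors.
#'
#' @param qtl,gwas data.tables sharing a `snp` column, each with z and se
#'   (beta/se also accepted via z = beta/se).
#' @param p1,p2,p12 Priors (defaults 1e-4, 1e-4, 1e-5).
#' @param W_qtl,W_gwas Prior effect variances (defaults 0.2^2 quantitative
#'   QTL scale, 0.15^2 GWAS).
#' @param gwas_p_min Region eligibility threshold: minimum GWAS p must be
#'   below this (default 1e-5).
#' @return data.table: PP0..PP4, n_snps, lead_qtl, lead_gwas, eligible.
#' @export
colocAbf <- function(qtl, gwas, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                     W_qtl = 0.2^2, W_gwas = 0.15^2, gwas_p_min = 1e-5) {
  q <- data.table::copy(data.table::as.data.table(qtl))
  g <- data.table::copy(data.table::as.data.table(gwas))
  if (!"z" %in% names(q)) q[, z := beta / se]
  if (!"z" %in% names(g)) g[, z := beta / se]
  if (any(q$se <= 0, na.rm = TRUE)) q <- q[se > 0]
  if (any(g$se <= 0, na.rm = TRUE)) g <- g[se > 0]
  m <- merge(q[, .(snp, z_q = z, se_q = se)],
             g[, .(snp, z_g = z, se_g = se)], by = "snp")
  if (!nrow(m)) stop("no shared SNPs between QTL and GWAS summaries")
  gwas_min_p <- min(2 * pnorm(-abs(m$z_g)))
  labf <- function(z, se, W) {
    r <- W / (W + se^2)
    0.5 * (log(1 - r) + r * z^2)
  }
  l1 <- labf(m$z_q, m$se_q, W_qtl)
  l2 <- labf(m$z_g, m$se_g, W_gwas)
  lsum1 <- .logsumexp(l1)
  lsum2 <- .logsumexp(l2)
  lsum12 <- .logsumexp(l1 + l2)
  lh0 <- 0
  lh1 <- log(p1) + lsum1
  lh2 <- log(p2) + lsum2
  ## both causal, distinct SNPs: sum_{i != j} ABF1_i ABF2_j
  both <- lsum1 + lsum2
  lh3 <- log(p1) + log(p2) +
    both + log1p(-pmin(exp(lsum12 - both), 1 - 1e-12))
  lh4 <- log(p12) + lsum12
  lall <- c(lh0, lh1, lh2, lh3, lh4)
  pp <- exp(lall - .logsumexp(lall))
  data.table::data.table(
    PP0 = pp[1], PP1 = pp[2], PP2 = pp[3], PP3 = pp[4], PP4 = pp[5],
    n_snps = nrow(m),
    lead_qtl = m$snp[which.max(abs(m$z_q))],
    lead_gwas = m$snp[which.max(abs(m$z_g))],
    eligible = gwas_min_p < gwas_p_min)
}

#' Genomic relationship matrix
#'
#' `Z Z' / M` over per-SNP standardized dosages (no MAF-dependent
#' weighting beyond standardization).
#'
#' @param genotypes Samples x SNPs dosage matrix.
#' @return Samples x samples GRM.
#' @export
grmMatrix <- function(genotypes) {
  Z <- scale(as.matrix(genotypes))
  Z[is.na(Z)] <- 0
  keep <- apply(Z, 2L, function(v) any(v != 0))
  Z <- Z[, keep, drop = FALSE]
  tcrossprod(Z) / ncol(Z)
}

#' REML variance-component estimation over SNP categories
#'
#' Average-information REML with EM fallback for the model
#' `y = mu + sum_k g_k + e`, `g_k ~ N(0, A_k sigma2_k)` where `A_k` is the
#' GRM of SNP category k. Heritability enrichment per category is the h2
#' share divided by the SNP share.
#'
#' @param y Phenotype vector.
#' @param genotypes Samples x SNPs dosage matrix.
#' @param categories Factor/character per SNP assigning categories.
#' @param max_iter Maximum iterations (default 50).
#' @param tol Convergence tolerance on the log-likelihood (default 1e-6).
#' @param n_em Initial EM iterations before AI updates (default 3).
#' @return List: `h2` (named per-category h2 plus `total`), `varcomp`
#'   (variances incl. residual), `enrichment` (per category),
#'   `converged`, `n_iter`.
#' @export
remlH2 <- function(y, genotypes, categories, max_iter = 50L, tol = 1e-6,
                   n_em = 3L) {
  y <- as.numeric(y)
  n <- length(y)
  categories <- as.character(categories)
  cats <- unique(categories)
  G <- as.matrix(genotypes)
  stopifnot(ncol(G) == length(categories))
  A <- lapply(cats, function(k) grmMatrix(G[, categories == k,
                                            drop = FALSE]))
  names(A) <- cats
  M_k <- table(categories)[cats]
  K <- length(A)
  X <- matrix(1, n, 1)
  vy <- var(y)
  s2 <- rep(vy / (K + 1), K + 1)      # components then residual
  Alist <- c(A, list(diag(n)))

  loglik <- function(P, Vi, yPy) {
    ## restricted LL up to a constant
    -0.5 * (determinant(Vi, logarithm = TRUE)$modulus * -1 +
            determinant(crossprod(X, Vi %*% X),
                        logarithm = TRUE)$modulus + yPy)
  }
  ll_old <- -Inf
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    V <- Reduce(`+`, Map(function(s, a) s * a, s2, Alist))
    Vi <- tryCatch(solve(V), error = function(e) NULL)
    if (is.null(Vi)) { s2 <- pmax(s2, vy * 1e-3); next }
    XtViX <- crossprod(X, Vi %*% X)
    P <- Vi - Vi %*% X %*% solve(XtViX, crossprod(X, Vi))
    Py <- P %*% y
    yPy <- drop(crossprod(y, Py))
    ll <- loglik(P, Vi, yPy)
    APy <- lapply(Alist, function(a) a %*% Py)
    if (it <= n_em) {
      ## EM update
      for (k in seq_along(s2)) {
        trPA <- sum(P * Alist[[k]])
        s2[k] <- max((s2[k]^2 * drop(crossprod(Py, APy[[k]])) +
                      n * s2[k] - s2[k]^2 * trPA) / n, vy * 1e-6)
      }
    } else {
      ## AI update
      dL <- vapply(seq_along(s2), function(k)
        -0.5 * (sum(P * Alist[[k]]) - drop(crossprod(Py, APy[[k]]))),
        numeric(1))
      AI <- matrix(0, length(s2), length(s2))
      for (i in seq_along(s2)) for (j in seq_along(s2)) {
        if (j < i) { AI[i, j] <- AI[j, i]; next }
        AI[i, j] <- 0.5 * drop(crossprod(APy[[i]], P %*% APy[[j]]))
      }
      step <- tryCatch(solve(AI, dL), error = function(e) NULL)
      if (is.null(step)) {
        for (k in seq_along(s2)) {
          trPA <- sum(P * Alist[[k]])
          s2[k] <- max((s2[k]^2 * drop(crossprod(Py, APy[[k]])) +
                        n * s2[k] - s2[k]^2 * trPA) / n, vy * 1e-6)
        }
      } else {
        s2_new <- s2 + step
        ## halve steps that go negative
        h <- 1
        while (any(s2_new < 0) && h > 1e-4) {
          h <- h / 2
          s2_new <- s2 + h * step
        }
        s2 <- pmax(s2_new, vy * 1e-6)
      }
    }
    if (abs(ll - ll_old) < tol && it > n_em) { converged <- TRUE; break }
    ll_old <- ll
  }
  tot <- sum(s2)
  h2_k <- setNames(s2[seq_len(K)] / tot, cats)
  h2_total <- sum(h2_k)
  share_snp <- as.numeric(M_k) / sum(M_k)
  enr <- setNames((h2_k / h2_total) / share_snp, cats)
  list(h2 = c(h2_k, total = h2_total),
       varcomp = setNames(s2, c(cats, "residual")),
       enrichment = enr, converged = converged, n_iter = it)
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail probability `P(X >= overlap)` for drawing `|query|` genes
#' from the background and hitting the set.
#'
#' @param query Character vector of query genes (subset of background).
#' @param sets Named list of gene sets.
#' @param background Character vector of background genes.
#' @return data.table: set, overlap, set_size, p.
#' @export
hypergeomEnrichment <- function(query, sets, background) {
  query <- unique(query)
  background <- unique(background)
  if (!all(query %in% background))
    stop("query must be a subset of background")
  data.table::rbindlist(lapply(names(sets), function(nm) {
    s <- intersect(unique(sets[[nm]]), background)
    k <- length(intersect(query, s))
    p <- phyper(k - 1, length(s), length(background) - length(s),
                length(query), lower.tail = FALSE)
    data.table::data.table(set = nm, overlap = k, set_size = length(s),
                           p = p)
  }))
}
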