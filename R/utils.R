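#' @importFrom stats rnorm rbinom runif rbeta rnbinom dbeta pbeta qbeta
#'   pbinom qnorm pnorm pt pchisq sd cor var lm residuals coef prcomp optim
#'   p.adjust quantile median wilcox.test ks.test phyper setNames
#'   complete.cases as.dist hclust cutree
#' @importFrom utils head tail write.table read.table modifyList
#' @import methods
#' @import data.table
NULL

## overlap helpers that tolerate disjoint seqlevel sets quietly
ovAny <- function(query, subject, ...) {
  suppressWarnings(IRanges::overlapsAny(query, subject, ...))
}

ovFind <- function(query, subject, ...) {
  suppressWarnings(GenomicRanges::findOverlaps(query, subject, ...))
}

logit <- function(p) log(p / (1 - p))

invlogit <- function(x) 1 / (1 + exp(-x))

## round-half-up at `digits` decimals (base round() is round-half-even)
roundHalfUp <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

## deterministic child seed: keep well inside 32-bit integer range
childSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1103L + offset) %% 2147483587)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x))
    stop(sprintf("'%s' must be a single non-missing number", name))
}

#' Percentage share with half-up rounding
#'
#' Computes `100 * numerator / denominator` rounded half-up at the requested
#' number of decimals, the convention used for all percentage fields in
#' summary reports.
#'
#' @param numerator,denominator Non-negative counts, `numerator <= denominator`.
#' @param decimals Number of decimals to render (default 2).
#' @return A numeric percentage in `[0, 100]`.
#' @examples
#' percentShare(33270, 36504)  # 91.14
#' @export
percentShare <- function(numerator, denominator, decimals = 2) {
  stopifnot_scalar(numerator, "numerator")
  stopifnot_scalar(denominator, "denominator")
  if (denominator <= 0) stop("denominator must be > 0")
  if (numerator < 0 || numerator > denominator)
    stop("numerator must lie in [0, denominator]")
  roundHalfUp(100 * numerator / denominator, decimals)
}
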