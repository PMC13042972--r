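## Summary assembly: headline counts and share arithmetic for a pipeline
## run, with deterministic rendering.

#' Single- versus multi-tissue occurrence summary
#'
#' @param records data.table with an entity key column(s) and a `tissue`
#'   column, or a named list mapping entity to a vector of tissues.
#' @param key Entity key columns (default `c("chrom", "pos")`).
#' @param decimals Rendering precision for shares (default 2).
#' @return data.table: single, multi, total, single_share, multi_share.
#' @export
tissueOccurrenceSummary <- function(records, key = c("chrom", "pos"),
                                    decimals = 2) {
  if (is.list(records) && !is.data.frame(records)) {
    n_tis <- lengths(lapply(records, unique))
  } else {
    r <- data.table::as.data.table(records)
    n_tis <- r[, .(n = data.table::uniqueN(tissue)), by = key]$n
  }
  single <- sum(n_tis == 1L)
  multi <- sum(n_tis >= 2L)
  total <- single + multi
  data.table::data.table(
    single = single, multi = multi, total = total,
    single_share = if (total) percentShare(single, total, decimals)
                   else NA_real_,
    multi_share = if (total) percentShare(multi, total, decimals)
                  else NA_real_)
}

#' Assemble a pipeline summary report
#'
#' Collects the named counts and derived shares from whichever stage
#' outputs are supplied; missing stages are marked absent with a warning.
#'
#' @param catalog Per-tissue site catalog (from [runFilterCascade()]).
#' @param edqtl edQTL result table (from [mapEdqtl()], possibly bound over
#'   tissues with a `tissue` column).
#' @param ased ASED results (from [asedScan()]).
#' @param specificity [tissueSpecificity()] output.
#' @param coloc data.table of [colocAbf()] rows.
#' @param conservation List with `n_lifted`, `n_conserved` (and optionally
#'   the [permutationEnrichment()] row).
#' @param decimals Percentage rendering precision.
#' @return data.table with columns section, metric, value.
#' @export
buildReport <- function(catalog = NULL, edqtl = NULL, ased = NULL,
                        specificity = NULL, coloc = NULL,
                        conservation = NULL, decimals = 2) {
  rows <- list()
  add <- function(section, metric, value)
    rows[[length(rows) + 1L]] <<- data.table::data.table(
      section = section, metric = metric, value = as.numeric(value))
  absent <- function(section) {
    warning(sprintf("report section '%s' absent", section))
    add(section, "absent", NA_real_)
  }
  if (!is.null(catalog)) {
    ct <- data.table::as.data.table(catalog)
    add("catalog", "n_site_tissue_records", nrow(ct))
    un <- unique(ct, by = c("chrom", "pos"))
    add("catalog", "n_unique_sites", nrow(un))
    if ("substitution" %in% names(un))
      add("catalog", "a2g_percent",
          percentShare(sum(un$substitution == "A>G"), nrow(un), decimals))
    if ("in_repeat" %in% names(un))
      add("catalog", "repeat_percent",
          percentShare(sum(un$in_repeat), nrow(un), decimals))
    if ("tissue" %in% names(ct)) {
      occ <- tissueOccurrenceSummary(ct, decimals = decimals)
      add("catalog", "single_tissue_percent", occ$single_share)
    }
  } else absent("catalog")
  if (!is.null(edqtl) && nrow(edqtl)) {
    eq <- data.table::as.data.table(edqtl)
    add("edqtl", "n_sites_tested", nrow(eq))
    add("edqtl", "n_significant", sum(eq$significant))
    add("edqtl", "significant_percent",
        percentShare(sum(eq$significant), nrow(eq), decimals))
  } else absent("edqtl")
  if (!is.null(ased) && nrow(ased)) {
    as_ <- data.table::as.data.table(ased)
    add("ased", "n_groups_tested", nrow(as_))
    add("ased", "n_significant", sum(as_$significant))
  } else absent("ased")
  if (!is.null(specificity) && nrow(specificity)) {
    sp <- data.table::as.data.table(specificity)
    add("specificity", "n_eligible", nrow(sp))
    add("specificity", "n_tissue_specific", sum(sp$is_specific))
  } else absent("specificity")
  if (!is.null(coloc) && nrow(coloc)) {
    cl <- data.table::as.data.table(coloc)
    add("coloc", "n_regions", nrow(cl))
    add("coloc", "n_colocalized", sum(cl$PP4 > 0.9))
  } else absent("coloc")
  if (!is.null(conservation)) {
    add("conservation", "n_lifted", conservation$n_lifted %||% NA_real_)
    add("conservation", "n_conserved",
        conservation$n_conserved %||% NA_real_)
    if (!is.null(conservation$n_lifted) &&
        !is.null(conservation$n_conserved) && conservation$n_lifted > 0)
      add("conservation", "conserved_percent",
          percentShare(conservation$n_conserved, conservation$n_lifted,
                       decimals))
  } else absent("conservation")
  data.table::rbindlist(rows)
}
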