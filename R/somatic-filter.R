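#' Separate somatic from germline variants with a panel of normals
#'
#' A variant is classified germline if it is present in any panel normal,
#' where presence means at least `min_alt` supporting reads at a site with at
#' least `min_depth` total reads; everything else is somatic. When a tumour
#' has a matched host normal (`host_map`), subtraction against the matched
#' host is applied first, then the full panel; the two steps are recorded
#' separately in the `reason` column. Variants present in every tumour of the
#' clone and absent from all normals cannot be resolved as somatic or germline
#' from the panel alone (the clone founder is not sampled); they stay in the
#' somatic partition but are flagged `ambiguous` for the clock module.
#'
#' @param calls list with `variants` (frame with `id`), `alt` and `dp`
#'   matrices (variants x samples), as produced by [simulate_cohort()] at
#'   `detail = "reads"`.
#' @param tumour_ids,normal_ids sample id vectors; the panel must be
#'   non-empty and disjoint from the tumours.
#' @param host_map optional named character: `tumour id -> matched normal id`.
#' @param min_alt,min_depth presence thresholds (defaults 2 reads, depth 10).
#' @return list with `classification` (id, status, ambiguous, reason),
#'   `somatic`, `germline`, `ambiguous` id vectors and a `counts` summary.
#' @export
classify_germline <- function(calls,
                              tumour_ids = calls$tumour_ids,
                              normal_ids = calls$normal_ids,
                              host_map = NULL,
                              min_alt = 2, min_depth = 10) {
  stop_if_not(length(normal_ids) > 0,
              "empty normal panel: cannot classify somatic vs germline")
  stop_if_not(length(intersect(tumour_ids, normal_ids)) == 0,
              "normal panel must be disjoint from the tumour sample set")
  present <- calls$alt >= min_alt & calls$dp >= min_depth
  ids <- calls$variants$id

  in_matched <- rep(FALSE, length(ids))
  if (!is.null(host_map)) {
    mn <- intersect(unique(host_map), normal_ids)
    if (length(mn)) in_matched <- rowSums(present[, mn, drop = FALSE]) > 0
  }
  in_panel <- rowSums(present[, normal_ids, drop = FALSE]) > 0
  germ <- in_matched | in_panel
  in_all_tumours <- rowSums(present[, tumour_ids, drop = FALSE]) == length(tumour_ids)
  ambiguous <- !germ & in_all_tumours

  status <- ifelse(germ, "germline", "somatic")
  reason <- ifelse(in_matched, "matched_host",
                   ifelse(in_panel, "panel",
                          ifelse(ambiguous, "clone_shared_ambiguous", "tumour_only")))
  classification <- data.frame(id = ids, status = status,
                               ambiguous = ambiguous, reason = reason,
                               stringsAsFactors = FALSE)
  list(classification = classification,
       somatic = ids[status == "somatic"],
       germline = ids[status == "germline"],
       ambiguous = ids[ambiguous],
       counts = c(somatic = sum(status == "somatic"),
                  germline = sum(status == "germline"),
                  ambiguous = sum(ambiguous)))
}

#' Per-sample heterozygosity per kilobase
#'
#' @param het_sites named numeric vector: heterozygous site count per sample.
#' @param callable_genome callable genome size in bp (> 0).
#' @return list with `per_sample` rates (sites/kb), cohort `median` and
#'   `range`.
#' @export
heterozygosity_per_kb <- function(het_sites, callable_genome) {
  stop_if_not(callable_genome > 0, "callable_genome must be positive")
  rate <- het_sites * 1000 / callable_genome
  list(per_sample = rate, median = median(rate), range = range(rate))
}

#' Count heterozygous germline sites per sample from allele counts
#'
#' A site is heterozygous in a sample if its VAF falls inside `vaf_band` at
#' depth at least `min_depth`.
#'
#' @param calls allele-count list (see [classify_germline()]).
#' @param samples sample ids to count.
#' @param germline_ids ids of germline variants to consider.
#' @param vaf_band inclusive VAF window for a heterozygous call.
#' @param min_depth minimum depth.
#' @return named integer vector of per-sample het site counts.
#' @export
count_het_sites <- function(calls, samples, germline_ids,
                            vaf_band = c(0.3, 0.7), min_depth = 10) {
  idx <- match(germline_ids, calls$variants$id)
  a <- calls$alt[idx, samples, drop = FALSE]
  d <- calls$dp[idx, samples, drop = FALSE]
  vaf <- ifelse(d > 0, a / d, 0)
  colSums(vaf >= vaf_band[1] & vaf <= vaf_band[2] & d >= min_depth)
}

#' Estimate tumour purity from clonal somatic VAFs
#'
#' For clonal heterozygous variants in diploid copy-neutral regions the
#' expected VAF is `purity / 2`, so purity is estimated as twice the median
#' VAF, capped at 1. Samples with fewer than `min_variants` usable variants
#' are flagged and return `NA`.
#'
#' @param vaf numeric vector of VAFs of clonal variants in copy-neutral
#'   diploid regions.
#' @param min_variants minimum number of variants (default 50).
#' @return list with `purity`, `n`, and `flagged`.
#' @export
estimate_purity <- function(vaf, min_variants = 50) {
  vaf <- vaf[!is.na(vaf)]
  if (length(vaf) < min_variants)
    return(list(purity = NA_real_, n = length(vaf), flagged = TRUE))
  list(purity = min(1, 2 * median(vaf)), n = length(vaf), flagged = FALSE)
}
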