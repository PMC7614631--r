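#' Segment binned coverage into integer copy-number segments
#'
#' Recursive least-squares binary segmentation per chromosome: the split
#' maximising the between-segment reduction in squared error is accepted
#' while the reduction exceeds `penalty_factor * sigma^2 * log(n)`, with
#' `sigma^2` estimated robustly from first differences of the bin depths;
#' segments shorter than `min_bins` are never created. Each segment's copy
#' number is the purity-corrected depth ratio rounded to an integer:
#' `CN = (R (purity * ploidy + 2(1-purity)) - 2(1-purity)) / purity`.
#'
#' @param bins data frame `chrom,start,end,depth` (0-based half-open bins,
#'   normalised depth).
#' @param purity sample purity.
#' @param ploidy modal copy number the depth is normalised to.
#' @param min_bins minimum segment length in bins (default 10).
#' @param penalty_factor split-penalty multiplier (default 3).
#' @return data frame of `CNSegment`s: `chrom,start,end,cn,n_bins,mean_depth`,
#'   tiling each chromosome exactly.
#' @export
segment_coverage <- function(bins, purity = 1, ploidy = 2, min_bins = 10,
                             penalty_factor = 3) {
  stop_if_not(all(bins$depth >= 0) && any(bins$depth > 0),
              "coverage is all zero; cannot segment")
  out <- lapply(split(bins, bins$chrom), function(b) {
    b <- b[order(b$start), ]
    x <- b$depth
    n <- length(x)
    sigma2 <- (mad(diff(x)) / sqrt(2))^2
    if (!is.finite(sigma2) || sigma2 == 0) sigma2 <- max(var(x), 1e-8)
    penalty <- penalty_factor * sigma2 * log(n)
    bounds <- segment_recurse(x, 1L, n, min_bins, penalty)
    starts <- c(1L, bounds + 1L)
    ends <- c(bounds, n)
    mean_depth <- vapply(seq_along(starts), function(i)
      mean(x[starts[i]:ends[i]]), 0)
    cn <- pmax(0L, as.integer(round(
      (mean_depth * (purity * ploidy + 2 * (1 - purity)) -
         2 * (1 - purity)) / purity)))
    data.frame(chrom = b$chrom[1], start = b$start[starts],
               end = b$end[ends], cn = cn,
               n_bins = ends - starts + 1L, mean_depth = mean_depth,
               stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, out)
  rownames(d) <- NULL
  d
}

## returns sorted interior breakpoints (last bin index of left parts)
segment_recurse <- function(x, lo, hi, min_bins, penalty) {
  n <- hi - lo + 1L
  if (n < 2L * min_bins) return(integer())
  seg <- x[lo:hi]
  cs <- cumsum(seg); css <- cumsum(seg^2)
  total_sse <- css[n] - cs[n]^2 / n
  k <- min_bins:(n - min_bins)
  sse_l <- css[k] - cs[k]^2 / k
  sse_r <- (css[n] - css[k]) - (cs[n] - cs[k])^2 / (n - k)
  gain <- total_sse - (sse_l + sse_r)
  best <- which.max(gain)
  if (gain[best] <= penalty) return(integer())
  cut <- lo + k[best] - 1L
  c(segment_recurse(x, lo, cut, min_bins, penalty), cut,
    segment_recurse(x, cut + 1L, hi, min_bins, penalty))
}

#' Screen genes for copy-number deletions
#'
#' Reports genes whose CDS overlaps a segment with copy number below the
#' sample's modal CN, distinguishing focal (< `focal_max` bp) from arm-scale
#' losses and flagging homozygous deletions (CN 0) distinctly. Used, e.g., to
#' screen mismatch-repair effectors for the lesion behind a hypermutator.
#'
#' @param segments per-sample segment frame from [segment_coverage()].
#' @param annotation gene frame `gene_id,chrom,start,end`.
#' @param gene_list optional subset of gene ids to screen.
#' @param focal_max focal/arm-scale size boundary in bp (default 10 Mb;
#'   scale alongside the simulated genome).
#' @return data frame `gene_id,chrom,cn,segment_size,focal,homozygous`.
#' @export
gene_deletion_screen <- function(segments, annotation, gene_list = NULL,
                                 focal_max = 1e7) {
  genes <- if (is.null(gene_list)) annotation
           else annotation[annotation$gene_id %in% gene_list, ]
  modal <- modal_cn(segments)
  hits <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    seg <- segments[segments$chrom == g$chrom &
                      segments$start < g$end & segments$end > g$start, ]
    seg <- seg[seg$cn < modal, , drop = FALSE]
    if (!nrow(seg)) return(NULL)
    j <- which.min(seg$cn)
    data.frame(gene_id = g$gene_id, chrom = g$chrom, cn = seg$cn[j],
               segment_size = seg$end[j] - seg$start[j],
               focal = (seg$end[j] - seg$start[j]) < focal_max,
               homozygous = seg$cn[j] == 0L, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, hits)
  if (is.null(out)) data.frame(gene_id = character(), chrom = character(),
                               cn = integer(), segment_size = integer(),
                               focal = logical(), homozygous = logical())
  else out
}

## base-pair weighted modal copy number
modal_cn <- function(segments) {
  w <- tapply(segments$end - segments$start, segments$cn, sum)
  as.integer(names(w)[which.max(w)])
}

#' Call whole-genome duplication from segments and allele fractions
#'
#' A sample is flagged tetraploid when its base-pair-weighted modal copy
#' number is 4 and the clonal VAF distribution in CN = 4 regions is bimodal
#' at the multiplicity-1 and multiplicity-2 positions
#' `m * purity / (4 purity + 2 (1 - purity))`, with both multiplicity
#' clusters holding at least `min_cluster_frac` of the variants.
#'
#' @param segments segment frame from [segment_coverage()].
#' @param vaf clonal somatic VAFs lying in CN = 4 regions.
#' @param purity sample purity.
#' @param min_variants minimum usable variants (default 200).
#' @param min_cluster_frac minimum occupancy of each multiplicity cluster.
#' @return a `ploidy_call` list: `modal_cn`, `tetraploid`, cluster modes and
#'   occupancies, `pre_count` (multiplicity 2) and `post_count`
#'   (multiplicity 1).
#' @export
call_wgd <- function(segments, vaf, purity = 1, min_variants = 200,
                     min_cluster_frac = 0.1) {
  modal <- modal_cn(segments)
  denom <- 4 * purity + 2 * (1 - purity)
  modes <- c(m1 = purity / denom, m2 = 2 * purity / denom)
  res <- list(modal_cn = modal, tetraploid = FALSE, modes = modes,
              occupancy = c(m1 = NA_real_, m2 = NA_real_),
              pre_count = NA_real_, post_count = NA_real_,
              n = length(vaf))
  if (modal != 4L || length(vaf) < min_variants) {
    class(res) <- "ploidy_call"
    return(res)
  }
  assign <- ifelse(abs(vaf - modes["m1"]) <= abs(vaf - modes["m2"]), 1L, 2L)
  occ <- c(mean(assign == 1L), mean(assign == 2L))
  res$occupancy <- setNames(occ, c("m1", "m2"))
  res$tetraploid <- all(occ >= min_cluster_frac)
  res$pre_count <- sum(assign == 2L)
  res$post_count <- sum(assign == 1L)
  class(res) <- "ploidy_call"
  res
}

#' @export
print.ploidy_call <- function(x, ...) {
  cat("<ploidy_call> modal CN", x$modal_cn,
      if (x$tetraploid) "- tetraploid" else "- not tetraploid", "\n")
  if (x$tetraploid)
    cat(sprintf("  multiplicity clusters at VAF %.3f/%.3f (occupancy %.2f/%.2f)\n",
                x$modes[1], x$modes[2], x$occupancy[1], x$occupancy[2]))
  invisible(x)
}

#' Date a whole-genome duplication from mutation multiplicity
#'
#' Mutations acquired before a WGD are doubled with the genome (multiplicity
#' 2); those after stay at multiplicity 1. The elapsed time since duplication
#' is `post_count / (kappa * r)`, where `r` is the clone's substitution rate
#' and `kappa` (default 2) scales post-duplication accrual with DNA content.
#' The interval combines exact Poisson uncertainty on `post_count` with the
#' rate's confidence interval.
#'
#' @param pre_count,post_count genome-wide-equivalent substitution counts at
#'   multiplicity 2 and 1.
#' @param rate clock rate: a single number, or `c(est, lo, hi)`.
#' @param sampling_date decimal year the tumour was sampled.
#' @param kappa post-WGD rate scaling (1 = per-genome rate unchanged).
#' @param lineage_total optional total lineage substitution expectation; a
#'   `post_count` above it triggers a warning.
#' @return list `date`, `lo`, `hi`, `elapsed`.
#' @export
date_wgd <- function(pre_count, post_count, rate, sampling_date, kappa = 2,
                     lineage_total = NULL) {
  stop_if_not(rate[1] > 0, "clock rate must be positive")
  if (!is.null(lineage_total) && post_count > lineage_total)
    warning("post-duplication count exceeds the lineage's total expectation")
  r_lo <- if (length(rate) >= 3) rate[2] else rate[1]
  r_hi <- if (length(rate) >= 3) rate[3] else rate[1]
  elapsed <- post_count / (kappa * rate[1])
  p_lo <- if (post_count > 0) qgamma(0.025, post_count) else 0
  p_hi <- qgamma(0.975, post_count + 1)
  list(date = sampling_date - elapsed,
       lo = sampling_date - p_hi / (kappa * r_lo),
       hi = sampling_date - p_lo / (kappa * r_hi),
       elapsed = unname(elapsed))
}

#' Detect somatic loss of chromosome Y
#'
#' For a male-founder clone, chromosome Y scales with the genome (one copy of
#' a diploid genome, two of a tetraploid), so the expected chrY/autosome
#' depth ratio with Y present is
#' \deqn{(purity \cdot ploidy/2 + (1-purity) \cdot hostY) /
#'       (purity \cdot ploidy + 2 (1-purity)),}
#' which at diploidy reduces to
#' `0.5 purity + 0.5 (1 - purity) host_male_fraction`. LoY is called when the
#' observed ratio falls below half the expectation.
#'
#' @param chry_bins,auto_bins coverage bin frames for chrY and the autosomes.
#' @param purity sample purity.
#' @param ploidy sample modal copy number.
#' @param founder_sex clone founder sex; a female founder carries no Y and
#'   the operation refuses.
#' @param host_male_fraction fraction of contaminating host cells carrying Y.
#' @return list `loy`, `observed_ratio`, `expected_ratio`.
#' @export
detect_loy <- function(chry_bins, auto_bins, purity = 1, ploidy = 2,
                       founder_sex = "male", host_male_fraction = 0) {
  if (founder_sex != "male")
    stop("founder is not male: no chromosome Y baseline exists for this clone",
         call. = FALSE)
  obs <- mean(chry_bins$depth) / mean(auto_bins$depth)
  expc <- (purity * ploidy / 2 + (1 - purity) * host_male_fraction) /
    (purity * ploidy + 2 * (1 - purity))
  list(loy = obs < 0.5 * expc, observed_ratio = obs, expected_ratio = expc)
}

#' Cohort CNV recurrence map
#'
#' Deviations from each sample's modal copy number are matched across samples
#' when their boundaries agree within `tol` bp and their direction (gain or
#' loss) matches; each matched CNV is deduplicated to its parsimony origins
#' on the phylogeny, so a mitotically inherited CNV counts once per
#' independent origin. Returns per-event origin counts, per-locus gain/loss
#' depth tracks, and CNV groups with identical carrier sets (candidate linked
#' CNVs).
#'
#' @param segments_by_sample named list (by tip label) of segment frames.
#' @param phy a `clone_tree` over the same tips.
#' @param tol boundary agreement tolerance in bp (default one 1-kb bin).
#' @return list `events` (one row per unique CNV: locus, direction, carriers,
#'   origins), `gain_track`/`loss_track` (per-interval depth), and `linked`
#'   (groups sharing carrier sets).
#' @export
recurrence_map <- function(segments_by_sample, phy, tol = 1000) {
  evs <- lapply(names(segments_by_sample), function(sm) {
    seg <- segments_by_sample[[sm]]
    modal <- modal_cn(seg)
    dev <- seg[seg$cn != modal, , drop = FALSE]
    if (!nrow(dev)) return(NULL)
    data.frame(sample = sm, chrom = dev$chrom, start = dev$start,
               end = dev$end,
               direction = ifelse(dev$cn > modal, "gain", "loss"),
               stringsAsFactors = FALSE)
  })
  evs <- do.call(rbind, evs)
  if (is.null(evs) || !nrow(evs))
    return(list(events = data.frame(), gain_track = data.frame(),
                loss_track = data.frame(), linked = list()))
  ## greedy matching into groups with agreeing boundaries and direction
  evs$group <- NA_integer_
  g <- 0L
  for (i in seq_len(nrow(evs))) {
    if (!is.na(evs$group[i])) next
    g <- g + 1L
    same <- which(is.na(evs$group) & evs$chrom == evs$chrom[i] &
                    evs$direction == evs$direction[i] &
                    abs(evs$start - evs$start[i]) <= tol &
                    abs(evs$end - evs$end[i]) <= tol)
    evs$group[same] <- g
  }
  groups <- split(evs, evs$group)
  events <- do.call(rbind, lapply(groups, function(gd) {
    carriers <- unique(gd$sample)
    origins <- map_event_to_tree(phy, carriers,
                                 if (gd$direction[1] == "gain") "gain" else "loss")
    data.frame(chrom = gd$chrom[1],
               start = as.integer(round(mean(gd$start))),
               end = as.integer(round(mean(gd$end))),
               direction = gd$direction[1],
               carriers = paste(sort(carriers), collapse = ","),
               n_carriers = length(carriers),
               n_origins = length(origins),
               stringsAsFactors = FALSE)
  }))
  rownames(events) <- NULL
  track <- function(dir) {
    ed <- events[events$direction == dir, , drop = FALSE]
    if (!nrow(ed)) return(data.frame())
    out <- lapply(split(ed, ed$chrom), function(cd) {
      bp <- sort(unique(c(cd$start, cd$end)))
      iv <- data.frame(chrom = cd$chrom[1], start = bp[-length(bp)],
                       end = bp[-1])
      iv$depth <- vapply(seq_len(nrow(iv)), function(i)
        sum(cd$n_origins[cd$start <= iv$start[i] & cd$end >= iv$end[i]]), 0)
      iv[iv$depth > 0, , drop = FALSE]
    })
    d <- do.call(rbind, out); rownames(d) <- NULL; d
  }
  linked <- split(seq_len(nrow(events)), events$carriers)
  linked <- unname(Filter(function(ix)
    length(ix) > 1 && events$n_carriers[ix[1]] >= 2, linked))
  list(events = events, gain_track = track("gain"), loss_track = track("loss"),
       linked = linked)
}

#' Arm-scale event enrichment in tetraploid tumours
#'
#' Two-sided Fisher exact test of the 2x2 table ploidy class (tetraploid vs
#' diploid) by presence of at least one whole-chromosome or arm-scale gain or
#' loss.
#'
#' @param tetraploid logical per sample.
#' @param has_arm_event logical per sample.
#' @return list `table`, `p`, `odds_ratio`.
#' @export
arm_event_enrichment <- function(tetraploid, has_arm_event) {
  stop_if_not(length(unique(tetraploid)) == 2,
              "need both ploidy classes represented")
  tab <- table(ploidy = factor(tetraploid, c(FALSE, TRUE),
                               c("diploid", "tetraploid")),
               arm_event = factor(has_arm_event, c(FALSE, TRUE),
                                  c("none", "event")))
  ft <- fisher.test(tab)
  list(table = tab, p = ft$p.value, odds_ratio = unname(ft$estimate))
}

#' Merge clustered rearrangement breakpoints into events
#'
#' Breakpoints of a sample within `gap` bp of each other (per chromosome) are
#' merged into a single rearrangement event before rate regression.
#'
#' @param calls frame with `chrom1,pos1,chrom2,pos2` breakpoint pairs.
#' @param gap merge distance (default 10 kb).
#' @return number of merged events.
#' @export
merge_rearrangements <- function(calls, gap = 10000) {
  if (is.null(calls) || !nrow(calls)) return(0L)
  bp <- rbind(data.frame(chrom = calls$chrom1, pos = calls$pos1),
              data.frame(chrom = calls$chrom2, pos = calls$pos2))
  clusters <- sum(vapply(split(bp$pos, bp$chrom), function(p) {
    p <- sort(p)
    1L + sum(diff(p) > gap)
  }, 0L))
  ## two breakpoints define one event; clustered breakpoints merge
  max(1L, as.integer(ceiling(clusters / 2)))
}
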