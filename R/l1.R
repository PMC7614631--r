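#' Attribute LINE-1 insertions to source elements via 3' transductions
#'
#' An insertion carrying a transduced segment is attributed to the annotated
#' full-length element whose 3' end lies within `window_bp` upstream of the
#' transduced sequence on the matching strand (for a plus-strand element the
#' transduction starts downstream of its end; mirrored for minus strand).
#' When several elements qualify, the nearest is chosen and the tie flagged;
#' transductions matching no element are orphans.
#'
#' @param insertions frame with `id` and transduction columns
#'   `td_chrom,td_start,td_end,td_strand` (`NA` when absent).
#' @param l1_annotation frame `element_id,chrom,start,end,strand`.
#' @param window_bp attribution window (default 10,000).
#' @return list `attribution` (per transduction-bearing insertion: source or
#'   orphan, distance, tie flag) and `activity` (per-source tallies).
#' @export
attribute_sources <- function(insertions, l1_annotation, window_bp = 10000) {
  td <- insertions[!is.na(insertions$td_chrom), , drop = FALSE]
  rows <- lapply(seq_len(nrow(td)), function(i) {
    x <- td[i, ]
    el <- l1_annotation[l1_annotation$chrom == x$td_chrom, , drop = FALSE]
    dist <- ifelse(el$strand == "+", x$td_start - el$end, el$start - x$td_end)
    ok <- which(dist >= 0 & dist <= window_bp &
                  (is.na(x$td_strand) | el$strand == x$td_strand))
    if (!length(ok))
      return(data.frame(id = x$id, source_id = NA_character_,
                        distance = NA_real_, tie = FALSE,
                        stringsAsFactors = FALSE))
    j <- ok[which.min(dist[ok])]
    data.frame(id = x$id, source_id = el$element_id[j],
               distance = dist[j], tie = length(ok) > 1,
               stringsAsFactors = FALSE)
  })
  attribution <- do.call(rbind, rows) %||%
    data.frame(id = character(), source_id = character(),
               distance = numeric(), tie = logical())
  tallies <- table(attribution$source_id[!is.na(attribution$source_id)])
  activity <- data.frame(source_id = names(tallies),
                         n_transductions = as.integer(tallies),
                         stringsAsFactors = FALSE)
  activity <- activity[order(-activity$n_transductions), , drop = FALSE]
  rownames(activity) <- NULL
  list(attribution = attribution, activity = activity,
       n_orphan = sum(is.na(attribution$source_id)))
}

#' Per-branch activity of LINE-1 source elements
#'
#' Each attributed insertion is placed on its parsimony branch (gain
#' polarity) from its carrier tips; counts are tabulated per source and
#' branch, and each source's tree depths of activity are summarised.
#'
#' @param attribution frame `id,source_id` from [attribute_sources()].
#' @param carriers named list: insertion id -> carrier tip labels.
#' @param phy a `clone_tree`.
#' @return list `by_branch` (source x branch counts) and `depth_summary`
#'   (per source: branches and distinct tree depths with activity).
#' @export
source_activity_by_node <- function(attribution, carriers, phy) {
  att <- attribution[!is.na(attribution$source_id), , drop = FALSE]
  depth <- node_depths(phy)
  rows <- lapply(seq_len(nrow(att)), function(i) {
    br <- map_event_to_tree(phy, carriers[[att$id[i]]], "gain")
    data.frame(id = att$id[i], source_id = att$source_id[i], branch = br,
               depth = depth[br], stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, rows) %||%
    data.frame(id = character(), source_id = character(), branch = integer(),
               depth = integer())
  by_branch <- if (nrow(d)) as.data.frame(table(source = d$source_id,
                                                branch = d$branch),
                                          stringsAsFactors = FALSE) else
    data.frame()
  if (nrow(by_branch)) by_branch <- by_branch[by_branch$Freq > 0, ]
  depth_summary <- if (nrow(d))
    aggregate(depth ~ source_id, d, function(z) length(unique(z))) else
    data.frame()
  if (nrow(depth_summary)) names(depth_summary)[2] <- "n_depths"
  list(by_branch = by_branch, depth_summary = depth_summary, placements = d)
}

node_depths <- function(phy) {
  n_node <- length(phy$parent)
  depth <- integer(n_node)
  for (v in rev(tree_postorder(phy))) {
    p <- phy$parent[v]
    depth[v] <- if (p == 0L) 0L else depth[p] + 1L
  }
  depth
}

#' LINE-1 insertion accumulation rate
#'
#' Convenience wrapper around [burden_regression()] for per-tumour insertion
#' burdens against sampling dates.
#'
#' @inheritParams burden_regression
#' @return a `rate_fit`.
#' @export
insertion_rate <- function(burden, dates) burden_regression(burden, dates)
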