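#' Binary mutation presence matrix from allele counts
#'
#' Clonal presence of a variant in a sample is called when its VAF reaches
#' `clonal_threshold` on the purity-adjusted scale (a clonal heterozygous
#' variant sits at `purity/2`). Variants present in no sample are dropped.
#'
#' @param calls allele-count list (`variants`, `alt`, `dp`).
#' @param sample_ids samples to include (default: tumours).
#' @param variant_ids variants to include (default: all in `calls`).
#' @param purity named per-sample purity (default 1).
#' @param clonal_threshold VAF threshold at purity 1 (default 0.2).
#' @return logical samples x variants matrix.
#' @export
build_mutation_matrix <- function(calls, sample_ids = calls$tumour_ids,
                                  variant_ids = NULL, purity = NULL,
                                  clonal_threshold = 0.2) {
  idx <- if (is.null(variant_ids)) seq_len(nrow(calls$variants))
         else match(variant_ids, calls$variants$id)
  a <- calls$alt[idx, sample_ids, drop = FALSE]
  d <- calls$dp[idx, sample_ids, drop = FALSE]
  vaf <- ifelse(d > 0, a / d, 0)
  pu <- if (is.null(purity)) rep(1, length(sample_ids))
        else purity[sample_ids]
  pres <- t(vaf) >= clonal_threshold * pu  # samples x variants
  rownames(pres) <- sample_ids
  colnames(pres) <- calls$variants$id[idx]
  pres[, colSums(pres) > 0, drop = FALSE]
}

#' Truth-level mutation matrix of a simulated cohort
#'
#' Presence by clade membership of each variant's branch; no read noise.
#'
#' @param cohort a [simulate_cohort()] result with variant records.
#' @param class mutation class to include.
#' @return logical samples x variants matrix.
#' @export
truth_mutation_matrix <- function(cohort, class = "substitution") {
  v <- cohort$variants[cohort$variants$class %in% class, ]
  clades <- tree_clades(cohort$tree)
  m <- matrix(FALSE, cohort$tree$n_tip, nrow(v),
              dimnames = list(cohort$tree$tip_label, v$id))
  for (b in unique(v$branch)) m[clades[[b]], v$branch == b] <- TRUE
  m
}

#' Build a clone phylogeny by greedy perfect-phylogeny construction
#'
#' Variants are processed in decreasing order of sharing count (ties broken
#' by input order, i.e. genomic order); a variant's carrier set is accepted if
#' it is nested within or disjoint from every previously accepted set, and
#' parked as conflicting otherwise. Accepted sets form a laminar family which
#' is the clone tree; each branch's mutation count is the number of variants
#' mapping to it. Parked variants are afterwards assigned to the branch whose
#' clade minimises the symmetric difference with their carrier set. Variants
#' present in every sample map to the trunk above the most recent common
#' ancestor and are reported separately. Valid for clonal somatic variants
#' under infinite sites, where conflicts arise only from genotyping noise.
#'
#' @param m logical samples x variants presence matrix.
#' @param dates optional named sampling dates for the tips.
#' @param conflict_warn warn if the conflicting fraction exceeds this
#'   (default 0.2: the clonal threshold is probably wrong).
#' @return a `clone_phylogeny` (also a `clone_tree`): topology, per-branch
#'   mutation counts `branch_count`, per-branch variant ids
#'   `branch_variants`, `trunk_ids`, `parked` ids, `conflict_fraction`.
#' @export
build_tree <- function(m, dates = NULL, conflict_warn = 0.2) {
  n <- nrow(m)
  stop_if_not(n >= 3, "need at least 3 samples to build a tree")
  samples <- rownames(m) %||% paste0("S", seq_len(n))
  cnt <- colSums(m)
  keys <- apply(m, 2, function(x) paste(which(x), collapse = ","))
  ord <- order(-cnt, seq_along(cnt))

  full_key <- paste(seq_len(n), collapse = ",")
  accepted <- list()
  acc_key <- character(0)
  parked_patterns <- character(0)
  pattern_status <- new.env(parent = emptyenv())
  for (j in ord) {
    k <- keys[j]
    if (k == full_key) { assign(k, "trunk", pattern_status); next }
    st <- pattern_status[[k]]
    if (!is.null(st)) next
    s <- as.integer(strsplit(k, ",", fixed = TRUE)[[1]])
    ok <- TRUE
    for (a in accepted) {
      i <- length(intersect(s, a))
      if (i != 0 && i != length(s) && i != length(a)) { ok <- FALSE; break }
    }
    if (ok) {
      accepted[[length(accepted) + 1L]] <- s
      acc_key <- c(acc_key, k)
      assign(k, "accepted", pattern_status)
    } else assign(k, "parked", pattern_status)
  }

  ## laminar family -> tree: add root clade and missing singletons
  sets <- accepted
  skeys <- acc_key
  if (!(full_key %in% skeys)) { sets <- c(sets, list(seq_len(n))); skeys <- c(skeys, full_key) }
  for (i in seq_len(n)) {
    k <- as.character(i)
    if (!(k %in% skeys)) { sets <- c(sets, list(i)); skeys <- c(skeys, k) }
  }
  sizes <- lengths(sets)
  ## node ids: tips first (by sample index), root, then internals by size desc
  is_single <- sizes == 1L
  tip_node <- integer(n)
  tip_node[vapply(sets[is_single], `[`, 1L, i = 1L)] <- 0L  # placeholder
  node_of_set <- integer(length(sets))
  node_of_set[is_single] <- unlist(sets[is_single])
  internal_sets <- which(!is_single)
  internal_sets <- internal_sets[order(-sizes[internal_sets])]
  node_of_set[internal_sets] <- n + seq_along(internal_sets)
  n_node <- n + length(internal_sets)
  parent <- integer(n_node)
  for (si in seq_along(sets)) {
    v <- node_of_set[si]
    s <- sets[[si]]
    if (length(s) == n) { parent[v] <- 0L; next }
    ## smallest strict superset
    best <- NULL; best_size <- Inf
    for (sj in seq_along(sets)) {
      if (sj == si) next
      a <- sets[[sj]]
      if (length(a) > length(s) && all(s %in% a) && length(a) < best_size) {
        best <- sj; best_size <- length(a)
      }
    }
    parent[v] <- node_of_set[[best]]
  }

  date <- rep(NA_real_, n_node)
  if (!is.null(dates)) date[seq_len(n)] <- dates[samples]
  phy <- new_clone_tree(parent, date, samples)
  clades <- tree_clades(phy)

  node_key <- vapply(clades, function(x) paste(x, collapse = ","), "")
  branch_variants <- vector("list", n_node)
  branch_count <- integer(n_node)
  parked <- character(0); trunk <- character(0)
  for (j in seq_along(keys)) {
    st <- pattern_status[[keys[j]]]
    if (identical(st, "trunk")) { trunk <- c(trunk, colnames(m)[j]); next }
    if (identical(st, "accepted")) {
      v <- match(keys[j], node_key)
      branch_variants[[v]] <- c(branch_variants[[v]], colnames(m)[j])
      branch_count[v] <- branch_count[v] + 1L
    } else parked <- c(parked, colnames(m)[j])
  }
  ## parsimony assignment of parked variants: min symmetric difference
  if (length(parked)) {
    for (id in parked) {
      s <- which(m[, id])
      dsym <- vapply(clades, function(cl)
        length(setdiff(cl, s)) + length(setdiff(s, cl)), 0L)
      dsym[n + 1L] <- .Machine$integer.max  # never the trunk
      v <- which.min(dsym)
      branch_variants[[v]] <- c(branch_variants[[v]], id)
      branch_count[v] <- branch_count[v] + 1L
    }
  }
  conflict_fraction <- length(parked) / max(1L, ncol(m))
  if (conflict_fraction > conflict_warn)
    warning(sprintf(paste("%.1f%% of variants conflict with the tree;",
                          "the clonal threshold is probably wrong"),
                    100 * conflict_fraction))
  phy$branch_count <- branch_count
  phy$branch_variants <- branch_variants
  phy$trunk_ids <- trunk
  phy$parked <- parked
  phy$conflict_fraction <- conflict_fraction
  class(phy) <- c("clone_phylogeny", "clone_tree")
  phy
}

#' @export
print.clone_phylogeny <- function(x, ...) {
  cat("<clone_phylogeny>", x$n_tip, "tips,",
      sum(x$branch_count), "mapped variants,",
      length(x$trunk_ids), "trunk,",
      length(x$parked), sprintf("conflicting (%.1f%%)\n", 100 * x$conflict_fraction))
  invisible(x)
}

#' Map a gain or loss event onto a phylogeny by irreversible parsimony
#'
#' Finds the minimum number of independent origins explaining the carrier
#' tips under irreversible (Camin-Sokal) parsimony: the origins are the
#' maximal clades entirely contained in the carrier set. A carrier set that
#' is not a union of clades simply yields multiple origins.
#'
#' @param phy a `clone_tree`/`clone_phylogeny`.
#' @param carriers tip labels (or indices) carrying the event.
#' @param polarity `"gain"` or `"loss"` (semantic label; the optimisation is
#'   identical for an irreversible character).
#' @return integer vector of originating nodes (each denotes the branch above
#'   it); `length()` of it is the origin count.
#' @export
map_event_to_tree <- function(phy, carriers, polarity = c("gain", "loss")) {
  polarity <- match.arg(polarity)
  if (is.character(carriers)) carriers <- match(carriers, phy$tip_label)
  stop_if_not(length(carriers) > 0 && !anyNA(carriers),
              "carrier set empty or contains unknown tips")
  clades <- tree_clades(phy)
  inside <- vapply(clades, function(cl) all(cl %in% carriers), TRUE)
  root <- phy$n_tip + 1L
  origins <- which(inside & (phy$parent == 0L | !inside[pmax(phy$parent, 1L)]))
  ## keep only origins covering carriers (they always do: tips are clades)
  sort(origins)
}

#' Detect polytomies from a dated phylogeny
#'
#' Internal branches whose (posterior mean) duration is shorter than
#' `epsilon_years` are collapsed into their parent; surviving nodes with
#' three or more children are reported as true- or near-polytomies, candidate
#' signatures of one donor transmitting to several recipients.
#'
#' @param tree a dated `clone_tree`, or a `clock_fit` (its posterior-median
#'   dated tree is used).
#' @param epsilon_years collapse threshold (default 0.25 years); `0` never
#'   collapses.
#' @return data frame `node,out_degree,date` of multifurcations (>= 3).
#' @export
detect_polytomies <- function(tree, epsilon_years = 0.25) {
  if (inherits(tree, "clock_fit")) tree <- tree$dated_tree
  n_node <- length(tree$parent)
  root <- tree$n_tip + 1L
  ## map each node to its surviving ancestor after collapsing short internal edges
  surv <- seq_len(n_node)
  ord <- rev(tree_postorder(tree))  # preorder: parents first
  for (v in ord) {
    p <- tree$parent[v]
    if (v <= tree$n_tip || p == 0L) next
    dur <- tree$date[v] - tree$date[p]
    if (!is.na(dur) && dur < epsilon_years) surv[v] <- surv[p]
  }
  survives <- surv == seq_len(n_node)
  child_nodes <- which(survives & seq_len(n_node) != root)
  kids <- table(surv[tree$parent[child_nodes]])
  out <- data.frame(node = as.integer(names(kids)),
                    out_degree = as.integer(kids))
  out <- out[out$out_degree >= 3L, , drop = FALSE]
  out$date <- tree$date[out$node]
  out[order(out$node), , drop = FALSE]
}
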