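## ---- clone_tree: rooted, dated clone genealogy -----------------------------
## Nodes are integers; 1..n_tip are tips, internals follow, root = n_tip + 1.
## parent[i] gives the parent node (0 at the root); date[i] the node's decimal
## year. Every non-root node defines the edge above it.

new_clone_tree <- function(parent, date, tip_label, ...) {
  structure(c(list(parent = as.integer(parent), date = as.numeric(date),
                   tip_label = tip_label, n_tip = length(tip_label)),
              list(...)),
            class = "clone_tree")
}

#' @export
print.clone_tree <- function(x, ...) {
  cat("<clone_tree>", x$n_tip, "tips,", length(x$parent) - x$n_tip,
      "internal nodes; root date", round(x$date[x$n_tip + 1L], 2),
      "; tips", round(min(x$date[seq_len(x$n_tip)]), 2), "-",
      round(max(x$date[seq_len(x$n_tip)]), 2), "\n")
  invisible(x)
}

tree_children <- function(tree) {
  n <- length(tree$parent)
  ch <- vector("list", n)
  for (v in seq_len(n)) if (tree$parent[v] > 0L)
    ch[[tree$parent[v]]] <- c(ch[[tree$parent[v]]], v)
  ch
}

## tip indices under each node (list over all nodes)
tree_clades <- function(tree) {
  n <- length(tree$parent)
  ch <- tree_children(tree)
  clade <- vector("list", n)
  ord <- tree_postorder(tree)
  for (v in ord) {
    clade[[v]] <- if (v <= tree$n_tip) v else
      sort(unlist(clade[ch[[v]]], use.names = FALSE))
  }
  clade
}

tree_postorder <- function(tree) {
  n <- length(tree$parent)
  root <- tree$n_tip + 1L
  ch <- tree_children(tree)
  out <- integer(0); stack <- root
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    out <- c(out, v)
    if (length(out) > n) stop("malformed tree: parent pointers contain a cycle")
    stack <- c(stack, ch[[v]])
  }
  rev(out)
}

## edge table: one row per non-root node (edge above it)
tree_edges <- function(tree) {
  v <- which(tree$parent > 0L)
  data.frame(node = v, parent = tree$parent[v],
             duration = tree$date[v] - tree$date[tree$parent[v]])
}

#' Convert a clone tree to an ape phylogeny
#'
#' Branch lengths are either branch durations in years or, for built
#' phylogenies carrying them, per-branch mutation counts.
#'
#' @param x a `clone_tree` or `clone_phylogeny`.
#' @param branch_units `"years"` or `"mutations"`.
#' @return an [ape::read.tree()]-compatible `phylo` object.
#' @export
as_phylo <- function(x, branch_units = c("years", "mutations")) {
  branch_units <- match.arg(branch_units)
  v <- which(x$parent > 0L)
  edge <- cbind(x$parent[v], v)
  len <- if (branch_units == "years") x$date[v] - x$date[x$parent[v]]
         else {
           stop_if_not(!is.null(x$branch_count),
                       "tree carries no branch mutation counts")
           x$branch_count[v]
         }
  phy <- list(edge = edge, tip.label = x$tip_label,
              Nnode = length(x$parent) - x$n_tip,
              edge.length = as.numeric(len))
  class(phy) <- "phylo"
  ape::reorder.phylo(phy, "cladewise")
}

#' Simulate a dated transmission tree
#'
#' Generates a rooted, dated clone genealogy: the root sits at the configured
#' origin year, tumour sampling dates are drawn uniformly over the sampling
#' window (the sampling design is configurable, not inferred), the topology is
#' a random coalescent of the sampled tumours, and internal node dates are
#' drawn uniformly between the parent date and the earliest descendant tip.
#' With `multifurcation_prob > 0`, internal nodes are collapsed into their
#' parents to produce polytomies, emulating single donors seeding several
#' recipient tumours.
#'
#' @param config a [cohort_config()].
#' @param seed optional seed (defaults to `config$seed`).
#' @return a `clone_tree` with `n_tumours` dated tips labelled
#'   `<clone>_T1, ...`.
#' @export
simulate_transmission_tree <- function(config, seed = config$seed) {
  with_seed(seed, {
    n <- config$n_tumours
    tip_dates <- sort(runif(n, config$sampling_window[1], config$sampling_window[2]))
    ## random coalescent joins over temporary ids
    members <- as.list(seq_len(n))
    parent_tmp <- integer(2L * n - 1L)
    next_id <- n
    active <- seq_len(n)
    while (length(active) > 1L) {
      pick <- sample.int(length(active), 2L)
      next_id <- next_id + 1L
      parent_tmp[active[pick]] <- next_id
      active <- c(active[-pick], next_id)
    }
    root_tmp <- active
    ## optionally collapse internal non-root nodes into their parents
    if (config$multifurcation_prob > 0) {
      for (v in setdiff((n + 1L):(2L * n - 1L), root_tmp)) {
        if (runif(1) < config$multifurcation_prob) {
          kids <- which(parent_tmp == v)
          parent_tmp[kids] <- parent_tmp[v]
          parent_tmp[v] <- -1L  # dropped
        }
      }
    }
    ## relabel: tips keep ids, root becomes n+1, other internals follow in
    ## preorder so parents precede children
    relabel <- integer(2L * n - 1L)
    relabel[seq_len(n)] <- seq_len(n)
    ch_tmp <- split(which(parent_tmp > 0L), parent_tmp[parent_tmp > 0L])
    pre <- integer(0); stack <- root_tmp
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (v > n) pre <- c(pre, v)
      stack <- c(stack, ch_tmp[[as.character(v)]] %||% integer())
    }
    relabel[pre] <- n + seq_along(pre)
    n_node <- n + length(pre)
    parent <- integer(n_node)
    for (v in c(seq_len(n), pre)) {
      p <- parent_tmp[v]
      parent[relabel[v]] <- if (v == root_tmp) 0L else relabel[p]
    }
    ## dates: root = origin; internals uniform(parent, min descendant tip)
    date <- numeric(n_node)
    date[seq_len(n)] <- sample(tip_dates)  # random assignment to topology
    tree <- new_clone_tree(parent, date, paste0(config$clone_label, "_T", seq_len(n)))
    clades <- tree_clades(tree)
    date[n + 1L] <- config$origin_year
    if (n_node > n + 1L) for (v in (n + 2L):n_node) {
      ub <- min(date[clades[[v]]])
      date[v] <- runif(1, date[parent[v]], ub)
    }
    tree$date <- date
    tree
  })
}
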