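path_to_root <- function(tree, tip) {
  out <- integer(0); v <- tip
  while (v > 0L) { out <- c(out, v); v <- tree$parent[v] }
  out
}

#' Simulate a complete synthetic transmissible-cancer cohort
#'
#' End-to-end generator: transmission tree, per-branch mutations, tumour
#' metadata (purity, ploidy, host), germline variation for the founder and a
#' panel of normal devils, and (at `detail = "reads"`) per-sample allele count
#' tables for every somatic and germline variant in every tumour and normal.
#' A truth table accompanies the cohort.
#'
#' @param config a [cohort_config()].
#' @param detail `"counts"` (per-branch counts and burdens only),
#'   `"variants"` (adds per-variant records and carrier information), or
#'   `"reads"` (adds per-sample allele depth tables and germline genotypes).
#' @param n_normals size of the normal panel.
#' @param genome optionally reuse a previously simulated genome.
#' @param seed seed (defaults to `config$seed`).
#' @return an object of class `cohort`.
#' @export
simulate_cohort <- function(config, detail = c("variants", "counts", "reads"),
                            n_normals = 20, genome = NULL,
                            seed = config$seed) {
  detail <- match.arg(detail)
  with_seed(seed, {
    if (is.null(genome))
      genome <- simulate_genome(config, with_sequence = (detail == "reads"))
    tree <- simulate_transmission_tree(config, seed = NULL)
    sim <- simulate_mutations(tree, config, genome,
                              detail = if (detail == "counts") "counts" else "variants")
    n <- tree$n_tip
    wgd_tips <- lapply(sim$truth$wgd, `[[`, "tips")
    tip_wgd <- rep(NA_real_, n)
    for (j in seq_along(wgd_tips)) tip_wgd[wgd_tips[[j]]] <- sim$truth$wgd[[j]]$year
    meta <- data.frame(
      sample_id = tree$tip_label,
      clone = config$clone_label,
      sampling_date = tree$date[seq_len(n)],
      host_id = paste0("H", seq_len(n)),
      host_sex = sample(c("male", "female"), n, replace = TRUE),
      purity = runif(n, config$purity_range[1], config$purity_range[2]),
      ploidy = ifelse(is.na(tip_wgd), 2L, 4L),
      wgd_year = tip_wgd,
      loy = seq_len(n) %in% sim$truth$loy_tips,
      stringsAsFactors = FALSE)

    germline <- simulate_germline(config, n_normals = n_normals, genome = genome)
    host_map <- NULL
    if (n_normals >= 2) {
      k <- min(3L, n_normals, n)
      host_map <- setNames(paste0("N", seq_len(k)), meta$sample_id[seq_len(k)])
    }

    ## subclone truth: mixed tumour = own lineage + sister lineage cells
    subclone_truth <- NULL
    if (!is.null(config$subclone) && detail != "counts") {
      tip <- match(config$subclone$tumour, tree$tip_label)
      stop_if_not(!is.na(tip), "subclone tumour id not found among tips")
      par <- tree$parent[tip]
      clades <- tree_clades(tree)
      ch <- tree_children(tree)
      sibs <- setdiff(ch[[par]], tip)
      stop_if_not(length(sibs) > 0, "subclone tumour has no sister lineage")
      sister_tip <- min(clades[[sibs[1]]])
      comp2_branches <- setdiff(path_to_root(tree, sister_tip),
                                path_to_root(tree, par))
      subclone_truth <- list(tumour = config$subclone$tumour, tip = tip,
                             fractions = config$subclone$fractions,
                             comp1_branches = tip,
                             comp2_branches = comp2_branches,
                             sister_tip = tree$tip_label[sister_tip])
    }

    cohort <- list(config = config, genome = genome, tree = tree,
                   variants = sim$variants, cnv_events = sim$cnv_events,
                   rearrangements = sim$rearrangements,
                   truth = c(sim$truth, list(subclone = subclone_truth)),
                   meta = meta, germline = germline, host_map = host_map)
    class(cohort) <- "cohort"
    if (detail == "reads") cohort$calls <- build_calls(cohort)
    cohort
  })
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort>", x$config$clone_label, "-", x$tree$n_tip, "tumours,",
      if (is.null(x$variants)) "burden-level" else
        paste(nrow(x$variants), "variants"),
      if (!is.null(x$calls)) "+ read-level calls" else "", "\n")
  invisible(x)
}

## Assemble per-sample allele-count matrices over all tumours and normals.
build_calls <- function(cohort) {
  tree <- cohort$tree; meta <- cohort$meta
  variants <- cohort$variants
  stop_if_not(!is.null(variants), "cohort was simulated without variant records")
  clades <- tree_clades(tree)
  n_tip <- tree$n_tip
  nv <- nrow(variants)
  carrier <- matrix(FALSE, nv, n_tip, dimnames = list(variants$id, meta$sample_id))
  for (b in unique(variants$branch))
    carrier[variants$branch == b, clades[[b]]] <- TRUE

  sub <- cohort$truth$subclone
  depth <- cohort$config$depth_mean
  pool <- cohort$germline$pool
  geno <- cohort$germline$genotype
  normals <- setdiff(cohort$germline$hosts, "founder")
  samples <- c(meta$sample_id, normals)

  ids <- c(variants$id, pool$id)
  alt <- dp <- matrix(0L, length(ids), length(samples),
                      dimnames = list(ids, samples))
  for (t in seq_len(n_tip)) {
    vt <- variants[, c("id", "time"), drop = FALSE]
    vt$germline <- FALSE
    vt$multiplicity <- 1
    vt$local_copies <- 2
    vt$cell_fraction <- ifelse(carrier[, t], 1, 0)
    if (!is.na(meta$wgd_year[t])) {
      vt$local_copies <- 4
      vt$multiplicity <- ifelse(!is.na(vt$time) & vt$time < meta$wgd_year[t], 2, 1)
    }
    if (!is.null(sub) && t == sub$tip) {
      c1 <- variants$branch %in% sub$comp1_branches
      c2 <- variants$branch %in% sub$comp2_branches
      vt$cell_fraction[c1] <- sub$fractions[1]
      vt$cell_fraction[c2] <- sub$fractions[2]
    }
    gt <- data.frame(id = pool$id, time = NA_real_, germline = geno[, "founder"],
                     multiplicity = 1, local_copies = 2,
                     cell_fraction = ifelse(geno[, "founder"], 1, 0))
    allv <- rbind(vt[, names(gt)], gt)[match(ids, c(vt$id, gt$id)), ]
    bulk <- make_bulk_sample(allv, purity = meta$purity[t], depth_mean = depth)
    alt[, t] <- bulk$alt
    dp[, t] <- bulk$dp
  }
  for (j in seq_along(normals)) {
    het <- geno[, normals[j]]
    d <- rpois(length(ids), depth)
    a <- integer(length(ids))
    gidx <- (nrow(variants) + 1):length(ids)
    a[gidx[het]] <- rbinom(sum(het), d[gidx[het]], 0.5)
    alt[, n_tip + j] <- a
    dp[, n_tip + j] <- d
  }
  vdf <- rbind(
    data.frame(id = variants$id, chrom = variants$chrom, pos = variants$pos,
               ref = variants$ref, alt_allele = variants$alt,
               class = variants$class, channel = variants$channel,
               branch = variants$branch, germline = FALSE,
               stringsAsFactors = FALSE),
    data.frame(id = pool$id, chrom = pool$chrom, pos = pool$pos,
               ref = pool$ref, alt_allele = pool$alt,
               class = "substitution", channel = NA_character_,
               branch = NA_integer_, germline = TRUE,
               stringsAsFactors = FALSE))
  list(variants = vdf, alt = alt, dp = dp,
       tumour_ids = meta$sample_id, normal_ids = normals)
}
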