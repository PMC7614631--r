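## all nodes in the subtree rooted at v (including v)
nodes_below <- function(tree, v) {
  ch <- tree_children(tree)
  out <- integer(0); stack <- v
  while (length(stack)) {
    u <- stack[length(stack)]; stack <- stack[-length(stack)]
    out <- c(out, u)
    stack <- c(stack, ch[[u]])
  }
  out
}

MUTATION_CLASSES <- c("substitution", "indel", "line1_insertion",
                      "rearrangement_event", "cnv_event")

#' Simulate mutations along a transmission tree
#'
#' Per-branch mutation counts are drawn as Poisson with mean `rate x branch
#' duration` for each mutation class. Substitution channels are drawn from the
#' configured signature mixture and placed uniformly over the simulated genome
#' without site collisions (infinite sites); indels are drawn from the reduced
#' 24-channel mixture and placed at compatible homopolymer runs. A configured
#' hypermutator branch multiplies substitution and indel rates from that
#' branch onward, with the excess drawn from the extra (mismatch-repair)
#' signatures. WGD events scale post-duplication substitution accrual by
#' `kappa`; LoY, CNV and rearrangement events are placed on their branches.
#' A truth table recording every per-branch count and event accompanies the
#' variants.
#'
#' @param tree a dated `clone_tree` from [simulate_transmission_tree()].
#' @param config a [cohort_config()].
#' @param genome a [simulate_genome()] result (sequence optional; without
#'   sequence, substitution/indel coordinates are left `NA`).
#' @param detail `"variants"` (per-variant records) or `"counts"` (per-branch
#'   counts only; much cheaper, sufficient for burden-level analyses).
#' @param seed optional seed.
#' @return list with elements `variants` (data frame), `cnv_events`,
#'   `rearrangements`, and `truth` (per-branch class counts, per-tip clonal
#'   burdens, WGD/LoY/hypermutator truth, LINE-1 source attribution).
#' @export
simulate_mutations <- function(tree, config, genome,
                               detail = c("variants", "counts"),
                               seed = NULL) {
  detail <- match.arg(detail)
  with_seed(seed, {
    edges <- tree_edges(tree)
    clades <- tree_clades(tree)
    n_node <- length(tree$parent)

    hyper_nodes <- if (!is.null(config$hypermutator))
      nodes_below(tree, config$hypermutator$branch) else integer()
    wgd_nodes <- lapply(config$wgd, function(w) nodes_below(tree, w$branch))
    loy_tips <- unique(unlist(lapply(config$loy, function(b)
      intersect(nodes_below(tree, b), seq_len(tree$n_tip)))))

    refs_sbs <- reference_signatures("sbs")
    refs_id <- reference_signatures("indel")
    mix_profile <- function(refs, w) as.numeric(refs[, names(w), drop = FALSE] %*% w)
    p_sbs0 <- mix_profile(refs_sbs, config$signature_mix$sbs)
    p_id0 <- mix_profile(refs_id, config$signature_mix$indel)

    counts <- matrix(0L, n_node, length(MUTATION_CLASSES),
                     dimnames = list(NULL, MUTATION_CLASSES))
    var_rows <- list(); cnv_rows <- list(); rr_rows <- list()
    vid <- 0L

    for (k in seq_len(nrow(edges))) {
      v <- edges$node[k]; dur <- edges$duration[k]
      t0 <- tree$date[edges$parent[k]]; t1 <- tree$date[v]
      hyper <- v %in% hyper_nodes
      sub_mult <- if (hyper) config$hypermutator$substitution_mult else 1
      ind_mult <- if (hyper) config$hypermutator$indel_mult else 1

      ## WGD kappa scaling of substitution accrual on this edge
      pre_dur <- dur; post_dur <- 0
      for (j in seq_along(config$wgd)) {
        if (v %in% wgd_nodes[[j]]) {
          y <- min(max(config$wgd[[j]]$year, t0), t1)
          if (v == config$wgd[[j]]$branch) {
            pre_dur <- y - t0; post_dur <- t1 - y
          } else { pre_dur <- 0; post_dur <- dur }
        }
      }
      sub_mean <- config$rates["substitution"] * sub_mult *
        (pre_dur + config$kappa * post_dur)
      n_sub <- rpois(1, sub_mean)
      n_ind <- rpois(1, config$rates["indel"] * ind_mult * dur)
      n_l1 <- rpois(1, config$rates["line1_insertion"] * dur)
      n_rr <- rpois(1, config$rates["rearrangement_event"] * dur)
      n_cnv <- rpois(1, config$rates["cnv_event"] * dur)
      counts[v, ] <- c(n_sub, n_ind, n_l1, n_rr, n_cnv)

      if (detail == "counts") next

      if (n_sub > 0) {
        p <- if (hyper)
          (p_sbs0 + (sub_mult - 1) * refs_sbs[, config$hypermutator$extra_sbs]) / sub_mult
        else p_sbs0
        chan <- rownames(refs_sbs)[sample.int(96L, n_sub, replace = TRUE, prob = p)]
        ## times: piecewise-uniform with post-WGD density kappa
        ppre <- pre_dur / (pre_dur + config$kappa * post_dur)
        is_pre <- runif(n_sub) < ppre
        tm <- ifelse(is_pre, t0 + runif(n_sub) * pre_dur,
                     t0 + pre_dur + runif(n_sub) * post_dur)
        pos <- if (!is.null(genome$sequence)) place_substitutions(genome, chan)
               else data.frame(chrom = NA_character_, pos = NA_integer_,
                               ref = NA_character_, alt = NA_character_)[rep(1, n_sub), ]
        var_rows[[length(var_rows) + 1L]] <- data.frame(
          id = paste0("s", vid + seq_len(n_sub)), branch = v,
          class = "substitution", channel = chan,
          chrom = pos$chrom, pos = pos$pos, ref = pos$ref, alt = pos$alt,
          time = tm, stringsAsFactors = FALSE)
        vid <- vid + n_sub
      }
      if (n_ind > 0) {
        p <- if (hyper)
          (p_id0 + (ind_mult - 1) * refs_id[, config$hypermutator$extra_id]) / ind_mult
        else p_id0
        chan <- rownames(refs_id)[sample.int(24L, n_ind, replace = TRUE, prob = p)]
        pos <- if (!is.null(genome$sequence)) place_indels(genome, chan)
               else data.frame(chrom = NA_character_, pos = NA_integer_,
                               ref = NA_character_, alt = NA_character_)[rep(1, n_ind), ]
        m <- nrow(pos)
        var_rows[[length(var_rows) + 1L]] <- data.frame(
          id = paste0("s", vid + seq_len(m)), branch = v, class = "indel",
          channel = chan[seq_len(m)],
          chrom = pos$chrom, pos = pos$pos, ref = pos$ref, alt = pos$alt,
          time = t0 + runif(m) * dur, stringsAsFactors = FALSE)
        vid <- vid + m
      }
      if (n_l1 > 0) {
        src_w <- config$l1_sources %||% rep(1, nrow(genome$l1))
        src_w <- rep_len(src_w, nrow(genome$l1))
        src <- sample.int(nrow(genome$l1), n_l1, replace = TRUE, prob = src_w)
        gpos <- sample.int(genome$total_length, n_l1)
        loc <- global_to_chrom(genome, gpos)
        has_td <- runif(n_l1) < config$l1_transduction_prob
        el <- genome$l1[src, ]
        td_off <- round(runif(n_l1, 50, 3000))
        td_len <- round(runif(n_l1, 100, 2000))
        td_start <- ifelse(el$strand == "+", el$end + td_off, el$start - td_off - td_len)
        td_end <- td_start + td_len
        var_rows[[length(var_rows) + 1L]] <- data.frame(
          id = paste0("s", vid + seq_len(n_l1)), branch = v,
          class = "line1_insertion", channel = NA_character_,
          chrom = loc$chrom, pos = loc$pos, ref = NA_character_, alt = "<INS:L1>",
          time = t0 + runif(n_l1) * dur,
          source_id = el$element_id,
          td_chrom = ifelse(has_td, el$chrom, NA_character_),
          td_start = ifelse(has_td, td_start, NA_real_),
          td_end = ifelse(has_td, td_end, NA_real_),
          td_strand = ifelse(has_td, el$strand, NA_character_),
          stringsAsFactors = FALSE)
        vid <- vid + n_l1
      }
      if (n_rr > 0) {
        g1 <- global_to_chrom(genome, sample.int(genome$total_length, n_rr))
        g2 <- global_to_chrom(genome, sample.int(genome$total_length, n_rr))
        rr_rows[[length(rr_rows) + 1L]] <- data.frame(
          branch = v, chrom1 = g1$chrom, pos1 = g1$pos,
          chrom2 = g2$chrom, pos2 = g2$pos, stringsAsFactors = FALSE)
      }
      if (n_cnv > 0) {
        for (e in seq_len(n_cnv)) {
          ci <- sample.int(7L, 1L, prob = genome$chrom$length[1:7])
          L <- genome$chrom$length[ci]
          if (runif(1) < 0.3) {  # whole-arm event
            half <- sample(c(TRUE, FALSE), 1)
            se <- if (half) c(1L, L %/% 2L) else c(L %/% 2L + 1L, L)
            arm <- TRUE
          } else {
            flen <- round(runif(1, 0.002, 0.02) * L)
            st <- sample.int(L - flen, 1L)
            se <- c(st, st + flen)
            arm <- FALSE
          }
          cnv_rows[[length(cnv_rows) + 1L]] <- data.frame(
            branch = v, chrom = genome$chrom$name[ci], start = se[1], end = se[2],
            delta = sample(c(1L, -1L), 1L), arm_scale = arm,
            stringsAsFactors = FALSE)
        }
      }
    }

    variants <- if (length(var_rows)) {
      base_cols <- c("id", "branch", "class", "channel", "chrom", "pos",
                     "ref", "alt", "time")
      all_cols <- unique(unlist(lapply(var_rows, names)))
      var_rows <- lapply(var_rows, function(d) {
        for (cc in setdiff(all_cols, names(d))) d[[cc]] <- NA
        d[union(base_cols, all_cols)]
      })
      do.call(rbind, var_rows)
    } else NULL

    tip_burden <- tip_class_burdens(tree, counts)
    truth <- list(
      branch_counts = cbind(edges, counts[edges$node, , drop = FALSE]),
      tip_burden = tip_burden,
      tip_label = tree$tip_label,
      wgd = lapply(config$wgd, function(w)
        list(branch = w$branch, year = w$year,
             tips = intersect(nodes_below(tree, w$branch), seq_len(tree$n_tip)))),
      loy_tips = loy_tips,
      hypermutator = config$hypermutator,
      l1_sources = if (!is.null(variants) && any(variants$class == "line1_insertion"))
        variants[variants$class == "line1_insertion", c("id", "source_id")] else NULL
    )
    list(variants = variants,
         cnv_events = if (length(cnv_rows)) do.call(rbind, cnv_rows) else NULL,
         rearrangements = if (length(rr_rows)) do.call(rbind, rr_rows) else NULL,
         truth = truth)
  })
}

## per-tip clonal burden by class: sum of counts over root-to-tip path
tip_class_burdens <- function(tree, counts) {
  n <- tree$n_tip
  out <- matrix(0, n, ncol(counts), dimnames = list(tree$tip_label, colnames(counts)))
  for (tip in seq_len(n)) {
    v <- tip
    while (tree$parent[v] > 0L) {
      out[tip, ] <- out[tip, ] + counts[v, ]
      v <- tree$parent[v]
    }
  }
  out
}
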