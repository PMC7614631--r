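IMPACT_CLASSES <- c("synonymous", "missense", "nonsense", "frameshift",
                    "inframe_indel")

#' Classify the coding impact of a variant
#'
#' Substitutions are translated codon-against-codon with the standard genetic
#' code; indels whose length is not a multiple of 3 are frameshifts, others
#' in-frame. Genes are single-exon plus-strand CDS models; a CDS whose length
#' is not divisible by 3 is an annotation error.
#'
#' @param variant one-row frame with `chrom,pos,ref,alt,class`.
#' @param gene one-row gene model `chrom,start,end,strand`.
#' @param genome genome with sequence.
#' @return one of `"synonymous"`, `"missense"`, `"nonsense"`, `"frameshift"`,
#'   `"inframe_indel"`, or `NA` if the variant does not overlap the CDS.
#' @export
classify_impact <- function(variant, gene, genome) {
  stop_if_not((gene$end - gene$start + 1L) %% 3L == 0L,
              "CDS length not divisible by 3: annotation error")
  stop_if_not(gene$strand == "+",
              "only plus-strand CDS models are supported")
  if (variant$chrom != gene$chrom || variant$pos < gene$start ||
      variant$pos > gene$end) return(NA_character_)
  if (variant$class == "indel") {
    shift <- abs(nchar(variant$alt) - nchar(variant$ref))
    return(if (shift %% 3L != 0L) "frameshift" else "inframe_indel")
  }
  ci <- match(gene$chrom, genome$chrom$name)
  off <- variant$pos - gene$start  # 0-based within CDS
  cstart <- gene$start + (off %/% 3L) * 3L
  codon <- as.character(Biostrings::subseq(genome$sequence[[ci]], cstart, cstart + 2L))
  pos_in <- off %% 3L + 1L
  alt_codon <- codon
  substr(alt_codon, pos_in, pos_in) <- variant$alt
  aa0 <- Biostrings::GENETIC_CODE[[codon]]
  aa1 <- Biostrings::GENETIC_CODE[[alt_codon]]
  if (aa1 == aa0) "synonymous" else if (aa1 == "*") "nonsense" else "missense"
}

## per-gene opportunity matrix: for every CDS site x 3 alternates, count by
## (96-channel, impact class). Vectorised over sites.
gene_opportunities <- function(gene, genome) {
  ci <- match(gene$chrom, genome$chrom$name)
  x <- chrom_codes(genome, ci)
  idx <- gene$start:gene$end
  L <- length(idx)
  refc <- x[idx]
  b5 <- x[idx - 1L]; b3 <- x[idx + 1L]
  comp <- c(4L, 3L, 2L, 1L)
  pyr <- refc == 2L | refc == 4L
  ctx <- paste0(DNA_BASES[ifelse(pyr, b5, comp[b3])],
                "[", DNA_BASES[ifelse(pyr, refc, comp[refc])])
  ctx3 <- DNA_BASES[ifelse(pyr, b3, comp[b5])]
  codon_i <- (seq_len(L) - 1L) %/% 3L
  pos_in <- (seq_len(L) - 1L) %% 3L + 1L
  codons <- paste0(DNA_BASES[refc[codon_i * 3L + 1L]],
                   DNA_BASES[refc[codon_i * 3L + 2L]],
                   DNA_BASES[refc[codon_i * 3L + 3L]])
  aa0 <- Biostrings::GENETIC_CODE[codons]
  opp <- matrix(0L, 96L, 3L, dimnames = list(sbs_channels(),
                                             c("synonymous", "missense", "nonsense")))
  for (alt_i in 1:4) {
    sel <- refc != alt_i
    if (!any(sel)) next
    altb <- DNA_BASES[alt_i]
    alt_codon <- codons[sel]
    substr(alt_codon, 1, 3) <- vapply(seq_along(alt_codon), function(z) {
      s <- alt_codon[z]
      substr(s, pos_in[sel][z], pos_in[sel][z]) <- altb
      s
    }, "")
    aa1 <- Biostrings::GENETIC_CODE[alt_codon]
    impact <- ifelse(aa1 == aa0[sel], "synonymous",
                     ifelse(aa1 == "*", "nonsense", "missense"))
    alt_pyr <- ifelse(pyr[sel], altb, COMPLEMENT[altb])
    chan <- paste0(ctx[sel], ">", alt_pyr, "]", ctx3[sel])
    tt <- table(chan, impact)
    opp[rownames(tt), colnames(tt)] <- opp[rownames(tt), colnames(tt)] + tt
  }
  opp
}

#' Observed and expected per-gene impact counts
#'
#' The core of a "dNdScv-lite": per-trinucleotide-channel mutation rates are
#' estimated from synonymous sites genome-wide (observed synonymous mutations
#' per channel divided by synonymous opportunities), then expected counts for
#' each gene and impact class are the rate-weighted sums of that gene's
#' site-level opportunities. Indel expectations are proportional to CDS
#' length times the cohort's per-base coding indel rate. No covariate or
#' negative-binomial shrinkage is applied.
#'
#' @param variants cohort somatic variant frame (`chrom,pos,ref,alt,class`).
#' @param annotation gene frame from the genome.
#' @param genome genome with sequence.
#' @return an `impact_counts` list: per-gene `observed` and `expected`
#'   matrices (genes x impact classes), per-variant `impact`, channel rates.
#' @export
expected_counts <- function(variants, annotation, genome) {
  genes <- annotation
  ng <- nrow(genes)
  obs <- matrix(0, ng, length(IMPACT_CLASSES),
                dimnames = list(genes$gene_id, IMPACT_CLASSES))
  impact <- rep(NA_character_, nrow(variants))
  opp <- vector("list", ng)
  for (i in seq_len(ng)) {
    g <- genes[i, ]
    opp[[i]] <- gene_opportunities(g, genome)
    hit <- which(variants$chrom == g$chrom & variants$pos >= g$start &
                   variants$pos <= g$end &
                   variants$class %in% c("substitution", "indel"))
    for (j in hit) {
      cl <- classify_impact(variants[j, ], g, genome)
      impact[j] <- cl
      if (!is.na(cl)) obs[i, cl] <- obs[i, cl] + 1
    }
  }
  syn_obs_total <- sum(obs[, "synonymous"])
  if (syn_obs_total == 0)
    stop("no synonymous mutations observed: per-context rates are undefined",
         call. = FALSE)
  if (syn_obs_total < 100)
    warning("fewer than 100 synonymous mutations; ",
            "expected counts will be noisy")
  ## channel rates from synonymous sites genome-wide
  syn_opp <- Reduce(`+`, lapply(opp, function(o) o[, "synonymous"]))
  coding_sub <- variants$class == "substitution" & !is.na(impact)
  syn_idx <- which(coding_sub & impact == "synonymous")
  syn_chan <- variant_channels(variants[syn_idx, , drop = FALSE], genome)
  obs_chan <- setNames(numeric(96), sbs_channels())
  tt <- table(syn_chan)
  obs_chan[names(tt)] <- as.numeric(tt)
  rate <- ifelse(syn_opp > 0, obs_chan / syn_opp, 0)

  expd <- matrix(0, ng, length(IMPACT_CLASSES),
                 dimnames = dimnames(obs))
  for (i in seq_len(ng))
    for (cl in c("synonymous", "missense", "nonsense"))
      expd[i, cl] <- sum(rate * opp[[i]][, cl])
  ## indel expectation: cohort coding indel rate spread by CDS length
  cds_len <- genes$end - genes$start + 1
  n_indel <- sum(variants$class == "indel" & !is.na(impact))
  fs_frac <- 2 / 3  # of random indel lengths 1..3+, ~2/3 shift the frame
  obs_fs <- sum(obs[, "frameshift"]); obs_if <- sum(obs[, "inframe_indel"])
  if (obs_fs + obs_if > 0) fs_frac <- obs_fs / (obs_fs + obs_if)
  expd[, "frameshift"] <- n_indel * fs_frac * cds_len / sum(cds_len)
  expd[, "inframe_indel"] <- n_indel * (1 - fs_frac) * cds_len / sum(cds_len)
  structure(list(observed = obs, expected = expd, impact = impact,
                 channel_rates = rate, syn_opportunities = syn_opp),
            class = "impact_counts")
}

## 96-channel labels for substitution variants
variant_channels <- function(variants, genome) {
  if (!nrow(variants)) return(character())
  ctx <- character(nrow(variants))
  for (cn in unique(variants$chrom)) {
    ci <- match(cn, genome$chrom$name)
    s <- as.character(genome$sequence[[ci]])
    sel <- variants$chrom == cn
    ctx[sel] <- substring(s, variants$pos[sel] - 1L, variants$pos[sel] + 1L)
  }
  ref <- variants$ref; alt <- variants$alt
  pur <- ref %in% c("G", "A")
  ctx[pur] <- revcomp_chr(ctx[pur])
  alt[pur] <- COMPLEMENT[alt[pur]]
  ref[pur] <- COMPLEMENT[ref[pur]]
  paste0(substr(ctx, 1, 1), "[", ref, ">", alt, "]", substr(ctx, 3, 3))
}

#' Per-gene and global dN/dS tests
#'
#' For each gene, a Poisson likelihood-ratio test of omega = 1 against a free
#' omega for (a) missense, (b) truncating (nonsense + frameshift) and (c) all
#' protein-altering mutations, with Benjamini-Hochberg correction across
#' tested genes (by default those with at least one observed protein-altering
#' mutation). Global omega per class is the summed observed/expected ratio
#' with an exact Poisson confidence interval.
#'
#' @param counts an `impact_counts` from [expected_counts()].
#' @param test_all test every gene instead of only those with observed
#'   protein-altering mutations.
#' @return a `dnds_result`: `global` frame (class, omega, CI) and `genes`
#'   frame (per-gene omega, LRT statistic, p, q per test class).
#' @export
gene_dnds_test <- function(counts, test_all = FALSE) {
  obs <- counts$observed; expd <- counts$expected
  comb <- function(m, cols) rowSums(m[, cols, drop = FALSE])
  sets <- list(missense = "missense",
               truncating = c("nonsense", "frameshift"),
               global = c("missense", "nonsense", "frameshift", "inframe_indel"))
  lrt <- function(o, e) {
    if (e <= 0) return(c(NA, NA, NA))
    w <- o / e
    stat <- if (o > 0) 2 * (o * log(o / e) - (o - e)) else 2 * e
    c(w, stat, pchisq(stat, 1, lower.tail = FALSE))
  }
  tested <- if (test_all) seq_len(nrow(obs))
            else which(comb(obs, sets$global) > 0)
  genes <- do.call(rbind, lapply(tested, function(i) {
    row <- data.frame(gene_id = rownames(obs)[i],
                      n_syn = obs[i, "synonymous"], stringsAsFactors = FALSE)
    for (nm in names(sets)) {
      r <- lrt(sum(obs[i, sets[[nm]]]), sum(expd[i, sets[[nm]]]))
      row[[paste0("omega_", nm)]] <- r[1]
      row[[paste0("stat_", nm)]] <- r[2]
      row[[paste0("p_", nm)]] <- r[3]
    }
    row
  }))
  if (!is.null(genes)) {
    for (nm in names(sets))
      genes[[paste0("q_", nm)]] <- p.adjust(genes[[paste0("p_", nm)]], "BH")
    genes <- genes[order(genes$q_global, genes$p_global), ]
    rownames(genes) <- NULL
  }
  global <- do.call(rbind, lapply(names(sets), function(nm) {
    O <- sum(obs[, sets[[nm]]]); E <- sum(expd[, sets[[nm]]])
    ci <- if (E > 0) poisson.test(round(O))$conf.int / E else c(NA, NA)
    data.frame(class = nm, observed = O, expected = E,
               omega = if (E > 0) O / E else NA_real_,
               lo = ci[1], hi = ci[2], stringsAsFactors = FALSE)
  }))
  structure(list(global = global, genes = genes %||% data.frame()),
            class = "dnds_result")
}

#' @export
print.dnds_result <- function(x, ...) {
  cat("<dnds_result>\n")
  print(transform(x$global, omega = round(omega, 3), lo = round(lo, 3),
                  hi = round(hi, 3)), row.names = FALSE)
  sig <- x$genes[!is.na(x$genes$q_global) & x$genes$q_global < 0.05, , drop = FALSE]
  cat(nrow(sig), "gene(s) with q_global < 0.05\n")
  invisible(x)
}
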