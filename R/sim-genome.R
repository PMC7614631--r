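#' Simulate a scaled reference genome with annotations
#'
#' Builds a random reference of `callable_genome * genome_scale` bases split
#' over 7 autosome-equivalents plus X and Y (mirroring a marsupial karyotype
#' where 99.8% of the assembly sits on seven scaffolds), together with a set
#' of single-exon protein-coding CDS models (lengths divisible by 3, plus
#' strand) and a set of full-length LINE-1 source-element coordinates.
#' Annotation counts default to the real genome's totals (19,228 coding genes,
#' 1,948 full-length LINE-1 elements) scaled by `genome_scale`.
#'
#' @param config a [cohort_config()].
#' @param n_genes,gene_length number and CDS length of simulated genes.
#' @param n_l1,l1_length number and length of full-length LINE-1 elements.
#' @param with_sequence if `FALSE`, only coordinates are generated (cheaper;
#'   sufficient for burden-level simulations).
#' @return an object of class `synthetic_genome`: chromosome table, optional
#'   `Biostrings::DNAStringSet` sequence, `genes` and `l1` annotation frames.
#' @export
simulate_genome <- function(config,
                            n_genes = max(5L, round(19228 * config$genome_scale)),
                            gene_length = 1500,
                            n_l1 = max(5L, round(1948 * config$genome_scale)),
                            l1_length = 6000,
                            with_sequence = TRUE) {
  total <- round(config$callable_genome * config$genome_scale)
  w <- c(chr1 = 0.21, chr2 = 0.18, chr3 = 0.15, chr4 = 0.13, chr5 = 0.11,
         chr6 = 0.09, chr7 = 0.05, chrX = 0.06, chrY = 0.02)
  len <- round(w / sum(w) * total)
  len[1] <- len[1] + (total - sum(len))
  chrom <- data.frame(name = names(w), length = as.integer(len),
                      offset = cumsum(c(0, len[-length(len)])),
                      row.names = NULL)
  stop_if_not(gene_length %% 3 == 0, "gene_length must be divisible by 3")

  sequence <- NULL
  if (with_sequence) {
    sequence <- Biostrings::DNAStringSet(vapply(chrom$length, function(L) {
      rawToChar(as.raw(c(65L, 67L, 71L, 84L))[sample.int(4L, L, replace = TRUE)])
    }, ""))
    names(sequence) <- chrom$name
  }

  autos <- chrom[1:7, ]
  place_features <- function(n, flen, prefix, strands) {
    taken <- vector("list", nrow(chrom))
    out <- vector("list", n)
    for (i in seq_len(n)) {
      for (try in 1:200) {
        ci <- sample.int(nrow(autos), 1, prob = autos$length)
        start <- sample.int(autos$length[ci] - flen - 2L, 1) + 1L
        iv <- c(start, start + flen - 1L)
        ok <- TRUE
        for (o in taken[[ci]]) if (iv[1] <= o[2] && o[1] <= iv[2]) { ok <- FALSE; break }
        if (ok) {
          taken[[ci]] <- c(taken[[ci]], list(iv))
          out[[i]] <- data.frame(chrom = autos$name[ci], start = iv[1], end = iv[2],
                                 strand = sample(strands, 1))
          break
        }
      }
      if (is.null(out[[i]])) stop("could not place non-overlapping features; ",
                                  "genome too small for requested annotation")
    }
    d <- do.call(rbind, out)
    d <- cbind(id = paste0(prefix, seq_len(n)), d)
    d
  }
  genes <- place_features(n_genes, gene_length, "gene", "+")
  names(genes)[1] <- "gene_id"
  l1 <- place_features(n_l1, l1_length, "L1_", c("+", "-"))
  names(l1)[1] <- "element_id"

  g <- list(chrom = chrom, sequence = sequence, genes = genes, l1 = l1,
            callable_genome = config$callable_genome,
            genome_scale = config$genome_scale,
            total_length = total, cache = new.env(parent = emptyenv()))
  class(g) <- "synthetic_genome"
  g
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat("<synthetic_genome>", round(x$total_length / 1e6, 2), "Mb over",
      nrow(x$chrom), "chromosomes;", nrow(x$genes), "genes,",
      nrow(x$l1), "LINE-1 elements;",
      if (is.null(x$sequence)) "no sequence" else "with sequence", "\n")
  invisible(x)
}

## integer codes 1..4 = A C G T for one chromosome
chrom_codes <- function(genome, ci) {
  key <- paste0("codes_", ci)
  if (is.null(genome$cache[[key]])) {
    s <- utf8ToInt(as.character(genome$sequence[[ci]]))
    genome$cache[[key]] <- match(s, c(65L, 67L, 71L, 84L))
  }
  genome$cache[[key]]
}

global_to_chrom <- function(genome, gpos) {
  ci <- findInterval(gpos, genome$chrom$offset + 1)
  data.frame(chrom = genome$chrom$name[ci], pos = gpos - genome$chrom$offset[ci],
             ci = ci)
}

## Pools of genomic positions indexed by pyrimidine-strand trinucleotide
## context (32 contexts). Positions are global coordinates; pools shrink as
## variants are placed (infinite-sites bookkeeping).
context_pools <- function(genome) {
  if (!is.null(genome$cache$pools)) return(genome$cache$pools)
  stop_if_not(!is.null(genome$sequence),
              "genome has no sequence; regenerate with with_sequence = TRUE")
  pools <- vector("list", 32L)
  comp <- c(4L, 3L, 2L, 1L)
  for (ci in seq_len(nrow(genome$chrom))) {
    x <- chrom_codes(genome, ci)
    L <- length(x)
    i <- 2:(L - 1L)
    b5 <- x[i - 1L]; bc <- x[i]; b3 <- x[i + 1L]
    pyr <- bc == 2L | bc == 4L
    cb5 <- ifelse(pyr, b5, comp[b3])
    cbc <- ifelse(pyr, bc, comp[bc])
    cb3 <- ifelse(pyr, b3, comp[b5])
    code <- (ifelse(cbc == 2L, 0L, 1L)) * 16L + (cb5 - 1L) * 4L + cb3
    gpos <- i + genome$chrom$offset[ci]
    sp <- split(gpos, code)
    for (nm in names(sp)) {
      k <- as.integer(nm)
      pools[[k]] <- c(pools[[k]], sp[[nm]])
    }
  }
  names(pools) <- context_code_names()
  genome$cache$pools <- pools
  pools
}

context_code_names <- function() {
  b <- DNA_BASES
  out <- character(32)
  for (cbc in c(2L, 4L)) for (cb5 in 1:4) for (cb3 in 1:4) {
    code <- (if (cbc == 2L) 0L else 1L) * 16L + (cb5 - 1L) * 4L + cb3
    out[code] <- paste0(b[cb5], b[cbc], b[cb3])
  }
  out
}

## run-length table of homopolymers (per base) across the genome
run_table <- function(genome) {
  if (!is.null(genome$cache$runs)) return(genome$cache$runs)
  out <- list()
  for (ci in seq_len(nrow(genome$chrom))) {
    x <- chrom_codes(genome, ci)
    r <- rle(x)
    start <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
    out[[ci]] <- data.frame(ci = ci, start = start, len = r$lengths,
                            base = r$values)
  }
  runs <- do.call(rbind, out)
  runs$cat <- cut(runs$len, c(0, 1, 4, Inf), labels = c("r1", "r2_4", "r5+"))
  genome$cache$runs <- runs
  runs
}

## Draw genomic positions for substitutions given 96-channel names; consumes
## context pools so no site is hit twice. Returns chrom/pos/ref/alt/context.
place_substitutions <- function(genome, channels) {
  if (length(channels) == 0)
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      context = character()))
  pools <- context_pools(genome)
  ctx <- paste0(substr(channels, 1, 1), substr(channels, 3, 3), substr(channels, 7, 7))
  alt_pyr <- substr(channels, 5, 5)
  gpos <- integer(length(channels))
  for (cx in unique(ctx)) {
    idx <- which(ctx == cx)
    pool <- pools[[cx]]
    if (length(pool) < length(idx))
      stop("context pool exhausted for ", cx,
           "; widen the simulated genome (smaller genome_scale denominator)")
    take <- if (length(pool) == 1L) 1L else sample.int(length(pool), length(idx))
    gpos[idx] <- pool[take]
    pools[[cx]] <- pool[-take]
  }
  genome$cache$pools <- pools
  loc <- global_to_chrom(genome, gpos)
  ref <- alt <- character(length(gpos))
  for (ci in unique(loc$ci)) {
    x <- chrom_codes(genome, ci)
    sel <- loc$ci == ci
    rb <- DNA_BASES[x[loc$pos[sel]]]
    ref[sel] <- rb
    pyr <- rb %in% c("C", "T")
    alt[sel] <- ifelse(pyr, alt_pyr[sel], unname(COMPLEMENT[alt_pyr[sel]]))
  }
  data.frame(chrom = loc$chrom, pos = loc$pos, ref = ref, alt = alt,
             context = ctx, stringsAsFactors = FALSE)
}

## pools of run_table row indices per placement category, consumed as drawn
indel_pools <- function(genome) {
  if (!is.null(genome$cache$indel_pools)) return(genome$cache$indel_pools)
  runs <- run_table(genome)
  ## drop chromosome-leading runs (no anchor base to their left)
  ok <- runs$start >= 2L
  key <- character(nrow(runs))
  key[ok & runs$base == 1L] <- paste0("A:", runs$cat[ok & runs$base == 1L])
  key[ok & runs$base == 4L] <- paste0("T:", runs$cat[ok & runs$base == 4L])
  cg <- ok & runs$base %in% c(2L, 3L)
  key[cg] <- paste0("CG:", runs$cat[cg])
  pools <- split(which(key != ""), key[key != ""])
  pools[["MULTI"]] <- which(ok & runs$len == 1L)
  genome$cache$indel_pools <- pools
  pools
}

## Draw positions/alleles for indels given 24-channel names.
place_indels <- function(genome, channels) {
  if (length(channels) == 0)
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character()))
  runs <- run_table(genome)
  pools <- indel_pools(genome)
  parts <- do.call(rbind, strsplit(channels, ":", fixed = TRUE))
  type <- parts[, 1]; unit <- parts[, 2]; rcat <- parts[, 3]
  n <- length(channels)
  chromv <- character(n); posv <- integer(n)
  refv <- character(n); altv <- character(n)
  for (i in seq_len(n)) {
    key <- if (unit[i] == "MULTI") "MULTI" else paste0(unit[i], ":", rcat[i])
    pool <- pools[[key]]
    if (is.null(pool) || length(pool) == 0)
      stop("no available site for indel channel ", channels[i],
           "; widen the simulated genome")
    take <- if (length(pool) == 1L) 1L else sample.int(length(pool), 1L)
    ri <- pool[take]
    pools[[key]] <- pool[-take]
    run <- runs[ri, ]
    x <- chrom_codes(genome, run$ci)
    anchor_pos <- run$start - 1L
    anchor <- DNA_BASES[x[anchor_pos]]
    base <- DNA_BASES[run$base]
    indel_seq <- if (unit[i] == "MULTI") {
      paste(DNA_BASES[sample.int(4L, sample(2:4, 1L), replace = TRUE)], collapse = "")
    } else base
    chromv[i] <- genome$chrom$name[run$ci]
    posv[i] <- anchor_pos
    if (type[i] == "ins") {
      refv[i] <- anchor
      altv[i] <- paste0(anchor, indel_seq)
    } else {
      del <- if (unit[i] == "MULTI") {
        substr(as.character(genome$sequence[[run$ci]]), run$start,
               min(run$start + nchar(indel_seq) - 1L, genome$chrom$length[run$ci]))
      } else base
      refv[i] <- paste0(anchor, del)
      altv[i] <- anchor
    }
  }
  genome$cache$indel_pools <- pools
  data.frame(chrom = chromv, pos = posv, ref = refv, alt = altv,
             stringsAsFactors = FALSE)
}
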