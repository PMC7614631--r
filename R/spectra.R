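#' Build a mutational spectrum from variant records
#'
#' Substitutions are tabulated over the 96 trinucleotide channels: the
#' reference base and its immediate 5'/3' flanks are read from the genome
#' sequence and purine-reference variants are reverse-complemented onto the
#' pyrimidine strand (a G>A at 5'-C G T-3' counts as C>T at A-C-A). Indels are
#' binned into the reduced 24-channel scheme from the repeated unit and the
#' reference homopolymer/repeat run length at the site.
#'
#' @param variants data frame with `class`, `chrom`, `pos`, `ref`, `alt`.
#' @param genome a [simulate_genome()] result with sequence.
#' @return a `mutation_spectrum`: named channel counts `sbs` (96) and
#'   `indel` (24).
#' @export
build_spectrum <- function(variants, genome) {
  stop_if_not(!is.null(genome$sequence), "genome carries no sequence")
  sbs <- setNames(integer(96), sbs_channels())
  ind <- setNames(integer(24), indel_channels())
  if (nrow(variants)) {
    ci <- match(variants$chrom, genome$chrom$name)
    bad <- is.na(ci) | variants$pos < 1 |
      variants$pos > genome$chrom$length[ifelse(is.na(ci), 1L, ci)]
    if (any(bad))
      stop("variant position outside the reference: ",
           paste(head(paste0(variants$chrom[bad], ":", variants$pos[bad]), 3),
                 collapse = ", "))
  }
  sv <- variants[variants$class == "substitution", , drop = FALSE]
  if (nrow(sv)) {
    ctx <- character(nrow(sv))
    for (cn in unique(sv$chrom)) {
      ci <- match(cn, genome$chrom$name)
      s <- as.character(genome$sequence[[ci]])
      sel <- sv$chrom == cn
      ctx[sel] <- substring(s, sv$pos[sel] - 1L, sv$pos[sel] + 1L)
    }
    ref <- sv$ref; alt <- sv$alt
    pur <- ref %in% c("G", "A")
    ctx[pur] <- revcomp_chr(ctx[pur])
    alt[pur] <- COMPLEMENT[alt[pur]]
    ref[pur] <- COMPLEMENT[ref[pur]]
    chan <- paste0(substr(ctx, 1, 1), "[", ref, ">", alt, "]", substr(ctx, 3, 3))
    tt <- table(chan)
    sbs[names(tt)] <- as.integer(tt)
  }
  iv <- variants[variants$class == "indel", , drop = FALSE]
  if (nrow(iv)) {
    chan <- character(nrow(iv))
    for (i in seq_len(nrow(iv))) {
      ci <- match(iv$chrom[i], genome$chrom$name)
      s <- genome$sequence[[ci]]
      chan[i] <- indel_channel_at(s, iv$pos[i], iv$ref[i], iv$alt[i])
    }
    tt <- table(chan)
    ind[names(tt)] <- as.integer(tt)
  }
  structure(list(sbs = sbs, indel = ind,
                 n = sum(sbs) + sum(ind)), class = "mutation_spectrum")
}

## classify one VCF-style (anchored) indel against the reference
indel_channel_at <- function(chrom_seq, pos, ref, alt) {
  is_ins <- nchar(alt) > nchar(ref)
  unit <- if (is_ins) substr(alt, nchar(ref) + 1L, nchar(alt))
          else substr(ref, nchar(alt) + 1L, nchar(ref))
  ucat <- if (nchar(unit) > 1) "MULTI"
          else if (unit %in% c("A", "T")) unit else "CG"
  ## reference run length of the unit immediately after the anchor base
  run <- 0L
  at <- pos + 1L
  L <- length(chrom_seq)
  ul <- nchar(unit)
  while (at + ul - 1L <= L &&
         as.character(Biostrings::subseq(chrom_seq, at, at + ul - 1L)) == unit) {
    run <- run + 1L
    at <- at + ul
  }
  rcat <- if (run <= 1L) "r1" else if (run <= 4L) "r2_4" else "r5+"
  paste(if (is_ins) "ins" else "del", ucat, rcat, sep = ":")
}

#' Tabulate a spectrum from channel-annotated variants
#'
#' For sequence-free simulations, where each variant already carries its
#' channel label.
#'
#' @param variants frame with `class` and `channel`.
#' @return a `mutation_spectrum`.
#' @export
spectrum_from_channels <- function(variants) {
  sbs <- setNames(integer(96), sbs_channels())
  ind <- setNames(integer(24), indel_channels())
  tt <- table(variants$channel[variants$class == "substitution"])
  sbs[names(tt)] <- as.integer(tt)
  tt <- table(variants$channel[variants$class == "indel"])
  ind[names(tt)] <- as.integer(tt)
  structure(list(sbs = sbs, indel = ind, n = sum(sbs) + sum(ind)),
            class = "mutation_spectrum")
}

#' @export
print.mutation_spectrum <- function(x, ...) {
  cat("<mutation_spectrum>", sum(x$sbs), "substitutions,",
      sum(x$indel), "indels\n")
  cls <- sub(".*\\[(.*)\\].*", "\\1", names(x$sbs))
  print(tapply(x$sbs, cls, sum))
  invisible(x)
}

#' Fit signature exposures by non-negative least squares
#'
#' Decomposes channel counts into non-negative exposures over reference
#' signature profiles (Lawson-Hanson NNLS via [pracma::lsqnonneg()]). A
#' sparsity pass zeroes signatures attributed less than `min_frac` of the
#' burden and refits on the remainder. Identical reference profiles are
#' flagged non-identifiable.
#'
#' @param counts named channel count vector (96 or 24 channels), or a
#'   `mutation_spectrum` (then `family` selects the part).
#' @param refs channels x signatures profile matrix, e.g.
#'   [reference_signatures()].
#' @param min_frac sparsity threshold as a fraction of total burden.
#' @param family when `counts` is a spectrum: `"sbs"` or `"indel"`.
#' @return an `exposure_fit`: `exposures` (mutation counts per signature),
#'   `residual` (Euclidean norm), `fitted`, `dropped`, `identifiable`.
#' @export
fit_signatures <- function(counts, refs, min_frac = 0.01,
                           family = c("sbs", "indel")) {
  if (inherits(counts, "mutation_spectrum")) {
    family <- match.arg(family)
    counts <- counts[[family]]
  }
  stop_if_not(ncol(refs) >= 1, "need at least one reference signature")
  common <- intersect(names(counts), rownames(refs))
  stop_if_not(length(common) == length(counts),
              "channel names of counts and reference signatures disagree")
  x <- as.numeric(counts[rownames(refs)])
  identifiable <- !any(duplicated(t(round(refs, 12))))
  if (!identifiable)
    warning("reference contains identical signature profiles; ",
            "exposures are not identifiable")
  w <- pracma::lsqnonneg(refs, x)$x
  names(w) <- colnames(refs)
  drop <- names(w)[w < min_frac * sum(x) & w > 0]
  if (length(drop) && length(drop) < ncol(refs)) {
    keep <- setdiff(colnames(refs), drop)
    w2 <- pracma::lsqnonneg(refs[, keep, drop = FALSE], x)$x
    w[] <- 0
    w[keep] <- w2
  }
  fitted <- as.numeric(refs %*% w)
  structure(list(exposures = w, residual = sqrt(sum((fitted - x)^2)),
                 fitted = setNames(fitted, rownames(refs)),
                 dropped = drop, identifiable = identifiable),
            class = "exposure_fit")
}

#' @export
print.exposure_fit <- function(x, ...) {
  cat("<exposure_fit>\n")
  e <- x$exposures[x$exposures > 0]
  pct <- 100 * e / sum(x$exposures)
  for (nm in names(e))
    cat(sprintf("  %-6s %8.1f (%.0f%%)\n", nm, e[nm], pct[nm]))
  cat(sprintf("  residual norm %.2f\n", x$residual))
  invisible(x)
}
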