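#' Mutation channel vocabularies
#'
#' Substitutions use the standard 96-channel classification: the six
#' pyrimidine-strand base substitution classes (C>A, C>G, C>T, T>A, T>C, T>G)
#' crossed with the 16 combinations of immediate 5' and 3' flanking bases,
#' named like `"A[C>T]G"`. Indels use a reduced 24-channel scheme: insertion or
#' deletion, crossed with the repeated unit (1-bp A, 1-bp T, 1-bp C/G, or a
#' multi-base unit) and the homopolymer/repeat run length at the site (1, 2-4,
#' or >= 5 copies), named like `"ins:T:r5+"`.
#'
#' @return character vector of channel names (length 96 or 24).
#' @export
sbs_channels <- function() {
  cls <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  b <- DNA_BASES
  unlist(lapply(cls, function(cl)
    as.vector(t(outer(b, b, function(p5, p3) paste0(p5, "[", cl, "]", p3))))))
}

#' @rdname sbs_channels
#' @export
indel_channels <- function() {
  as.vector(t(outer(c("ins", "del"), as.vector(t(outer(
    c("A", "T", "CG", "MULTI"), c("r1", "r2_4", "r5+"), paste, sep = ":"
  ))), paste, sep = ":")))
}

#' Packaged reference mutational signatures
#'
#' Returns the packaged flat-text signature matrix: substitution signatures
#' SBS1 (C>T at NpCpG, the 5-methylcytosine deamination clock), SBS5 (flat,
#' clock-like) and SBS6 (mismatch-repair deficiency), or indel signatures ID1
#' (1-bp T/A insertion at long homopolymers), ID2 (1-bp T/A deletion at long
#' homopolymers) and ID7 (mismatch-repair deficiency deletion mix). The
#' profiles are deterministic synthetic analogues built from the signatures'
#' qualitative definitions, not the COSMIC estimates; the cohort simulator
#' draws from the same profiles, so simulation and fitting are coherent.
#'
#' @param type `"sbs"` (96 channels) or `"indel"` (24 channels).
#' @return numeric matrix, channels x signatures; columns sum to 1.
#' @export
reference_signatures <- local({
  memo <- new.env(parent = emptyenv())
  function(type = c("sbs", "indel")) {
    type <- match.arg(type)
    if (!is.null(memo[[type]])) return(memo[[type]])
    f <- if (type == "sbs") "sbs_signatures_synthetic.tsv" else "id_signatures_synthetic.tsv"
    path <- system.file("extdata", f, package = "devilclones", mustWork = TRUE)
    d <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
    m <- as.matrix(d[-1])
    rownames(m) <- d$channel
    memo[[type]] <- m
    m
  }
})
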