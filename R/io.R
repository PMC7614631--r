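need_pkg <- function(pkg) {
  if (!requireNamespace(pkg, quietly = TRUE))
    stop("package '", pkg, "' is required for this operation", call. = FALSE)
}

#' Write a simulated cohort to standard file formats
#'
#' Writes sample metadata (TSV), the truth transmission tree (newick, branch
#' lengths in years), the reference sequence (FASTA), gene and LINE-1
#' annotations (GFF3), the truth table (JSON), and, when read-level calls are
#' present, one VCF 4.2 per tumour with `AD`/`DP` FORMAT fields and
#' `CLASS`/`CTX` INFO tags.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  p <- file.path(dir, "metadata.tsv")
  write.table(cohort$meta, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(dir, "truth_tree.nwk")
  ape::write.tree(as_phylo(cohort$tree, "years"), p)
  paths <- c(paths, p)
  if (!is.null(cohort$genome$sequence)) {
    p <- file.path(dir, "reference.fa")
    Biostrings::writeXStringSet(cohort$genome$sequence, p)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "annotation.gff3")
  write_annotation_gff3(cohort$genome, p)
  paths <- c(paths, p)
  p <- file.path(dir, "truth.json")
  truth <- cohort$truth
  truth$branch_counts <- as.list(truth$branch_counts)
  jsonlite::write_json(truth, p, auto_unbox = TRUE, digits = NA, force = TRUE)
  paths <- c(paths, p)
  if (!is.null(cohort$calls)) {
    for (sm in cohort$calls$tumour_ids) {
      p <- file.path(dir, paste0(sm, ".vcf.gz"))
      write_sample_vcf(cohort$calls, sm, p)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}

write_annotation_gff3 <- function(genome, path) {
  need_pkg("rtracklayer")
  si <- GenomicRanges::seqinfo(GenomicRanges::GRanges(
    genome$chrom$name, IRanges::IRanges(1, genome$chrom$length)))
  gr_genes <- GenomicRanges::GRanges(
    genome$genes$chrom,
    IRanges::IRanges(genome$genes$start, genome$genes$end),
    strand = genome$genes$strand, type = "CDS", ID = genome$genes$gene_id,
    phase = 0L, seqinfo = si)
  gr_l1 <- GenomicRanges::GRanges(
    genome$l1$chrom, IRanges::IRanges(genome$l1$start, genome$l1$end),
    strand = genome$l1$strand, type = "mobile_genetic_element",
    ID = genome$l1$element_id, phase = NA_integer_, seqinfo = si)
  rtracklayer::export(c(gr_genes, gr_l1), path, format = "gff3")
}

#' Read a GFF3 annotation into gene and LINE-1 frames
#'
#' @param path GFF3 file.
#' @return list with `genes` and `l1` data frames.
#' @export
read_annotation_gff3 <- function(path) {
  need_pkg("rtracklayer")
  gr <- rtracklayer::import(path, format = "gff3")
  d <- as.data.frame(gr)
  genes <- d[d$type == "CDS", ]
  l1 <- d[d$type == "mobile_genetic_element", ]
  list(genes = data.frame(gene_id = genes$ID, chrom = as.character(genes$seqnames),
                          start = genes$start, end = genes$end,
                          strand = as.character(genes$strand),
                          stringsAsFactors = FALSE),
       l1 = data.frame(element_id = l1$ID, chrom = as.character(l1$seqnames),
                       start = l1$start, end = l1$end,
                       strand = as.character(l1$strand),
                       stringsAsFactors = FALSE))
}

## one-sample VCF with AD/DP FORMAT and CLASS/CTX INFO
write_sample_vcf <- function(calls, sample, path) {
  need_pkg("vcfR")
  keep <- which(calls$alt[, sample] > 0)
  v <- calls$variants[keep, ]
  a <- calls$alt[keep, sample]
  d <- calls$dp[keep, sample]
  info <- paste0("CLASS=", v$class,
                 ifelse(is.na(v$channel), "", paste0(";CTX=", v$channel)),
                 ifelse(v$germline, ";GERMLINE=1", ""))
  fix <- cbind(CHROM = ifelse(is.na(v$chrom), "chrUn", v$chrom),
               POS = as.character(ifelse(is.na(v$pos), seq_along(keep), v$pos)),
               ID = v$id,
               REF = ifelse(is.na(v$ref), "N", v$ref),
               ALT = ifelse(is.na(v$alt_allele), "N", v$alt_allele),
               QUAL = ".", FILTER = "PASS", INFO = info)
  gt <- cbind(FORMAT = "AD:DP",
              paste0(pmax(d - a, 0), ",", a, ":", d))
  colnames(gt)[2] <- sample
  meta <- c("##fileformat=VCFv4.2",
            "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"Mutation class\">",
            "##INFO=<ID=CTX,Number=1,Type=String,Description=\"Mutation channel\">",
            "##INFO=<ID=GERMLINE,Number=0,Type=Flag,Description=\"Germline variant\">",
            "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
            "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">")
  x <- methods::new("vcfR", meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(x, path)
  invisible(path)
}

#' Read one or more single-sample VCFs into an allele-count list
#'
#' @param paths VCF paths (one sample each, `AD:DP` FORMAT).
#' @return a calls list (`variants`, `alt`, `dp`, sample ids) as consumed by
#'   [classify_germline()] and [build_mutation_matrix()].
#' @export
read_sample_vcfs <- function(paths) {
  need_pkg("vcfR")
  per <- lapply(paths, function(p) {
    x <- vcfR::read.vcfR(p, verbose = FALSE)
    ad <- vcfR::extract.gt(x, "AD")
    dp <- as.integer(vcfR::extract.gt(x, "DP"))
    alt <- as.integer(sub(".*,", "", ad))
    info <- vcfR::getINFO(x)
    data.frame(sample = colnames(ad)[1], id = x@fix[, "ID"],
               chrom = x@fix[, "CHROM"], pos = as.integer(x@fix[, "POS"]),
               ref = x@fix[, "REF"], alt_allele = x@fix[, "ALT"],
               class = sub(".*CLASS=([^;]*).*", "\\1", info),
               germline = grepl("GERMLINE", info, fixed = TRUE),
               alt = alt, dp = dp, stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, per)
  ids <- unique(all$id)
  samples <- unique(all$sample)
  altm <- dpm <- matrix(0L, length(ids), length(samples),
                        dimnames = list(ids, samples))
  idx <- cbind(match(all$id, ids), match(all$sample, samples))
  altm[idx] <- all$alt
  dpm[idx] <- all$dp
  first <- all[!duplicated(all$id), ]
  variants <- data.frame(id = first$id, chrom = first$chrom, pos = first$pos,
                         ref = first$ref, alt_allele = first$alt_allele,
                         class = first$class, germline = first$germline,
                         stringsAsFactors = FALSE)[match(ids, first$id), ]
  list(variants = variants, alt = altm, dp = dpm,
       tumour_ids = samples, normal_ids = character())
}
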