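# tiny deterministic genome for exhaustive checks
toy_genome <- function(seed = 9, n_genes = 5, gene_length = 300) {
  cfg <- dft1_config(n_tumours = 4, genome_scale = 1 / 20000, seed = seed)
  with_seed <- devilclones:::with_seed
  with_seed(seed, simulate_genome(cfg, n_genes = n_genes,
                                  gene_length = gene_length, n_l1 = 2))
}

test_that("impact classification follows the genetic code", {
  g <- toy_genome()
  gene <- g$genes[1, ]
  ci <- match(gene$chrom, g$chrom$name)
  cds <- as.character(Biostrings::subseq(g$sequence[[ci]], gene$start, gene$end))

  ## find a codon position giving Leu->Leu (synonymous third position)
  find_case <- function(want) {
    for (off in 0:(nchar(cds) - 1)) {
      codon <- substr(cds, (off %/% 3) * 3 + 1, (off %/% 3) * 3 + 3)
      pos_in <- off %% 3 + 1
      for (alt in setdiff(c("A", "C", "G", "T"), substr(codon, pos_in, pos_in))) {
        alt_codon <- codon
        substr(alt_codon, pos_in, pos_in) <- alt
        aa0 <- Biostrings::GENETIC_CODE[[codon]]
        aa1 <- Biostrings::GENETIC_CODE[[alt_codon]]
        type <- if (aa1 == aa0) "synonymous" else if (aa1 == "*") "nonsense"
                else "missense"
        if (type == want)
          return(data.frame(chrom = gene$chrom, pos = gene$start + off,
                            ref = substr(codon, pos_in, pos_in), alt = alt,
                            class = "substitution"))
      }
    }
    NULL
  }
  for (want in c("synonymous", "missense", "nonsense")) {
    v <- find_case(want)
    expect_equal(classify_impact(v, gene, g), want)
  }
  del <- data.frame(chrom = gene$chrom, pos = gene$start + 10,
                    ref = "AT", alt = "A", class = "indel")
  expect_equal(classify_impact(del, gene, g), "frameshift")
  del3 <- data.frame(chrom = gene$chrom, pos = gene$start + 10,
                     ref = "ATTT", alt = "A", class = "indel")
  expect_equal(classify_impact(del3, gene, g), "inframe_indel")

  bad_gene <- gene; bad_gene$end <- gene$end - 1
  expect_error(classify_impact(del, bad_gene, g), "divisible by 3")
})

test_that("expected counts match an exhaustive site enumeration oracle", {
  g <- toy_genome()
  ## cohort variants: uniform random substitutions inside and outside CDS
  set.seed(10)
  n <- 4000
  gpos <- sample.int(g$total_length, n)
  loc <- devilclones:::global_to_chrom(g, gpos)
  ref <- alt <- character(n)
  for (ci in unique(loc$ci)) {
    sel <- loc$ci == ci
    codes <- devilclones:::chrom_codes(g, ci)
    ref[sel] <- c("A", "C", "G", "T")[codes[loc$pos[sel]]]
  }
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1), "")
  v <- data.frame(chrom = loc$chrom, pos = loc$pos, ref = ref, alt = alt,
                  class = "substitution", stringsAsFactors = FALSE)
  counts <- suppressWarnings(expected_counts(v, g$genes, g))

  ## conservation: summed expected synonymous equals observed synonymous
  expect_equal(sum(counts$expected[, "synonymous"]),
               sum(counts$observed[, "synonymous"]))

  ## oracle: loop over every CDS site x 3 alternates with its own translation
  rate <- counts$channel_rates
  for (gi in c(1, 3)) {
    gene <- g$genes[gi, ]
    ci <- match(gene$chrom, g$chrom$name)
    s <- g$sequence[[ci]]
    exp_or <- c(synonymous = 0, missense = 0, nonsense = 0)
    for (p in gene$start:gene$end) {
      tri <- as.character(Biostrings::subseq(s, p - 1, p + 1))
      refb <- substr(tri, 2, 2)
      off <- p - gene$start
      cstart <- gene$start + (off %/% 3) * 3
      codon <- as.character(Biostrings::subseq(s, cstart, cstart + 2))
      pos_in <- off %% 3 + 1
      for (altb in setdiff(c("A", "C", "G", "T"), refb)) {
        tri_p <- tri; alt_p <- altb; ref_p <- refb
        if (ref_p %in% c("G", "A")) {
          tri_p <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(tri)))
          alt_p <- as.character(Biostrings::complement(Biostrings::DNAString(altb)))
          ref_p <- as.character(Biostrings::complement(Biostrings::DNAString(refb)))
        }
        chan <- paste0(substr(tri_p, 1, 1), "[", ref_p, ">", alt_p, "]",
                       substr(tri_p, 3, 3))
        alt_codon <- codon
        substr(alt_codon, pos_in, pos_in) <- altb
        aa0 <- Biostrings::GENETIC_CODE[[codon]]
        aa1 <- Biostrings::GENETIC_CODE[[alt_codon]]
        cls <- if (aa1 == aa0) "synonymous" else if (aa1 == "*") "nonsense"
               else "missense"
        exp_or[cls] <- exp_or[cls] + rate[chan]
      }
    }
    expect_equal(unname(counts$expected[gi, c("synonymous", "missense",
                                              "nonsense")]),
                 unname(exp_or), tolerance = 1e-10)
  }

  ## no synonymous mutations -> explicit error
  v_none <- v[0, ]
  expect_error(expected_counts(v_none, g$genes, g), "synonymous")
})

test_that("dN/dS tests are calibrated and detect planted truncations", {
  g <- toy_genome()
  set.seed(11)
  n <- 6000
  gpos <- sample.int(g$total_length, n)
  loc <- devilclones:::global_to_chrom(g, gpos)
  ref <- character(n)
  for (ci in unique(loc$ci)) {
    sel <- loc$ci == ci
    codes <- devilclones:::chrom_codes(g, ci)
    ref[sel] <- c("A", "C", "G", "T")[codes[loc$pos[sel]]]
  }
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1), "")
  v <- data.frame(chrom = loc$chrom, pos = loc$pos, ref = ref, alt = alt,
                  class = "substitution", stringsAsFactors = FALSE)
  counts <- suppressWarnings(expected_counts(v, g$genes, g))
  res <- gene_dnds_test(counts)
  glob <- res$global[res$global$class == "global", ]
  expect_true(glob$lo <= 1 && glob$hi >= 1)  # neutral cohort covers omega = 1
  if (nrow(res$genes))
    expect_true(all(res$genes$q_global >= res$genes$p_global, na.rm = TRUE))

  ## planted repeated truncation: six nonsense hits in one gene
  gene <- g$genes[2, ]
  ci <- match(gene$chrom, g$chrom$name)
  s <- g$sequence[[ci]]
  trunc_rows <- list()
  for (p in gene$start:gene$end) {
    if (length(trunc_rows) == 6) break
    off <- p - gene$start
    cstart <- gene$start + (off %/% 3) * 3
    codon <- as.character(Biostrings::subseq(s, cstart, cstart + 2))
    pos_in <- off %% 3 + 1
    for (altb in setdiff(c("A", "C", "G", "T"),
                         substr(codon, pos_in, pos_in))) {
      alt_codon <- codon
      substr(alt_codon, pos_in, pos_in) <- altb
      if (Biostrings::GENETIC_CODE[[alt_codon]] == "*" &&
          Biostrings::GENETIC_CODE[[codon]] != "*") {
        trunc_rows[[length(trunc_rows) + 1L]] <-
          data.frame(chrom = gene$chrom, pos = p,
                     ref = substr(codon, pos_in, pos_in), alt = altb,
                     class = "substitution", stringsAsFactors = FALSE)
        break
      }
    }
  }
  v2 <- rbind(v[1:500, ], do.call(rbind, trunc_rows))
  counts2 <- suppressWarnings(expected_counts(v2, g$genes, g))
  expect_lt(sum(counts2$expected[2, c("nonsense", "frameshift")]), 0.5)
  res2 <- gene_dnds_test(counts2)
  hit <- res2$genes[res2$genes$gene_id == gene$gene_id, ]
  expect_lt(hit$q_truncating, 0.005)

  ## observed = expected exactly -> zero statistic, p = 1
  counts_eq <- counts
  counts_eq$observed <- counts_eq$expected
  res_eq <- gene_dnds_test(counts_eq)
  expect_true(all(abs(res_eq$genes$stat_global) < 1e-8))
  expect_true(all(res_eq$genes$p_global > 0.999))
})
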