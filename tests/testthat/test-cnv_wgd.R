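flat_bins <- function(n, depth, chrom = "chr1", bin = 1000) {
  data.frame(chrom = chrom, start = (seq_len(n) - 1) * bin,
             end = seq_len(n) * bin, depth = depth)
}

test_that("binary segmentation recovers flat, step and focal profiles", {
  seg <- segment_coverage(flat_bins(500, 1.0), purity = 1, ploidy = 2)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$cn, 2L)

  ## noiseless step 1.0 -> 1.5 at bin 500: breakpoint within 1 bin, CN 2|3
  b <- flat_bins(1000, c(rep(1.0, 500), rep(1.5, 500)))
  seg <- segment_coverage(b, purity = 1, ploidy = 2)
  expect_equal(nrow(seg), 2)
  expect_lte(abs(seg$end[1] - 500 * 1000), 1000)
  expect_equal(seg$cn, c(2L, 3L))

  expect_error(segment_coverage(flat_bins(100, 0)), "all zero")

  ## focal deletion over a gene in noisy coverage, recovered by the screen
  co <- fixture("reads_dft1")
  g <- co$genome$genes[3, ]
  prof <- data.frame(chrom = g$chrom, start = g$start - 15000,
                     end = g$end + 15000, cn = 1L)
  set.seed(4)
  bins <- simulate_coverage_bins(co$genome, prof, purity = 1, ploidy = 2,
                                 bin_size = 1000, noise_sd = 0.08)
  bins <- bins[bins$chrom == g$chrom, ]
  seg <- segment_coverage(bins, purity = 1, ploidy = 2)
  hit <- gene_deletion_screen(seg, co$genome$genes)
  expect_true(g$gene_id %in% hit$gene_id)
  expect_equal(hit$cn[hit$gene_id == g$gene_id], 1L)
  expect_true(hit$focal[hit$gene_id == g$gene_id])
  expect_false(hit$homozygous[hit$gene_id == g$gene_id])

  ## homozygous deletions are flagged distinctly
  prof0 <- transform(prof, cn = 0L)
  set.seed(5)
  bins0 <- simulate_coverage_bins(co$genome, prof0, purity = 1, ploidy = 2,
                                  bin_size = 1000, noise_sd = 0.08)
  seg0 <- segment_coverage(bins0[bins0$chrom == g$chrom, ], 1, 2)
  hit0 <- gene_deletion_screen(seg0, co$genome$genes)
  expect_true(hit0$homozygous[hit0$gene_id == g$gene_id])
})

test_that("tetraploidy calls require modal CN 4 plus bimodal VAFs", {
  dip <- data.frame(chrom = "chr1", start = 0, end = 1e6, cn = 2L)
  expect_false(call_wgd(dip, runif(300, 0.4, 0.6))$tetraploid)

  tet <- data.frame(chrom = "chr1", start = 0, end = 1e6, cn = 4L)
  set.seed(6)
  vaf_m2 <- rbinom(300, 80, 0.5) / 80
  vaf_m1 <- rbinom(300, 80, 0.25) / 80
  pc <- call_wgd(tet, c(vaf_m2, vaf_m1), purity = 1)
  expect_true(pc$tetraploid)
  expect_equal(unname(pc$modes), c(0.25, 0.5))
  ## multiplicity clusters recovered up to boundary noise
  expect_lt(abs(pc$pre_count - 300), 15)
  expect_lt(abs(pc$post_count - 300), 15)

  ## purity 0.8: modes at m * 0.8 / (4*0.8 + 2*0.2)
  pc8 <- call_wgd(tet, runif(300, 0.1, 0.5), purity = 0.8)
  expect_equal(unname(pc8$modes), c(0.8 / 3.6, 1.6 / 3.6))

  ## unimodal VAFs at CN 4 do not qualify
  pc1 <- call_wgd(tet, rbinom(300, 80, 0.5) / 80, purity = 1)
  expect_false(pc1$tetraploid)
})

test_that("WGD dating inverts the simulator's event placement", {
  expect_equal(date_wgd(100, 0, 500, 2018)$date, 2018)
  expect_equal(date_wgd(100, 1985, 496.3, 2018)$elapsed, 1985 / (2 * 496.3))
  expect_equal(round(date_wgd(100, 1985, 496.3, 2018)$elapsed, 3), 2.000)
  expect_warning(date_wgd(100, 5000, 500, 2018, lineage_total = 3000),
                 "exceeds")

  ## round trip on a simulated tetraploid tumour
  co <- fixture("reads_dft2")
  wtip <- which(!is.na(co$meta$wgd_year))[1]
  cls <- classify_germline(co$calls, host_map = co$host_map)
  som <- match(cls$somatic, co$calls$variants$id)
  vaf <- co$calls$alt[som, wtip] / pmax(co$calls$dp[som, wtip], 1)
  prof <- tip_cn_profile(co, wtip)
  set.seed(7)
  bins <- simulate_coverage_bins(co$genome, prof, purity = co$meta$purity[wtip],
                                 ploidy = 4, bin_size = 5000)
  seg <- segment_coverage(bins, purity = co$meta$purity[wtip], ploidy = 4)
  pc <- call_wgd(seg, vaf[vaf > 0.02], purity = co$meta$purity[wtip])
  expect_true(pc$tetraploid)
  est <- date_wgd(pc$pre_count, pc$post_count,
                  co$config$rates["substitution"],
                  co$meta$sampling_date[wtip], kappa = co$config$kappa)
  expect_lt(abs(est$date - co$meta$wgd_year[wtip]), 0.5)
})

test_that("LoY flags follow the sex-aware depth ratio", {
  y_ok <- flat_bins(100, 0.5, chrom = "chrY")
  auto <- flat_bins(1000, 1.0)
  expect_false(detect_loy(y_ok, auto, purity = 1)$loy)
  y_lost <- flat_bins(100, 0.01, chrom = "chrY")
  expect_true(detect_loy(y_lost, auto, purity = 1)$loy)
  expect_error(detect_loy(y_ok, auto, founder_sex = "female"), "not male")

  ## five planted loss branches yield five parsimony origins, one of them a
  ## clade stem shared by several tumours
  cfg <- dft2_config(n_tumours = 20, seed = 31)
  tr <- simulate_transmission_tree(cfg)
  cl <- devilclones:::tree_clades(tr)
  stem <- which(lengths(cl) >= 3 & lengths(cl) <= 8 &
                  seq_along(cl) > tr$n_tip + 1)[1]
  parents <- tr$parent[stem]
  picked <- stem
  for (tip in setdiff(seq_len(tr$n_tip), cl[[stem]])) {
    if (length(picked) == 5) break
    if (!(tr$parent[tip] %in% parents)) {
      picked <- c(picked, tip); parents <- c(parents, tr$parent[tip])
    }
  }
  carriers <- tr$tip_label[unlist(cl[picked])]
  origins <- map_event_to_tree(tr, carriers, "loss")
  expect_length(origins, 5)
  expect_true(stem %in% origins)
  expect_gte(length(cl[[stem]]), 3)
})

test_that("recurrence maps deduplicate mitotically inherited CNVs", {
  ## manual tree: ((A,B),(C,D)) with E outgroup
  tr <- manual_tree(c(7, 7, 8, 8, 6, 0, 6, 6),
                    c(2015, 2016, 2017, 2015, 2016, 2010, 2012, 2013),
                    c("A", "B", "C", "D", "E"))
  seg_with <- function(cnv) {
    base <- data.frame(chrom = "chr1", start = 0, end = 1e6, cn = 2L,
                       n_bins = 1000, mean_depth = 1)
    if (is.null(cnv)) return(base)
    rbind(data.frame(chrom = "chr1", start = 0, end = cnv$start, cn = 2L,
                     n_bins = 1, mean_depth = 1),
          data.frame(chrom = "chr1", start = cnv$start, end = cnv$end,
                     cn = cnv$cn, n_bins = 1, mean_depth = cnv$cn / 2),
          data.frame(chrom = "chr1", start = cnv$end, end = 1e6, cn = 2L,
                     n_bins = 1, mean_depth = 1))
  }
  amp <- list(start = 2e5, end = 3e5, cn = 3L)
  ## same CNV in sister tips A,B: one origin -> depth 1
  segs <- list(A = seg_with(amp), B = seg_with(amp), C = seg_with(NULL),
               D = seg_with(NULL), E = seg_with(NULL))
  rm1 <- recurrence_map(segs, tr, tol = 1000)
  expect_equal(rm1$events$n_origins, 1)
  expect_equal(rm1$gain_track$depth, 1)

  ## same CNV in two unrelated tips A,C: two origins -> depth 2
  segs2 <- list(A = seg_with(amp), B = seg_with(NULL), C = seg_with(amp),
                D = seg_with(NULL), E = seg_with(NULL))
  rm2 <- recurrence_map(segs2, tr, tol = 1000)
  expect_equal(rm2$events$n_origins, 2)
  expect_equal(rm2$gain_track$depth, 2)

  ## three independent hits -> depth 3; conservation of origin counts
  segs3 <- list(A = seg_with(amp), B = seg_with(NULL), C = seg_with(amp),
                D = seg_with(NULL), E = seg_with(amp))
  rm3 <- recurrence_map(segs3, tr, tol = 1000)
  expect_equal(rm3$gain_track$depth, 3)
  expect_equal(sum(rm3$events$n_origins), 3)

  ## linked CNVs: two loci sharing an identical multi-tumour carrier set
  amp2 <- list(start = 6e5, end = 7e5, cn = 3L)
  seg_two <- function() {
    s <- seg_with(amp)
    rbind(s[s$end <= 3e5 | s$start >= 3e5, ],
          data.frame(chrom = "chr1", start = c(6e5), end = c(7e5), cn = 3L,
                     n_bins = 1, mean_depth = 1.5))
  }
  segs4 <- list(A = seg_two(), B = seg_two(), C = seg_with(NULL),
                D = seg_with(NULL), E = seg_with(NULL))
  rm4 <- recurrence_map(segs4, tr, tol = 1000)
  expect_length(rm4$linked, 1)
})

test_that("arm-event enrichment reproduces the hypergeometric exact test", {
  expect_equal(arm_event_enrichment(rep(c(TRUE, FALSE), each = 10),
                                    rep(c(TRUE, FALSE), 10))$p, 1)
  r <- arm_event_enrichment(rep(c(FALSE, TRUE), each = 10),
                            rep(c(FALSE, TRUE), each = 10))
  ## enumeration oracle for table [[10,0],[0,10]]: only the two extreme
  ## tables are as unlikely as the observed one
  expect_equal(r$p, 2 * dhyper(10, 10, 10, 10))
  expect_error(arm_event_enrichment(rep(TRUE, 5), rep(TRUE, 5)), "both ploidy")

  ## planted 4x arm-event rate in tetraploids is detected
  set.seed(8)
  hits <- 0L
  for (i in 1:5) {
    tetra <- rep(c(TRUE, FALSE), c(19, 100))
    ev <- c(runif(19) < 0.8, runif(100) < 0.2)
    hits <- hits + (arm_event_enrichment(tetra, ev)$p < 0.01)
  }
  expect_gte(hits, 3L)
})

test_that("clustered rearrangement breakpoints merge into events", {
  calls <- data.frame(chrom1 = "chr1", pos1 = c(1e6, 1.004e6),
                      chrom2 = "chr2", pos2 = c(5e6, 5.002e6))
  expect_equal(merge_rearrangements(calls, gap = 10000), 1L)
  expect_equal(merge_rearrangements(calls[0, ]), 0L)
  far <- data.frame(chrom1 = "chr1", pos1 = c(1e6, 3e6),
                    chrom2 = "chr2", pos2 = c(5e6, 8e6))
  expect_equal(merge_rearrangements(far, gap = 10000), 2L)
})
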