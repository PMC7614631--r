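test_that("transmission trees respect dates, topology and polytomy options", {
  cfg <- dft1_config(n_tumours = 2, seed = 1)
  tr <- simulate_transmission_tree(cfg)
  expect_equal(tr$n_tip, 2L)
  expect_equal(length(tr$parent) - tr$n_tip, 1L)  # single internal node

  cfg <- dft1_config(n_tumours = 10, multifurcation_prob = 0, seed = 2)
  tr <- simulate_transmission_tree(cfg)
  ch <- devilclones:::tree_children(tr)
  expect_true(all(lengths(ch[(tr$n_tip + 1):length(ch)]) == 2))

  ## replicate sweep: every tip inside the window, internals after origin
  for (s in 1:60) {
    cfg <- dft1_config(n_tumours = 6, origin_year = 1986,
                       sampling_window = c(2003, 2018),
                       multifurcation_prob = 0.3, seed = s)
    tr <- simulate_transmission_tree(cfg)
    tips <- tr$date[seq_len(tr$n_tip)]
    expect_true(all(tips >= 2003 & tips <= 2018))
    expect_true(all(tr$date >= 1986))
    e <- devilclones:::tree_edges(tr)
    expect_true(all(e$duration >= 0))
  }

  expect_error(dft1_config(origin_year = 2020, sampling_window = c(2003, 2018)),
               "precedes")
})

test_that("per-branch mutation counts follow the configured Poisson clock", {
  cfg0 <- dft1_config(n_tumours = 4, seed = 5,
                      rates = c(substitution = 0, indel = 0, line1_insertion = 0,
                                rearrangement_event = 0, cnv_event = 0))
  g <- simulate_genome(cfg0, with_sequence = FALSE)
  tr <- simulate_transmission_tree(cfg0)
  sim <- simulate_mutations(tr, cfg0, g, seed = 1)
  expect_null(sim$variants)
  expect_true(all(sim$truth$tip_burden == 0))

  ## Poisson moment oracle on a fixed 10-year branch at 496.3 subs/yr
  cfg <- dft2_config(n_tumours = 2, sampling_window = c(2020.999, 2021),
                     origin_year = 2011, seed = 1)
  g2 <- simulate_genome(cfg, with_sequence = FALSE)
  tr2 <- simulate_transmission_tree(cfg)
  ## force both tip branches to span exactly 10 years from the root
  tr2$date[] <- c(2021, 2021, 2011)
  reps <- 600
  counts <- vapply(seq_len(reps), function(i) {
    s <- simulate_mutations(tr2, cfg, g2, detail = "counts", seed = 1000 + i)
    sum(s$truth$branch_counts$substitution)
  }, 0)
  mu <- mean(counts) / 2          # two 10-year branches per replicate
  se <- sd(counts / 2) / sqrt(reps)
  expect_lt(abs(mu - 4963), 3 * se)
})

test_that("substitution channels follow the signature mixture", {
  cfg <- dft1_config(n_tumours = 4, genome_scale = 1 / 1000,
                     signature_mix = list(sbs = c(SBS1 = 0.08, SBS5 = 0.92),
                                          indel = c(ID1 = 0.66, ID2 = 0.34)),
                     seed = 7)
  g <- simulate_genome(cfg, with_sequence = FALSE)
  tr <- simulate_transmission_tree(cfg)
  sim <- simulate_mutations(tr, cfg, g, seed = 3)
  chan <- sim$variants$channel[sim$variants$class == "substitution"]
  refs <- reference_signatures("sbs")
  mix <- 0.08 * refs[, "SBS1"] + 0.92 * refs[, "SBS5"]
  cpg <- grepl("\\[C>T\\]G", names(mix))
  p_expect <- sum(mix[cpg])
  p_obs <- mean(grepl("\\[C>T\\]G", chan))
  n <- length(chan)
  expect_lt(abs(p_obs - p_expect), 4 * sqrt(p_expect * (1 - p_expect) / n))
})

test_that("bulk sampling reproduces the expected VAF formula", {
  v <- data.frame(id = "x")
  expect_equal(make_bulk_sample(v, purity = 1, depth_mean = 80,
                                seed = 1)$vaf_expected, 0.5)
  expect_equal(make_bulk_sample(v, purity = 0.8, depth_mean = 80,
                                seed = 1)$vaf_expected, 0.4)
  ## subclone-private variants in a 60/40 mixture at purity 1
  v2 <- data.frame(id = c("a", "b"), subclone = c(1L, 2L))
  b <- make_bulk_sample(v2, purity = 1, depth_mean = 80,
                        subclone_mix = c(0.6, 0.4), seed = 1)
  expect_equal(b$vaf_expected, c(0.30, 0.20))
  ## germline sites sit at 0.5 irrespective of purity
  v3 <- data.frame(id = "g", germline = TRUE)
  expect_equal(make_bulk_sample(v3, purity = 0.6, seed = 1)$vaf_expected, 0.5)
  expect_error(make_bulk_sample(v, depth_mean = 0), "depth_mean")
})

test_that("truth table conserves per-tip burdens and seeds are reproducible", {
  co <- fixture("reads_dft1")
  m <- truth_mutation_matrix(co)
  ## tip clonal variant count equals the sum over its ancestral branches
  sub_burden <- co$truth$tip_burden[, "substitution"]
  expect_equal(unname(rowSums(m)), unname(sub_burden))

  cfg <- dft1_config(n_tumours = 5, genome_scale = 1 / 2000, seed = 77)
  a <- simulate_cohort(cfg, detail = "variants", n_normals = 4)
  b <- simulate_cohort(cfg, detail = "variants", n_normals = 4)
  expect_identical(a$variants, b$variants)
  expect_identical(a$meta, b$meta)
  expect_identical(a$truth$branch_counts, b$truth$branch_counts)
})
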