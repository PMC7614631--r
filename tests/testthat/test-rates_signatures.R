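test_that("spectra follow the pyrimidine-strand convention", {
  co <- fixture("reads_dft2")
  v <- co$variants[co$variants$class %in% c("substitution", "indel"), ]
  spec <- build_spectrum(v, co$genome)
  expect_equal(sum(spec$sbs), sum(v$class == "substitution"))

  ## purine-reference variants land on the reverse-complement channel:
  ## sequence-derived channels equal the simulator's drawn channels
  spec_truth <- spectrum_from_channels(v)
  expect_equal(spec$sbs, spec_truth$sbs)
  expect_equal(spec$indel, spec_truth$indel)

  ## a G>A substitution checked by hand against its genomic context
  gsub <- v[v$class == "substitution" & v$ref == "G", ][1, ]
  ci <- match(gsub$chrom, co$genome$chrom$name)
  tri <- as.character(Biostrings::subseq(co$genome$sequence[[ci]],
                                         gsub$pos - 1, gsub$pos + 1))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(tri)))
  alt_rc <- as.character(Biostrings::complement(Biostrings::DNAString(gsub$alt)))
  chan <- paste0(substr(rc, 1, 1), "[C>", alt_rc, "]", substr(rc, 3, 3))
  expect_equal(chan, gsub$channel)

  ## empty input and brute-force channel oracle
  empty <- build_spectrum(v[0, ], co$genome)
  expect_true(all(empty$sbs == 0) && all(empty$indel == 0))
  sv <- v[v$class == "substitution", ][1:200, ]
  oracle <- table(vapply(seq_len(nrow(sv)), function(i) {
    x <- sv[i, ]
    ci <- match(x$chrom, co$genome$chrom$name)
    tri <- as.character(Biostrings::subseq(co$genome$sequence[[ci]],
                                           x$pos - 1, x$pos + 1))
    ref <- x$ref; alt <- x$alt
    if (ref %in% c("G", "A")) {
      tri <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(tri)))
      alt <- as.character(Biostrings::complement(Biostrings::DNAString(alt)))
      ref <- as.character(Biostrings::complement(Biostrings::DNAString(ref)))
    }
    paste0(substr(tri, 1, 1), "[", ref, ">", alt, "]", substr(tri, 3, 3))
  }, ""))
  spec200 <- build_spectrum(sv, co$genome)
  expect_equal(spec200$sbs[names(oracle)], unclass(oracle)[names(oracle)],
               ignore_attr = TRUE)
  ## positions outside the reference are rejected
  bad <- sv[1, ]; bad$pos <- 10^9
  expect_error(build_spectrum(bad, co$genome), "outside")
})

test_that("NNLS exposure fitting is exact on pure and mixed signatures", {
  refs <- reference_signatures("sbs")
  x <- 1000 * refs[, "SBS1"]
  f <- fit_signatures(setNames(as.numeric(x), rownames(refs)), refs)
  expect_equal(unname(f$exposures["SBS1"]), 1000, tolerance = 1e-6)
  expect_lt(f$residual, 1e-6)
  expect_equal(unname(f$exposures["SBS5"]), 0)

  ## indel mixes recovered within 5 points
  idr <- reference_signatures("indel")
  for (mix in list(c(ID1 = 0.66, ID2 = 0.34), c(ID1 = 0.47, ID2 = 0.53))) {
    set.seed(9)
    counts <- rmultinom(1, 2000, idr[, names(mix)] %*% mix)[, 1]
    f <- fit_signatures(setNames(counts, rownames(idr)),
                        idr[, c("ID1", "ID2")])
    share <- f$exposures["ID1"] / sum(f$exposures)
    expect_lt(abs(share - mix["ID1"]), 0.05)
  }

  ## degenerate identical profiles are flagged
  dup <- cbind(A = refs[, "SBS5"], B = refs[, "SBS5"])
  expect_warning(fit_signatures(setNames(as.numeric(x), rownames(refs)), dup),
                 "identical")
})

test_that("burden regression matches closed forms and flags n.s. classes", {
  r <- 123.4
  fit <- burden_regression(c(0, r, 2 * r), c(2000, 2001, 2002))
  expect_equal(fit$slope, r)
  expect_lt(fit$p, 1e-6)

  flat <- burden_regression(rep(5, 6), 2000:2005)
  expect_equal(flat$slope, 0)
  expect_false(flat$significant)

  expect_error(burden_regression(c(1, 2, 3), rep(2000, 3)), "one sampling date")
  expect_error(burden_regression(1:2, 1:2), "3 samples")
})

test_that("rate ratios propagate uncertainty and respect suppression rules", {
  dft1 <- rate_fit(163.2, c(119.6, 206.8), n = 62)
  dft2 <- rate_fit(496.3, c(436.0, 556.5), n = 41)
  rr <- rate_ratio(dft1, dft2)
  expect_equal(round(rr$ratio, 3), 3.041)
  sbs5 <- rate_ratio(rate_fit(150.6, c(108.8, 192.4), n = 62),
                     rate_fit(479.2, c(422.1, 536.4), n = 41))
  expect_equal(round(sbs5$ratio, 3), 3.182)

  expect_equal(rate_ratio(dft1, dft1)$ratio, 1.0)
  ## reciprocity is exact
  expect_equal(rate_ratio(dft1, dft2)$ratio * rate_ratio(dft2, dft1)$ratio, 1.0)

  ## delta interval against a Monte-Carlo propagation oracle (small CVs)
  a <- rate_fit(200, c(190, 210), n = 100)
  b <- rate_fit(600, c(580, 620), n = 100)
  rr2 <- rate_ratio(a, b)
  set.seed(1)
  mc <- quantile(rnorm(1e5, b$slope, b$se) / rnorm(1e5, a$slope, a$se),
                 c(0.025, 0.975))
  expect_lt(abs(rr2$ci["lo"] - mc[1]) / rr2$ratio, 0.02)
  expect_lt(abs(rr2$ci["hi"] - mc[2]) / rr2$ratio, 0.02)

  ## non-significant denominator suppresses the ratio with a reason
  ns <- rate_fit(-0.2, c(-0.35, 0.04), p = 0.3)
  out <- rate_ratio(ns, dft2)
  expect_true(is.na(out$ratio))
  expect_match(out$reason, "denominator")
})

test_that("clade rate shifts are detected with calibrated type-I error", {
  build_cohort_burdens <- function(seed, offset_branch = NULL, offset = 0) {
    cfg <- dft1_config(n_tumours = 40, seed = seed,
                       rates = c(substitution = 202, indel = 0,
                                 line1_insertion = 0, rearrangement_event = 0,
                                 cnv_event = 0))
    co <- simulate_cohort(cfg, detail = "counts")
    burden <- co$truth$tip_burden[, "substitution"]
    clades <- devilclones:::tree_clades(co$tree)
    if (!is.null(offset_branch)) {
      v <- which(lengths(clades) >= 10 & lengths(clades) <= 25 &
                   seq_along(clades) > co$tree$n_tip)[1]
      burden[clades[[v]]] <- burden[clades[[v]]] + offset
      offset_branch <- v
    }
    list(tree = co$tree, burden = burden,
         dates = setNames(co$meta$sampling_date, co$meta$sample_id),
         branch = offset_branch)
  }

  ## null calibration under the model's own assumptions (independent Poisson
  ## noise around the clock line; shared-branch deviations are a documented
  ## limitation of the unweighted regression)
  false_hits <- 0L
  for (s in 1:8) {
    d <- build_cohort_burdens(700 + s)
    set.seed(s)
    indep <- rpois(length(d$dates), 202 * (d$dates - 1986))
    names(indep) <- names(d$dates)
    sh <- detect_rate_shift(d$tree, indep, d$dates)
    false_hits <- false_hits + (nrow(sh) > 0 && min(sh$q) < 0.05)
  }
  expect_lte(false_hits, 1L)

  ## planted -1200 deficit: flagged and estimated within 20%
  d <- build_cohort_burdens(901, offset_branch = TRUE, offset = -1200)
  sh <- detect_rate_shift(d$tree, d$burden, d$dates)
  top <- sh[1, ]
  expect_lt(top$q, 0.05)
  expect_equal(top$node, d$branch)
  expect_lt(abs(abs(top$offset) - 1200) / 1200, 0.2)
})

test_that("hypermutators are flagged with their fold-excess", {
  dates <- seq(2004, 2018, length.out = 15)
  burden <- 200 * (dates - 1986)
  expect_false(any(flag_hypermutators(burden, dates)$flagged))

  set.seed(2)
  noisy <- rpois(15, burden)
  noisy[8] <- round(6 * 200 * (dates[8] - 1986))
  indels <- rpois(15, 22 * (dates - 1986))
  indels[8] <- round(10 * 22 * (dates[8] - 1986))
  names(noisy) <- names(indels) <- paste0("T", 1:15)
  fsub <- flag_hypermutators(noisy, dates)
  find <- flag_hypermutators(indels, dates)
  expect_true(fsub$flagged[8] && find$flagged[8])
  expect_equal(sum(fsub$flagged), 1)
  expect_lt(abs(fsub$fold[8] - 6), 1.2)
  expect_lt(abs(find$fold[8] - 10), 2.0)

  ## flags are monotonically non-increasing in the threshold
  nflags <- vapply(c(1.5, 2, 3, 5, 8, 12),
                   function(th) sum(flag_hypermutators(noisy, dates,
                                                       multiplier = th)$flagged),
                   0L)
  expect_true(all(diff(nflags) <= 0))
})

test_that("hypermutator lineages carry the mismatch-repair signatures", {
  cfg <- dft1_config(n_tumours = 6, genome_scale = 1 / 1000, seed = 55,
                     hypermutator = list(branch = 1L, substitution_mult = 6,
                                         indel_mult = 10, extra_sbs = "SBS6",
                                         extra_id = "ID7"))
  co <- simulate_cohort(cfg, detail = "variants", n_normals = 2)
  hyper_tip <- 1L
  v <- co$variants[co$variants$branch == hyper_tip, ]
  spec <- spectrum_from_channels(v)
  f <- fit_signatures(spec, reference_signatures("sbs"))
  ## the terminal branch's excess is dominated by the extra signature
  expect_gt(f$exposures["SBS6"] / sum(f$exposures), 0.5)
  fi <- fit_signatures(spec, reference_signatures("indel"), family = "indel")
  expect_gt(fi$exposures["ID7"] / sum(fi$exposures), 0.5)
  ## and the burden multipliers are visible in the truth table
  b <- co$truth$tip_burden
  other <- b[-hyper_tip, "substitution"] /
    (co$meta$sampling_date[-hyper_tip] - 1986)
  hyper_rate <- b[hyper_tip, "substitution"] /
    (co$meta$sampling_date[hyper_tip] - 1986)
  expect_gt(hyper_rate / mean(other), 2)  # x6 applies to the terminal branch only
})
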