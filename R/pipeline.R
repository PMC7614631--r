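#' True copy-number profile of one simulated tumour
#'
#' Reconstructs the tumour's integer copy-number segments from the truth
#' events on its root-to-tip path: the diploid baseline (sex chromosomes per
#' founder sex), CNV events ordered against any WGD (pre-duplication events
#' are doubled with the genome), and loss of chromosome Y.
#'
#' @param cohort a simulated cohort.
#' @param tip tip index or label.
#' @return data frame `chrom,start,end,cn` (0-based half-open).
#' @export
tip_cn_profile <- function(cohort, tip) {
  if (is.character(tip)) tip <- match(tip, cohort$tree$tip_label)
  path <- path_to_root(cohort$tree, tip)
  male <- cohort$config$founder_sex == "male"
  wgd_year <- cohort$meta$wgd_year[tip]
  ev <- cohort$cnv_events
  ev <- if (is.null(ev)) ev else ev[ev$branch %in% path, , drop = FALSE]
  out <- lapply(seq_len(nrow(cohort$genome$chrom)), function(ci) {
    nm <- cohort$genome$chrom$name[ci]
    L <- cohort$genome$chrom$length[ci]
    base <- if (nm == "chrY") (if (male) 1 else 0)
            else if (nm == "chrX") (if (male) 1 else 2) else 2
    ce <- if (is.null(ev)) NULL else ev[ev$chrom == nm, , drop = FALSE]
    bp <- sort(unique(c(0, L, ce$start, ce$end)))
    seg <- data.frame(chrom = nm, start = bp[-length(bp)], end = bp[-1])
    seg$cn <- vapply(seq_len(nrow(seg)), function(i) {
      pre <- post <- 0
      if (!is.null(ce) && nrow(ce)) {
        hit <- ce$start <= seg$start[i] & ce$end >= seg$end[i]
        if (!is.na(wgd_year)) {
          pre <- sum(ce$delta[hit & ce$time < wgd_year])
          post <- sum(ce$delta[hit & ce$time >= wgd_year])
        } else pre <- sum(ce$delta[hit])
      }
      cn <- if (!is.na(wgd_year)) (base + pre) * 2 + post else base + pre
      max(cn, 0)
    }, 0)
    if (nm == "chrY" && (cohort$meta$loy[tip] || !male)) seg$cn <- 0
    seg
  })
  d <- do.call(rbind, out)
  rownames(d) <- NULL
  d
}

#' Whether a simulated tumour carries an arm-scale CNV event
#'
#' @param cohort a simulated cohort.
#' @param tip tip index or label.
#' @return logical.
#' @export
tip_has_arm_event <- function(cohort, tip) {
  if (is.character(tip)) tip <- match(tip, cohort$tree$tip_label)
  path <- path_to_root(cohort$tree, tip)
  ev <- cohort$cnv_events
  !is.null(ev) && any(ev$arm_scale & ev$branch %in% path)
}

#' Run the full clonal-evolution pipeline on a simulated cohort
#'
#' Orchestrates simulate -> somatic filter -> tree -> clock -> subclones ->
#' spectra/signatures/rates -> CNV/WGD/LoY -> dN/dS -> LINE-1 -> report.
#' Stages can be toggled; later stages that depend on a disabled stage are
#' skipped. All seeds and thresholds are recorded in the report, which is
#' also written as JSON when `out_dir` is given.
#'
#' @param config a [cohort_config()].
#' @param stages character vector of stage names to run (default all):
#'   `simulate, filter, tree, clock, subclones, rates, cnv, dnds, l1`.
#' @param out_dir optional output directory for `report.json`.
#' @param seed master seed (defaults to `config$seed`, else 1).
#' @param n_normals normal panel size.
#' @param clock_iterations,clock_burn_in MCMC settings for the clock stage.
#' @return a `pipeline_report` list.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "filter", "tree", "clock",
                                    "subclones", "rates", "cnv", "dnds", "l1"),
                         out_dir = NULL, seed = NULL, n_normals = 20,
                         clock_iterations = 50000, clock_burn_in = 10000) {
  seed <- seed %||% config$seed %||% 1L
  t0 <- Sys.time()
  report <- list(schema = "devilclones-report/1",
                 package_version = as.character(utils::packageVersion("devilclones")),
                 clone = config$clone_label, seed = seed,
                 stages = stages)
  run_stage <- function(name, expr) {
    if (!(name %in% stages)) return(NULL)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  cohort <- run_stage("simulate",
                      simulate_cohort(config, detail = "reads",
                                      n_normals = n_normals, seed = seed))
  if (is.null(cohort)) stop("the 'simulate' stage is required", call. = FALSE)
  scaled_genome <- cohort$genome$total_length
  report$n_tumours <- cohort$tree$n_tip

  filt <- run_stage("filter", {
    cls <- classify_germline(cohort$calls, host_map = cohort$host_map)
    het <- count_het_sites(cohort$calls, cohort$calls$normal_ids, cls$germline)
    hz <- heterozygosity_per_kb(het, scaled_genome)
    pur <- vapply(seq_len(cohort$tree$n_tip), function(t) {
      som <- match(cls$somatic, cohort$calls$variants$id)
      vaf <- cohort$calls$alt[som, t] / pmax(cohort$calls$dp[som, t], 1)
      estimate_purity(vaf[vaf > 0.05])$purity
    }, 0)
    list(cls = cls, het = hz, purity_est = setNames(pur, cohort$meta$sample_id))
  })
  if (!is.null(filt)) {
    report$somatic_count <- unname(filt$cls$counts["somatic"])
    report$germline_count <- unname(filt$cls$counts["germline"])
    report$ambiguous_count <- unname(filt$cls$counts["ambiguous"])
    report$het_per_kb_median <- filt$het$median
    report$het_per_kb_range <- filt$het$range
  }

  phy <- run_stage("tree", {
    stop_if_not(!is.null(filt), "tree stage needs the filter stage")
    som_sub <- with(cohort$calls$variants,
                    id[id %in% filt$cls$somatic & class == "substitution"])
    m <- build_mutation_matrix(cohort$calls, variant_ids = som_sub,
                               purity = setNames(cohort$meta$purity,
                                                 cohort$meta$sample_id))
    build_tree(m, dates = setNames(cohort$meta$sampling_date,
                                   cohort$meta$sample_id))
  })
  if (!is.null(phy)) report$tree <- list(
    conflict_fraction = phy$conflict_fraction,
    newick_mutations = ape::write.tree(as_phylo(phy, "mutations")))

  clock <- run_stage("clock", {
    stop_if_not(!is.null(phy), "clock stage needs the tree stage")
    fit <- fit_strict_clock(phy, seed = seed, iterations = clock_iterations,
                            burn_in = clock_burn_in)
    shared <- sum(filt$cls$ambiguous %in%
                    cohort$calls$variants$id[cohort$calls$variants$class ==
                                               "substitution"])
    origin <- origin_interval_with_ambiguity(fit, shared, seed = seed)
    list(fit = fit, origin = origin,
         polytomies = detect_polytomies(fit))
  })
  if (!is.null(clock)) report$clock <- list(
    rate = as.list(clock$fit$rate), mrca = as.list(clock$fit$root),
    origin = clock$origin[c("median", "lo", "hi", "f_prior")],
    origin_date = as.character(calendar_date(clock$origin$median)),
    polytomies = clock$polytomies,
    convergence = as.list(clock$fit$convergence))

  subcl <- run_stage("subclones", {
    stop_if_not(!is.null(filt), "subclones stage needs the filter stage")
    som <- match(filt$cls$somatic, cohort$calls$variants$id)
    out <- list()
    for (t in seq_len(cohort$tree$n_tip)) {
      a <- cohort$calls$alt[som, t]; d <- cohort$calls$dp[som, t]
      use <- a / pmax(d, 1) > 0.05
      model <- detect_subclones(a[use], d[use],
                                purity = cohort$meta$purity[t], seed = seed)
      if (model$k >= 2 && !model$underpowered) {
        ids <- filt$cls$somatic[use]
        sp <- split_subclones(model, ids)
        placement <- if (!is.null(phy))
          place_on_tree(sp$subclones, phy) else NULL
        out[[cohort$meta$sample_id[t]]] <-
          list(model = model, split = sp, placement = placement)
      }
    }
    out
  })
  if (!is.null(subcl)) report$subclones <- lapply(subcl, function(s)
    list(k = s$model$k, fractions = s$model$fractions,
         placement = s$placement))

  rates <- run_stage("rates", {
    stop_if_not(!is.null(filt), "rates stage needs the filter stage")
    som <- cohort$calls$variants[cohort$calls$variants$id %in% filt$cls$somatic, ]
    pres <- build_mutation_matrix(cohort$calls, variant_ids = som$id,
                                  purity = setNames(cohort$meta$purity,
                                                    cohort$meta$sample_id))
    dates <- setNames(cohort$meta$sampling_date, cohort$meta$sample_id)
    burdens <- sapply(c("substitution", "indel", "line1_insertion"),
                      function(cl) {
      ids <- som$id[som$class == cl]
      rowSums(pres[, colnames(pres) %in% ids, drop = FALSE])
    })
    fits <- apply(burdens, 2, function(b) tryCatch(
      burden_regression(b, dates[rownames(burdens)]), error = function(e) NULL))
    hyper <- flag_hypermutators(burdens[, "substitution"],
                                dates[rownames(burdens)])
    shift <- if (!is.null(phy))
      detect_rate_shift(phy, burdens[, "substitution"],
                        dates[rownames(burdens)]) else NULL
    spectrum <- if (!is.null(cohort$genome$sequence))
      build_spectrum(som[som$class %in% c("substitution", "indel"), ],
                     cohort$genome)
      else spectrum_from_channels(som)
    refs_s <- reference_signatures("sbs"); refs_i <- reference_signatures("indel")
    exp_s <- fit_signatures(spectrum, refs_s[, c("SBS1", "SBS5"), drop = FALSE])
    exp_i <- fit_signatures(spectrum, refs_i[, c("ID1", "ID2"), drop = FALSE],
                            family = "indel")
    list(fits = fits, hyper = hyper, shift = shift, spectrum = spectrum,
         exposures = list(sbs = exp_s, indel = exp_i))
  })
  if (!is.null(rates)) report$rates <- list(
    slopes = lapply(Filter(Negate(is.null), rates$fits), function(f)
      list(slope = f$slope, ci = as.list(f$ci), p = f$p,
           significant = f$significant)),
    hypermutators = rates$hyper[rates$hyper$flagged, , drop = FALSE],
    rate_shift_top = if (!is.null(rates$shift) && nrow(rates$shift))
      rates$shift[1, ] else NULL,
    exposures = list(sbs = as.list(rates$exposures$sbs$exposures),
                     indel = as.list(rates$exposures$indel$exposures)))

  cnv <- run_stage("cnv", {
    segs <- list(); ploidy_calls <- list()
    arm_ev <- tetra <- logical(cohort$tree$n_tip)
    wgd_dates <- list()
    rate_est <- if (!is.null(clock)) clock$fit$rate else
      c(median = unname(cohort$config$rates["substitution"]), lo = NA, hi = NA)
    som <- match(filt$cls$somatic, cohort$calls$variants$id)
    loy_flags <- rep(NA, cohort$tree$n_tip)
    for (t in seq_len(cohort$tree$n_tip)) {
      sm <- cohort$meta$sample_id[t]
      host_male <- cohort$meta$host_sex[t] == "male"
      prof <- tip_cn_profile(cohort, t)
      bins <- simulate_coverage_bins(
        cohort$genome, prof, purity = cohort$meta$purity[t],
        ploidy = cohort$meta$ploidy[t],
        host_cn = c(chrX = if (host_male) 1 else 2,
                    chrY = if (host_male) 1 else 0),
        bin_size = 5000)
      segs[[sm]] <- segment_coverage(bins, purity = cohort$meta$purity[t],
                                     ploidy = cohort$meta$ploidy[t])
      a <- cohort$calls$alt[som, t]; d <- cohort$calls$dp[som, t]
      vaf <- a / pmax(d, 1)
      pc <- call_wgd(segs[[sm]], vaf[vaf > 0.02],
                     purity = cohort$meta$purity[t])
      ploidy_calls[[sm]] <- pc
      tetra[t] <- pc$tetraploid
      arm_ev[t] <- tip_has_arm_event(cohort, t)
      if (pc$tetraploid)
        wgd_dates[[sm]] <- date_wgd(pc$pre_count, pc$post_count, rate_est,
                                    cohort$meta$sampling_date[t],
                                    kappa = cohort$config$kappa)
      if (cohort$config$founder_sex == "male")
        loy_flags[t] <- detect_loy(bins[bins$chrom == "chrY", ],
                                   bins[bins$chrom %in% paste0("chr", 1:7), ],
                                   purity = cohort$meta$purity[t],
                                   ploidy = cohort$meta$ploidy[t],
                                   host_male_fraction = as.numeric(host_male))$loy
    }
    enrich <- if (length(unique(tetra)) == 2)
      arm_event_enrichment(tetra, arm_ev) else NULL
    loy_origins <- if (isTRUE(any(loy_flags)) && !is.null(phy))
      map_event_to_tree(phy, cohort$meta$sample_id[which(loy_flags)], "loss")
      else integer()
    recur <- if (!is.null(phy)) recurrence_map(segs, phy, tol = 5000) else NULL
    list(segments = segs, ploidy = ploidy_calls, wgd_dates = wgd_dates,
         enrichment = enrich, loy = loy_flags, loy_origins = loy_origins,
         recurrence = recur)
  })
  if (!is.null(cnv)) report$cnv <- list(
    n_tetraploid = sum(vapply(cnv$ploidy, `[[`, TRUE, "tetraploid")),
    wgd_dates = lapply(cnv$wgd_dates, function(w) w[c("date", "lo", "hi")]),
    arm_enrichment_p = if (!is.null(cnv$enrichment)) cnv$enrichment$p else NULL,
    n_loy = sum(cnv$loy, na.rm = TRUE),
    loy_origins = cnv$loy_origins,
    n_recurrent_cnvs = if (!is.null(cnv$recurrence))
      sum(cnv$recurrence$events$n_origins > 1) else NULL)

  dnds <- run_stage("dnds", {
    stop_if_not(!is.null(cohort$genome$sequence),
                "dnds stage needs a genome with sequence")
    som <- cohort$calls$variants[cohort$calls$variants$id %in% filt$cls$somatic, ]
    names(som)[names(som) == "alt_allele"] <- "alt"
    counts <- expected_counts(som, cohort$genome$genes, cohort$genome)
    gene_dnds_test(counts)
  })
  if (!is.null(dnds)) report$dnds <- list(
    global = dnds$global,
    top_genes = head(dnds$genes, 5))

  l1 <- run_stage("l1", {
    ins <- cohort$variants[cohort$variants$class == "line1_insertion", ,
                           drop = FALSE]
    if (!nrow(ins)) list(attribution = NULL, rate = NULL)
    else {
      att <- attribute_sources(ins, cohort$genome$l1)
      clades <- tree_clades(cohort$tree)
      carriers <- setNames(lapply(ins$branch, function(b)
        cohort$tree$tip_label[clades[[b]]]), ins$id)
      act <- if (!is.null(phy))
        source_activity_by_node(att$attribution, carriers, phy) else NULL
      burden <- cohort$truth$tip_burden[, "line1_insertion"]
      rate <- tryCatch(insertion_rate(burden,
                                      setNames(cohort$meta$sampling_date,
                                               cohort$meta$sample_id)[names(burden)]),
                       error = function(e) NULL)
      list(attribution = att, activity = act, rate = rate)
    }
  })
  if (!is.null(l1)) report$l1 <- list(
    top_sources = if (!is.null(l1$attribution)) head(l1$attribution$activity, 5),
    n_orphan = if (!is.null(l1$attribution)) l1$attribution$n_orphan,
    rate = if (!is.null(l1$rate))
      list(slope = l1$rate$slope, ci = as.list(l1$rate$ci),
           significant = l1$rate$significant))

  report$runtime_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         pretty = TRUE)
  }
  structure(c(report, list(cohort = cohort, results = list(
    filter = filt, phy = phy, clock = clock, subclones = subcl,
    rates = rates, cnv = cnv, dnds = dnds, l1 = l1))),
    class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>", x$clone, "-", x$n_tumours, "tumours; stages:",
      paste(x$stages, collapse = ", "), "\n")
  if (!is.null(x$clock))
    cat(sprintf("  origin %.1f [%.1f-%.1f]; rate %.1f subs/genome/yr\n",
                x$clock$origin$median, x$clock$origin$lo, x$clock$origin$hi,
                x$clock$rate$median))
  invisible(x)
}
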