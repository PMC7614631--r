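#' Simulate bulk allele counts for one tumour sample
#'
#' Draws a per-variant total depth from Poisson(`depth_mean`) and alt reads
#' from Binomial(depth, expected VAF), where for a somatic variant
#' \deqn{VAF = purity \cdot multiplicity \cdot cellfraction /
#'   (purity \cdot copies + 2 (1 - purity))}
#' with `copies` the local tumour total copy number. Germline heterozygous
#' sites are emitted at VAF 0.5 irrespective of purity (host and tumour cells
#' share them).
#'
#' @param variants data frame with one row per variant; optional columns
#'   `multiplicity` (default 1), `cell_fraction` (default 1), `local_copies`
#'   (default 2), `germline` (default `FALSE`), and `subclone` (integer
#'   component index into `subclone_mix`, `NA` = clonal).
#' @param purity tumour cell fraction of the bulk sample.
#' @param depth_mean mean sequencing depth; must be positive.
#' @param subclone_mix optional numeric vector of subclone cell fractions
#'   summing to 1; rows with `subclone = j` get `cell_fraction = subclone_mix[j]`.
#' @param seed optional seed.
#' @return the input frame with columns `dp`, `alt` and `vaf_expected` added.
#' @export
make_bulk_sample <- function(variants, purity = 1, depth_mean = 83,
                             subclone_mix = NULL, seed = NULL) {
  stop_if_not(depth_mean > 0, "depth_mean must be positive")
  stop_if_not(purity >= 0 && purity <= 1, "purity must lie in [0, 1]")
  if (!is.null(subclone_mix))
    stop_if_not(abs(sum(subclone_mix) - 1) < 1e-8,
                "subclone fractions must sum to 1")
  with_seed(seed, {
    n <- nrow(variants)
    mult <- variants$multiplicity %||% rep(1, n)
    cf <- variants$cell_fraction %||% rep(1, n)
    copies <- variants$local_copies %||% rep(2, n)
    germ <- variants$germline %||% rep(FALSE, n)
    if (!is.null(subclone_mix) && !is.null(variants$subclone)) {
      j <- variants$subclone
      cf <- ifelse(is.na(j), cf, subclone_mix[ifelse(is.na(j), 1L, j)])
    }
    vaf <- purity * mult * cf / (purity * copies + 2 * (1 - purity))
    vaf[germ] <- 0.5
    vaf <- pmin(pmax(vaf, 0), 1)
    dp <- rpois(n, depth_mean)
    alt <- rbinom(n, dp, vaf)
    out <- variants
    out$dp <- dp; out$alt <- alt; out$vaf_expected <- vaf
    out
  })
}

#' Simulate population germline variation
#'
#' Generates a pool of germline heterozygous sites with per-variant population
#' heterozygosity and per-host scaling, yielding per-sample heterozygosity
#' rates centred on `config$het_per_kb` with realistic between-host spread.
#' The clone founder is host 1; every tumour of the clone carries the founder
#' genotype.
#'
#' @param config a [cohort_config()].
#' @param n_normals number of normal devils in the panel (founder excluded).
#' @param genome optional genome for coordinates.
#' @param seed optional seed.
#' @return list with `pool` (variant frame), `genotype` (pool x hosts logical
#'   heterozygosity matrix; column 1 is the founder) and `hosts`.
#' @export
simulate_germline <- function(config, n_normals = 20, genome = NULL,
                              seed = NULL) {
  with_seed(seed, {
    scaled <- round(config$callable_genome * config$genome_scale)
    target <- config$het_per_kb * scaled / 1000
    h <- runif(max(10, round(target / 0.325)), 0.05, 0.6)
    pool_n <- length(h)
    hosts <- c("founder", paste0("N", seq_len(n_normals)))
    a <- pmin(pmax(rnorm(length(hosts), 1, 0.12), 0.6), 1.25)
    geno <- matrix(runif(pool_n * length(hosts)) <
                     rep(pmin(h * rep(a, each = pool_n), 1), 1),
                   pool_n, length(hosts), dimnames = list(NULL, hosts))
    pos <- sort(sample.int(scaled, pool_n))
    loc <- if (!is.null(genome)) global_to_chrom(genome, pos)
           else data.frame(chrom = "chr1", pos = pos)
    pool <- data.frame(id = paste0("g", seq_len(pool_n)),
                       chrom = loc$chrom, pos = loc$pos,
                       ref = sample(DNA_BASES, pool_n, replace = TRUE),
                       pop_het = h, stringsAsFactors = FALSE)
    pool$alt <- vapply(pool$ref, function(r) sample(setdiff(DNA_BASES, r), 1), "")
    list(pool = pool, genotype = geno, hosts = hosts)
  })
}

#' Simulate normalised coverage bins for one sample
#'
#' Tiles each chromosome with fixed-size bins and draws a normalised depth per
#' bin around the purity-corrected copy-number ratio
#' `(purity * CN + 2 (1 - purity)) / (purity * ploidy + 2 (1 - purity))`.
#'
#' @param genome a [simulate_genome()] result.
#' @param cn_profile data frame `chrom,start,end,cn` (0-based half-open); bins
#'   not covered use the baseline CN.
#' @param purity,ploidy sample purity and modal copy number.
#' @param baseline_cn named per-chromosome baseline copy number (defaults to
#'   `ploidy` everywhere).
#' @param host_cn named per-chromosome copy number of the contaminating host
#'   (normal) cells; defaults to 2 everywhere. Set `chrX`/`chrY` from the
#'   host's sex for realistic sex-chromosome depth.
#' @param bin_size bin width in bp (default 1000).
#' @param noise_sd Gaussian depth noise.
#' @param seed optional seed.
#' @return data frame `chrom,start,end,depth` (0-based half-open bins).
#' @export
simulate_coverage_bins <- function(genome, cn_profile = NULL, purity = 1,
                                   ploidy = 2, baseline_cn = NULL,
                                   host_cn = NULL, bin_size = 1000,
                                   noise_sd = 0.1, seed = NULL) {
  with_seed(seed, {
    out <- lapply(seq_len(nrow(genome$chrom)), function(ci) {
      L <- genome$chrom$length[ci]
      nm <- genome$chrom$name[ci]
      starts <- seq(0L, L - 1L, by = bin_size)
      ends <- pmin(starts + bin_size, L)
      cn <- rep(if (!is.null(baseline_cn)) baseline_cn[[nm]] else ploidy,
                length(starts))
      if (!is.null(cn_profile)) {
        seg <- cn_profile[cn_profile$chrom == nm, , drop = FALSE]
        for (i in seq_len(nrow(seg))) {
          hit <- starts < seg$end[i] & ends > seg$start[i]
          cn[hit] <- seg$cn[i]
        }
      }
      hcn <- if (!is.null(host_cn) && nm %in% names(host_cn)) host_cn[[nm]] else 2
      mu <- (purity * cn + hcn * (1 - purity)) /
        (purity * ploidy + 2 * (1 - purity))
      data.frame(chrom = nm, start = starts, end = ends,
                 depth = pmax(rnorm(length(starts), mu, noise_sd), 0),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}
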