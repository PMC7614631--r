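#' Configure a synthetic transmissible-cancer cohort
#'
#' A cohort configuration fixes everything the simulator needs: the clone's
#' origin year, the number of tumours and their sampling window, per-class
#' mutation rates (mutations per genome per year), the signature mixtures
#' generating substitution and indel channels, sequencing depth and purity
#' ranges, the callable genome size and the scale factor at which it is
#' simulated, and optional hypermutator, whole-genome-duplication (WGD),
#' loss-of-Y (LoY), subclone and LINE-1 source specifications.
#'
#' Rates are always expressed genome-wide (per full callable genome per year);
#' the simulated reference is `callable_genome * genome_scale` base pairs, but
#' per-branch mutation counts are drawn at the genome-wide rate, so burdens and
#' fitted slopes are directly comparable to genome-wide rates.
#'
#' @param clone_label clone name, e.g. `"DFT1"`.
#' @param origin_year decimal year at which the clone arose (tree root date).
#' @param n_tumours number of sampled tumours (tips); at least 2.
#' @param sampling_window numeric length-2, decimal-year window in which tips
#'   are sampled; must lie after `origin_year`.
#' @param rates named numeric: mutations/genome/year for classes
#'   `substitution`, `indel`, `line1_insertion`, `rearrangement_event`,
#'   `cnv_event`. All must be >= 0.
#' @param signature_mix list with elements `sbs` and `indel`, each a named
#'   weight vector over packaged signatures, summing to 1.
#' @param depth_mean mean sequencing depth (reads).
#' @param purity_range length-2 vector in `[0,1]`; tumour purities are drawn
#'   uniformly from it.
#' @param callable_genome callable genome size in bp.
#' @param genome_scale fraction of the callable genome actually simulated.
#' @param het_per_kb median germline heterozygosity (het sites per kb) of the
#'   host population.
#' @param multifurcation_prob probability that an internal node is collapsed
#'   into its parent, producing polytomies (candidate superspreading events).
#' @param hypermutator optional list `(branch, substitution_mult, indel_mult,
#'   extra_sbs, extra_id)`: from branch `branch` onward, substitution and indel
#'   rates are multiplied and the excess is drawn from the extra signatures.
#' @param wgd list of lists `(branch, year)`: tetraploidization events.
#' @param kappa post-WGD rate scaling (accrual scales with DNA content).
#' @param loy integer vector of branch (node) ids that lose chromosome Y.
#' @param subclone optional list `(tumour, fractions)`: that tumour is sampled
#'   as a mixture of its own lineage and its phylogenetic sister lineage.
#' @param l1_sources optional numeric vector of per-source activity weights
#'   for LINE-1 source elements (recycled over annotated elements).
#' @param l1_transduction_prob probability an insertion carries a 3'
#'   transduction identifying its source.
#' @param founder_sex `"male"` or `"female"`; male founders carry chromosome Y.
#' @param seed optional integer seed stored with the configuration.
#' @return an object of class `cohort_config`.
#' @seealso [dft1_config()], [dft2_config()], [simulate_cohort()]
#' @export
cohort_config <- function(clone_label = "DFT1",
                          origin_year = 1986,
                          n_tumours = 63,
                          sampling_window = c(2003, 2018),
                          rates = c(substitution = 163.2, indel = 22.2,
                                    line1_insertion = 0, rearrangement_event = 1.1,
                                    cnv_event = 0.7),
                          signature_mix = list(
                            sbs = c(SBS1 = 0.08, SBS5 = 0.92),
                            indel = c(ID1 = 0.66, ID2 = 0.34)),
                          depth_mean = 83,
                          purity_range = c(0.75, 1),
                          callable_genome = 2983750195,
                          genome_scale = 1 / 300,
                          het_per_kb = 0.132,
                          multifurcation_prob = 0,
                          hypermutator = NULL,
                          wgd = list(),
                          kappa = 2,
                          loy = integer(),
                          subclone = NULL,
                          l1_sources = NULL,
                          l1_transduction_prob = 0.25,
                          founder_sex = "male",
                          seed = NULL) {
  classes <- c("substitution", "indel", "line1_insertion",
               "rearrangement_event", "cnv_event")
  miss <- setdiff(classes, names(rates))
  stop_if_not(length(miss) == 0,
              paste("rates missing for class(es):", paste(miss, collapse = ", ")))
  stop_if_not(all(rates[classes] >= 0), "all rates must be >= 0")
  stop_if_not(n_tumours >= 2, "n_tumours must be >= 2")
  stop_if_not(length(sampling_window) == 2 && diff(sampling_window) >= 0,
              "sampling_window must be an increasing length-2 vector")
  if (sampling_window[1] <= origin_year)
    stop("sampling window [", sampling_window[1], ", ", sampling_window[2],
         "] precedes or touches the clone origin year ", origin_year,
         "; tumours cannot be sampled before the clone exists", call. = FALSE)
  for (fam in names(signature_mix)) {
    w <- signature_mix[[fam]]
    stop_if_not(abs(sum(w) - 1) < 1e-8,
                paste("signature weights for", fam, "must sum to 1"))
    stop_if_not(all(w >= 0), "signature weights must be non-negative")
  }
  if (!is.null(subclone)) {
    stop_if_not(abs(sum(subclone$fractions) - 1) < 1e-8,
                "subclone fractions must sum to 1")
  }
  stop_if_not(all(purity_range >= 0 & purity_range <= 1),
              "purity_range must lie in [0, 1]")
  structure(list(
    clone_label = clone_label, origin_year = origin_year,
    n_tumours = n_tumours, sampling_window = sampling_window,
    rates = rates[classes], signature_mix = signature_mix,
    depth_mean = depth_mean, purity_range = purity_range,
    callable_genome = callable_genome, genome_scale = genome_scale,
    het_per_kb = het_per_kb, multifurcation_prob = multifurcation_prob,
    hypermutator = hypermutator, wgd = wgd, kappa = kappa, loy = loy,
    subclone = subclone, l1_sources = l1_sources,
    l1_transduction_prob = l1_transduction_prob,
    founder_sex = founder_sex, seed = seed
  ), class = "cohort_config")
}

#' DFT1- and DFT2-like cohort presets
#'
#' Presets matching the published study designs: DFT1 (origin 1986, 63 newly
#' sequenced tumours sampled 2003-2018, regression substitution rate 163.2/yr,
#' indels 22.2/yr, no LINE-1 activity, SBS1:SBS5 roughly 8:92, ID1:ID2 66:34,
#' female founder) and DFT2 (origin 2011, 41 tumours sampled 2014-2018,
#' substitutions 496.3/yr, indels 86.5/yr, LINE-1 insertions 24.1/yr,
#' ID1:ID2 47:53, male founder). Any field can be overridden via `...`.
#'
#' @param ... overrides passed to [cohort_config()].
#' @return a `cohort_config`.
#' @export
dft1_config <- function(...) {
  args <- list(
    clone_label = "DFT1", origin_year = 1986, n_tumours = 63,
    sampling_window = c(2003, 2018),
    rates = c(substitution = 163.2, indel = 22.2, line1_insertion = 0,
              rearrangement_event = 1.1, cnv_event = 0.7),
    signature_mix = list(sbs = c(SBS1 = 0.08, SBS5 = 0.92),
                         indel = c(ID1 = 0.66, ID2 = 0.34)),
    founder_sex = "female")
  args[names(list(...))] <- list(...)
  do.call(cohort_config, args)
}

#' @rdname dft1_config
#' @export
dft2_config <- function(...) {
  args <- list(
    clone_label = "DFT2", origin_year = 2011, n_tumours = 41,
    sampling_window = c(2014, 2018),
    rates = c(substitution = 496.3, indel = 86.5, line1_insertion = 24.1,
              rearrangement_event = 3.6, cnv_event = 5.6),
    signature_mix = list(sbs = c(SBS1 = 0.034, SBS5 = 0.966),
                         indel = c(ID1 = 0.47, ID2 = 0.53)),
    founder_sex = "male")
  args[names(list(...))] <- list(...)
  do.call(cohort_config, args)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config> clone", x$clone_label, "\n")
  cat("  origin", x$origin_year, "| tumours", x$n_tumours,
      "| sampling", x$sampling_window[1], "-", x$sampling_window[2], "\n")
  cat("  rates (/genome/yr):",
      paste(names(x$rates), signif(x$rates, 4), sep = "=", collapse = ", "), "\n")
  cat("  genome:", round(x$callable_genome * x$genome_scale / 1e6, 2),
      "Mb simulated (scale", signif(x$genome_scale, 3), "of",
      x$callable_genome, "bp callable)\n")
  invisible(x)
}
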