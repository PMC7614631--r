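# Shared simulated fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name) {
  if (!is.null(.fixture_env[[name]])) return(.fixture_env[[name]])
  x <- switch(name,
    # small DFT1-like cohort with read-level calls and a panel of 20 normals
    reads_dft1 = simulate_cohort(
      dft1_config(n_tumours = 8, genome_scale = 1 / 1000, depth_mean = 80,
                  seed = 101),
      detail = "reads", n_normals = 20),
    # DFT2-like cohort: LINE-1 activity, one WGD, one LoY branch, a subclone
    reads_dft2 = simulate_cohort(
      dft2_config(n_tumours = 8, genome_scale = 1 / 1000, depth_mean = 80,
                  wgd = list(list(branch = 2L, year = 2013.5)), loy = 3L,
                  subclone = list(tumour = "DFT2_T5", fractions = c(0.6, 0.4)),
                  seed = 202),
      detail = "reads", n_normals = 12),
    # burden-level DFT1-like cohort at the published design
    counts_dft1 = simulate_cohort(dft1_config(seed = 303), detail = "counts"),
    stop("unknown fixture ", name))
  .fixture_env[[name]] <- x
  x
}

# minimal hand-built dated tree:
#   parent pointers, node dates, tip labels
manual_tree <- function(parent, date, tips) {
  devilclones:::new_clone_tree(as.integer(parent), date, tips)
}

# calls object from explicit matrices (variants inherit simple metadata)
manual_calls <- function(alt, dp, germline = NULL, class = "substitution") {
  ids <- rownames(alt) %||% paste0("v", seq_len(nrow(alt)))
  list(variants = data.frame(
         id = ids, chrom = "chr1", pos = seq_len(nrow(alt)),
         ref = "A", alt_allele = "T", class = class,
         germline = germline %||% rep(FALSE, nrow(alt)),
         stringsAsFactors = FALSE),
       alt = alt, dp = dp,
       tumour_ids = grep("^T", colnames(alt), value = TRUE),
       normal_ids = grep("^N", colnames(alt), value = TRUE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
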