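#' Detect subclonal cell populations by binomial-mixture EM
#'
#' Somatic variants in copy-neutral diploid regions of a bulk tumour have
#' expected VAF `purity * cellfraction / 2`. The observed alt/total read
#' counts are modelled as a k-component binomial mixture over component VAFs;
#' EM is run for k = 1..`k_max` with `restarts` seeded restarts each, and k is
#' chosen by BIC. A clonal cluster (cell fraction ~ 1) is always permitted.
#' Samples with fewer than `min_variants` usable variants return k = 1 with
#' an `underpowered` flag.
#'
#' @param alt,dp integer vectors of alt and total read counts (copy-neutral
#'   diploid variants only; exclude CNV regions before calling).
#' @param purity tumour purity.
#' @param k_max maximum number of components (default 3; bulk ~80x depth
#'   cannot resolve more).
#' @param restarts EM restarts per k (default 10).
#' @param min_variants minimum usable variants (default 100).
#' @param min_depth variants below this depth are dropped (default 20).
#' @param max_variants at most this many variants enter the EM (a seeded
#'   subsample; binomial sampling error on the fractions at this size is far
#'   below the reporting scale).
#' @param seed seed.
#' @return a `subclone_model`: chosen `k`, `fractions` (cell fractions,
#'   decreasing), component VAFs `p`, mixture `weights`, per-variant
#'   `posteriors` (rows sum to 1), `assignment`, per-k `scores`
#'   (log-likelihood, BIC), and flags.
#' @export
detect_subclones <- function(alt, dp, purity = 1, k_max = 3, restarts = 10,
                             min_variants = 100, min_depth = 20,
                             max_variants = 5000, seed = 1) {
  keep <- !is.na(alt) & !is.na(dp) & dp >= min_depth
  alt <- alt[keep]; dp <- dp[keep]
  n <- length(alt)
  underpowered <- n < min_variants
  kmax_eff <- if (underpowered) 1L else as.integer(k_max)

  fits <- with_seed(seed, {
    if (n > max_variants) {
      sub <- sample.int(n, max_variants)
      lapply(seq_len(kmax_eff), function(k)
        best_binmix(alt[sub], dp[sub], k, restarts))
    } else
      lapply(seq_len(kmax_eff), function(k) best_binmix(alt, dp, k, restarts))
  })
  n_fit <- min(n, max_variants)
  ll <- vapply(fits, `[[`, 0, "ll")
  bic <- -2 * ll + (2 * seq_len(kmax_eff) - 1) * log(max(n_fit, 1))
  k <- which.min(bic)
  fit <- fits[[k]]
  ord <- order(-fit$p)
  p <- fit$p[ord]; w <- fit$w[ord]
  ## posteriors for the full variant set at the fitted parameters
  post <- vapply(seq_len(k), function(j)
    dbinom(alt, dp, p[j], log = TRUE) + log(w[j]), numeric(n))
  post <- matrix(post, nrow = n)
  mx <- apply(post, 1, max)
  post <- exp(post - (mx + log(rowSums(exp(post - mx)))))
  fractions <- pmin(2 * p / purity, 1)
  structure(list(
    k = k, fractions = fractions, p = p, weights = w,
    posteriors = post, assignment = max.col(post, ties.method = "first"),
    scores = data.frame(k = seq_len(kmax_eff), loglik = ll, bic = bic),
    n = n, purity = purity, underpowered = underpowered),
    class = "subclone_model")
}

## EM for a k-component binomial mixture. Restarts are run short; the best
## restart is refined to convergence (standard short-run/long-run scheme).
best_binmix <- function(alt, dp, k, restarts) {
  n <- length(alt)
  if (n == 0) return(list(ll = -Inf, p = 0.25, w = 1,
                          post = matrix(1, 0, k)))
  if (k == 1) {  # closed-form MLE
    p <- min(max(sum(alt) / max(sum(dp), 1), 1e-3), 1 - 1e-3)
    return(list(ll = sum(dbinom(alt, dp, p, log = TRUE)), p = p, w = 1,
                post = matrix(1, n, 1)))
  }
  em <- function(p, w, max_iter) {
    ll_old <- -Inf; post <- NULL; ll <- -Inf
    for (it in seq_len(max_iter)) {
      lg <- vapply(seq_len(k), function(j)
        dbinom(alt, dp, p[j], log = TRUE) + log(w[j]), numeric(n))
      m <- apply(lg, 1, max)
      li <- m + log(rowSums(exp(lg - m)))
      ll <- sum(li)
      post <- exp(lg - li)
      w <- pmax(colMeans(post), 1e-12)
      p <- pmin(pmax(colSums(post * alt) / pmax(colSums(post * dp), 1e-12),
                     1e-3), 1 - 1e-3)
      if (ll - ll_old < 1e-6) break
      ll_old <- ll
    }
    list(ll = ll, p = p, w = w, post = post)
  }
  vaf <- ifelse(dp > 0, alt / dp, 0)
  best <- NULL
  for (s in seq_len(restarts)) {
    p <- if (s == 1) quantile(vaf, (seq_len(k) - 0.5) / k, names = FALSE)
         else sort(runif(k, 0.02, max(vaf) + 0.02))
    p <- pmin(pmax(p, 1e-3), 1 - 1e-3)
    fit <- em(p, rep(1 / k, k), 25L)
    if (is.null(best) || fit$ll > best$ll) best <- fit
  }
  em(best$p, best$w, 400L)
}

#' @export
print.subclone_model <- function(x, ...) {
  cat("<subclone_model> k =", x$k,
      if (x$underpowered) "(underpowered)" else "", "\n")
  cat("  cell fractions:", paste(sprintf("%.2f", x$fractions), collapse = ", "),
      "| component VAFs:", paste(sprintf("%.3f", x$p), collapse = ", "), "\n")
  invisible(x)
}

#' Split a tumour's variants into per-subclone sets
#'
#' Each subclonal variant is assigned to its maximum-posterior component
#' (exact posterior ties go to the larger-fraction component); variants with
#' cell fraction ~ 1 (clonal component) are shared by all pseudo-samples.
#' Each pseudo-sample carries the clonal variants plus its own component's
#' private variants.
#'
#' @param model a `subclone_model` with `k >= 2`.
#' @param variant_ids ids aligned with the rows of `model$posteriors`.
#' @param clonal_fraction components with cell fraction at least this are
#'   treated as clonal (default 0.9).
#' @return list with `clonal` ids and a `subclones` list of private-id sets.
#' @export
split_subclones <- function(model, variant_ids, clonal_fraction = 0.9) {
  stop_if_not(model$k >= 2, "model has a single component; nothing to split")
  stop_if_not(length(variant_ids) == nrow(model$posteriors),
              "variant_ids must align with the model's posteriors")
  post <- model$posteriors
  ## tie-break: order columns by fraction (already decreasing), max.col first
  assign <- max.col(post, ties.method = "first")
  clonal_comp <- which(model$fractions >= clonal_fraction)
  is_clonal <- assign %in% clonal_comp
  sub_comps <- setdiff(seq_len(model$k), clonal_comp)
  subclones <- lapply(sub_comps, function(j) variant_ids[assign == j & !is_clonal])
  names(subclones) <- paste0("subclone", seq_along(sub_comps))
  list(clonal = variant_ids[is_clonal], subclones = subclones,
       assignment = assign)
}

#' Attach subclone pseudo-samples to a clone phylogeny
#'
#' Scores every branch by the number of its root-to-branch path's defining
#' variants present in the pseudo-sample minus the number absent, and attaches
#' at the maximising branch. Attachments within one variant of the optimum
#' are reported as ambiguous alternatives. Sister samples (tips below the
#' attachment's parent) are listed.
#'
#' @param variant_sets list of pseudo-sample variant-id sets.
#' @param phy a `clone_phylogeny` with `branch_variants`.
#' @return data frame: pseudo-sample, attachment node, score, sister tips,
#'   ambiguous alternatives.
#' @export
place_on_tree <- function(variant_sets, phy) {
  n_node <- length(phy$parent)
  clades <- tree_clades(phy)
  ## path variant sets: variants on edges from root to node v
  path_ids <- vector("list", n_node)
  for (v in rev(tree_postorder(phy))) {  # preorder
    p <- phy$parent[v]
    own <- phy$branch_variants[[v]] %||% character()
    path_ids[[v]] <- if (p == 0L) own else c(path_ids[[p]], own)
  }
  out <- lapply(names(variant_sets) %||% seq_along(variant_sets), function(nm) {
    ids <- variant_sets[[nm]]
    score <- vapply(seq_len(n_node), function(v) {
      pres <- sum(path_ids[[v]] %in% ids)
      pres - (length(path_ids[[v]]) - pres)
    }, 0)
    best <- which.max(score)
    alt <- setdiff(which(score >= score[best] - 1), best)
    par <- phy$parent[best]
    sisters <- if (par > 0)
      phy$tip_label[setdiff(clades[[par]], clades[[best]])] else character()
    data.frame(pseudo_sample = as.character(nm), node = best,
               score = score[best],
               sisters = paste(sisters, collapse = ","),
               ambiguous = paste(alt, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
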