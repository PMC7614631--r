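#' Regress mutation burden against sampling date
#'
#' Ordinary least squares of per-tumour mutation burden on decimal sampling
#' date. The slope is the mutation rate in mutations/genome/year, with a 95%
#' confidence interval from the t distribution and an F test for a non-zero
#' slope; classes failing the F test are labelled not significant and their
#' rate ratios are suppressed downstream.
#'
#' @param burden numeric per-sample mutation counts.
#' @param dates decimal-year sampling dates (same length; >= 3 samples and
#'   >= 2 distinct dates).
#' @param level confidence level (default 0.95).
#' @return a `rate_fit`: `slope`, `intercept`, `se`, `ci`, `p` (F test), `n`,
#'   `significant`, `residuals`, and the underlying `lm`.
#' @export
burden_regression <- function(burden, dates, level = 0.95) {
  stop_if_not(length(burden) == length(dates), "burden/dates length mismatch")
  stop_if_not(length(burden) >= 3, "need at least 3 samples")
  if (length(unique(dates)) < 2)
    stop("all samples share one sampling date: no rate is estimable",
         call. = FALSE)
  fit <- lm(burden ~ dates)
  ## zero-residual (exact) data triggers a spurious "perfect fit" warning;
  ## the degenerate F statistic is handled explicitly below
  sm <- suppressWarnings(summary(fit))
  slope <- unname(coef(fit)[2])
  se <- sm$coefficients[2, 2]
  ci <- unname(suppressWarnings(confint(fit, "dates", level = level)))
  f <- sm$fstatistic
  p <- if (is.null(f)) NaN
       else unname(stats::pf(f[1], f[2], f[3], lower.tail = FALSE))
  ## a perfectly constant burden gives a 0/0 F statistic: no signal
  if (!is.finite(p)) p <- if (abs(unname(coef(fit)[2])) < 1e-10) 1 else 0
  structure(list(slope = slope, intercept = unname(coef(fit)[1]), se = se,
                 ci = c(lo = ci[1], hi = ci[2]), p = p, n = length(burden),
                 significant = p < 0.05, residuals = unname(residuals(fit)),
                 model = fit), class = "rate_fit")
}

#' Construct a rate fit from summary numbers
#'
#' For combining externally reported regression summaries (a slope with its
#' 95% CI) with [rate_ratio()] without access to the underlying samples.
#'
#' @param slope slope estimate (mutations/genome/year).
#' @param ci length-2 95% confidence interval.
#' @param p F-test p-value (default a significant placeholder).
#' @param n sample size (used to convert the CI to a standard error via the
#'   t distribution; `Inf` uses the normal quantile).
#' @return a `rate_fit`.
#' @export
rate_fit <- function(slope, ci, p = 1e-9, n = Inf) {
  q <- if (is.finite(n)) qt(0.975, df = n - 2) else 1.959964
  structure(list(slope = slope, intercept = NA_real_,
                 se = diff(range(ci)) / (2 * q),
                 ci = c(lo = min(ci), hi = max(ci)), p = p, n = n,
                 significant = p < 0.05, residuals = NULL, model = NULL),
            class = "rate_fit")
}

#' @export
print.rate_fit <- function(x, ...) {
  cat(sprintf("<rate_fit> %.1f [%.1f-%.1f] mutations/genome/year%s (n=%s)\n",
              x$slope, x$ci[1], x$ci[2],
              if (!x$significant) ", n.s." else "", x$n))
  invisible(x)
}

#' Ratio of two mutation rates with propagated uncertainty
#'
#' Point ratio `slopeB / slopeA` with a first-order delta-method interval,
#' \deqn{SE(R) = R \sqrt{(SE_A/A)^2 + (SE_B/B)^2},}
#' plus a parametric-bootstrap interval from Gaussian draws of both slopes.
#' The ratio is suppressed (with a reason) when either fit failed its F test
#' or the denominator slope is not positive, matching the convention of
#' printing "-" for non-significant classes.
#'
#' @param fitA denominator `rate_fit` (e.g. DFT1).
#' @param fitB numerator `rate_fit` (e.g. DFT2).
#' @param n_boot bootstrap draws (default 1e5).
#' @param seed seed for the bootstrap.
#' @return a `rate_ratio` object: `ratio`, `se`, `ci` (delta), `ci_boot`, or
#'   a suppressed result with `reason`.
#' @export
rate_ratio <- function(fitA, fitB, n_boot = 1e5, seed = 1) {
  if (!fitA$significant || !fitB$significant || fitA$slope <= 0)
    return(structure(list(ratio = NA_real_,
                          reason = if (!fitA$significant || fitA$slope <= 0)
                            "denominator rate not significant or not positive"
                          else "numerator rate not significant"),
                     class = "rate_ratio"))
  R <- fitB$slope / fitA$slope
  se <- R * sqrt((fitA$se / fitA$slope)^2 + (fitB$se / fitB$slope)^2)
  boot <- with_seed(seed, {
    a <- rnorm(n_boot, fitA$slope, fitA$se)
    b <- rnorm(n_boot, fitB$slope, fitB$se)
    quantile(b / a, c(0.025, 0.975), names = FALSE)
  })
  structure(list(ratio = R, se = se,
                 ci = c(lo = R - 1.959964 * se, hi = R + 1.959964 * se),
                 ci_boot = c(lo = boot[1], hi = boot[2])),
            class = "rate_ratio")
}

#' @export
print.rate_ratio <- function(x, ...) {
  if (is.na(x$ratio)) cat("<rate_ratio> - (", x$reason, ")\n")
  else cat(sprintf("<rate_ratio> %.3f [%.3f-%.3f] (bootstrap [%.3f-%.3f])\n",
                   x$ratio, x$ci[1], x$ci[2], x$ci_boot[1], x$ci_boot[2]))
  invisible(x)
}

#' Detect clade-level mutation-rate shifts
#'
#' For every internal branch with at least `min_desc` descendant tips (and as
#' many non-descendants), fits `burden ~ date + clade indicator` and tests
#' the indicator by F test; Benjamini-Hochberg correction is applied across
#' branches. The indicator coefficient estimates the clade's genome-wide
#' mutation offset (deficit if negative); per-clade and background slopes
#' with confidence intervals are co-reported.
#'
#' @param phy a `clone_tree`/`clone_phylogeny` whose tips match
#'   `names(burden)`.
#' @param burden named per-tip mutation burdens.
#' @param dates named per-tip decimal sampling dates.
#' @param min_desc minimum descendant (and non-descendant) tips (default 4).
#' @return data frame per tested branch: `node`, `n_desc`, `offset`, `p`,
#'   `q`, clade and background slopes with CIs, ordered by `q`.
#' @export
detect_rate_shift <- function(phy, burden, dates, min_desc = 4) {
  n <- phy$n_tip
  clades <- tree_clades(phy)
  burden <- burden[phy$tip_label]
  dates <- dates[phy$tip_label]
  cand <- which(seq_along(clades) > n &
                  lengths(clades) >= min_desc &
                  lengths(clades) <= n - min_desc)
  rows <- lapply(cand, function(v) {
    ind <- seq_len(n) %in% clades[[v]]
    fit <- lm(burden ~ dates + ind)
    if (anyNA(coef(fit))) return(NULL)
    sm <- summary(fit)$coefficients
    slope_in <- slope_out <- c(NA, NA, NA)
    if (length(unique(dates[ind])) >= 2 && sum(ind) >= 3) {
      f1 <- burden_regression(burden[ind], dates[ind])
      slope_in <- c(f1$slope, f1$ci)
    }
    if (length(unique(dates[!ind])) >= 2 && sum(!ind) >= 3) {
      f0 <- burden_regression(burden[!ind], dates[!ind])
      slope_out <- c(f0$slope, f0$ci)
    }
    data.frame(node = v, n_desc = sum(ind),
               offset = unname(coef(fit)["indTRUE"]),
               p = sm["indTRUE", 4],
               clade_slope = slope_in[1], clade_lo = slope_in[2],
               clade_hi = slope_in[3],
               bg_slope = slope_out[1], bg_lo = slope_out[2],
               bg_hi = slope_out[3])
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame())
  out$q <- p.adjust(out$p, "BH")
  out[order(out$q, out$p), , drop = FALSE]
}

#' Flag hypermutator outliers against the cohort clock
#'
#' Each sample's burden is compared with the prediction of a leave-one-out
#' burden-date regression; samples whose burden exceeds `multiplier` times
#' their prediction are flagged, with the fold-excess reported.
#'
#' @param burden named per-sample burdens (one mutation class).
#' @param dates named decimal sampling dates.
#' @param multiplier flagging threshold on the observed/expected fold
#'   (default 3).
#' @return data frame `sample`, `burden`, `expected`, `fold`, `flagged`.
#' @export
flag_hypermutators <- function(burden, dates, multiplier = 3) {
  stop_if_not(length(burden) == length(dates), "burden/dates length mismatch")
  nm <- names(burden) %||% as.character(seq_along(burden))
  expected <- vapply(seq_along(burden), function(i) {
    fit <- lm(burden[-i] ~ dates[-i])
    unname(coef(fit)[1] + coef(fit)[2] * dates[i])
  }, 0)
  fold <- ifelse(expected > 0, burden / expected, Inf)
  data.frame(sample = nm, burden = as.numeric(burden), expected = expected,
             fold = fold, flagged = fold >= multiplier,
             stringsAsFactors = FALSE, row.names = NULL)
}
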