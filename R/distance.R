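# Distance-parity diagnostics. The calibration transfers a ratio estimated on
# interhemispheric (callosal) fibers to intrahemispheric connections, which is
# valid only if tractography treats the two pair sets similarly at matched
# fiber lengths. Diagnostics: (1) connectivity averaged in equal-width fiber
# length bins with percentile-bootstrap CIs, separately for intra- and
# interhemispheric pairs; (2) OLS regressions of log-connectivity on length
# restricted to the common length domain, with bootstrap CIs on the
# slope/intercept differences and a permutation test comparing the
# length-connectivity correlations.

#' Bin pairwise connectivity by fiber length
#'
#' Averages pairwise connectivity within equal-width fiber-length bins for one
#' pair set (intra- or interhemispheric), with seeded percentile-bootstrap
#' confidence intervals obtained by resampling parcel pairs within each bin.
#' Empty bins are reported with `n = 0`, not dropped.
#'
#' @param m symmetric connectivity matrix (streamlines or axons).
#' @param lengths symmetric fiber-length matrix, mm.
#' @param parcels parcel table.
#' @param pair_set `"intra"` or `"inter"`.
#' @param n_bins number of equal-width bins over the pair set's length range.
#' @param n_boot bootstrap resamples per bin.
#' @param seed RNG seed.
#' @param conf confidence level (default 0.95).
#' @return an object of class `"distance_binning"`: a data frame `bins` with
#'   `bin_lo`, `bin_hi`, `bin_mid`, `n`, `mean`, `ci_lo`, `ci_hi`.
#' @export
bin_by_length <- function(m, lengths, parcels, pair_set = c("intra", "inter"),
                          n_bins = 15, n_boot = 1000, seed = 1L, conf = 0.95) {
  pair_set <- match.arg(pair_set)
  if (n_bins < 2) stop("n_bins must be >= 2", call. = FALSE)
  pt <- pair_table(m, parcels, lengths)
  pt <- pt[if (pair_set == "intra") pt$intra else !pt$intra, ]
  if (any(pt$length <= 0 & pt$value > 0)) {
    stop("pairs with positive connectivity but no length", call. = FALSE)
  }
  edges <- seq(min(pt$length), max(pt$length), length.out = n_bins + 1)
  bin <- findInterval(pt$length, edges, rightmost.closed = TRUE)
  alpha <- (1 - conf) / 2
  bins <- with_local_seed(seed, {
    do.call(rbind, lapply(seq_len(n_bins), function(b) {
      v <- pt$value[bin == b]
      if (!length(v)) {
        return(data.frame(bin_lo = edges[b], bin_hi = edges[b + 1],
                          bin_mid = (edges[b] + edges[b + 1]) / 2,
                          n = 0L, mean = NA_real_,
                          ci_lo = NA_real_, ci_hi = NA_real_))
      }
      boots <- vapply(seq_len(n_boot), function(i) {
        mean(sample(v, length(v), replace = TRUE))
      }, 0)
      ci <- stats::quantile(boots, c(alpha, 1 - alpha), names = FALSE)
      data.frame(bin_lo = edges[b], bin_hi = edges[b + 1],
                 bin_mid = (edges[b] + edges[b + 1]) / 2,
                 n = length(v), mean = mean(v), ci_lo = ci[1], ci_hi = ci[2])
    }))
  })
  structure(list(bins = bins, pair_set = pair_set, n_bins = n_bins,
                 n_boot = n_boot, conf = conf),
            class = "distance_binning")
}

#' @export
print.distance_binning <- function(x, ...) {
  cat(sprintf("Length-binned connectivity (%shemispheric pairs, %d bins)\n",
              x$pair_set, x$n_bins))
  print(x$bins, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
plot.distance_binning <- function(x, log = "y", ...) {
  b <- x$bins[x$bins$n > 0, ]
  graphics::plot(b$bin_mid, b$mean, type = "b", log = log,
                 xlab = "fiber length (mm)", ylab = "mean connectivity", ...)
  graphics::arrows(b$bin_mid, b$ci_lo, b$bin_mid, b$ci_hi,
                   angle = 90, code = 3, length = 0.03)
  invisible(x)
}

#' Intra- vs interhemispheric distance-parity test
#'
#' Restricts intra- and interhemispheric parcel pairs to their common fiber
#' length domain ("distance-matched"), fits ordinary least squares of
#' log-connectivity on length in each set, and compares them: bootstrap 95%
#' CIs on the slope and intercept differences (resampling pairs within set),
#' and a seeded permutation test of the difference in Pearson correlation
#' between log-connectivity and length, with a Fisher-z comparison as a
#' secondary statistic. The permutation shuffles the intra/inter labels
#' within equal-width length strata, so every permuted set keeps its length
#' distribution; without stratification the two sets' different length
#' profiles alone would move the correlations and the null would be violated
#' even when both sets obey the same law. Pairs with zero connectivity cannot
#' be log-transformed; they are excluded and counted.
#'
#' @param m symmetric connectivity matrix.
#' @param lengths symmetric fiber-length matrix.
#' @param parcels parcel table.
#' @param n_boot bootstrap resamples for the difference CIs.
#' @param n_perm label permutations for the correlation comparison; labels are
#'   shuffled within `n_strata` equal-width length strata so that each
#'   permuted set keeps its length distribution (distance-matched null).
#' @param n_strata length strata for the stratified permutation.
#' @param seed RNG seed.
#' @return an object of class `"parity_test"` with per-set fits (`slope`,
#'   `intercept`, `r`, `n`), `slope_diff`/`intercept_diff` with bootstrap CIs,
#'   two-sided permutation p (`p_correlation`), Fisher-z p (`p_fisher_z`), the
#'   common length domain, and the number of zero-connectivity pairs dropped.
#' @export
parity_test <- function(m, lengths, parcels, n_boot = 1000, n_perm = 999,
                        n_strata = 15, seed = 1L) {
  pt <- pair_table(m, parcels, lengths)
  intra <- pt[pt$intra, ]
  inter <- pt[!pt$intra, ]
  lo <- max(min(intra$length), min(inter$length))
  hi <- min(max(intra$length), max(inter$length))
  if (lo >= hi) stop("intra- and interhemispheric length ranges do not overlap",
                     call. = FALSE)
  clip <- function(d) d[d$length >= lo & d$length <= hi, ]
  intra <- clip(intra)
  inter <- clip(inter)
  n_zero <- c(intra = sum(intra$value <= 0), inter = sum(inter$value <= 0))
  intra <- intra[intra$value > 0, ]
  inter <- inter[inter$value > 0, ]
  if (nrow(intra) < 3 || nrow(inter) < 3) {
    stop("too few positive pairs in the common length domain", call. = FALSE)
  }

  fit_set <- function(d) {
    f <- stats::lm(log(value) ~ length, data = d)
    list(slope = unname(stats::coef(f)[2]),
         intercept = unname(stats::coef(f)[1]),
         r = stats::cor(log(d$value), d$length),
         n = nrow(d))
  }
  f_intra <- fit_set(intra)
  f_inter <- fit_set(inter)
  obs_slope_diff <- f_inter$slope - f_intra$slope
  obs_int_diff <- f_inter$intercept - f_intra$intercept
  obs_r_diff <- f_inter$r - f_intra$r

  res <- with_local_seed(seed, {
    boot_diffs <- vapply(seq_len(n_boot), function(b) {
      bi <- intra[sample(nrow(intra), replace = TRUE), ]
      be <- inter[sample(nrow(inter), replace = TRUE), ]
      fi <- fit_set(bi)
      fe <- fit_set(be)
      c(fe$slope - fi$slope, fe$intercept - fi$intercept)
    }, c(0, 0))
    pooled <- rbind(intra[c("value", "length")], inter[c("value", "length")])
    lab <- rep(c(TRUE, FALSE), c(nrow(intra), nrow(inter)))
    stratum <- findInterval(pooled$length,
                            seq(lo, hi, length.out = n_strata + 1),
                            rightmost.closed = TRUE)
    strata_idx <- split(seq_along(lab), stratum)
    perm_r <- vapply(seq_len(n_perm), function(p) {
      sh <- lab
      for (ix in strata_idx) sh[ix] <- sh[ix][sample(length(ix))]
      stats::cor(log(pooled$value[!sh]), pooled$length[!sh]) -
        stats::cor(log(pooled$value[sh]), pooled$length[sh])
    }, 0)
    list(boot_diffs = boot_diffs, perm_r = perm_r)
  })
  slope_ci <- stats::quantile(res$boot_diffs[1, ], c(0.025, 0.975), names = FALSE)
  int_ci <- stats::quantile(res$boot_diffs[2, ], c(0.025, 0.975), names = FALSE)
  p_perm <- (1 + sum(abs(res$perm_r) >= abs(obs_r_diff))) / (n_perm + 1)

  # Fisher z comparison of the two correlations (independent groups)
  z <- (atanh(f_inter$r) - atanh(f_intra$r)) /
    sqrt(1 / (f_inter$n - 3) + 1 / (f_intra$n - 3))
  p_fisher <- 2 * stats::pnorm(-abs(z))

  structure(
    list(intra = f_intra, inter = f_inter,
         slope_diff = obs_slope_diff, slope_diff_ci = slope_ci,
         intercept_diff = obs_int_diff, intercept_diff_ci = int_ci,
         r_diff = obs_r_diff, p_correlation = p_perm, p_fisher_z = p_fisher,
         common_domain = c(lo, hi), n_zero_excluded = n_zero,
         n_boot = n_boot, n_perm = n_perm, seed = seed),
    class = "parity_test"
  )
}

#' @export
print.parity_test <- function(x, digits = 4, ...) {
  cat("Intra- vs interhemispheric distance-parity test\n")
  cat(sprintf("  common length domain: [%.1f, %.1f] mm\n",
              x$common_domain[1], x$common_domain[2]))
  cat(sprintf("  intra: slope %.*g, intercept %.*g, r %.3f (n = %d)\n",
              digits, x$intra$slope, digits, x$intra$intercept,
              x$intra$r, x$intra$n))
  cat(sprintf("  inter: slope %.*g, intercept %.*g, r %.3f (n = %d)\n",
              digits, x$inter$slope, digits, x$inter$intercept,
              x$inter$r, x$inter$n))
  cat(sprintf("  slope difference:     %.*g, 95%% CI [%.*g, %.*g]\n",
              digits, x$slope_diff, digits, x$slope_diff_ci[1],
              digits, x$slope_diff_ci[2]))
  cat(sprintf("  intercept difference: %.*g, 95%% CI [%.*g, %.*g]\n",
              digits, x$intercept_diff, digits, x$intercept_diff_ci[1],
              digits, x$intercept_diff_ci[2]))
  cat(sprintf("  correlation comparison: permutation p = %.3f (Fisher z p = %.3f)\n",
              x$p_correlation, x$p_fisher_z))
  invisible(x)
}
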