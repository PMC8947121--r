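# Summaries of the absolute axon-count matrix: medians over unordered parcel
# pairs, adjacency fractions, the bound on the fraction of pyramidal cells
# projecting outside their parcel, per-parcel totals and area-normalized
# densities, and log-binned histograms. The matrix is undirected, so every
# statistic pools unordered pairs (i < j); intrahemispheric pairs pool both
# hemispheres, interhemispheric pairs are the 180 x 180 left-right block.

#' Unordered parcel-pair view of a connectivity matrix
#'
#' Flattens the upper triangle into a data frame of unordered pairs with
#' hemisphere and adjacency annotations (and lengths if supplied). The
#' workhorse behind medians, distance binning and the brute-force oracles in
#' the tests.
#'
#' @param m symmetric matrix.
#' @param parcels parcel table.
#' @param lengths optional symmetric fiber-length matrix.
#' @return data frame with columns `i`, `j` (row/col indices), `value`,
#'   `intra` (logical), `adjacent` (logical), and `length` if supplied.
#' @export
pair_table <- function(m, parcels, lengths = NULL) {
  ut <- upper.tri(m)
  idx <- which(ut, arr.ind = TRUE)
  out <- data.frame(
    i = idx[, 1], j = idx[, 2],
    value = m[ut],
    intra = same_hemisphere_matrix(parcels)[ut],
    adjacent = adjacency_matrix(parcels)[ut]
  )
  if (!is.null(lengths)) out$length <- lengths[ut]
  out
}

#' Summarize an axon-count matrix
#'
#' Computes the connectivity summaries reported from a calibrated axon-count
#' matrix: total interareal axons, median intra- and interhemispheric pairwise
#' counts, the fraction of axons running to physically adjacent parcels, the
#' implied bounds on the fraction of cortical pyramidal cells projecting
#' outside their own parcel (each interareal axon attributed to exactly one
#' projecting neuron) and beyond the adjacent parcels, per-parcel totals and
#' area-normalized densities, and log10-binned histograms split into
#' interhemispheric, intra-adjacent and intra-nonadjacent pair sets.
#'
#' @param n symmetric axon-count matrix.
#' @param parcels parcel table.
#' @param pyramidal_count total number of cortical pyramidal cells used for
#'   the projection-fraction bound (default 11.5e9).
#' @param include_zero_pairs include pairs with zero axons in the medians
#'   (default `TRUE`); set `FALSE` to drop them.
#' @param hist_binwidth histogram bin width in dex (default 0.25).
#' @return an object of class `"connectivity_summary"`.
#' @export
summarize_connectivity <- function(n, parcels, pyramidal_count = 11.5e9,
                                   include_zero_pairs = TRUE,
                                   hist_binwidth = 0.25) {
  pt <- pair_table(n, parcels)
  keep <- if (include_zero_pairs) rep(TRUE, nrow(pt)) else pt$value > 0
  total <- sum(pt$value)
  adjacent_total <- sum(pt$value[pt$adjacent])
  med <- function(v) if (length(v)) stats::median(v) else NA_real_
  per_parcel_totals <- rowSums(n)
  names(per_parcel_totals) <- parcel_labels(parcels)
  per_parcel_density <- per_parcel_totals / parcels$surface_area_mm2

  pos <- pt$value[pt$value > 0]
  hist_groups <- list(
    inter = pt$value[!pt$intra],
    intra_adjacent = pt$value[pt$intra & pt$adjacent],
    intra_nonadjacent = pt$value[pt$intra & !pt$adjacent]
  )
  histograms <- NULL
  if (length(pos)) {
    lo <- floor(log10(min(pos)) / hist_binwidth) * hist_binwidth
    hi <- ceiling(log10(max(pos)) / hist_binwidth) * hist_binwidth
    if (hi <= lo) hi <- lo + hist_binwidth  # all pairs equal: one bin
    edges <- seq(lo, hi + hist_binwidth / 2, by = hist_binwidth)
    histograms <- lapply(hist_groups, function(v) {
      counts <- if (sum(v > 0)) {
        graphics::hist(log10(v[v > 0]), breaks = edges, plot = FALSE)$counts
      } else rep(0L, length(edges) - 1)
      list(log10_edges = edges, counts = counts, n_zero = sum(v == 0))
    })
  }

  structure(
    list(total_axons = total,
         median_intra = med(pt$value[pt$intra & keep]),
         median_inter = med(pt$value[!pt$intra & keep]),
         adjacent_fraction = if (total > 0) adjacent_total / total else NA_real_,
         frac_projecting = total / pyramidal_count,
         frac_projecting_beyond_adjacent = (total - adjacent_total) / pyramidal_count,
         per_parcel_totals = per_parcel_totals,
         per_parcel_density = per_parcel_density,
         histograms = histograms,
         pyramidal_count = pyramidal_count,
         include_zero_pairs = include_zero_pairs,
         n_pairs = c(intra = sum(pt$intra), inter = sum(!pt$intra))),
    class = "connectivity_summary"
  )
}

#' @export
print.connectivity_summary <- function(x, ...) {
  cat("Interareal axon-count summary\n")
  cat(sprintf("  total interareal axons:      %.3g\n", x$total_axons))
  cat(sprintf("  median intrahemispheric:     %.4g axons\n", x$median_intra))
  cat(sprintf("  median interhemispheric:     %.4g axons\n", x$median_inter))
  cat(sprintf("  axons to adjacent parcels:   %.1f%%\n", 100 * x$adjacent_fraction))
  cat(sprintf("  pyramidal cells projecting outside parcel:  < %.1f%%\n",
              100 * x$frac_projecting))
  cat(sprintf("  projecting beyond adjacent parcels:         < %.1f%%\n",
              100 * x$frac_projecting_beyond_adjacent))
  invisible(x)
}

#' Hemisphere-averaged intrahemispheric matrix
#'
#' Mean of the left- and right-hemisphere intrahemispheric blocks after
#' matching homologous parcels by name.
#'
#' @param n symmetric matrix over all parcels.
#' @param parcels parcel table; every left parcel name must have a right
#'   homolog.
#' @return square matrix over one hemisphere's parcels (left names).
#' @export
hemisphere_averaged_intra <- function(n, parcels) {
  lidx <- left_idx(parcels)
  ridx <- right_idx(parcels)
  m <- match(parcels$name[lidx], parcels$name[ridx])
  if (anyNA(m)) {
    stop(sprintf("left parcel(s) without right homolog: %s",
                 paste(parcels$name[lidx][is.na(m)], collapse = ", ")),
         call. = FALSE)
  }
  ridx <- ridx[m]
  out <- (n[lidx, lidx] + n[ridx, ridx]) / 2
  dimnames(out) <- list(parcels$name[lidx], parcels$name[lidx])
  out
}

#' Target-area-normalized connectivity profile of one parcel
#'
#' The axon counts from a source parcel to every other parcel, each divided by
#' the *target* parcel's surface area (axons/mm^2) — e.g. the hippocampal
#' profile showing distant areas connected by fewer than 10 axons/mm^2.
#'
#' @param n symmetric axon-count matrix.
#' @param parcels parcel table.
#' @param source_parcel parcel name; with `hemisphere` selects the source row.
#' @param hemisphere `"left"` or `"right"`; ignored if `hemisphere_average`.
#' @param hemisphere_average if `TRUE`, average the profiles of the left and
#'   right homologs of `source_parcel` over target homolog pairs.
#' @return named numeric vector of axons/mm^2 by target parcel.
#' @export
target_normalized_profile <- function(n, parcels, source_parcel,
                                      hemisphere = "left",
                                      hemisphere_average = FALSE) {
  if (hemisphere_average) {
    avg <- hemisphere_averaged_intra(n, parcels)
    if (!source_parcel %in% rownames(avg)) {
      stop(sprintf("unknown parcel name: '%s'", source_parcel), call. = FALSE)
    }
    lidx <- left_idx(parcels)
    areas <- parcels$surface_area_mm2[lidx]
    names(areas) <- parcels$name[lidx]
    return(avg[source_parcel, ] / areas[colnames(avg)])
  }
  row <- which(parcels$name == source_parcel & parcels$hemisphere == hemisphere)
  if (length(row) != 1) {
    stop(sprintf("unknown parcel name: '%s' (%s hemisphere)", source_parcel,
                 hemisphere), call. = FALSE)
  }
  prof <- n[row, ] / parcels$surface_area_mm2
  names(prof) <- parcel_labels(parcels)
  prof[-row]
}

#' Compare interhemispheric axon totals across demographic groups
#'
#' One-way F tests of per-subject interhemispheric axon counts on sex and on
#' age group, a sex-by-age interaction test, and seeded bootstrap 95%
#' confidence intervals of the group means.
#'
#' @param values per-subject interhemispheric axon counts.
#' @param sex per-subject sex labels.
#' @param age_group per-subject age-group labels.
#' @param n_boot bootstrap replicates for the group-mean CIs.
#' @param seed RNG seed.
#' @return an object of class `"group_comparison"`: data frame `tests`
#'   (effect, F, df1, df2, p) and data frame `group_means` (factor, level, n,
#'   mean, ci_lo, ci_hi).
#' @export
group_compare <- function(values, sex, age_group, n_boot = 1000, seed = 1L) {
  sex <- factor(sex)
  age_group <- factor(age_group)
  if (nlevels(sex) < 2 && nlevels(age_group) < 2) {
    stop("need at least two groups in sex or age_group", call. = FALSE)
  }
  counts <- c(table(sex), table(age_group))
  if (any(counts < 2)) {
    stop(sprintf("degenerate group(s) with < 2 subjects: %s",
                 paste(names(counts)[counts < 2], collapse = ", ")),
         call. = FALSE)
  }
  one_way <- function(fac, name) {
    if (nlevels(fac) < 2) return(NULL)
    a <- stats::anova(stats::aov(values ~ fac))
    data.frame(effect = name, F = a$`F value`[1], df1 = a$Df[1], df2 = a$Df[2],
               p = a$`Pr(>F)`[1], stringsAsFactors = FALSE)
  }
  tests <- rbind(one_way(sex, "sex"), one_way(age_group, "age_group"))
  if (nlevels(sex) >= 2 && nlevels(age_group) >= 2 &&
      all(table(sex, age_group) > 0)) {
    a <- stats::anova(stats::aov(values ~ sex * age_group))
    k <- which(rownames(a) == "sex:age_group")
    if (length(k)) {
      tests <- rbind(tests, data.frame(
        effect = "sex:age_group", F = a$`F value`[k], df1 = a$Df[k],
        df2 = a$Df[nrow(a)], p = a$`Pr(>F)`[k], stringsAsFactors = FALSE))
    }
  }
  group_means <- with_local_seed(seed, {
    do.call(rbind, lapply(list(sex = sex, age_group = age_group), function(fac) {
      do.call(rbind, lapply(levels(fac), function(lv) {
        v <- values[fac == lv]
        boots <- vapply(seq_len(n_boot), function(b) {
          mean(sample(v, length(v), replace = TRUE))
        }, 0)
        ci <- stats::quantile(boots, c(0.025, 0.975), names = FALSE)
        data.frame(level = lv, n = length(v), mean = mean(v),
                   ci_lo = ci[1], ci_hi = ci[2], stringsAsFactors = FALSE)
      }))
    }))
  })
  group_means <- cbind(factor = sub("\\.\\d+$", "", rownames(group_means)),
                       group_means)
  rownames(group_means) <- NULL
  structure(list(tests = tests, group_means = group_means,
                 n_boot = n_boot, seed = seed),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Group comparison of interhemispheric axon counts\n")
  print(x$tests, row.names = FALSE, digits = 4)
  cat("\nGroup means with bootstrap 95% CIs:\n")
  print(x$group_means, row.names = FALSE, digits = 4)
  invisible(x)
}
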