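test_that("summary medians match the brute-force pair enumeration", {
  p <- toy_parcels(3, 3)
  set.seed(42)
  vals <- c(rpois(14, 50), 0)  # include a zero pair
  n <- sym_matrix(6, sample(vals))
  for (inc in c(TRUE, FALSE)) {
    s <- summarize_connectivity(n, p, include_zero_pairs = inc)
    o <- oracle_pair_medians(n, p, include_zeros = inc)
    expect_equal(s$median_intra, o$intra)
    expect_equal(s$median_inter, o$inter)
  }
  # fixture-scale check too
  fx <- make_fixture()
  N <- predict(axon_calibration(fx$cohort, fx$parcels),
               cohort_mean_matrix(fx$cohort))
  s <- summarize_connectivity(N, fx$parcels)
  o <- oracle_pair_medians(N, fx$parcels)
  expect_equal(s$median_intra, o$intra)
  expect_equal(s$median_inter, o$inter)
})

test_that("uniform matrices give the counting-measure adjacent fraction", {
  fx <- make_fixture()
  n <- matrix(1, nrow(fx$parcels), nrow(fx$parcels)); diag(n) <- 0
  s <- summarize_connectivity(n, fx$parcels)
  pt <- pair_table(n, fx$parcels)
  expect_equal(s$adjacent_fraction, sum(pt$adjacent) / nrow(pt))
  expect_equal(s$total_axons, nrow(pt))
})

test_that("projection fractions follow from total axons and pyramidal count", {
  p <- toy_parcels(2, 2)
  n <- matrix(0, 4, 4)
  n[1, 3] <- n[3, 1] <- 2.43e9  # all axons on one interhemispheric pair
  s <- summarize_connectivity(n, p, pyramidal_count = 11.5e9)
  expect_equal(s$frac_projecting, 2.43e9 / 11.5e9)
  expect_lt(s$frac_projecting, 0.22)
  expect_equal(s$frac_projecting_beyond_adjacent,
               (s$total_axons - s$adjacent_fraction * s$total_axons) / 11.5e9)
  # per-parcel accounting
  expect_equal(unname(s$per_parcel_totals), rowSums(n))
  expect_equal(unname(s$per_parcel_density),
               rowSums(n) / p$surface_area_mm2)
})

test_that("histogram masses account for every pair in each group", {
  fx <- make_fixture()
  N <- predict(axon_calibration(fx$cohort, fx$parcels),
               cohort_mean_matrix(fx$cohort))
  s <- summarize_connectivity(N, fx$parcels)
  pt <- pair_table(N, fx$parcels)
  expect_equal(sum(s$histograms$inter$counts) + s$histograms$inter$n_zero,
               sum(!pt$intra))
  expect_equal(sum(s$histograms$intra_adjacent$counts) +
                 s$histograms$intra_adjacent$n_zero,
               sum(pt$intra & pt$adjacent))
  expect_equal(sum(s$histograms$intra_nonadjacent$counts) +
                 s$histograms$intra_nonadjacent$n_zero,
               sum(pt$intra & !pt$adjacent))
})

test_that("medians are invariant under monotone rescaling of all pairs", {
  # 4 + 3 parcels: 9 intrahemispheric pairs, so the median is a single pair
  p <- toy_parcels(4, 3)
  set.seed(5)
  N <- sym_matrix(7, rgamma(21, 2, 1) * 1e4)
  transforms <- list(function(x) 2 * x,
                     function(x) x^1.3,
                     function(x) x + sqrt(x))
  s0 <- summarize_connectivity(N, p)
  pt <- pair_table(N, p)
  for (tr in transforms) {
    Nt <- tr(N); diag(Nt) <- 0
    st <- summarize_connectivity(Nt, p)
    # strictly monotone transform: the median pair is the same pair
    expect_equal(st$median_intra, tr(s0$median_intra))
    # and ranks are unchanged throughout
    ptt <- pair_table(Nt, p)
    expect_equal(order(ptt$value), order(pt$value))
  }
})

test_that("area normalization stabilizes area-proportional connectivity", {
  # matrix built with connectivity proportional to both parcels' areas:
  # totals vary with area, densities do not
  set.seed(7)
  areas <- rgamma(20, 4, 1) * 50
  p <- toy_parcels(10, 10, areas = areas)
  n <- outer(areas, areas) * (1 + 0.05 * sym_matrix(20, runif(190)))
  diag(n) <- 0
  s <- summarize_connectivity(n, p)
  cv <- function(x) sd(x) / mean(x)
  expect_lt(cv(s$per_parcel_density), cv(s$per_parcel_totals))
})

test_that("target-normalized profiles divide by the target parcel's area", {
  areas <- c(2, 4, 8, 2, 4, 8)
  p <- toy_parcels(3, 3, areas = areas)
  n <- sym_matrix(6, seq_len(15) * 10)
  prof <- target_normalized_profile(n, p, "T02", hemisphere = "left")
  # hand-divided oracle: row 2 entries over the other parcels' areas
  expect_equal(unname(prof), (n[2, -2]) / areas[-2])
  # uniform matrix with equal areas gives a constant profile
  pu <- toy_parcels(3, 3)
  u <- matrix(1, 6, 6); diag(u) <- 0
  expect_true(all(target_normalized_profile(u, pu, "T01") == 1))
  # doubling one target's area halves its entry
  p2 <- toy_parcels(3, 3, areas = c(2, 4, 8, 2, 4, 16))
  prof2 <- target_normalized_profile(n, p2, "T02", hemisphere = "left")
  expect_equal(unname(prof2["R_T03"]), unname(prof["R_T03"]) / 2)
  expect_error(target_normalized_profile(n, p, "nope"), "unknown parcel")
})

test_that("hemisphere averaging matches homologous parcels by name", {
  p <- toy_parcels(3, 3)
  n <- sym_matrix(6, seq_len(15))
  avg <- hemisphere_averaged_intra(n, p)
  expect_equal(dim(avg), c(3, 3))
  expect_equal(avg[1, 2], (n[1, 2] + n[4, 5]) / 2)
  expect_equal(avg[2, 3], (n[2, 3] + n[5, 6]) / 2)
})

test_that("group comparison separates shifted groups and not identical ones", {
  # identical groups: F = 0, p = 1
  v <- rep(c(10, 12, 14, 16), 2)
  sex <- rep(c("F", "M"), each = 4)
  age <- rep(c("22-25", "26-30"), 4)
  g <- group_compare(v, sex, age, n_boot = 50, seed = 1)
  expect_equal(g$tests$F[g$tests$effect == "sex"], 0, tolerance = 1e-12)
  expect_equal(g$tests$p[g$tests$effect == "sex"], 1, tolerance = 1e-12)
  # 5-SD separation at n = 50 per group is detected overwhelmingly
  set.seed(11)
  v2 <- c(rnorm(50, 0, 1), rnorm(50, 5, 1))
  sex2 <- rep(c("F", "M"), each = 50)
  age2 <- rep(c("22-25", "26-30"), 50)
  g2 <- group_compare(v2, sex2, age2, n_boot = 50, seed = 2)
  expect_lt(g2$tests$p[g2$tests$effect == "sex"], 1e-6)
  ci <- g2$group_means[g2$group_means$factor == "sex", ]
  expect_lt(ci$ci_hi[ci$level == "F"], ci$ci_lo[ci$level == "M"])
  expect_error(group_compare(v2, rep("F", 100), rep("22-25", 100)),
               "at least two groups")
  expect_error(group_compare(v2[1:3], c("F", "F", "M"), rep("22-25", 3)),
               "degenerate")
})

test_that("group tests are calibrated under label permutation", {
  set.seed(99)
  v <- rnorm(60)
  age <- rep(c("22-25", "26-30", "31-35"), 20)
  ps <- vapply(1:60, function(i) {
    g <- group_compare(v, sample(rep(c("F", "M"), 30)), age,
                       n_boot = 2, seed = i)
    g$tests$p[g$tests$effect == "sex"]
  }, 0)
  # roughly uniform: around 5% land below 0.05, none pile up at 0
  expect_lt(mean(ps < 0.05), 0.2)
  expect_gt(mean(ps), 0.3)
  expect_lt(mean(ps), 0.7)
})
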