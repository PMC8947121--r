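test_that("short-fiber boost leaves matrices without short fibers unchanged", {
  p <- toy_parcels(3, 3)
  n <- sym_matrix(6, rpois(15, 100))
  L <- sym_matrix(6, runif(15, 50, 300))  # all >= 40 mm
  res <- adjust_uniform_short(n, L, p, short_length_threshold = 40,
                              short_factor = 2)
  expect_equal(res$adjusted, n)
  expect_equal(res$report$delta_total_pct, 0)
  expect_true(res$report$rank_order_preserved)
  expect_error(adjust_uniform_short(n, L, p, short_factor = 0.5),
               "short_factor")
})

test_that("doubling short pairs holding half the total adds exactly 50%", {
  p <- toy_parcels(3, 3)
  # 5 short pairs worth 40 each (total 200) and 10 long pairs worth 20 each
  # (total 200): doubling the short half adds half the grand total
  vals <- c(rep(40, 5), rep(20, 10))
  lens <- c(rep(20, 5), rep(100, 10))
  n <- sym_matrix(6, vals)
  L <- sym_matrix(6, lens)
  res <- adjust_uniform_short(n, L, p, short_length_threshold = 40,
                              short_factor = 2)
  expect_equal(res$report$delta_total_pct, 50)
})

test_that("rank-preserving short-fiber doubling leaves medians unchanged", {
  # noise-free EDR cohort: counts decrease monotonically with length, so the
  # short pairs are already the largest and doubling them preserves ranks
  cfg <- small_config(lognormal_sigma = 0, adjacency_boost = 1)
  fx <- make_fixture(cfg)
  N <- predict(axon_calibration(fx$cohort, fx$parcels,
                                histology_params(callosal_density = cfg$calibration_density)),
               cohort_mean_matrix(fx$cohort))
  res <- adjust_uniform_short(N, fx$lengths, fx$parcels,
                              short_length_threshold = 40, short_factor = 2)
  expect_true(res$report$rank_order_preserved)
  expect_equal(res$report$delta_median_intra_pct, 0)
  expect_equal(res$report$delta_median_inter_pct, 0)
  expect_gt(res$report$delta_total_pct, 0)
})

test_that("inverse-length adjustment is the identity at zero slope", {
  fx <- make_fixture()
  N <- predict(axon_calibration(fx$cohort, fx$parcels),
               cohort_mean_matrix(fx$cohort))
  res <- adjust_inverse_length(N, fx$lengths, fx$parcels, slope = 0)
  expect_equal(res$adjusted, N, ignore_attr = TRUE)
  expect_equal(res$area_factor, 1)
  expect_equal(res$density_factor, 1)
  expect_equal(res$report$multiplier_at_min, 1)
  expect_error(adjust_inverse_length(N, fx$lengths, fx$parcels, slope = -1),
               "slope")
  expect_error(adjust_inverse_length(N, fx$lengths, fx$parcels), "supply")
})

test_that("multiplier targeting doubles the shortest pairs exactly", {
  fx <- make_fixture()
  N <- predict(axon_calibration(fx$cohort, fx$parcels),
               cohort_mean_matrix(fx$cohort))
  res <- adjust_inverse_length(N, fx$lengths, fx$parcels, multiplier_at_min = 2)
  expect_equal(res$report$multiplier_at_min, 2)
  off <- fx$lengths[row(fx$lengths) != col(fx$lengths)]
  shortest <- which(fx$lengths == min(off), arr.ind = TRUE)[1, ]
  expect_equal(res$adjusted[shortest[1], shortest[2]],
               2 * N[shortest[1], shortest[2]])
  # multiplier vanishes at the reference (longest) length
  longest <- which(fx$lengths == max(off), arr.ind = TRUE)[1, ]
  expect_equal(res$adjusted[longest[1], longest[2]],
               N[longest[1], longest[2]])
  # multiplier is >= 1 everywhere in between
  expect_true(all(res$adjusted >= N - 1e-12))
})

test_that("occupied WM volume is invariant under the volume constraint", {
  fx <- make_fixture()
  N <- predict(axon_calibration(fx$cohort, fx$parcels),
               cohort_mean_matrix(fx$cohort))
  a0 <- effective_axon_area(histology_params())
  v0 <- occupied_wm_volume(N, fx$lengths, a0)$volume_mm3
  for (s in c(0, 5, 20, 80, 300)) {
    res <- adjust_inverse_length(N, fx$lengths, fx$parcels, slope = s,
                                 per_axon_area = a0)
    v1 <- occupied_wm_volume(res$adjusted, fx$lengths,
                             res$adjusted_per_axon_area)$volume_mm3
    expect_equal(v1, v0, tolerance = 1e-12)
    expect_equal(res$density_factor * res$area_factor, 1, tolerance = 1e-12)
  }
})

test_that("median and total adjustments are nondecreasing in slope", {
  fx <- make_fixture()
  N <- predict(axon_calibration(fx$cohort, fx$parcels),
               cohort_mean_matrix(fx$cohort))
  sw <- sensitivity_sweep(N, fx$lengths, fx$parcels,
                          slopes = c(0, 10, 40, 100, 250))
  expect_equal(sw$delta_median_intra_pct[1], 0)
  expect_true(all(diff(sw$delta_median_intra_pct) >= -1e-10))
  expect_true(all(diff(sw$delta_median_inter_pct) >= -1e-10))
  expect_true(all(diff(sw$delta_total_pct) >= -1e-10))
  expect_true(all(diff(sw$multiplier_at_min) > 0))
  # monotone in the short factor as well
  d1 <- adjust_uniform_short(N, fx$lengths, fx$parcels, short_factor = 1.5)
  d2 <- adjust_uniform_short(N, fx$lengths, fx$parcels, short_factor = 3)
  expect_gt(d2$report$delta_total_pct, d1$report$delta_total_pct)
})

test_that("doubling the shortest pairs shifts the median only modestly", {
  # on a log-normal/EDR cohort the short-fiber tail is adjusted strongly but
  # the median pair moves much less than the tail does
  cfg <- generator_config(n_parcels_per_hemisphere = 40, n_subjects = 5,
                          seed = 505)
  fx <- make_fixture(cfg)
  N <- predict(axon_calibration(fx$cohort, fx$parcels,
                                histology_params(callosal_density = cfg$calibration_density)),
               cohort_mean_matrix(fx$cohort))
  res <- adjust_inverse_length(N, fx$lengths, fx$parcels, multiplier_at_min = 2)
  expect_gt(res$report$delta_median_intra_pct, 0)
  expect_lt(res$report$delta_median_intra_pct, 50)
})
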