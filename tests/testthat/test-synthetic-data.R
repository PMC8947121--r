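test_that("parcel table honors size, area budget, and mirror symmetry", {
  fx <- make_fixture()
  p <- fx$parcels
  n <- fx$config$n_parcels_per_hemisphere
  expect_equal(nrow(p), 2 * n)
  expect_equal(sum(p$surface_area_mm2), fx$config$total_cortical_area)
  expect_true(all(p$surface_area_mm2 > 0))
  lidx <- which(p$hemisphere == "left")
  ridx <- which(p$hemisphere == "right")
  expect_equal(length(lidx), n)
  # mirror symmetry: homologous names, areas, networks
  expect_equal(p$name[lidx], p$name[ridx])
  expect_equal(p$surface_area_mm2[lidx], p$surface_area_mm2[ridx])
  expect_equal(p$network[lidx], p$network[ridx])
  expect_true(all(p$network %in% 1:10))

  adj <- adjacency_matrix(p)
  expect_true(all(adj == t(adj)))
  expect_false(any(diag(adj)))
  # adjacency confined to, and connected within, each hemisphere
  expect_false(any(adj[lidx, ridx]))
  reachable <- function(a) {
    seen <- c(1L); frontier <- c(1L)
    while (length(frontier)) {
      nxt <- setdiff(which(rowSums(a[, frontier, drop = FALSE]) > 0), seen)
      seen <- c(seen, nxt); frontier <- nxt
    }
    length(seen) == nrow(a)
  }
  expect_true(reachable(adj[lidx, lidx]))
  expect_true(reachable(adj[ridx, ridx]))
})

test_that("two parcels per hemisphere give the one-edge minimal graph", {
  cfg <- generator_config(n_parcels_per_hemisphere = 2, n_subjects = 2, seed = 5)
  p <- generate_parcel_table(cfg)
  expect_equal(nrow(p), 4)
  adj <- adjacency_matrix(p)
  lidx <- which(p$hemisphere == "left")
  expect_equal(sum(adj[lidx, lidx]) / 2, 1)  # exactly one undirected edge
})

test_that("generation is deterministic in (config, seed) and config is validated", {
  cfg <- small_config()
  fx1 <- make_fixture(cfg)
  fx2 <- make_fixture(cfg)
  expect_identical(fx1$parcels, fx2$parcels)
  expect_identical(fx1$lengths, fx2$lengths)
  expect_identical(fx1$cohort, fx2$cohort)
  fx3 <- make_fixture(small_config(seed = 202))
  expect_false(identical(fx1$cohort$subjects[[1]]$streamlines,
                         fx3$cohort$subjects[[1]]$streamlines))

  expect_error(generator_config(edr_lambda = -1), "edr_lambda")
  expect_error(generator_config(adjacency_boost = 0.5), "adjacency_boost")
  expect_error(generator_config(length_range = c(5, 5)), "length_range")
  expect_error(generator_config(n_parcels_per_hemisphere = 0),
               "n_parcels_per_hemisphere")
})

test_that("length matrix is symmetric, bounded, and hemisphere-structured", {
  fx <- make_fixture()
  L <- fx$lengths
  expect_equal(L, t(L))
  expect_equal(unname(diag(L)), rep(0, nrow(L)))
  off <- L[upper.tri(L)]
  expect_true(all(off >= fx$config$length_range[1]))
  expect_true(all(off <= fx$config$length_range[2]))

  pt <- pair_table(L, fx$parcels)
  expect_gt(mean(pt$value[!pt$intra]), mean(pt$value[pt$intra]))
  # adjacent parcels receive short lengths
  expect_lt(mean(pt$value[pt$adjacent]), mean(pt$value[pt$intra & !pt$adjacent]))
})

test_that("noise-free cohort is an exact deterministic function of length", {
  cfg <- small_config(lognormal_sigma = 0, adjacency_boost = 1,
                      callosal_area_sd = 0)
  fx <- make_fixture(cfg)
  S1 <- fx$cohort$subjects[[1]]$streamlines
  S2 <- fx$cohort$subjects[[2]]$streamlines
  expect_identical(S1, S2)
  # S = s0 * exp(-lambda * L) off the diagonal
  s0 <- fx$cohort$manifest$streamline_scale
  expected <- s0 * exp(-cfg$edr_lambda * fx$lengths)
  diag(expected) <- 0
  expect_equal(S1, expected, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("subject matrices are symmetric, nonnegative, labeled", {
  fx <- make_fixture()
  for (s in fx$cohort$subjects) {
    expect_equal(s$streamlines, t(s$streamlines))
    expect_true(all(s$streamlines >= 0))
    expect_equal(unname(diag(s$streamlines)), rep(0, nrow(s$streamlines)))
    expect_gt(s$callosal_area, 0)
    expect_true(s$sex %in% c("F", "M"))
    expect_true(s$age_group %in% c("22-25", "26-30", "31-35"))
  }
  expect_equal(fx$cohort$manifest$true_axons_per_streamline,
               fx$config$true_axons_per_streamline)
})

test_that("pooled mean log-streamlines decline at the configured EDR rate", {
  cfg <- generator_config(n_parcels_per_hemisphere = 30, n_subjects = 50,
                          seed = 77)
  fx <- make_fixture(cfg)
  logs <- Reduce(`+`, lapply(fx$cohort$subjects, function(s) {
    log(s$streamlines + diag(1, nrow(s$streamlines)))
  })) / length(fx$cohort$subjects)
  pt <- pair_table(logs, fx$parcels, fx$lengths)
  pt <- pt[!pt$adjacent, ]  # boosted pairs sit off the EDR line by design
  fit <- lm(value ~ length, data = pt)
  ci <- confint(fit)["length", ]
  expect_gt(-cfg$edr_lambda, ci[1])
  expect_lt(-cfg$edr_lambda, ci[2])
  expect_equal(unname(coef(fit)["length"]), -cfg$edr_lambda, tolerance = 0.02)
})

test_that("log weights of nonadjacent pairs pass a normality check", {
  fx <- make_fixture(generator_config(n_parcels_per_hemisphere = 30,
                                      n_subjects = 2, seed = 13))
  S <- fx$cohort$subjects[[1]]$streamlines
  B <- true_axon_matrix(fx$cohort) / fx$config$true_axons_per_streamline
  pt_s <- pair_table(S, fx$parcels)
  pt_b <- pair_table(B, fx$parcels)
  # residual log weight about the EDR expectation is the pair noise
  resid <- log(pt_s$value[!pt_s$adjacent]) - log(pt_b$value[!pt_b$adjacent])
  resid <- if (length(resid) > 4000) resid[seq(1, length(resid), length.out = 4000)] else resid
  expect_gt(shapiro.test(resid)$p.value, 0.01)
})

test_that("intra- and interhemispheric EDR slopes agree by construction", {
  cfg <- generator_config(n_parcels_per_hemisphere = 30, n_subjects = 1,
                          adjacency_boost = 1, seed = 31)
  fx <- make_fixture(cfg)
  res <- parity_test(fx$cohort$subjects[[1]]$streamlines, fx$lengths,
                     fx$parcels, n_boot = 200, n_perm = 199, seed = 9)
  expect_gt(res$slope_diff_ci[2], 0)
  expect_lt(res$slope_diff_ci[1], 0)
})

test_that("a written cohort round-trips through the readers", {
  fx <- make_fixture(small_config(n_subjects = 3))
  dir <- withr::local_tempdir()
  write_cohort(fx$cohort, fx$parcels, fx$lengths, dir)
  p2 <- read_parcel_table(file.path(dir, "parcels.tsv"))
  expect_equal(p2, fx$parcels)
  L2 <- read_matrix(file.path(dir, "lengths.csv"), p2, "length")
  expect_equal(L2, fx$lengths, tolerance = 1e-10)
  subj <- read_subjects(file.path(dir, "subjects.tsv"), p2)
  expect_equal(length(subj), 3)
  expect_equal(subj[[2]]$streamlines, fx$cohort$subjects[[2]]$streamlines,
               tolerance = 1e-6)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$true_axons_per_streamline,
               fx$config$true_axons_per_streamline)
})
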