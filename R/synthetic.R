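# Seeded synthetic connectome cohorts. The generator reproduces the
# statistical structure the downstream analyses assume: pairwise connectivity
# that is log-normally distributed across nonadjacent pairs, declines
# exponentially with fiber length at the same rate within and between
# hemispheres, and is disproportionally strong for physically adjacent pairs;
# callosal areas scattered about the cohort mean; mirror-symmetric parcel
# geometry. Parcel geometry is abstract: lengths come from a random planar
# embedding of each hemisphere plus an interhemispheric offset, not from
# anatomy, because the pipeline only ever consumes a length matrix.

#' Synthetic cohort generator configuration
#'
#' Free parameters of the synthetic connectome generator. Defaults encode the
#' study conditions the analyses assume: 180 parcels per hemisphere, total
#' white-gray surface area 1.77e5 mm^2, mean callosal cross-section
#' 689.45 mm^2, fiber lengths up to 300 mm, and a ground-truth conversion
#' ratio of 2 axons per streamline. The streamline scale is chosen internally
#' so that callosal anatomy and the ground-truth ratio are mutually
#' consistent: `callosal_area_mean * calibration_density =
#' true_axons_per_streamline * E[interhemispheric streamline sum]`, which is
#' what makes calibration a closed loop on synthetic data.
#'
#' @param n_parcels_per_hemisphere parcels per hemisphere (default 180).
#' @param n_subjects subjects in the cohort (default 50).
#' @param total_cortical_area total white-gray interface area, mm^2.
#' @param edr_lambda exponential decay rate of mean log-connectivity with
#'   fiber length, 1/mm.
#' @param lognormal_sigma standard deviation of the multiplicative log-normal
#'   pair noise (natural-log scale); 0 gives a noise-free cohort.
#' @param adjacency_boost multiplicative factor (>= 1) applied to adjacent
#'   parcel pairs.
#' @param callosal_area_mean,callosal_area_sd mean and SD (mm^2) of the
#'   per-subject callosal cross-sectional area (normal truncated at 0).
#' @param true_axons_per_streamline ground-truth conversion ratio recorded in
#'   the cohort manifest.
#' @param calibration_density callosal packing density (axons/mm^2) used to
#'   tie the streamline scale to callosal anatomy.
#' @param length_range `c(min, max)` fiber length in mm.
#' @param adjacency_k neighbors per parcel in the k-nearest-neighbor adjacency
#'   construction.
#' @param seed integer RNG seed; identical `(config, seed)` gives an
#'   identical cohort.
#' @return an object of class `"generator_config"`.
#' @export
generator_config <- function(n_parcels_per_hemisphere = 180,
                             n_subjects = 50,
                             total_cortical_area = 1.77e5,
                             edr_lambda = 0.05,
                             lognormal_sigma = 1.0,
                             adjacency_boost = 8,
                             callosal_area_mean = 689.45,
                             callosal_area_sd = 80,
                             true_axons_per_streamline = 2.0,
                             calibration_density = 3.7e5,
                             length_range = c(10, 300),
                             adjacency_k = 3,
                             seed = 1L) {
  chk_pos <- function(x, field, allow_zero = FALSE) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x) ||
        (if (allow_zero) x < 0 else x <= 0)) {
      stop_config(field, if (allow_zero) "must be a nonnegative number"
                  else "must be a positive number")
    }
  }
  chk_pos(n_parcels_per_hemisphere, "n_parcels_per_hemisphere")
  if (n_parcels_per_hemisphere != round(n_parcels_per_hemisphere)) {
    stop_config("n_parcels_per_hemisphere", "must be an integer")
  }
  chk_pos(n_subjects, "n_subjects")
  chk_pos(total_cortical_area, "total_cortical_area")
  chk_pos(edr_lambda, "edr_lambda")
  chk_pos(lognormal_sigma, "lognormal_sigma", allow_zero = TRUE)
  if (!is.numeric(adjacency_boost) || adjacency_boost < 1) {
    stop_config("adjacency_boost", "must be >= 1")
  }
  chk_pos(callosal_area_mean, "callosal_area_mean")
  chk_pos(callosal_area_sd, "callosal_area_sd", allow_zero = TRUE)
  chk_pos(true_axons_per_streamline, "true_axons_per_streamline")
  chk_pos(calibration_density, "calibration_density")
  if (length(length_range) != 2 || any(!is.finite(length_range)) ||
      length_range[1] <= 0 || length_range[2] <= length_range[1]) {
    stop_config("length_range", "must be c(min, max) with 0 < min < max")
  }
  chk_pos(adjacency_k, "adjacency_k")
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    stop_config("seed", "must be a single integer")
  }
  structure(
    list(n_parcels_per_hemisphere = as.integer(n_parcels_per_hemisphere),
         n_subjects = as.integer(n_subjects),
         total_cortical_area = total_cortical_area,
         edr_lambda = edr_lambda,
         lognormal_sigma = lognormal_sigma,
         adjacency_boost = adjacency_boost,
         callosal_area_mean = callosal_area_mean,
         callosal_area_sd = callosal_area_sd,
         true_axons_per_streamline = true_axons_per_streamline,
         calibration_density = calibration_density,
         length_range = as.numeric(length_range),
         adjacency_k = as.integer(adjacency_k),
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

# Deterministic planar embedding of the left hemisphere's parcels (unit disc);
# the right hemisphere is its mirror image. Derived from the config seed so
# that parcel table and length matrix built separately still agree.
parcel_embedding <- function(config) {
  n <- config$n_parcels_per_hemisphere
  with_local_seed(seed_offset(config$seed, 1), {
    r <- sqrt(stats::runif(n))
    th <- stats::runif(n, 0, 2 * pi)
    cbind(x = r * cos(th), y = r * sin(th))
  })
}

# Mirror-symmetric within-hemisphere adjacency: union of k-nearest-neighbor
# pairs in the embedding, augmented with a minimum spanning tree so each
# hemisphere's graph is connected ("planar-like", no long chords beyond kNN).
hemisphere_adjacency <- function(emb, k) {
  n <- nrow(emb)
  adj <- matrix(FALSE, n, n)
  if (n == 1) return(adj)
  d <- as.matrix(stats::dist(emb))
  k <- min(k, n - 1)
  for (i in seq_len(n)) {
    nn <- order(d[i, ])[2:(k + 1)]
    adj[i, nn] <- TRUE
    adj[nn, i] <- TRUE
  }
  # Prim's MST to guarantee connectivity
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  while (!all(in_tree)) {
    dd <- d[in_tree, !in_tree, drop = FALSE]
    w <- which(dd == min(dd), arr.ind = TRUE)[1, ]
    i <- which(in_tree)[w[1]]
    j <- which(!in_tree)[w[2]]
    adj[i, j] <- adj[j, i] <- TRUE
    in_tree[j] <- TRUE
  }
  diag(adj) <- FALSE
  adj
}

#' Generate a synthetic parcel table
#'
#' Builds `2 * n_parcels_per_hemisphere` parcels with mirror-symmetric areas,
#' networks and adjacency. Areas are gamma-distributed, mirrored across
#' hemispheres, and rescaled to sum exactly to `total_cortical_area`. Networks
#' are 10 angular sectors of the embedding, so they are spatially contiguous.
#'
#' @param config a `"generator_config"`.
#' @return a `"parcel_table"` with left-hemisphere parcels first.
#' @export
generate_parcel_table <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_parcels_per_hemisphere
  emb <- parcel_embedding(config)
  areas_half <- with_local_seed(seed_offset(config$seed, 2), {
    stats::rgamma(n, shape = 6, rate = 1)
  })
  areas_half <- areas_half / sum(areas_half) * (config$total_cortical_area / 2)
  network <- as.integer(cut(atan2(emb[, "y"], emb[, "x"]),
                            breaks = seq(-pi, pi, length.out = 11),
                            include.lowest = TRUE))
  adj_half <- hemisphere_adjacency(emb, config$adjacency_k)
  names_half <- sprintf("P%03d", seq_len(n))
  # left parcels get ids 0..n-1, right mirror ids n..2n-1
  neighbors <- c(
    lapply(seq_len(n), function(i) which(adj_half[i, ]) - 1L),
    lapply(seq_len(n), function(i) which(adj_half[i, ]) - 1L + n)
  )
  parcel_table(
    parcel_id = 0:(2L * n - 1L),
    name = rep(names_half, 2),
    hemisphere = rep(c("left", "right"), each = n),
    surface_area_mm2 = rep(areas_half, 2),
    network = rep(network, 2),
    neighbors = neighbors
  )
}

#' Generate a synthetic fiber-length matrix
#'
#' Lengths are affine-rescaled Euclidean distances in the parcel embedding:
#' each hemisphere occupies a disc, the right hemisphere mirrors the left, and
#' interhemispheric pairs incur the physical separation of the two discs (a
#' callosal detour), so interhemispheric fibers are on average longer. All
#' entries fall inside `length_range`; adjacent parcels, being embedding
#' neighbors, receive short lengths.
#'
#' @param parcels parcel table from `generate_parcel_table()` on the same
#'   config.
#' @param config the same `"generator_config"`.
#' @return symmetric matrix of fiber lengths (mm), zero diagonal.
#' @export
generate_length_matrix <- function(parcels, config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_parcels_per_hemisphere
  if (nrow(parcels) != 2 * n) {
    stop_config("n_parcels_per_hemisphere", "does not match the parcel table")
  }
  emb <- parcel_embedding(config)
  sep <- 2.4  # distance between disc centers, in embedding units (radius 1)
  pos <- rbind(cbind(emb[, "x"] - sep / 2, emb[, "y"]),
               cbind(sep / 2 - emb[, "x"], emb[, "y"]))
  raw <- as.matrix(stats::dist(pos))
  off <- raw[upper.tri(raw)]
  lr <- config$length_range
  scaled <- (raw - min(off)) / (max(off) - min(off)) * (lr[2] - lr[1]) + lr[1]
  diag(scaled) <- 0
  dimnames(scaled) <- list(parcel_labels(parcels), parcel_labels(parcels))
  scaled
}

# Noise-free expected streamline matrix: exponential distance rule with a
# common decay rate for intra- and interhemispheric pairs (the parity
# assumption built in), adjacency boost on within-hemisphere neighbor pairs.
base_streamline_matrix <- function(parcels, lengths, config) {
  B <- exp(-config$edr_lambda * lengths)
  diag(B) <- 0
  adj <- adjacency_matrix(parcels)
  B[adj] <- B[adj] * config$adjacency_boost
  lidx <- left_idx(parcels)
  ridx <- right_idx(parcels)
  inter_sum <- sum(B[lidx, ridx])
  # streamline scale tying callosal anatomy to the ground-truth ratio
  s0 <- config$callosal_area_mean * config$calibration_density /
    (config$true_axons_per_streamline * inter_sum)
  structure(B * s0, s0 = s0)
}

#' Generate a synthetic subject cohort
#'
#' Each subject's streamline matrix is the shared noise-free base matrix (see
#' Details) perturbed by independent mean-one log-normal pair noise
#' `exp(sigma * z - sigma^2 / 2)`, drawn symmetrically. Callosal areas are
#' drawn from a normal truncated at zero; sex and age-group labels are
#' assigned. The manifest records the configuration, the ground-truth
#' conversion ratio, and the implied true mean axon matrix
#' (`true_axons_per_streamline` times the base matrix).
#'
#' @details The base matrix follows an exponential distance rule,
#' `E[S_ij] = S0 * exp(-edr_lambda * L_ij)`, with adjacent within-hemisphere
#' pairs multiplied by `adjacency_boost`, and identical decay rates for intra-
#' and interhemispheric pairs. Because the pair noise has unit mean, the mean
#' log-streamline declines with length at exactly `-edr_lambda` per mm.
#'
#' @param parcels parcel table from the same config.
#' @param lengths length matrix from the same config.
#' @param config the `"generator_config"`.
#' @return a list of class `"synthetic_cohort"` with elements `subjects`
#'   (list of `"subject_record"`) and `manifest`.
#' @export
generate_cohort <- function(parcels, lengths, config) {
  stopifnot(inherits(config, "generator_config"))
  B <- base_streamline_matrix(parcels, lengths, config)
  s0 <- attr(B, "s0")
  attr(B, "s0") <- NULL
  n <- nrow(parcels)
  ut <- upper.tri(B)
  sigma <- config$lognormal_sigma
  with_local_seed(seed_offset(config$seed, 3), {
    subjects <- lapply(seq_len(config$n_subjects), function(s) {
      S <- B
      if (sigma > 0) {
        z <- stats::rnorm(sum(ut))
        noise <- matrix(1, n, n)
        noise[ut] <- exp(sigma * z - sigma^2 / 2)
        tn <- t(noise)
        noise[lower.tri(noise)] <- tn[lower.tri(noise)]
        S <- B * noise
      }
      area <- -1
      while (area <= 0) {
        area <- stats::rnorm(1, config$callosal_area_mean, config$callosal_area_sd)
      }
      subject_record(
        sprintf("S%04d", s), S, area,
        sex = sample(c("F", "M"), 1),
        age_group = sample(c("22-25", "26-30", "31-35"), 1,
                           prob = c(0.4, 0.45, 0.15))
      )
    })
    manifest <- list(
      config = unclass(config),
      true_axons_per_streamline = config$true_axons_per_streamline,
      streamline_scale = s0,
      true_mean_axon_matrix = config$true_axons_per_streamline * B
    )
    structure(list(subjects = subjects, manifest = manifest),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cfg <- x$manifest$config
  cat(sprintf("Synthetic cohort: %d subjects, %d parcels (%d per hemisphere)\n",
              length(x$subjects), 2 * cfg$n_parcels_per_hemisphere,
              cfg$n_parcels_per_hemisphere))
  cat(sprintf("  true axons/streamline: %.4g, EDR lambda: %.3g /mm, sigma: %.3g\n",
              cfg$true_axons_per_streamline, cfg$edr_lambda, cfg$lognormal_sigma))
  invisible(x)
}

#' Ground-truth mean axon matrix of a synthetic cohort
#'
#' @param cohort a `"synthetic_cohort"`.
#' @return the manifest's implied true mean axon matrix.
#' @export
true_axon_matrix <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  cohort$manifest$true_mean_axon_matrix
}

#' Write a full synthetic cohort to disk
#'
#' Writes the parcel table (TSV), length matrix (CSV), per-subject matrices
#' plus subjects table (TSV), the base/true-axon matrix (CSV), and a JSON
#' manifest carrying the configuration and ground truth.
#'
#' @param cohort a `"synthetic_cohort"`.
#' @param parcels,lengths the cohort's parcel table and length matrix.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, parcels, lengths, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_parcel_table(parcels, file.path(dir, "parcels.tsv"))
  write_matrix(lengths, parcels, file.path(dir, "lengths.csv"))
  write_subjects(cohort$subjects, parcels, dir)
  write_matrix(cohort$manifest$true_mean_axon_matrix, parcels,
               file.path(dir, "true_mean_axons.csv"))
  manifest <- cohort$manifest
  manifest$true_mean_axon_matrix <- "true_mean_axons.csv"
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
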