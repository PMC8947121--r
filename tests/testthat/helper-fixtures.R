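# Shared fixtures: small seeded synthetic cohorts plus hand-built toy parcel
# tables, and brute-force oracles (plain double loops over unordered pairs)
# against which the vectorized implementations are checked.

small_config <- function(...) {
  args <- utils::modifyList(
    list(n_parcels_per_hemisphere = 12, n_subjects = 6, seed = 101),
    list(...)
  )
  do.call(generator_config, args)
}

make_fixture <- function(config = small_config()) {
  parcels <- generate_parcel_table(config)
  lengths <- generate_length_matrix(parcels, config)
  cohort <- generate_cohort(parcels, lengths, config)
  list(config = config, parcels = parcels, lengths = lengths, cohort = cohort)
}

# n_left + n_right parcels, chain adjacency within each hemisphere,
# unit areas unless given.
toy_parcels <- function(n_left = 3, n_right = 3, areas = NULL) {
  n <- n_left + n_right
  hemi <- rep(c("left", "right"), c(n_left, n_right))
  ids <- 0:(n - 1)
  chain <- function(first, len) {
    lapply(seq_len(len), function(i) {
      nb <- integer(0)
      if (i > 1) nb <- c(nb, first + i - 2L)
      if (i < len) nb <- c(nb, first + i)
      nb
    })
  }
  parcel_table(
    parcel_id = ids,
    name = c(sprintf("T%02d", seq_len(n_left)), sprintf("T%02d", seq_len(n_right))),
    hemisphere = hemi,
    surface_area_mm2 = if (is.null(areas)) rep(1, n) else areas,
    network = rep(1L, n),
    neighbors = c(chain(0L, n_left), chain(n_left, n_right))
  )
}

# symmetric matrix from upper-triangle values (row-major over i<j)
sym_matrix <- function(n, upper_values) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- NA
  k <- 1
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    m[i, j] <- m[j, i] <- upper_values[k]
    k <- k + 1
  }
  m
}

# Oracles ----------------------------------------------------------------

oracle_pair_medians <- function(m, parcels, include_zeros = TRUE) {
  hemi <- parcels$hemisphere
  intra <- c(); inter <- c()
  for (i in seq_len(nrow(m) - 1)) for (j in (i + 1):nrow(m)) {
    v <- m[i, j]
    if (!include_zeros && v == 0) next
    if (hemi[i] == hemi[j]) intra <- c(intra, v) else inter <- c(inter, v)
  }
  list(intra = stats::median(intra), inter = stats::median(inter))
}

oracle_occupied_volume <- function(n, lengths, per_axon_area) {
  tot <- 0
  for (i in seq_len(nrow(n) - 1)) for (j in (i + 1):nrow(n)) {
    tot <- tot + n[i, j] * lengths[i, j] * per_axon_area
  }
  tot
}

oracle_trans_terminal <- function(n, parcels, anterior, posterior, hemi,
                                  capacity) {
  tot <- 0
  for (a in anterior) for (p in posterior) {
    ia <- which(parcels$name == a & parcels$hemisphere == hemi)
    ip <- which(parcels$name == p & parcels$hemisphere == hemi)
    tot <- tot + n[ia, ip]
  }
  tot / capacity
}
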