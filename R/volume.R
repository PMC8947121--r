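# White-matter volume and interface-area accounting. An axon's effective
# cross-sectional area is the reciprocal of the callosal packing density, so
# it includes myelin, supporting cells and extracellular space by
# construction. Occupied white-matter volume is the sum over parcel pairs of
# axon count x fiber length x per-axon area; interface area is total axons x
# per-axon area. Both are exactly linear in the axon matrix.

#' Effective per-axon cross-sectional area
#'
#' Reciprocal of the callosal packing density, mm^2/axon. Includes myelin and
#' extracellular space, since the packing density counts axons per mm^2 of
#' whole tissue.
#'
#' @param params a [histology_params()] object.
#' @return area in mm^2/axon.
#' @export
#' @examples
#' effective_axon_area(histology_params())  # about 2.7e-6 mm^2
effective_axon_area <- function(params = histology_params()) {
  1 / params$callosal_density
}

#' White-matter volume occupied by interareal axons
#'
#' Sum over unordered parcel pairs of axon count times mean fiber length
#' times effective per-axon cross-sectional area.
#'
#' @param n symmetric axon-count matrix.
#' @param lengths symmetric fiber-length matrix, mm.
#' @param per_axon_area effective per-axon area, mm^2/axon.
#' @param reference_volume optional total hemispheric WM volume, mm^3, for the
#'   occupied fraction.
#' @return list with `volume_mm3` and (if a reference is given) `fraction`.
#' @export
occupied_wm_volume <- function(n, lengths, per_axon_area = effective_axon_area(),
                               reference_volume = NULL) {
  if (!identical(dim(n), dim(lengths))) {
    stop("axon and length matrices are not conformable", call. = FALSE)
  }
  ut <- upper.tri(n)
  missing_len <- which(ut & n > 0 & lengths <= 0, arr.ind = TRUE)
  if (nrow(missing_len)) {
    pairs <- apply(missing_len[seq_len(min(5, nrow(missing_len))), , drop = FALSE],
                   1, paste, collapse = "-")
    stop(sprintf("pairs with axons but no length: %s%s",
                 paste(pairs, collapse = ", "),
                 if (nrow(missing_len) > 5) ", ..." else ""), call. = FALSE)
  }
  vol <- sum(n[ut] * lengths[ut]) * per_axon_area
  out <- list(volume_mm3 = vol)
  if (!is.null(reference_volume)) out$fraction <- vol / reference_volume
  out
}

#' White-gray interface area claimed by interareal axons
#'
#' Total interareal axons times per-axon area, and the fraction of the total
#' white-gray interface this represents.
#'
#' @param total_axons total number of interareal axons.
#' @param per_axon_area effective per-axon area, mm^2/axon.
#' @param white_gray_area_reference total white-gray interface area, mm^2
#'   (default 1.77e5).
#' @return list with `area_mm2` and `fraction`.
#' @export
interface_area <- function(total_axons, per_axon_area = effective_axon_area(),
                           white_gray_area_reference = 1.77e5) {
  area <- total_axons * per_axon_area
  list(area_mm2 = area, fraction = area / white_gray_area_reference)
}

#' Volume budget of subcortical projections
#'
#' Parameterized helper for what-if budgeting: the fraction of white-matter
#' volume that a population of subcortical projection neurons would occupy,
#' assuming one axon per neuron at the given mean path length and per-axon
#' area.
#'
#' @param projecting_neurons number of projecting neurons.
#' @param mean_path_length mean axonal path length, mm.
#' @param per_axon_area effective per-axon area, mm^2/axon.
#' @param wm_volume_reference reference WM volume, mm^3.
#' @return fraction of the reference volume.
#' @export
subcortical_budget <- function(projecting_neurons, mean_path_length,
                               per_axon_area = effective_axon_area(),
                               wm_volume_reference) {
  projecting_neurons * mean_path_length * per_axon_area / wm_volume_reference
}

#' Cortical neural surface density
#'
#' Total cortical neurons divided by total white-gray interface area.
#'
#' @param total_neurons total cortical neurons, interneurons included
#'   (default 16.34e9).
#' @param white_gray_area total white-gray interface area, mm^2
#'   (default 1.77e5).
#' @return neurons/mm^2.
#' @export
#' @examples
#' neural_density()  # about 92,300 neurons/mm^2
neural_density <- function(total_neurons = 16.34e9, white_gray_area = 1.77e5) {
  if (total_neurons <= 0 || white_gray_area <= 0) {
    stop("inputs must be positive", call. = FALSE)
  }
  total_neurons / white_gray_area
}
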