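# Trans-terminal tract fractions: of the axons in the mid-section of a
# fasciculus, how many run the tract's entire length between its two cortical
# termination fields ("tunnel" traffic) rather than entering and exiting
# mid-course ("highway" traffic)? The tract's total axon capacity is its
# cross-sectional area times the ipsilateral packing density; the
# trans-terminal count is the calibrated axon sum between the two termination
# fields, attributing every field-to-field axon to the tract (upper-bound
# semantics: if some run outside the tract, the true fraction is lower).

#' Specify a fiber tract for trans-terminal analysis
#'
#' Termination fields are sets of parcel names (data, not code): conservative
#' and liberal arcuate/superior-longitudinal-fasciculus definitions are
#' shipped as YAML files, see [read_tract_spec()]. Cross-sections may be
#' vectors when the "tract" is a system of bundles (e.g. AF plus SLF); they
#' are summed.
#'
#' @param name tract name.
#' @param cross_section_left,cross_section_right mid-tract cross-sectional
#'   areas, mm^2 (one value per constituent bundle).
#' @param anterior_field,posterior_field disjoint, nonempty sets of parcel
#'   names.
#' @param density axon packing density of ipsilateral tracts, axons/mm^2
#'   (default 3.5e5).
#' @return an object of class `"tract_spec"`.
#' @export
tract_spec <- function(name, cross_section_left, cross_section_right,
                       anterior_field, posterior_field, density = 3.5e5) {
  if (any(cross_section_left <= 0) || any(cross_section_right <= 0)) {
    stop_config("cross_section", "must be positive")
  }
  if (density <= 0) stop_config("density", "must be positive")
  anterior_field <- as.character(anterior_field)
  posterior_field <- as.character(posterior_field)
  if (!length(anterior_field) || !length(posterior_field)) {
    stop("termination fields must be nonempty", call. = FALSE)
  }
  both <- intersect(anterior_field, posterior_field)
  if (length(both)) {
    stop(sprintf("termination fields overlap: %s", paste(both, collapse = ", ")),
         call. = FALSE)
  }
  structure(
    list(name = as.character(name),
         cross_section_left = as.numeric(cross_section_left),
         cross_section_right = as.numeric(cross_section_right),
         anterior_field = anterior_field,
         posterior_field = posterior_field,
         density = density),
    class = "tract_spec"
  )
}

#' Read/write a tract specification (YAML)
#'
#' The package ships AF/SLF specifications under
#' `system.file("extdata", package = "axoncount")`:
#' `afslf_conservative.yaml` (anterior field 44, 45, 6r, IFSa, IFSp, FOP4;
#' posterior field PSL, RI, STV, PFcm) and `afslf_liberal.yaml` (adding 47l,
#' p47r anteriorly and PF, PFm, PGi posteriorly).
#'
#' @param path YAML file path.
#' @return a `"tract_spec"`.
#' @export
read_tract_spec <- function(path) {
  y <- yaml::read_yaml(path)
  tract_spec(
    name = y$name,
    cross_section_left = unlist(y$cross_section_left),
    cross_section_right = unlist(y$cross_section_right),
    anterior_field = unlist(y$anterior_field),
    posterior_field = unlist(y$posterior_field),
    density = y$density %||% 3.5e5
  )
}

#' @rdname read_tract_spec
#' @param spec a `"tract_spec"`.
#' @export
write_tract_spec <- function(spec, path) {
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' Total axon capacity of a tract
#'
#' Sum of the constituent cross-sectional areas times the ipsilateral packing
#' density, per hemisphere.
#'
#' @param spec a `"tract_spec"`.
#' @return named vector `c(left = , right = )`, axons.
#' @export
#' @examples
#' afslf <- read_tract_spec(system.file("extdata", "afslf_conservative.yaml",
#'                                      package = "axoncount"))
#' tract_axon_capacity(afslf)  # about 1.3e8 left, 0.8e8 right
tract_axon_capacity <- function(spec) {
  stopifnot(inherits(spec, "tract_spec"))
  c(left = sum(spec$cross_section_left) * spec$density,
    right = sum(spec$cross_section_right) * spec$density)
}

#' Trans-terminal fraction of a tract's axons
#'
#' Calibrated axons between the tract's two termination fields within each
#' hemisphere (each unordered pair once), divided by the tract's total axon
#' capacity. Assumes every field-to-field axon runs through the tract, so the
#' fraction is an upper bound.
#'
#' @param n symmetric axon-count matrix.
#' @param spec a `"tract_spec"`.
#' @param parcels parcel table; every field parcel name must resolve in both
#'   hemispheres.
#' @return an object of class `"tract_fraction"`: per-hemisphere
#'   `trans_terminal_axons`, `capacity` and `fraction`.
#' @export
trans_terminal_fraction <- function(n, spec, parcels) {
  stopifnot(inherits(spec, "tract_spec"))
  resolve <- function(names_wanted, hemi) {
    idx <- match(names_wanted, parcels$name[parcels$hemisphere == hemi])
    rows <- which(parcels$hemisphere == hemi)[idx]
    if (anyNA(rows)) {
      stop(sprintf("unknown parcel name(s) in %s hemisphere: %s", hemi,
                   paste(names_wanted[is.na(rows)], collapse = ", ")),
           call. = FALSE)
    }
    rows
  }
  capacity <- tract_axon_capacity(spec)
  per_hemi <- vapply(c("left", "right"), function(h) {
    a <- resolve(spec$anterior_field, h)
    p <- resolve(spec$posterior_field, h)
    sum(n[a, p])  # fields disjoint: block sum = each unordered pair once
  }, 0)
  structure(
    list(tract = spec$name,
         trans_terminal_axons = per_hemi,
         capacity = capacity,
         fraction = per_hemi / capacity),
    class = "tract_fraction"
  )
}

#' @export
print.tract_fraction <- function(x, ...) {
  cat(sprintf("Trans-terminal fraction: %s\n", x$tract))
  for (h in c("left", "right")) {
    cat(sprintf("  %s: %.3g of %.3g tract axons = %.2f%%\n", h,
                x$trans_terminal_axons[h], x$capacity[h],
                100 * x$fraction[h]))
  }
  invisible(x)
}
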