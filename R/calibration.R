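# Callosal calibration: the axons-per-streamline conversion ratio.
#
# For each subject s, the number of axons traversing the corpus callosum is
# the callosal cross-sectional area times the histological packing density,
#   K_s = A_s * rho,
# and the conversion ratio is that count divided by the subject's total
# interhemispheric streamline sum,
#   c_s = K_s / sum_{i in L, j in R} S_ij^(s).
# The cohort ratio is the arithmetic mean of the per-subject quotients; the
# ratio of cohort means is reported alongside as a diagnostic (the two differ
# when area and streamline totals covary). The procedure is independent of
# the overall scale of the dMRI metric: rescaling all streamline matrices by
# k rescales every c_s by 1/k, leaving calibrated axon counts unchanged.

#' Number of axons traversing the corpus callosum
#'
#' Callosal cross-sectional area times the histological callosal packing
#' density.
#'
#' @param callosal_area callosal cross-sectional area(s), mm^2; must be > 0.
#' @param params a [histology_params()] object.
#' @return axon count(s), same length as `callosal_area`.
#' @export
#' @examples
#' callosal_axon_count(689.45, histology_params())  # about 2.6e8
callosal_axon_count <- function(callosal_area, params = histology_params()) {
  if (any(!is.finite(callosal_area) | callosal_area <= 0)) {
    stop("callosal_area must be positive", call. = FALSE)
  }
  callosal_area * params$callosal_density
}

#' Total interhemispheric streamline sum
#'
#' Sum of connectivity over all unordered left-right parcel pairs (each pair
#' counted once): the dMRI estimate of total callosal connectivity, since
#' essentially all interhemispheric corticocortical axons cross the callosum.
#'
#' @param m symmetric streamline matrix.
#' @param parcels parcel table defining hemispheres.
#' @return a single number.
#' @export
interhemispheric_streamline_sum <- function(m, parcels) {
  lidx <- left_idx(parcels)
  ridx <- right_idx(parcels)
  if (nrow(m) != nrow(parcels) || ncol(m) != nrow(parcels)) {
    stop("matrix dimensions do not match the parcel table", call. = FALSE)
  }
  sum(m[lidx, ridx])
}

#' Calibrate the axons-per-streamline conversion ratio
#'
#' Fits the streamline-to-axon conversion on a cohort: per subject, divides
#' the anatomically determined callosal axon count (area x density) by the
#' subject's interhemispheric streamline sum; the cohort ratio is the mean of
#' these quotients.
#'
#' @param cohort list of [subject_record()]s, or a generated
#'   `"synthetic_cohort"`.
#' @param parcels parcel table.
#' @param params a [histology_params()] object.
#' @return an object of class `"axon_calibration"` with components
#'   `per_subject` (data frame: id, callosal area, callosal axons,
#'   interhemispheric streamlines, ratio), `cohort_ratio` (mean of quotients),
#'   `ratio_of_means` (diagnostic), `cohort_mean_callosal_axons` and
#'   `cohort_mean_interhemispheric_streamlines`.
#' @seealso [predict.axon_calibration()] to convert a streamline matrix to
#'   axon counts; [apply_conversion()].
#' @export
axon_calibration <- function(cohort, parcels, params = histology_params()) {
  subjects <- as_subject_list(cohort)
  validate_parcel_table(parcels)
  inter <- vapply(subjects, function(s) {
    interhemispheric_streamline_sum(s$streamlines, parcels)
  }, 0)
  ids <- vapply(subjects, `[[`, "", "subject_id")
  if (any(inter <= 0)) {
    stop(sprintf("subject(s) with zero interhemispheric streamlines: %s",
                 paste(ids[inter <= 0], collapse = ", ")), call. = FALSE)
  }
  area <- vapply(subjects, `[[`, 0, "callosal_area")
  axons <- callosal_axon_count(area, params)
  ratio <- axons / inter
  per_subject <- data.frame(
    subject_id = ids,
    callosal_area_mm2 = area,
    callosal_axons = axons,
    interhemispheric_streamlines = inter,
    ratio = ratio,
    stringsAsFactors = FALSE
  )
  structure(
    list(per_subject = per_subject,
         cohort_ratio = mean(ratio),
         ratio_of_means = mean(axons) / mean(inter),
         cohort_mean_callosal_axons = mean(axons),
         cohort_mean_interhemispheric_streamlines = mean(inter),
         params = params,
         n_subjects = length(subjects),
         call = match.call()),
    class = "axon_calibration"
  )
}

#' @export
print.axon_calibration <- function(x, digits = 4, ...) {
  cat("Callosal streamline-to-axon calibration\n")
  cat(sprintf("  subjects: %d\n", x$n_subjects))
  cat(sprintf("  axons per streamline (mean of quotients): %.*g\n",
              digits, x$cohort_ratio))
  cat(sprintf("  ratio of cohort means (diagnostic):       %.*g\n",
              digits, x$ratio_of_means))
  cat(sprintf("  mean callosal axons:                %.*g\n",
              digits, x$cohort_mean_callosal_axons))
  cat(sprintf("  mean interhemispheric streamlines:  %.*g\n",
              digits, x$cohort_mean_interhemispheric_streamlines))
  invisible(x)
}

#' @export
coef.axon_calibration <- function(object, ...) {
  c(axons_per_streamline = object$cohort_ratio)
}

#' @export
summary.axon_calibration <- function(object, ...) {
  r <- object$per_subject$ratio
  structure(
    list(calibration = object,
         ratio_sd = stats::sd(r),
         ratio_range = range(r),
         ratio_quartiles = stats::quantile(r, c(0.25, 0.5, 0.75))),
    class = "summary.axon_calibration"
  )
}

#' @export
print.summary.axon_calibration <- function(x, digits = 4, ...) {
  print(x$calibration, digits = digits)
  cat(sprintf("  per-subject ratio sd: %.*g, range: [%.*g, %.*g]\n",
              digits, x$ratio_sd, digits, x$ratio_range[1],
              digits, x$ratio_range[2]))
  invisible(x)
}

#' Convert streamlines to axon counts
#'
#' `predict()` applies the fitted conversion ratio elementwise to a streamline
#' matrix (typically the cohort mean), yielding the absolute axon-count
#' matrix. `apply_conversion()` is the underlying plain function.
#'
#' @param object an `"axon_calibration"` fit.
#' @param newdata a symmetric streamline matrix.
#' @param ... unused.
#' @return symmetric axon-count matrix with attribute `"ratio"`.
#' @export
predict.axon_calibration <- function(object, newdata, ...) {
  apply_conversion(newdata, object$cohort_ratio)
}

#' @rdname predict.axon_calibration
#' @param mean_streamlines streamline matrix.
#' @param ratio conversion ratio, axons per streamline (> 0).
#' @export
apply_conversion <- function(mean_streamlines, ratio) {
  if (!is.numeric(ratio) || length(ratio) != 1 || !is.finite(ratio) || ratio <= 0) {
    stop("ratio must be a single positive number", call. = FALSE)
  }
  out <- mean_streamlines * ratio
  diag(out) <- 0
  attr(out, "ratio") <- ratio
  out
}

#' @export
plot.axon_calibration <- function(x, ...) {
  graphics::hist(x$per_subject$ratio, breaks = "FD",
                 main = "Per-subject axons-per-streamline ratio",
                 xlab = "axons / streamline", ...)
  graphics::abline(v = x$cohort_ratio, lwd = 2)
  invisible(x)
}
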