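# On-disk interchange: parcel table TSV, dense matrix CSV, subjects TSV,
# histology parameters YAML. Dense CSV is the canonical matrix format; all
# readers validate type invariants and all writers emit files their paired
# reader accepts unchanged.

ASYMMETRY_TOL <- 1e-8  # relative; larger asymmetries are data errors, not rounding

#' Histology parameter set
#'
#' Axon packing densities used for calibration and volume accounting. The
#' defaults are shrinkage-corrected literature values: 3.7e5 axons/mm^2 for the
#' corpus callosum and 3.5e5 axons/mm^2 for ipsilateral (prefrontal) white
#' matter. Densities are taken as already corrected for tissue shrinkage;
#' `shrinkage_corrected` is metadata, no further correction is applied.
#'
#' @param callosal_density callosal axon packing density, axons/mm^2.
#' @param ipsilateral_density ipsilateral tract packing density, axons/mm^2.
#' @param shrinkage_corrected logical flag recording that densities are
#'   shrinkage-corrected.
#' @return an object of class `"histology_params"`.
#' @export
histology_params <- function(callosal_density = 3.7e5,
                             ipsilateral_density = 3.5e5,
                             shrinkage_corrected = TRUE) {
  if (!is.numeric(callosal_density) || length(callosal_density) != 1 ||
      !is.finite(callosal_density) || callosal_density <= 0) {
    stop_config("callosal_density", "must be a single positive number")
  }
  if (!is.numeric(ipsilateral_density) || length(ipsilateral_density) != 1 ||
      !is.finite(ipsilateral_density) || ipsilateral_density <= 0) {
    stop_config("ipsilateral_density", "must be a single positive number")
  }
  structure(
    list(callosal_density = callosal_density,
         ipsilateral_density = ipsilateral_density,
         shrinkage_corrected = isTRUE(shrinkage_corrected)),
    class = "histology_params"
  )
}

#' @export
print.histology_params <- function(x, ...) {
  cat("Histology parameters\n")
  cat(sprintf("  callosal density:    %.3g axons/mm^2\n", x$callosal_density))
  cat(sprintf("  ipsilateral density: %.3g axons/mm^2\n", x$ipsilateral_density))
  cat(sprintf("  shrinkage corrected: %s\n", x$shrinkage_corrected))
  invisible(x)
}

#' Read or write histology parameters (YAML)
#'
#' @param path file path.
#' @return `read_histology_params()` returns a `"histology_params"` object.
#' @export
read_histology_params <- function(path) {
  y <- yaml::read_yaml(path)
  histology_params(
    callosal_density = y$callosal_density %||% 3.7e5,
    ipsilateral_density = y$ipsilateral_density %||% 3.5e5,
    shrinkage_corrected = y$shrinkage_corrected %||% TRUE
  )
}

#' @rdname read_histology_params
#' @param params a `"histology_params"` object.
#' @export
write_histology_params <- function(params, path) {
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# parcel table ------------------------------------------------------------

#' Construct and validate a parcel table
#'
#' A parcel table lists the cortical parcels of the atlas: dense 0-based ids,
#' names, hemisphere, white-gray surface area (mm^2), a functional network
#' label in 1..10, and the within-hemisphere adjacency (neighbor) relation.
#'
#' @param parcel_id integer ids, 0-based and dense.
#' @param name parcel names (unique within hemisphere).
#' @param hemisphere `"left"` or `"right"` per parcel.
#' @param surface_area_mm2 positive surface areas.
#' @param network integer network labels in 1..10.
#' @param neighbors list of integer vectors of neighbor parcel ids; must be
#'   symmetric and irreflexive.
#' @return a `data.frame` of class `"parcel_table"`.
#' @export
parcel_table <- function(parcel_id, name, hemisphere, surface_area_mm2,
                         network, neighbors) {
  tab <- data.frame(
    parcel_id = as.integer(parcel_id),
    name = as.character(name),
    hemisphere = as.character(hemisphere),
    surface_area_mm2 = as.numeric(surface_area_mm2),
    network = as.integer(network),
    stringsAsFactors = FALSE
  )
  tab$neighbors <- lapply(neighbors, function(v) sort(as.integer(v)))
  class(tab) <- c("parcel_table", "data.frame")
  validate_parcel_table(tab)
  tab
}

#' @rdname parcel_table
#' @param parcels object to validate.
#' @export
validate_parcel_table <- function(parcels) {
  n <- nrow(parcels)
  req <- c("parcel_id", "name", "hemisphere", "surface_area_mm2",
           "network", "neighbors")
  missing_cols <- setdiff(req, names(parcels))
  if (length(missing_cols)) {
    stop(sprintf("parcel table is missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  ids <- parcels$parcel_id
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate parcel ids at rows: %s",
                 paste(which(duplicated(ids)), collapse = ", ")), call. = FALSE)
  }
  if (!setequal(ids, seq_len(n) - 1L)) {
    stop("parcel ids must be dense 0..n-1", call. = FALSE)
  }
  if (!all(parcels$hemisphere %in% c("left", "right"))) {
    bad <- which(!parcels$hemisphere %in% c("left", "right"))
    stop(sprintf("unknown hemisphere label at row(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (any(!is.finite(parcels$surface_area_mm2) | parcels$surface_area_mm2 <= 0)) {
    bad <- which(!is.finite(parcels$surface_area_mm2) | parcels$surface_area_mm2 <= 0)
    stop(sprintf("nonpositive surface area at row(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (any(!parcels$network %in% 1:10)) {
    stop("network labels must be integers in 1..10", call. = FALSE)
  }
  # neighbor relation: known ids, irreflexive, symmetric
  for (i in seq_len(n)) {
    nb <- parcels$neighbors[[i]]
    if (any(!nb %in% ids)) {
      stop(sprintf("row %d: neighbor id(s) not in table: %s", i,
                   paste(setdiff(nb, ids), collapse = ", ")), call. = FALSE)
    }
    if (ids[i] %in% nb) {
      stop(sprintf("row %d: parcel listed as its own neighbor", i), call. = FALSE)
    }
    for (j in nb) {
      row_j <- match(j, ids)
      if (!(ids[i] %in% parcels$neighbors[[row_j]])) {
        stop(sprintf("asymmetric adjacency: parcel %d lists %d but not vice versa (row %d)",
                     ids[i], j, i), call. = FALSE)
      }
    }
  }
  invisible(parcels)
}

#' Read/write a parcel table (TSV)
#'
#' Columns: `parcel_id`, `name`, `hemisphere`, `surface_area_mm2`, `network`,
#' `neighbors` (semicolon-joined ids, empty allowed). Invariants are validated
#' on read; write-then-read is the identity on canonical form.
#'
#' @param path TSV file path.
#' @return a `"parcel_table"`.
#' @export
read_parcel_table <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE)
  req <- c("parcel_id", "name", "hemisphere", "surface_area_mm2",
           "network", "neighbors")
  missing_cols <- setdiff(req, names(raw))
  if (length(missing_cols)) {
    stop(sprintf("parcel table file '%s' is missing column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  neighbors <- lapply(raw$neighbors, function(s) {
    if (is.na(s) || !nzchar(s)) integer(0) else as.integer(strsplit(s, ";")[[1]])
  })
  ord <- order(as.integer(raw$parcel_id))
  parcel_table(
    parcel_id = as.integer(raw$parcel_id)[ord],
    name = raw$name[ord],
    hemisphere = raw$hemisphere[ord],
    surface_area_mm2 = as.numeric(raw$surface_area_mm2)[ord],
    network = as.integer(raw$network)[ord],
    neighbors = neighbors[ord]
  )
}

#' @rdname read_parcel_table
#' @param parcels a `"parcel_table"`.
#' @export
write_parcel_table <- function(parcels, path) {
  validate_parcel_table(parcels)
  out <- data.frame(
    parcel_id = parcels$parcel_id,
    name = parcels$name,
    hemisphere = parcels$hemisphere,
    surface_area_mm2 = parcels$surface_area_mm2,
    network = parcels$network,
    neighbors = vapply(parcels$neighbors, function(v) paste(v, collapse = ";"), ""),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# matrices ----------------------------------------------------------------

validate_square_matrix <- function(m, parcels, what, negative_ok = FALSE) {
  n <- nrow(parcels)
  if (!is.matrix(m) || nrow(m) != n || ncol(m) != n) {
    stop(sprintf("%s matrix must be %d x %d, got %d x %d", what, n, n,
                 NROW(m), NCOL(m)), call. = FALSE)
  }
  if (anyNA(m) || any(!is.finite(m))) {
    stop(sprintf("%s matrix contains NA/non-finite entries", what), call. = FALSE)
  }
  if (!negative_ok && any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("%s matrix has a negative entry at [%d, %d]", what,
                 bad[1], bad[2]), call. = FALSE)
  }
  # symmetrize within tolerance, reject beyond it
  asym <- abs(m - t(m))
  scale <- max(abs(m), .Machine$double.xmin)
  rel <- max(asym) / scale
  if (rel > ASYMMETRY_TOL) {
    w <- sort(which(asym == max(asym), arr.ind = TRUE)[1, ])
    stop(sprintf(
      "%s matrix asymmetric beyond tolerance (relative %.3g at cell [%d, %d])",
      what, rel, w[1], w[2]), call. = FALSE)
  }
  m <- (m + t(m)) / 2
  diag(m) <- 0
  dimnames(m) <- list(parcel_labels(parcels), parcel_labels(parcels))
  m
}

#' Read/write a dense square connectivity or length matrix (CSV)
#'
#' Matrices are stored as dense CSV with a header row of hemisphere-qualified
#' parcel labels, rows in parcel-id order. On read, dimensions are checked
#' against the parcel table, NA/negative entries are rejected, and asymmetry
#' up to a relative tolerance of 1e-8 is averaged away (beyond it, an error
#' names the worst cell).
#'
#' @param path CSV file path.
#' @param parcels parcel table defining dimension and order.
#' @param kind `"streamline"` (or `"axon"`) for nonnegative connectivity,
#'   `"length"` for fiber lengths in mm.
#' @return validated symmetric numeric matrix with zero diagonal.
#' @export
read_matrix <- function(path, parcels, kind = c("streamline", "length", "axon")) {
  kind <- match.arg(kind)
  raw <- utils::read.csv(path, header = TRUE, check.names = FALSE)
  m <- as.matrix(raw)
  storage.mode(m) <- "double"
  validate_square_matrix(m, parcels, kind)
}

#' @rdname read_matrix
#' @param m square numeric matrix.
#' @export
write_matrix <- function(m, parcels, path) {
  m <- validate_square_matrix(m, parcels, "output")
  utils::write.table(m, path, sep = ",", quote = FALSE, row.names = FALSE,
                     col.names = parcel_labels(parcels))
  invisible(path)
}

# subjects ----------------------------------------------------------------

#' Construct a subject record
#'
#' One subject's streamline matrix together with the anatomical and
#' demographic fields used by calibration and group comparison.
#'
#' @param subject_id subject identifier.
#' @param streamlines symmetric nonnegative streamline matrix.
#' @param callosal_area callosal cross-sectional area, mm^2 (> 0).
#' @param sex `"F"` or `"M"`.
#' @param age_group age-group label.
#' @return an object of class `"subject_record"`.
#' @export
subject_record <- function(subject_id, streamlines, callosal_area,
                           sex = NA_character_, age_group = NA_character_) {
  if (!is.numeric(callosal_area) || length(callosal_area) != 1 ||
      !is.finite(callosal_area) || callosal_area <= 0) {
    stop(sprintf("subject '%s': callosal_area must be a positive number",
                 subject_id), call. = FALSE)
  }
  structure(
    list(subject_id = as.character(subject_id), streamlines = streamlines,
         callosal_area = callosal_area, sex = as.character(sex),
         age_group = as.character(age_group)),
    class = "subject_record"
  )
}

#' Read/write a subject table plus per-subject matrices
#'
#' The subjects TSV has columns `subject_id`, `callosal_area_mm2`, `sex`,
#' `age_group`, `matrix_path` (relative to the TSV's directory). Each matrix
#' is read and validated against the parcel table.
#'
#' @param path subjects TSV path.
#' @param parcels parcel table.
#' @return list of `"subject_record"` objects.
#' @export
read_subjects <- function(path, parcels) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  req <- c("subject_id", "callosal_area_mm2", "sex", "age_group", "matrix_path")
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols)) {
    stop(sprintf("subjects table missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  base <- dirname(path)
  lapply(seq_len(nrow(tab)), function(i) {
    m <- read_matrix(file.path(base, tab$matrix_path[i]), parcels, "streamline")
    subject_record(tab$subject_id[i], m, tab$callosal_area_mm2[i],
                   tab$sex[i], tab$age_group[i])
  })
}

#' @rdname read_subjects
#' @param subjects list of `"subject_record"` objects.
#' @param dir output directory (created if absent); matrices are written as
#'   `<subject_id>.csv` beside the `subjects.tsv`.
#' @export
write_subjects <- function(subjects, parcels, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tab <- data.frame(
    subject_id = vapply(subjects, `[[`, "", "subject_id"),
    callosal_area_mm2 = vapply(subjects, `[[`, 0, "callosal_area"),
    sex = vapply(subjects, `[[`, "", "sex"),
    age_group = vapply(subjects, `[[`, "", "age_group"),
    matrix_path = paste0(vapply(subjects, `[[`, "", "subject_id"), ".csv"),
    stringsAsFactors = FALSE
  )
  for (s in subjects) {
    write_matrix(s$streamlines, parcels, file.path(dir, paste0(s$subject_id, ".csv")))
  }
  utils::write.table(tab, file.path(dir, "subjects.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file.path(dir, "subjects.tsv"))
}

#' Mean streamline matrix of a cohort
#'
#' Elementwise mean of the subjects' streamline matrices, the cohort-level
#' connectivity to which the conversion ratio is applied.
#'
#' @param subjects list of `"subject_record"`s (or a generated cohort).
#' @return symmetric numeric matrix.
#' @export
cohort_mean_matrix <- function(subjects) {
  subjects <- as_subject_list(subjects)
  Reduce(`+`, lapply(subjects, `[[`, "streamlines")) / length(subjects)
}

# Accept either a bare list of subject records or a generated cohort object.
as_subject_list <- function(x) {
  if (inherits(x, "subject_record")) return(list(x))
  if (is.list(x) && !is.null(x$subjects)) x <- x$subjects
  if (!length(x) || !all(vapply(x, inherits, TRUE, "subject_record"))) {
    stop("expected a list of subject_record objects", call. = FALSE)
  }
  x
}
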