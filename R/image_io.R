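#' 3D scalar volume with voxel geometry
#'
#' A `volume_image` is the package's container for a 3D scalar grid (signal
#' intensity in arbitrary units, or T2 in milliseconds) together with its
#' voxel spacing in mm per axis and the world position of the first voxel
#' centre. All distances in the package are computed in mm from the spacing,
#' never in raw voxel units, because the morphological and quantitative
#' acquisitions live on different grids (roughly 0.5 mm isotropic vs
#' 0.37 x 0.37 x 3 mm).
#'
#' @param values 3D numeric array. `NA` marks missing/masked voxels.
#' @param spacing numeric length-3, mm per axis; all entries > 0.
#' @param origin numeric length-3, world coordinate (mm) of voxel (1,1,1).
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite numbers (mm)")
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite numbers (mm)")
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  cat("<volume_image> ", paste(dim(x$values), collapse = " x "),
      " voxels, spacing ", paste(format(x$spacing), collapse = " x "),
      " mm\n", sep = "")
  v <- x$values[is.finite(x$values)]
  if (length(v))
    cat("  value range: ", format(min(v)), " .. ", format(max(v)),
        "  (", sum(is.na(x$values)), " missing)\n", sep = "")
  invisible(x)
}

#' @export
dim.volume_image <- function(x) dim(x$values)

#' Integer-labelled 3D grid
#'
#' A `label_map` shares the grid geometry of [volume_image()] but stores
#' non-negative integer labels plus a dictionary mapping label codes to
#' region names. Label 0 is always background and never appears in the
#' dictionary.
#'
#' @param values 3D integer array of labels (>= 0).
#' @param dict named integer vector: names are region names, values codes.
#'   Every nonzero label present in `values` must appear in `dict`.
#' @param spacing,origin as in [volume_image()].
#' @return An object of class `label_map`.
#' @export
label_map <- function(values, dict, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  storage.mode(values) <- "integer"
  if (anyNA(values) || any(values < 0L))
    stop("labels must be non-negative integers without NA")
  dict <- as.integer(dict) |> setNames(names(dict))
  if (is.null(names(dict)) || any(names(dict) == ""))
    stop("`dict` must be a fully named integer vector")
  if (any(dict == 0L)) stop("label 0 is reserved for background")
  if (anyDuplicated(dict) || anyDuplicated(names(dict)))
    stop("`dict` codes and names must be unique")
  present <- setdiff(unique(as.vector(values)), 0L)
  missing <- setdiff(present, dict)
  if (length(missing))
    stop("labels present but not in dictionary: ",
         paste(missing, collapse = ", "))
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be 3 positive numbers (mm)")
  structure(list(values = values, dict = dict, spacing = spacing,
                 origin = as.numeric(origin)),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat("<label_map> ", paste(dim(x$values), collapse = " x "),
      " voxels, ", length(x$dict), " labelled regions\n", sep = "")
  invisible(x)
}

#' @export
dim.label_map <- function(x) dim(x$values)

# Shared-grid check used before any voxelwise comparison of two images.
same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

stopifnot_same_grid <- function(a, b) {
  if (!same_grid(a, b))
    stop("images are not on the same grid (dimensions, spacing or origin differ)")
  invisible(TRUE)
}

#' Canonical cartilage subregion label vocabulary
#'
#' The fixed label dictionary for the 21 anatomical cartilage subregions
#' (6 patellar, 6 tibial, 9 femoral) plus the three depth layers and the
#' bone/bulk-cartilage codes used by the phantom generator.
#'
#' @return Named integer vector of the 21 subregion codes (10--30).
#' @export
subregion_labels <- function() {
  c(patella_medial_superior   = 10L,
    patella_medial_central    = 11L,
    patella_medial_inferior   = 12L,
    patella_lateral_superior  = 13L,
    patella_lateral_central   = 14L,
    patella_lateral_inferior  = 15L,
    tibia_medial_anterior     = 16L,
    tibia_medial_central      = 17L,
    tibia_medial_posterior    = 18L,
    tibia_lateral_anterior    = 19L,
    tibia_lateral_central     = 20L,
    tibia_lateral_posterior   = 21L,
    femur_trochlea_medial     = 22L,
    femur_trochlea_central    = 23L,
    femur_trochlea_lateral    = 24L,
    femur_medial_anterior     = 25L,
    femur_medial_central      = 26L,
    femur_medial_posterior    = 27L,
    femur_lateral_anterior    = 28L,
    femur_lateral_central     = 29L,
    femur_lateral_posterior   = 30L)
}

layer_labels <- function() c(deep = 1L, transitional = 2L, superficial = 3L)

# ---------------------------------------------------------------------------
# NIfTI I/O (via RNifti)

nifti_geometry <- function(img) {
  xf <- RNifti::xform(img)
  spacing <- sqrt(colSums(xf[1:3, 1:3]^2))
  if (any(spacing <= 0)) {
    pd <- RNifti::pixdim(img)
    spacing <- pd[seq_len(3)]
  }
  origin <- xf[1:3, 4]
  list(spacing = as.numeric(spacing), origin = as.numeric(origin))
}

#' Read a 3D volume from a NIfTI file
#'
#' @param path path to a `.nii` or `.nii.gz` file containing a 3D image.
#' @return A [volume_image()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  if (length(dim(a)) != 3L)
    stop("expected a 3D image, got ", length(dim(a)), " dimensions: ", path)
  g <- nifti_geometry(img)
  attributes(a) <- list(dim = dim(a))
  volume_image(a, spacing = g$spacing, origin = g$origin)
}

#' Write a volume to a NIfTI file
#'
#' Spacing and origin are written to both the qform and sform so the file is
#' interpreted identically by third-party viewers.
#'
#' @param volume a [volume_image()].
#' @param path destination path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "volume_image"))
  write_nifti_raw(volume$values, volume$spacing, volume$origin, path,
                  datatype = "double")
}

write_nifti_raw <- function(values, spacing, origin, path, datatype) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir)
  img <- RNifti::asNifti(values, datatype = datatype)
  img <- RNifti::updateNifti(img, list(pixdim = c(-1, spacing, 1, 1, 1, 1)))
  m <- diag(c(spacing, 1))
  m[1:3, 4] <- origin
  RNifti::qform(img) <- structure(m, code = 2L)
  RNifti::sform(img) <- structure(m, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a label map from a NIfTI file
#'
#' @param path path to an integer-valued NIfTI file.
#' @param dict label dictionary (named integer vector); defaults to the
#'   labels actually present, named `label_<code>`.
#' @return A [label_map()].
#' @export
read_label_map <- function(path, dict = NULL) {
  vol <- read_volume(path)
  vals <- vol$values
  if (max(abs(vals - round(vals)), na.rm = TRUE) > 1e-6)
    stop("file does not contain integer labels: ", path)
  vals <- array(as.integer(round(vals)), dim(vals))
  if (is.null(dict)) {
    present <- setdiff(sort(unique(as.vector(vals))), 0L)
    dict <- setNames(present, paste0("label_", present))
  }
  label_map(vals, dict, spacing = vol$spacing, origin = vol$origin)
}

#' Write a label map to a NIfTI file
#'
#' Labels are stored as 16-bit integers; the dictionary is written to a
#' YAML sidecar `<path>.labels.yaml`.
#'
#' @param labels a [label_map()].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_label_map <- function(labels, path) {
  stopifnot(inherits(labels, "label_map"))
  write_nifti_raw(labels$values, labels$spacing, labels$origin, path,
                  datatype = "int16")
  yaml::write_yaml(as.list(labels$dict), paste0(path, ".labels.yaml"))
  invisible(path)
}

# ---------------------------------------------------------------------------
# Feature tables

feature_table_columns <- function() {
  c("subregion", "layer", "n_voxels", "volume_mm3", "mean_thickness_mm",
    "mean_t2_ms", "autocorrelation", "contrast", "correlation",
    "dissimilarity", "energy", "entropy", "homogeneity")
}

#' Write a per-region feature table to CSV
#'
#' One row per (subregion, layer) with a fixed column order: voxel count,
#' volume, thickness, mean T2 and the 7 GLCM features. Columns absent from
#' `table` are written as `NA` so files are schema-stable.
#'
#' @param table data.frame with at least `subregion` and `layer` columns.
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  if (!is.data.frame(table) || nrow(table) == 0L)
    stop("feature table must be a non-empty data.frame")
  if (!all(c("subregion", "layer") %in% names(table)))
    stop("feature table needs `subregion` and `layer` columns")
  key <- paste(table$subregion, table$layer)
  if (anyDuplicated(key))
    stop("duplicate (subregion, layer) keys: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  cols <- feature_table_columns()
  for (cl in setdiff(cols, names(table))) table[[cl]] <- NA_real_
  out <- table[, cols]
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#' @param path CSV path.
#' @return data.frame with the canonical column order.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  read.csv(path, stringsAsFactors = FALSE)
}
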