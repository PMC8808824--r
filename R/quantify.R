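# Morphometry and T2 statistics per subregion and layer: region volumes,
# distance-transform thickness, the [5, 150] ms T2 physical window, and
# laminar mean T2 extraction.

#' Region volumes from a label map
#'
#' Voxel count and physical volume (count x voxel volume) per labelled
#' region. Regions present in the dictionary but absent from the map are
#' reported with zero count.
#'
#' @param labels a [label_map()].
#' @return data.frame with columns `region`, `n_voxels`, `volume_mm3`.
#' @export
region_volume <- function(labels) {
  stopifnot(inherits(labels, "label_map"))
  vv <- prod(labels$spacing)
  counts <- vapply(labels$dict,
                   function(code) sum(labels$values == code), integer(1))
  data.frame(region = names(labels$dict),
             n_voxels = as.integer(counts),
             volume_mm3 = counts * vv,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Voxelwise cartilage thickness map
#'
#' Local thickness at each cartilage voxel is estimated from the two
#' distance transforms as `d_surf + d_bci - s`, where `s` is the mean voxel
#' spacing. The correction accounts for the fact that both distances are
#' measured to the *centres* of voxels one step beyond the cartilage, which
#' together overshoot the physical thickness by about one voxel. Validated
#' against slabs and analytic shells of known thickness.
#'
#' @param depth a [compute_depth_field()] result.
#' @return An object of class `thickness_map`: the thickness array (`NA`
#'   outside cartilage, mm) plus spacing.
#' @export
thickness_map <- function(depth) {
  stopifnot(inherits(depth, "depth_field"))
  corr <- mean(depth$spacing)
  th <- depth$d_surf + depth$d_bci - corr
  th[!depth$mask] <- NA_real_
  th[depth$mask & th <= 0] <- min(depth$spacing)  # never 0 on cartilage
  structure(list(values = th, spacing = depth$spacing,
                 correction_mm = corr),
            class = "thickness_map")
}

#' @export
print.thickness_map <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat("<thickness_map> mean ", format(mean(v), digits = 4), " mm (range ",
      format(min(v), digits = 3), " .. ", format(max(v), digits = 3),
      ")\n", sep = "")
  invisible(x)
}

#' Mean regional thickness
#' @param thickness a [thickness_map()].
#' @param labels a [label_map()] of regions on the same grid.
#' @return data.frame with columns `region`, `mean_thickness_mm`.
#' @export
region_thickness <- function(thickness, labels) {
  stopifnot(inherits(thickness, "thickness_map"),
            inherits(labels, "label_map"))
  means <- vapply(labels$dict, function(code) {
    v <- thickness$values[labels$values == code]
    if (!length(v)) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  data.frame(region = names(labels$dict), mean_thickness_mm = means,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Apply the T2 physical window
#'
#' Voxels with T2 below 5 ms or above 150 ms are marked missing and excluded
#' from all downstream statistics; the retained interval is closed
#' (exactly 5 or 150 ms is kept).
#'
#' @param t2 a [volume_image()] T2 map in ms.
#' @param lower,upper window bounds (ms).
#' @return The thresholded T2 map.
#' @export
threshold_t2 <- function(t2, lower = 5, upper = 150) {
  stopifnot(inherits(t2, "volume_image"))
  vals <- t2$values
  vals[!is.na(vals) & (vals < lower | vals > upper)] <- NA_real_
  volume_image(vals, t2$spacing, t2$origin)
}

#' Mean T2 per subregion and layer
#'
#' For every subregion: the bulk mean T2 plus the deep, transitional and
#' superficial layer means, with the count of contributing (non-missing)
#' voxels. Missing voxels are excluded, never counted as zero; a cell whose
#' voxels are all missing is reported as `NA`. The bulk mean equals the
#' voxel-count-weighted mean of its three layer means by construction.
#'
#' @param t2 a [volume_image()] T2 map, coregistered to the label grid and
#'   thresholded.
#' @param labels subregion [label_map()].
#' @param layers layer [label_map()] from [assign_layers()], or `NULL` for
#'   bulk-only extraction.
#' @return data.frame with columns `subregion`, `layer` (bulk, deep,
#'   transitional, superficial), `n_voxels`, `mean_t2_ms`.
#' @export
region_mean_t2 <- function(t2, labels, layers = NULL) {
  stopifnot(inherits(t2, "volume_image"), inherits(labels, "label_map"))
  stopifnot_same_grid(t2, labels)
  if (!is.null(layers)) {
    stopifnot(inherits(layers, "label_map"))
    stopifnot_same_grid(labels, layers)
  }
  rows <- list()
  for (rn in names(labels$dict)) {
    code <- labels$dict[[rn]]
    in_region <- labels$values == code
    cell <- function(sel, layer_name) {
      v <- t2$values[sel]
      v <- v[!is.na(v)]
      data.frame(subregion = rn, layer = layer_name,
                 n_voxels = length(v),
                 mean_t2_ms = if (length(v)) mean(v) else NA_real_,
                 stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <- cell(in_region, "bulk")
    if (!is.null(layers)) {
      for (ln in names(layer_labels())) {
        sel <- in_region & layers$values == layer_labels()[[ln]]
        rows[[length(rows) + 1L]] <- cell(sel, ln)
      }
    }
  }
  do.call(rbind, rows)
}

#' Assemble the per-region feature table
#'
#' Joins volume, thickness, laminar T2 and (optionally) GLCM texture into
#' one row per (subregion, layer); the canonical tabular product of the
#' pipeline. Volume and thickness are morphological quantities and are
#' reported on the bulk rows and per-layer voxel splits.
#'
#' @param labels subregion [label_map()].
#' @param layers layer [label_map()].
#' @param t2 thresholded, coregistered T2 [volume_image()].
#' @param depth the [compute_depth_field()] result.
#' @param texture optional data.frame from [texture_table()].
#' @return data.frame in [write_feature_table()] column order.
#' @export
region_feature_table <- function(labels, layers, t2, depth, texture = NULL) {
  t2tab <- region_mean_t2(t2, labels, layers)
  th <- thickness_map(depth)
  vv <- prod(labels$spacing)
  t2tab$volume_mm3 <- NA_real_
  t2tab$mean_thickness_mm <- NA_real_
  for (i in seq_len(nrow(t2tab))) {
    code <- labels$dict[[t2tab$subregion[i]]]
    sel <- labels$values == code
    if (t2tab$layer[i] != "bulk")
      sel <- sel & layers$values == layer_labels()[[t2tab$layer[i]]]
    t2tab$volume_mm3[i] <- sum(sel) * vv
    tv <- th$values[sel]
    t2tab$mean_thickness_mm[i] <-
      if (any(is.finite(tv))) mean(tv, na.rm = TRUE) else NA_real_
  }
  if (!is.null(texture)) {
    t2tab <- merge(t2tab, texture, by = c("subregion", "layer"),
                   all.x = TRUE, sort = FALSE)
  }
  cols <- intersect(feature_table_columns(), names(t2tab))
  t2tab[order(t2tab$subregion, t2tab$layer), cols]
}
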