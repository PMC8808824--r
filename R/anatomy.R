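# Anatomical stratification: depth field along the surface-BCI axis,
# laminar thirds, and partition of bulk cartilage into the 21 subregions
# (6 patellar, 6 tibial, 9 femoral).

# Distance (mm) from every voxel to the nearest TRUE voxel, anisotropy-aware.
edt_mm <- function(feature, spacing) {
  stopifnot(is.array(feature), length(dim(feature)) == 3L)
  d2 <- .edt_sq_cpp(as.logical(feature), dim(feature), as.numeric(spacing))
  array(sqrt(d2), dim(feature))
}

#' Compute the cartilage depth field
#'
#' For every cartilage voxel: `d_bci`, the Euclidean distance in mm to the
#' nearest bone voxel; `d_surf`, the distance to the nearest background
#' voxel (neither cartilage nor bone, i.e. the articular surface side); and
#' the normalized depth fraction `f = d_bci / (d_bci + d_surf)`, which is 0
#' toward the bone-cartilage interface (BCI) and 1 toward the articular
#' surface. Distances are computed with an exact Euclidean distance
#' transform in physical units, so anisotropic grids are handled correctly.
#'
#' @param cartilage logical 3D array, or a [label_map()] whose nonzero
#'   voxels are cartilage.
#' @param bone logical 3D array, or a [label_map()] whose nonzero voxels are
#'   bone.
#' @param spacing voxel spacing mm/axis (taken from the label map if one is
#'   given).
#' @return An object of class `depth_field` with fields `d_bci`, `d_surf`,
#'   `f` (arrays, `NA` outside cartilage), `mask`, and `spacing`.
#' @export
compute_depth_field <- function(cartilage, bone, spacing = NULL) {
  if (inherits(cartilage, "label_map")) {
    if (is.null(spacing)) spacing <- cartilage$spacing
    cartilage <- cartilage$values > 0L
  }
  if (inherits(bone, "label_map")) bone <- bone$values > 0L
  if (is.null(spacing)) stop("`spacing` is required with plain array input")
  stopifnot(identical(dim(cartilage), dim(bone)))
  if (!any(cartilage)) stop("cartilage mask is empty")
  if (!any(bone)) stop("bone mask is empty")
  background <- !cartilage & !bone
  if (!any(background)) stop("no background voxels: articular surface undefined")
  d_bci <- edt_mm(bone, spacing)
  d_surf <- edt_mm(background, spacing)
  # cartilage must actually touch bone somewhere
  if (min(d_bci[cartilage]) > 2 * max(spacing))
    stop("cartilage has no bone contact: nearest bone voxel is ",
         format(min(d_bci[cartilage])), " mm away")
  f <- d_bci / (d_bci + d_surf)
  d_bci[!cartilage] <- NA_real_
  d_surf[!cartilage] <- NA_real_
  f[!cartilage] <- NA_real_
  structure(list(d_bci = d_bci, d_surf = d_surf, f = f,
                 mask = cartilage, spacing = as.numeric(spacing)),
            class = "depth_field")
}

#' @export
print.depth_field <- function(x, ...) {
  cat("<depth_field> ", sum(x$mask), " cartilage voxels; depth fraction ",
      format(min(x$f, na.rm = TRUE), digits = 3), " .. ",
      format(max(x$f, na.rm = TRUE), digits = 3), "\n", sep = "")
  invisible(x)
}

#' Assign laminar layers by depth thirds
#'
#' Cartilage is stratified into three layers as equal thirds along the
#' surface-BCI axis: deep (`f <= 1/3`), transitional (`1/3 < f <= 2/3`) and
#' superficial (`f > 2/3`). Ties at the boundaries are closed on the deep
#' side. The three layers partition the cartilage mask exactly.
#'
#' @param depth a [compute_depth_field()] result.
#' @return A [label_map()] with codes deep = 1, transitional = 2,
#'   superficial = 3.
#' @export
assign_layers <- function(depth) {
  stopifnot(inherits(depth, "depth_field"))
  f <- depth$f
  lay <- array(0L, dim(f))
  lay[depth$mask] <- ifelse(f[depth$mask] <= 1 / 3, 1L,
                            ifelse(f[depth$mask] <= 2 / 3, 2L, 3L))
  label_map(lay, layer_labels(), spacing = depth$spacing)
}

#' Atlas specification for the 21-subregion partition
#'
#' Parameterizes the anatomical split planes and break fractions. The
#' medial/lateral split is the intercondylar sagittal plane (midpoint of
#' each compartment's cartilage extent along x); tibial plateaus are split
#' anterior/central/posterior by fractions of the compartment's
#' anteroposterior (y) extent; the patella is split into medial/lateral
#' halves and superior/central/inferior fractions of its z extent; femoral
#' cartilage anterior to the trochlear boundary forms the trochlea (split
#' medial/central/lateral along x), the remainder splits into medial and
#' lateral condyles, each cut into three equal angular sectors about the
#' condylar (x) axis.
#'
#' @param ap_breaks increasing fractions in (0,1) cutting the tibial AP
#'   extent (default thirds).
#' @param si_breaks increasing fractions in (0,1) cutting the patellar
#'   superoinferior extent (default thirds).
#' @param troch_frac fraction of the femoral angular range (from its
#'   anterior end) assigned to the trochlea.
#' @param max_bone_distance_mm cartilage farther than this from every bone
#'   is reported as unassignable.
#' @return An object of class `atlas_spec`.
#' @export
atlas_spec <- function(ap_breaks = c(1 / 3, 2 / 3),
                       si_breaks = c(1 / 3, 2 / 3),
                       troch_frac = 1 / 3,
                       max_bone_distance_mm = 10) {
  chk <- function(b, nm) {
    if (length(b) != 2L || any(b <= 0) || any(b >= 1) || diff(b) <= 0)
      stop("`", nm, "` must be two strictly increasing fractions in (0,1)")
  }
  chk(ap_breaks, "ap_breaks"); chk(si_breaks, "si_breaks")
  if (troch_frac <= 0 || troch_frac >= 1)
    stop("`troch_frac` must be in (0,1)")
  structure(list(ap_breaks = ap_breaks, si_breaks = si_breaks,
                 troch_frac = troch_frac,
                 max_bone_distance_mm = max_bone_distance_mm),
            class = "atlas_spec")
}

# cut values into 3 bins at range fractions, closed on the lower side
cut_thirds <- function(v, breaks) {
  rng <- range(v)
  b <- rng[1] + breaks * diff(rng)
  ifelse(v <= b[1], 1L, ifelse(v <= b[2], 2L, 3L))
}

#' Partition bulk cartilage into the 21 anatomical subregions
#'
#' Every cartilage voxel is first attributed to its nearest bone compartment
#' (femur, tibia or patella, by Euclidean distance in mm), then subdivided
#' by the [atlas_spec()] rules. The output labels use the fixed
#' [subregion_labels()] vocabulary and form a voxel-exact partition of the
#' input cartilage mask.
#'
#' @param cartilage a [label_map()] whose nonzero voxels are bulk cartilage.
#' @param bones a [label_map()] with compartment codes; names in its
#'   dictionary must contain "femur", "tibia" and/or "patella".
#' @param atlas an [atlas_spec()].
#' @return A [label_map()] with the 21 subregion codes (10--30).
#' @export
partition_subregions <- function(cartilage, bones, atlas = atlas_spec()) {
  stopifnot(inherits(cartilage, "label_map"), inherits(bones, "label_map"),
            inherits(atlas, "atlas_spec"))
  stopifnot_same_grid(cartilage, bones)
  dims <- dim(cartilage$values); sp <- cartilage$spacing
  cart <- cartilage$values > 0L
  if (!any(cart)) stop("cartilage mask is empty")
  comp_of <- function(pattern) {
    codes <- bones$dict[grepl(pattern, names(bones$dict))]
    if (!length(codes)) return(NULL)
    bones$values %in% codes & bones$values > 0L
  }
  comp_masks <- Filter(Negate(is.null),
                       list(femur = comp_of("femur"),
                            tibia = comp_of("tibia"),
                            patella = comp_of("patella")))
  comp_masks <- Filter(function(m) any(m), comp_masks)
  if (!length(comp_masks)) stop("no femur/tibia/patella bone compartments found")
  dists <- lapply(comp_masks, function(m) edt_mm(array(m, dims), sp))
  dmat <- sapply(dists, function(d) d[cart])
  if (is.null(dim(dmat))) dmat <- matrix(dmat, ncol = length(dists))
  nearest <- max.col(-dmat, ties.method = "first")
  dmin <- dmat[cbind(seq_len(nrow(dmat)), nearest)]
  bad <- which(dmin > atlas$max_bone_distance_mm)
  if (length(bad)) {
    offenders <- which(cart)[bad]
    stop("cartilage voxels unassignable to a bone compartment (distance > ",
         atlas$max_bone_distance_mm, " mm): linear indices ",
         paste(utils::head(offenders, 10), collapse = ", "),
         if (length(offenders) > 10) " ..." else "")
  }
  compartment <- names(comp_masks)[nearest]

  idx <- which(cart)
  ai <- arrayInd(idx, dims)
  wx <- (ai[, 1] - 1) * sp[1]
  wy <- (ai[, 2] - 1) * sp[2]
  wz <- (ai[, 3] - 1) * sp[3]
  labs <- subregion_labels()
  out <- integer(length(idx))

  assign_tibia <- function(sel) {
    ml <- ifelse(wx[sel] <= stats::median(range(wx[sel])), "medial", "lateral")
    ap <- c("anterior", "central", "posterior")[cut_thirds(-wy[sel],
                                                           atlas$ap_breaks)]
    labs[paste0("tibia_", ml, "_", ap)]
  }
  assign_patella <- function(sel) {
    ml <- ifelse(wx[sel] <= stats::median(range(wx[sel])), "medial", "lateral")
    si <- c("superior", "central", "inferior")[cut_thirds(-wz[sel],
                                                          atlas$si_breaks)]
    labs[paste0("patella_", ml, "_", si)]
  }
  assign_femur <- function(sel) {
    bone_idx <- which(comp_masks$femur)
    bi <- arrayInd(bone_idx, dims)
    yc <- mean((bi[, 2] - 1) * sp[2])
    zc <- mean((bi[, 3] - 1) * sp[3])
    th <- atan2(wz[sel] - zc, wy[sel] - yc) * 180 / pi
    # unwrap about the occupied range so the arc is contiguous
    med <- atan2(mean(sin(th * pi / 180)), mean(cos(th * pi / 180))) * 180 / pi
    th <- (th - med + 180) %% 360 - 180 + med
    rng <- range(th)
    troch_cut <- rng[2] - atlas$troch_frac * diff(rng)
    res <- integer(length(th))
    is_troch <- th > troch_cut
    if (any(is_troch)) {
      mlc <- c("medial", "central", "lateral")[cut_thirds(wx[sel][is_troch],
                                                          c(1 / 3, 2 / 3))]
      res[is_troch] <- labs[paste0("femur_trochlea_", mlc)]
    }
    if (any(!is_troch)) {
      xs <- wx[sel][!is_troch]
      ml <- ifelse(xs <= stats::median(range(xs)), "medial", "lateral")
      thc <- th[!is_troch]
      sector <- c("posterior", "central", "anterior")[cut_thirds(thc,
                                                                 c(1 / 3, 2 / 3))]
      res[!is_troch] <- labs[paste0("femur_", ml, "_", sector)]
    }
    res
  }

  for (cmp in unique(compartment)) {
    sel <- compartment == cmp
    out[sel] <- switch(cmp,
                       tibia = assign_tibia(sel),
                       patella = assign_patella(sel),
                       femur = assign_femur(sel))
  }
  vals <- array(0L, dims)
  vals[idx] <- out
  if (any(vals[cart] == 0L)) stop("internal error: unlabelled cartilage voxel")
  label_map(vals, labs, spacing = sp, origin = cartilage$origin)
}
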