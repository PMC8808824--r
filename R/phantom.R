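# Synthetic knee-like phantoms with known ground truth. These stand in for
# 7-T patient data: a high-resolution morphological volume (DESS-like,
# 0.5 mm isotropic by default) with bone/cartilage labels, plus T2 maps with
# a laminar depth profile, optional focal lesions, test-retest replicates
# and boundary-perturbed masks for agreement studies.

# Evaluate code with a local, restorable RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(code)
}

#' Laminar T2 depth profile
#'
#' Describes how T2 varies with normalized depth f (0 at the bone-cartilage
#' interface, 1 at the articular surface). `linear` interpolates between the
#' deep and superficial endpoint; `layers` paints each depth third at its own
#' constant value; `constant` is flat. Defaults are the healthy-cartilage
#' laminar group means reported for 7-T knee T2 (deep 22.3 ms, superficial
#' 33.9 ms).
#'
#' @param type one of `"linear"`, `"layers"`, `"constant"`.
#' @param deep,superficial T2 (ms) at the deep/superficial end.
#' @param transitional T2 (ms) of the middle third (only for `"layers"`).
#' @param value T2 (ms) for `"constant"`.
#' @return An object of class `t2_profile`.
#' @export
t2_profile <- function(type = c("linear", "layers", "constant"),
                       deep = 22.3, superficial = 33.9,
                       transitional = 26.8, value = 27.7) {
  type <- match.arg(type)
  vals <- switch(type,
                 linear = c(deep, superficial),
                 layers = c(deep, transitional, superficial),
                 constant = value)
  if (any(vals <= 5 | vals >= 150))
    stop("profile T2 values must lie inside the (5, 150) ms physical window")
  structure(list(type = type, deep = deep, superficial = superficial,
                 transitional = transitional, value = value),
            class = "t2_profile")
}

profile_eval <- function(profile, f) {
  switch(profile$type,
         linear = profile$deep + (profile$superficial - profile$deep) * f,
         layers = ifelse(f <= 1 / 3, profile$deep,
                         ifelse(f <= 2 / 3, profile$transitional,
                                profile$superficial)),
         constant = rep(profile$value, length(f)))
}

#' Phantom specification
#'
#' Parameters of a synthetic cartilage phantom. Geometry is either a flat
#' `slab` (cartilage sheet on a bone substrate, through-thickness along z) or
#' a `curved-shell` (constant-thickness cartilage over a cylindrical bone
#' cap, axis along x, with known analytic thickness everywhere).
#'
#' @param geometry `"slab"` or `"curved-shell"`.
#' @param shape grid size in voxels (length 3).
#' @param spacing voxel spacing mm/axis (length 3 or scalar).
#' @param cartilage_thickness_mm cartilage thickness (> 0).
#' @param bone_thickness_mm bone substrate thickness.
#' @param profile a [t2_profile()].
#' @param noise_sigma additive Gaussian noise SD on painted T2 (ms).
#' @param lesions list of [lesion_spec()] objects.
#' @param inplane_margin_mm background margin around the slab in-plane
#'   (default 0 = slab spans the full in-plane extent); a nonzero margin
#'   leaves room for rigid-motion replicates.
#' @param z_margin_mm background below the bone substrate (default 0).
#' @param angular_extent_deg angular coverage of the shell cartilage (deg).
#' @param bone_radius_mm outer bone radius of the shell; default fits grid.
#' @param morph_noise_sigma noise SD on the morphological intensities (a.u.).
#' @param seed integer random seed; identical spec + seed gives bit-identical
#'   phantoms.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(geometry = c("slab", "curved-shell"),
                         shape = c(32L, 32L, 24L),
                         spacing = c(0.5, 0.5, 0.5),
                         cartilage_thickness_mm = 2,
                         bone_thickness_mm = 2,
                         profile = t2_profile(),
                         noise_sigma = 1,
                         lesions = list(),
                         inplane_margin_mm = 0,
                         z_margin_mm = 0,
                         angular_extent_deg = 120,
                         bone_radius_mm = NULL,
                         morph_noise_sigma = 2,
                         seed = 0L) {
  geometry <- match.arg(geometry)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (!is.numeric(cartilage_thickness_mm) || cartilage_thickness_mm <= 0)
    stop("cartilage thickness must be > 0")
  if (bone_thickness_mm <= 0) stop("bone thickness must be > 0")
  stopifnot(inherits(profile, "t2_profile"))
  if (noise_sigma < 0) stop("noise sigma must be >= 0")
  structure(list(geometry = geometry, shape = as.integer(shape),
                 spacing = as.numeric(spacing),
                 cartilage_thickness_mm = cartilage_thickness_mm,
                 bone_thickness_mm = bone_thickness_mm,
                 profile = profile, noise_sigma = noise_sigma,
                 lesions = lesions,
                 inplane_margin_mm = inplane_margin_mm,
                 z_margin_mm = z_margin_mm,
                 angular_extent_deg = angular_extent_deg,
                 bone_radius_mm = bone_radius_mm,
                 morph_noise_sigma = morph_noise_sigma,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Focal low-grade lesion specification
#'
#' Models an ICRS grade I-like lesion: normal thickness and surface, but an
#' intrachondral signal alteration — an additive T2 shift plus local
#' smoothing that lowers high-frequency T2 variance (so GLCM homogeneity
#' rises and dissimilarity falls in the lesional region).
#'
#' @param center_mm ellipsoid centre in world mm (length 3).
#' @param radii_mm ellipsoid semi-axes in mm (length 3 or scalar).
#' @param delta_t2_ms additive T2 change inside the lesion (ms).
#' @param smoothing unitless factor >= 1; local T2 fluctuations are divided
#'   by this factor (1 = no smoothing).
#' @return An object of class `lesion_spec`.
#' @export
lesion_spec <- function(center_mm, radii_mm, delta_t2_ms = 1.4,
                        smoothing = 2) {
  if (length(radii_mm) == 1L) radii_mm <- rep(radii_mm, 3L)
  if (any(radii_mm <= 0)) stop("lesion radii must be > 0")
  if (smoothing < 1) stop("smoothing factor must be >= 1")
  structure(list(center_mm = as.numeric(center_mm),
                 radii_mm = as.numeric(radii_mm),
                 delta_t2_ms = delta_t2_ms, smoothing = smoothing),
            class = "lesion_spec")
}

# world coordinates of voxel centres along each axis (origin at 0)
axis_coords <- function(n, spacing) (seq_len(n) - 1) * spacing

morph_intensity <- function(region, wx, wy, wz, sigma, seed) {
  # region codes: 0 bg, 1 bone, 2 cartilage. Smooth deterministic modulation
  # gives the registration metric in-plane structure beyond the interfaces.
  base <- c(20, 120, 400)[region + 1L]
  modul <- 1 + 0.15 * sin(0.37 * wx) * cos(0.23 * wy) + 0.1 * sin(0.29 * wz)
  vals <- base * ifelse(region == 2L, modul, 1)
  if (sigma > 0) vals <- vals + with_seed(seed, rnorm(length(vals), 0, sigma))
  vals
}

#' Generate a slab phantom
#'
#' Bone substrate below a flat cartilage sheet, through-thickness along the
#' z axis, cartilage spanning the full in-plane extent.
#'
#' @param spec a [phantom_spec()] with `geometry = "slab"`.
#' @return list with `volume` ([volume_image()]), `labels` ([label_map()]
#'   with codes bone = 1, cartilage = 2) and `truth` (ground-truth geometry).
#' @export
make_slab <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (spec$geometry != "slab") stop("spec geometry is not 'slab'")
  dims <- spec$shape; sp <- spec$spacing
  nb <- max(1L, as.integer(round(spec$bone_thickness_mm / sp[3])))
  nc <- as.integer(round(spec$cartilage_thickness_mm / sp[3]))
  mz <- as.integer(round(spec$z_margin_mm / sp[3]))
  if (nc < 1L) stop("cartilage thickness must be at least one voxel")
  if (mz + nb + nc + 1L > dims[3])
    stop("slab (bone + cartilage) exceeds the grid along z")
  mx <- as.integer(round(spec$inplane_margin_mm / sp[1]))
  my <- as.integer(round(spec$inplane_margin_mm / sp[2]))
  if (2L * mx >= dims[1] - 1L || 2L * my >= dims[2] - 1L)
    stop("in-plane margin leaves no slab")
  ix <- (mx + 1L):(dims[1] - mx)
  iy <- (my + 1L):(dims[2] - my)
  region <- array(0L, dims)
  region[ix, iy, mz + seq_len(nb)] <- 1L
  region[ix, iy, mz + nb + seq_len(nc)] <- 2L
  w <- expand_world(dims, sp)
  vol_values <- array(morph_intensity(as.vector(region), w$x, w$y, w$z,
                                      spec$morph_noise_sigma, spec$seed),
                      dims)
  labels <- label_map(region, c(bone = 1L, cartilage = 2L), spacing = sp)
  list(volume = volume_image(vol_values, spacing = sp),
       labels = labels,
       truth = list(geometry = "slab",
                    thickness_mm = nc * sp[3],
                    cartilage_voxels = length(ix) * length(iy) * nc,
                    cartilage_z = mz + nb + seq_len(nc)))
}

expand_world <- function(dims, sp) {
  cx <- axis_coords(dims[1], sp[1])
  cy <- axis_coords(dims[2], sp[2])
  cz <- axis_coords(dims[3], sp[3])
  list(x = rep(cx, times = dims[2] * dims[3]),
       y = rep(rep(cy, each = dims[1]), times = dims[3]),
       z = rep(cz, each = dims[1] * dims[2]))
}

#' Generate a curved-shell phantom
#'
#' Constant-thickness cartilage shell over a cylindrical bone cap (axis
#' along x), emulating femoral-condyle-like curvature. The analytic
#' thickness is known everywhere and recorded in `truth`.
#'
#' @param spec a [phantom_spec()] with `geometry = "curved-shell"`.
#' @return list with `volume`, `labels` and `truth` as in [make_slab()].
#' @export
make_shell <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (spec$geometry != "curved-shell") stop("spec geometry is not 'curved-shell'")
  if (spec$angular_extent_deg <= 0)
    stop("angular extent must be > 0 degrees")
  dims <- spec$shape; sp <- spec$spacing
  ext <- (dims - 1) * sp
  yc <- ext[2] / 2; zc <- ext[3] / 2
  th <- spec$cartilage_thickness_mm
  rb <- spec$bone_radius_mm
  if (is.null(rb)) rb <- min(ext[2], ext[3]) / 2 - th - 2 * max(sp)
  if (rb <= spec$bone_thickness_mm)
    stop("bone radius too small for the requested bone thickness")
  if (rb + th > min(yc, zc))
    stop("shell radii inconsistent with the grid: cartilage would be clipped")
  w <- expand_world(dims, sp)
  r <- sqrt((w$y - yc)^2 + (w$z - zc)^2)
  theta <- atan2(w$z - zc, w$y - yc) * 180 / pi
  half <- spec$angular_extent_deg / 2
  in_arc <- abs(theta - (-90)) <= half | abs(theta - (-90) + 360) <= half |
    abs(theta - (-90) - 360) <= half
  region <- integer(length(r))
  region[r <= rb & r > rb - spec$bone_thickness_mm] <- 1L
  region[r > rb & r <= rb + th & in_arc] <- 2L
  region <- array(region, dims)
  if (!any(region == 2L)) stop("shell spec yields an empty cartilage mask")
  vol_values <- array(morph_intensity(as.vector(region), w$x, w$y, w$z,
                                      spec$morph_noise_sigma, spec$seed),
                      dims)
  labels <- label_map(region, c(bone = 1L, cartilage = 2L), spacing = sp)
  list(volume = volume_image(vol_values, spacing = sp),
       labels = labels,
       truth = list(geometry = "curved-shell", thickness_mm = th,
                    bone_radius_mm = rb, center_mm = c(yc, zc),
                    cartilage_voxels = sum(region == 2L)))
}

#' Paint a laminar T2 map onto a cartilage mask
#'
#' T2 at each cartilage voxel is the profile evaluated at its normalized
#' depth fraction, plus optional Gaussian noise. Non-cartilage voxels are
#' `NA`. A monotone profile therefore produces the expected laminar ordering
#' superficial > transitional > deep.
#'
#' @param labels a [label_map()] whose cartilage voxels match `depth`.
#' @param depth a [compute_depth_field()] result on the same grid.
#' @param profile a [t2_profile()].
#' @param noise_sigma Gaussian noise SD (ms).
#' @param seed random seed for the noise.
#' @return A [volume_image()] T2 map in ms.
#' @export
paint_t2_laminar <- function(labels, depth, profile = t2_profile(),
                             noise_sigma = 0, seed = 0L) {
  stopifnot(inherits(depth, "depth_field"), inherits(profile, "t2_profile"))
  mask <- depth$mask
  vals <- array(NA_real_, dim(mask))
  f <- depth$f[mask]
  t2 <- profile_eval(profile, f)
  if (noise_sigma > 0)
    t2 <- t2 + with_seed(seed, rnorm(length(t2), 0, noise_sigma))
  vals[mask] <- t2
  volume_image(vals, spacing = depth$spacing)
}

lesion_support <- function(lesion, dims, sp) {
  w <- expand_world(dims, sp)
  d2 <- ((w$x - lesion$center_mm[1]) / lesion$radii_mm[1])^2 +
    ((w$y - lesion$center_mm[2]) / lesion$radii_mm[2])^2 +
    ((w$z - lesion$center_mm[3]) / lesion$radii_mm[3])^2
  array(d2 <= 1, dims)
}

#' Insert a focal lesion into a T2 map
#'
#' Raises the mean T2 inside the lesion support by exactly `delta_t2_ms` and
#' divides local high-frequency T2 fluctuations by the smoothing factor
#' (local structure is replaced by a neighbourhood mean plus shrunken
#' residual, re-centred so the mean shift is exact).
#'
#' @param t2 a [volume_image()] T2 map.
#' @param labels cartilage [label_map()]; the lesion must lie inside the
#'   cartilage mask.
#' @param lesion a [lesion_spec()].
#' @return The modified T2 map.
#' @export
insert_lesion <- function(t2, labels, lesion) {
  stopifnot(inherits(t2, "volume_image"), inherits(labels, "label_map"),
            inherits(lesion, "lesion_spec"))
  stopifnot_same_grid(t2, labels)
  dims <- dim(t2$values)
  supp <- lesion_support(lesion, dims, t2$spacing)
  cart <- labels$values > 0L & is.finite(t2$values)
  if (!any(supp)) stop("lesion support is empty on this grid")
  if (any(supp & !cart))
    stop("lesion support extends outside the cartilage mask")
  vals <- t2$values
  v <- vals
  v[!supp] <- NA_real_
  if (lesion$smoothing > 1) {
    sm <- box_mean3(v)          # neighbourhood mean over support only
    idx <- which(supp)
    res <- vals[idx] - sm[idx]
    new <- sm[idx] + res / lesion$smoothing
    new <- new - mean(new) + mean(vals[idx])   # exact mean preservation
    vals[idx] <- new
  }
  vals[supp] <- vals[supp] + lesion$delta_t2_ms
  volume_image(vals, spacing = t2$spacing, origin = t2$origin)
}

# 3x3x3 box mean ignoring NAs (NA where no finite neighbour).
box_mean3 <- function(a) {
  dims <- dim(a)
  fin <- is.finite(a)
  av <- ifelse(fin, a, 0)
  acc <- array(0, dims); cnt <- array(0, dims)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    sh <- shift3(av, dx, dy, dz)
    cn <- shift3(fin * 1, dx, dy, dz)
    acc <- acc + ifelse(is.na(sh), 0, sh)
    cnt <- cnt + ifelse(is.na(cn), 0, cn)
  }
  out <- acc / cnt
  out[cnt == 0] <- NA_real_
  out
}

# integer shift with NA padding
shift3 <- function(a, dx, dy, dz) {
  dims <- dim(a)
  out <- array(NA_real_, dims)
  sx <- seq_len(dims[1]); sy <- seq_len(dims[2]); sz <- seq_len(dims[3])
  fx <- sx - dx; fy <- sy - dy; fz <- sz - dz
  okx <- fx >= 1 & fx <= dims[1]
  oky <- fy >= 1 & fy <= dims[2]
  okz <- fz >= 1 & fz <= dims[3]
  out[sx[okx], sy[oky], sz[okz]] <- a[fx[okx], fy[oky], fz[okz]]
  out
}

#' Simulate a retest visit by rigid motion and fresh noise
#'
#' Applies a small rigid motion (translation in mm, rotation in degrees
#' about the volume centre) to a volume and its label map, resampling onto
#' the original grid (linear for intensities, nearest neighbour for labels),
#' then adds fresh Gaussian noise. The ground-truth resampling transform is
#' returned for registration recovery tests. Identity motion with zero noise
#' returns bit-identical copies.
#'
#' @param volume a [volume_image()].
#' @param labels a [label_map()] on the same grid.
#' @param translation_mm,rotation_deg rigid motion (length 3 each).
#' @param noise_sigma fresh noise SD added to the volume.
#' @param seed random seed.
#' @return list with `volume`, `labels` and `transform` (the
#'   [affine_transform()] mapping replicate-world to original-world).
#' @export
retest_replicate <- function(volume, labels, translation_mm = c(0, 0, 0),
                             rotation_deg = c(0, 0, 0), noise_sigma = 0,
                             seed = 0L) {
  stopifnot(inherits(volume, "volume_image"), inherits(labels, "label_map"))
  stopifnot_same_grid(volume, labels)
  center <- volume$origin + (dim(volume$values) - 1) * volume$spacing / 2
  motion <- rigid_transform(translation_mm, rotation_deg, center = center)
  tr <- invert_transform(motion)   # resampling transform: new grid -> old
  identityish <- all(translation_mm == 0) && all(rotation_deg == 0)
  if (identityish) {
    new_vol <- volume
    new_lab <- labels
  } else {
    new_vol <- apply_transform(volume, tr, target = volume)
    lab_vol <- apply_transform(
      volume_image(array(as.numeric(labels$values), dim(labels$values)),
                   labels$spacing, labels$origin),
      tr, target = volume, interpolation = "nearest")
    lv <- lab_vol$values
    lv[is.na(lv)] <- 0
    new_lab <- label_map(array(as.integer(round(lv)), dim(lv)), labels$dict,
                         spacing = labels$spacing, origin = labels$origin)
    n0 <- sum(labels$values > 0L); n1 <- sum(new_lab$values > 0L)
    if (n1 < 0.9 * n0)
      stop("rigid motion moves the segmented tissue off the grid (",
           n0 - n1, " voxels lost)")
  }
  if (noise_sigma > 0) {
    vals <- new_vol$values
    vals <- vals + with_seed(seed, array(rnorm(length(vals), 0, noise_sigma),
                                         dim(vals)))
    new_vol <- volume_image(vals, new_vol$spacing, new_vol$origin)
  }
  list(volume = new_vol, labels = new_lab, transform = tr)
}

#' Randomly perturb a segmentation boundary
#'
#' Each boundary voxel (foreground with a background 6-neighbour, or
#' background with a foreground 6-neighbour) is flipped independently with
#' probability `level`. Level 0 is the identity; expected Dice against the
#' original decreases monotonically with level.
#'
#' @param mask a [label_map()]; treated as the binary mask of nonzero labels.
#' @param level flip probability in [0, 1].
#' @param seed random seed.
#' @return A binary [label_map()] (`cartilage = 1`).
#' @export
perturb_mask <- function(mask, level, seed = 0L) {
  stopifnot(inherits(mask, "label_map"))
  if (level < 0 || level > 1) stop("level must be in [0, 1]")
  fg <- mask$values > 0L
  out <- fg
  if (level > 0) {
    nb <- neighbor_count(fg)
    boundary_fg <- fg & nb < 6L
    boundary_bg <- !fg & nb > 0L
    idx <- which(boundary_fg | boundary_bg)
    flip <- with_seed(seed, runif(length(idx)) < level)
    out[idx[flip]] <- !out[idx[flip]]
  }
  label_map(array(as.integer(out), dim(out)), c(cartilage = 1L),
            spacing = mask$spacing, origin = mask$origin)
}

# number of foreground 6-neighbours per voxel (outside grid counts as bg)
neighbor_count <- function(fg) {
  f <- fg * 1
  n <- array(0, dim(fg))
  for (d in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))) {
    sh <- shift3(f, d[1], d[2], d[3])
    n <- n + ifelse(is.na(sh), 0, sh)
  }
  n
}
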