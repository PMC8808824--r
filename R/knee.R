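# Composite knee phantom: three bone compartments (femoral cylinder cap,
# tibial plateau slab, patellar slab) each carrying a cartilage sheet, so
# that the 21-subregion partition, laminar analysis, registration and the
# full pipeline can be exercised end to end with known ground truth.

#' Generate a three-compartment knee phantom
#'
#' World axes: x = medial-lateral, y = posterior-anterior, z =
#' inferior-superior. The femur is a cylindrical bone cap (axis along x)
#' with a constant-thickness cartilage shell over its inferior-to-anterior
#' arc; the tibia is a horizontal plateau slab below it; the patella is a
#' vertical slab anterior to the femur with cartilage facing it. All three
#' cartilage plates have known constant thickness, and a laminar T2 map is
#' painted from the depth field.
#'
#' @param shape grid size in voxels (default 96^3).
#' @param spacing isotropic voxel spacing in mm (default 0.5, the
#'   morphological resolution).
#' @param cartilage_thickness_mm cartilage plate thickness.
#' @param profile a [t2_profile()] for the painted T2 map.
#' @param noise_sigma voxel noise SD on the T2 map (ms).
#' @param t2_spacing spacing of the T2 grid; default `c(0.37, 0.37, 3)`
#'   emulates the coarser quantitative acquisition, forcing the
#'   registration/resampling path. Use `NULL` for a T2 map on the
#'   morphological grid.
#' @param lesion optional [lesion_spec()], or `TRUE` for a default lesion
#'   in the lateral femoral condyle.
#' @param morph_noise_sigma noise SD on morphological intensities.
#' @param seed random seed.
#' @return list with `volume` (morphological [volume_image()]), `bones`
#'   ([label_map()]: bone_femur = 1, bone_tibia = 2, bone_patella = 3),
#'   `cartilage` (binary [label_map()]), `t2` ([volume_image()], on the T2
#'   grid), `depth`, and `truth`.
#' @export
make_knee <- function(shape = c(96L, 96L, 96L), spacing = 0.5,
                      cartilage_thickness_mm = 2,
                      profile = t2_profile(),
                      noise_sigma = 1,
                      t2_spacing = c(0.37, 0.37, 3),
                      lesion = NULL,
                      morph_noise_sigma = 2,
                      seed = 0L) {
  shape <- as.integer(shape)
  sp <- rep(as.numeric(spacing), length.out = 3L)
  ext <- (shape - 1) * sp
  th <- cartilage_thickness_mm
  w <- expand_world(shape, sp)

  region <- integer(prod(shape))   # 0 bg, 1-3 bones, 4 cartilage
  cart <- logical(prod(shape))

  # tibia: plateau slab in the lower part of the grid
  tib_x <- w$x >= 0.10 * ext[1] & w$x <= 0.90 * ext[1]
  tib_y <- w$y >= 0.15 * ext[2] & w$y <= 0.72 * ext[2]
  tib_bone <- tib_x & tib_y & w$z >= 0.08 * ext[3] & w$z <= 0.16 * ext[3]
  tib_cart <- tib_x & tib_y & w$z > 0.16 * ext[3] &
    w$z <= 0.16 * ext[3] + th
  # femur: cylinder along x, centred above the tibial plateau
  yc <- 0.44 * ext[2]; zc <- 0.16 * ext[3] + th + 3 + 0.27 * ext[3]
  rb <- 0.23 * ext[3]
  fem_x <- tib_x
  r <- sqrt((w$y - yc)^2 + (w$z - zc)^2)
  theta <- atan2(w$z - zc, w$y - yc) * 180 / pi   # -90 = inferior, 0 = anterior
  fem_arc <- theta >= -170 & theta <= 80
  fem_bone <- fem_x & r <= rb
  fem_cart <- fem_x & r > rb & r <= rb + th & fem_arc
  # patella: vertical slab anterior to the femur, cartilage facing it
  pat_x <- w$x >= 0.25 * ext[1] & w$x <= 0.75 * ext[1]
  pat_z <- w$z >= zc - 0.18 * ext[3] & w$z <= zc + 0.18 * ext[3]
  y_front <- yc + rb + th
  pat_cart <- pat_x & pat_z & w$y > y_front + 2 & w$y <= y_front + 2 + th
  pat_bone <- pat_x & pat_z & w$y > y_front + 2 + th &
    w$y <= min(y_front + 2 + th + 3, ext[2])

  region[tib_bone] <- 2L
  region[fem_bone] <- 1L
  region[pat_bone] <- 3L
  cart[(tib_cart | fem_cart | pat_cart) & region == 0L] <- TRUE
  region[cart] <- 4L
  region <- array(region, shape)

  morph <- array(morph_intensity(pmin(as.vector(region), 2L), w$x, w$y, w$z,
                                 morph_noise_sigma, seed), shape)
  volume <- volume_image(morph, spacing = sp)
  bones <- label_map(array(ifelse(region %in% 1:3, region, 0L), shape),
                     c(bone_femur = 1L, bone_tibia = 2L, bone_patella = 3L),
                     spacing = sp)
  cart_map <- label_map(array(as.integer(region == 4L), shape),
                        c(cartilage = 1L), spacing = sp)
  depth <- compute_depth_field(cart_map, bones)
  t2 <- paint_t2_laminar(cart_map, depth, profile, noise_sigma, seed + 1L)
  # full-field T2: short T2 in bone, long T2 in the joint space, so the map
  # carries enough structure for multimodal registration (the physical
  # window and the labels confine downstream statistics to cartilage)
  t2v <- t2$values
  fill <- with_seed(seed + 2L, rnorm(length(t2v), 0, max(noise_sigma, 0.5)))
  bone_sel <- region %in% 1:3
  bg_sel <- region == 0L
  t2v[bone_sel] <- 9 + fill[which(bone_sel)]
  t2v[bg_sel] <- 45 + fill[which(bg_sel)]
  t2 <- volume_image(t2v, t2$spacing, t2$origin)
  truth <- list(thickness_mm = th, profile = profile,
                noise_sigma = noise_sigma,
                cartilage_voxels = sum(region == 4L))
  if (isTRUE(lesion)) {
    lesion <- lesion_spec(center_mm = c(0.75 * ext[1], yc, zc - rb - th / 2),
                          radii_mm = c(4, 3, 2), delta_t2_ms = 1.4,
                          smoothing = 4)
  }
  if (inherits(lesion, "lesion_spec")) {
    t2 <- insert_lesion(t2, cart_map, lesion)
    truth$lesion <- lesion
  }
  if (!is.null(t2_spacing)) {
    t2 <- resample_to_grid(t2, t2_spacing)
  }
  list(volume = volume, bones = bones, cartilage = cart_map, t2 = t2,
       depth = depth, truth = truth)
}

#' Resample a volume onto a new grid spacing (identity transform)
#'
#' Covers the same world extent with the requested spacing; used to emulate
#' the coarser quantitative acquisition grid.
#'
#' @param vol a [volume_image()].
#' @param new_spacing length-3 spacing (mm).
#' @return A [volume_image()] on the new grid.
#' @export
resample_to_grid <- function(vol, new_spacing) {
  new_spacing <- rep(as.numeric(new_spacing), length.out = 3L)
  ext <- (dim(vol$values) - 1) * vol$spacing
  ndim <- pmax(2L, as.integer(floor(ext / new_spacing)) + 1L)
  target <- volume_image(array(0, ndim), spacing = new_spacing,
                         origin = vol$origin)
  apply_transform(vol, identity_transform(), target = target)
}
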