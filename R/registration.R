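# Multimodal affine coregistration of T2 maps (moving) onto morphological
# volumes (fixed): 12-DOF affine, mutual-information metric, (1+1)
# evolutionary optimizer over a resolution pyramid, plus a windowed
# similarity-index map as a registration quality marker.

#' 12-DOF affine transform
#'
#' World-coordinate affine map `y = A x + t` (mm). Used as a resampling
#' transform: the value of the registered image at fixed-world position `x`
#' is the moving image sampled at `A x + t`.
#'
#' @param A 3x3 linear part (invertible).
#' @param t length-3 translation (mm).
#' @return An object of class `affine_transform`.
#' @export
affine_transform <- function(A = diag(3), t = c(0, 0, 0)) {
  A <- matrix(as.numeric(A), 3, 3)
  if (abs(det(A)) < 1e-12) stop("linear part is singular (det ~ 0)")
  structure(list(A = A, t = as.numeric(t)), class = "affine_transform")
}

#' @export
print.affine_transform <- function(x, ...) {
  m <- cbind(x$A, x$t)
  dimnames(m) <- list(c("x", "y", "z"), c("Ax", "Ay", "Az", "t_mm"))
  cat("<affine_transform>\n")
  print(round(m, 6))
  invisible(x)
}

#' @rdname affine_transform
#' @export
identity_transform <- function() affine_transform()

#' Rigid transform from translation and Euler angles
#'
#' Rotation (degrees, applied in z-y-x order) about `center`, followed by
#' translation.
#'
#' @param translation_mm,rotation_deg length-3 each.
#' @param center rotation centre in world mm.
#' @return An [affine_transform()].
#' @export
rigid_transform <- function(translation_mm = c(0, 0, 0),
                            rotation_deg = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  r <- rotation_deg * pi / 180
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  R <- Rx %*% Ry %*% Rz
  t <- as.numeric(center - R %*% center + translation_mm)
  affine_transform(R, t)
}

#' Compose and invert affine transforms
#'
#' `compose_transforms(a, b)` is the map `x -> a(b(x))`;
#' `invert_transform(t)` satisfies `compose(t, invert(t)) ~ identity`.
#'
#' @param a,b,transform [affine_transform()] objects.
#' @return An [affine_transform()].
#' @export
compose_transforms <- function(a, b) {
  affine_transform(a$A %*% b$A, as.numeric(a$A %*% b$t) + a$t)
}

#' @rdname compose_transforms
#' @export
invert_transform <- function(transform) {
  Ainv <- solve(transform$A)
  affine_transform(Ainv, as.numeric(-Ainv %*% transform$t))
}

#' Apply a transform to world points
#' @param transform an [affine_transform()].
#' @param pts n x 3 matrix of world coordinates (mm).
#' @return n x 3 matrix of mapped coordinates.
#' @export
transform_points <- function(transform, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  t(transform$A %*% t(pts) + transform$t)
}

#' Optimizer settings for affine registration
#'
#' Settings of the (1+1) evolutionary optimizer: a mutation radius that
#' grows on improvement and shrinks on failure, stopping when it falls below
#' `epsilon` or after `max_iterations`. Defaults follow the tuned values
#' used for DESS/TESS knee coregistration: initial radius 0.001, epsilon
#' 1.5e-4, growth factor 1.01, 300 iterations.
#'
#' @param initial_radius starting mutation radius (relative scale).
#' @param epsilon radius below which the search stops.
#' @param growth_factor radius growth per successful mutation (> 1); failed
#'   mutations shrink the radius by `growth_factor^-0.25`.
#' @param max_iterations iteration cap per pyramid level.
#' @param bins joint-histogram bins of the mutual-information metric.
#' @param pyramid_levels coarse-to-fine resolution levels.
#' @param seed RNG seed making the optimizer deterministic.
#' @return An object of class `optimizer_settings`.
#' @export
optimizer_settings <- function(initial_radius = 0.001, epsilon = 1.5e-4,
                               growth_factor = 1.01, max_iterations = 300L,
                               bins = 32L, pyramid_levels = 3L, seed = 0L) {
  if (initial_radius <= 0 || epsilon <= 0 || growth_factor <= 1)
    stop("need initial_radius > 0, epsilon > 0, growth_factor > 1")
  structure(list(initial_radius = initial_radius, epsilon = epsilon,
                 growth_factor = growth_factor,
                 max_iterations = as.integer(max_iterations),
                 bins = as.integer(bins),
                 pyramid_levels = as.integer(pyramid_levels),
                 seed = as.integer(seed)),
            class = "optimizer_settings")
}

finite_range <- function(v) {
  r <- range(v[is.finite(v)])
  if (r[1] == r[2]) r[2] <- r[1] + 1
  r
}

mi_metric <- function(fixed_vals, moving_resampled, bins, frange, mrange,
                      normalized = TRUE) {
  # normalized (Studholme) form by default: plain MI has spurious maxima
  # where the transform shrinks the overlap region
  .mutual_information_cpp(fixed_vals, moving_resampled, bins,
                          frange[1], frange[2], mrange[1], mrange[2],
                          as.integer(normalized))
}

resample_values <- function(moving, transform, target, interpolation) {
  method <- match(interpolation, c("linear", "nearest")) - 1L
  vals <- .resample_affine_cpp(as.numeric(moving$values), dim(moving$values),
                               moving$spacing, moving$origin,
                               as.numeric(transform$A), transform$t,
                               dim(target$values), target$spacing,
                               target$origin, method)
  array(vals, dim(target$values))
}

#' Resample a moving image through an affine transform
#'
#' The output lives on the target grid; each target voxel at world position
#' `x` takes the moving image's value at `transform(x)` (linear
#' interpolation for intensities, nearest neighbour for label-like data).
#' Voxels mapping outside the moving field of view are `NA`.
#'
#' @param moving a [volume_image()].
#' @param transform an [affine_transform()].
#' @param target a [volume_image()] or [label_map()] defining the output
#'   grid (defaults to the moving image's own grid).
#' @param interpolation `"linear"` or `"nearest"`.
#' @return A [volume_image()] on the target grid.
#' @export
apply_transform <- function(moving, transform, target = moving,
                            interpolation = c("linear", "nearest")) {
  stopifnot(inherits(moving, "volume_image"),
            inherits(transform, "affine_transform"))
  interpolation <- match.arg(interpolation)
  vals <- resample_values(moving, transform, target, interpolation)
  volume_image(vals, spacing = target$spacing, origin = target$origin)
}

# 3x3x3 box presmoothing (NA-aware). Applied to both images before metric
# evaluation: voxel noise otherwise rewards transforms that sample the
# moving image at maximally-interpolating (half-voxel) offsets, biasing the
# mutual-information optimum away from the true alignment.
smooth_box3 <- function(vol) {
  v <- vol$values
  fin <- is.finite(v)
  num <- box_sum(ifelse(fin, v, 0), 3L)
  den <- box_sum(fin * 1, 3L)
  out <- num / den
  out[den == 0] <- NA_real_
  volume_image(array(out, dim(v)), vol$spacing, vol$origin)
}

# 2x downsampling by block average (NA-aware); spacing doubles.
downsample2 <- function(vol) {
  d <- dim(vol$values)
  nd <- pmax(1L, d %/% 2L)
  v <- vol$values[seq_len(nd[1] * 2), seq_len(nd[2] * 2), seq_len(nd[3] * 2),
                  drop = FALSE]
  acc <- array(0, nd); cnt <- array(0, nd)
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    sub <- v[seq(1 + dx, by = 2, length.out = nd[1]),
             seq(1 + dy, by = 2, length.out = nd[2]),
             seq(1 + dz, by = 2, length.out = nd[3]), drop = FALSE]
    fin <- is.finite(sub)
    acc <- acc + ifelse(fin, sub, 0)
    cnt <- cnt + fin
  }
  out <- acc / cnt
  out[cnt == 0] <- NA_real_
  volume_image(out, spacing = vol$spacing * 2,
               origin = vol$origin + vol$spacing / 2)
}

# intensity-weighted centroid in world mm (above-median mass only, so the
# background level does not dominate)
intensity_centroid <- function(vol) {
  v <- vol$values
  fin <- is.finite(v)
  w <- v - stats::median(v[fin])
  w[!fin | w < 0] <- 0
  idx <- which(w > 0)
  ai <- arrayInd(idx, dim(v))
  ww <- w[idx] / sum(w[idx])
  vol$origin + c(sum((ai[, 1] - 1) * ww) * vol$spacing[1],
                 sum((ai[, 2] - 1) * ww) * vol$spacing[2],
                 sum((ai[, 3] - 1) * ww) * vol$spacing[3])
}

params_to_transform <- function(p, center) {
  A <- diag(3) + matrix(p[1:9], 3, 3)
  t <- p[10:12] + as.numeric((diag(3) - A) %*% center)
  affine_transform(A, t)
}

#' Register a moving image to a fixed image (12-DOF affine)
#'
#' Maximizes Mattes-style mutual information between the fixed image and
#' the resampled moving image under a full affine transform, using a (1+1)
#' evolutionary optimizer over a coarse-to-fine resolution pyramid.
#' Initialization aligns the intensity centroids of the two images. The
#' result is deterministic for fixed `settings` (including its seed).
#'
#' @param fixed,moving [volume_image()] objects with overlapping fields of
#'   view; neither may be constant.
#' @param settings an [optimizer_settings()].
#' @return An [affine_transform()] mapping fixed-world to moving-world
#'   coordinates, with attributes `metric` (final mutual information) and
#'   `iterations`.
#' @export
register_affine <- function(fixed, moving, settings = optimizer_settings()) {
  stopifnot(inherits(fixed, "volume_image"), inherits(moving, "volume_image"),
            inherits(settings, "optimizer_settings"))
  fv <- fixed$values[is.finite(fixed$values)]
  mv <- moving$values[is.finite(moving$values)]
  if (!length(fv) || stats::sd(fv) == 0)
    stop("fixed image is constant or empty: registration is degenerate")
  if (!length(mv) || stats::sd(mv) == 0)
    stop("moving image is constant or empty: registration is degenerate")
  flo <- fixed$origin; fhi <- fixed$origin + (dim(fixed$values) - 1) * fixed$spacing
  mlo <- moving$origin; mhi <- moving$origin + (dim(moving$values) - 1) * moving$spacing
  if (any(pmin(fhi, mhi) < pmax(flo, mlo)))
    stop("fixed and moving fields of view do not overlap")

  # initial translation: align intensity centroids (fixed-world -> moving-world)
  t0 <- intensity_centroid(moving) - intensity_centroid(fixed)
  center <- (flo + fhi) / 2
  extent <- mean(fhi - flo)

  fixed_s <- smooth_box3(fixed)
  moving_s <- smooth_box3(moving)
  pyr_f <- list(fixed_s); pyr_m <- list(moving_s)
  for (l in seq_len(settings$pyramid_levels - 1L)) {
    pyr_f[[l + 1L]] <- downsample2(pyr_f[[l]])
    pyr_m[[l + 1L]] <- downsample2(pyr_m[[l]])
  }
  frange <- finite_range(fixed_s$values)
  mrange <- finite_range(moving_s$values)

  p <- c(rep(0, 9), t0)
  scale <- c(rep(1, 9), rep(extent, 3))
  total_iter <- 0L
  with_seed(settings$seed, {
    for (lev in rev(seq_len(settings$pyramid_levels))) {
      f <- pyr_f[[lev]]; m <- pyr_m[[lev]]
      fvals <- as.numeric(f$values)
      eval_p <- function(pp) {
        tr <- params_to_transform(pp, center)
        mi_metric(fvals, as.numeric(resample_values(m, tr, f, "linear")),
                  settings$bins, frange, mrange)
      }
      # multi-start guard: the carried solution competes with the two
      # initializations (header/world alignment, and centroid alignment —
      # the latter only meaningful for same-modality content) at every
      # resolution, so drift at a coarser level cannot survive
      cands <- list(p, c(rep(0, 9), t0), rep(0, 12))
      vals <- vapply(cands, eval_p, numeric(1))
      if (all(is.na(vals))) stop("similarity metric undefined: no overlap")
      pick <- which.max(vals)
      p <- cands[[pick]]
      best <- vals[pick]
      radius <- settings$initial_radius * 2^(lev - 1)
      iter <- 0L
      while (iter < settings$max_iterations && radius > settings$epsilon) {
        iter <- iter + 1L
        cand <- p + radius * scale * rnorm(12)
        val <- eval_p(cand)
        if (!is.na(val) && (is.na(best) || val > best)) {
          p <- cand
          best <- val
          radius <- radius * settings$growth_factor
        } else {
          radius <- radius * settings$growth_factor^(-0.25)
        }
      }
      total_iter <- total_iter + iter
    }
    # deterministic local polish at the finest level: per-parameter
    # parabolic line search on the metric (the stochastic search provides
    # the capture range; this stage provides subvoxel convergence)
    f <- pyr_f[[1]]; m <- pyr_m[[1]]
    fvals <- as.numeric(f$values)
    eval_p <- function(pp) {
      tr <- params_to_transform(pp, center)
      mi_metric(fvals, as.numeric(resample_values(m, tr, f, "linear")),
                settings$bins, frange, mrange)
    }
    h <- c(rep(0.004, 9), rep(0.4 * min(fixed$spacing), 3))
    best <- eval_p(p)
    for (sweep in 1:3) {
      for (i in c(10:12, 1:9)) {
        hp <- h[i] / sweep
        pm <- p; pm[i] <- p[i] - hp
        pp2 <- p; pp2[i] <- p[i] + hp
        vm <- eval_p(pm); vp <- eval_p(pp2)
        if (is.na(vm) || is.na(vp)) next
        denom <- vm - 2 * best + vp
        delta <- if (denom < 0) 0.5 * hp * (vm - vp) / denom else
          hp * sign(vp - vm)
        delta <- max(min(delta, 2 * hp), -2 * hp)
        cand <- p; cand[i] <- p[i] + delta
        vc <- eval_p(cand)
        vals <- c(best, vm, vp, vc)
        pick <- which.max(vals)
        if (pick == 2L) { p <- pm; best <- vm }
        else if (pick == 3L) { p <- pp2; best <- vp }
        else if (pick == 4L) { p <- cand; best <- vc }
      }
    }
  })
  out <- params_to_transform(p, center)
  attr(out, "metric") <- attr(out, "metric", exact = TRUE)
  tr_final <- out
  fvals1 <- as.numeric(pyr_f[[1]]$values)
  attr(tr_final, "metric") <- mi_metric(
    fvals1, as.numeric(resample_values(pyr_m[[1]], out, pyr_f[[1]], "linear")),
    settings$bins, frange, mrange)
  attr(tr_final, "iterations") <- total_iter
  tr_final
}

#' Windowed similarity-index map
#'
#' Per-voxel structural-similarity-style index between a fixed image and a
#' registered image on the same grid, computed over a cubic moving window;
#' values lie in [-1, 1] (1 = locally identical structure). The mean over a
#' mask serves as a scalar coregistration quality marker.
#'
#' @param fixed,registered [volume_image()] objects on the same grid.
#' @param window odd window edge length in voxels.
#' @param mask optional logical array or [label_map()] over which the
#'   summary mean is taken.
#' @return A [volume_image()] similarity map with attribute
#'   `mean_similarity`.
#' @export
similarity_map <- function(fixed, registered, window = 5L, mask = NULL) {
  stopifnot(inherits(fixed, "volume_image"),
            inherits(registered, "volume_image"))
  stopifnot_same_grid(fixed, registered)
  x <- fixed$values; y <- registered$values
  ok <- is.finite(x) & is.finite(y)
  xs <- ifelse(ok, x, 0); ys <- ifelse(ok, y, 0)
  n <- box_sum(ok * 1, window)
  sx <- box_sum(xs, window);  sy <- box_sum(ys, window)
  sxx <- box_sum(xs * xs, window); syy <- box_sum(ys * ys, window)
  sxy <- box_sum(xs * ys, window)
  mx <- sx / n; my <- sy / n
  vx <- pmax(sxx / n - mx^2, 0); vy <- pmax(syy / n - my^2, 0)
  cxy <- sxy / n - mx * my
  L <- diff(finite_range(x))
  c1 <- (0.01 * L)^2; c2 <- (0.03 * L)^2
  s <- ((2 * mx * my + c1) * (2 * cxy + c2)) /
    ((mx^2 + my^2 + c1) * (vx + vy + c2))
  s[n < 2] <- NA_real_
  s <- pmin(pmax(s, -1), 1)
  out <- volume_image(array(s, dim(x)), fixed$spacing, fixed$origin)
  if (!is.null(mask)) {
    if (inherits(mask, "label_map")) mask <- mask$values > 0L
    attr(out, "mean_similarity") <- mean(s[mask], na.rm = TRUE)
  } else {
    attr(out, "mean_similarity") <- mean(s, na.rm = TRUE)
  }
  out
}

# sliding cubic box sum via cumulative sums (zero padding)
box_sum <- function(a, window) {
  h <- (window - 1L) %/% 2L
  d <- dim(a)
  for (ax in 1:3) {
    cs <- apply(a, setdiff(1:3, ax), function(v) {
      c0 <- cumsum(v)
      n <- length(v)
      hi <- pmin(seq_len(n) + h, n)
      lo <- seq_len(n) - h - 1L
      c0[hi] - ifelse(lo >= 1L, c0[pmax(lo, 1L)], 0)
    })
    a <- aperm(array(cs, c(d[ax], d[setdiff(1:3, ax)])),
               order(c(ax, setdiff(1:3, ax))))
  }
  a
}

#' Write/read an affine transform as plain text
#'
#' Twelve numbers: the 3x3 linear part in row-major order, then the
#' translation (mm).
#'
#' @param transform an [affine_transform()].
#' @param path destination path.
#' @return `path` (write) or an [affine_transform()] (read).
#' @export
write_transform <- function(transform, path) {
  m <- rbind(t(transform$A), transform$t)
  writeLines(c("# affine transform: rows 1-3 = linear part (row-major), row 4 = translation mm",
               apply(m, 1, function(r) paste(format(r, digits = 17),
                                             collapse = " "))),
             path)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  ln <- readLines(path)
  ln <- ln[!grepl("^#", ln)]
  m <- do.call(rbind, lapply(ln, function(s) as.numeric(strsplit(trimws(s),
                                                                 "\\s+")[[1]])))
  affine_transform(t(m[1:3, ]), m[4, ])
}
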