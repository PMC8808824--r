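# GLCM texture analysis of T2 maps per cartilage region, following the
# cartilage-texture configuration: per-slice ROI rotation, flattening and
# resampling to a depth-by-tangent grid; 16-level min-max quantization;
# co-occurrence at offset 1 parallel to the cartilage surface; 7 features
# (autocorrelation, contrast, correlation, dissimilarity, energy, entropy,
# homogeneity); unweighted averaging over slices.

#' GLCM texture configuration
#'
#' @param levels gray levels for quantization (default 16).
#' @param offset co-occurrence offset in pixels along the surface-tangential
#'   axis (default 1).
#' @param symmetric count each pair in both orders (default TRUE), making
#'   features invariant to the direction sign.
#' @param homogeneity_kernel `"inverse_difference"` (1/(1+|i-j|), default)
#'   or `"inverse_difference_squared"` (1/(1+(i-j)^2)).
#' @param entropy_base `"natural"` (ln, default) or `"log2"`.
#' @param min_pixels minimum valid pixels per slice for a slice to be
#'   eligible (below this, GLCM statistics are degenerate).
#' @param depth_samples number of depth rows of the flattened ROI.
#' @return An object of class `texture_config`.
#' @export
texture_config <- function(levels = 16L, offset = 1L, symmetric = TRUE,
                           homogeneity_kernel = c("inverse_difference",
                                                  "inverse_difference_squared"),
                           entropy_base = c("natural", "log2"),
                           min_pixels = 16L, depth_samples = 8L) {
  homogeneity_kernel <- match.arg(homogeneity_kernel)
  entropy_base <- match.arg(entropy_base)
  if (levels < 2L) stop("need at least 2 gray levels")
  if (offset < 1L) stop("offset must be >= 1 pixel")
  structure(list(levels = as.integer(levels), offset = as.integer(offset),
                 symmetric = isTRUE(symmetric),
                 homogeneity_kernel = homogeneity_kernel,
                 entropy_base = entropy_base,
                 min_pixels = as.integer(min_pixels),
                 depth_samples = as.integer(depth_samples)),
            class = "texture_config")
}

#' Flatten a cartilage region slice-by-slice
#'
#' For each slice along `slice_axis` intersecting the region with at least
#' `min_pixels` valid pixels, the region is rotated so its principal
#' surface-tangential axis is horizontal (principal component of the
#' in-slice pixel coordinates), then resampled onto a fixed grid: rows are
#' `depth_samples` equal steps of normalized depth ordered deep to
#' superficial, columns are tangential bins one in-plane pixel wide. Cells
#' with no support are missing.
#'
#' @param t2 a [volume_image()] T2 map.
#' @param region_mask logical 3D array (or [label_map()]) selecting the
#'   region.
#' @param depth a [compute_depth_field()] result on the same grid.
#' @param slice_axis axis index of the slice direction (1 = sagittal for
#'   x-first arrays).
#' @param config a [texture_config()].
#' @return List of numeric matrices (one per eligible slice), rows deep to
#'   superficial; each has attribute `slice` (index).
#' @export
flatten_roi <- function(t2, region_mask, depth, slice_axis = 1L,
                        config = texture_config()) {
  stopifnot(inherits(t2, "volume_image"), inherits(depth, "depth_field"))
  if (inherits(region_mask, "label_map")) region_mask <- region_mask$values > 0L
  stopifnot(identical(dim(region_mask), dim(t2$values)))
  dims <- dim(t2$values)
  inplane_axes <- setdiff(1:3, slice_axis)
  wa <- t2$spacing[inplane_axes[1]]
  wb <- t2$spacing[inplane_axes[2]]
  col_width <- mean(c(wa, wb))
  R <- config$depth_samples
  f_rows <- (seq_len(R) - 0.5) / R
  out <- list()
  for (s in seq_len(dims[slice_axis])) {
    sel <- slice_indices(dims, slice_axis, s)
    use <- region_mask[sel$idx] & is.finite(t2$values[sel$idx]) &
      is.finite(depth$f[sel$idx])
    if (sum(use) < config$min_pixels) next
    idx <- sel$idx[use]
    ai <- arrayInd(idx, dims)
    a <- (ai[, inplane_axes[1]] - 1) * wa
    b <- (ai[, inplane_axes[2]] - 1) * wb
    vals <- t2$values[idx]
    fv <- depth$f[idx]
    pc <- stats::prcomp(cbind(a, b), center = TRUE, scale. = FALSE)
    tang <- pc$x[, 1]
    cols <- as.integer(floor((tang - min(tang)) / col_width)) + 1L
    C <- max(cols)
    m <- matrix(NA_real_, R, C)
    for (cc in unique(cols)) {
      pick <- cols == cc
      ff <- fv[pick]; vv <- vals[pick]
      if (anyDuplicated(ff)) {
        agg <- tapply(vv, ff, mean)
        ff <- as.numeric(names(agg)); vv <- as.numeric(agg)
      }
      o <- order(ff)
      ff <- ff[o]; vv <- vv[o]
      if (length(ff) >= 2L) {
        m[, cc] <- stats::approx(ff, vv, xout = f_rows, rule = 1)$y
      } else {
        r <- which.min(abs(f_rows - ff))
        m[r, cc] <- vv
      }
    }
    attr(m, "slice") <- s
    out[[length(out) + 1L]] <- m
  }
  if (!length(out))
    stop("region absent (or below min_pixels) on every slice")
  out
}

slice_indices <- function(dims, axis, s) {
  args <- list(seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3]))
  args[[axis]] <- s
  g <- expand.grid(args[[1]], args[[2]], args[[3]])
  idx <- g[, 1] + dims[1] * (g[, 2] - 1) + dims[1] * dims[2] * (g[, 3] - 1)
  list(idx = as.integer(idx))
}

#' Quantize a flattened ROI to discrete gray levels
#'
#' Linear min-max mapping of the non-missing values onto levels
#' `1..levels`; the maximum maps to the top level, a constant ROI maps
#' entirely to level 1, missing pixels stay missing.
#'
#' @param roi numeric matrix from [flatten_roi()].
#' @param levels number of gray levels.
#' @return Integer matrix of levels with `NA` for missing pixels.
#' @export
quantize <- function(roi, levels = 16L) {
  fin <- is.finite(roi)
  if (!any(fin)) stop("ROI is entirely missing: cannot quantize")
  lo <- min(roi[fin]); hi <- max(roi[fin])
  q <- matrix(NA_integer_, nrow(roi), ncol(roi))
  if (hi <= lo) {
    q[fin] <- 1L
  } else {
    lv <- as.integer(floor((roi[fin] - lo) / (hi - lo) * levels)) + 1L
    lv[lv > levels] <- as.integer(levels)
    q[fin] <- lv
  }
  q
}

#' Gray-level co-occurrence matrix and Haralick-style features
#'
#' Counts co-occurring level pairs one `offset` apart along the tangential
#' (column) axis of the flattened ROI; pairs with a missing member are
#' skipped. In symmetric mode each pair is counted in both orders. The
#' normalized matrix p(i, j) yields the 7 features: autocorrelation
#' sum(i j p), contrast sum((i-j)^2 p), correlation
#' (sum(i j p) - mu_x mu_y) / (sigma_x sigma_y), dissimilarity
#' sum(|i-j| p), energy sum(p^2), entropy -sum(p log p) (0 log 0 = 0), and
#' homogeneity sum(p / (1 + |i-j|)). Correlation is undefined (NA) when
#' either marginal is degenerate.
#'
#' @param q integer level matrix from [quantize()].
#' @param config a [texture_config()].
#' @return list with `glcm` (levels x levels matrix) and `features` (named
#'   numeric length 7).
#' @export
glcm_features <- function(q, config = texture_config()) {
  N <- config$levels
  off <- config$offset
  if (ncol(q) <= off) stop("ROI too narrow for the requested offset")
  i <- as.vector(q[, seq_len(ncol(q) - off), drop = FALSE])
  j <- as.vector(q[, seq_len(ncol(q) - off) + off, drop = FALSE])
  ok <- !is.na(i) & !is.na(j)
  if (!any(ok)) stop("no valid co-occurring pixel pairs")
  i <- i[ok]; j <- j[ok]
  counts <- matrix(0, N, N)
  tab <- tabulate(i + N * (j - 1L), nbins = N * N)
  counts[] <- tab
  if (config$symmetric) counts <- counts + t(counts)
  p <- counts / sum(counts)
  lev <- seq_len(N)
  ii <- matrix(lev, N, N)
  jj <- t(ii)
  px <- rowSums(p); py <- colSums(p)
  mux <- sum(lev * px); muy <- sum(lev * py)
  sdx <- sqrt(sum((lev - mux)^2 * px))
  sdy <- sqrt(sum((lev - muy)^2 * py))
  sij <- sum(ii * jj * p)
  plog <- p[p > 0]
  ent <- -sum(plog * log(plog))
  if (config$entropy_base == "log2") ent <- ent / log(2)
  hom_den <- if (config$homogeneity_kernel == "inverse_difference")
    1 + abs(ii - jj) else 1 + (ii - jj)^2
  feats <- c(
    autocorrelation = sij,
    contrast = sum((ii - jj)^2 * p),
    correlation = if (sdx * sdy > 0) (sij - mux * muy) / (sdx * sdy)
                  else NA_real_,
    dissimilarity = sum(abs(ii - jj) * p),
    energy = sum(p^2),
    entropy = ent,
    homogeneity = sum(p / hom_den))
  list(glcm = p, features = feats)
}

#' Texture features of a cartilage region
#'
#' Flattens the region slice-by-slice, quantizes each slice, computes the
#' GLCM features per slice, and averages them (unweighted) across eligible
#' slices. Slices with undefined correlation are excluded from the
#' correlation average only.
#'
#' @inheritParams flatten_roi
#' @return Named numeric vector of the 7 averaged features, with attribute
#'   `n_slices`.
#' @export
region_texture <- function(t2, region_mask, depth, slice_axis = 1L,
                           config = texture_config()) {
  rois <- flatten_roi(t2, region_mask, depth, slice_axis, config)
  per_slice <- lapply(rois, function(m) {
    q <- quantize(m, config$levels)
    if (ncol(q) <= config$offset) return(NULL)
    ok_pairs <- tryCatch(glcm_features(q, config)$features,
                         error = function(e) NULL)
    ok_pairs
  })
  per_slice <- Filter(Negate(is.null), per_slice)
  if (!length(per_slice)) stop("no eligible slice for texture analysis")
  fm <- do.call(rbind, per_slice)
  out <- colMeans(fm, na.rm = FALSE)
  out["correlation"] <- mean(fm[, "correlation"], na.rm = TRUE)
  if (is.nan(out["correlation"])) out["correlation"] <- NA_real_
  attr(out, "n_slices") <- nrow(fm)
  out
}

#' Texture features for every subregion
#'
#' Runs [region_texture()] per subregion (bulk cartilage of that
#' subregion); subregions with no eligible slice get an `NA` row.
#'
#' @param t2 thresholded, coregistered T2 [volume_image()].
#' @param labels subregion [label_map()].
#' @param depth a [compute_depth_field()] result.
#' @param slice_axis,config as in [flatten_roi()].
#' @return data.frame with `subregion`, `layer` (= "bulk") and the 7
#'   feature columns.
#' @export
texture_table <- function(t2, labels, depth, slice_axis = 1L,
                          config = texture_config()) {
  stopifnot(inherits(labels, "label_map"))
  rows <- lapply(names(labels$dict), function(rn) {
    mask <- labels$values == labels$dict[[rn]]
    feats <- tryCatch(
      region_texture(t2, mask, depth, slice_axis, config),
      error = function(e) setNames(rep(NA_real_, 7), c(
        "autocorrelation", "contrast", "correlation", "dissimilarity",
        "energy", "entropy", "homogeneity")))
    cbind(data.frame(subregion = rn, layer = "bulk",
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(feats)))
  })
  do.call(rbind, rows)
}
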