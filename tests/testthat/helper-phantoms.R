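# Shared fixtures and independent oracles for the test suite. Everything is
# generated in code; no binary fixtures.

# small slab with depth field, cached across tests
slab_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- phantom_spec(shape = c(20L, 20L, 16L), spacing = 0.5,
                           cartilage_thickness_mm = 2)
      ph <- make_slab(spec)
      depth <- compute_depth_field(ph$labels$values == 2L,
                                   ph$labels$values == 1L,
                                   spacing = spec$spacing)
      cache <<- list(spec = spec, ph = ph, depth = depth,
                     layers = assign_layers(depth))
    }
    cache
  }
})

# independent brute-force GLCM oracle: explicit pair enumeration and naive
# double-loop feature formulas (no shared code with the implementation)
glcm_oracle <- function(q, levels, offset = 1L, symmetric = TRUE,
                        entropy_log = log) {
  counts <- matrix(0, levels, levels)
  for (r in seq_len(nrow(q))) {
    for (cc in seq_len(ncol(q) - offset)) {
      i <- q[r, cc]; j <- q[r, cc + offset]
      if (is.na(i) || is.na(j)) next
      counts[i, j] <- counts[i, j] + 1
      if (symmetric) counts[j, i] <- counts[j, i] + 1
    }
  }
  stopifnot(sum(counts) > 0)
  p <- counts / sum(counts)
  auto <- 0; contr <- 0; diss <- 0; ener <- 0; entr <- 0; hom <- 0
  for (i in seq_len(levels)) for (j in seq_len(levels)) {
    pij <- p[i, j]
    auto <- auto + i * j * pij
    contr <- contr + (i - j)^2 * pij
    diss <- diss + abs(i - j) * pij
    ener <- ener + pij^2
    if (pij > 0) entr <- entr - pij * entropy_log(pij)
    hom <- hom + pij / (1 + abs(i - j))
  }
  px <- rowSums(p); py <- colSums(p)
  mux <- sum(seq_len(levels) * px); muy <- sum(seq_len(levels) * py)
  sdx <- sqrt(sum((seq_len(levels) - mux)^2 * px))
  sdy <- sqrt(sum((seq_len(levels) - muy)^2 * py))
  corr <- if (sdx * sdy > 0) (auto - mux * muy) / (sdx * sdy) else NA_real_
  c(autocorrelation = auto, contrast = contr, correlation = corr,
    dissimilarity = diss, energy = ener, entropy = entr, homogeneity = hom)
}

# mean displacement (mm) between two transforms over a mask's voxel centres
transform_error_mm <- function(recovered, truth, mask_map) {
  idx <- which(mask_map$values > 0L)
  ai <- arrayInd(idx, dim(mask_map$values))
  pts <- sweep(ai - 1, 2, mask_map$spacing, "*")
  pr <- transform_points(recovered, pts)
  pt <- transform_points(truth, pts)
  mean(sqrt(rowSums((pr - pt)^2)))
}

# random blob mask (connected-ish ellipsoid union) for agreement tests
random_mask <- function(dims = c(24L, 24L, 16L), n_blobs = 3L, seed = 1L) {
  set.seed(seed)
  w <- array(FALSE, dims)
  ctr <- cbind(runif(n_blobs, 4, dims[1] - 4), runif(n_blobs, 4, dims[2] - 4),
               runif(n_blobs, 4, dims[3] - 4))
  rad <- cbind(runif(n_blobs, 2, 6), runif(n_blobs, 2, 6),
               runif(n_blobs, 2, 5))
  ai <- arrayInd(seq_len(prod(dims)), dims)
  for (b in seq_len(n_blobs)) {
    d2 <- ((ai[, 1] - ctr[b, 1]) / rad[b, 1])^2 +
      ((ai[, 2] - ctr[b, 2]) / rad[b, 2])^2 +
      ((ai[, 3] - ctr[b, 3]) / rad[b, 3])^2
    w[d2 <= 1] <- TRUE
  }
  w
}
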