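test_that("GLCM features match the hand-derived small-grid oracle", {
  # rows = depth, columns = tangential; pairs one step along columns
  q <- matrix(c(1L, 1L, 1L, 2L, 2L, 2L), nrow = 2)
  res <- glcm_features(q, texture_config(levels = 2))
  expect_equal(unname(res$features["contrast"]), 0.5)
  expect_equal(unname(res$features["dissimilarity"]), 0.5)
  expect_equal(unname(res$features["homogeneity"]), 0.75)
  expect_equal(unname(res$features["energy"]), 0.25)
  expect_equal(unname(res$features["entropy"]), log(4))
  expect_equal(unname(res$features["autocorrelation"]), 2.25)
  expect_equal(unname(res$features["correlation"]), 0)
  expect_true(all(res$glcm == 0.25 | res$glcm == 0))
})

test_that("GLCM is normalized, symmetric, and oracle-equivalent", {
  set.seed(20)
  cfg <- texture_config()
  for (k in 1:50) {
    nr <- sample(3:8, 1); nc <- sample(4:12, 1)
    q <- matrix(sample.int(16L, nr * nc, TRUE), nr, nc)
    if (k %% 3 == 0) q[sample(length(q), 2)] <- NA  # missing support
    res <- tryCatch(glcm_features(q, cfg), error = function(e) NULL)
    if (is.null(res)) next
    expect_equal(sum(res$glcm), 1, tolerance = 1e-12)
    expect_equal(res$glcm, t(res$glcm), tolerance = 1e-15)
    orc <- glcm_oracle(q, 16L)
    expect_equal(res$features, orc, tolerance = 1e-12)
    # dissimilarity <= sqrt(contrast) by Cauchy-Schwarz
    expect_lte(res$features[["dissimilarity"]],
               sqrt(res$features[["contrast"]]) + 1e-12)
  }
})

test_that("quantization is min-max with the degenerate-constant rule", {
  roi <- matrix(c(10, 12, 14, 20, NA, 30), 2, 3)
  q <- quantize(roi, 16L)
  expect_equal(q[which(roi == 10)], 1L)   # min -> level 1
  expect_equal(q[which(roi == 30)], 16L)  # max -> top level
  expect_true(is.na(q[is.na(roi)]))
  expect_true(all(quantize(matrix(5, 3, 3), 16L) == 1L))
  expect_error(quantize(matrix(NA_real_, 2, 2)), "missing")
  # uniform ramp gives near-equal level counts
  ramp <- matrix(seq(0, 1, length.out = 160), 10, 16)
  counts <- table(quantize(ramp, 16L))
  expect_true(all(abs(counts - 10) <= 1))
})

test_that("features are invariant to affine intensity rescaling", {
  fx <- slab_fixture()
  t2 <- paint_t2_laminar(fx$ph$labels, fx$depth, t2_profile(),
                         noise_sigma = 2, seed = 13)
  mask <- fx$ph$labels$values == 2L
  f1 <- region_texture(t2, mask, fx$depth)
  t2b <- volume_image(3.7 * t2$values + 11, t2$spacing)
  f2 <- region_texture(t2b, mask, fx$depth)
  expect_equal(unclass(f1), unclass(f2), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("flattening is rotation invariant on a rotated slab", {
  dims <- c(8L, 48L, 48L); sp <- rep(0.5, 3)
  build <- function(angle_deg) {
    th <- angle_deg * pi / 180
    w <- cartiquant:::expand_world(dims, sp)
    yc <- 11.75; zc <- 11.75
    u <- cos(th) * (w$y - yc) + sin(th) * (w$z - zc)
    v <- -sin(th) * (w$y - yc) + cos(th) * (w$z - zc)
    region <- array(0L, dims)
    region[abs(u) <= 9 & v > -4 & v <= 0] <- 1L
    region[abs(u) <= 9 & v > 0 & v <= 3] <- 2L
    depth <- compute_depth_field(region == 2L, region == 1L, spacing = sp)
    vals <- array(NA_real_, dims)
    m <- region == 2L
    vals[m] <- 22 + 12 * depth$f[m] + 3 * sin(2 * u[as.vector(m)])
    list(t2 = volume_image(vals, sp), mask = m, depth = depth)
  }
  a0 <- build(0); a30 <- build(30)
  f0 <- region_texture(a0$t2, a0$mask, a0$depth)
  f30 <- region_texture(a30$t2, a30$mask, a30$depth)
  for (nm in c("contrast", "dissimilarity", "homogeneity", "entropy"))
    expect_lt(abs(f0[[nm]] - f30[[nm]]) / max(abs(f0[[nm]]), 0.1), 0.15)
  # a region on 5 slices yields 5 flattened ROIs
  m5 <- a0$mask; m5[6:8, , ] <- FALSE
  expect_length(flatten_roi(a0$t2, m5, a0$depth), 5L)
  expect_error(flatten_roi(a0$t2, array(FALSE, dims), a0$depth), "absent")
})

test_that("per-slice averaging and noise monotonicity behave as expected", {
  fx <- slab_fixture()
  mask <- fx$ph$labels$values == 2L
  # identical ROI on every slice: average equals the single-slice features
  t2 <- paint_t2_laminar(fx$ph$labels, fx$depth, t2_profile())
  vals <- t2$values
  vals[2:20, , ] <- vals[rep(1, 19), , ]  # copy slice 1 everywhere
  t2c <- volume_image(vals, t2$spacing)
  fall <- region_texture(t2c, mask, fx$depth)
  m1 <- mask; m1[2:20, , ] <- FALSE
  f1 <- region_texture(t2c, m1, fx$depth)
  expect_equal(unclass(fall), unclass(f1), tolerance = 1e-9,
               ignore_attr = TRUE)
  # more noise -> higher contrast, lower homogeneity (expectation over seeds)
  feats_at <- function(sig) {
    fs <- sapply(1:5, function(s) {
      tt <- paint_t2_laminar(fx$ph$labels, fx$depth, t2_profile(),
                             noise_sigma = sig, seed = 100 + s)
      region_texture(tt, mask, fx$depth)[c("contrast", "homogeneity")]
    })
    rowMeans(fs)
  }
  lo <- feats_at(0.5); hi <- feats_at(3)
  expect_gt(hi[["contrast"]], lo[["contrast"]])
  expect_lt(hi[["homogeneity"]], lo[["homogeneity"]])
})
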