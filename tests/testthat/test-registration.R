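reg_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- phantom_spec(shape = c(48L, 48L, 40L), spacing = 0.5,
                           cartilage_thickness_mm = 3,
                           inplane_margin_mm = 5, z_margin_mm = 3,
                           morph_noise_sigma = 2)
      cache <<- make_slab(spec)
    }
    cache
  }
})

test_that("affine transforms compose, invert and reject singular input", {
  tr <- rigid_transform(c(2, -1, 0.5), c(5, -3, 2), center = c(10, 10, 10))
  rt <- compose_transforms(tr, invert_transform(tr))
  pts <- matrix(runif(30, -20, 20), ncol = 3)
  expect_lt(max(abs(transform_points(rt, pts) - pts)), 1e-6)
  expect_error(affine_transform(matrix(0, 3, 3)), "singular")
  # plain-text round trip
  path <- withr::local_tempfile(fileext = ".txt")
  write_transform(tr, path)
  back <- read_transform(path)
  expect_equal(back$A, tr$A, tolerance = 1e-12)
  expect_equal(back$t, tr$t, tolerance = 1e-12)
})

test_that("optimizer settings carry the documented defaults", {
  s <- optimizer_settings()
  expect_equal(s$initial_radius, 0.001)
  expect_equal(s$epsilon, 1.5e-4)
  expect_equal(s$growth_factor, 1.01)
  expect_equal(s$max_iterations, 300L)
  expect_error(optimizer_settings(growth_factor = 0.9), "growth_factor")
})

test_that("resampling through identity and inverse round-trips", {
  ph <- reg_fixture()
  v <- ph$volume
  out <- apply_transform(v, identity_transform(), target = v)
  expect_equal(out$values, v$values)  # exact on-grid sampling
  # translate-then-invert on a smooth field stays within interpolation error
  w <- cartiquant:::expand_world(c(32L, 32L, 32L), rep(0.5, 3))
  smooth <- volume_image(array(sin(0.4 * w$x) * cos(0.3 * w$y) +
                                 0.5 * sin(0.2 * w$z), rep(32L, 3)),
                         rep(0.5, 3))
  tr <- affine_transform(diag(3), c(1.3, -0.7, 0.4))
  fwd <- apply_transform(smooth, tr, target = smooth)
  bwd <- apply_transform(fwd, invert_transform(tr), target = smooth)
  ok <- !is.na(bwd$values)
  rng <- diff(range(smooth$values))
  expect_lt(max(abs(bwd$values[ok] - smooth$values[ok])) / rng, 0.05)
  # everything mapped outside the field of view is missing
  far <- apply_transform(v, affine_transform(diag(3), c(500, 0, 0)),
                         target = v)
  expect_true(all(is.na(far$values)))
  # nearest-neighbour keeps labels integral
  lv <- volume_image(array(as.numeric(ph$labels$values),
                           dim(ph$labels$values)), v$spacing)
  nn <- apply_transform(lv, tr, target = v, interpolation = "nearest")
  expect_true(all(nn$values[!is.na(nn$values)] %in% c(0, 1, 2)))
})

test_that("self-registration recovers the identity", {
  ph <- reg_fixture()
  tr <- register_affine(ph$volume, ph$volume)
  expect_lt(transform_error_mm(tr, identity_transform(), ph$labels), 0.1)
  # angle of the recovered linear part stays below 0.1 degree
  ang <- acos(pmin(1, (sum(diag(tr$A)) - 1) / 2)) * 180 / pi
  expect_lt(ang, 0.1)
})

test_that("registration rejects degenerate problems", {
  ph <- reg_fixture()
  flat <- volume_image(array(1, dim(ph$volume$values)), ph$volume$spacing)
  expect_error(register_affine(ph$volume, flat), "constant")
  away <- volume_image(ph$volume$values, ph$volume$spacing,
                       origin = c(1e4, 1e4, 1e4))
  expect_error(register_affine(ph$volume, away), "overlap")
})

test_that("known rigid motions are recovered within half a voxel", {
  ph <- reg_fixture()
  set.seed(42)
  errs <- vapply(1:3, function(k) {
    tm <- runif(3, -1, 1) * c(4, 4, 2) / sqrt(3)
    rot <- runif(3, -1, 1) * 5 / sqrt(3)
    rp <- retest_replicate(ph$volume, ph$labels, translation_mm = tm,
                           rotation_deg = rot, noise_sigma = 1,
                           seed = 400 + k)
    tr <- register_affine(ph$volume, rp$volume)
    transform_error_mm(tr, invert_transform(rp$transform), ph$labels)
  }, numeric(1))
  expect_true(all(errs < 0.25))  # 0.5 x the 0.5 mm in-plane spacing
})

test_that("coarse-grid T2 maps register to morphology within a slice", {
  kn <- make_knee(shape = c(64L, 64L, 64L), spacing = 0.75,
                  t2_spacing = c(0.75, 0.75, 3), noise_sigma = 1, seed = 3)
  dims <- dim(kn$t2$values)
  center <- kn$t2$origin + (dims - 1) * kn$t2$spacing / 2
  motion <- rigid_transform(c(2, -1.5, 1), c(2, 0, -2), center = center)
  moved <- apply_transform(kn$t2, invert_transform(motion), target = kn$t2)
  rec <- register_affine(kn$volume, moved)
  expect_lt(transform_error_mm(rec, motion, kn$cartilage), 3)  # slice 3 mm
})

test_that("similarity map flags identity, anticorrelation and misalignment", {
  ph <- reg_fixture()
  s1 <- similarity_map(ph$volume, ph$volume)
  expect_gt(attr(s1, "mean_similarity"), 0.999)
  neg <- volume_image(-ph$volume$values, ph$volume$spacing)
  s2 <- similarity_map(ph$volume, neg)
  expect_lt(attr(s2, "mean_similarity"), 0)
  moved <- retest_replicate(ph$volume, ph$labels,
                            translation_mm = c(1, 0, 0))$volume
  s3 <- similarity_map(ph$volume, moved)
  expect_lt(attr(s3, "mean_similarity"), attr(s1, "mean_similarity"))
  expect_error(similarity_map(ph$volume,
                              volume_image(array(1, c(4, 4, 4)),
                                           ph$volume$spacing)), "grid")
})
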