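test_that("slab phantom has the prescribed cartilage extent and volume", {
  spec <- phantom_spec(shape = c(20L, 20L, 16L), spacing = 0.5,
                       cartilage_thickness_mm = 2)
  ph <- make_slab(spec)
  expect_equal(sum(ph$labels$values == 2L), 1600L)  # 20 x 20 x 4 voxels
  rv <- region_volume(ph$labels)
  expect_equal(rv$volume_mm3[rv$region == "cartilage"], 200)  # 1600 x 0.125
  # determinism: same spec, same seed, bit-identical
  ph2 <- make_slab(spec)
  expect_identical(ph$volume$values, ph2$volume$values)
  expect_identical(ph$labels$values, ph2$labels$values)
  expect_error(make_slab(phantom_spec(cartilage_thickness_mm = 0)), "> 0")
  expect_error(make_slab(phantom_spec(shape = c(8L, 8L, 4L),
                                      cartilage_thickness_mm = 50)),
               "exceeds")
})

test_that("shell phantom recovers its analytic thickness", {
  spec <- phantom_spec("curved-shell", shape = c(12L, 56L, 56L),
                       spacing = 0.5, cartilage_thickness_mm = 2)
  sh <- make_shell(spec)
  depth <- compute_depth_field(sh$labels$values == 2L,
                               sh$labels$values == 1L, spacing = rep(0.5, 3))
  th <- thickness_map(depth)
  expect_lt(abs(mean(th$values, na.rm = TRUE) - 2), 0.25)
  expect_error(make_shell(phantom_spec("curved-shell",
                                       angular_extent_deg = 0)), "> 0")
  # zero-noise geometry is seed-independent
  g1 <- make_shell(phantom_spec("curved-shell", shape = c(8L, 40L, 40L),
                                morph_noise_sigma = 0, seed = 1))
  g2 <- make_shell(phantom_spec("curved-shell", shape = c(8L, 40L, 40L),
                                morph_noise_sigma = 0, seed = 99))
  expect_identical(g1$labels$values, g2$labels$values)
  expect_identical(g1$volume$values, g2$volume$values)
})

test_that("laminar painting follows the profile at the depth endpoints", {
  fx <- slab_fixture()
  # linear profile with no noise: T2 is an affine function of f
  t2 <- paint_t2_laminar(fx$ph$labels, fx$depth,
                         t2_profile("linear", deep = 22.3,
                                    superficial = 33.9))
  m <- fx$depth$mask
  expect_equal(t2$values[m],
               22.3 + (33.9 - 22.3) * fx$depth$f[m], tolerance = 1e-12)
  # constant profile paints every cartilage voxel at that value
  tc <- paint_t2_laminar(fx$ph$labels, fx$depth,
                         t2_profile("constant", value = 27.7))
  expect_true(all(tc$values[m] == 27.7))
  expect_true(all(is.na(tc$values[!m])))
  # CLT check on the noise
  tn <- paint_t2_laminar(fx$ph$labels, fx$depth,
                         t2_profile("constant", value = 27.7),
                         noise_sigma = 2, seed = 3)
  n <- sum(m)
  expect_lt(abs(mean(tn$values[m]) - 27.7), 3 * 2 / sqrt(n))
  expect_error(t2_profile("linear", deep = 3), "window")
})

test_that("lesion insertion shifts the mean exactly and reduces variance", {
  fx <- slab_fixture()
  t2 <- paint_t2_laminar(fx$ph$labels, fx$depth, t2_profile(),
                         noise_sigma = 2, seed = 5)
  les <- lesion_spec(center_mm = c(4.75, 4.75, 2.25),
                     radii_mm = c(3, 3, 0.6), delta_t2_ms = 1.4,
                     smoothing = 4)
  supp <- cartiquant:::lesion_support(les, dim(t2$values), t2$spacing)
  pre <- mean(t2$values[supp])
  t2l <- insert_lesion(t2, fx$ph$labels, les)
  expect_equal(mean(t2l$values[supp]) - pre, 1.4, tolerance = 1e-9)
  expect_lt(sd(t2l$values[supp]), sd(t2$values[supp]))
  # identity lesion leaves the image unchanged
  les0 <- lesion_spec(center_mm = c(4.75, 4.75, 2.25),
                      radii_mm = c(3, 3, 0.6), delta_t2_ms = 0,
                      smoothing = 1)
  expect_equal(insert_lesion(t2, fx$ph$labels, les0)$values, t2$values)
  # lesion poking out of cartilage is rejected
  bad <- lesion_spec(center_mm = c(4.75, 4.75, 0.5), radii_mm = 2)
  expect_error(insert_lesion(t2, fx$ph$labels, bad), "outside")
})

test_that("retest replicates preserve identity and volume under motion", {
  fx <- slab_fixture()
  r0 <- retest_replicate(fx$ph$volume, fx$ph$labels)
  expect_identical(r0$volume$values, fx$ph$volume$values)
  expect_identical(r0$labels$values, fx$ph$labels$values)
  # same seed, same replicate
  ra <- retest_replicate(fx$ph$volume, fx$ph$labels, noise_sigma = 1,
                         seed = 7)
  rb <- retest_replicate(fx$ph$volume, fx$ph$labels, noise_sigma = 1,
                         seed = 7)
  expect_identical(ra$volume$values, rb$volume$values)
  # 2 mm translation of a slab with margin: mask volume within 2%
  spec <- phantom_spec(shape = c(40L, 40L, 20L), spacing = 0.5,
                       cartilage_thickness_mm = 2, inplane_margin_mm = 4)
  ph <- make_slab(spec)
  rt <- retest_replicate(ph$volume, ph$labels, translation_mm = c(2, 0, 0))
  n0 <- sum(ph$labels$values > 0L)
  expect_lt(abs(sum(rt$labels$values > 0L) - n0) / n0, 0.02)
  # motion pushing tissue off-grid errors
  expect_error(retest_replicate(fx$ph$volume, fx$ph$labels,
                                translation_mm = c(9, 0, 0)), "off the grid")
})

test_that("boundary perturbation degrades Dice monotonically from 1", {
  fx <- slab_fixture()
  p0 <- perturb_mask(fx$ph$labels, 0)
  expect_equal(dice_jaccard(fx$ph$labels, p0)$dice, 1)
  dices <- vapply(c(0.1, 0.3, 0.6, 0.9), function(lev)
    dice_jaccard(fx$ph$labels, perturb_mask(fx$ph$labels, lev,
                                            seed = 11))$dice, numeric(1))
  expect_true(all(diff(dices) < 0))
  # flipping ~10% of the boundary shell matches the direct-count prediction
  lev <- 0.1
  fg <- fx$ph$labels$values > 0L
  nb <- cartiquant:::neighbor_count(fg)
  boundary <- (fg & nb < 6) | (!fg & nb > 0)
  pm <- perturb_mask(fx$ph$labels, lev, seed = 2)
  flipped <- sum(fg != (pm$values > 0L))
  exp_flips <- lev * sum(boundary)
  expect_lt(abs(flipped - exp_flips) / exp_flips, 0.35)  # binomial spread
  d_pred <- 1 - flipped / (sum(fg) + sum(pm$values > 0L))  # exact identity
  expect_equal(dice_jaccard(fx$ph$labels, pm)$dice, d_pred, tolerance = 1e-12)
})
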