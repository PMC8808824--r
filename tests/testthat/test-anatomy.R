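test_that("depth field orders voxels along the surface-BCI axis", {
  # 9-voxel slab: f = k/10 for the k-th cartilage voxel above the bone
  spec <- phantom_spec(shape = c(12L, 12L, 16L), spacing = 0.5,
                       cartilage_thickness_mm = 4.5, bone_thickness_mm = 1)
  ph <- make_slab(spec)
  depth <- compute_depth_field(ph$labels$values == 2L,
                               ph$labels$values == 1L, spacing = rep(0.5, 3))
  zc <- ph$truth$cartilage_z
  mid <- c(6, 6)
  fs <- depth$f[mid[1], mid[2], zc]
  expect_equal(fs, (1:9) / 10, tolerance = 1e-12)
  expect_true(all(diff(fs) > 0))  # strictly increasing bone -> surface
  expect_lt(fs[1], 1 / 3)         # voxel adjacent to bone is deep
  expect_equal(fs[5], 0.5)        # mid-slab voxel by symmetry
  # no bone contact is an error
  nob <- array(FALSE, dim(ph$labels$values))
  expect_error(compute_depth_field(ph$labels$values == 2L, nob,
                                   spacing = rep(0.5, 3)), "bone")
})

test_that("depth fraction is invariant to isotropic spacing rescaling", {
  spec1 <- phantom_spec(shape = c(10L, 10L, 16L), spacing = 0.5,
                        cartilage_thickness_mm = 3, bone_thickness_mm = 1)
  spec2 <- phantom_spec(shape = c(10L, 10L, 16L), spacing = 1,
                        cartilage_thickness_mm = 6, bone_thickness_mm = 2)
  d1 <- with(make_slab(spec1),
             compute_depth_field(labels$values == 2L, labels$values == 1L,
                                 spacing = rep(0.5, 3)))
  d2 <- with(make_slab(spec2),
             compute_depth_field(labels$values == 2L, labels$values == 1L,
                                 spacing = rep(1, 3)))
  expect_equal(d1$f, d2$f, tolerance = 1e-12)
})

test_that("layer thirds partition the mask with the deep-closed tie rule", {
  fx <- slab_fixture()
  layers <- fx$layers
  # exhaustive and disjoint by construction of a single label value
  expect_equal(sum(layers$values > 0L), sum(fx$depth$mask))
  expect_true(all(layers$values[fx$depth$mask] %in% 1:3))
  # the mapping itself
  f <- fx$depth$f[fx$depth$mask]
  l <- layers$values[fx$depth$mask]
  expect_true(all(l[f <= 1 / 3] == 1L))
  expect_true(all(l[f > 1 / 3 & f <= 2 / 3] == 2L))
  expect_true(all(l[f > 2 / 3] == 3L))
  # thick slab: equal thirds within one voxel shell
  spec <- phantom_spec(shape = c(12L, 12L, 20L), spacing = 0.5,
                       cartilage_thickness_mm = 6, bone_thickness_mm = 1)
  ph <- make_slab(spec)
  d <- compute_depth_field(ph$labels$values == 2L, ph$labels$values == 1L,
                           spacing = rep(0.5, 3))
  counts <- table(assign_layers(d)$values[d$mask])
  n <- sum(d$mask)
  shell <- 12 * 12  # one voxel layer of the slab
  expect_true(all(abs(counts - n / 3) <= shell))
})

test_that("subregion partition produces exactly 21 labels on a knee", {
  kn <- make_knee(shape = c(64L, 64L, 64L), spacing = 0.75,
                  t2_spacing = NULL, seed = 2)
  part <- partition_subregions(kn$cartilage, kn$bones)
  present <- setdiff(unique(as.vector(part$values)), 0L)
  expect_length(present, 21L)
  expect_setequal(present, as.integer(subregion_labels()))
  # voxel-exact partition of the bulk mask
  expect_equal(sum(part$values > 0L), sum(kn$cartilage$values > 0L))
  expect_true(all(part$values[kn$cartilage$values > 0L] > 0L))
  expect_true(all(part$values[kn$cartilage$values == 0L] == 0L))
})

test_that("a single-compartment slab splits into equal AP thirds", {
  spec <- phantom_spec(shape = c(10L, 30L, 12L), spacing = 0.5,
                       cartilage_thickness_mm = 2, bone_thickness_mm = 1)
  ph <- make_slab(spec)
  cart <- label_map(array(as.integer(ph$labels$values == 2L),
                          dim(ph$labels$values)),
                    c(cartilage = 1L), spacing = rep(0.5, 3))
  bones <- label_map(array(as.integer(ph$labels$values == 1L) * 2L,
                           dim(ph$labels$values)),
                     c(bone_tibia = 2L), spacing = rep(0.5, 3))
  part <- partition_subregions(cart, bones)
  counts <- table(part$values[part$values > 0L])
  # 30 columns along y split at (1/3, 2/3): 10 voxel-columns per AP sector,
  # medial/lateral halves of 5 x-columns each
  expect_equal(sort(unique(as.integer(names(counts)))),
               as.integer(subregion_labels()[c("tibia_medial_anterior",
                                               "tibia_medial_central",
                                               "tibia_medial_posterior",
                                               "tibia_lateral_anterior",
                                               "tibia_lateral_central",
                                               "tibia_lateral_posterior")]))
  expect_true(all(counts == 5 * 10 * 4))  # 5 x-cols, 10 y-cols, 4 z-voxels
  expect_equal(sum(counts), sum(cart$values))
})
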