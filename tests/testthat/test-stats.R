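test_that("Dice and Jaccard follow the overlap formulas", {
  a <- array(FALSE, c(10, 10, 2)); a[1:10, 1:10, 1] <- TRUE
  m <- a
  expect_equal(dice_jaccard(a, m)$dice, 1)
  expect_equal(dice_jaccard(a, m)$jaccard, 1)
  disj <- array(FALSE, c(10, 10, 2)); disj[, , 2] <- TRUE
  expect_equal(dice_jaccard(a, disj)$dice, 0)
  # |A| = |M| = 100, overlap 80
  b <- array(FALSE, c(10, 10, 2))
  b[c(which(a)[1:80], which(!a & disj)[1:20])] <- TRUE
  r <- dice_jaccard(a, b)
  expect_equal(r$dice, 0.8)
  expect_equal(r$jaccard, 80 / 120)
  expect_error(dice_jaccard(array(FALSE, c(2, 2, 2)),
                            array(FALSE, c(2, 2, 2))), "empty")
  expect_error(dice_jaccard(a, array(TRUE, c(3, 3, 3))), "grid")
})

test_that("Dice equals 2J/(1+J) voxel-exactly on random mask pairs", {
  for (k in 1:25) {
    a <- random_mask(seed = 2 * k)
    m <- random_mask(seed = 2 * k + 1)
    if (!any(a) || !any(m)) next
    r <- dice_jaccard(a, m)
    expect_equal(r$dice, 2 * r$jaccard / (1 + r$jaccard), tolerance = 1e-12)
    expect_gte(r$jaccard, 0); expect_lte(r$dice, 1)
  }
})

test_that("SEM and SDC follow the test-retest definitions", {
  expect_equal(sem_sdc(c(3, 4, 5), c(3, 4, 5))$sem, 0)
  r <- sem_sdc(c(0, 0), c(1, -1))
  expect_equal(r$sem, 1)                      # SD(d) = sqrt(2)
  expect_equal(r$sdc, 1.96 * sqrt(2), tolerance = 1e-12)
  expect_error(sem_sdc(1, 2), "at least 2")
  # simulation: independent noise sigma per visit gives SEM ~ sigma
  set.seed(5)
  truth <- rnorm(200, 50, 5)
  v1 <- truth + rnorm(200, 0, 2)
  v2 <- truth + rnorm(200, 0, 2)
  expect_lt(abs(sem_sdc(v1, v2)$sem - 2) / 2, 0.15)
})

test_that("layer agreement reports ms, percent and voxel differences", {
  a <- data.frame(subregion = c("r1", "r1"), layer = c("deep", "bulk"),
                  n_voxels = c(100L, 300L), mean_t2_ms = c(21, 25))
  b <- data.frame(subregion = c("r1", "r1"), layer = c("deep", "bulk"),
                  n_voxels = c(90L, 310L), mean_t2_ms = c(20, 25))
  out <- layer_agreement(a, b)
  expect_equal(out$delta_t2_ms[out$layer == "deep"], 1)
  expect_equal(out$delta_t2_pct[out$layer == "deep"], 5)
  expect_equal(out$delta_voxels[out$layer == "deep"], 10L)
  expect_named(out, c("subregion", "layer", "delta_t2_pct", "delta_t2_ms",
                      "delta_voxels"))
  expect_equal(unname(attr(out, "summary")["mean_abs_delta_t2_ms"]), 0.5)
  bad <- b; bad$layer[1] <- "superficial"
  expect_error(layer_agreement(a, bad), "unmatched")
})

test_that("group comparison matches the t-distribution oracle", {
  set.seed(8)
  x <- rnorm(12, 29.1, 4); y <- rnorm(60, 27.7, 2.7)
  vals <- c(x, y); flags <- c(rep(TRUE, 12), rep(FALSE, 60))
  r <- group_compare(vals, flags)
  o <- t.test(x, y, var.equal = TRUE)   # independent textbook route
  expect_equal(r$t, unname(o$statistic), tolerance = 1e-10)
  expect_equal(r$p_value, o$p.value, tolerance = 1e-10)
  expect_equal(r$df, unname(o$parameter))
  # per-group CI half-width identity
  g <- r$groups[r$groups$group == "no_lesion", ]
  expect_equal(g$ci_upper - g$mean, qt(0.975, 59) * g$sd / sqrt(60),
               tolerance = 1e-12)
  # identical groups: t = 0, P = 1
  same <- group_compare(c(1, 2, 3, 1, 2, 3),
                        c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  expect_error(group_compare(c(1, 2, 3), c(TRUE, FALSE, FALSE)),
               "at least 2")
  # well-separated groups are detected essentially always
  set.seed(9)
  strong <- group_compare(c(rnorm(12, 3, 1), rnorm(60, 0, 1)),
                          c(rep(TRUE, 12), rep(FALSE, 60)))
  expect_lt(strong$p_value, 0.001)
  # paired variant agrees with the paired oracle
  set.seed(10)
  p1 <- rnorm(15); p2 <- p1 + rnorm(15, 0.3, 0.2)
  rp <- group_compare(c(p2, p1), c(rep(TRUE, 15), rep(FALSE, 15)),
                      paired = TRUE)
  op <- t.test(p2, p1, paired = TRUE)
  expect_equal(rp$t, unname(op$statistic), tolerance = 1e-10)
  expect_equal(rp$p_value, op$p.value, tolerance = 1e-10)
})

test_that("reliability report aggregates SEM/SDC across a cohort", {
  mk_tab <- function(vals) {
    data.frame(subregion = c("r1", "r2"), layer = "bulk",
               n_voxels = c(100L, 120L), volume_mm3 = c(10, 12),
               mean_thickness_mm = c(2, 2.1), mean_t2_ms = vals)
  }
  v1 <- list(s1 = mk_tab(c(27, 28)), s2 = mk_tab(c(26, 29)),
             s3 = mk_tab(c(28, 27)))
  # identical visits: all SDC zero
  rep0 <- reliability_report(v1, v1)
  expect_true(all(rep0$per_region$sdc == 0))
  # SDC column is exactly 2.7719 x SEM column
  set.seed(4)
  v2 <- lapply(v1, function(tb) { tb$mean_t2_ms <- tb$mean_t2_ms +
    rnorm(2); tb })
  rel <- reliability_report(v1, v2)
  expect_equal(rel$per_region$sdc, 1.96 * sqrt(2) * rel$per_region$sem,
               tolerance = 1e-12)
  expect_true(all(c("mean_t2_ms", "volume_mm3") %in%
                    rel$per_region$metric))
  # subject with a missing visit is dropped with a warning
  expect_warning(reliability_report(v1, v2[1:2]), "dropped")
})
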