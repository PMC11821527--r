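test_that("probability-map binarization uses the >= 0.5 convention", {
  z <- array(0, c(3, 4, 4))
  out <- binarizeProbabilityMap(z)
  expect_equal(sum(out$mask), 0)
  expect_equal(max(out$labels), 0)
  ## exact 0.5 is foreground
  z[2, 2, 2] <- 0.5
  expect_equal(sum(binarizeProbabilityMap(z)$mask), 1)
  z[1, 1, 1] <- 1.2
  expect_error(binarizeProbabilityMap(z), "input error")
})

test_that("3-D component labelling distinguishes 26- from 6-connectivity", {
  m <- array(FALSE, c(3, 3, 3))
  m[1, 1, 1] <- TRUE
  m[2, 2, 2] <- TRUE   # corner-adjacent to the first voxel
  expect_equal(max(labelComponents3d(m, 26)), 1)
  expect_equal(max(labelComponents3d(m, 6)), 2)
  ## blob voxel count survives blur + threshold of a generated stack
  sim <- simulateImageStack(n_cells = 1, a_um = 4, b_um = 2.5,
                            organelle_fraction = 0.03, blob_radius_vox = 6,
                            seed = 3)
  seg <- binarizeProbabilityMap(sim$organelle_map)
  expect_equal(sum(seg$mask), sum(sim$organelle_truth), tolerance = 0.05)
})

test_that("cell segmentation labels disjoint cells with accurate footprints", {
  sim <- simulateImageStack(n_cells = 2, a_um = c(4, 3), b_um = c(2.5, 2),
                            organelle_fraction = 0, seed = 2)
  lab <- segmentCells(sim$cell_stack)
  expect_equal(max(lab), 2)
  ## the larger footprint matches the projected ellipse area within 2%
  areas <- table(lab[lab > 0]) * prod(sim$voxel_dims[2:3])
  expect_equal(max(areas), pi * 4 * 2.5, tolerance = 0.02)
  ## empty field
  expect_warning(empty <- segmentCells(array(0, c(3, 10, 10))), "no cells")
  expect_equal(max(empty), 0)
})

test_that("prolate-ellipsoid fits recover closed-form volumes", {
  expect_equal(prolateEllipsoidVolume(5, 5), 523.5988, tolerance = 1e-6)
  expect_equal(prolateEllipsoidVolume(10, 5), 1047.1976, tolerance = 1e-6)
  ## moments fit on a rasterized 10 x 5 um ellipse at 0.1 um pixels
  px <- 0.1
  yy <- seq(px / 2, 14, by = px); xx <- seq(px / 2, 24, by = px)
  mask <- outer(((yy - 7) / 5)^2, ((xx - 12) / 10)^2, `+`) <= 1
  fit <- fitProlateEllipsoid(mask, c(px, px))
  expect_equal(fit$a_um, 10, tolerance = 0.02)
  expect_equal(fit$b_um, 5, tolerance = 0.02)
  expect_equal(fit$v_cell_um3, 1047.1976, tolerance = 0.05)
  expect_error(fitProlateEllipsoid(mask & FALSE, c(px, px)),
               "geometry error")
})

test_that("organelle volumes count voxels inside the footprint in physical units", {
  org <- array(FALSE, c(10, 20, 20))
  org[1:10, 1:10, 1:10] <- TRUE          # 1000 voxels
  foot <- matrix(TRUE, 20, 20)
  expect_equal(organelleVolume(org, foot, c(0.2, 0.1, 0.1)), 2.0)
  ## footprint restriction
  half <- matrix(FALSE, 20, 20); half[, 1:5] <- TRUE
  expect_equal(organelleVolume(org, half, c(0.2, 0.1, 0.1)), 1.0)
  expect_equal(organelleVolume(org & FALSE, foot, c(0.2, 0.1, 0.1)), 0)
  expect_error(organelleVolume(org, matrix(TRUE, 5, 5), c(0.2, 0.1, 0.1)),
               "alignment error")
  expect_equal(volumeFraction(2, 4), 0.5)
  expect_equal(volumeFraction(0, 4), 0)
  expect_error(volumeFraction(1, 0), "geometry error")
})

test_that("voxel-size changes rescale counts but not volumes", {
  ## a 2 um sphere rasterized at two lateral resolutions
  rast <- function(px) {
    zz <- seq(0.1, 6, by = 0.2); yy <- seq(px / 2, 6, by = px)
    xx <- yy
    arr <- array(FALSE, c(length(zz), length(yy), length(xx)))
    for (k in seq_along(zz))
      arr[k, , ] <- outer((yy - 3)^2, (xx - 3)^2, `+`) + (zz[k] - 3)^2 <= 4
    arr
  }
  v1 <- sum(rast(0.1)) * 0.2 * 0.1 * 0.1
  v2 <- sum(rast(0.05)) * 0.2 * 0.05 * 0.05
  expect_equal(v1, 4 / 3 * pi * 8, tolerance = 0.05)
  expect_equal(v2, v1, tolerance = 0.02)
})

test_that("normality rule applies the 1.5 s.d. band with a none-detected class", {
  wt <- c(0.04, 0.05, 0.06, 0.05)        # mean 0.05
  sg <- sd(wt)
  out <- classifyNormality(c(0.05 + 1.49 * sg, 0.05 + 1.51 * sg,
                             0.05 - 1.51 * sg, 0), wt)
  expect_identical(out$labels, c("normal", "abnormal_high", "abnormal_low",
                                 "none_detected"))
  expect_equal(out$percent_none, 25)
  ## the worked boundary arithmetic: WT mean 0.05, sd 0.01
  wt2 <- c(0.04, 0.06, 0.05 + sqrt(0.5) * 0.01, 0.05 - sqrt(0.5) * 0.01)
  expect_equal(mean(wt2), 0.05); expect_equal(sd(wt2), 0.01)
  expect_identical(classifyNormality(c(0.064, 0.066), wt2)$labels,
                   c("normal", "abnormal_high"))
  ## joint affine rescaling leaves labels unchanged
  f <- c(0.02, 0.05, 0.09, 0)
  l1 <- classifyNormality(f, wt)$labels
  l2 <- classifyNormality(f[f > 0] * 3 + 1, wt * 3 + 1)$labels
  expect_identical(l1[f > 0], l2)
  expect_error(classifyNormality(0.05, rep(0.05, 3)),
               "degenerate-reference")
})

test_that("kernel density estimates integrate to one and find the mode", {
  set.seed(8)
  x <- rnorm(1e5, mean = 0.3, sd = 0.05)
  d <- kdeDensity(x, n = 1024)
  expect_equal(sum(d$density) * diff(d$x[1:2]), 1, tolerance = 1e-3)
  expect_lt(abs(d$x[which.max(d$density)] - 0.3), 0.05 / 10)
  ## symmetric sample gives a near-symmetric curve around its mean
  xs <- c(x, 0.6 - x)
  ds <- kdeDensity(xs)
  lo <- ds$density[ds$x > 0.1 & ds$x < 0.3]
  hi <- rev(ds$density[ds$x > 0.3 & ds$x < 0.5])
  m <- min(length(lo), length(hi))
  expect_lt(max(abs(lo[1:m] - hi[1:m])), 0.05 * max(ds$density))
  expect_warning(kdeDensity(rep(0.2, 5)), "degenerate")
})

test_that("planted volume fractions are recovered end to end", {
  sim <- simulateImageStack(n_cells = 1, a_um = 6, b_um = 3.5,
                            organelle_fraction = 0.05, blob_radius_vox = 8,
                            seed = 11)
  res <- cellVolumeFractions(sim$cell_stack, sim$organelle_map,
                             sim$voxel_dims)
  expect_equal(nrow(res), 1)
  expect_equal(res$volume_fraction, sim$truth$true_fraction,
               tolerance = 0.05)
})
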