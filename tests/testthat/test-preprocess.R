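# Intensity/geometry conditioning: histogram matching, rescaling, masking,
# signed distance transforms, orientation stages.

test_that("histogram matching is idempotent, monotone, and matches percentiles", {
  img <- fx_reference()$np
  same <- histogram_match(img, img)
  expect_equal(same$data, img$data, tolerance = 1e-9)

  half <- volumetric_image(img$data * 0.5, img$spacing, img$origin, "NP")
  matched <- histogram_match(half, img)
  expect_lt(abs(median(matched$data) - median(img$data)), 1)
  # mapping is non-decreasing over all input levels
  lv <- sort(unique(as.numeric(half$data)))
  key <- match(as.numeric(half$data), lv)
  mapped_by_level <- vapply(split(as.numeric(matched$data), key), mean, 0)
  expect_true(all(diff(mapped_by_level) >= -1e-9))

  flat <- volumetric_image(array(7, c(8, 8, 4)), c(1, 1, 1))
  expect_warning(histogram_match(flat, img), "constant")
})

test_that("robust_rescale clips outliers into [0, 1]", {
  set.seed(3)
  v <- array(runif(8000, 10, 100), c(20, 20, 20))
  v[sample(8000, 8)] <- 5000  # 0.1% saturated outliers, above the 99.8 cut
  img <- volumetric_image(v, c(1, 1, 1))
  r <- robust_rescale(img)
  expect_true(all(r$data >= 0 & r$data <= 1))
  expect_equal(unique(as.numeric(r$data[v == 5000])), 1)
  body <- as.numeric(r$data[v < 1000])
  expect_gt(max(body), 0.9)
  expect_lt(min(body), 0.1)

  flat <- volumetric_image(array(3, c(6, 6, 6)), c(1, 1, 1))
  expect_warning(rr <- robust_rescale(flat), "constant")
  expect_true(all(rr$data == 0))
})

test_that("coarse_brain_mask keeps the object, drops specks, errors on empty", {
  # phantom: large ellipsoid + 3-voxel speck
  g <- list(dim = c(64L, 48L, 16L), spacing = c(1, 1, 2), origin = c(0, 0, 0))
  pts <- grid_points(g)
  obj <- ((pts[, 1] - 32) / 18)^2 + ((pts[, 2] - 24) / 14)^2 +
    ((pts[, 3] - 16) / 10)^2 <= 1
  arr <- array(ifelse(obj, 200, 5) + rnorm(prod(g$dim), 0, 2), g$dim)
  arr[c(100, 101, 102)] <- 220  # speck far from the object
  img <- volumetric_image(pmax(arr, 0), g$spacing, g$origin, "NP")
  m <- coarse_brain_mask(img)
  obj_arr <- array(obj, g$dim)
  dice <- 2 * sum(m$data * obj_arr) / (sum(m$data) + sum(obj_arr))
  expect_gt(dice, 0.9)
  expect_equal(m$data[100], 0)  # speck removed

  expect_error(coarse_brain_mask(
    volumetric_image(array(0, c(16, 16, 16)), c(1, 1, 1))),
    "no neuropil signal")
})

test_that("opening-based and threshold-based masks agree on the clean phantom", {
  np <- fx_reference()$np
  m1 <- coarse_brain_mask(np)
  m2 <- threshold_brain_mask(np)
  dice <- 2 * sum(m1$data * m2$data) / (sum(m1$data) + sum(m2$data))
  expect_gte(dice, 0.95)
})

test_that("coarse_brain_mask is stable under salt noise", {
  np <- fx_reference()$np
  m_clean <- coarse_brain_mask(np)
  set.seed(9)
  noisy <- np$data
  hit <- sample(length(noisy), round(0.001 * length(noisy)))
  noisy[hit] <- 255
  m_noisy <- coarse_brain_mask(volumetric_image(noisy, np$spacing,
                                                np$origin, "NP"))
  dice <- 2 * sum(m_clean$data * m_noisy$data) /
    (sum(m_clean$data) + sum(m_noisy$data))
  expect_gte(dice, 0.99)
})

test_that("signed distance transform matches a brute-force oracle", {
  set.seed(5)
  g <- list(dim = c(11L, 11L, 11L), spacing = c(0.7, 1.1, 1.9),
            origin = c(0, 0, 0))
  arr <- array(0, g$dim)
  arr[4:8, 3:9, 5:8] <- 1
  arr[6, 6, 6] <- 1
  mask <- volumetric_image(arr, g$spacing, g$origin, "mask")
  sdt <- signed_distance_transform(mask)

  pts <- grid_points(g)
  fg <- which(arr == 1)
  bg <- which(arr == 0)
  brute <- numeric(length(arr))
  for (i in seq_along(arr)) {
    targets <- if (arr[i] == 1) bg else fg
    d <- sqrt(colSums((t(pts[targets, , drop = FALSE]) - pts[i, ])^2))
    brute[i] <- if (arr[i] == 1) -min(d) else min(d)
  }
  expect_lt(max(abs(as.numeric(sdt$data) - brute)), 1e-6)
})

test_that("SDT of a sphere and the eikonal property", {
  g <- list(dim = c(40L, 40L, 34L), spacing = c(1, 1, 1), origin = c(0, 0, 0))
  pts <- grid_points(g)
  r <- 12
  ctr <- c(19.5, 19.5, 16.5)
  arr <- array(as.numeric(rowSums(sweep(pts, 2, ctr)^2) <= r^2), g$dim)
  mask <- volumetric_image(arr, g$spacing, g$origin, "mask")
  sdt <- signed_distance_transform(mask)
  cidx <- which.min(rowSums(sweep(pts, 2, ctr)^2))
  expect_lt(abs(as.numeric(sdt$data)[cidx] - (-r)), max(g$spacing) + 1e-9)
  # boundary voxels: |value| at most half a voxel diagonal
  half_diag <- sqrt(sum(g$spacing^2)) / 2
  dist_to_surface <- abs(sqrt(rowSums(sweep(pts, 2, ctr)^2)) - r)
  on_boundary <- dist_to_surface < min(g$spacing) / 2
  expect_true(all(abs(as.numeric(sdt$data)[on_boundary]) <=
                    sqrt(sum(g$spacing^2)) + 1e-9))
  # eikonal: |grad SDT| ~ 1 at interior sample points away from the
  # medial axis (where the distance ridge makes the gradient undefined)
  f <- sdt$data
  interior <- which(arr == 1 & as.numeric(sdt$data) < -3 &
                      as.numeric(sdt$data) > -8)
  set.seed(6)
  interior <- sample(interior, 50)
  ii <- arrayInd(interior, g$dim)
  ok <- ii[, 1] > 1 & ii[, 1] < g$dim[1] & ii[, 2] > 1 & ii[, 2] < g$dim[2] &
    ii[, 3] > 1 & ii[, 3] < g$dim[3]
  ii <- ii[ok, , drop = FALSE]
  gx <- (f[cbind(ii[, 1] + 1, ii[, 2], ii[, 3])] -
           f[cbind(ii[, 1] - 1, ii[, 2], ii[, 3])]) / (2 * g$spacing[1])
  gy <- (f[cbind(ii[, 1], ii[, 2] + 1, ii[, 3])] -
           f[cbind(ii[, 1], ii[, 2] - 1, ii[, 3])]) / (2 * g$spacing[2])
  gz <- (f[cbind(ii[, 1], ii[, 2], ii[, 3] + 1)] -
           f[cbind(ii[, 1], ii[, 2], ii[, 3] - 1)]) / (2 * g$spacing[3])
  gm <- sqrt(gx^2 + gy^2 + gz^2)
  # within 10% at the bulk of the samples; isolated voxels sitting on the
  # discretized-boundary staircase may exceed it
  expect_lt(as.numeric(quantile(abs(gm - 1), 0.9)), 0.10)
  expect_lt(max(abs(gm - 1)), 0.30)
})

test_that("dorsal-ventral alignment translates, flips conditionally, idempotent", {
  np <- fx_reference()$np
  g <- image_geometry(np)
  r1 <- orient_dorsal_ventral(np, g)
  expect_false(r1$flipped)  # phantom mass sits in the top (anterior) half
  # flipped input: center of mass in the bottom half -> flip applied
  flipped_in <- volumetric_image(np$data[, dim(np$data)[2]:1, ],
                                 np$spacing, np$origin, "NP")
  r2 <- orient_dorsal_ventral(flipped_in, g)
  expect_true(r2$flipped)
  # idempotence: a second call never flips again
  r3 <- orient_dorsal_ventral(r2$image, g)
  expect_false(r3$flipped)
  com <- center_of_mass(r3$image)
  expect_lt(max(abs(com - larvreg:::geometric_center(g))), 1.0)
})

test_that("z-flip candidates: exact flip arithmetic and involution", {
  # 101 slices at 2 um: extent center exactly 100 um
  g <- list(dim = c(8L, 8L, 101L), spacing = c(1, 1, 2), origin = c(0, 0, 0))
  img <- volumetric_image(array(runif(prod(g$dim)), g$dim), g$spacing,
                          g$origin, "NP")
  cands <- z_flip_candidates(img)
  expect_length(cands, 2L)
  flipT <- cands[[2]]$transform
  expect_equal(as.numeric(apply_transform(flipT, c(0, 0, 10))),
               c(0, 0, 190))
  # flipping twice restores the image exactly (grid maps onto itself)
  again <- z_flip_candidates(cands[[2]]$image)[[2]]$image
  expect_equal(again$data, img$data)
  # z-symmetric volume: both candidates voxel-identical
  sym <- img$data + img$data[, , dim(img$data)[3]:1]
  simg <- volumetric_image(sym, g$spacing, g$origin, "NP")
  cs <- z_flip_candidates(simg)
  expect_equal(cs[[1]]$image$data, cs[[2]]$image$data)
})
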