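# Linear, B-spline and dense-field transforms; resampling; averaging.

test_that("apply_transform matches matrix arithmetic oracles", {
  expect_equal(apply_transform(identity_transform(), c(1, 2, 3)),
               rbind(c(1, 2, 3)))
  tr <- linear_transform("translation", translation = c(3, 4, 0))
  expect_equal(apply_transform(tr, c(0, 0, 0)), rbind(c(3, 4, 0)))
  # similarity s = 2 about the origin
  s2 <- similarity_transform(scale = 2)
  expect_equal(apply_transform(s2, c(1, 0, 0)), rbind(c(2, 0, 0)))
  # oracle: direct matrix arithmetic for a rotation + scale about a center
  ang <- 0.3
  tr2 <- similarity_transform(scale = 1.5, angles = c(0, 0, ang),
                              translation = c(1, -1, 2),
                              center = c(5, 6, 7))
  p <- c(2, 3, 4)
  R <- rbind(c(cos(ang), -sin(ang), 0), c(sin(ang), cos(ang), 0),
             c(0, 0, 1))
  manual <- 1.5 * R %*% (p - c(5, 6, 7)) + c(5, 6, 7) + c(1, -1, 2)
  expect_equal(as.numeric(apply_transform(tr2, p)), as.numeric(manual))
})

test_that("similarity validation rejects shear", {
  M <- diag(3); M[1, 2] <- 0.3
  expect_error(linear_transform("similarity", M), "uniform scale")
})

test_that("compose(t, inverse(t)) is the identity on random points", {
  set.seed(2)
  for (k in 1:5) {
    tr <- similarity_transform(scale = exp(rnorm(1, 0, 0.1)),
                               angles = c(0, 0, rnorm(1, 0, 0.5)),
                               translation = rnorm(3, 0, 5),
                               center = rnorm(3, 0, 3))
    comp <- linear_compose(tr, invert_linear(tr))
    pts <- matrix(rnorm(300, 0, 20), 100, 3)
    expect_lt(max(abs(apply_transform(comp, pts) - pts)), 1e-6)
  }
})

test_that("composite transforms apply right-to-left", {
  a <- linear_transform("translation", translation = c(1, 0, 0))
  b <- similarity_transform(scale = 2)
  comp <- composite_transform(list(a, b))
  # b first: (1,0,0) -> (2,0,0); then a: -> (3,0,0)
  expect_equal(as.numeric(apply_transform(comp, c(1, 0, 0))), c(3, 0, 0))
})

test_that("resample: identity, integer shift oracle, binary masks", {
  img <- ramp_image(c(8L, 7L, 6L), spacing = c(1, 1, 1))
  out <- resample(img, identity_transform(), img)
  expect_equal(out$data, img$data)

  # one-voxel translation with nearest interpolation == index shift
  tr <- linear_transform("translation", translation = c(1, 0, 0))
  sh <- resample(img, tr, img, interp = "nearest")
  expect_equal(sh$data[1:7, , ], img$data[2:8, , ])
  expect_true(all(sh$data[8, , ] == 0))  # background fill
  # intensity conserving on the interior (histogram unchanged)
  expect_equal(sort(as.numeric(sh$data[1:7, , ])),
               sort(as.numeric(img$data[2:8, , ])))

  m <- volumetric_image(array(as.numeric(img$data > 20), dim(img)),
                        img$spacing, img$origin, "mask")
  mres <- resample(m, tr, m, interp = "nearest")
  expect_true(all(mres$data %in% c(0, 1)))

  sing <- linear_transform("affine", diag(c(1, 1, 0)))
  expect_error(resample(img, sing, img), "degenerate")
})

test_that("to_displacement_field matches direct evaluation", {
  g <- list(dim = c(6L, 5L, 4L), spacing = c(1, 1, 2), origin = c(0, 0, 0))
  f0 <- to_displacement_field(identity_transform(), g)
  expect_true(all(f0$vectors == 0))
  ft <- to_displacement_field(
    linear_transform("translation", translation = c(1, 2, 3)), g)
  expect_true(all(abs(sweep(matrix(ft$vectors, ncol = 3), 2,
                            c(1, 2, 3)) ) < 1e-12))

  # B-spline with one displaced control point vs direct spline evaluation
  bs0 <- bspline_identity_for(g, 4)
  coef <- bs0$coef
  coef[3, 3, 2, 1] <- 2.5
  bs <- bspline_transform(coef, bs0$grid_origin, bs0$grid_spacing)
  fd <- to_displacement_field(bs, g)
  probe_idx <- rbind(c(2, 2, 1), c(3, 2, 2), c(1, 1, 1), c(4, 3, 2),
                     c(5, 4, 3))
  pts <- voxel_to_phys(g, probe_idx)
  direct <- apply_transform(bs, pts) - pts
  # the field sampled at those grid nodes
  at <- probe_idx + 1
  from_field <- t(vapply(seq_len(nrow(at)), function(i)
    fd$vectors[at[i, 1], at[i, 2], at[i, 3], ], numeric(3)))
  expect_equal(from_field, unname(direct), tolerance = 1e-12)
})

test_that("field-advected points equal directly transformed points at nodes", {
  g <- list(dim = c(8L, 6L, 5L), spacing = c(0.5, 0.5, 2), origin = c(0, 0, 0))
  tr <- similarity_transform(scale = 1.02, angles = c(0, 0, 0.05),
                             translation = c(0.3, -0.2, 0.5),
                             center = c(2, 1.5, 4))
  fd <- to_displacement_field(tr, g)
  pts <- grid_points(g)
  expect_lt(max(abs(apply_transform(fd, pts) - apply_transform(tr, pts))),
            1e-9)
})

test_that("mean_displacement_field follows its definition", {
  g <- list(dim = c(4L, 4L, 3L), spacing = c(1, 1, 1), origin = c(0, 0, 0))
  mk <- function(v) displacement_field(
    array(rep(v, each = prod(g$dim)), c(g$dim, 3)), g$spacing, g$origin)
  F1 <- mk(c(1, 0, 0)); F2 <- mk(c(2, 0, 0)); F3 <- mk(c(3, 0, 0))
  m <- mean_displacement_field(list(F1, F2, F3), include_identity = FALSE)
  expect_equal(unique(as.numeric(m$vectors[, , , 1])), 2)
  # {F, -F} cancel
  Fm <- mk(c(-1, 0, 0))
  z <- mean_displacement_field(list(F1, Fm), include_identity = FALSE)
  expect_true(all(z$vectors == 0))
  # single field + identity term -> F/2
  h <- mean_displacement_field(list(F2), include_identity = TRUE)
  expect_equal(unique(as.numeric(h$vectors[, , , 1])), 1)
  expect_error(mean_displacement_field(list()), "empty")
})

test_that("dense-field inversion reaches its stated tolerance", {
  g <- list(dim = c(24L, 20L, 10L), spacing = c(1, 1, 2), origin = c(0, 0, 0))
  set.seed(4)
  bs0 <- bspline_identity_for(g, 8)
  bs <- bspline_transform(array(rnorm(length(bs0$coef), 0, 0.8),
                                dim(bs0$coef)),
                          bs0$grid_origin, bs0$grid_spacing)
  fd <- to_displacement_field(bs, g)
  inv <- invert_displacement_field(fd)
  pts <- grid_points(g)[seq(1, prod(g$dim), by = 7), ]
  round_trip <- apply_transform(fd, apply_transform(inv, pts))
  # interior points come back within the 0.1 um stopping tolerance
  interior <- pts[, 1] > 2 & pts[, 1] < 21 & pts[, 2] > 2 & pts[, 2] < 17 &
    pts[, 3] > 2 & pts[, 3] < 16
  expect_lt(stats::median(sqrt(rowSums(
    (round_trip[interior, ] - pts[interior, ])^2))), 0.1)
})

test_that("transform JSON serialization roundtrips all classes", {
  p <- withr::local_tempfile(fileext = ".json")
  tr <- similarity_transform(scale = 1.1, angles = c(0, 0, 0.2),
                             translation = c(1, 2, 3), center = c(4, 5, 6))
  bs0 <- bspline_identity_for(list(dim = c(5L, 5L, 4L),
                                   spacing = c(1, 1, 1),
                                   origin = c(0, 0, 0)), 3)
  comp <- composite_transform(list(tr, bs0))
  write_transform(comp, p)
  back <- read_transform(p)
  pts <- matrix(rnorm(30, 2, 1), 10, 3)
  expect_equal(apply_transform(back, pts), apply_transform(comp, pts),
               tolerance = 1e-12)
})

test_that("B-spline support margin covers the fixed domain", {
  g <- list(dim = c(30L, 20L, 10L), spacing = c(0.5, 0.5, 2),
            origin = c(0, 0, 0))
  bs <- bspline_identity_for(g, 12)
  extent <- (g$dim - 1) * g$spacing
  # every domain corner must have full 4^3 support inside the grid
  nodes <- dim(bs$coef)[1:3]
  u <- (rbind(c(0, 0, 0), extent) -
          matrix(bs$grid_origin, 2, 3, byrow = TRUE)) /
    matrix(bs$grid_spacing, 2, 3, byrow = TRUE)
  expect_true(all(floor(u[1, ]) - 1 >= 0))
  expect_true(all(floor(u[2, ]) + 2 <= nodes - 1))
})
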