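# Fusion, average-space construction, channel propagation.  The full
# cohort build is exercised at production scale in test-acceptance.R; here
# the pieces are checked on constructed inputs plus one reduced-scale
# pairwise run.

test_that("fuse: identity on identical inputs, median/mean arithmetic", {
  img <- ramp_image(c(5L, 4L, 3L))
  expect_equal(fuse(list(img, img, img), "median")$data, img$data)
  expect_equal(fuse(list(img, img, img), "mean")$data, img$data)

  mk <- function(v) volumetric_image(array(v, c(2, 2, 2)), c(1, 1, 1))
  st <- list(mk(10), mk(12), mk(200))
  expect_equal(unique(as.numeric(fuse(st, "median")$data)), 12)
  expect_equal(unique(as.numeric(fuse(st, "mean")$data)), 74)
  # even count: lower of the two middle values (preserves gray levels)
  st4 <- list(mk(10), mk(12), mk(14), mk(200))
  expect_equal(unique(as.numeric(fuse(st4, "median")$data)), 12)
})

test_that("median fusion resists minority corruption (breakdown property)", {
  set.seed(31)
  base <- array(runif(250, 50, 60), c(5, 5, 10))
  imgs <- lapply(1:5, function(i)
    volumetric_image(base, c(1, 1, 1)))
  # corrupt floor((N-1)/2) = 2 members at arbitrary voxels
  for (i in 1:2) {
    d <- imgs[[i]]$data
    d[sample(250, 60)] <- 255
    imgs[[i]] <- volumetric_image(d, c(1, 1, 1))
  }
  med <- fuse(imgs, "median")
  expect_equal(med$data, base)
})

test_that("build_average_space: two-field closed form and zero diagonal", {
  g <- list(dim = c(10L, 8L, 6L), spacing = c(1, 1, 2), origin = c(0, 0, 0))
  set.seed(32)
  bs0 <- bspline_identity_for(g, 6)
  F <- to_displacement_field(
    bspline_transform(array(rnorm(length(bs0$coef), 0, 0.6),
                            dim(bs0$coef)),
                      bs0$grid_origin, bs0$grid_spacing), g)
  Finv <- invert_displacement_field(F)
  zero <- displacement_field(array(0, c(g$dim, 3)), g$spacing, g$origin)
  # column-major fill: fields[[1,2]] = F (deformation of scan 1 to scan 2)
  fields <- matrix(list(zero, Finv, F, zero), 2, 2)
  t_i <- build_average_space(fields, include_identity = TRUE)
  # T_1 = (F + 0)/2 = F/2 on grid nodes
  expect_equal(t_i[[1]]$vectors, F$vectors / 2, tolerance = 1e-9)
  # identical scans -> all T_i ~ 0
  fields0 <- matrix(list(zero, zero, zero, zero), 2, 2)
  t0 <- build_average_space(fields0)
  expect_true(all(abs(t0[[1]]$vectors) < 1e-12))
})

test_that("mean field is smaller than individual fields on asymmetric sets", {
  g <- list(dim = c(6L, 6L, 4L), spacing = c(1, 1, 1), origin = c(0, 0, 0))
  mk <- function(v) displacement_field(
    array(rep(v, each = prod(g$dim)), c(g$dim, 3)), g$spacing, g$origin)
  flds <- list(mk(c(4, 0, 0)), mk(c(-2, 2, 0)), mk(c(0, -3, 1)))
  m <- mean_displacement_field(flds, include_identity = TRUE)
  mag <- function(f) mean(sqrt(rowSums(matrix(f$vectors, ncol = 3)^2)))
  expect_true(all(mag(m) < vapply(flds, mag, 0)))
})

test_that("propagate_channel warps with the NP transform, never re-registers", {
  ph <- fx_clean_phantom()
  g <- image_geometry(ph$scan$channels$NP)
  # identity chain leaves the channel untouched
  same <- propagate_channel(ph$scan, "NT", identity_transform())
  expect_equal(same$data, ph$scan$channels$NT$data)
  # integer-voxel translation with nearest interpolation preserves the
  # GE histogram on the retained region
  tr <- linear_transform("translation",
                         translation = c(ph$scan$channels$GE$spacing[1],
                                         0, 0))
  gew <- propagate_channel(ph$scan, "GE", tr, interp = "nearest")
  expect_equal(sort(as.numeric(gew$data[1:(g$dim[1] - 1), , ])),
               sort(as.numeric(ph$scan$channels$GE$data[
                 2:g$dim[1], , ])))
  expect_error(propagate_channel(
    brain_scan("x", list(NP = ph$scan$channels$NP)), "NT",
    identity_transform()), "no NT")
})

test_that("NT structures follow the NP ground-truth transform", {
  ref <- fx_reference()
  ph <- fx_clean_phantom()
  inv <- invert_displacement_field(ph$applied_transform)
  nt_back <- propagate_channel(ph$scan, "NT", inv,
                               reference = image_geometry(ref$nt))
  # the warped-back tract image must correlate strongly with the
  # canonical tract image near the tracts
  sel <- ref$nt$data > 60
  expect_gt(cor(as.numeric(ref$nt$data[sel]),
                as.numeric(nt_back$data[sel])), 0.8)
})

test_that("pairwise registration of identical scans is near zero", {
  # 3 identical scans; reduced iterations (identity is reached instantly)
  ph <- generate_phantom(80, deform_amplitude = 0)
  scans <- lapply(1:3, function(i) {
    s <- ph$scan; s$scan_id <- paste0("id", i); s
  })
  cfg <- larvreg_config()
  cfg$global$iterations <- 60L
  cfg$global$levels <- 2L
  cfg$deformable <- fast_deformable(levels = 2L,
                                    iterations_per_level = 40L)
  fields <- pairwise_register_all(scans, cfg)
  for (i in 1:3) expect_true(all(fields[[i, i]]$vectors == 0))
  offdiag <- sqrt(rowSums(matrix(fields[[1, 2]]$vectors, ncol = 3)^2))
  expect_lt(max(offdiag), 1.5)
  expect_error(pairwise_register_all(scans[1:2], cfg), "at least 3")
})

test_that("template_package validates anchors and mask", {
  ref <- fx_reference()
  good_anchors <- fx_template()$qa_anchors
  cal <- fx_template()$qa_calibration
  expect_error(template_package(ref$np, ref$mask,
                                good_anchors[1:4, ], cal),
               "8 QA anchor labels")
  empty_mask <- volumetric_image(array(0, dim(ref$np$data)),
                                 ref$np$spacing, ref$np$origin, "mask")
  expect_error(template_package(ref$np, empty_mask, good_anchors, cal),
               "empty")
})

test_that("template package directory roundtrip", {
  tpl <- fx_template()
  dir <- withr::local_tempdir()
  save_template_package(tpl, dir)
  back <- load_template_package(dir)
  expect_equal(back$np_template$data, tpl$np_template$data)
  expect_equal(back$qa_calibration$strain_median,
               tpl$qa_calibration$strain_median)
  expect_identical(sort(back$qa_anchors$label), sort(tpl$qa_anchors$label))
  expect_equal(unname(back$qa_calibration$vi_max[tpl$qa_anchors$label[1]]),
               unname(tpl$qa_calibration$vi_max[tpl$qa_anchors$label[1]]))
})
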