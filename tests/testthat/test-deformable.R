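# Masked B-spline deformable registration and the multi-metric mode.

test_that("config invariants are enforced", {
  ref <- fx_reference()
  expect_error(check_deformable_config <- larvreg:::check_deformable_config(
    deformable_config(grid_spacing = 1.5), ref$np), "grid_spacing")
  expect_error(larvreg:::check_deformable_config(
    deformable_config(subregion_edge = 1), ref$np), "subregion_edge")
  expect_error(register_bspline(ref$np, ref$np,
                                cfg = deformable_config(
                                  metric = "masked_local_NCC")),
               "mask is required")
})

test_that("identical images stay still under registration", {
  ref <- fx_reference()
  res <- register_bspline(ref$np, ref$np, init = NULL,
                          cfg = fast_deformable(seed = 5))
  expect_lt(max_displacement(res$stack, image_geometry(ref$np)), 1)
})

test_that("a known smooth deformation is recovered to ~2 um", {
  ref <- fx_reference()
  ph <- fx_clean_phantom()  # amplitude 7 um
  cfg <- fast_deformable(metric = "masked_local_NCC", seed = 6)
  res <- register_bspline(ref$np, ph$scan$channels$NP, init = NULL,
                          cfg = cfg, mask = ref$mask)
  lre <- landmark_registration_error(ph$canonical_landmarks, ph$landmarks,
                                     res$transform)
  expect_lt(lre$mean, 2.0)
  # deformable must beat (or match) the unregistered state
  lre0 <- landmark_registration_error(ph$canonical_landmarks, ph$landmarks)
  expect_lt(lre$mean, lre0$mean)
})

test_that("masked metric ignores bright artifacts outside the mask", {
  ref <- fx_reference()
  ph <- generate_phantom(71, deform_amplitude = 6)
  np <- ph$scan$channels$NP
  # inject a bright block artifact in the background
  bad <- np$data
  bad[5:25, 60:90, 3:9] <- 230
  np_bad <- volumetric_image(bad, np$spacing, np$origin, "NP")
  cfg <- fast_deformable(metric = "masked_local_NCC", seed = 7)
  res_clean <- register_bspline(ref$np, np, init = NULL, cfg = cfg,
                                mask = ref$mask)
  res_bad <- register_bspline(ref$np, np_bad, init = NULL, cfg = cfg,
                              mask = ref$mask)
  l_clean <- landmark_registration_error(ph$canonical_landmarks,
                                         ph$landmarks,
                                         res_clean$transform)$mean
  l_bad <- landmark_registration_error(ph$canonical_landmarks,
                                       ph$landmarks,
                                       res_bad$transform)$mean
  expect_lt(abs(l_bad - l_clean), 2.5)
  expect_lt(l_bad, 2.5)
})

test_that("recovered deformations do not fold (positive Jacobian)", {
  ref <- fx_reference()
  ph <- generate_phantom(72, deform_amplitude = 9)
  cfg <- fast_deformable(metric = "masked_local_NCC", seed = 8)
  res <- register_bspline(ref$np, ph$scan$channels$NP, init = NULL,
                          cfg = cfg, mask = ref$mask)
  fd <- to_displacement_field(res$stack, image_geometry(ref$np))
  jd <- jacobian_determinant(fd)
  inside <- ref$mask$data != 0
  expect_gte(mean(jd[inside] > 0), 0.999)
})

test_that("multi-metric with zero landmark weight equals plain registration", {
  ref <- fx_reference()
  ph <- generate_phantom(73, deform_amplitude = 5)
  cfg <- fast_deformable(metric = "masked_local_NCC", seed = 9,
                         levels = 2L, iterations_per_level = 60L)
  al <- qa_anchor_labels()$vnc
  guide <- landmark_set(al, lm_coords(ph$landmarks)[
    match(al, ph$landmarks$label), , drop = FALSE], "subject")
  tpl_pts <- landmark_set(al, lm_coords(ph$canonical_landmarks)[
    match(al, ph$canonical_landmarks$label), , drop = FALSE], "template")
  mm0 <- suppressWarnings(multimetric_config(tpl_pts, guide,
                                             relative_weight = 0))
  r_plain <- register_bspline(ref$np, ph$scan$channels$NP, init = NULL,
                              cfg = cfg, mask = ref$mask)
  r_mm <- register_multimetric(ref$np, ph$scan$channels$NP, init = NULL,
                               cfg = cfg, mm = mm0, mask = ref$mask)
  p <- grid_points(list(dim = c(7L, 5L, 3L), spacing = c(10, 11, 22),
                        origin = c(0, 0, 0)))
  expect_equal(apply_transform(r_mm$stack, p),
               apply_transform(r_plain$stack, p), tolerance = 1e-10)
})

test_that("guide landmarks land on their targets at high relative weight", {
  ref <- fx_reference()
  ph <- generate_phantom(74, deform_amplitude = 6,
                         corruption = "vnc_shift")
  sim <- simulate_registration(ph)   # failed automatic result
  al <- qa_anchor_labels()$vnc
  guide <- landmark_set(al, lm_coords(ph$landmarks)[
    match(al, ph$landmarks$label), , drop = FALSE], "subject")
  tpl_pts <- landmark_set(al, lm_coords(ph$canonical_landmarks)[
    match(al, ph$canonical_landmarks$label), , drop = FALSE], "template")
  mm <- multimetric_config(tpl_pts, guide, relative_weight = 4)
  cfg <- fast_deformable(metric = "masked_local_NCC", seed = 10)
  res <- register_multimetric(ref$np, ph$scan$channels$NP,
                              init = sim$transform, cfg = cfg, mm = mm,
                              mask = ref$mask)
  expect_lt(res$guide_residual_um, 2)
  # label mismatch is rejected
  bad <- landmark_set(c("left A8 nerve entry", "wrong label"),
                      lm_coords(guide), "subject")
  expect_error(multimetric_config(tpl_pts, bad), "labels must match")
})

test_that("deformable improves on the global initialization", {
  ref <- fx_reference()
  ph <- generate_phantom(75, deform_amplitude = 8)
  mis <- similarity_transform(scale = 1.03, angles = c(0, 0, 0.1),
                              translation = c(2, 1, 0),
                              center = c(32, 24, 23))
  subj <- resample(ph$scan$channels$NP, mis, image_geometry(ref$np))
  init <- register_linear(ref$np, subj, kind = "similarity", levels = 2,
                          iterations = 150, seed = 11)$transform
  cfg <- fast_deformable(metric = "masked_local_NCC", seed = 11)
  res <- register_bspline(ref$np, subj, init = init, cfg = cfg,
                          mask = ref$mask)
  ncc_global <- larvreg:::final_masked_ncc(
    ref$np, resample(subj, init, image_geometry(ref$np)),
    identity_transform(), ref$mask)
  expect_gte(res$metric$value, ncc_global - 1e-3)
})
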