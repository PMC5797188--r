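# Staged linear alignment.

test_that("register_linear: identical images give a near-identity", {
  np <- fx_reference()$np
  r <- register_linear(np, np, kind = "similarity", levels = 2,
                       iterations = 120, seed = 1)
  expect_lt(max(abs(r$transform$matrix - diag(3))), 1e-2)
  tr_mag <- sqrt(sum(apply_transform(r$transform, c(32, 24, 23)) -
                       c(32, 24, 23))^2)
  expect_lt(tr_mag, 0.5)
  expect_gt(r$metric$value, 0.99)
})

test_that("register_linear recovers a known similarity misalignment", {
  ref <- fx_reference()
  ph <- generate_phantom(61, deform_amplitude = 0)
  mis <- similarity_transform(scale = 1.1, angles = c(0, 0, 10 * pi / 180),
                              translation = c(2, -1, 1),
                              center = c(32, 24, 23))
  subj <- resample(ph$scan$channels$NP, mis, image_geometry(ref$np))
  r <- register_linear(ref$np, subj, kind = "similarity", seed = 2,
                       levels = 3, iterations = 250)
  # estimated transform approximates mis^{-1}
  M <- r$transform$matrix
  s <- det(M)^(1 / 3)
  expect_lt(abs(s - 1 / 1.1) / (1 / 1.1), 0.02)      # scale within 2%
  ang <- atan2(M[2, 1], M[1, 1]) * 180 / pi
  expect_lt(abs(ang - (-10)), 1)                     # rotation within 1 deg
  # similarity never introduces shear: polar factor orthonormal
  R <- M / s
  expect_lt(max(abs(t(R) %*% R - diag(3))), 1e-6)
})

test_that("SDT registration recovers a 60 degree rotation where intensity fails", {
  ref <- fx_reference()
  ph <- generate_phantom(62, deform_amplitude = 0)
  rot <- similarity_transform(angles = c(0, 0, 60 * pi / 180),
                              center = c(32, 24, 23))
  subj <- resample(ph$scan$channels$NP, rot, image_geometry(ref$np))
  m_f <- threshold_brain_mask(ref$np)
  m_m <- coarse_brain_mask(subj)
  sf <- signed_distance_transform(m_f)
  sm <- signed_distance_transform(m_m)
  r <- register_sdt(sf, sm, seed = 3, iterations = 200)
  ang <- atan2(r$transform$matrix[2, 1], r$transform$matrix[1, 1]) * 180 / pi
  expect_lt(abs(ang - (-60)), 2)
  # intensity-only registration gets stuck near identity on this case
  ri <- register_linear(ref$np, subj, kind = "similarity", metric = "NCC",
                        levels = 3, iterations = 200, seed = 3)
  angi <- atan2(ri$transform$matrix[2, 1], ri$transform$matrix[1, 1]) *
    180 / pi
  expect_gt(abs(angi - (-60)), 10)
  # SDT registration of identical masks is the identity
  r0 <- register_sdt(sf, sf, seed = 4, levels = 2, iterations = 120)
  expect_lt(max(abs(r0$transform$matrix - diag(3))), 0.02)
})

test_that("select_global_path implements the fallback rule exactly", {
  tf1 <- identity_transform()
  tf2 <- linear_transform("translation", translation = c(1, 0, 0))
  ran <- FALSE
  # sdt passes: intensity never run
  r <- select_global_path(list(transform = tf1, score = 0.6),
                          function() { ran <<- TRUE; stop("should not run") })
  expect_identical(r$selected_path, "sdt")
  expect_false(ran)
  expect_null(r$warning)
  # sdt fails, intensity passes
  r2 <- select_global_path(list(transform = tf1, score = 0.3),
                           function() list(transform = tf2, score = 0.5))
  expect_identical(r2$selected_path, "intensity")
  expect_null(r2$warning)
  # both fail: higher score wins + failure warning
  r3 <- select_global_path(list(transform = tf1, score = 0.3),
                           function() list(transform = tf2, score = 0.2))
  expect_identical(r3$selected_path, "sdt")
  expect_match(r3$warning, "failure")
  r4 <- select_global_path(list(transform = tf1, score = 0.1),
                           function() list(transform = tf2, score = 0.2))
  expect_identical(r4$selected_path, "intensity")
  expect_match(r4$warning, "failure")
  # boundary: exactly the threshold passes
  r5 <- select_global_path(list(transform = tf1, score = 0.4),
                           function() stop("should not run"))
  expect_identical(r5$selected_path, "sdt")
})

test_that("run_global_pipeline recovers a misaligned phantom and selects z flips", {
  tpl <- fx_template()
  geom <- image_geometry(tpl$np_template)
  ph <- generate_phantom(63, deform_amplitude = 0)
  mis <- similarity_transform(scale = 1.05, angles = c(0, 0, 20 * pi / 180),
                              translation = c(3, 2, 2),
                              center = c(32, 24, 23))
  subj <- resample(ph$scan$channels$NP, mis, geom)
  scan <- brain_scan("g1", list(NP = subj))
  g <- run_global_pipeline(tpl, scan, fast_global())
  expect_false(g$z_flipped)
  expect_null(g$warning)
  subj_lm <- apply_transform(invert_linear(mis),
                             lm_coords(ph$landmarks))
  lre <- landmark_registration_error(
    ph$canonical_landmarks,
    landmark_set(ph$landmarks$label, subj_lm, "g1"), g$transform)
  expect_lt(lre$mean, 4)  # all 30 landmarks within reach of the deformable stage
  expect_lt(lre$max, 8)

  # z-flipped subject: flip branch wins by final NCC
  zc <- larvreg:::geometric_center(geom)[3]
  flip <- linear_transform("affine", diag(c(1, 1, -1)), center = c(0, 0, zc))
  subz <- resample(ph$scan$channels$NP, flip, geom, interp = "nearest")
  gz <- run_global_pipeline(tpl, brain_scan("g2", list(NP = subz)),
                            fast_global())
  expect_true(gz$z_flipped)
  sc <- gz$stage_scores$z_flip_branch_scores
  expect_gt(sc[2], sc[1])
})

test_that("already-aligned scan yields a near-identity composite", {
  tpl <- fx_template()
  ph <- fx_clean_phantom()
  # amplitude-7 phantom is already grid-aligned up to its smooth warp
  g <- run_global_pipeline(tpl, ph$scan, fast_global())
  disp <- max_displacement(g$transform,
                           list(dim = c(9L, 7L, 5L),
                                spacing = c(8, 8, 12),
                                origin = c(0, 0, 0)))
  expect_lt(disp, 8)  # bounded by the smooth deformation scale
  # the linear stage cannot recover the 7 um warp, so the NP correlation
  # is moderate but must be far from failure level
  expect_gt(g$score, 0.3)
})
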