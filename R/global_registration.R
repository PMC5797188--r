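# Staged linear alignment: the six-stage subject-to-template framework and
# the simpler two-candidate affine alignment used during template
# generation.

# (M, v) form of a linear transform: q = M p + v
linear_Mv <- function(t) {
  list(M = t$matrix,
       v = as.numeric(-t$matrix %*% t$center) + t$center + t$translation)
}

#' Compose two linear transforms: `(a %o% b)(p) = a(b(p))`
#' @param a,b `linear_transform`s.
#' @export
linear_compose <- function(a, b) {
  A <- linear_Mv(a); B <- linear_Mv(b)
  M <- A$M %*% B$M
  v <- as.numeric(A$M %*% B$v) + A$v
  kind <- if (a$kind == "translation" && b$kind == "translation")
    "translation"
  else if (a$kind != "affine" && b$kind != "affine" &&
           all(abs(M - diag(3)) < 1e-12)) "translation"
  else {
    s <- det(M)
    if (s > 0 && max(abs(t(M / s^(1 / 3)) %*% (M / s^(1 / 3)) - diag(3))) < 1e-6)
      "similarity" else "affine"
  }
  linear_transform(kind, M, translation = v, center = c(0, 0, 0))
}

# smoothing sigmas (voxels per axis) for a resolution level l of L
pyramid_sigma <- function(spacing, level, levels) {
  f <- 2^(levels - level)
  s_in <- f / 2
  c(s_in, s_in, s_in * spacing[1] / spacing[3])
}

smoothed_data <- function(img, sigma) {
  if (all(sigma < 1e-6)) img$data
  else cpp_smooth_gauss(img$data, sigma)
}

# delta transform families used by the linear optimizer
delta_transform <- function(kind, par, center) {
  if (kind == "similarity") {
    similarity_transform(scale = exp(par[5]), angles = c(0, 0, par[4]),
                         translation = par[1:3], center = center)
  } else if (kind == "affine") {
    linear_transform("affine", diag(3) + matrix(par[1:9], 3, 3),
                     translation = par[10:12], center = center)
  } else {
    linear_transform("translation", diag(3), translation = par[1:3],
                     center = center)
  }
}

delta_npar <- c(similarity = 5L, affine = 12L, translation = 3L)
delta_parscale <- function(kind) {
  switch(kind,
         similarity = c(2, 2, 2, 0.05, 0.05),
         affine = c(rep(0.05, 9), 2, 2, 2),
         translation = c(2, 2, 2))
}

#' Multi-resolution linear registration
#'
#' Estimates the linear transform mapping fixed-image points into the
#' moving image by maximizing an intensity similarity over a fixed, seeded
#' voxel subsample per resolution level, using a deterministic Nelder-Mead
#' search over the transform parameters.  Rotation is parameterized
#' in-plane only (large out-of-plane rotations do not occur in this
#' imaging setup).
#'
#' @param fixed,moving `volumetric_image`s.
#' @param kind `"similarity"` (uniform scale, no shear) or `"affine"`.
#' @param metric `"NCC"` or `"MMI"`.
#' @param init optional initial `linear_transform` (the optimum is
#'   composed with it).
#' @param levels resolution levels (Gaussian smoothing pyramid).
#' @param iterations Nelder-Mead iterations per level.
#' @param n_samples voxel samples used for the metric per level.
#' @param seed RNG seed for the (deterministic) subsample.
#' @param fixed_mask optional binary image restricting the samples.
#' @param angle_sweep optional radians vector: at the coarsest level the
#'   in-plane rotation is initialized from the best of these candidate
#'   angles (multi-start, for rotation-robust feature registration).
#' @return list with `transform` (a `linear_transform`) and `metric`
#'   (a `metric_value` of the final level).
#' @export
register_linear <- function(fixed, moving,
                            kind = c("similarity", "affine", "translation"),
                            metric = c("NCC", "MMI"), init = NULL,
                            levels = 3L, iterations = 250L,
                            n_samples = 2500L, seed = 0L,
                            fixed_mask = NULL, angle_sweep = NULL) {
  kind <- match.arg(kind)
  metric <- match.arg(metric)
  if (is.null(init)) init <- identity_transform()
  center <- geometric_center(fixed)
  cand_idx <- if (is.null(fixed_mask)) seq_along(fixed$data) else
    which(fixed_mask$data != 0)
  if (length(cand_idx) < 16L) stop("too few candidate sample voxels")
  all_pts <- grid_points(fixed)

  np <- delta_npar[[kind]]
  level_best <- rep(NA_real_, levels)
  worse_streak <- 0L

  for (lev in seq_len(levels)) {
    sig <- pyramid_sigma(fixed$spacing, lev, levels)
    fdat <- smoothed_data(fixed, sig)
    mdat <- smoothed_data(moving, sig)

    seed_state <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    set.seed(seed * 1009L + lev)
    idx <- if (length(cand_idx) > n_samples)
      sort(sample(cand_idx, n_samples)) else cand_idx
    if (!is.null(seed_state)) assign(".Random.seed", seed_state, globalenv())

    pts <- all_pts[idx, , drop = FALSE]
    fvals <- as.numeric(fdat[idx])

    objective <- function(par) {
      tr <- linear_compose(init, delta_transform(kind, par, center))
      vox <- phys_to_voxel(moving, apply_transform(tr, pts))
      mvals <- cpp_interp(mdat, vox, 1L, 0)
      if (stats::sd(mvals) == 0 || stats::sd(fvals) == 0) return(0)
      if (metric == "NCC") -stats::cor(fvals, mvals)
      else -mattes_mi(fvals, mvals)
    }

    par0 <- rep(0, np)
    if (!is.null(angle_sweep) && lev == 1L && kind == "similarity") {
      vals <- vapply(angle_sweep, function(a) {
        p <- par0; p[4] <- a; objective(p)
      }, 0)
      par0[4] <- angle_sweep[which.min(vals)]
    }
    opt <- stats::optim(par0, objective, method = "Nelder-Mead",
                        control = list(maxit = iterations,
                                       parscale = delta_parscale(kind)))
    level_best[lev] <- -opt$value
    if (lev > 1L && level_best[lev] < level_best[lev - 1L] - 1e-6) {
      worse_streak <- worse_streak + 1L
      if (worse_streak >= 3L)
        stop("optimizer divergence: metric worsened over 3 consecutive levels")
    } else worse_streak <- 0L
    init <- linear_compose(init, delta_transform(kind, opt$par, center))
  }
  list(transform = init,
       metric = metric_value(metric, level_best[levels],
                             n_samples = min(length(cand_idx), n_samples),
                             domain = if (is.null(fixed_mask)) "full"
                                      else "masked"))
}

#' Rotation-robust similarity registration of signed-distance images
#'
#' Registers two signed-distance-transform images with a similarity
#' transform and the Mattes MI metric, multi-starting the in-plane
#' rotation over +/- 90 degrees so large X-Y rotations are recovered where
#' plain intensity registration gets stuck.
#' @param fixed_sdt,moving_sdt SDT `volumetric_image`s (see
#'   [signed_distance_transform()]).
#' @param init optional initial transform.
#' @param seed,levels,iterations as in [register_linear()].
#' @export
register_sdt <- function(fixed_sdt, moving_sdt, init = NULL, seed = 0L,
                         levels = 3L, iterations = 250L) {
  register_linear(fixed_sdt, moving_sdt, kind = "similarity",
                  metric = "MMI", init = init, levels = levels,
                  iterations = iterations, seed = seed,
                  angle_sweep = seq(-pi / 2, pi / 2, by = pi / 12))
}

#' Candidate-path selection rule for the global stage
#'
#' Implements the fallback rule: if the SDT-feature registration scores at
#' least the acceptance threshold it is selected and the intensity path is
#' never run.  Otherwise the intensity registration is run; it is selected
#' if it reaches the threshold; otherwise the higher-scoring candidate is
#' kept and a registration failure warning is recorded.  Scores are NCC of
#' the NP channel under the candidate transform, so both candidates are
#' compared on one scale.
#'
#' @param sdt_result list with `transform` and `score`.
#' @param run_intensity zero-argument callback returning the same shape of
#'   list; only invoked when the SDT score is below the threshold.
#' @param threshold acceptance threshold (default 0.4).
#' @return list with `transform`, `stage_scores`, `selected_path`
#'   (`"sdt"` or `"intensity"`) and `warning` (`NULL` or a message).
#' @export
select_global_path <- function(sdt_result, run_intensity, threshold = 0.4) {
  scores <- list(sdt = sdt_result$score)
  if (sdt_result$score >= threshold) {
    return(list(transform = sdt_result$transform, stage_scores = scores,
                selected_path = "sdt", warning = NULL))
  }
  int_result <- run_intensity()
  scores$intensity <- int_result$score
  if (int_result$score >= threshold) {
    return(list(transform = int_result$transform, stage_scores = scores,
                selected_path = "intensity", warning = NULL))
  }
  if (sdt_result$score >= int_result$score) {
    list(transform = sdt_result$transform, stage_scores = scores,
         selected_path = "sdt",
         warning = "registration failure warning: no method passed the similarity threshold")
  } else {
    list(transform = int_result$transform, stage_scores = scores,
         selected_path = "intensity",
         warning = "registration failure warning: no method passed the similarity threshold")
  }
}

# NCC of the NP channel under a candidate transform, evaluated on the full
# masked template domain (the commensurable score used for candidate
# selection).
np_score <- function(template_np, template_mask, moving_np, transform) {
  warped <- resample(moving_np, transform, image_geometry(template_np))
  idx <- which(template_mask$data != 0)
  f <- as.numeric(template_np$data[idx])
  m <- as.numeric(warped$data[idx])
  if (stats::sd(m) == 0) return(0)
  as.numeric(stats::cor(f, m))
}

#' Six-stage global alignment of a scan to the template
#'
#' Stages: (1) dorsal-ventral alignment by translation to the template
#' center with conditional y flip; (2) two z-flip candidate branches, both
#' carried through the remaining linear stages and selected by the final
#' NP similarity; (3) SDT feature registration (rescale, coarse mask,
#' signed distance transform, similarity + MMI); (4) fallback rule against
#' the 0.4 NP-NCC threshold with an intensity-based similarity
#' registration as alternative path; (5) NP similarity refinement with
#' NCC; (6) composition of the final global transform.
#'
#' @param template a `template_package`.
#' @param scan a `brain_scan` (NP channel required).
#' @param cfg global-stage configuration, see [larvreg_config()].
#' @return list with `transform` (a `composite_transform` mapping template
#'   points into the input scan), `stage_scores`, `selected_path`,
#'   `z_flipped`, `warning`, `score` (final NP NCC).
#' @export
run_global_pipeline <- function(template, scan, cfg = larvreg_config()$global) {
  np <- scan$channels$NP
  if (sum(np$data) <= 0 || stats::sd(np$data) == 0)
    stop("no neuropil signal: NP channel carries no intensity structure")
  tnp <- template$np_template
  tmask <- template$brain_mask
  tgeom <- image_geometry(tnp)
  sdt_fixed <- signed_distance_transform(tmask)

  st1 <- orient_dorsal_ventral(np, tgeom)
  candidates <- z_flip_candidates(st1$image)

  run_branch <- function(cand, branch_seed) {
    img <- cand$image
    mask_c <- coarse_brain_mask(img, cfg$opening_radius_um)
    sdt_mov <- signed_distance_transform(mask_c)
    sdtr <- register_sdt(sdt_fixed, sdt_mov, seed = branch_seed,
                         levels = cfg$levels, iterations = cfg$iterations)
    sdt_score <- np_score(tnp, tmask, img, sdtr$transform)
    sel <- select_global_path(
      list(transform = sdtr$transform, score = sdt_score),
      run_intensity = function() {
        r <- register_linear(tnp, img, kind = "similarity", metric = "NCC",
                             levels = cfg$levels,
                             iterations = cfg$iterations,
                             n_samples = cfg$n_samples,
                             seed = branch_seed + 1L, fixed_mask = tmask)
        list(transform = r$transform,
             score = np_score(tnp, tmask, img, r$transform))
      },
      threshold = cfg$similarity_threshold)
    ref <- register_linear(tnp, img, kind = "similarity", metric = "NCC",
                           init = sel$transform, levels = cfg$levels,
                           iterations = cfg$iterations,
                           n_samples = cfg$n_samples,
                           seed = branch_seed + 2L, fixed_mask = tmask)
    final_score <- np_score(tnp, tmask, img, ref$transform)
    # monotone guard: keep the pre-refinement transform if refinement hurt
    if (final_score < sel$stage_scores[[sel$selected_path]] - 1e-6) {
      ref$transform <- sel$transform
      final_score <- sel$stage_scores[[sel$selected_path]]
    }
    list(transform = ref$transform, sel = sel, score = final_score)
  }

  branches <- lapply(seq_along(candidates), function(i)
    run_branch(candidates[[i]], cfg$seed + 10L * i))
  best <- which.max(vapply(branches, `[[`, 0, "score"))
  br <- branches[[best]]

  total <- composite_transform(list(st1$transform,
                                    candidates[[best]]$transform,
                                    br$transform))
  list(transform = total,
       stage_scores = c(list(dorsal_ventral = NA_real_,
                             z_flip_branch_scores =
                               vapply(branches, `[[`, 0, "score")),
                        br$sel$stage_scores,
                        list(final = br$score)),
       selected_path = br$sel$selected_path,
       z_flipped = best == 2L,
       warning = br$sel$warning,
       score = br$score)
}

#' Two-candidate affine alignment used during template generation
#'
#' The pairwise template-generation pipeline's linear part: the moving
#' image (already histogram-matched) is registered twice with an affine
#' transform and NCC -- once as-is and once initialized with a z flip --
#' and the candidate with the better final similarity is selected.
#' @param fixed,moving `volumetric_image`s.
#' @param cfg global-stage configuration.
#' @return list with `transform`, `score`, `z_flipped`.
#' @export
register_template_linear <- function(fixed, moving,
                                     cfg = larvreg_config()$global) {
  fmask <- threshold_brain_mask(fixed)
  candidates <- z_flip_candidates(moving)
  res <- lapply(seq_along(candidates), function(i) {
    cand <- candidates[[i]]
    r <- register_linear(fixed, cand$image, kind = "affine", metric = "NCC",
                         levels = cfg$levels, iterations = cfg$iterations,
                         n_samples = cfg$n_samples,
                         seed = cfg$seed + i, fixed_mask = fmask)
    score <- np_score(fixed, fmask, cand$image, r$transform)
    list(transform = composite_transform(list(cand$transform, r$transform)),
         score = score)
  })
  best <- which.max(vapply(res, `[[`, 0, "score"))
  list(transform = res[[best]]$transform, score = res[[best]]$score,
       z_flipped = best == 2L)
}
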