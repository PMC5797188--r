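# Masked B-spline registration: subject-to-template and pairwise
# template-generation modes, plus the landmark-guided multi-metric mode
# used for semi-automatic correction.

#' Deformable registration configuration
#'
#' @param grid_spacing finest B-spline control grid spacing, micron
#'   (default 12).
#' @param levels resolution levels (default 5); the control-grid spacing
#'   follows the pyramid `grid_spacing * c(8, 4, 2, 1, 1)` (finest level
#'   value repeated), the image pyramid is a Gaussian smoothing pyramid.
#' @param metric `"global_random_NCC"` (random samples over the whole
#'   domain; template-generation mode) or `"masked_local_NCC"` (all
#'   samples from one random cubic subregion inside the mask per
#'   iteration; subject-to-template mode).
#' @param subregion_edge cubic subregion edge length, micron (default 20).
#' @param iterations_per_level stochastic-gradient iterations (default
#'   300).
#' @param samples_per_iteration intensity samples per iteration (default
#'   2048).
#' @param step0 initial step length of the decaying gradient step, micron
#'   (default 1).
#' @param step_A,step_alpha step-decay parameters
#'   `step_k = step0 * ((A+1)/(A+k))^alpha`.
#' @param seed RNG seed; recorded in the result for reproducibility.
#' @export
deformable_config <- function(grid_spacing = 12, levels = 5L,
                              metric = c("global_random_NCC",
                                         "masked_local_NCC"),
                              subregion_edge = 20,
                              iterations_per_level = 300L,
                              samples_per_iteration = 2048L,
                              step0 = 1.0, step_A = 20, step_alpha = 0.602,
                              seed = 1L) {
  metric <- match.arg(metric)
  structure(list(grid_spacing = grid_spacing, levels = as.integer(levels),
                 metric = metric, subregion_edge = subregion_edge,
                 iterations_per_level = as.integer(iterations_per_level),
                 samples_per_iteration = as.integer(samples_per_iteration),
                 step0 = step0, step_A = step_A, step_alpha = step_alpha,
                 seed = as.integer(seed)),
            class = "deformable_config")
}

check_deformable_config <- function(cfg, fixed) {
  if (cfg$grid_spacing <= max(fixed$spacing))
    stop("grid_spacing must exceed the largest voxel spacing")
  if (cfg$subregion_edge <= sqrt(sum(fixed$spacing^2)))
    stop("subregion_edge must exceed the voxel diagonal")
  invisible(cfg)
}

grid_spacing_pyramid <- function(cfg) {
  mult <- if (cfg$levels == 1L) 1 else c(2^((cfg$levels - 2):0), 1)
  cfg$grid_spacing * mult
}

#' Additive multi-level B-spline deformation
#'
#' The deformable optimizer's transform model: a stack of cubic B-spline
#' levels whose displacements add, the finest level on the configured
#' (default 12 micron) grid.  `p -> p + sum_l B_l(p)`.
#' @param levels list of `bspline_transform`s, coarse to fine.
#' @export
bspline_stack <- function(levels) {
  stopifnot(length(levels) >= 1L,
            all(vapply(levels, inherits, TRUE, "bspline_transform")))
  structure(list(levels = levels),
            class = c("bspline_stack", "spatial_transform"))
}

#' @export
apply_transform.bspline_stack <- function(t, p) {
  p <- rbind(p)
  disp <- matrix(0, nrow(p), 3)
  for (b in t$levels)
    disp <- disp + cpp_bspline_disp(b$coef, b$grid_origin, b$grid_spacing, p)
  p + disp
}

stack_disp_at <- function(levels, pts) {
  disp <- matrix(0, nrow(pts), 3)
  for (b in levels)
    disp <- disp + cpp_bspline_disp(b$coef, b$grid_origin, b$grid_spacing,
                                    pts)
  disp
}

# core stochastic-gradient multi-level B-spline engine.
# guide: NULL, or list(points = fixed-space K x 3, targets = K x 3 in
# moving_w space, relative_weight).
bspline_engine <- function(fixed, moving_w, cfg, mask = NULL,
                           guide = NULL) {
  geom <- image_geometry(fixed)
  gs_pyr <- grid_spacing_pyramid(cfg)
  all_pts <- grid_points(geom)
  pool <- if (!is.null(mask)) which(mask$data != 0) else
    seq_len(prod(geom$dim))
  if (length(pool) < 64L) stop("too few sample voxels in the domain/mask")
  mask_pts <- all_pts[pool, , drop = FALSE]
  half <- cfg$subregion_edge / 2
  n_s <- cfg$samples_per_iteration
  acc <- list()
  history <- list()

  for (lev in seq_len(cfg$levels)) {
    sig <- pyramid_sigma(fixed$spacing, lev, cfg$levels)
    fdat <- smoothed_data(fixed, sig)
    mdat <- smoothed_data(moving_w, sig)
    bs <- bspline_identity_for(geom, gs_pyr[lev])
    coef <- bs$coef
    set.seed(cfg$seed * 10007L + lev)
    hist_lev <- numeric(cfg$iterations_per_level)

    # landmark-term weight balanced against the NCC gradient at level start
    w_pt <- 0
    guide_targets_resid <- NULL
    if (!is.null(guide) && guide$relative_weight > 0) {
      base_lm <- stack_disp_at(acc, guide$points)
      guide_targets_resid <- guide$targets - base_lm
      idx0 <- pool[sample.int(length(pool), min(n_s, length(pool)))]
      pts0 <- all_pts[idx0, , drop = FALSE]
      r0 <- cpp_bspline_ncc_grad(as.numeric(fdat[idx0]), mdat,
                                 fixed$spacing, fixed$origin, pts0,
                                 stack_disp_at(acc, pts0), coef,
                                 bs$grid_origin, bs$grid_spacing)
      p0 <- cpp_point_term_grad(coef, bs$grid_origin, bs$grid_spacing,
                                guide$points, guide_targets_resid)
      gn <- max(abs(r0$grad)); gp <- max(abs(p0$grad))
      w_pt <- if (gp > 1e-12) guide$relative_weight * max(gn, 1e-4) / gp
              else 0
    }

    for (k in seq_len(cfg$iterations_per_level)) {
      if (cfg$metric == "masked_local_NCC") {
        sel <- integer(0)
        for (try in 1:10) {
          # during guided correction, half the subregions concentrate on
          # the landmark neighbourhoods being corrected
          if (!is.null(guide) && guide$relative_weight > 0 &&
              stats::runif(1) < 0.5) {
            gi <- sample.int(nrow(guide$points), 1L)
            ctr <- guide$points[gi, ] + stats::rnorm(3, 0, 5)
          } else {
            ctr <- mask_pts[sample.int(nrow(mask_pts), 1L), ]
          }
          inside <- abs(mask_pts[, 1] - ctr[1]) <= half &
            abs(mask_pts[, 2] - ctr[2]) <= half &
            abs(mask_pts[, 3] - ctr[3]) <= half
          sel <- pool[inside]
          if (length(sel) >= 32L) break
        }
        if (length(sel) < 32L)
          sel <- pool[sample.int(length(pool), min(n_s, length(pool)))]
        if (length(sel) > n_s) sel <- sel[sample.int(length(sel), n_s)]
      } else {
        sel <- pool[sample.int(length(pool), min(n_s, length(pool)))]
      }
      pts <- all_pts[sel, , drop = FALSE]
      fv <- as.numeric(fdat[sel])
      base <- stack_disp_at(acc, pts)
      r <- cpp_bspline_ncc_grad(fv, mdat, fixed$spacing, fixed$origin,
                                pts, base, coef, bs$grid_origin,
                                bs$grid_spacing)
      if (!is.finite(r$ncc))
        stop("NaN in deformable metric at level ", lev, ", iteration ", k,
             " (n valid samples = ", r$n, ")")
      g <- r$grad
      if (w_pt > 0) {
        p <- cpp_point_term_grad(coef, bs$grid_origin, bs$grid_spacing,
                                 guide$points, guide_targets_resid)
        g <- g - w_pt * p$grad
      }
      gmax <- max(abs(g))
      hist_lev[k] <- r$ncc
      if (gmax < 1e-12) next
      step <- cfg$step0 *
        ((cfg$step_A + 1) / (cfg$step_A + k))^cfg$step_alpha
      coef <- coef + (step / gmax) * g
    }
    acc <- c(acc, list(bspline_transform(coef, bs$grid_origin,
                                         bs$grid_spacing)))
    history[[lev]] <- hist_lev
  }
  list(stack = bspline_stack(acc), history = history)
}

final_masked_ncc <- function(fixed, moving_w, transform, mask = NULL) {
  warped <- resample(moving_w, transform, image_geometry(fixed))
  idx <- if (!is.null(mask)) which(mask$data != 0) else
    seq_along(fixed$data)
  f <- as.numeric(fixed$data[idx])
  m <- as.numeric(warped$data[idx])
  if (stats::sd(m) == 0 || stats::sd(f) == 0) return(0)
  as.numeric(stats::cor(f, m))
}

#' Multi-resolution B-spline deformable registration
#'
#' Estimates an additive multi-level cubic B-spline deformation (finest
#' level on the configured 12 micron grid) maximizing NCC with an
#' adaptive-decay stochastic gradient ascent.  The moving image is
#' pre-warped with `init` onto the fixed grid, and the returned transform
#' composes `init` with the estimated deformation (deformation applied
#' first), per the repo-wide fixed-to-moving resampling convention.
#'
#' @param fixed,moving `volumetric_image`s.
#' @param init initial transform (the global-stage result); `NULL` only
#'   when the images are already grid-aligned.
#' @param cfg a [deformable_config()].
#' @param mask binary `volumetric_image` on the fixed grid; required for
#'   the `masked_local_NCC` metric.
#' @return list with `transform` (composite of init and the B-spline
#'   stack, or the stack itself), `stack` (the `bspline_stack`), `metric`
#'   (final NCC as a `metric_value`), `history` (per-level NCC traces) and
#'   `seed`.
#' @export
register_bspline <- function(fixed, moving, init = NULL, cfg = deformable_config(),
                             mask = NULL) {
  check_deformable_config(cfg, fixed)
  if (cfg$metric == "masked_local_NCC" && is.null(mask))
    stop("mask is required for the masked_local_NCC metric")
  moving_w <- if (is.null(init)) {
    if (geometry_equal(fixed, moving)) moving
    else resample(moving, identity_transform(), image_geometry(fixed))
  } else resample(moving, init, image_geometry(fixed))
  eng <- bspline_engine(fixed, moving_w, cfg, mask = mask)
  total <- if (is.null(init)) eng$stack
           else composite_transform(list(init, eng$stack))
  val <- final_masked_ncc(fixed, moving_w, eng$stack, mask)
  list(transform = total, stack = eng$stack,
       metric = metric_value("NCC", val,
                             n_samples = cfg$samples_per_iteration,
                             domain = if (is.null(mask)) "full" else "masked"),
       history = eng$history, seed = cfg$seed)
}

#' Multi-metric configuration for landmark-guided registration
#'
#' @param template_points `landmark_set` in template (fixed) space; 2
#'   points for a VNC-terminal correction, 6 for a thoracic correction, 8
#'   for both.
#' @param subject_points `landmark_set` in the subject (original moving
#'   image) space; labels must match `template_points` one to one.
#' @param relative_weight balance of the two metric gradients: the
#'   landmark-distance gradient is rescaled at each level so its magnitude
#'   is `relative_weight` times the NCC gradient magnitude (default 1;
#'   0 reduces to plain [register_bspline()]).
#' @export
multimetric_config <- function(template_points, subject_points,
                               relative_weight = 1) {
  lt <- template_points$label
  ls <- subject_points$label
  if (!setequal(lt, ls) || length(lt) != length(ls))
    stop("landmark labels must match 1:1 between template and subject sets; ",
         "template has {", paste(lt, collapse = ", "), "}, subject {",
         paste(ls, collapse = ", "), "}")
  if (!length(lt) %in% c(2L, 6L, 8L))
    warning("expected 2 (VNC), 6 (thoracic) or 8 guide landmarks, got ",
            length(lt))
  list(template_points = template_points, subject_points = subject_points,
       relative_weight = relative_weight)
}

#' Landmark-guided multi-metric B-spline registration
#'
#' As [register_bspline()], but the cost adds a corresponding-point term:
#' the mean Euclidean distance between the transformed template guide
#' landmarks and their manually annotated subject positions.  Rather than
#' balancing the two metric values, the *gradients* are balanced: at each
#' level the point-term gradient is rescaled so the two gradient
#' magnitudes sit at the configured ratio, which keeps the optimization
#' smoothly guided by both landmark correspondence and image intensity.
#'
#' @param fixed,moving images.
#' @param init initial transform (typically the failed automatic result).
#' @param cfg a [deformable_config()].
#' @param mm a [multimetric_config()].
#' @param mask binary mask on the fixed grid.
#' @return as [register_bspline()], plus `guide_residual_um` (mean final
#'   distance of the guide landmarks).
#' @export
register_multimetric <- function(fixed, moving, init, cfg = deformable_config(),
                                 mm, mask = NULL) {
  check_deformable_config(cfg, fixed)
  moving_w <- if (is.null(init)) moving
              else resample(moving, init, image_geometry(fixed))
  tpl_pts <- landmark_coords(mm$template_points)
  ord <- match(mm$template_points$label, mm$subject_points$label)
  sub_pts <- landmark_coords(mm$subject_points)[ord, , drop = FALSE]
  # express subject targets in the pre-warped moving frame (= fixed grid)
  targets <- if (is.null(init)) sub_pts else {
    inv <- invert_displacement_field(
      to_displacement_field(init, image_geometry(fixed)))
    apply_transform(inv, sub_pts)
  }
  guide <- list(points = tpl_pts, targets = targets,
                relative_weight = mm$relative_weight)
  eng <- bspline_engine(fixed, moving_w, cfg, mask = mask, guide = guide)
  total <- if (is.null(init)) eng$stack
           else composite_transform(list(init, eng$stack))
  val <- final_masked_ncc(fixed, moving_w, eng$stack, mask)
  resid <- sqrt(rowSums((apply_transform(eng$stack, tpl_pts) - targets)^2))
  list(transform = total, stack = eng$stack,
       metric = metric_value("NCC", val,
                             n_samples = cfg$samples_per_iteration,
                             domain = if (is.null(mask)) "full" else "masked"),
       history = eng$history, seed = cfg$seed,
       guide_residual_um = mean(resid))
}
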