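# Seeded generator of synthetic larval-CNS-like scans with ground-truth
# transforms, landmarks and controlled failure modes.  The canonical
# anatomy is a fixed geometric model (two ellipsoidal brain lobes, a
# tapering ventral nerve cord with six thoracic protrusions and abdominal
# nerve-root bumps); every phantom is a smoothly deformed, noisy rendering
# of it, so all ground truth is known by construction.

.larvreg_cache <- new.env(parent = emptyenv())

phantom_default_shape <- c(128L, 96L, 24L)
phantom_default_spacing <- c(0.5, 0.5, 2.0)

# VNC radius taper (micron) as a function of the anterior-posterior
# coordinate y
vnc_radius <- function(y) 7.5 - 3.0 * pmin(pmax((y - 18) / 26, 0), 1)

canonical_landmark_table <- function() {
  r <- vnc_radius
  off_t <- function(y) r(y) + 1.5   # thoracic bump centers
  off_a <- function(y) r(y) + 1.2   # abdominal bump centers
  L <- rbind(
    "left antennal nerve"            = c(15, 6.5, 23),
    "right antennal nerve"           = c(49, 6.5, 23),
    "left tip of vertical lobe"      = c(18, 9, 31),
    "right tip of vertical lobe"     = c(46, 9, 31),
    "end of ventral nerve cord"      = c(32, 44, 23),
    "left thoracic nerve entry T1"   = c(32 - off_t(22), 22, 23),
    "right thoracic nerve entry T1"  = c(32 + off_t(22), 22, 23),
    "left thoracic nerve entry T2"   = c(32 - off_t(26), 26, 23),
    "right thoracic nerve entry T2"  = c(32 + off_t(26), 26, 23),
    "left thoracic nerve entry T3"   = c(32 - off_t(30), 30, 23),
    "right thoracic nerve entry T3"  = c(32 + off_t(30), 30, 23),
    "left upper peduncle"            = c(25, 12, 28),
    "right upper peduncle"           = c(39, 12, 28),
    "anterior upper commisure"       = c(32, 11.5, 26),
    "posterior upper commisure"      = c(32, 16, 26),
    "left anterior LON nerve"        = c(11, 13, 23),
    "right anterior LON nerve"       = c(53, 13, 23),
    "left MB vertical medial lobe connection"  = c(25, 17, 25),
    "right MB vertical medial lobe connection" = c(39, 17, 25),
    "center SEZ neuropil fusion"     = c(32, 19, 23),
    "left upper most anterior nerve entry"  = c(17, 4.5, 23),
    "right upper most anterior nerve entry" = c(47, 4.5, 23),
    "right basal brain neuropil border posterior" = c(43, 24, 19),
    "left basal brain neuropil border posterior"  = c(21, 24, 19),
    "left A8 nerve entry"            = c(32 - off_a(40), 40, 23),
    "right A8 nerve entry"           = c(32 + off_a(40), 40, 23),
    "right A7 nerve entry"           = c(32 + off_a(37), 37, 23),
    "left A7 nerve entry"            = c(32 - off_a(37), 37, 23),
    "left A6 nerve entry"            = c(32 - off_a(34), 34, 23),
    "right A6 nerve entry"           = c(32 + off_a(34), 34, 23))
  L[gold_standard_labels(), , drop = FALSE]
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
  })
  force(code)
}

#' Canonical CNS reference of the phantom world
#'
#' The undeformed, noise-free anatomy all phantoms are rendered from:
#' NP, NT and GE channels, the binary anatomy mask, and the 30
#' gold-standard-schema landmarks.  Deterministic (internal texture seed
#' is fixed) and memoized per geometry.
#'
#' @param shape voxel dimensions (default 128 x 96 x 24).
#' @param spacing voxel spacing, micron (default 0.5 x 0.5 x 2.0 -- the
#'   anisotropy of the real acquisitions at reduced in-plane scale).
#' @return list with `np`, `nt`, `ge`, `mask` (`volumetric_image`s) and
#'   `landmarks` (`landmark_set` in canonical space).
#' @export
canonical_reference <- function(shape = phantom_default_shape,
                                spacing = phantom_default_spacing) {
  key <- paste(c(shape, spacing), collapse = "_")
  if (!is.null(.larvreg_cache[[key]])) return(.larvreg_cache[[key]])
  geom <- list(dim = as.integer(shape), spacing = spacing,
               origin = c(0, 0, 0))
  pts <- grid_points(geom)
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]

  inside <- rep(FALSE, nrow(pts))
  # brain lobes (ellipsoids)
  for (cx in c(21, 43))
    inside <- inside |
      (((x - cx) / 13)^2 + ((y - 14) / 11)^2 + ((z - 23) / 12)^2 <= 1)
  # ventral nerve cord (tapering tube) with rounded terminal
  rv <- vnc_radius(y)
  inside <- inside |
    (y >= 18 & y <= 44 & (x - 32)^2 + (z - 23)^2 <= rv^2) |
    ((x - 32)^2 + (y - 44)^2 + (z - 23)^2 <= vnc_radius(44)^2)
  # dorsal vertical-lobe bulges (break the z symmetry of the anatomy)
  for (cx in c(18, 46))
    inside <- inside |
      (((x - cx) / 5)^2 + ((y - 9) / 4.5)^2 + ((z - 31) / 6)^2 <= 1)
  # thoracic protrusions and abdominal nerve-root bumps
  bump <- function(cx, cy, r) (x - cx)^2 + (y - cy)^2 + (z - 23)^2 <= r^2
  for (cy in c(22, 26, 30)) {
    o <- vnc_radius(cy) + 1.5
    inside <- inside | bump(32 - o, cy, 2.8) | bump(32 + o, cy, 2.8)
  }
  for (cy in c(34, 37, 40)) {
    o <- vnc_radius(cy) + 1.2
    inside <- inside | bump(32 - o, cy, 2.0) | bump(32 + o, cy, 2.0)
  }
  mask_arr <- array(as.numeric(inside), dim = geom$dim)
  mask <- volumetric_image(mask_arr, spacing, geom$origin, "mask")

  sdt <- signed_distance_transform(mask)$data
  body <- pmin(pmax(-as.numeric(sdt) / 1.2, 0), 1)  # ~1 um soft edge
  tex <- with_seed(7771L, {
    t0 <- cpp_smooth_gauss(array(stats::rnorm(prod(geom$dim)),
                                 dim = geom$dim),
                           c(3, 3, 1))
    t0 / stats::sd(as.numeric(t0))
  })
  np_arr <- 8 + 185 * body * (1 + 0.25 * pmin(pmax(as.numeric(tex), -2), 2))
  np_arr <- array(pmin(pmax(np_arr, 0), 255), dim = geom$dim)

  # nerve tracts: VNC midline, a loop in each lobe, one commissure
  ts <- seq(0, 1, length.out = 160)
  curve <- rbind(
    cbind(32, 18 + ts * 26.5, 23),                          # midline
    cbind(21 + 7 * cos(2 * pi * ts), 14 + 7 * sin(2 * pi * ts), 23),
    cbind(43 + 7 * cos(2 * pi * ts), 14 + 7 * sin(2 * pi * ts), 23),
    cbind(21 + ts * 22, 14, 23))                            # commissure
  cv <- round(phys_to_voxel(geom, curve))
  keep <- cv[, 1] >= 0 & cv[, 2] >= 0 & cv[, 3] >= 0 &
    cv[, 1] < geom$dim[1] & cv[, 2] < geom$dim[2] & cv[, 3] < geom$dim[3]
  cv <- cv[keep, , drop = FALSE]
  cmask <- array(0L, dim = geom$dim)
  cmask[cbind(cv[, 1] + 1L, cv[, 2] + 1L, cv[, 3] + 1L)] <- 1L
  dcurve <- cpp_edt(cmask, spacing)
  nt_arr <- array(pmin(8 + 200 * exp(-(as.numeric(dcurve) / 1.3)^2), 255),
                  dim = geom$dim)

  # gene expression: sparse blobs
  ge_arr <- rep(4, nrow(pts))
  blobs <- rbind(c(25, 12, 28), c(39, 12, 28), c(32, 19, 23),
                 c(32, 36, 23))
  for (b in seq_len(nrow(blobs))) {
    d2 <- (x - blobs[b, 1])^2 + (y - blobs[b, 2])^2 + (z - blobs[b, 3])^2
    ge_arr <- ge_arr + 180 * exp(-d2 / (2 * 3^2))
  }
  ge_arr <- array(pmin(ge_arr, 255), dim = geom$dim)

  lm <- canonical_landmark_table()
  ref <- list(np = volumetric_image(np_arr, spacing, geom$origin, "NP"),
              nt = volumetric_image(nt_arr, spacing, geom$origin, "NT"),
              ge = volumetric_image(ge_arr, spacing, geom$origin, "GE"),
              mask = mask,
              landmarks = landmark_set(rownames(lm), lm, "canonical"))
  .larvreg_cache[[key]] <- ref
  ref
}

# random smooth B-spline displacement scaled to a stated peak amplitude
random_smooth_field <- function(geom, amplitude, grid_spacing = 16) {
  bs <- bspline_identity_for(geom, grid_spacing)
  coef <- array(stats::rnorm(length(bs$coef)), dim = dim(bs$coef))
  bs2 <- bspline_transform(coef, bs$grid_origin, bs$grid_spacing)
  probe <- grid_points(list(dim = c(17L, 13L, 7L),
                            spacing = (geom$dim - 1) * geom$spacing /
                              c(16, 12, 6),
                            origin = geom$origin))
  disp <- apply_transform(bs2, probe) - probe
  peak <- max(sqrt(rowSums(disp^2)))
  if (peak <= 0) return(bs)
  bspline_transform(coef * amplitude / peak, bs$grid_origin,
                    bs$grid_spacing)
}

gaussian_window_disp <- function(pts, center, sigma, direction, amplitude) {
  d2 <- rowSums(sweep(pts, 2, center)^2)
  w <- amplitude * exp(-d2 / (2 * sigma^2))
  outer(w, direction)
}

phantom_noise <- function(arr, sd_read = 3, poisson_scale = 0.3) {
  v <- as.numeric(arr)
  noisy <- v + stats::rnorm(length(v), sd = sd_read) +
    stats::rnorm(length(v), sd = poisson_scale * sqrt(pmax(v, 0)))
  array(pmin(pmax(round(noisy), 0), 255), dim = dim(arr))
}

#' Generate a synthetic CNS phantom with ground truth
#'
#' Renders the canonical anatomy through a random smooth B-spline
#' deformation of stated peak amplitude (recorded exactly), adds imaging
#' noise (Gaussian read noise sd 3 gray levels plus an intensity-dependent
#' term), and optionally applies one corruption mode emulating the
#' registration failure categories seen in practice:
#'
#' * `vnc_shift` -- the ventral-nerve-cord terminal is additionally
#'   displaced by `corruption_amplitude` micron under a smooth local
#'   window (the signature of a VNC-terminal registration failure).  The
#'   shift is part of the recorded ground-truth transform, so the
#'   landmarks remain consistent.
#' * `thoracic_fold` -- a concentrated local warp near the thoracic
#'   nerves whose gradient exceeds 1 (negative-Jacobian fold), the
#'   distortion signature the strain indicator detects.
#' * `weak_staining` -- NP intensity attenuated in a region; no
#'   geometric corruption.
#' * `truncated` -- the last 20% of z slices are cropped.
#' * `no_np` -- NP channel zeroed (unregistrable scan).
#'
#' Same seed and parameters give a bit-identical phantom.
#'
#' @param seed integer seed.
#' @param shape,spacing grid geometry (defaults as
#'   [canonical_reference()]).
#' @param deform_amplitude peak smooth-deformation amplitude in micron; a
#'   length-2 range is drawn from uniformly.  Must not exceed half the
#'   smallest physical grid extent.
#' @param corruption one of `"none"`, `"vnc_shift"`, `"thoracic_fold"`,
#'   `"weak_staining"`, `"truncated"`, `"no_np"`.
#' @param corruption_amplitude micron (defaults: 15 for `vnc_shift`, 12
#'   for `thoracic_fold`).
#' @param background_streaks if `TRUE`, bright axis-aligned blocks are
#'   added to the background (acquisition-artifact stand-in for fusion
#'   experiments).
#' @return a `phantom_truth` list: `scan` (`brain_scan` with NP/NT/GE),
#'   `landmarks` (subject space), `canonical_landmarks`,
#'   `applied_transform` (a `displacement_field` mapping subject space to
#'   canonical space), `smooth_transform` (the corruption-free part),
#'   `seed`, `corruption`, `deform_amplitude`.
#' @export
generate_phantom <- function(seed, shape = phantom_default_shape,
                             spacing = phantom_default_spacing,
                             deform_amplitude = 7,
                             corruption = c("none", "vnc_shift",
                                            "thoracic_fold",
                                            "weak_staining", "truncated",
                                            "no_np"),
                             corruption_amplitude = NULL,
                             background_streaks = FALSE) {
  corruption <- match.arg(corruption)
  if (any(shape < c(64, 48, 16)))
    stop("phantom shape must be at least 64 x 48 x 16")
  ref <- canonical_reference(shape, spacing)
  geom <- image_geometry(ref$np)
  extent <- (geom$dim - 1) * geom$spacing
  if (is.null(corruption_amplitude))
    corruption_amplitude <- switch(corruption, vnc_shift = 12,
                                   thoracic_fold = 12, 0)
  with_seed(seed, {
    amp <- if (length(deform_amplitude) == 2L)
      stats::runif(1, deform_amplitude[1], deform_amplitude[2])
    else deform_amplitude
    if (amp > 0.5 * min(extent))
      stop("deform_amplitude ", amp, " exceeds half the grid extent")

    pts <- grid_points(geom)
    smooth_disp <- if (amp > 0) {
      bs <- random_smooth_field(geom, amp)
      apply_transform(bs, pts) - pts
    } else matrix(0, nrow(pts), 3)

    corr_disp <- matrix(0, nrow(pts), 3)
    corruption_info <- NULL
    if (corruption == "vnc_shift" && corruption_amplitude > 0) {
      ang <- stats::runif(1, 0, 2 * pi)
      dir <- c(cos(ang), sin(ang) * 0.4, 0)
      dir <- dir / sqrt(sum(dir^2))
      ctr <- c(32, 42, 23)
      # window sized so the offset is local to the terminal (decayed to
      # noise by the thoracic region) yet near-rigid over the tail (max
      # field gradient ~0.8)
      corruption_info <- list(center = ctr, sigma = 9, direction = dir,
                              amplitude = corruption_amplitude)
      corr_disp <- gaussian_window_disp(pts, ctr, 9, dir,
                                        corruption_amplitude)
    } else if (corruption == "thoracic_fold" && corruption_amplitude > 0) {
      side <- sample(c(-1, 1), 1)
      ctr <- c(32 + side * 5, 26, 23)
      corruption_info <- list(center = ctr, sigma = 5,
                              direction = c(-side, 0, 0),
                              amplitude = corruption_amplitude)
      corr_disp <- gaussian_window_disp(pts, ctr, 5, c(-side, 0, 0),
                                        corruption_amplitude)
    }

    smooth_tf <- displacement_field(array(smooth_disp,
                                          dim = c(geom$dim, 3)),
                                    geom$spacing, geom$origin)
    # invariant: outside the deliberate fold, the ground-truth deformation
    # must stay invertible; where the smooth and corruption gradients
    # stack up, the corruption is scaled back until the Jacobian is
    # safely positive
    if (corruption == "vnc_shift" && corruption_amplitude > 0) {
      for (try in 1:12) {
        total_tf <- displacement_field(
          array(smooth_disp + corr_disp, dim = c(geom$dim, 3)),
          geom$spacing, geom$origin)
        if (min(jacobian_determinant(total_tf)) > 0.1) break
        corr_disp <- corr_disp * 0.85
        corruption_info$amplitude <- corruption_info$amplitude * 0.85
      }
      corruption_amplitude <- corruption_info$amplitude
    }
    total_disp <- smooth_disp + corr_disp
    total_tf <- displacement_field(array(total_disp, dim = c(geom$dim, 3)),
                                   geom$spacing, geom$origin)

    warp <- function(img) resample(img, total_tf, geom)
    np_w <- warp(ref$np)$data
    if (corruption == "weak_staining") {
      d2 <- rowSums(sweep(pts, 2, c(32, 40, 23))^2)
      np_w <- np_w * (1 - 0.8 * exp(-d2 / (2 * 8^2)))
    }
    np_arr <- phantom_noise(array(np_w, dim = geom$dim))
    nt_arr <- phantom_noise(warp(ref$nt)$data, sd_read = 2)
    ge_arr <- phantom_noise(warp(ref$ge)$data, sd_read = 2)

    if (background_streaks) {
      bgmask <- warp(ref$mask)$data < 0.5
      for (s in 1:2) {
        x0 <- stats::runif(1, 0, extent[1] - 10)
        z0 <- stats::runif(1, 0, extent[3] - 8)
        block <- pts[, 1] >= x0 & pts[, 1] <= x0 + 10 &
          pts[, 3] >= z0 & pts[, 3] <= z0 + 8
        sel <- array(block, dim = geom$dim) & bgmask
        np_arr[sel] <- pmin(np_arr[sel] + 70, 255)
      }
    }
    if (corruption == "no_np") np_arr[] <- 0

    out_geom <- geom
    if (corruption == "truncated") {
      keep_z <- seq_len(ceiling(0.8 * geom$dim[3]))
      np_arr <- np_arr[, , keep_z, drop = FALSE]
      nt_arr <- nt_arr[, , keep_z, drop = FALSE]
      ge_arr <- ge_arr[, , keep_z, drop = FALSE]
      out_geom$dim <- dim(np_arr)
    }

    mk <- function(a, lab) volumetric_image(a, out_geom$spacing,
                                            out_geom$origin, lab)
    scan <- brain_scan(sprintf("phantom_%d_%s", seed, corruption),
                       list(NP = mk(np_arr, "NP"), NT = mk(nt_arr, "NT"),
                            GE = mk(ge_arr, "GE")))

    # subject landmark positions: invert x + u(x) = p by fixed point
    canon <- landmark_coords(ref$landmarks)
    xk <- canon
    for (it in 1:60) {
      vox <- phys_to_voxel(geom, xk)
      u <- vapply(1:3, function(d)
        cpp_interp(total_tf$vectors[, , , d], vox, 1L, 0),
        numeric(nrow(xk)))
      xnew <- canon - rbind(u)
      if (max(abs(xnew - xk)) < 1e-9) { xk <- xnew; break }
      xk <- xnew
    }
    subj_lm <- landmark_set(ref$landmarks$label, xk, scan$scan_id)

    structure(list(scan = scan, landmarks = subj_lm,
                   canonical_landmarks = ref$landmarks,
                   applied_transform = total_tf,
                   smooth_transform = smooth_tf, seed = seed,
                   corruption = corruption,
                   corruption_amplitude = corruption_amplitude,
                   corruption_info = corruption_info,
                   deform_amplitude = amp),
              class = "phantom_truth")
  })
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth seed %d> corruption %s, amplitude %.1f um\n",
              x$seed, x$corruption, x$deform_amplitude))
  invisible(x)
}

#' Generate a cohort of phantoms sharing the canonical space
#'
#' @param n cohort size.
#' @param seed base seed; member i uses `seed + i`.
#' @param deform_amplitude amplitude or range, micron (default the 5-10
#'   micron smooth-deformation regime).
#' @param corruption recycled over members.
#' @param ... forwarded to [generate_phantom()].
#' @return list of `phantom_truth`.
#' @export
phantom_cohort <- function(n, seed = 1L, deform_amplitude = c(5, 10),
                           corruption = "none", ...) {
  corruption <- rep_len(corruption, n)
  lapply(seq_len(n), function(i)
    generate_phantom(seed + i, deform_amplitude = deform_amplitude,
                     corruption = corruption[i], ...))
}

#' Simulate the outcome of automatic registration on a phantom
#'
#' Returns the registered NP image and deformation field a realistic
#' automatic registration would produce, without running the optimizer:
#' for clean (and intensity-only-corrupted) phantoms the exact
#' ground-truth transform; for `vnc_shift` the smooth component only (the
#' optimizer cannot follow the weakly stained, displaced terminal, which
#' is precisely the failure VI detects); for `thoracic_fold` the full
#' transform including the fold (a distorted registration, which TI
#' detects via strain).  Used to exercise the QA indicators cheaply and
#' deterministically.
#'
#' @param phantom a `phantom_truth`.
#' @return list with `registered_np`, `field` (a `displacement_field` on
#'   the canonical grid, mapping template space into the subject),
#'   `transform`.
#' @export
simulate_registration <- function(phantom) {
  # the recorded ground truth maps subject -> canonical; a registration
  # estimates the opposite direction (template -> subject), so the
  # simulated result starts from the inverted smooth field
  geom <- field_geometry(phantom$applied_transform)
  inv <- switch(phantom$corruption,
    vnc_shift = invert_displacement_field(phantom$smooth_transform),
    thoracic_fold = {
      # a distorted registration: the fold sits in the *computed*
      # transform itself (constructed directly in template space, since
      # the folded ground truth has no well-defined inverse)
      base <- invert_displacement_field(phantom$smooth_transform)
      ci <- phantom$corruption_info
      disp <- gaussian_window_disp(grid_points(geom), ci$center, ci$sigma,
                                   ci$direction, ci$amplitude)
      displacement_field(base$vectors + array(disp, c(geom$dim, 3)),
                         geom$spacing, geom$origin)
    },
    invert_displacement_field(phantom$applied_transform))
  reg <- resample(phantom$scan$channels$NP, inv, geom)
  list(registered_np = reg, field = inv, transform = inv)
}

#' Lightweight template package from the canonical phantom reference
#'
#' A testing fixture: the canonical NP image plays the template, the mask
#' comes from thresholding, anchors are the canonical anchor landmarks,
#' and the QA calibration is observed from `n_calib` clean phantoms
#' scored through [simulate_registration()].  This gives the QA module a
#' fully specified `template_package` without the cost of a cohort
#' build.
#'
#' @param n_calib clean calibration phantoms (default 8, a scaled-down analogue of the 20-scan calibration cohort).
#' @param seed base seed for the calibration phantoms.
#' @param shape,spacing phantom geometry.
#' @return a `template_package`.
#' @export
phantom_template <- function(n_calib = 8L, seed = 900L,
                             shape = phantom_default_shape,
                             spacing = phantom_default_spacing) {
  ref <- canonical_reference(shape, spacing)
  al <- unlist(qa_anchor_labels(), use.names = FALSE)
  canon <- landmark_coords(ref$landmarks)
  anchors <- landmark_set(al,
                          canon[match(al, ref$landmarks$label), ,
                                drop = FALSE], "template")
  calib <- phantom_cohort(n_calib, seed = seed)
  sims <- lapply(calib, simulate_registration)
  qa_cal <- calibrate_qa(ref$np, lapply(sims, `[[`, "registered_np"),
                         lapply(sims, `[[`, "field"), anchors)
  template_package(ref$np, threshold_brain_mask(ref$np), anchors, qa_cal,
                   fusion = "median", nt_template = ref$nt,
                   provenance = list(scan_ids = vapply(
                     calib, function(p) p$scan$scan_id, "")),
                   template_landmarks = ref$landmarks)
}
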