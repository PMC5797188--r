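# Intensity and geometry conditioning before registration.

#' Percentile-based histogram matching
#'
#' Monotone piecewise-linear intensity standardization: the moving image's
#' intensity distribution is matched to the fixed image's at a small set of
#' percentile match points (default 7, plus the range endpoints), so that
#' after mapping the moving percentiles at the match points equal the
#' fixed ones.
#'
#' @param moving,fixed `volumetric_image`s.
#' @param n_levels number of gray levels assumed (default 256; only used
#'   for rounding integer-valued inputs back to levels).
#' @param n_match_points number of interior percentile match points.
#' @return the intensity-mapped moving image.
#' @export
histogram_match <- function(moving, fixed, n_levels = 256L,
                            n_match_points = 7L) {
  mv <- as.numeric(moving$data)
  fx <- as.numeric(fixed$data)
  if (max(mv) == min(mv) || max(fx) == min(fx)) {
    warning("constant image in histogram_match; returning moving unchanged")
    return(moving)
  }
  probs <- c(0, seq(0.01, 0.99, length.out = n_match_points), 1)
  qm <- as.numeric(stats::quantile(mv, probs, names = FALSE))
  qf <- as.numeric(stats::quantile(fx, probs, names = FALSE))
  # enforce strictly increasing knots on the input side
  keep <- c(TRUE, diff(qm) > 1e-9)
  qm <- qm[keep]; qf <- qf[keep]
  qf <- cummax(qf)  # monotone output
  mapped <- stats::approx(qm, qf, xout = mv, rule = 2, ties = "ordered")$y
  integer_in <- all(moving$data == round(moving$data))
  if (integer_in)
    mapped <- pmin(pmax(round(mapped), 0), n_levels - 1)
  volumetric_image(array(mapped, dim = dim(moving$data)), moving$spacing,
                   moving$origin, moving$channel_label)
}

#' Robust intensity rescale to \[0, 1\]
#'
#' Clips to the `p_low`/`p_high` percentiles, then scales to \[0, 1\], so
#' that bright acquisition artifacts (e.g. tile-block artifacts in the
#' background) are saturated instead of compressing the intensity body.
#' @param img `volumetric_image`.
#' @param p_low,p_high clip percentiles (defaults 1 and 99.8).
#' @export
robust_rescale <- function(img, p_low = 1, p_high = 99.8) {
  v <- as.numeric(img$data)
  lo <- as.numeric(stats::quantile(v, p_low / 100))
  hi <- as.numeric(stats::quantile(v, p_high / 100))
  if (hi <= lo) {
    warning("constant image in robust_rescale; returning all zeros")
    out <- array(0, dim = dim(img$data))
  } else {
    out <- array(pmin(pmax((v - lo) / (hi - lo), 0), 1),
                 dim = dim(img$data))
  }
  volumetric_image(out, img$spacing, img$origin, img$channel_label)
}

#' Otsu threshold of a numeric vector
#' @param v numeric values.
#' @param n_bins histogram bins (default 256).
#' @return threshold value; foreground is `v > threshold`.
#' @export
otsu_threshold <- function(v, n_bins = 256L) {
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  h <- graphics::hist(v, breaks = seq(rng[1], rng[2],
                                      length.out = n_bins + 1L),
                      plot = FALSE)
  w <- h$counts / sum(h$counts)
  mids <- h$mids
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[length(mu)]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

mask_image <- function(bin, like) {
  volumetric_image(array(as.numeric(bin != 0), dim = dim(like$data)),
                   like$spacing, like$origin, "mask")
}

int_array <- function(x) {
  a <- array(as.integer(x != 0), dim = dim(x))
  a
}

# morphological erosion/dilation of a binary array via the anisotropic EDT
morph_erode <- function(bin, spacing, radius_um) {
  d_bg <- cpp_edt(int_array(bin == 0), spacing)   # distance to background
  array(as.numeric(bin != 0 & d_bg > radius_um), dim = dim(bin))
}

morph_dilate <- function(bin, spacing, radius_um) {
  d_fg <- cpp_edt(int_array(bin), spacing)
  array(as.numeric(d_fg <= radius_um), dim = dim(bin))
}

#' Morphological opening of a binary volume
#' @param bin binary 3D array.
#' @param spacing voxel spacing (micron).
#' @param radius_um ball radius in micron.
#' @export
morph_open <- function(bin, spacing, radius_um) {
  morph_dilate(morph_erode(bin, spacing, radius_um), spacing, radius_um)
}

#' Largest connected component of a binary volume (6-connectivity)
#' @param bin binary 3D array.
#' @export
largest_component <- function(bin) {
  lab <- cpp_label_cc(int_array(bin))
  if (max(lab) == 0L) return(array(0, dim = dim(bin)))
  counts <- tabulate(lab[lab > 0L])
  array(as.numeric(lab == which.max(counts)), dim = dim(bin))
}

halve_inplane <- function(img) {
  d <- dim(img$data)
  nx2 <- d[1] %/% 2L; ny2 <- d[2] %/% 2L
  a <- img$data[seq_len(2L * nx2), seq_len(2L * ny2), , drop = FALSE]
  # 2x2 in-plane block average
  a <- (a[seq(1, 2 * nx2, 2), , , drop = FALSE] +
        a[seq(2, 2 * nx2, 2), , , drop = FALSE]) / 2
  a <- (a[, seq(1, 2 * ny2, 2), , drop = FALSE] +
        a[, seq(2, 2 * ny2, 2), , drop = FALSE]) / 2
  volumetric_image(a, img$spacing * c(2, 2, 1),
                   img$origin + c(img$spacing[1] / 2, img$spacing[2] / 2, 0),
                   img$channel_label)
}

#' Coarse brain mask
#'
#' Rescales robustly, binarizes a half-resolution (in-plane) copy with an
#' Otsu threshold, removes small artifacts by morphological opening, keeps
#' the largest connected component only, and returns the mask at full
#' resolution.
#'
#' @param img `volumetric_image` (NP channel).
#' @param opening_radius_um opening ball radius, micron (default 2: removes fragments smaller than the 2-8 micron landmark-structure scale while keeping nerve-entry protrusions of that scale).
#' @return binary `volumetric_image` with `channel_label = "mask"`.
#' @export
coarse_brain_mask <- function(img, opening_radius_um = 2) {
  half <- halve_inplane(robust_rescale(img))
  thr <- otsu_threshold(as.numeric(half$data))
  bin <- half$data > thr
  if (!any(bin))
    stop("no neuropil signal: empty foreground after thresholding")
  opened <- morph_open(bin, half$spacing, opening_radius_um)
  if (!any(opened != 0))
    stop("no neuropil signal: foreground vanished after opening")
  comp <- largest_component(opened)
  half_mask <- mask_image(comp, half)
  full <- resample(half_mask, identity_transform(), image_geometry(img),
                   interp = "nearest")
  mask_image(full$data > 0.5, img)
}

#' Brain mask by simple intensity thresholding
#'
#' For images with a homogeneous background (e.g. a median-fused template)
#' a precise mask needs no morphology: threshold, keep the largest
#' component.
#' @param img `volumetric_image`.
#' @param threshold absolute intensity threshold, or `NULL` for Otsu.
#' @export
threshold_brain_mask <- function(img, threshold = NULL) {
  v <- as.numeric(img$data)
  if (is.null(threshold)) threshold <- otsu_threshold(v)
  bin <- img$data > threshold
  if (!any(bin)) stop("no neuropil signal: empty foreground")
  mask_image(largest_component(bin), img)
}

#' Signed Euclidean distance transform of a binary mask
#'
#' Anisotropy-aware distance in micron between voxel centers: negative
#' inside the mask (distance to the nearest background voxel center),
#' positive outside (distance to the nearest foreground voxel center).
#' This sign convention is fixed repo-wide.
#' @param mask binary `volumetric_image`.
#' @return float `volumetric_image`.
#' @export
signed_distance_transform <- function(mask) {
  bin <- int_array(mask$data)
  if (!any(bin == 1L)) stop("empty mask has no signed distance transform")
  inside <- bin == 1L
  if (all(inside))
    stop("mask covers the whole volume; signed distance undefined")
  d_out <- cpp_edt(bin, mask$spacing)
  d_in <- cpp_edt(int_array(bin == 0L), mask$spacing)
  sdt <- array(ifelse(inside, -d_in, d_out), dim = dim(mask$data))
  volumetric_image(sdt, mask$spacing, mask$origin, "other")
}

#' Center of mass of an image, physical coordinates
#' @param img `volumetric_image`.
#' @export
center_of_mass <- function(img) {
  w <- as.numeric(img$data)
  if (sum(w) <= 0) stop("cannot compute center of mass of a non-positive image")
  pts <- grid_points(img)
  colSums(pts * w) / sum(w)
}

geometric_center <- function(geom) {
  g <- as_geometry(geom)
  g$origin + (g$dim - 1) * g$spacing / 2
}

#' Dorsal-ventral alignment stage
#'
#' Translates the scan so its intensity center of mass lands on the
#' geometric center of the template grid, and flips the dorsal-ventral
#' (y) axis if the center of mass lies in the bottom half of the image.
#' Applying the operation twice is idempotent (the second call never
#' flips).
#'
#' @param img `volumetric_image` (NP channel).
#' @param template_geometry geometry of the template grid.
#' @return list with `image` (resampled onto the template grid) and
#'   `transform` (maps template-space points into the input image space).
#' @export
orient_dorsal_ventral <- function(img, template_geometry) {
  g <- as_geometry(template_geometry)
  com <- center_of_mass(img)
  ycen <- geometric_center(img)[2]
  flip <- com[2] > ycen + 1e-9
  M <- diag(c(1, if (flip) -1 else 1, 1))
  tc <- geometric_center(g)
  # T(p) = M (p - tc) + com : template center -> scan center of mass
  tr <- linear_transform("affine", M, translation = com - tc, center = tc)
  list(image = resample(img, tr, g, interp = "linear"), transform = tr,
       flipped = flip)
}

#' Candidate z-flip initializations
#'
#' Brain samples may be mounted anterior- or posterior-side up, flipping
#' the acquired stack along z.  Returns the image itself and its z-flipped
#' copy, each with the transform that produced it; both candidates are
#' meant to be registered and the better final similarity kept.  The flip
#' is about the physical center of the z-extent, which maps the voxel grid
#' onto itself exactly.
#' @param img `volumetric_image`.
#' @return list of two lists, each with `image` and `transform`.
#' @export
z_flip_candidates <- function(img) {
  zc <- geometric_center(img)[3]
  flipT <- linear_transform("affine", diag(c(1, 1, -1)),
                            center = c(0, 0, zc))
  flipped <- resample(img, flipT, image_geometry(img), interp = "nearest")
  list(list(image = img, transform = identity_transform()),
       list(image = flipped, transform = flipT))
}
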