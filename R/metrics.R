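# Similarity measures driving the registrations and the QA indicators.

#' Metric value record
#' @param name `"NCC"`, `"MMI"` or `"point_distance"`.
#' @param value metric value.
#' @param n_samples number of samples it was computed from.
#' @param domain `"full"`, `"masked"` or `"subregion"`.
#' @export
metric_value <- function(name = c("NCC", "MMI", "point_distance"), value,
                         n_samples, domain = c("full", "masked",
                                               "subregion")) {
  name <- match.arg(name)
  domain <- match.arg(domain)
  if (name == "NCC" && is.finite(value) &&
      (value < -1 - 1e-9 || value > 1 + 1e-9))
    stop("NCC value outside [-1, 1]")
  stopifnot(n_samples > 0)
  structure(list(name = name, value = value, n_samples = n_samples,
                 domain = domain), class = "metric_value")
}

#' Normalized cross correlation (Pearson) of two sample vectors
#'
#' Invariant under positive affine intensity rescaling of either argument.
#' Constant input yields 0 with a warning.
#' @param fixed_samples,moving_samples equal-length numeric vectors.
#' @export
ncc <- function(fixed_samples, moving_samples) {
  stopifnot(length(fixed_samples) == length(moving_samples),
            length(fixed_samples) >= 2L)
  sf <- stats::sd(fixed_samples)
  sm <- stats::sd(moving_samples)
  if (sf == 0 || sm == 0) {
    warning("constant input to ncc; returning 0")
    return(0)
  }
  as.numeric(stats::cor(fixed_samples, moving_samples))
}

# weighted accumulation of w into n bins at integer idx (1-based)
accum_bins <- function(idx, w, n) {
  r <- rowsum(w, idx)
  out <- numeric(n)
  out[as.integer(rownames(r))] <- r
  out
}

#' Mutual information from a Parzen-smoothed joint histogram
#'
#' Each sample deposits cubic-B-spline Parzen mass over 4 adjacent bins in
#' each marginal; MI is the plug-in estimate on the smoothed joint
#' histogram, in nats (>= 0 up to float rounding).  A constant channel
#' yields 0.
#' @param fixed_samples,moving_samples paired intensity samples.
#' @param n_bins histogram bins per channel (default 32, suited to 8-bit
#'   microscopy).
#' @export
mattes_mi <- function(fixed_samples, moving_samples, n_bins = 32L) {
  n <- length(fixed_samples)
  stopifnot(n == length(moving_samples), n >= n_bins)
  rf <- range(fixed_samples)
  rm_ <- range(moving_samples)
  if (diff(rf) == 0 || diff(rm_) == 0) return(0)

  # continuous bin coordinate in [0, n_bins-1]
  bin_setup <- function(v, r) {
    u <- (v - r[1]) / diff(r) * (n_bins - 1)
    base <- floor(u)
    t <- u - base
    t2 <- t * t; t3 <- t2 * t
    w <- cbind((1 - 3 * t + 3 * t2 - t3) / 6,
               (4 - 6 * t2 + 3 * t3) / 6,
               (1 + 3 * t + 3 * t2 - 3 * t3) / 6,
               t3 / 6)
    idx <- cbind(base - 1, base, base + 1, base + 2)
    # clamp support to the valid bin range, folding weight onto the edge
    idx[idx < 0] <- 0
    idx[idx > n_bins - 1] <- n_bins - 1
    list(idx = idx + 1L, w = w)
  }
  bf <- bin_setup(fixed_samples, rf)
  bm <- bin_setup(moving_samples, rm_)

  jh <- numeric(n_bins * n_bins)
  for (a in 1:4)
    for (b in 1:4) {
      idx <- bf$idx[, a] + n_bins * (bm$idx[, b] - 1L)
      jh <- jh + accum_bins(idx, bf$w[, a] * bm$w[, b], n_bins * n_bins)
    }
  jh <- jh / sum(jh)
  J <- matrix(jh, n_bins, n_bins)
  pf <- rowSums(J)
  pm <- colSums(J)
  nz <- J > 0
  outer_p <- outer(pf, pm)
  mi <- sum(J[nz] * log(J[nz] / outer_p[nz]))
  max(mi, 0)
}

#' Voxel linear indices whose centers lie inside a sphere
#' @param geom image or geometry list.
#' @param center physical center, micron.
#' @param radius micron.
#' @return integer vector of 1-based linear indices into the array.
#' @export
sphere_voxel_indices <- function(geom, center, radius) {
  g <- as_geometry(geom)
  ax <- ((seq_len(g$dim[1]) - 1) * g$spacing[1] + g$origin[1] - center[1])^2
  ay <- ((seq_len(g$dim[2]) - 1) * g$spacing[2] + g$origin[2] - center[2])^2
  az <- ((seq_len(g$dim[3]) - 1) * g$spacing[3] + g$origin[3] - center[3])^2
  d2 <- outer(outer(ax, ay, `+`), az, `+`)
  which(d2 <= radius^2)
}

#' Local NCC over a random cubic subregion
#'
#' NCC computed from the voxels of one random, isotropic cubic subregion
#' (edge length in micron) centered on a random mask voxel and restricted
#' to the mask -- the sampling strategy used by the masked deformable
#' metric, exposed for inspection.  Uses the R RNG; seed for
#' reproducibility.  If the subregion intersection with the mask is
#' degenerate a new subregion is drawn (at most `max_tries`), then the
#' whole mask is used as a fallback.
#' @param fixed,moving_warped images on a common grid.
#' @param mask binary `volumetric_image`.
#' @param subregion_edge cube edge length, micron (default 20).
#' @param max_tries redraw attempts (default 10).
#' @export
local_ncc <- function(fixed, moving_warped, mask, subregion_edge = 20,
                      max_tries = 10L) {
  stopifnot(geometry_equal(fixed, moving_warped),
            geometry_equal(fixed, mask))
  midx <- which(mask$data != 0)
  if (length(midx) == 0L) stop("empty mask in local_ncc")
  pts <- grid_points(fixed)
  half <- subregion_edge / 2
  for (try in seq_len(max_tries)) {
    c_idx <- midx[sample.int(length(midx), 1L)]
    ctr <- pts[c_idx, ]
    inside <- abs(pts[midx, 1] - ctr[1]) <= half &
      abs(pts[midx, 2] - ctr[2]) <= half &
      abs(pts[midx, 3] - ctr[3]) <= half
    sel <- midx[inside]
    if (length(sel) >= 8L &&
        stats::sd(fixed$data[sel]) > 0 &&
        stats::sd(moving_warped$data[sel]) > 0) {
      return(ncc(fixed$data[sel], moving_warped$data[sel]))
    }
  }
  ncc(fixed$data[midx], moving_warped$data[midx])
}

#' Regional mutual information within a sphere
#'
#' Mattes MI over the voxels whose physical center lies within `radius`
#' micron of `center`; symmetric in its image arguments.
#' @param fixed,moving_warped images on a common grid.
#' @param center physical point, micron.
#' @param radius micron.
#' @param n_bins histogram bins.
#' @export
regional_mi <- function(fixed, moving_warped, center, radius,
                        n_bins = 32L) {
  stopifnot(geometry_equal(fixed, moving_warped))
  idx <- sphere_voxel_indices(fixed, center, radius)
  if (length(idx) < 50L)
    stop("sphere of radius ", radius,
         " um holds fewer than 50 voxels on this grid")
  mattes_mi(as.numeric(fixed$data[idx]),
            as.numeric(moving_warped$data[idx]), n_bins)
}
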