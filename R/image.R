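#' Volumetric image
#'
#' The unit of all registration: a 3D scalar grid with physical geometry.
#' The array layout is fixed repo-wide: `data[i, j, k]` with `i` the fast
#' in-plane axis (x), `j` the slow in-plane axis (y) and `k` the slice
#' axis (z).  Voxel indices are 0-based in all coordinate computations and
#' the physical position (micron) of voxel `(i, j, k)` is
#' `origin + c(i, j, k) * spacing`, i.e. the origin sits at the center of
#' voxel `(0, 0, 0)`.
#'
#' @param data 3D numeric array of intensities.
#' @param spacing numeric length-3, voxel spacing in micron (all > 0).
#' @param origin numeric length-3, physical position of voxel (0,0,0) in
#'   micron.
#' @param channel_label one of `"NP"`, `"NT"`, `"GE"`, `"mask"`, `"other"`.
#' @return An object of class `volumetric_image`.
#' @export
volumetric_image <- function(data, spacing, origin = c(0, 0, 0),
                             channel_label = "other") {
  if (length(dim(data)) != 3L)
    stop("data must have exactly 3 axes, got ", length(dim(data)))
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite values (micron/voxel)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be 3 finite values (micron)")
  channel_label <- match.arg(channel_label,
                             c("NP", "NT", "GE", "mask", "other"))
  structure(list(data = data, spacing = spacing, origin = origin,
                 channel_label = channel_label),
            class = "volumetric_image")
}

#' @export
print.volumetric_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<volumetric_image %s> %d x %d x %d voxels, spacing (%g, %g, %g) um,\n",
    x$channel_label, d[1], d[2], d[3],
    x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (%g, %g, %g) um, extent (%g, %g, %g) um, range [%g, %g]\n",
              x$origin[1], x$origin[2], x$origin[3],
              d[1] * x$spacing[1], d[2] * x$spacing[2], d[3] * x$spacing[3],
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.volumetric_image <- function(x) dim(x$data)

is_volumetric_image <- function(x) inherits(x, "volumetric_image")

#' Grid geometry of an image
#'
#' The (dim, spacing, origin) triple used as a resampling reference.
#' @param img a `volumetric_image`.
#' @return list with `dim`, `spacing`, `origin`.
#' @export
image_geometry <- function(img) {
  list(dim = dim(img$data), spacing = img$spacing, origin = img$origin)
}

as_geometry <- function(x) {
  if (is_volumetric_image(x)) image_geometry(x)
  else if (is.list(x) && all(c("dim", "spacing", "origin") %in% names(x))) x
  else stop("not an image geometry")
}

geometry_equal <- function(a, b, tol = 1e-9) {
  a <- as_geometry(a); b <- as_geometry(b)
  all(a$dim == b$dim) && all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

#' Convert voxel indices to physical coordinates
#'
#' @param geom image or geometry list.
#' @param idx N x 3 matrix of 0-based (possibly fractional) voxel indices.
#' @return N x 3 matrix of physical coordinates (micron).
#' @export
voxel_to_phys <- function(geom, idx) {
  g <- as_geometry(geom)
  idx <- rbind(idx)
  sweep(sweep(idx, 2, g$spacing, `*`), 2, g$origin, `+`)
}

#' Convert physical coordinates to (fractional) voxel indices
#' @param geom image or geometry list.
#' @param pts N x 3 matrix of physical coordinates (micron).
#' @return N x 3 matrix of 0-based voxel indices.
#' @export
phys_to_voxel <- function(geom, pts) {
  g <- as_geometry(geom)
  pts <- rbind(pts)
  sweep(sweep(pts, 2, g$origin, `-`), 2, g$spacing, `/`)
}

#' All voxel centers of a grid as physical points
#'
#' Row order matches the linearisation of the image array (x fastest).
#' @param geom image or geometry list.
#' @return N x 3 matrix (micron), N = prod(dim).
#' @export
grid_points <- function(geom) {
  g <- as_geometry(geom)
  d <- g$dim
  ix <- (seq_len(d[1]) - 1) * g$spacing[1] + g$origin[1]
  iy <- (seq_len(d[2]) - 1) * g$spacing[2] + g$origin[2]
  iz <- (seq_len(d[3]) - 1) * g$spacing[3] + g$origin[3]
  cbind(rep(ix, times = d[2] * d[3]),
        rep(rep(iy, each = d[1]), times = d[3]),
        rep(iz, each = d[1] * d[2]))
}

#' Multi-channel brain scan
#'
#' @param scan_id character identifier.
#' @param channels named list of `volumetric_image` keyed by channel label;
#'   the NP (neuropil) channel is required, NT and GE are optional.  All
#'   channels must share shape, spacing and origin.
#' @return object of class `brain_scan`.
#' @export
brain_scan <- function(scan_id, channels) {
  stopifnot(is.character(scan_id), length(scan_id) == 1L)
  if (!"NP" %in% names(channels))
    stop("brain_scan '", scan_id, "' is missing the required NP channel")
  ref <- image_geometry(channels[["NP"]])
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (!is_volumetric_image(ch)) stop("channel ", nm, " is not a volumetric_image")
    if (!geometry_equal(ref, ch))
      stop("channel ", nm, " does not share the NP grid geometry")
  }
  structure(list(scan_id = scan_id, channels = channels), class = "brain_scan")
}

#' @export
print.brain_scan <- function(x, ...) {
  cat(sprintf("<brain_scan %s> channels: %s\n", x$scan_id,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Named 3D landmarks in physical coordinates
#'
#' @param labels character vector of unique landmark names.
#' @param coords N x 3 numeric matrix, micron.
#' @param frame_id name of the image space the points live in.
#' @return object of class `landmark_set`: a data.frame with columns
#'   `label`, `x`, `y`, `z` plus a `frame_id` attribute.
#' @export
landmark_set <- function(labels, coords, frame_id = "unknown") {
  labels <- as.character(labels)
  coords <- rbind(matrix(numeric(0), 0, 3), coords)
  if (length(labels) != nrow(coords))
    stop("labels and coords disagree in length")
  if (anyDuplicated(labels))
    stop("duplicate landmark labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  if (length(labels) && any(!is.finite(coords)))
    stop("landmark coordinates must be finite")
  df <- data.frame(label = labels,
                   x = as.numeric(coords[, 1]),
                   y = as.numeric(coords[, 2]),
                   z = as.numeric(coords[, 3]),
                   stringsAsFactors = FALSE)
  structure(df, frame_id = frame_id, class = c("landmark_set", "data.frame"))
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> %d points in frame '%s'\n", nrow(x),
              attr(x, "frame_id")))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}

landmark_coords <- function(set) {
  as.matrix(as.data.frame(set)[, c("x", "y", "z"), drop = FALSE])
}

#' The 30-landmark gold-standard labelling scheme
#'
#' Landmark names covering the entire larval CNS: paired brain-lobe
#' structures, the ventral nerve cord terminal, the six thoracic nerve
#' entry points (T1-T3, left/right) and the abdominal nerve entries.
#' @return character vector of 30 labels.
#' @export
gold_standard_labels <- function() {
  c("left antennal nerve", "right antennal nerve",
    "left tip of vertical lobe", "right tip of vertical lobe",
    "end of ventral nerve cord",
    "left thoracic nerve entry T1", "right thoracic nerve entry T1",
    "left thoracic nerve entry T2", "right thoracic nerve entry T2",
    "left thoracic nerve entry T3", "right thoracic nerve entry T3",
    "left upper peduncle", "right upper peduncle",
    "anterior upper commisure", "posterior upper commisure",
    "left anterior LON nerve", "right anterior LON nerve",
    "left MB vertical medial lobe connection",
    "right MB vertical medial lobe connection",
    "center SEZ neuropil fusion",
    "left upper most anterior nerve entry",
    "right upper most anterior nerve entry",
    "right basal brain neuropil border posterior",
    "left basal brain neuropil border posterior",
    "left A8 nerve entry", "right A8 nerve entry",
    "right A7 nerve entry", "left A7 nerve entry",
    "left A6 nerve entry", "right A6 nerve entry")
}

#' Labels of the 8 quality-assessment anchor landmarks
#'
#' Two ventral-nerve-cord terminal anchors (the posterior-most paired nerve
#' entries) and the six thoracic nerve entry points.
#' @return named list with elements `vnc` (2 labels) and `thoracic`
#'   (6 labels).
#' @export
qa_anchor_labels <- function() {
  list(vnc = c("left A8 nerve entry", "right A8 nerve entry"),
       thoracic = c("left thoracic nerve entry T1",
                    "right thoracic nerve entry T1",
                    "left thoracic nerve entry T2",
                    "right thoracic nerve entry T2",
                    "left thoracic nerve entry T3",
                    "right thoracic nerve entry T3"))
}

#' Registration quality report
#'
#' @param scan_id scan identifier.
#' @param vi VNC-terminal confidence, percent in \[0, 100\].
#' @param ti thoracic-nerve confidence, percent; must equal
#'   `m_score * s_score / 100` within floating tolerance.
#' @param m_score regional mutual-information score, percent.
#' @param s_score normalized-strain confidence score, percent.
#' @param threshold decision threshold, percent (default 50).
#' @return object of class `qa_report` with a `decision` field:
#'   `"flagged"` iff `min(vi, ti) < threshold`, else `"accepted"`.
#' @export
qa_report <- function(scan_id, vi, ti, m_score, s_score, threshold = 50) {
  stopifnot(is.finite(vi), is.finite(ti), vi >= 0, vi <= 100,
            ti >= 0, ti <= 100)
  if (abs(ti - m_score * s_score / 100) > 1e-6)
    stop("TI must equal M * S / 100 (got ", ti, " vs ",
         m_score * s_score / 100, ")")
  decision <- if (min(vi, ti) < threshold) "flagged" else "accepted"
  structure(list(scan_id = scan_id, vi = vi, ti = ti, m_score = m_score,
                 s_score = s_score, decision = decision,
                 threshold = threshold),
            class = "qa_report")
}

#' @export
print.qa_report <- function(x, ...) {
  cat(sprintf("<qa_report %s> VI = %.1f%%, TI = %.1f%% (M = %.1f, S = %.1f), %s at %.0f%%\n",
              x$scan_id, x$vi, x$ti, x$m_score, x$s_score, x$decision,
              x$threshold))
  invisible(x)
}
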