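# Spatial transforms.  Convention (fixed repo-wide): every transform maps
# fixed-image physical points (micron) into moving-image physical space, so
# warping the moving image onto the fixed grid is a single resample.

#' Linear transform
#'
#' Maps `p -> matrix %*% (p - center) + center + translation`.
#'
#' @param kind `"translation"`, `"similarity"` or `"affine"`.  A similarity
#'   matrix must be a uniform scaling of a rotation (`s * R`, det > 0);
#'   affine also permits shear and anisotropic scaling.
#' @param matrix 3 x 3 matrix.
#' @param translation length-3 vector, micron.
#' @param center rotation/scaling center, micron.
#' @export
linear_transform <- function(kind = c("affine", "similarity", "translation"),
                             matrix = diag(3), translation = c(0, 0, 0),
                             center = c(0, 0, 0)) {
  kind <- match.arg(kind)
  matrix <- base::matrix(as.numeric(matrix), 3, 3)
  translation <- as.numeric(translation)
  center <- as.numeric(center)
  if (kind == "translation" && any(abs(matrix - diag(3)) > 1e-12))
    stop("translation transform must have an identity matrix")
  if (kind == "similarity") {
    s <- det(matrix)^(1 / 3)
    if (!is.finite(s) || s <= 0) stop("similarity must have det > 0")
    R <- matrix / s
    if (max(abs(t(R) %*% R - diag(3))) > 1e-6)
      stop("similarity matrix must be uniform scale times a rotation")
  }
  structure(list(kind = kind, matrix = matrix, translation = translation,
                 center = center),
            class = c("linear_transform", "spatial_transform"))
}

#' Build a similarity transform from scale, Euler angles and translation
#'
#' Rotation is applied as `Rz(rz) %*% Ry(ry) %*% Rx(rx)`; angles in
#' radians.  In this imaging setup essentially only in-plane (`rz`)
#' rotations occur.
#' @param scale uniform scale factor.
#' @param angles length-3 `(rx, ry, rz)` radians.
#' @param translation,center micron.
#' @export
similarity_transform <- function(scale = 1, angles = c(0, 0, 0),
                                 translation = c(0, 0, 0),
                                 center = c(0, 0, 0)) {
  cx <- cos(angles[1]); sx <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cz <- cos(angles[3]); sz <- sin(angles[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  linear_transform("similarity", scale * (Rz %*% Ry %*% Rx), translation,
                   center)
}

#' Identity transform
#' @export
identity_transform <- function() linear_transform("translation")

#' Cubic B-spline free-form deformation
#'
#' Control-point displacements on a regular grid in physical space; the
#' transform is `p -> p + B(p)` with `B` the cubic-B-spline interpolated
#' displacement.  Control nodes outside the stored grid contribute zero
#' displacement, i.e. the transform extrapolates to the identity.
#'
#' @param coef array `(ncx, ncy, ncz, 3)` of node displacements, micron.
#' @param grid_origin physical position of control node (0,0,0), micron.
#' @param grid_spacing control-grid spacing, micron (scalar = isotropic).
#' @param order spline order; only cubic (3) is implemented.
#' @export
bspline_transform <- function(coef, grid_origin, grid_spacing, order = 3L) {
  if (order != 3L) stop("only cubic B-splines (order 3) are implemented")
  stopifnot(length(dim(coef)) == 4L, dim(coef)[4] == 3L)
  if (length(grid_spacing) == 1L) grid_spacing <- rep(grid_spacing, 3)
  structure(list(coef = coef, grid_origin = as.numeric(grid_origin),
                 grid_spacing = as.numeric(grid_spacing), order = 3L),
            class = c("bspline_transform", "spatial_transform"))
}

#' Control grid covering a fixed-image domain
#'
#' Returns the `(grid_origin, grid_spacing, nc)` of a B-spline control grid
#' covering the domain of `geom` plus the one-node support margin cubic
#' splines need on each side.
#' @param geom image or geometry list.
#' @param grid_spacing micron (scalar isotropic or length 3).
#' @return a zero-displacement `bspline_transform` on that grid.
#' @export
bspline_identity_for <- function(geom, grid_spacing) {
  g <- as_geometry(geom)
  if (length(grid_spacing) == 1L) grid_spacing <- rep(grid_spacing, 3)
  extent <- (g$dim - 1) * g$spacing
  nc <- pmax(4L, as.integer(ceiling(extent / grid_spacing)) + 4L)
  origin <- g$origin - grid_spacing
  bspline_transform(array(0, dim = c(nc, 3)), origin, grid_spacing)
}

#' Dense displacement field
#'
#' Vectors (micron) sampled on a stated reference grid; the transform is
#' `p -> p + u(p)` with `u` interpolated trilinearly (zero outside).
#' @param vectors array `(nx, ny, nz, 3)`, micron.
#' @param spacing,origin geometry of the reference grid, micron.
#' @export
displacement_field <- function(vectors, spacing, origin = c(0, 0, 0)) {
  stopifnot(length(dim(vectors)) == 4L, dim(vectors)[4] == 3L)
  if (any(!is.finite(vectors))) stop("displacement field must be finite")
  structure(list(vectors = vectors, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = c("displacement_field", "spatial_transform"))
}

field_geometry <- function(f)
  list(dim = dim(f$vectors)[1:3], spacing = f$spacing, origin = f$origin)

#' Composite transform
#'
#' Ordered list applied right-to-left: `composite_transform(list(A, B))`
#' maps `p -> A(B(p))`.
#' @param transforms list of transforms.
#' @export
composite_transform <- function(transforms) {
  stopifnot(length(transforms) >= 1L,
            all(vapply(transforms, inherits, TRUE, "spatial_transform")))
  structure(list(transforms = transforms),
            class = c("composite_transform", "spatial_transform"))
}

#' Apply a transform to physical points
#'
#' @param t any spatial transform.
#' @param p N x 3 matrix (or length-3 vector) of physical points, micron.
#' @return N x 3 matrix of mapped points (moving space), micron.
#' @export
apply_transform <- function(t, p) UseMethod("apply_transform")

#' @export
apply_transform.linear_transform <- function(t, p) {
  p <- rbind(p)
  ctr <- base::matrix(t$center, nrow(p), 3, byrow = TRUE)
  out <- (p - ctr) %*% t(t$matrix) + ctr +
    base::matrix(t$translation, nrow(p), 3, byrow = TRUE)
  dimnames(out) <- NULL
  out
}

#' @export
apply_transform.bspline_transform <- function(t, p) {
  p <- rbind(p)
  p + cpp_bspline_disp(t$coef, t$grid_origin, t$grid_spacing, p)
}

#' @export
apply_transform.displacement_field <- function(t, p) {
  p <- rbind(p)
  vox <- phys_to_voxel(field_geometry(t), p)
  disp <- vapply(1:3, function(d)
    cpp_interp(t$vectors[, , , d], vox, 1L, 0), numeric(nrow(p)))
  p + rbind(disp)
}

#' @export
apply_transform.composite_transform <- function(t, p) {
  for (tr in rev(t$transforms)) p <- apply_transform(tr, p)
  p
}

#' Invert a linear transform
#' @param t a `linear_transform`.
#' @export
invert_linear <- function(t) {
  stopifnot(inherits(t, "linear_transform"))
  Ainv <- solve(t$matrix)
  # q = A (p - c) + c + tr  =>  p = Ainv (q - (c + tr)) + (c + tr) - tr
  linear_transform(t$kind, Ainv,
                   translation = -t$translation,
                   center = t$center + t$translation)
}

transform_determinant <- function(t) {
  if (inherits(t, "linear_transform")) det(t$matrix)
  else if (inherits(t, "composite_transform"))
    prod(vapply(t$transforms, transform_determinant, 0))
  else 1.0
}

#' Resample an image through a transform
#'
#' Produces the moving image warped onto the reference grid:
#' `out(x) = moving(T(x))` at every reference voxel center, with zero
#' background outside the moving domain.
#'
#' @param moving a `volumetric_image`.
#' @param t transform mapping reference (fixed) points to moving points.
#' @param reference image or geometry list defining the output grid
#'   (default: the moving image grid).
#' @param interp `"linear"`, `"cubic"` or `"nearest"`.
#' @return a `volumetric_image` on the reference grid.
#' @export
resample <- function(moving, t, reference = moving,
                     interp = c("linear", "cubic", "nearest")) {
  interp <- match.arg(interp)
  g <- as_geometry(reference)
  # reflections (z flip, dorsal-ventral flip) are legitimate; only a
  # singular linear part makes resampling ill-posed
  if (abs(transform_determinant(t)) < 1e-12)
    stop("degenerate transform (det = 0) cannot be used for resampling")
  pts <- apply_transform(t, grid_points(g))
  vox <- phys_to_voxel(moving, pts)
  mode <- c(nearest = 0L, linear = 1L, cubic = 2L)[[interp]]
  vals <- cpp_interp(moving$data, vox, mode, 0)
  volumetric_image(array(vals, dim = g$dim), g$spacing, g$origin,
                   moving$channel_label)
}

#' Express a transform as a dense displacement field
#'
#' `vectors[v] = T(x_v) - x_v` at every reference grid point `x_v`.
#' @param t any spatial transform.
#' @param reference image or geometry list.
#' @return a `displacement_field` on the reference grid.
#' @export
to_displacement_field <- function(t, reference) {
  g <- as_geometry(reference)
  pts <- grid_points(g)
  disp <- apply_transform(t, pts) - pts
  displacement_field(array(disp, dim = c(g$dim, 3)), g$spacing, g$origin)
}

#' Pointwise mean of displacement fields
#'
#' @param fields list of `displacement_field` objects sharing one reference
#'   grid.
#' @param include_identity if `TRUE` (default) a zero field -- the scan's
#'   own deformation to itself -- enters the average as one more term.
#' @return a `displacement_field`.
#' @export
mean_displacement_field <- function(fields, include_identity = TRUE) {
  if (length(fields) == 0L) stop("empty list of displacement fields")
  g <- field_geometry(fields[[1]])
  acc <- array(0, dim = dim(fields[[1]]$vectors))
  for (f in fields) {
    if (!geometry_equal(field_geometry(f), g))
      stop("displacement fields do not share a reference grid")
    acc <- acc + f$vectors
  }
  n <- length(fields) + as.integer(include_identity)
  displacement_field(acc / n, g$spacing, g$origin)
}

#' Invert a dense displacement field
#'
#' Damped fixed-point iteration `v <- (1-a) v - a u(x + v)` (damping 0.6);
#' stops when the maximum residual `|v + u(x + v)|` drops below `tol`
#' (micron) or after `max_iter` sweeps.  The damping keeps the iteration
#' convergent for fields whose gradient approaches 1, where the plain
#' fixed point oscillates; the tolerance sits far below the voxel size.
#' @param field a `displacement_field`.
#' @param max_iter iteration cap (default 60).
#' @param tol stopping tolerance in micron (default 0.1).
#' @param damping relaxation factor in (0, 1] (default 0.6).
#' @export
invert_displacement_field <- function(field, max_iter = 60L, tol = 0.1,
                                      damping = 0.6) {
  g <- field_geometry(field)
  pts <- grid_points(g)
  v <- matrix(0, nrow(pts), 3)
  for (it in seq_len(max_iter)) {
    q <- pts + v
    vox <- phys_to_voxel(g, q)
    u_at <- vapply(1:3, function(d)
      cpp_interp(field$vectors[, , , d], vox, 1L, 0), numeric(nrow(pts)))
    res <- v + u_at
    if (max(abs(res)) < tol) break
    v <- v - damping * res
  }
  displacement_field(array(v, dim = c(g$dim, 3)), g$spacing, g$origin)
}

#' Maximum displacement magnitude of a transform over a grid
#' @param t transform.
#' @param reference geometry.
#' @export
max_displacement <- function(t, reference) {
  g <- as_geometry(reference)
  pts <- grid_points(g)
  disp <- apply_transform(t, pts) - pts
  max(sqrt(rowSums(disp^2)))
}

# ---- transform JSON I/O ---------------------------------------------------

transform_to_list <- function(t) {
  if (inherits(t, "linear_transform")) {
    list(type = "linear", kind = t$kind, matrix = as.numeric(t$matrix),
         translation = t$translation, center = t$center)
  } else if (inherits(t, "bspline_transform")) {
    list(type = "bspline", dim = dim(t$coef), coef = as.numeric(t$coef),
         grid_origin = t$grid_origin, grid_spacing = t$grid_spacing)
  } else if (inherits(t, "displacement_field")) {
    list(type = "displacement_field", dim = dim(t$vectors),
         vectors = as.numeric(t$vectors), spacing = t$spacing,
         origin = t$origin)
  } else if (inherits(t, "bspline_stack")) {
    list(type = "bspline_stack",
         levels = lapply(t$levels, transform_to_list))
  } else if (inherits(t, "composite_transform")) {
    list(type = "composite", transforms = lapply(t$transforms,
                                                 transform_to_list))
  } else stop("unknown transform class")
}

transform_from_list <- function(x) {
  num <- function(v) as.numeric(unlist(v))
  switch(as.character(x$type),
    linear = linear_transform(as.character(x$kind),
                              matrix(num(x$matrix), 3, 3),
                              num(x$translation), num(x$center)),
    bspline = bspline_transform(array(num(x$coef),
                                      dim = as.integer(unlist(x$dim))),
                                num(x$grid_origin), num(x$grid_spacing)),
    displacement_field = displacement_field(
      array(num(x$vectors), dim = as.integer(unlist(x$dim))),
      num(x$spacing), num(x$origin)),
    bspline_stack = bspline_stack(lapply(x$levels, transform_from_list)),
    composite = composite_transform(lapply(x$transforms,
                                           transform_from_list)),
    stop("unknown transform type: ", x$type))
}

#' Write any transform to JSON
#' @param t transform.
#' @param path output path.
#' @export
write_transform <- function(t, path) {
  jsonlite::write_json(transform_to_list(t), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a transform from JSON
#' @param path JSON written by [write_transform()].
#' @export
read_transform <- function(path) {
  transform_from_list(jsonlite::read_json(path, simplifyVector = FALSE))
}

#' Write a displacement field as a 3-component NRRD
#' @param field a `displacement_field`.
#' @param path output path.
#' @export
write_displacement_field <- function(field, path) {
  write_nrrd(field$vectors, path, field$spacing, field$origin,
             type = "double")
  invisible(path)
}

#' Read a displacement field from NRRD
#' @param path NRRD with a 3-vector per voxel.
#' @export
read_displacement_field <- function(path) {
  r <- read_nrrd(path)
  if (length(dim(r$data)) != 4L) stop(path, " is not a vector field")
  displacement_field(r$data, r$spacing, r$origin)
}
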