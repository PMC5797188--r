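# Population-based template construction: pairwise deformable
# registrations between all cohort members, per-member mean deformation
# fields defining the average shape space, and voxelwise fusion.

#' Template package
#'
#' The deliverable of template construction: fused NP (and optionally NT)
#' template, brain mask, the 8 QA anchor landmarks in template space, and
#' the QA calibration statistics frozen at build time so single new scans
#' can be scored without re-observing a cohort.
#'
#' @param np_template,brain_mask `volumetric_image`s.
#' @param nt_template optional NT-channel template.
#' @param qa_anchors `landmark_set` with exactly the 8 anchor labels (2
#'   VNC terminal + 6 thoracic nerve entries).
#' @param qa_calibration list with `vi_max` (named, max regional MI per
#'   VNC anchor), `ti_max` (named, per thoracic anchor), `strain_median`,
#'   `strain_mad`.
#' @param fusion `"mean"` or `"median"`.
#' @param provenance list of scan ids (and optionally the pairwise
#'   transforms used).
#' @param template_landmarks optional full `landmark_set` in template
#'   space (available for phantom cohorts).
#' @export
template_package <- function(np_template, brain_mask, qa_anchors,
                             qa_calibration, fusion = c("median", "mean"),
                             nt_template = NULL, provenance = list(),
                             template_landmarks = NULL) {
  fusion <- match.arg(fusion)
  anchors <- unlist(qa_anchor_labels(), use.names = FALSE)
  if (!setequal(qa_anchors$label, anchors) || nrow(qa_anchors) != 8L)
    stop("qa_anchors must contain exactly the 8 QA anchor labels")
  if (!any(brain_mask$data != 0)) stop("brain mask is empty")
  structure(list(np_template = np_template, nt_template = nt_template,
                 brain_mask = brain_mask, qa_anchors = qa_anchors,
                 qa_calibration = qa_calibration, fusion = fusion,
                 provenance = provenance,
                 template_landmarks = template_landmarks),
            class = "template_package")
}

#' @export
print.template_package <- function(x, ...) {
  d <- dim(x$np_template$data)
  cat(sprintf("<template_package> %d x %d x %d, %s fusion, %d cohort scans\n",
              d[1], d[2], d[3], x$fusion,
              length(x$provenance$scan_ids %||% x$provenance)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pairwise deformable registration between all cohort members
#'
#' For every ordered pair (i fixed, j moving) runs the 4-stage
#' template-generation pipeline -- histogram matching, two-candidate
#' z-flip affine registration, candidate selection, deformable B-spline
#' registration -- and stores the resulting deformation as a dense
#' displacement field on the grid of scan i.  The diagonal holds zero
#' fields.
#'
#' @param scans list of `brain_scan` (NP required), length >= 3.
#' @param cfg full configuration (see [larvreg_config()]).
#' @param progress optional function(msg) for status lines.
#' @return N x N list-matrix of `displacement_field`s.
#' @export
pairwise_register_all <- function(scans, cfg = larvreg_config(),
                                  progress = NULL) {
  n <- length(scans)
  if (n < 3L) stop("template construction needs at least 3 scans")
  fields <- vector("list", n * n)
  dim(fields) <- c(n, n)
  for (i in seq_len(n)) {
    gi <- image_geometry(scans[[i]]$channels$NP)
    zero <- displacement_field(array(0, dim = c(gi$dim, 3)), gi$spacing,
                               gi$origin)
    fields[[i, i]] <- zero
    for (j in seq_len(n)) {
      if (i == j) next
      if (!is.null(progress))
        progress(sprintf("pairwise registration %s <- %s",
                         scans[[i]]$scan_id, scans[[j]]$scan_id))
      fixed <- scans[[i]]$channels$NP
      moving <- histogram_match(scans[[j]]$channels$NP, fixed)
      lin <- tryCatch(
        register_template_linear(fixed, moving, cfg$global),
        error = function(e)
          stop("pairwise linear registration failed for pair (",
               scans[[i]]$scan_id, ", ", scans[[j]]$scan_id, "): ",
               conditionMessage(e)))
      dcfg <- cfg$deformable
      dcfg$metric <- "global_random_NCC"  # template-generation mode split
      dcfg$seed <- cfg$deformable$seed + 131L * i + j
      def <- tryCatch(
        register_bspline(fixed, moving, init = lin$transform, cfg = dcfg),
        error = function(e)
          stop("pairwise deformable registration failed for pair (",
               scans[[i]]$scan_id, ", ", scans[[j]]$scan_id, "): ",
               conditionMessage(e)))
      fields[[i, j]] <- to_displacement_field(def$transform, gi)
    }
  }
  fields
}

#' Mean deformation fields defining the average shape space
#'
#' For each member i, the mean deformation field over its deformations to
#' all other members (plus, by default, the zero deformation to itself):
#' the transform carrying member i into the population average space.
#' @param fields N x N list-matrix from [pairwise_register_all()].
#' @param include_identity include the zero self-deformation term
#'   (default TRUE).
#' @return list of N `displacement_field`s.
#' @export
build_average_space <- function(fields, include_identity = TRUE) {
  n <- nrow(fields)
  lapply(seq_len(n), function(i) {
    others <- fields[i, setdiff(seq_len(n), i)]
    mean_displacement_field(others, include_identity = include_identity)
  })
}

#' Voxelwise fusion of warped images
#'
#' @param warped list of `volumetric_image`s on a common grid.
#' @param method `"median"` (even counts take the lower of the two middle
#'   values, preserving 8-bit levels) or `"mean"`.
#' @export
fuse <- function(warped, method = c("median", "mean")) {
  method <- match.arg(method)
  stopifnot(length(warped) >= 1L)
  g <- image_geometry(warped[[1]])
  for (w in warped)
    if (!geometry_equal(g, w)) stop("fusion inputs must share one grid")
  stack <- vapply(warped, function(w) as.numeric(w$data),
                  numeric(prod(g$dim)))
  fused <- cpp_fuse(stack, if (method == "mean") 0L else 1L)
  volumetric_image(array(fused, dim = g$dim), g$spacing, g$origin,
                   warped[[1]]$channel_label)
}

#' Warp a secondary channel with the NP-derived transform
#'
#' The NT and GE channels are never registered themselves; they are
#' carried along by the transform estimated on the NP channel.
#' @param scan `brain_scan`.
#' @param channel `"NT"` or `"GE"`.
#' @param transform_chain transform mapping reference points into the
#'   scan.
#' @param reference output grid (default: the scan's own grid).
#' @param interp interpolation (default linear).
#' @export
propagate_channel <- function(scan, channel = c("NT", "GE"),
                              transform_chain,
                              reference = scan$channels$NP,
                              interp = "linear") {
  channel <- match.arg(channel)
  img <- scan$channels[[channel]]
  if (is.null(img)) stop("scan ", scan$scan_id, " has no ", channel,
                         " channel")
  resample(img, transform_chain, as_geometry(reference), interp = interp)
}

# QA calibration from the warped cohort: max regional MI per anchor and
# the pooled strain median/MAD at the thoracic anchors.
calibrate_qa <- function(np_template, warped_list, fields_to_member,
                         anchors, radii = qa_radii()) {
  al <- qa_anchor_labels()
  anchor_pt <- function(lab)
    as.numeric(landmark_coords(anchors)[match(lab, anchors$label), ])
  vi_max <- vapply(al$vnc, function(lab) {
    max(vapply(warped_list, function(w)
      regional_mi(np_template, w, anchor_pt(lab), radii$vi_mi), 0))
  }, 0)
  ti_max <- vapply(al$thoracic, function(lab) {
    max(vapply(warped_list, function(w)
      regional_mi(np_template, w, anchor_pt(lab), radii$ti_mi), 0))
  }, 0)
  per_field <- lapply(fields_to_member, function(f) {
    mag <- suppressWarnings(eulerian_strain_magnitude(f))
    lapply(al$thoracic, function(lab) {
      idx <- sphere_voxel_indices(field_geometry(f), anchor_pt(lab),
                                  radii$ti_strain)
      as.numeric(mag[idx])
    })
  })
  strains <- unlist(per_field)
  med <- stats::median(strains)
  mad_raw <- stats::median(abs(strains - med))
  if (mad_raw <= 0) mad_raw <- stats::IQR(strains)
  if (mad_raw <= 0) mad_raw <- 1.0
  # worst per-anchor p95 of the normalized strain over the calibration
  # cohort: anchors the 0-100% scaling of the S score
  z95_max <- max(1, vapply(per_field, function(anchor_strains)
    max(vapply(anchor_strains, function(s)
      as.numeric(stats::quantile((s - med) / mad_raw, 0.95)), 0)), 0))
  list(vi_max = vi_max, ti_max = ti_max,
       strain_median = med, strain_mad = mad_raw,
       strain_z95_max = z95_max)
}

#' Build the population-based template
#'
#' Full procedure: pairwise deformable registration between all members,
#' mean deformation field per member, warp of every member into the
#' average space, voxelwise fusion (median by default), brain mask by
#' intensity thresholding of the fused NP image, and QA calibration from
#' the warped cohort.  The common sampling grid of the average space is
#' the grid of the first cohort scan.
#'
#' @param scans list of `brain_scan`s (>= 3).
#' @param fusion `"median"` (default) or `"mean"`.
#' @param cfg full configuration.
#' @param cohort_landmarks optional list of `landmark_set`s (one per
#'   scan, subject space); if given, template-space landmark positions
#'   and the 8 QA anchors are derived as the per-label mean of the
#'   members' positions mapped into the average space; otherwise
#'   `qa_anchors` must be supplied.
#' @param qa_anchors optional `landmark_set` of the 8 anchors in template
#'   space (required when `cohort_landmarks` is absent).
#' @param include_identity forwarded to [build_average_space()].
#' @param progress optional function(msg).
#' @return a `template_package`.
#' @export
build_template <- function(scans, fusion = c("median", "mean"),
                           cfg = larvreg_config(), cohort_landmarks = NULL,
                           qa_anchors = NULL, include_identity = TRUE,
                           progress = NULL) {
  fusion <- match.arg(fusion)
  n <- length(scans)
  g <- image_geometry(scans[[1]]$channels$NP)
  for (s in scans)
    if (!geometry_equal(g, s$channels$NP))
      stop("cohort scans must share one sampling grid (average-space grid ",
           "is the grid of the first scan)")
  fields <- pairwise_register_all(scans, cfg, progress)
  t_i <- build_average_space(fields, include_identity)
  # warping member i into the average space needs the avg -> i mapping
  inv_t_i <- lapply(t_i, invert_displacement_field)
  warped_np <- lapply(seq_len(n), function(i)
    resample(scans[[i]]$channels$NP, inv_t_i[[i]], g))
  np_template <- fuse(warped_np, fusion)
  have_nt <- all(vapply(scans, function(s) !is.null(s$channels$NT), TRUE))
  nt_template <- if (have_nt) {
    fuse(lapply(seq_len(n), function(i)
      propagate_channel(scans[[i]], "NT", inv_t_i[[i]], g)), fusion)
  } else NULL
  brain_mask <- threshold_brain_mask(np_template)

  template_landmarks <- NULL
  if (!is.null(cohort_landmarks)) {
    stopifnot(length(cohort_landmarks) == n)
    labs <- cohort_landmarks[[1]]$label
    mapped <- lapply(seq_len(n), function(i) {
      p <- landmark_coords(cohort_landmarks[[i]])
      apply_transform(t_i[[i]], p)  # member space -> average space
    })
    mean_pos <- Reduce(`+`, mapped) / n
    template_landmarks <- landmark_set(labs, mean_pos, "template")
    al <- unlist(qa_anchor_labels(), use.names = FALSE)
    qa_anchors <- landmark_set(
      al, mean_pos[match(al, labs), , drop = FALSE], "template")
  }
  if (is.null(qa_anchors))
    stop("qa_anchors must be supplied when no cohort landmarks are given")

  qa_calibration <- calibrate_qa(np_template, warped_np, inv_t_i,
                                 qa_anchors)
  template_package(np_template, brain_mask, qa_anchors, qa_calibration,
                   fusion, nt_template = nt_template,
                   provenance = list(
                     scan_ids = vapply(scans, `[[`, "", "scan_id"),
                     include_identity = include_identity),
                   template_landmarks = template_landmarks)
}

# ---- template package directory I/O ---------------------------------------

#' Save a template package to a directory
#' @param pkg a `template_package`.
#' @param dir output directory (created if missing).
#' @export
save_template_package <- function(pkg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_stack(pkg$np_template, file.path(dir, "np_template.nrrd"))
  if (!is.null(pkg$nt_template))
    write_stack(pkg$nt_template, file.path(dir, "nt_template.nrrd"))
  write_stack(pkg$brain_mask, file.path(dir, "brain_mask.nrrd"))
  write_landmarks(pkg$qa_anchors, file.path(dir, "qa_anchors.csv"))
  if (!is.null(pkg$template_landmarks))
    write_landmarks(pkg$template_landmarks,
                    file.path(dir, "template_landmarks.csv"))
  qc <- pkg$qa_calibration
  qc$vi_max <- as.list(qc$vi_max)  # keep anchor names through JSON
  qc$ti_max <- as.list(qc$ti_max)
  meta <- list(fusion = pkg$fusion, qa_calibration = qc,
               provenance = pkg$provenance)
  jsonlite::write_json(meta, file.path(dir, "template_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a template package from a directory
#' @param dir directory written by [save_template_package()].
#' @export
load_template_package <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "template_meta.json"),
                              simplifyVector = TRUE)
  qc <- meta$qa_calibration
  qc$vi_max <- unlist(qc$vi_max)
  qc$ti_max <- unlist(qc$ti_max)
  np <- read_stack(file.path(dir, "np_template.nrrd"),
                   channel_label = "NP")
  ntp <- file.path(dir, "nt_template.nrrd")
  nt <- if (file.exists(ntp)) read_stack(ntp, channel_label = "NT") else NULL
  tlm <- file.path(dir, "template_landmarks.csv")
  template_package(
    np_template = np,
    brain_mask = read_stack(file.path(dir, "brain_mask.nrrd"),
                            channel_label = "mask"),
    qa_anchors = read_landmarks(file.path(dir, "qa_anchors.csv"),
                                "template"),
    qa_calibration = qc, fusion = meta$fusion, nt_template = nt,
    provenance = meta$provenance,
    template_landmarks = if (file.exists(tlm))
      read_landmarks(tlm, "template") else NULL)
}
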