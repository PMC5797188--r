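# Automatic detection of local registration failures: the VNC-terminal
# indicator VI (regional mutual information at the two terminal anchors)
# and the thoracic-nerve indicator TI = M * S / 100 combining regional MI
# (M) with a normalized Eulerian strain score (S).

#' QA region radii (micron)
#'
#' Spherical region radii used by the indicators: 10 for the VNC-terminal
#' MI, 15 for the thoracic MI, 35 for the thoracic strain neighbourhood.
#' These are true physical radii and are kept in micron regardless of the
#' image scale.
#' @export
qa_radii <- function() list(vi_mi = 10, ti_mi = 15, ti_strain = 35)

# central-difference gradient of one scalar component along one axis,
# one-sided at the borders; physical units (per micron)
axis_gradient <- function(a, axis, h) {
  d <- dim(a)
  n <- d[axis]
  g <- array(0, dim = d)
  if (n == 1L) return(g)
  idx <- function(shift) {
    i <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    i[[axis]] <- pmin(pmax(i[[axis]] + shift, 1L), n)
    i
  }
  ip <- idx(1L); im <- idx(-1L)
  num <- a[ip[[1]], ip[[2]], ip[[3]], drop = FALSE] -
         a[im[[1]], im[[2]], im[[3]], drop = FALSE]
  # denominator: 2h interior, h at the two border slices
  den <- array(2 * h, dim = d)
  bidx <- function(at) {
    i <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    i[[axis]] <- at
    i
  }
  b1 <- bidx(1L); bn <- bidx(n)
  den[b1[[1]], b1[[2]], b1[[3]]] <- h
  den[bn[[1]], bn[[2]], bn[[3]]] <- h
  g[] <- num / den
  g
}

displacement_jacobian <- function(field) {
  u <- field$vectors
  sp <- field$spacing
  J <- vector("list", 9L)  # J[[3*(q-1)+p]] = d u_p / d x_q
  for (p in 1:3)
    for (q in 1:3)
      J[[3L * (q - 1L) + p]] <- axis_gradient(u[, , , p], q, sp[q])
  J
}

#' Jacobian determinant of the deformation `x + u(x)`
#'
#' Central differences in physical micron on the field grid.  Positive
#' everywhere means no folding.
#' @param field a `displacement_field`.
#' @return 3D array of determinant values.
#' @export
jacobian_determinant <- function(field) {
  J <- displacement_jacobian(field)
  F11 <- 1 + J[[1]]; F21 <- J[[2]];     F31 <- J[[3]]
  F12 <- J[[4]];     F22 <- 1 + J[[5]]; F32 <- J[[6]]
  F13 <- J[[7]];     F23 <- J[[8]];     F33 <- 1 + J[[9]]
  F11 * (F22 * F33 - F23 * F32) - F12 * (F21 * F33 - F23 * F31) +
    F13 * (F21 * F32 - F22 * F31)
}

#' Magnitude of the Eulerian (Almansi) strain tensor of a deformation
#'
#' From the deformation gradient `F = I + grad(u)` (central differences in
#' physical micron), the Eulerian strain is
#' `e = (I - (F F^T)^{-1}) / 2`; the returned magnitude is its Frobenius
#' norm per voxel.  Identity and pure translation give 0; isotropic
#' scaling by `s` gives `sqrt(3) * |1 - s^-2| / 2`.
#'
#' Voxels where `det F` falls below `det_tol` (locally folded or
#' degenerate deformation) are set to the largest finite magnitude in the
#' field (the cohort cap) with a warning.
#'
#' @param field a `displacement_field`.
#' @param at optional integer vector of linear voxel indices; default all.
#' @param det_tol singularity tolerance on `det F` (default 1e-6).
#' @return 3D array (or vector over `at`) of strain magnitudes >= 0.
#' @export
eulerian_strain_magnitude <- function(field, at = NULL, det_tol = 1e-6) {
  J <- displacement_jacobian(field)
  F11 <- 1 + J[[1]]; F21 <- J[[2]];     F31 <- J[[3]]
  F12 <- J[[4]];     F22 <- 1 + J[[5]]; F32 <- J[[6]]
  F13 <- J[[7]];     F23 <- J[[8]];     F33 <- 1 + J[[9]]
  # C = F F^T (left Cauchy-Green), symmetric
  C11 <- F11^2 + F12^2 + F13^2
  C22 <- F21^2 + F22^2 + F23^2
  C33 <- F31^2 + F32^2 + F33^2
  C12 <- F11 * F21 + F12 * F22 + F13 * F23
  C13 <- F11 * F31 + F12 * F32 + F13 * F33
  C23 <- F21 * F31 + F22 * F32 + F23 * F33
  detF <- F11 * (F22 * F33 - F23 * F32) - F12 * (F21 * F33 - F23 * F31) +
    F13 * (F21 * F32 - F22 * F31)
  detC <- detF^2
  bad <- abs(detF) <= det_tol
  detC[bad] <- 1  # placeholder, overwritten below
  iC11 <- (C22 * C33 - C23^2) / detC
  iC22 <- (C11 * C33 - C13^2) / detC
  iC33 <- (C11 * C22 - C12^2) / detC
  iC12 <- (C13 * C23 - C12 * C33) / detC
  iC13 <- (C12 * C23 - C13 * C22) / detC
  iC23 <- (C12 * C13 - C11 * C23) / detC
  e11 <- (1 - iC11) / 2; e22 <- (1 - iC22) / 2; e33 <- (1 - iC33) / 2
  e12 <- -iC12 / 2; e13 <- -iC13 / 2; e23 <- -iC23 / 2
  mag <- sqrt(e11^2 + e22^2 + e33^2 + 2 * (e12^2 + e13^2 + e23^2))
  if (any(bad)) {
    cap <- if (any(!bad)) max(mag[!bad]) else 1
    mag[bad] <- cap
    warning(sum(bad), " voxels with singular deformation gradient; ",
            "strain magnitude set to the field cap ", signif(cap, 4))
  }
  if (is.null(at)) mag else as.numeric(mag[at])
}

#' VNC-terminal error indicator (VI)
#'
#' Regional mutual information between template and registered NP channel
#' in 10 micron spheres at the two terminal VNC anchors, expressed in
#' percent of the maximum score observed on the calibration cohort (the
#' best-registered terminal of the calibration cohort defines 100%).
#' Reduced over the two anchors by the minimum, so a single failed
#' terminal flags the scan.
#'
#' @param template `volumetric_image` (NP template).
#' @param registered_np subject NP channel warped onto the template grid.
#' @param anchors `landmark_set` with the 2 VNC-terminal anchors in
#'   template space.
#' @param calibration_max named numeric (per anchor label) of maximum
#'   regional MI from calibration.
#' @param radius sphere radius, micron (default 10).
#' @return VI percent in \[0, 100\].
#' @export
vi_indicator <- function(template, registered_np, anchors, calibration_max,
                         radius = qa_radii()$vi_mi) {
  stopifnot(nrow(anchors) == 2L)
  pts <- landmark_coords(anchors)
  vi <- vapply(seq_len(2L), function(i) {
    mx <- calibration_max[[anchors$label[i]]]
    if (is.null(mx) || !is.finite(mx) || mx <= 0)
      stop("missing VI calibration for anchor '", anchors$label[i], "'")
    100 * regional_mi(template, registered_np, pts[i, ], radius) / mx
  }, 0)
  min(max(min(vi), 0), 100)
}

#' Thoracic-nerve error indicator (TI = M * S / 100)
#'
#' Per thoracic anchor: `M` is regional MI in a 15 micron sphere in
#' percent of the calibration maximum; `S` is a confidence score from the
#' Eulerian strain magnitudes in a 35 micron sphere -- strain is
#' normalized by the calibration median and MAD, its 95th percentile
#' taken, and mapped to percent with inverted orientation (low strain =
#' high confidence), anchored to the calibration cohort's own strain
#' range: `S = 100 * (1 - clip(z95 / (2.5 * z95_cal_max), 0, 1))`, so the
#' 50% confidence threshold sits at 1.25 times the worst normalized
#' strain seen during calibration.  The indicator is
#' reduced over the six anchors by the minimum TI; the reported M and S
#' are those of the minimizing anchor so that TI = M * S / 100 holds
#' exactly.
#'
#' @param template NP template image.
#' @param registered_np subject NP warped onto the template grid.
#' @param field `displacement_field` of the registration on the template
#'   grid.
#' @param anchors `landmark_set` with the 6 thoracic anchors.
#' @param calibration list with `ti_max` (named per anchor),
#'   `strain_median`, `strain_mad`.
#' @param radii list as [qa_radii()].
#' @return list with `ti`, `m`, `s` (percent) and `per_anchor` data.frame.
#' @export
ti_indicator <- function(template, registered_np, field, anchors,
                         calibration, radii = qa_radii()) {
  stopifnot(nrow(anchors) == 6L)
  mag <- suppressWarnings(eulerian_strain_magnitude(field))
  gf <- field_geometry(field)
  pts <- landmark_coords(anchors)
  rows <- lapply(seq_len(6L), function(i) {
    lab <- anchors$label[i]
    mx <- calibration$ti_max[[lab]]
    if (is.null(mx) || !is.finite(mx) || mx <= 0)
      stop("missing TI calibration for anchor '", lab, "'")
    m <- 100 * min(max(
      regional_mi(template, registered_np, pts[i, ], radii$ti_mi) / mx,
      0), 1)
    idx <- sphere_voxel_indices(gf, pts[i, ], radii$ti_strain)
    z <- (mag[idx] - calibration$strain_median) / calibration$strain_mad
    z95 <- as.numeric(stats::quantile(z, 0.95))
    zscale <- 2.5 * max(calibration$strain_z95_max %||% 1, 1)
    s <- 100 * (1 - min(max(z95 / zscale, 0), 1))
    data.frame(anchor = lab, m = m, s = s, ti = m * s / 100, p95 = z95)
  })
  per_anchor <- do.call(rbind, rows)
  k <- which.min(per_anchor$ti)
  list(ti = per_anchor$ti[k], m = per_anchor$m[k], s = per_anchor$s[k],
       per_anchor = per_anchor)
}

#' Accept/flag decision from the VI and TI confidences
#'
#' A scan is flagged for manual correction iff either confidence falls
#' strictly below the threshold (default 50%); exactly 50 is accepted.
#' @param vi,ti confidences, percent.
#' @param threshold percent (default 50).
#' @param m_score,s_score optional component scores for the report; when
#'   absent, M defaults to 100 and S to TI (so TI = M*S/100 holds).
#' @param scan_id identifier for the report.
#' @return a `qa_report`.
#' @export
qa_decide <- function(vi, ti, threshold = 50, m_score = NULL,
                      s_score = NULL, scan_id = "scan") {
  if (is.null(m_score)) m_score <- 100
  if (is.null(s_score)) s_score <- ti * 100 / m_score
  qa_report(scan_id, vi, ti, m_score, s_score, threshold)
}

#' Full automatic quality assessment of a registered scan
#'
#' @param template a `template_package` with QA calibration.
#' @param registered_np subject NP channel warped onto the template grid.
#' @param field `displacement_field` of the registration (template grid).
#' @param scan_id identifier.
#' @param threshold percent (default 50).
#' @return a `qa_report` with attribute `"detail"` holding the per-anchor
#'   table.
#' @export
assess_quality <- function(template, registered_np, field,
                           scan_id = "scan", threshold = 50) {
  al <- qa_anchor_labels()
  anch <- template$qa_anchors
  vnc <- anch[match(al$vnc, anch$label), , drop = FALSE]
  tho <- anch[match(al$thoracic, anch$label), , drop = FALSE]
  vi <- vi_indicator(template$np_template, registered_np,
                     landmark_set(vnc$label, as.matrix(vnc[, c("x", "y", "z")]),
                                  "template"),
                     template$qa_calibration$vi_max)
  ti <- ti_indicator(template$np_template, registered_np, field,
                     landmark_set(tho$label, as.matrix(tho[, c("x", "y", "z")]),
                                  "template"),
                     template$qa_calibration)
  rep <- qa_decide(vi, ti$ti, threshold, m_score = ti$m, s_score = ti$s,
                   scan_id = scan_id)
  attr(rep, "detail") <- ti$per_anchor
  rep
}

#' Write a batch QA table
#' @param reports list of `qa_report`s.
#' @param path output CSV.
#' @export
write_qa_batch_csv <- function(reports, path) {
  df <- do.call(rbind, lapply(reports, function(r)
    data.frame(scan_id = r$scan_id, vi = r$vi, ti = r$ti,
               decision = r$decision)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
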