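# Gold-standard evaluation: landmark registration error (LRE), intra-rater
# statistics, cohort aggregation and QA-vs-expert confusion matrices.

#' Landmark registration error of one scan
#'
#' For every label present in both sets, the Euclidean distance (micron)
#' between the transformed reference (template-space) landmark and the
#' annotated subject landmark.  The transform maps template space into
#' subject space (the resampling convention used throughout).  Labels
#' present in only one set are excluded with a warning, never silently
#' dropped.
#'
#' @param reference `landmark_set` in template space.
#' @param subject_landmarks `landmark_set` annotated in subject space.
#' @param transform transform mapping template points to subject points
#'   (default identity).
#' @param scan_id identifier.
#' @return an `lre_result`: list with `scan_id`, `per_landmark` (named
#'   numeric, micron), `mean`, `sd`, `median`, `max`.
#' @export
landmark_registration_error <- function(reference, subject_landmarks,
                                        transform = identity_transform(),
                                        scan_id = "scan") {
  common <- intersect(reference$label, subject_landmarks$label)
  missing <- union(setdiff(reference$label, subject_landmarks$label),
                   setdiff(subject_landmarks$label, reference$label))
  if (length(missing))
    warning("labels present in only one set are excluded: ",
            paste(missing, collapse = ", "))
  if (!length(common)) stop("no common landmark labels")
  rp <- landmark_coords(reference)[match(common, reference$label), ,
                                   drop = FALSE]
  sp <- landmark_coords(subject_landmarks)[
    match(common, subject_landmarks$label), , drop = FALSE]
  mapped <- apply_transform(transform, rp)
  err <- sqrt(rowSums((mapped - sp)^2))
  names(err) <- common
  structure(list(scan_id = scan_id, per_landmark = err,
                 mean = mean(err), sd = stats::sd(err),
                 median = stats::median(err), max = max(err)),
            class = "lre_result")
}

#' @export
print.lre_result <- function(x, ...) {
  cat(sprintf("<lre_result %s> n = %d, mean %.1f, sd %.1f, median %.1f, max %.1f um\n",
              x$scan_id, length(x$per_landmark), x$mean,
              if (is.na(x$sd)) 0 else x$sd, x$median, x$max))
  invisible(x)
}

#' Cohort aggregation of landmark registration errors
#'
#' The reporting convention of the evaluation tables: errors are first
#' averaged per registration, then the cohort mean, (sample) standard
#' deviation and median of these per-scan means are computed; the cohort
#' maximum is the mean over each registration's largest error.
#'
#' @param results list of `lre_result`s (or a numeric vector of per-scan
#'   means together with `maxima`).
#' @return list with `mean`, `sd`, `median`, `max`, `n`.
#' @export
aggregate_scans <- function(results) {
  stopifnot(length(results) >= 1L)
  means <- vapply(results, function(r) r$mean, 0)
  maxima <- vapply(results, function(r) r$max, 0)
  list(mean = mean(means),
       sd = if (length(means) > 1L) stats::sd(means) else 0,
       median = stats::median(means),
       max = mean(maxima),
       n = length(results))
}

#' Intra-rater deviation statistics
#'
#' For a landmarks x scans table of annotation deviations (micron):
#' the grand mean and (sample) standard deviation over all entries, the
#' per-landmark maximum column, its mean and standard deviation, and the
#' overall maximum.
#' @param deviations numeric matrix, rows = landmarks, columns = repeat
#'   scans.
#' @return list with `grand_mean`, `grand_sd`, `per_landmark_max`,
#'   `mean_of_maxima`, `sd_of_maxima`, `overall_max`, `per_scan_mean`.
#' @export
intra_rater_stats <- function(deviations) {
  deviations <- as.matrix(deviations)
  stopifnot(is.numeric(deviations), all(is.finite(deviations)))
  per_landmark_max <- apply(deviations, 1L, max)
  list(grand_mean = mean(deviations),
       grand_sd = stats::sd(as.numeric(deviations)),
       per_landmark_max = per_landmark_max,
       mean_of_maxima = mean(per_landmark_max),
       sd_of_maxima = stats::sd(per_landmark_max),
       overall_max = max(deviations),
       per_scan_mean = colMeans(deviations))
}

#' Confusion matrix of expert vs automatic quality decisions
#'
#' @param expert,predicted named character vectors (`scan_id ->`
#'   `"accepted"`/`"rejected"`); names must coincide.
#' @return list with `counts` (2 x 2 matrix, rows = expert, columns =
#'   predicted), `row_sums`, `col_sums`, `total`.
#' @export
qa_confusion <- function(expert, predicted) {
  if (!setequal(names(expert), names(predicted)))
    stop("expert and predicted decisions must cover the same scans")
  predicted <- predicted[names(expert)]
  lv <- c("accepted", "rejected")
  stopifnot(all(expert %in% lv), all(predicted %in% lv))
  counts <- table(factor(expert, lv), factor(predicted, lv))
  counts <- matrix(as.integer(counts), 2, 2,
                   dimnames = list(expert = lv, predicted = lv))
  list(counts = counts, row_sums = rowSums(counts),
       col_sums = colSums(counts), total = sum(counts))
}

#' Round half-up to a number of decimals (table reporting convention)
#' @param x numeric.
#' @param digits decimals (default 1).
#' @export
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}
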