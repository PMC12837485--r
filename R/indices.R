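#' @include AllClasses.R mask_io.R
NULL

#' Percentile with a named convention
#'
#' All percentile computations in the package (the PLD bottom-q\% threshold
#' and the HD95 percentile) go through this one function so the convention
#' is stated once and alternates can be swapped. \code{"linear"} is linear
#' interpolation between order statistics (\code{stats::quantile} type 7);
#' \code{"nearest-rank"} is the smallest order statistic whose cumulative
#' fraction reaches p (type 1).
#'
#' @param x numeric vector, non-empty.
#' @param p probability in [0, 1].
#' @param rule percentile convention.
#' @return Scalar percentile value.
#' @export
pvQuantile <- function(x, p, rule = c("linear", "nearest-rank")) {
  rule <- match.arg(rule)
  if (!length(x)) stopPrecondition("percentile of an empty set is undefined")
  type <- if (rule == "linear") 7L else 1L
  unname(stats::quantile(x, probs = p, type = type, names = FALSE))
}

#' Shared-slice support of a volume
#'
#' The slice set K: every depth slice containing at least one PV pixel and
#' at least one LA pixel. Slices with only one or neither structure are
#' excluded. Pixel coordinates are (row, col) within the slice.
#'
#' @param volume a \code{LabelVolume}.
#' @param mergeVein merge the confluent-vein label into PV (default TRUE).
#' @return List of slice pairs, each \code{list(k, pv, la)} with \code{k}
#'   the 1-based depth index and \code{pv}/\code{la} 2-column integer
#'   matrices of (row, col) coordinates; ascending in k. May be empty.
#' @export
sliceSupport <- function(volume, mergeVein = TRUE) {
  pv <- structureMask(volume, "PV", mergeVein = mergeVein)
  la <- structureMask(volume, "LA")
  d <- dim(pv)
  out <- list()
  for (k in seq_len(d[1L])) {
    pvk <- which(pv[k, , ], arr.ind = TRUE)
    lak <- which(la[k, , ], arr.ind = TRUE)
    if (nrow(pvk) && nrow(lak)) {
      colnames(pvk) <- colnames(lak) <- c("row", "col")
      out[[length(out) + 1L]] <- list(k = k, pv = pvk, la = lak)
    }
  }
  out
}

#' Minimum in-plane PV-LA distance of one slice
#'
#' Minimum Euclidean distance over all PV x LA pixel pairs of one depth
#' slice, in isotropic pixel units. Distances are strictly in-plane (2D);
#' disjoint integer-grid pixel sets are always at least 1 apart.
#'
#' @param pair one element of \code{\link{sliceSupport}} (both pixel sets
#'   non-empty).
#' @return Minimum distance in pixels.
#' @export
minSliceDistance <- function(pair) {
  pv <- pair$pv; la <- pair$la
  if (!nrow(pv) || !nrow(la))
    stopPrecondition("minSliceDistance requires both PV and LA pixels in the slice")
  ## pairwise squared distances via outer sums; slices are small enough
  dr <- outer(pv[, 1L], la[, 1L], "-")
  dc <- outer(pv[, 2L], la[, 2L], "-")
  sqrt(min(dr * dr + dc * dc))
}

#' Bottom-q\% subset of a distance set
#'
#' Computes the threshold t_q as the q-th percentile of the distances and
#' returns the distances d with d <= t_q. q = 100 returns the full set; a
#' constant set is returned whole for any q. The retained subset is never
#' empty.
#'
#' @param distances non-empty numeric vector (pixels).
#' @param q percent in (0, 100].
#' @param rule percentile convention, see \code{\link{pvQuantile}}.
#' @return List with \code{subset} (retained distances), \code{tQ}, and
#'   \code{keep} (logical over the input).
#' @export
quantileSubset <- function(distances, q = 100, rule = "linear") {
  if (!length(distances))
    stopPrecondition("distance set is empty")
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q <= 0 || q > 100)
    stopValidation("q must be a single value in (0, 100]")
  tQ <- pvQuantile(distances, q / 100, rule = rule)
  keep <- distances <= tQ + 1e-9
  list(subset = distances[keep], tQ = tQ, keep = keep)
}

#' PV-LA distance index (PLD)
#'
#' For every slice in the shared-slice set K the minimum in-plane Euclidean
#' distance between PV and LA pixels is computed; the bottom-q\% subset of
#' those per-slice minima (by the t_q percentile threshold) is retained and
#' its arithmetic mean is the PLD, in pixels. Because one voxel carries one
#' label, PV and LA pixels are disjoint and the minimum attainable PLD is
#' 1.00, which indicates a PV-LA connection (edge-adjacent pixels in every
#' retained slice); larger values mean the PV and LA are more divergent.
#'
#' @param volume a \code{LabelVolume} with at least one shared slice.
#' @param q bottom-percentage of per-slice distances retained, in (0, 100].
#'   Default 100 (all shared slices).
#' @param rule percentile convention for t_q, see \code{\link{pvQuantile}}.
#' @param mergeVein merge the confluent-vein label into PV (default TRUE).
#' @return A \code{\link[=PLDResult-class]{PLDResult}}.
#' @examples
#' v <- generatePhantom(phantomConfig(gap = 0, angle = 0, seed = 1))
#' indexValue(computePLD(v))  # 1.00: touching structures
#' @export
computePLD <- function(volume, q = 100, rule = "linear", mergeVein = TRUE) {
  support <- sliceSupport(volume, mergeVein = mergeVein)
  if (!length(support)) noSharedSliceError(volume, mergeVein)
  d <- vapply(support, minSliceDistance, numeric(1L))
  k <- vapply(support, function(p) p$k, numeric(1L))
  qs <- quantileSubset(d, q = q, rule = rule)
  methods::new("PLDResult",
    pld = mean(qs$subset), q = as.numeric(q), tQ = qs$tQ,
    percentileRule = rule,
    distances = data.frame(k = as.integer(k), d = d, retained = qs$keep),
    nUsed = length(qs$subset),
    caseId = caseId(volume), videoId = videoId(volume))
}

noSharedSliceError <- function(volume, mergeVein = TRUE) {
  pv <- structureMask(volume, "PV", mergeVein = mergeVein)
  la <- structureMask(volume, "LA")
  rng <- function(m) {
    kk <- which(apply(m, 1L, any))
    if (!length(kk)) "absent" else sprintf("slices %d..%d", min(kk), max(kk))
  }
  stopNoSharedSlice(sprintf(
    "no slice contains both PV and LA (PV: %s; LA: %s); the PV-LA indices are undefined for this volume",
    rng(pv), rng(la)),
    pvRange = rng(pv), laRange = rng(la))
}

#' Centroid of a pixel set
#'
#' Unweighted center of gravity of a binary-mask pixel set.
#'
#' @param pixels 2-column (row, col) matrix, non-empty.
#' @return Numeric (row, col) centroid.
#' @export
sliceCentroid <- function(pixels) {
  if (!nrow(pixels)) stopPrecondition("centroid of an empty pixel set is undefined")
  c(row = mean(pixels[, 1L]), col = mean(pixels[, 2L]))
}

#' Major-axis direction of a pixel region
#'
#' Direction of the major axis of the moment-equivalent ellipse of a pixel
#' set: the principal eigenvector of the 2x2 second central-moment matrix
#' of the (row, col) coordinates, computed in closed form from mu20, mu02
#' and mu11. The sign of the returned vector is arbitrary (an axis, not a
#' ray). The axis is degenerate - no unique major direction - for a single
#' pixel or when the two eigenvalues are equal within tolerance (isotropic
#' region, e.g. a filled square or circle).
#'
#' @param pixels 2-column (row, col) matrix, non-empty.
#' @param tol relative eigenvalue-gap tolerance for degeneracy (default
#'   1e-9: ratio within 1 + 1e-9 of unity is degenerate).
#' @return \code{list(direction = c(row, col) unit vector, degenerate =
#'   FALSE)} or \code{list(degenerate = TRUE, reason = ...)}.
#' @export
majorAxisDirection <- function(pixels, tol = 1e-9) {
  n <- nrow(pixels)
  if (!n) stopPrecondition("major axis of an empty pixel set is undefined")
  if (n == 1L)
    return(list(degenerate = TRUE, reason = "single pixel"))
  r <- pixels[, 1L] - mean(pixels[, 1L])
  c_ <- pixels[, 2L] - mean(pixels[, 2L])
  mrr <- sum(r * r) / n
  mcc <- sum(c_ * c_) / n
  mrc <- sum(r * c_) / n
  tr <- mrr + mcc
  gap <- sqrt((mrr - mcc)^2 + 4 * mrc^2)
  lam1 <- (tr + gap) / 2
  lam2 <- (tr - gap) / 2
  if (lam1 <= lam2 * (1 + tol) || lam1 <= 0)
    return(list(degenerate = TRUE,
                reason = "isotropic second moments (no unique major axis)"))
  ## eigenvector of [[mrr, mrc], [mrc, mcc]] for lam1
  if (abs(mrc) > .Machine$double.eps * max(1, tr)) {
    v <- c(mrc, lam1 - mrr)
  } else if (mrr >= mcc) {
    v <- c(1, 0)
  } else {
    v <- c(0, 1)
  }
  list(direction = v / sqrt(sum(v^2)), degenerate = FALSE)
}

#' Folded PV-LA angle of one slice
#'
#' Angle between the vector from the PV centroid to the LA centroid and the
#' PV's major axis, folded into [0, 90] degrees: with raw angle theta in
#' [0, 180], the folded angle is min(theta, 180 - theta), which removes the
#' arbitrary sign of the axis direction. Degenerate when the PV has no
#' unique major axis or the two centroids coincide.
#'
#' @param pair one element of \code{\link{sliceSupport}}.
#' @param tol degeneracy tolerances (eigenvalue ratio and centroid
#'   coincidence, both 1e-9).
#' @return \code{list(theta = degrees, degenerate = FALSE)} or
#'   \code{list(degenerate = TRUE, reason = ...)}.
#' @export
sliceAngle <- function(pair, tol = 1e-9) {
  if (!nrow(pair$pv) || !nrow(pair$la))
    stopPrecondition("sliceAngle requires both PV and LA pixels in the slice")
  ax <- majorAxisDirection(pair$pv, tol = tol)
  if (ax$degenerate)
    return(list(degenerate = TRUE, reason = ax$reason))
  gP <- sliceCentroid(pair$pv)
  gL <- sliceCentroid(pair$la)
  v <- gL - gP
  nv <- sqrt(sum(v^2))
  if (nv < tol)
    return(list(degenerate = TRUE, reason = "coincident PV and LA centroids"))
  cosT <- sum(v / nv * ax$direction)
  cosT <- min(1, max(-1, cosT))
  thetaRaw <- acos(cosT) * 180 / pi        # in [0, 180]
  list(theta = min(thetaRaw, 180 - thetaRaw), degenerate = FALSE)
}

#' PV-LA angle index (PLA)
#'
#' Mean over the shared-slice set K of the per-slice folded angle between
#' the PV-centroid-to-LA-centroid vector and the PV's moment major axis,
#' in degrees. Ranges from 0 (LA displaced along the PV's own axis, the
#' normal draining geometry) to 90 (PV lying broadside to the LA). Slices
#' where the angle is degenerate (isotropic PV, coincident centroids) are
#' excluded and listed with reasons.
#'
#' @param volume a \code{LabelVolume} with at least one shared slice and at
#'   least one non-degenerate slice.
#' @param mergeVein merge the confluent-vein label into PV (default TRUE).
#' @return A \code{\link[=PLAResult-class]{PLAResult}}.
#' @export
computePLA <- function(volume, mergeVein = TRUE) {
  support <- sliceSupport(volume, mergeVein = mergeVein)
  if (!length(support)) noSharedSliceError(volume, mergeVein)
  ks <- integer(0); th <- numeric(0)
  exK <- integer(0); exR <- character(0)
  for (p in support) {
    a <- sliceAngle(p)
    if (a$degenerate) {
      exK <- c(exK, p$k); exR <- c(exR, a$reason)
    } else {
      ks <- c(ks, p$k); th <- c(th, a$theta)
    }
  }
  if (!length(th))
    stopNoMeasurableAngle(sprintf(
      "all %d shared slices are angle-degenerate (%s)",
      length(support), paste(unique(exR), collapse = "; ")))
  methods::new("PLAResult",
    pla = mean(th), angles = data.frame(k = ks, theta = th),
    nUsed = length(th), excluded = data.frame(k = exK, reason = exR),
    caseId = caseId(volume), videoId = videoId(volume))
}

#' Compute both indices for every volume of a cohort
#'
#' Batch driver: reads each volume listed in a cohort table, computes PLD
#' and PLA, and returns one long data.frame. Per-volume failures (e.g. a
#' volume with no shared slice) are recorded in the \code{error} column and
#' do not abort the batch.
#'
#' @param cohort data.frame from \code{\link{loadCohort}}, or a list of
#'   \code{LabelVolume}s with an attached cohort attribute (as produced by
#'   \code{\link{generateCohort}}).
#' @param q,rule,mergeVein passed to \code{\link{computePLD}} /
#'   \code{\link{computePLA}}.
#' @return data.frame with columns case_id, video_id, model_name, role,
#'   group, index_name, value, q, t_q, n_used, percentile_rule, error.
#' @export
indexCohort <- function(cohort, q = 100, rule = "linear", mergeVein = TRUE) {
  rows <- list()
  for (i in seq_len(nrow(cohort))) {
    rec <- cohort[i, ]
    vol <- tryCatch(
      readLabelVolume(rec$volume_path, caseId = rec$case_id,
                      videoId = rec$video_id),
      error = function(e) e)
    for (index in c("PLD", "PLA")) {
      row <- data.frame(
        case_id = rec$case_id, video_id = rec$video_id,
        model_name = rec$model_name, role = rec$role, group = rec$group,
        index_name = index, value = NA_real_, q = as.numeric(q),
        t_q = NA_real_, n_used = NA_integer_, percentile_rule = rule,
        error = NA_character_, stringsAsFactors = FALSE)
      if (inherits(vol, "error")) {
        row$error <- conditionMessage(vol)
      } else {
        res <- tryCatch(
          if (index == "PLD")
            computePLD(vol, q = q, rule = rule, mergeVein = mergeVein)
          else computePLA(vol, mergeVein = mergeVein),
          error = function(e) e)
        if (inherits(res, "error")) {
          row$error <- conditionMessage(res)
        } else {
          row$value <- indexValue(res)
          row$n_used <- res@nUsed
          if (index == "PLD") row$t_q <- res@tQ
        }
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}
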