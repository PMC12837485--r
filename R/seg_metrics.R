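#' @include AllClasses.R mask_io.R indices.R
NULL

#' Dice coefficient of one structure
#'
#' Voxelwise overlap Dice = 2TP / (2TP + FP + FN) over the whole 3D volume
#' for the chosen structure; \code{"PV_LA"} treats the PV-LA aggregate
#' (union) as one foreground. Ranges over [0, 1], 1 meaning perfect
#' agreement. When both masks are empty the metric is 0/0 and an
#' undefined-metric error is raised rather than reporting an arbitrary
#' value.
#'
#' @param pred,truth \code{LabelVolume}s of identical dimensions.
#' @param structure \code{"PV"}, \code{"LA"} or \code{"PV_LA"}.
#' @param mergeVein merge the confluent-vein label into PV (default TRUE).
#' @return List with \code{dice}, \code{tp}, \code{fp}, \code{fn}.
#' @export
diceCoefficient <- function(pred, truth, structure = c("PV", "LA", "PV_LA"),
                            mergeVein = TRUE) {
  structure <- match.arg(structure)
  if (!identical(dim(pred), dim(truth)))
    stopValidation(sprintf("shape mismatch: pred %s vs truth %s",
                           paste(dim(pred), collapse = "x"),
                           paste(dim(truth), collapse = "x")))
  p <- structureMask(pred, structure, mergeVein = mergeVein)
  g <- structureMask(truth, structure, mergeVein = mergeVein)
  tp <- sum(p & g); fp <- sum(p & !g); fn <- sum(!p & g)
  if (tp + fp + fn == 0L)
    stopUndefinedMetric(sprintf(
      "Dice undefined for %s: both masks are empty (2*0/0)", structure))
  list(dice = 2 * tp / (2 * tp + fp + fn),
       tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn))
}

#' Surface voxels of a binary mask
#'
#' Foreground voxels with at least one background 6-neighbor; voxels on the
#' volume border count their out-of-bounds neighbors as background. 6-
#' connectivity (face neighbors) is the surface convention used throughout.
#'
#' @param mask logical 3D array, non-empty.
#' @return Integer matrix of (depth, row, col) surface-voxel coordinates.
#' @export
surfacePoints <- function(mask) {
  if (!any(mask)) stopPrecondition("surface of an empty mask is undefined")
  d <- dim(mask)
  interior <- array(TRUE, dim = d)
  shift1 <- function(m, axis, by) {
    ## neighbor value along an axis; out-of-bounds neighbors are background
    out <- array(FALSE, dim = dim(m))
    n <- dim(m)[axis]
    src <- seq_len(n) + by
    ok <- src >= 1L & src <= n
    idx <- list(seq_len(dim(m)[1L]), seq_len(dim(m)[2L]), seq_len(dim(m)[3L]))
    dst <- idx; dst[[axis]] <- which(ok)
    srcI <- idx; srcI[[axis]] <- src[ok]
    out[dst[[1L]], dst[[2L]], dst[[3L]]] <- m[srcI[[1L]], srcI[[2L]], srcI[[3L]]]
    out
  }
  for (axis in 1:3) for (by in c(-1L, 1L))
    interior <- interior & shift1(mask, axis, by)
  which(mask & !interior, arr.ind = TRUE)
}

## for each row of a, Euclidean distance to the nearest row of b (chunked)
nearestDistances <- function(a, b, chunk = 2048L) {
  b2 <- rowSums(b * b)
  out <- numeric(nrow(a))
  for (s in seq(1L, nrow(a), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(a))
    ab <- a[s:e, , drop = FALSE]
    d2 <- outer(rowSums(ab * ab), b2, "+") - 2 * (ab %*% t(b))
    out[s:e] <- sqrt(pmax(apply(d2, 1L, min), 0))
  }
  out
}

surfacePair <- function(pred, truth, structure, mergeVein) {
  p <- structureMask(pred, structure, mergeVein = mergeVein)
  g <- structureMask(truth, structure, mergeVein = mergeVein)
  if (!any(p) || !any(g))
    stopUndefinedMetric(sprintf(
      "surface distance undefined for %s: %s mask is empty", structure,
      if (!any(p)) "predicted" else "ground-truth"))
  list(P = surfacePoints(p), G = surfacePoints(g))
}

#' 95th-percentile Hausdorff distance
#'
#' Pools the two directed nearest-surface distance sets D(P->G) and
#' D(G->P) - for each surface voxel of one mask, the Euclidean distance to
#' the nearest surface voxel of the other - and takes the 95th percentile
#' of the pooled set (the same percentile convention as the PLD threshold,
#' \code{\link{pvQuantile}}). Symmetric in its arguments by construction of
#' the union; outlier-robust compared with the exact Hausdorff distance.
#' Distances are 3D Euclidean in voxel units.
#'
#' @param pred,truth \code{LabelVolume}s of identical dimensions, the
#'   structure non-empty in both.
#' @param structure \code{"PV"}, \code{"LA"} or \code{"PV_LA"}.
#' @param rule percentile convention.
#' @param mergeVein merge the confluent-vein label into PV (default TRUE).
#' @return HD95 in voxel units.
#' @seealso \code{\link{hausdorffDistance}} for the exact (100th-percentile
#'   max) variant.
#' @export
hd95 <- function(pred, truth, structure = c("PV", "LA", "PV_LA"),
                 rule = "linear", mergeVein = TRUE) {
  structure <- match.arg(structure)
  if (!identical(dim(pred), dim(truth)))
    stopValidation("shape mismatch between pred and truth")
  s <- surfacePair(pred, truth, structure, mergeVein)
  dPG <- nearestDistances(s$P, s$G)
  dGP <- nearestDistances(s$G, s$P)
  pvQuantile(c(dPG, dGP), 0.95, rule = rule)
}

#' Exact Hausdorff distance
#'
#' max( max_p min_g d(p, g), max_g min_p d(g, p) ) over the surface-voxel
#' sets; the outlier-sensitive upper envelope of which HD95 is the robust
#' variant (HD95 <= HD always).
#'
#' @inheritParams hd95
#' @return Hausdorff distance in voxel units.
#' @export
hausdorffDistance <- function(pred, truth, structure = c("PV", "LA", "PV_LA"),
                              mergeVein = TRUE) {
  structure <- match.arg(structure)
  s <- surfacePair(pred, truth, structure, mergeVein)
  max(max(nearestDistances(s$P, s$G)), max(nearestDistances(s$G, s$P)))
}

#' Evaluate one predicted volume against its ground truth
#'
#' Dice and HD95 for PV, LA and the PV-LA aggregate of one volume pair.
#' Undefined metrics (empty structure masks) are flagged per structure via
#' NA and a note; they do not abort the evaluation.
#'
#' @param pred,truth \code{LabelVolume}s of identical dimensions.
#' @param rule percentile convention for HD95.
#' @param mergeVein merge the confluent-vein label into PV (default TRUE).
#' @return data.frame with one row per structure: case_id, video_id,
#'   structure, dice, hd95, tp, fp, fn, note.
#' @export
evaluatePair <- function(pred, truth, rule = "linear", mergeVein = TRUE) {
  if (!identical(dim(pred), dim(truth)))
    stopValidation("shape mismatch between pred and truth")
  rows <- lapply(c("PV", "LA", "PV_LA"), function(structure) {
    note <- ""
    dc <- tryCatch(diceCoefficient(pred, truth, structure, mergeVein),
                   pvlaUndefinedMetricError = function(e) e)
    if (inherits(dc, "error")) {
      note <- conditionMessage(dc)
      dc <- list(dice = NA_real_, tp = NA_integer_, fp = NA_integer_,
                 fn = NA_integer_)
    }
    h <- tryCatch(hd95(pred, truth, structure, rule, mergeVein),
                  pvlaUndefinedMetricError = function(e) e)
    if (inherits(h, "error")) {
      note <- paste(note, conditionMessage(h), sep = if (nzchar(note)) "; " else "")
      h <- NA_real_
    }
    data.frame(case_id = caseId(truth), video_id = videoId(truth),
               structure = structure, dice = dc$dice, hd95 = h,
               tp = dc$tp, fp = dc$fp, fn = dc$fn, note = note,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Evaluate a prediction cohort against a ground-truth cohort
#'
#' Matches prediction rows to ground-truth rows by (case_id, video_id),
#' reads the volumes, and runs \code{\link{evaluatePair}} per pair.
#'
#' @param predCohort,truthCohort cohort data.frames (\code{\link{loadCohort}}).
#' @param rule,mergeVein passed to \code{\link{evaluatePair}}.
#' @return Per-video metric data.frame with model_name and group attached.
#' @export
evaluateCohort <- function(predCohort, truthCohort, rule = "linear",
                           mergeVein = TRUE) {
  pk <- paste(predCohort$case_id, predCohort$video_id)
  tk <- paste(truthCohort$case_id, truthCohort$video_id)
  orphans <- setdiff(pk, tk)
  if (length(orphans))
    stopValidation(paste0("prediction rows without ground truth: ",
                          paste(orphans, collapse = ", ")))
  if (!length(pk))
    stopValidation("empty prediction cohort")
  out <- list()
  for (i in seq_along(pk)) {
    predRec <- predCohort[i, ]
    truthRec <- truthCohort[match(pk[i], tk), ]
    pred <- readLabelVolume(predRec$volume_path, caseId = predRec$case_id,
                            videoId = predRec$video_id)
    truth <- readLabelVolume(truthRec$volume_path, caseId = truthRec$case_id,
                             videoId = truthRec$video_id)
    m <- evaluatePair(pred, truth, rule = rule, mergeVein = mergeVein)
    m$model_name <- predRec$model_name
    m$group <- truthRec$group
    out[[i]] <- m
  }
  do.call(rbind, out)
}

#' Group-level metric summary
#'
#' Per (model, group, structure) mean Dice (mDice) and mean HD95 across
#' videos. Two mDice variants are reported and labeled distinctly: rows
#' with structure \code{"PV_LA"} are computed on the aggregate (union)
#' mask, and rows with structure \code{"PV_LA_structure_mean"} average the
#' per-video PV and LA Dice values.
#'
#' @param metrics per-video data.frame from \code{\link{evaluateCohort}}.
#' @return Summary data.frame: model_name, group, structure, m_dice,
#'   mean_hd95, n_videos.
#' @export
summarizeMetrics <- function(metrics) {
  base <- metrics
  sm <- base[base$structure %in% c("PV", "LA"), ]
  if (nrow(sm)) {
    agg <- stats::aggregate(cbind(dice, hd95) ~ case_id + video_id +
                              model_name + group, data = sm, FUN = mean,
                            na.action = stats::na.pass)
    agg$structure <- "PV_LA_structure_mean"
    agg <- agg[, c("case_id", "video_id", "structure", "dice", "hd95",
                   "model_name", "group")]
    base <- rbind(base[, names(agg)], agg)
  }
  out <- stats::aggregate(cbind(dice, hd95) ~ model_name + group + structure,
                          data = base, na.action = stats::na.pass,
                          FUN = function(x) mean(x, na.rm = TRUE))
  n <- stats::aggregate(dice ~ model_name + group + structure, data = base,
                        FUN = length, na.action = stats::na.pass)
  names(out)[names(out) == "dice"] <- "m_dice"
  names(out)[names(out) == "hd95"] <- "mean_hd95"
  out$n_videos <- n$dice
  out[order(out$model_name, out$group, out$structure), ]
}
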