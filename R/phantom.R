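#' @include AllClasses.R mask_io.R indices.R
NULL

#' Phantom configuration
#'
#' Parameters of one synthetic label volume emulating the mask geometry the
#' PV-LA indices assume: a compact LA blob (filled ellipse) present in every
#' slice, and a thin elongated PV bar present in a central band of
#' \code{sharedSlices} slices. The bar's moment major axis runs along the
#' slice column direction; the LA centroid is placed at bearing
#' \code{angle} degrees from that axis, so the generated volume realizes
#' the configured per-slice folded angle. The LA's nearest pixel to the PV
#' sits at distance \code{gap + 1}: \code{gap = 0} means touching
#' (edge-adjacent pixels, the normal PV-LA connection), positive gaps
#' emulate the diverged PV of TAPVC. \code{vein = TRUE} adds a disjoint
#' confluent-vein blob (label 3) coaxially extending the PV on the side
#' away from the LA - the common venous channel the PVs drain into in
#' TAPVC. With a vein present the gap and angle are realized for the merged
#' PV-class structure (vein merged into PV), matching how the indices read
#' the labels by default.
#'
#' @param shape (depth, height, width) in voxels.
#' @param laRadii (row, col) semi-axes of the LA ellipse, px.
#' @param pvLength,pvThickness bar extent along columns / rows, px
#'   (thickness < length so the major axis is well defined).
#' @param gap target PV-LA separation beyond adjacency, px >= 0.
#' @param angle target per-slice folded angle, degrees in [0, 90].
#' @param sharedSlices number of slices containing both structures.
#' @param laCenter optional fixed (row, col) LA center; default centered
#'   placement.
#' @param vein add a confluent-vein blob behind the LA.
#' @param jitterSd boundary-noise scale, px; 0 (default) is the exact-
#'   geometry mode. Boundary voxels are flipped with the probability that
#'   |N(0, jitterSd)| exceeds half a pixel, so the expected geometry is
#'   unbiased.
#' @param seed RNG seed; identical config + seed gives voxel-identical
#'   output.
#' @return Validated config object of class \code{pvlaPhantomConfig}.
#' @export
phantomConfig <- function(shape = c(16L, 96L, 96L), laRadii = c(10, 13),
                          pvLength = 13L, pvThickness = 3L, gap = 0,
                          angle = 0, sharedSlices = 8L, laCenter = NULL,
                          vein = FALSE, jitterSd = 0, seed = 1L) {
  cfg <- list(shape = as.integer(shape), laRadii = laRadii,
              pvLength = as.integer(pvLength),
              pvThickness = as.integer(pvThickness), gap = gap,
              angle = angle, sharedSlices = as.integer(sharedSlices),
              laCenter = laCenter, vein = isTRUE(vein), jitterSd = jitterSd,
              seed = as.integer(seed))
  class(cfg) <- "pvlaPhantomConfig"
  validatePhantomConfig(cfg)
  cfg
}

validatePhantomConfig <- function(cfg) {
  if (length(cfg$shape) != 3L || any(cfg$shape < 1L))
    stopConfig("shape must be three positive extents (depth, height, width)")
  if (cfg$sharedSlices < 1L || cfg$sharedSlices > cfg$shape[1L])
    stopConfig(sprintf("sharedSlices (%d) must lie in 1..depth (%d)",
                       cfg$sharedSlices, cfg$shape[1L]))
  if (cfg$gap < 0) stopConfig("gap must be >= 0")
  if (cfg$angle < 0 || cfg$angle > 90)
    stopConfig("angle must lie in [0, 90] degrees")
  if (cfg$pvThickness >= cfg$pvLength)
    stopConfig("pvThickness must be smaller than pvLength (the bar must be elongated)")
  if (cfg$pvThickness < 1L) stopConfig("pvThickness must be >= 1")
  if (any(cfg$laRadii < 1)) stopConfig("laRadii must be >= 1 px")
  if (cfg$jitterSd < 0) stopConfig("jitterSd must be >= 0")
  invisible(TRUE)
}

## filled-ellipse pixel offsets about (0, 0); symmetric, so the centroid is
## exactly the center
ellipseOffsets <- function(radii) {
  a <- radii[1L]; b <- radii[2L]
  r <- seq(-floor(a), floor(a))
  c_ <- seq(-floor(b), floor(b))
  g <- expand.grid(row = r, col = c_)
  g <- g[(g$row / a)^2 + (g$col / b)^2 <= 1 + 1e-12, ]
  as.matrix(g)
}

## bar pixel offsets about its centroid (thickness rows x length cols)
barOffsets <- function(thickness, len) {
  r <- seq_len(thickness) - (thickness + 1) / 2
  c_ <- seq_len(len) - (len + 1) / 2
  as.matrix(expand.grid(row = r, col = c_))
}

minPairDistance <- function(a, b) {
  dr <- outer(a[, 1L], b[, 1L], "-")
  dc <- outer(a[, 2L], b[, 2L], "-")
  sqrt(min(dr * dr + dc * dc))
}

## confluent-vein pixel offsets in the bar-center frame: an elongated blob
## coaxial with the PV bar, extending it on the side away from the LA, so
## the merged PV+vein structure keeps the bar's major axis exactly (both
## pieces are symmetric about the bar's center row)
veinOffsets <- function(cfg) {
  if (!cfg$vein) return(NULL)
  vr <- c(max(1, (cfg$pvThickness - 1) / 2 + 1),
          max(2, round(cfg$pvLength / 3)))
  vell <- ellipseOffsets(vr)
  shift <- -((cfg$pvLength - 1) / 2 + 2 + max(vell[, 2L]))
  sweep(vell, 2L, c(0, shift), "+")
}

## pixel set of the PV-class structure (bar plus optional vein) about the
## bar center, and its centroid in that frame
pvClassOffsets <- function(cfg) {
  pvSet <- rbind(barOffsets(cfg$pvThickness, cfg$pvLength), veinOffsets(cfg))
  list(pixels = pvSet, centroid = colMeans(pvSet))
}

## choose the integer LA-center offset v (relative to the PV bar center)
## whose nearest-pixel distance to the PV-class structure best matches
## gap + 1 and whose bearing from the structure's centroid best matches the
## target angle; lexicographic and therefore deterministic
placeLA <- function(cfg) {
  target <- cfg$gap + 1
  u <- c(sin(cfg$angle * pi / 180), cos(cfg$angle * pi / 180))  # (row, col)
  pv <- pvClassOffsets(cfg)
  ell <- ellipseOffsets(cfg$laRadii)
  reachPv <- max(sweep(pv$pixels, 2L, pv$centroid) %*% u)
  reachEll <- max(ell %*% (-u))
  l0 <- target + reachPv + reachEll
  v0 <- round(pv$centroid + l0 * u)
  best <- NULL
  for (dr in -6:6) for (dc in -6:6) {
    v <- v0 + c(dr, dc)
    d <- minPairDistance(pv$pixels, sweep(ell, 2L, v, "+"))
    w <- v - pv$centroid               # centroid-to-centroid bearing
    nw <- sqrt(sum(w^2))
    if (nw < 1e-9) next
    cosT <- min(1, max(-1, w[2L] / nw))
    bearing <- acos(abs(cosT)) * 180 / pi  # folded angle vs the column axis
    ## gap = 0 must realize exact edge adjacency (min distance 1); positive
    ## gaps are binned to +/- 0.45 px so the bearing decides within the band
    gapScore <- if (cfg$gap == 0) round(abs(d - 1), 9)
                else floor(abs(d - target) / 0.45 + 1e-9)
    score <- c(gapScore, abs(bearing - cfg$angle), v[1L], v[2L])
    if (is.null(best) || lexLess(score, best$score))
      best <- list(v = v, d = d, bearing = bearing, score = score)
  }
  best
}

lexLess <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i] - 1e-12) return(TRUE)
    if (a[i] > b[i] + 1e-12) return(FALSE)
  }
  FALSE
}

#' Generate a synthetic label volume
#'
#' Draws the geometry described in \code{\link{phantomConfig}} into a
#' \code{LabelVolume}: LA in every depth slice, PV in the central shared
#' band, optional confluent vein behind the LA. With \code{jitterSd = 0}
#' the construction is exact: \code{gap = 0} yields at least one
#' edge-adjacent PV/LA pixel pair in every shared slice (PLD = 1.00 at
#' q = 100), and the realized per-slice angle matches \code{angle} up to
#' integer-grid discretization of the centroid offset.
#'
#' @param config a \code{\link{phantomConfig}}.
#' @param caseId,videoId identifiers for the volume.
#' @return A \code{LabelVolume}.
#' @examples
#' v <- generatePhantom(phantomConfig(gap = 5, angle = 45, seed = 7))
#' v
#' @export
generatePhantom <- function(config, caseId = "phantom", videoId = "v1") {
  validatePhantomConfig(config)
  canon <- canonicalLabels()
  d <- config$shape
  pl <- placeLA(config)
  bar <- barOffsets(config$pvThickness, config$pvLength)
  ell <- ellipseOffsets(config$laRadii)
  if (is.null(config$laCenter)) {
    mid <- c((d[2L] + 1) / 2, (d[3L] + 1) / 2)
    pvC <- round(mid - pl$v / 2)
    laC <- pvC + pl$v
  } else {
    laC <- round(config$laCenter)
    pvC <- laC - pl$v
  }
  ## the bar centroid may be half-integer (even extents); snap its top-left
  barPix <- sweep(bar, 2L, pvC, "+")
  if (any(abs(barPix - round(barPix)) > 1e-9))
    barPix <- floor(barPix + 0.5)
  laPix <- sweep(ell, 2L, laC, "+")
  checkExtent <- function(pix, what) {
    if (any(pix[, 1L] < 1 | pix[, 1L] > d[2L]))
      stopConfig(sprintf("%s exceeds the height extent (rows %d..%d vs 1..%d)",
                         what, min(pix[, 1L]), max(pix[, 1L]), d[2L]))
    if (any(pix[, 2L] < 1 | pix[, 2L] > d[3L]))
      stopConfig(sprintf("%s exceeds the width extent (cols %d..%d vs 1..%d)",
                         what, min(pix[, 2L]), max(pix[, 2L]), d[3L]))
  }
  checkExtent(barPix, "PV bar")
  checkExtent(laPix, "LA ellipse")
  veinPix <- NULL
  if (config$vein) {
    veinPix <- sweep(veinOffsets(config), 2L, pvC, "+")
    checkExtent(veinPix, "confluent vein")
  }
  vol <- array(0L, dim = d)
  k0 <- floor((d[1L] - config$sharedSlices) / 2)
  sharedK <- seq_len(config$sharedSlices) + k0
  fill <- function(k, pix, lab) {
    vol[cbind(k, pix[, 1L], pix[, 2L])] <<- lab
  }
  for (k in seq_len(d[1L])) fill(k, laPix, canon[["LA"]])
  for (k in sharedK) {
    fill(k, barPix, canon[["PV"]])
    if (!is.null(veinPix)) fill(k, veinPix, canon[["VEIN"]])
  }
  if (config$jitterSd > 0)
    vol <- applyJitter(vol, config, sharedK)
  LabelVolume(vol, caseId = caseId, videoId = videoId)
}

## boundary-voxel coin flips: remove boundary pixels of PV/LA and add
## background pixels adjacent to them, each with probability
## P(|N(0, sd)| > 0.5); in-plane 4-neighborhood, exclusivity preserved
applyJitter <- function(vol, config, sharedK) {
  p <- 2 * stats::pnorm(0.5, 0, config$jitterSd, lower.tail = FALSE)
  set.seed(config$seed)
  canon <- canonicalLabels()
  d <- dim(vol)
  nb <- rbind(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  for (k in seq_len(d[1L])) {
    sl <- vol[k, , ]
    for (lab in c(canon[["LA"]], canon[["PV"]])) {
      pix <- which(sl == lab, arr.ind = TRUE)
      if (!nrow(pix)) next
      inSet <- function(m) {
        ok <- m[, 1L] >= 1 & m[, 1L] <= d[2L] & m[, 2L] >= 1 & m[, 2L] <= d[3L]
        r <- logical(nrow(m)); r[ok] <- sl[m[ok, , drop = FALSE]] == lab
        r
      }
      onBoundary <- rep(FALSE, nrow(pix))
      addCand <- NULL
      for (i in seq_len(4L)) {
        sh <- sweep(pix, 2L, nb[i, ], "+")
        onBoundary <- onBoundary | !inSet(sh)
        ok <- sh[, 1L] >= 1 & sh[, 1L] <= d[2L] & sh[, 2L] >= 1 & sh[, 2L] <= d[3L]
        sh <- sh[ok, , drop = FALSE]
        addCand <- rbind(addCand, sh[sl[sh] == 0L, , drop = FALSE])
      }
      addCand <- unique(addCand)
      rm_ <- which(onBoundary)[stats::runif(sum(onBoundary)) < p]
      if (length(rm_) < nrow(pix))  # never empty the structure
        sl[pix[rm_, , drop = FALSE]] <- 0L
      if (nrow(addCand)) {
        add <- addCand[stats::runif(nrow(addCand)) < p, , drop = FALSE]
        sl[add[sl[add] == 0L, , drop = FALSE]] <- lab
      }
    }
    vol[k, , ] <- sl
  }
  vol
}

#' Cohort specification for synthetic data
#'
#' Describes a two-group synthetic cohort. Per-video gap and angle are drawn
#' from stated distribution families per group. The defaults emulate the
#' clinical geometry: normal videos have gap 0 (PV joins the LA; index value
#' 1.00) with angles around 37.8 +/- 7.72 degrees, TAPVC videos have
#' positive gaps around 1.64 +/- 0.667 px (index values around 2.64) with
#' angles around 55.1 +/- 14.5 degrees; 6 cases x 2 sweep videos per group.
#' Distributions: \code{list(dist = "const", value = )} or
#' \code{list(dist = "norm", mean = , sd = , min = , max = )} (truncated by
#' resampling).
#'
#' @param nNormal,nTapvc cases per group.
#' @param videosPerCase sweep videos per case.
#' @param normalGap,normalAngle,tapvcGap,tapvcAngle distribution specs.
#' @param shape,sharedSlices,jitterSd shared volume geometry.
#' @param vein add a confluent vein to TAPVC volumes (default TRUE).
#' @param seed master seed; per-video seeds are derived from it
#'   deterministically.
#' @return Object of class \code{pvlaCohortSpec}.
#' @export
cohortSpec <- function(nNormal = 6L, nTapvc = 6L, videosPerCase = 2L,
                       normalGap = list(dist = "const", value = 0),
                       normalAngle = list(dist = "norm", mean = 37.8,
                                          sd = 7.72, min = 0, max = 90),
                       tapvcGap = list(dist = "norm", mean = 1.64,
                                       sd = 0.667, min = 0.3, max = 12),
                       tapvcAngle = list(dist = "norm", mean = 55.1,
                                         sd = 14.5, min = 0, max = 90),
                       shape = c(16L, 96L, 96L), sharedSlices = 8L,
                       jitterSd = 0, vein = TRUE, seed = 20260101L) {
  spec <- list(nNormal = as.integer(nNormal), nTapvc = as.integer(nTapvc),
               videosPerCase = as.integer(videosPerCase),
               normalGap = normalGap, normalAngle = normalAngle,
               tapvcGap = tapvcGap, tapvcAngle = tapvcAngle,
               shape = as.integer(shape),
               sharedSlices = as.integer(sharedSlices),
               jitterSd = jitterSd, vein = isTRUE(vein),
               seed = as.integer(seed))
  if (spec$nNormal < 1L || spec$nTapvc < 1L)
    stopConfig("both groups need at least one case")
  class(spec) <- "pvlaCohortSpec"
  spec
}

drawDist <- function(d, n) {
  if (d$dist == "const") return(rep(d$value, n))
  if (d$dist != "norm") stopConfig(sprintf("unknown distribution '%s'", d$dist))
  x <- stats::rnorm(n, d$mean, d$sd)
  for (i in seq_len(100L)) {
    out <- x < d$min | x > d$max
    if (!any(out)) break
    x[out] <- stats::rnorm(sum(out), d$mean, d$sd)
  }
  pmin(pmax(x, d$min), d$max)
}

#' Generate a synthetic cohort
#'
#' Draws per-video gap/angle parameters per group, generates one phantom
#' volume per video, and (optionally) writes the volumes as NIfTI plus the
#' cohort CSV consumed by \code{\link{loadCohort}}. Fully deterministic for
#' a fixed spec: per-video seeds are derived from the master seed.
#'
#' @param spec a \code{\link{cohortSpec}}.
#' @param outDir if non-NULL, write volumes and \code{cohort.csv} there.
#' @return List with \code{volumes} (list of LabelVolume), \code{cohort}
#'   (data.frame in the cohort-table schema, with \code{volume_path} when
#'   written), and \code{params} (per-video gap/angle actually drawn).
#' @export
generateCohort <- function(spec, outDir = NULL) {
  stopifnot(inherits(spec, "pvlaCohortSpec"))
  nVid <- (spec$nNormal + spec$nTapvc) * spec$videosPerCase
  set.seed(spec$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, nVid)
  gaps <- c(drawDist(spec$normalGap, spec$nNormal * spec$videosPerCase),
            drawDist(spec$tapvcGap, spec$nTapvc * spec$videosPerCase))
  angles <- c(drawDist(spec$normalAngle, spec$nNormal * spec$videosPerCase),
              drawDist(spec$tapvcAngle, spec$nTapvc * spec$videosPerCase))
  groups <- rep(c("normal", "TAPVC"),
                c(spec$nNormal, spec$nTapvc) * spec$videosPerCase)
  caseIdx <- c(rep(seq_len(spec$nNormal), each = spec$videosPerCase),
               rep(seq_len(spec$nTapvc), each = spec$videosPerCase))
  caseIds <- ifelse(groups == "normal", sprintf("normal%02d", caseIdx),
                    sprintf("tapvc%02d", caseIdx))
  videoIds <- rep(sprintf("v%d", seq_len(spec$videosPerCase)),
                  times = spec$nNormal + spec$nTapvc)
  volumes <- vector("list", nVid)
  for (i in seq_len(nVid)) {
    cfg <- phantomConfig(shape = spec$shape, gap = gaps[i], angle = angles[i],
                         sharedSlices = spec$sharedSlices,
                         jitterSd = spec$jitterSd,
                         vein = spec$vein && groups[i] == "TAPVC",
                         seed = seeds[i])
    volumes[[i]] <- generatePhantom(cfg, caseId = caseIds[i],
                                    videoId = videoIds[i])
  }
  cohort <- data.frame(case_id = caseIds, video_id = videoIds,
                       volume_ref = sprintf("%s_%s.nii.gz", caseIds, videoIds),
                       group = groups, role = "ground_truth",
                       model_name = "", stringsAsFactors = FALSE)
  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    for (i in seq_len(nVid))
      writeLabelVolume(volumes[[i]], file.path(outDir, cohort$volume_ref[i]))
    utils::write.csv(cohort, file.path(outDir, "cohort.csv"),
                     row.names = FALSE)
    cohort$volume_path <- file.path(normalizePath(outDir), cohort$volume_ref)
  }
  list(volumes = volumes, cohort = cohort,
       params = data.frame(case_id = caseIds, video_id = videoIds,
                           group = groups, gap = gaps, angle = angles,
                           seed = seeds))
}

#' Degrade one structure of a volume
#'
#' Deterministic, seeded perturbations standing in for imperfect model
#' predictions: in-plane erosion or dilation (4-neighborhood, one layer per
#' magnitude step), rigid in-plane translation, or dropping the structure
#' from randomly chosen slices. Label exclusivity is preserved (dilation
#' and translation never overwrite another structure). If the perturbation
#' empties the structure a warning is raised and the returned volume
#' carries \code{attr(, "emptyStructure") = TRUE}.
#'
#' @param volume a \code{LabelVolume}.
#' @param mode one of \code{"erode"}, \code{"dilate"}, \code{"translate"},
#'   \code{"drop_slices"}.
#' @param magnitude integer >= 1: layers, pixels, or slice count.
#' @param seed RNG seed (used by \code{drop_slices}).
#' @param structure which structure to degrade (default PV).
#' @param direction (row, col) unit step for \code{translate}; default
#'   \code{c(0, 1)}.
#' @return Perturbed \code{LabelVolume}.
#' @export
perturbMask <- function(volume, mode = c("erode", "dilate", "translate",
                                         "drop_slices"),
                        magnitude, seed = 1L, structure = "PV",
                        direction = c(0L, 1L)) {
  mode <- match.arg(mode)
  if (missing(magnitude) || !is.numeric(magnitude) || magnitude < 1)
    stopPrecondition("magnitude must be an integer >= 1")
  magnitude <- as.integer(magnitude)
  canon <- canonicalLabels()
  lab <- canon[[structure]]
  vol <- voxels(volume)
  d <- dim(vol)
  nb <- rbind(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  inB <- function(m) m[, 1L] >= 1 & m[, 1L] <= d[2L] &
    m[, 2L] >= 1 & m[, 2L] <= d[3L]
  if (mode == "drop_slices") {
    set.seed(seed)
    ks <- which(apply(vol == lab, 1L, any))
    drop <- ks[sample.int(length(ks), min(magnitude, length(ks)))]
    for (k in drop) { sl <- vol[k, , ]; sl[sl == lab] <- 0L; vol[k, , ] <- sl }
  } else {
    for (k in seq_len(d[1L])) {
      sl <- vol[k, , ]
      pix <- which(sl == lab, arr.ind = TRUE)
      if (!nrow(pix)) next
      if (mode == "translate") {
        sl[pix] <- 0L
        np <- sweep(pix, 2L, as.integer(direction) * magnitude, "+")
        np <- np[inB(np), , drop = FALSE]
        np <- np[sl[np] == 0L, , drop = FALSE]  # never overwrite other labels
        if (nrow(np)) sl[np] <- lab
      } else {
        for (step in seq_len(magnitude)) {
          pix <- which(sl == lab, arr.ind = TRUE)
          if (!nrow(pix)) break
          if (mode == "erode") {
            boundary <- rep(FALSE, nrow(pix))
            for (i in seq_len(4L)) {
              sh <- sweep(pix, 2L, nb[i, ], "+")
              ok <- inB(sh)
              nbIn <- logical(nrow(pix))
              nbIn[ok] <- sl[sh[ok, , drop = FALSE]] == lab
              boundary <- boundary | !nbIn
            }
            sl[pix[boundary, , drop = FALSE]] <- 0L
          } else {
            for (i in seq_len(4L)) {
              sh <- sweep(pix, 2L, nb[i, ], "+")
              sh <- sh[inB(sh), , drop = FALSE]
              sh <- sh[sl[sh] == 0L, , drop = FALSE]
              if (nrow(sh)) sl[sh] <- lab
            }
          }
        }
      }
      vol[k, , ] <- sl
    }
  }
  out <- LabelVolume(vol, labelMap = labelMap(volume),
                     caseId = caseId(volume), videoId = videoId(volume))
  if (!any(vol == lab)) {
    warning(sprintf("perturbation '%s' emptied structure %s", mode, structure))
    attr(out, "emptyStructure") <- TRUE
  }
  out
}
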