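#' @include conditions.R
NULL

#' Canonical label encoding
#'
#' Label volumes use a fixed integer alphabet: 0 background, 1 left atrium
#' (LA), 2 pulmonary vein (PV), 3 confluent vein (the abnormal common venous
#' channel behind the LA seen in TAPVC). Exactly one label per voxel, so PV
#' and LA are mutually exclusive by construction.
#'
#' @return Named integer vector mapping structure names to label codes.
#' @examples
#' canonicalLabels()
#' @export
canonicalLabels <- function() {
  c(BACKGROUND = 0L, LA = 1L, PV = 2L, VEIN = 3L)
}

#' LabelVolume: a 3D labeled voxel grid
#'
#' S4 container for one segmentation label volume reconstructed from a 2D
#' sweep-scan ultrasound video. The voxel array uses axis order
#' (depth, height, width): depth is the sweep/time direction, so slice
#' \code{k} of the volume is frame \code{k} of the video. Values live in the
#' canonical label alphabet (see \code{\link{canonicalLabels}}); the
#' \code{labelMap} slot records which of the canonical labels this volume
#' declares.
#'
#' @slot voxels 3D integer array, dim = (depth, height, width).
#' @slot labelMap named integer vector; subset of \code{canonicalLabels()},
#'   always containing BACKGROUND = 0.
#' @slot caseId character scalar case identifier.
#' @slot videoId character scalar identifying the sweep/video within a case.
#' @slot sourcePath path the volume was read from ("" if built in memory).
#'
#' @seealso \code{\link{LabelVolume}} constructor,
#'   \code{\link{readLabelVolume}}, \code{\link{generatePhantom}}
#' @name LabelVolume-class
#' @aliases LabelVolume-class
#' @export
setClass("LabelVolume",
  representation(
    voxels = "array",
    labelMap = "integer",
    caseId = "character",
    videoId = "character",
    sourcePath = "character"
  )
)

setValidity("LabelVolume", function(object) {
  v <- object@voxels
  if (length(dim(v)) != 3L)
    return("voxels must be a 3D array (depth, height, width)")
  if (any(dim(v) < 1L))
    return("all dimensions must be >= 1")
  lm <- object@labelMap
  if (is.null(names(lm)) || any(!nzchar(names(lm))))
    return("labelMap must be named")
  if (!("BACKGROUND" %in% names(lm)) || lm[["BACKGROUND"]] != 0L)
    return("labelMap must contain BACKGROUND = 0")
  canon <- canonicalLabels()
  bad <- setdiff(names(lm), names(canon))
  if (length(bad))
    return(paste0("unknown structure name(s) in labelMap: ",
                  paste(bad, collapse = ", ")))
  if (any(lm != canon[names(lm)]))
    return("labelMap values must follow the canonical encoding")
  if (anyDuplicated(lm))
    return("labelMap values must be unique")
  out <- !(v %in% lm)
  if (any(out)) {
    i <- which(out)[1L]
    co <- arrayInd(i, dim(v))
    return(sprintf(
      "voxel value %s outside the declared label alphabet (first at depth=%d, row=%d, col=%d)",
      format(v[i]), co[1L], co[2L], co[3L]))
  }
  if (length(object@caseId) != 1L || is.na(object@caseId))
    return("caseId must be a single string")
  TRUE
})

#' Construct a LabelVolume
#'
#' @param voxels 3D integer array in (depth, height, width) order, values in
#'   the canonical label alphabet.
#' @param labelMap named integer vector of the labels the volume declares;
#'   defaults to the full canonical alphabet.
#' @param caseId,videoId identifiers; default "case"/"v1".
#' @param sourcePath provenance path, "" for in-memory volumes.
#' @return A validated \code{LabelVolume}.
#' @examples
#' v <- LabelVolume(array(0L, dim = c(3, 4, 4)))
#' dim(v)
#' @export
LabelVolume <- function(voxels, labelMap = canonicalLabels(),
                        caseId = "case", videoId = "v1", sourcePath = "") {
  storage.mode(voxels) <- "integer"
  lm <- as.integer(labelMap)
  names(lm) <- names(labelMap)
  if (!("BACKGROUND" %in% names(lm)))
    lm <- c(BACKGROUND = 0L, lm)
  methods::new("LabelVolume", voxels = voxels, labelMap = lm,
               caseId = as.character(caseId), videoId = as.character(videoId),
               sourcePath = as.character(sourcePath))
}

#' PLD result: PV-LA distance index for one volume
#'
#' @slot pld mean of the retained per-slice minimum PV-LA distances (pixels).
#' @slot q bottom-percentage retained (percent, (0, 100]).
#' @slot tQ the bottom-q\% quantile threshold on the distance set (pixels).
#' @slot percentileRule name of the percentile convention used.
#' @slot distances data.frame with columns \code{k} (1-based slice index) and
#'   \code{d} (minimum distance, pixels) for every shared slice.
#' @slot nUsed number of slices retained in the quantile subset.
#' @slot caseId,videoId provenance.
#' @name PLDResult-class
#' @export
setClass("PLDResult",
  representation(pld = "numeric", q = "numeric", tQ = "numeric",
                 percentileRule = "character", distances = "data.frame",
                 nUsed = "integer", caseId = "character",
                 videoId = "character"))

setValidity("PLDResult", function(object) {
  if (object@pld < 1 - 1e-12)
    return("PLD must be >= 1 (disjoint integer-grid structures)")
  if (object@nUsed < 1L) return("nUsed must be >= 1")
  if (object@q <= 0 || object@q > 100) return("q must be in (0, 100]")
  TRUE
})

#' PLA result: PV-LA angle index for one volume
#'
#' @slot pla mean folded angle over non-degenerate shared slices (degrees).
#' @slot angles data.frame with columns \code{k} (1-based) and \code{theta}
#'   (folded angle, degrees in [0, 90]).
#' @slot nUsed number of slices contributing to the mean.
#' @slot excluded data.frame (k, reason) of degenerate shared slices.
#' @slot caseId,videoId provenance.
#' @name PLAResult-class
#' @export
setClass("PLAResult",
  representation(pla = "numeric", angles = "data.frame", nUsed = "integer",
                 excluded = "data.frame", caseId = "character",
                 videoId = "character"))

setValidity("PLAResult", function(object) {
  th <- object@angles$theta
  if (length(th) && (any(th < -1e-9) || any(th > 90 + 1e-9)))
    return("all folded angles must lie in [0, 90] degrees")
  if (object@pla < -1e-9 || object@pla > 90 + 1e-9)
    return("PLA must lie in [0, 90] degrees")
  TRUE
})

setMethod("show", "LabelVolume", function(object) {
  d <- dim(object@voxels)
  cnt <- table(factor(object@voxels, levels = object@labelMap,
                      labels = names(object@labelMap)))
  cat(sprintf("LabelVolume '%s' (video %s): %d x %d x %d (depth x height x width)\n",
              object@caseId, object@videoId, d[1L], d[2L], d[3L]))
  cat("  voxels per label: ",
      paste(sprintf("%s=%d", names(cnt), as.integer(cnt)), collapse = ", "),
      "\n", sep = "")
  if (nzchar(object@sourcePath))
    cat("  source: ", object@sourcePath, "\n", sep = "")
})

setMethod("show", "PLDResult", function(object) {
  cat(sprintf("PLD = %.4f px  (case %s/%s; q = %g%%, rule = %s, t_q = %.4f, slices used = %d/%d)\n",
              object@pld, object@caseId, object@videoId, object@q,
              object@percentileRule, object@tQ, object@nUsed,
              nrow(object@distances)))
})

setMethod("show", "PLAResult", function(object) {
  cat(sprintf("PLA = %.3f deg  (case %s/%s; slices used = %d, degenerate = %d)\n",
              object@pla, object@caseId, object@videoId, object@nUsed,
              nrow(object@excluded)))
})

#' @describeIn LabelVolume-class dimensions (depth, height, width)
#' @param x a LabelVolume
#' @export
setMethod("dim", "LabelVolume", function(x) dim(x@voxels))
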