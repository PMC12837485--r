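#' @include AllClasses.R
NULL

## default file-value -> structure mapping (identical to the canonical codes)
defaultFileLabels <- function() c(LA = 1L, PV = 2L, VEIN = 3L)

#' Read a labeled 3D volume
#'
#' Reads a segmentation label volume from either a NIfTI file
#' (\code{.nii}/\code{.nii.gz}) or a directory of equally sized 8-bit
#' grayscale PNG slices ordered by filename (slice index = depth index).
#' Voxel values are remapped from the file's label values to the canonical
#' alphabet (0 background, 1 LA, 2 PV, 3 confluent vein). Any voxel whose
#' value is neither 0 nor listed in \code{fileLabels} raises a validation
#' error naming the value and its first coordinate.
#'
#' For NIfTI input the file's slowest-varying axis is taken as depth (the
#' sweep/time direction); \code{axes} overrides this for volumes stored
#' otherwise.
#'
#' @param path NIfTI file or slice-image directory.
#' @param fileLabels named integer vector mapping structure names (LA, PV,
#'   VEIN) to the values they carry in the file.
#' @param axes length-3 integer: which file axis supplies (depth, height,
#'   width). Default \code{c(3, 2, 1)}. NIfTI only.
#' @param caseId,videoId identifiers attached to the volume; default derived
#'   from the file name.
#' @return A \code{\link{LabelVolume}}.
#' @seealso \code{\link{writeLabelVolume}}
#' @export
readLabelVolume <- function(path, fileLabels = defaultFileLabels(),
                            axes = c(3L, 2L, 1L),
                            caseId = NULL, videoId = "v1") {
  if (!file.exists(path))
    stopIO(sprintf("no such file or directory: %s", path))
  if (is.null(caseId))
    caseId <- sub("\\.nii(\\.gz)?$", "", basename(path))
  if (dir.exists(path)) {
    raw <- readSliceDirectory(path)
  } else {
    a <- as.array(RNifti::readNifti(path))
    d <- dim(a)
    if (is.null(d)) d <- length(a)
    if (length(d) < 3L)              # trailing singleton axes dropped on read
      dim(a) <- d <- c(d, rep(1L, 3L - length(d)))
    if (length(d) == 4L && d[4L] == 1L)
      a <- array(a, dim = d[1:3])
    if (length(dim(a)) != 3L)
      stopFormat(sprintf("expected a 3D volume, got %d dimensions in %s",
                         length(dim(a)), path))
    if (length(axes) != 3L || !setequal(axes, 1:3))
      stopValidation("axes must be a permutation of 1:3")
    raw <- aperm(a, as.integer(axes))
  }
  raw <- round(raw)
  storage.mode(raw) <- "integer"
  vox <- remapLabels(raw, fileLabels, path)
  lm <- canonicalLabels()[c("BACKGROUND", names(fileLabels))]
  LabelVolume(vox, labelMap = lm, caseId = caseId, videoId = videoId,
              sourcePath = normalizePath(path))
}

readSliceDirectory <- function(path) {
  files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
  if (!length(files))
    stopIO(sprintf("no .png slices found in directory %s", path))
  slices <- lapply(files, function(f) {
    im <- png::readPNG(f)
    if (length(dim(im)) == 3L) im <- im[, , 1L]  # collapse gray stored as RGB
    round(im * 255)
  })
  dims <- vapply(slices, dim, integer(2L))
  if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != dims[2L, 1L]))
    stopFormat(sprintf(
      "inconsistent slice dimensions in %s: first mismatch at %s",
      path, basename(files[which(colSums(dims != dims[, 1L]) > 0)[1L]])))
  vol <- array(0, dim = c(length(slices), dims[1L, 1L], dims[2L, 1L]))
  for (k in seq_along(slices)) vol[k, , ] <- slices[[k]]
  vol
}

remapLabels <- function(raw, fileLabels, path) {
  canon <- canonicalLabels()
  bad <- setdiff(names(fileLabels), setdiff(names(canon), "BACKGROUND"))
  if (length(bad))
    stopValidation(paste0("unknown structure name(s): ",
                          paste(bad, collapse = ", ")))
  known <- c(0L, as.integer(fileLabels))
  out <- !(raw %in% known)
  if (any(out)) {
    i <- which(out)[1L]
    co <- arrayInd(i, dim(raw))
    stopValidation(sprintf(
      "voxel value %d in %s is absent from the label map (first at depth=%d, row=%d, col=%d)",
      raw[i], path, co[1L], co[2L], co[3L]))
  }
  vox <- array(0L, dim = dim(raw))
  for (nm in names(fileLabels))
    vox[raw == fileLabels[[nm]]] <- canon[[nm]]
  vox
}

#' Write a labeled 3D volume
#'
#' Writes a \code{LabelVolume} in the canonical encoding, either as NIfTI
#' (path ending in \code{.nii} or \code{.nii.gz}) or as a directory of 8-bit
#' grayscale PNG slices (any other path). The round trip through
#' \code{\link{readLabelVolume}} is voxel-exact.
#'
#' @param volume a \code{LabelVolume}.
#' @param path output file (NIfTI) or directory (PNG slices).
#' @return \code{path}, invisibly.
#' @export
writeLabelVolume <- function(volume, path) {
  stopifnot(methods::is(volume, "LabelVolume"))
  if (!dir.exists(dirname(path)))
    stopIO(sprintf("parent directory does not exist: %s", dirname(path)))
  v <- voxels(volume)
  if (grepl("\\.nii(\\.gz)?$", path)) {
    a <- aperm(v, c(3L, 2L, 1L))  # (w, h, d): depth to the slowest axis
    RNifti::writeNifti(RNifti::asNifti(a, datatype = "uint8"), path)
  } else {
    if (!dir.exists(path)) dir.create(path)
    d <- dim(v)
    for (k in seq_len(d[1L])) {
      png::writePNG(v[k, , ] / 255,
                    file.path(path, sprintf("slice_%04d.png", k)))
    }
  }
  invisible(path)
}

#' Extract one structure as a binary mask
#'
#' Returns the logical 3D mask of a structure. \code{"PV_LA"} is the
#' aggregate foreground (PV plus LA). By default the confluent-vein label is
#' merged into PV, since in TAPVC cases the confluent vein is annotated as
#' the PV-class structure; \code{mergeVein = FALSE} keeps it separate.
#'
#' @param volume a \code{LabelVolume}.
#' @param structure one of \code{"PV"}, \code{"LA"}, \code{"PV_LA"},
#'   \code{"VEIN"}.
#' @param mergeVein merge label 3 (confluent vein) into PV (default TRUE).
#' @return Logical array with the volume's dimensions.
#' @export
structureMask <- function(volume, structure = c("PV", "LA", "PV_LA", "VEIN"),
                          mergeVein = TRUE) {
  structure <- match.arg(structure)
  v <- voxels(volume)
  canon <- canonicalLabels()
  pvVals <- canon[["PV"]]
  if (mergeVein) pvVals <- c(pvVals, canon[["VEIN"]])
  switch(structure,
    PV = array(v %in% pvVals, dim = dim(v)),
    LA = v == canon[["LA"]],
    VEIN = v == canon[["VEIN"]],
    PV_LA = array(v %in% c(pvVals, canon[["LA"]]), dim = dim(v))
  )
}

#' Load a cohort table
#'
#' Reads a CSV mapping label-volume files to cases and groups. Required
#' columns: \code{case_id}, \code{volume_ref}, \code{group} (normal or
#' TAPVC), \code{role} (ground_truth or prediction), \code{model_name}
#' (empty allowed for ground truth). An optional \code{video_id} column
#' distinguishes several sweep videos of one case; it defaults to "v1".
#' Relative \code{volume_ref} paths are resolved against the CSV's
#' directory; every referenced file must exist.
#'
#' @param tablePath path to the cohort CSV.
#' @param checkFiles verify that every volume_ref exists (default TRUE).
#' @return data.frame with the table's columns plus \code{volume_path}
#'   (resolved path).
#' @export
loadCohort <- function(tablePath, checkFiles = TRUE) {
  if (!file.exists(tablePath))
    stopIO(sprintf("cohort table not found: %s", tablePath))
  tab <- utils::read.csv(tablePath, stringsAsFactors = FALSE,
                         colClasses = "character")
  required <- c("case_id", "volume_ref", "group", "role", "model_name")
  miss <- setdiff(required, names(tab))
  if (length(miss))
    stopSchema(paste0("cohort table missing column(s): ",
                      paste(miss, collapse = ", ")))
  if (!("video_id" %in% names(tab))) tab$video_id <- "v1"
  tab$video_id[!nzchar(tab$video_id)] <- "v1"
  if (any(!nzchar(tab$case_id)))
    stopValidation("case_id must be non-empty in every row")
  badGroup <- setdiff(unique(tab$group), c("normal", "TAPVC"))
  if (length(badGroup))
    stopValidation(paste0("unknown group value(s): ",
                          paste(badGroup, collapse = ", ")))
  badRole <- setdiff(unique(tab$role), c("ground_truth", "prediction"))
  if (length(badRole))
    stopValidation(paste0("unknown role value(s): ",
                          paste(badRole, collapse = ", ")))
  key <- paste(tab$case_id, tab$video_id, tab$role, tab$model_name, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- tab$case_id[duplicated(key)]
    stopValidation(paste0("duplicate (case_id, video_id, role, model_name): ",
                          paste(unique(dup), collapse = ", ")))
  }
  base <- dirname(normalizePath(tablePath))
  tab$volume_path <- ifelse(grepl("^(/|[A-Za-z]:)", tab$volume_ref),
                            tab$volume_ref,
                            file.path(base, tab$volume_ref))
  if (checkFiles) {
    missing <- tab$volume_path[!file.exists(tab$volume_path)]
    if (length(missing))
      stopIO(paste0("missing volume file(s):\n  ",
                    paste(missing, collapse = "\n  ")))
  }
  tab
}
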