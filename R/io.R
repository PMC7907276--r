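# File round-tripping: multi-page grayscale TIFF for stacks and volumes
# (32-bit float, with a JSON sidecar carrying the intensity scaling and
# geometry), CSV for pose and track tables, JSON for poses and metrics.
# Every writer has a reader; write -> read -> write is byte-identical.

.sidecarPath <- function(path) paste0(path, ".json")

# write a list of matrices as a multi-page float TIFF with [min, max]
# recorded in the sidecar entries (TIFF payload is scaled to [0, 1])
.writePages <- function(pages, path, extra = list()) {
  lo <- min(vapply(pages, min, numeric(1L)))
  hi <- max(vapply(pages, max, numeric(1L)))
  scale <- if (hi > lo) hi - lo else 1
  # snap a negligible offset to zero so that write -> read -> write is
  # byte-identical (the offset would otherwise wobble at float precision)
  if (abs(lo) < 1e-9 * scale) {
    lo <- 0
    scale <- if (hi > 0) hi else 1
  }
  # the TIFF backend stores 32-bit unsigned integers by *flooring*
  # value * (2^32 - 1); passing grid-centre values (m + 0.5)/(2^32 - 1)
  # makes that quantisation exact and write -> read -> write idempotent
  a <- 4294967295
  tiff::writeTIFF(lapply(pages, function(p) {
    m <- floor(pmin(pmax((p - lo) / scale, 0), 1) * a)
    ifelse(m >= a, 1, (m + 0.5) / a)
  }), path, bits.per.sample = 32L, compression = "none")
  side <- c(list(intensity_min = lo, intensity_scale = scale), extra)
  jsonlite::write_json(side, .sidecarPath(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

.readPages <- function(path) {
  side <- jsonlite::read_json(.sidecarPath(path), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  # undo the backend's read convention (m / 2^32) and re-centre on the
  # write grid so a re-write stores identical pixel data
  a <- 4294967295
  pages <- lapply(pages, function(p) {
    m <- round(p * 4294967296)
    ifelse(m >= a, 1, (m + 0.5) / a) * side$intensity_scale +
      side$intensity_min
  })
  list(pages = pages, sidecar = side)
}

.cameraToList <- function(cam) {
  list(focal_length = focalLength(cam), pixel_pitch = pixelPitch(cam),
       principal_point = principalPoint(cam),
       image_size = imageSize(cam), standoff = standoff(cam))
}

.cameraFromList <- function(x) {
  cameraModel(x$focal_length, as.integer(x$image_size), x$pixel_pitch,
              as.numeric(x$principal_point), x$standoff)
}

#' Write / read a projection stack as multi-page TIFF
#'
#' Frames are stored as 32-bit float TIFF pages; the JSON sidecar
#' (\code{<path>.json}) records the intensity scaling and the camera.
#' Ground-truth poses and tracks, when present, are written alongside as
#' \code{<path>.poses.csv} and \code{<path>.tracks.csv}.
#'
#' @param stack a [ProjectionStack-class].
#' @param path output TIFF path.
#' @return \code{path}, invisibly (writer); a [ProjectionStack-class]
#'   (reader).
#' @export
writeProjectionStack <- function(stack, path) {
  stopifnot(is(stack, "ProjectionStack"))
  n <- nFrames(stack)
  .writePages(lapply(seq_len(n), function(k) stack@frames[, , k]), path,
              extra = list(kind = "projection_stack",
                           camera = .cameraToList(stack@camera)))
  if (length(stack@groundTruthPoses)) {
    writePoseTable(stack@groundTruthPoses, paste0(path, ".poses.csv"))
  }
  if (nrow(stack@groundTruthTracks)) {
    writeTrackTable(beadTrackTable(stack@groundTruthTracks, n),
                    paste0(path, ".tracks.csv"))
  }
  invisible(path)
}

#' @rdname writeProjectionStack
#' @export
readProjectionStack <- function(path) {
  x <- .readPages(path)
  cam <- .cameraFromList(x$sidecar$camera)
  H <- nrow(x$pages[[1L]]); W <- ncol(x$pages[[1L]])
  frames <- array(unlist(x$pages), dim = c(H, W, length(x$pages)))
  poses <- if (file.exists(paste0(path, ".poses.csv"))) {
    readPoseTable(paste0(path, ".poses.csv"))
  } else list()
  tracks <- if (file.exists(paste0(path, ".tracks.csv"))) {
    as.data.frame(readTrackTable(paste0(path, ".tracks.csv")))
  } else data.frame(frame = integer(), bead_id = integer(),
                    u = numeric(), v = numeric())
  new("ProjectionStack", frames = frames, camera = cam,
      groundTruthPoses = poses, groundTruthTracks = tracks)
}

#' Write / read a per-frame pose table as CSV
#'
#' Schema: \code{frame, r11..r33 (row-major), tx, ty, tz}; 0-based frames.
#'
#' @param poses list of [Pose-class] or a [PoseChain-class] (absolute poses).
#' @param file CSV path.
#' @return \code{file} invisibly (writer); list of [Pose-class] (reader).
#' @export
writePoseTable <- function(poses, file) {
  if (is(poses, "PoseChain")) poses <- absolutePoses(poses)
  rows <- lapply(seq_along(poses), function(k) {
    p <- poses[[k]]
    R <- rotation(p); tt <- translation(p)
    d <- data.frame(frame = k - 1L)
    for (i in 1:3) for (j in 1:3) d[[paste0("r", i, j)]] <- R[i, j]
    d$tx <- tt[1L]; d$ty <- tt[2L]; d$tz <- tt[3L]
    d
  })
  write.csv(do.call(rbind, rows), file, row.names = FALSE)
  invisible(file)
}

#' @rdname writePoseTable
#' @export
readPoseTable <- function(file) {
  d <- read.csv(file)
  lapply(seq_len(nrow(d)), function(k) {
    R <- matrix(as.numeric(d[k, paste0("r", c("11", "12", "13", "21", "22",
                                              "23", "31", "32", "33"))]),
                3L, 3L, byrow = TRUE)
    pose(orthonormalize(R), as.numeric(d[k, c("tx", "ty", "tz")]))
  })
}

#' Serialize a pose to / from JSON (4x4 row-major homogeneous matrix)
#'
#' @param p a [Pose-class].
#' @param file JSON path.
#' @return \code{file} invisibly (writer); a [Pose-class] (reader).
#' @export
writePoseJSON <- function(p, file) {
  m <- asHomogeneous(p)
  jsonlite::write_json(list(homogeneous_row_major = as.numeric(t(m))),
                       file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname writePoseJSON
#' @export
readPoseJSON <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  m <- matrix(x$homogeneous_row_major, 4L, 4L, byrow = TRUE)
  p <- poseFromMatrix(m)
  pose(orthonormalize(rotation(p)), translation(p))
}

#' Write / read a bead track table as CSV
#'
#' Schema: \code{frame, bead_id, u, v}; 0-based frames, floating-point
#' pixel coordinates.
#'
#' @param table a [BeadTrackTable-class].
#' @param file CSV path.
#' @param nFrames frame count override for the reader.
#' @return \code{file} invisibly (writer); a [BeadTrackTable-class] (reader).
#' @export
writeTrackTable <- function(table, file) {
  stopifnot(is(table, "BeadTrackTable"))
  write.csv(table@tracks[, c("frame", "bead_id", "u", "v")], file,
            row.names = FALSE)
  invisible(file)
}

#' @rdname writeTrackTable
#' @export
readTrackTable <- function(file, nFrames = NULL) {
  beadTrackTable(read.csv(file), nFrames = nFrames)
}

#' Write / read a sinogram (TIFF + JSON sidecar)
#'
#' The sidecar records the nominal angles and the source image row.
#'
#' @param sino a [Sinogram-class].
#' @param path TIFF path.
#' @return \code{path} invisibly (writer); a [Sinogram-class] (reader).
#' @export
writeSinogram <- function(sino, path) {
  stopifnot(is(sino, "Sinogram"))
  .writePages(list(sino@rows), path,
              extra = list(kind = "sinogram", angles = sino@angles,
                           row_index = sino@rowIndex))
  invisible(path)
}

#' @rdname writeSinogram
#' @export
readSinogram <- function(path) {
  x <- .readPages(path)
  new("Sinogram", rows = x$pages[[1L]],
      angles = as.numeric(x$sidecar$angles),
      rowIndex = as.integer(x$sidecar$row_index))
}

#' Write / read a reconstruction volume (multi-page TIFF, Z pages)
#'
#' Page k holds the constant-Z plane k as an (X, Y)-indexed matrix; the
#' sidecar records voxel size and origin.
#'
#' @param grid a [VolumeGrid-class].
#' @param path TIFF path.
#' @return \code{path} invisibly (writer); a [VolumeGrid-class] (reader).
#' @export
writeVolume <- function(grid, path) {
  stopifnot(is(grid, "VolumeGrid"))
  nz <- dim(grid@voxels)[3L]
  .writePages(lapply(seq_len(nz), function(k) grid@voxels[, , k]), path,
              extra = list(kind = "volume", voxel_size = grid@voxelSize,
                           origin = grid@origin,
                           n_frames_summed = grid@nFramesSummed))
  invisible(path)
}

#' @rdname writeVolume
#' @export
readVolume <- function(path) {
  x <- .readPages(path)
  nx <- nrow(x$pages[[1L]]); ny <- ncol(x$pages[[1L]])
  new("VolumeGrid", voxels = array(unlist(x$pages),
                                   dim = c(nx, ny, length(x$pages))),
      voxelSize = as.numeric(x$sidecar$voxel_size),
      origin = as.numeric(x$sidecar$origin),
      nFramesSummed = as.integer(x$sidecar$n_frames_summed))
}
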