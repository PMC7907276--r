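# Pose-corrected back-projection (the flOPT core) and the standard
# inverse-Radon / filtered back-projection baseline.

#' Construct an empty reconstruction grid
#'
#' The default grid is a cube with side 1.5x the detector length (in
#' voxels of one pixel pitch), centred on the world origin — "suitably
#' large" so realigned rays of the sample region are not lost.
#'
#' @param side voxel count per side (scalar or length-3).
#' @param voxelSize world units per voxel.
#' @param origin world coordinate of voxel (0,0,0) centre; default centres
#'   the grid on the origin.
#' @return a [VolumeGrid-class] of zeros.
#' @export
volumeGrid <- function(side, voxelSize = 1, origin = NULL) {
  side <- as.integer(rep(side, length.out = 3L))
  if (is.null(origin)) origin <- -(side - 1) / 2 * voxelSize
  new("VolumeGrid", voxels = array(0, dim = side), voxelSize = voxelSize,
      origin = as.numeric(origin), nFramesSummed = 0L)
}

#' Default reconstruction grid for a camera
#'
#' @param cam a [CameraModel-class].
#' @param factor grid side as a multiple of the detector length.
#' @return a [VolumeGrid-class].
#' @export
defaultGrid <- function(cam, factor = 1.5) {
  volumeGrid(round(factor * imageSize(cam)[1L]), voxelSize = pixelPitch(cam))
}

#' Back-project one frame into a volume grid
#'
#' Voxel-driven gather: every voxel of the grid (sample frame) is carried
#' through the frame's pose and the camera projection to a pixel position
#' and gathers that position's bilinearly interpolated intensity. This is
#' equivalent to smearing each pixel along its ray realigned by the inverse
#' pose, which is how the algorithm is usually stated. Accumulates into the
#' existing grid; voxels projecting outside the frame contribute 0 and
#' their fraction is recorded in the \code{"fractionOutside"} attribute.
#'
#' @param frame numeric matrix (H x W).
#' @param samplePose the frame's [Pose-class] (sample -> world).
#' @param cam a [CameraModel-class].
#' @param grid a [VolumeGrid-class] accumulator.
#' @return the accumulated [VolumeGrid-class].
#' @export
backprojectFrame <- function(frame, samplePose, cam, grid) {
  stopifnot(is.matrix(frame), is(samplePose, "Pose"), is(cam, "CameraModel"),
            is(grid, "VolumeGrid"))
  validObject(samplePose)
  G <- cameraExtrinsic(cam)
  acc <- as.numeric(grid@voxels) * 1  # force a copy; C++ accumulates in place
  fracOut <- .backprojectGather(frame, acc, dim(grid@voxels),
                                grid@voxelSize, grid@origin,
                                samplePose@rotation, samplePose@translation,
                                G@rotation, G@translation,
                                cam@focalLength, cam@pixelPitch,
                                cam@principalPoint[1L], cam@principalPoint[2L])
  out <- new("VolumeGrid",
             voxels = array(acc, dim = dim(grid@voxels)),
             voxelSize = grid@voxelSize, origin = grid@origin,
             nFramesSummed = grid@nFramesSummed + 1L)
  attr(out, "fractionOutside") <- fracOut
  out
}

#' Ram-Lak ramp filter along the detector axis
#'
#' Frequency-domain \eqn{|\omega|} filtering of each detector line,
#' zero-padded to the next power of two at least twice the line length; the
#' DC component of every filtered line is zero.
#'
#' @param x numeric matrix (frame or sinogram).
#' @param axis detector axis: 2 (default) filters each row along the
#'   columns, 1 filters each column.
#' @return filtered matrix of the same shape.
#' @export
rampFilter <- function(x, axis = 2L) {
  stopifnot(is.matrix(x))
  if (axis == 1L) return(t(rampFilter(t(x), axis = 2L)))
  L <- ncol(x)
  if (L < 2L) stop("detector axis length must be >= 2")
  n <- 2^ceiling(log2(2L * L))
  freq <- c(seq(0, n / 2), seq(n / 2 - 1, 1)) / n  # |f| in cycles/sample
  pad <- matrix(0, nrow(x), n)
  pad[, seq_len(L)] <- x
  ft <- t(stats::mvfft(t(pad)))
  ft <- sweep(ft, 2L, freq, `*`)
  out <- Re(t(stats::mvfft(t(ft), inverse = TRUE))) / n
  out[, seq_len(L), drop = FALSE]
}

#' Pose-corrected reconstruction from a projection stack
#'
#' The frame-localisation reconstruction: every frame is (optionally) ramp
#' filtered along the detector axis and back-projected along its
#' pose-corrected rays into a common volume grid; the realigned
#' back-projections are summed. With filtering on, the sum is scaled by
#' \eqn{\pi / (2 n)} (angles cover \eqn{2\pi}, so every line is measured
#' twice) over the pixel pitch, the standard filtered back-projection
#' normalisation.
#'
#' @param stack a [ProjectionStack-class].
#' @param poses a [PoseChain-class] (its absolute poses are used), a list of
#'   [Pose-class] (one per frame), or NULL to use the stack's ground-truth
#'   poses.
#' @param grid a [VolumeGrid-class]; default [defaultGrid()] of the camera.
#' @param filtered logical; apply the ramp filter per frame.
#' @return the accumulated [VolumeGrid-class].
#' @export
floptReconstruct <- function(stack, poses = NULL, grid = NULL,
                             filtered = TRUE) {
  stopifnot(is(stack, "ProjectionStack"))
  cam <- stack@camera
  if (is.null(poses)) poses <- stack@groundTruthPoses
  if (is(poses, "PoseChain")) poses <- absolutePoses(poses)
  n <- nFrames(stack)
  if (length(poses) != n) {
    stop("need one pose per frame: ", n, " frames vs ", length(poses), " poses")
  }
  if (is.null(grid)) grid <- defaultGrid(cam)
  G <- cameraExtrinsic(cam)
  acc <- as.numeric(grid@voxels) * 1  # C++ accumulates in place
  for (k in seq_len(n)) {
    fr <- stack@frames[, , k]
    if (filtered) fr <- rampFilter(fr, axis = 2L)
    .backprojectGather(fr, acc, dim(grid@voxels), grid@voxelSize, grid@origin,
                       poses[[k]]@rotation, poses[[k]]@translation,
                       G@rotation, G@translation,
                       cam@focalLength, cam@pixelPitch,
                       cam@principalPoint[1L], cam@principalPoint[2L])
  }
  if (filtered) acc <- acc * pi / (2 * n) / cam@pixelPitch
  new("VolumeGrid", voxels = array(acc, dim = dim(grid@voxels)),
      voxelSize = grid@voxelSize, origin = grid@origin,
      nFramesSummed = grid@nFramesSummed + as.integer(n))
}

#' Inverse-Radon (filtered back-projection) baseline
#'
#' Standard parallel-beam reconstruction of a sinogram over its nominal
#' equal-step angles — the baseline that assumes perfect circular motion.
#' Output is an L x L image (L = detector length) on the same world grid
#' convention as the phantom mid-plane (first index = world X, second =
#' world Y, spacing = pixel pitch, centred on the rotation axis).
#'
#' @param sino a [Sinogram-class].
#' @param filtered logical; apply the Ram-Lak filter to each line first.
#' @param cam optional [CameraModel-class] (for pixel pitch and principal
#'   point); defaults to a unit-pitch centred detector.
#' @return L x L numeric matrix.
#' @export
radonReconstruct <- function(sino, filtered = TRUE, cam = NULL) {
  stopifnot(is(sino, "Sinogram"))
  P <- sino@rows
  n <- nrow(P)
  L <- ncol(P)
  pitch <- if (is.null(cam)) 1 else pixelPitch(cam)
  u0 <- if (is.null(cam)) (L - 1) / 2 else principalPoint(cam)[1L]
  if (filtered) P <- rampFilter(P, axis = 2L)
  coords <- (seq_len(L) - 1 - (L - 1) / 2) * pitch
  A <- matrix(coords, L, L)                 # world X (first index)
  B <- matrix(coords, L, L, byrow = TRUE)   # world Y (second index)
  out <- matrix(0, L, L)
  for (k in seq_len(n)) {
    th <- sino@angles[k]
    u <- (A * cos(th) - B * sin(th)) / pitch + u0   # detector position
    iu <- floor(u)
    fu <- u - iu
    ok <- iu >= 0 & iu <= L - 2L
    line <- P[k, ]
    val <- matrix(0, L, L)
    val[ok] <- line[iu[ok] + 1L] * (1 - fu[ok]) + line[iu[ok] + 2L] * fu[ok]
    out <- out + val
  }
  if (filtered) out <- out * pi / (2 * n) / pitch
  out
}
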