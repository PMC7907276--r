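# S4 containers shared by all modules. Validity functions enforce the
# geometric invariants (orthonormal rotations, positive intrinsics, shape
# consistency) so that every object circulating in the package is usable.

.ORTHO_TOL <- 1e-6

.is_rotation <- function(R, tol = .ORTHO_TOL) {
  is.matrix(R) && all(dim(R) == c(3L, 3L)) && all(is.finite(R)) &&
    max(abs(crossprod(R) - diag(3))) < tol && abs(det(R) - 1) < tol
}

#' Pinhole camera model
#'
#' Intrinsic description of the OPT camera: focal length \eqn{f} (world
#' units), principal point \eqn{(u_0, v_0)} (pixels), pixel pitch (world
#' units per pixel) and image size, plus the calibrated stand-off distance
#' from the camera centre to the rotation axis. The derived intrinsic matrix
#' \eqn{K} (see [intrinsicMatrix()]) converts image-plane coordinates to
#' pixel coordinates and is upper-triangular with positive diagonal.
#'
#' OPT optics are close to telecentric; the model is therefore used in a
#' weak-perspective regime with a focal length large relative to the sample
#' (default 50 sample diameters, see [defaultCamera()]).
#'
#' @slot focalLength focal length, world units; positive.
#' @slot principalPoint numeric(2), pixels.
#' @slot pixelPitch world units per pixel; positive.
#' @slot imageSize integer(2), c(width, height) in pixels.
#' @slot standoff distance from camera centre to the nominal rotation axis,
#'   world units; positive.
#' @seealso [cameraModel()], [projectPoint()], [imageToPixel()]
#' @export
setClass("CameraModel",
  representation(
    focalLength = "numeric",
    principalPoint = "numeric",
    pixelPitch = "numeric",
    imageSize = "integer",
    standoff = "numeric"
  )
)

setValidity("CameraModel", function(object) {
  msg <- character()
  if (length(object@focalLength) != 1L || !is.finite(object@focalLength) ||
      object@focalLength <= 0) {
    msg <- c(msg, "focalLength must be a single positive finite number")
  }
  if (length(object@pixelPitch) != 1L || !is.finite(object@pixelPitch) ||
      object@pixelPitch <= 0) {
    msg <- c(msg, "pixelPitch must be a single positive finite number")
  }
  if (length(object@principalPoint) != 2L || !all(is.finite(object@principalPoint))) {
    msg <- c(msg, "principalPoint must be a finite 2-vector")
  }
  if (length(object@imageSize) != 2L || any(object@imageSize < 1L)) {
    msg <- c(msg, "imageSize components must be >= 1")
  }
  if (length(object@standoff) != 1L || !is.finite(object@standoff) ||
      object@standoff <= 0) {
    msg <- c(msg, "standoff must be a single positive finite number")
  }
  if (length(msg)) msg else TRUE
})

#' Rigid pose (rotation + translation)
#'
#' A rigid transform \eqn{X = R s + T} mapping sample-frame coordinates to
#' world coordinates (or, where documented, one camera frame to another).
#' Losslessly convertible to/from the 4x4 augmented homogeneous matrix
#' \eqn{[R | T; 0\,0\,0\,1]} via [asHomogeneous()] and [poseFromMatrix()].
#'
#' @slot rotation 3x3 orthonormal matrix with determinant +1.
#' @slot translation numeric(3), world units.
#' @seealso [pose()], [composePose()], [invertPose()]
#' @export
setClass("Pose",
  representation(rotation = "matrix", translation = "numeric")
)

setValidity("Pose", function(object) {
  msg <- character()
  if (!.is_rotation(object@rotation)) {
    msg <- c(msg, "rotation must be a proper orthonormal 3x3 matrix (R'R = I, det R = +1)")
  }
  if (length(object@translation) != 3L || !all(is.finite(object@translation))) {
    msg <- c(msg, "translation must be a finite 3-vector")
  }
  if (length(msg)) msg else TRUE
})

#' Phantom volume
#'
#' A 3D non-negative intensity grid with world-coordinate mapping. Voxel
#' \code{(i, j, k)} (0-based) has its centre at
#' \code{origin + voxelSize * c(i, j, k)}, with array axes mapping to world
#' \eqn{(X, Y, Z)}.
#'
#' @slot voxels 3D array of finite, non-negative intensities.
#' @slot voxelSize world units per voxel.
#' @slot origin numeric(3), world coordinate of the centre of voxel (0,0,0).
#' @seealso [makeTestcardVolume()]
#' @export
setClass("PhantomVolume",
  representation(voxels = "array", voxelSize = "numeric", origin = "numeric")
)

setValidity("PhantomVolume", function(object) {
  msg <- character()
  if (length(dim(object@voxels)) != 3L) msg <- c(msg, "voxels must be a 3D array")
  if (any(!is.finite(object@voxels)) || any(object@voxels < 0)) {
    msg <- c(msg, "voxel intensities must be finite and >= 0")
  }
  if (length(object@voxelSize) != 1L || object@voxelSize <= 0) {
    msg <- c(msg, "voxelSize must be a single positive number")
  }
  if (length(object@origin) != 3L || !all(is.finite(object@origin))) {
    msg <- c(msg, "origin must be a finite 3-vector")
  }
  if (length(msg)) msg else TRUE
})

#' Fiducial bead set
#'
#' Bead centres in the sample frame, rendered in projections as Gaussian
#' spots. \code{radius} is the Gaussian sigma of a bead in world units; beads
#' are kept at least 4 radii apart so their images remain separable.
#'
#' @slot positions n x 3 matrix of bead centres (sample frame, world units).
#' @slot amplitude rendered peak intensity of one bead.
#' @slot radius Gaussian sigma of the rendered bead, world units.
#' @seealso [placeBeads()]
#' @export
setClass("BeadSet",
  representation(positions = "matrix", amplitude = "numeric", radius = "numeric")
)

setValidity("BeadSet", function(object) {
  msg <- character()
  if (!is.matrix(object@positions) || ncol(object@positions) != 3L ||
      any(!is.finite(object@positions))) {
    msg <- c(msg, "positions must be a finite n x 3 matrix")
  }
  if (object@amplitude <= 0) msg <- c(msg, "amplitude must be positive")
  if (object@radius <= 0) msg <- c(msg, "radius must be positive")
  if (length(msg)) msg else TRUE
})

#' Acquisition motion model
#'
#' Parameterises the (possibly corrupted) stage motion over an acquisition:
#' \code{nFrames} equal nominal angular steps covering \code{totalAngle}
#' about \code{axis}, plus systematic lateral drift (world units per frame),
#' axis precession (the rotation axis tips about the camera's horizontal
#' axis by \code{precessionRate} radians per frame) and random per-frame
#' jitter in translation and angle.
#'
#' @slot nFrames integer >= 2.
#' @slot totalAngle radians, default \eqn{2\pi}.
#' @slot axis unit 3-vector, nominal rotation axis (default world Z).
#' @slot driftVelocity numeric(3), world units per frame.
#' @slot precessionRate radians per frame of axis tip.
#' @slot jitterSigmaTranslation world units (sd of per-frame random offset).
#' @slot jitterSigmaAngle radians (sd of per-frame random rotation).
#' @slot seed integer RNG seed; motion sequences are deterministic given it.
#' @seealso [motionModel()], [motionSequence()]
#' @export
setClass("MotionModel",
  representation(
    nFrames = "integer",
    totalAngle = "numeric",
    axis = "numeric",
    driftVelocity = "numeric",
    precessionRate = "numeric",
    jitterSigmaTranslation = "numeric",
    jitterSigmaAngle = "numeric",
    seed = "integer"
  )
)

setValidity("MotionModel", function(object) {
  msg <- character()
  if (object@nFrames < 2L) msg <- c(msg, "nFrames must be >= 2")
  if (length(object@axis) != 3L || abs(sqrt(sum(object@axis^2)) - 1) > 1e-8) {
    msg <- c(msg, "axis must be a unit 3-vector")
  }
  if (length(object@driftVelocity) != 3L) msg <- c(msg, "driftVelocity must be a 3-vector")
  if (object@jitterSigmaTranslation < 0 || object@jitterSigmaAngle < 0) {
    msg <- c(msg, "jitter sigmas must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' Projection stack
#'
#' The N acquired frames of an OPT acquisition, stored as an array of
#' dimension \code{c(H, W, N)} (rows = image v axis), together with the
#' camera and, for simulated data, the ground-truth per-frame poses and
#' exact projected bead tracks.
#'
#' @slot frames numeric array c(H, W, N), finite, >= 0.
#' @slot camera the [CameraModel-class] used for acquisition.
#' @slot groundTruthPoses list of [Pose-class], length N (empty if unknown).
#' @slot groundTruthTracks data.frame (frame, bead_id, u, v); 0 rows if unknown.
#' @seealso [simulateAcquisition()], [buildSinogram()]
#' @export
setClass("ProjectionStack",
  representation(
    frames = "array",
    camera = "CameraModel",
    groundTruthPoses = "list",
    groundTruthTracks = "data.frame"
  )
)

setValidity("ProjectionStack", function(object) {
  msg <- character()
  if (length(dim(object@frames)) != 3L) msg <- c(msg, "frames must be a 3D array (H, W, N)")
  if (any(!is.finite(object@frames)) || any(object@frames < 0)) {
    msg <- c(msg, "frame intensities must be finite and >= 0")
  }
  n <- dim(object@frames)[3L]
  if (length(object@groundTruthPoses) &&
      length(object@groundTruthPoses) != n) {
    msg <- c(msg, "groundTruthPoses must have one pose per frame")
  }
  if (length(msg)) msg else TRUE
})

#' Sinogram
#'
#' One detector row per frame: row \eqn{k} of \code{rows} is pixel row
#' \code{rowIndex} (0-based) of frame \eqn{k}, with the nominal acquisition
#' angles attached.
#'
#' @slot rows numeric matrix N x W.
#' @slot angles numeric(N), nominal rotation angles (radians).
#' @slot rowIndex 0-based image row the sinogram was extracted from.
#' @seealso [buildSinogram()], [radonReconstruct()]
#' @export
setClass("Sinogram",
  representation(rows = "matrix", angles = "numeric", rowIndex = "integer")
)

setValidity("Sinogram", function(object) {
  msg <- character()
  if (nrow(object@rows) != length(object@angles)) {
    msg <- c(msg, "one angle per sinogram row required")
  }
  if (object@rowIndex < 0L) msg <- c(msg, "rowIndex must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Bead track table
#'
#' Per-frame sub-pixel image coordinates of each identified fiducial with
#' persistent bead identities: rows of (frame, bead_id, u, v), 0-based
#' frames, floating-point pixel coordinates. Each (frame, bead_id) pair
#' appears at most once. Tracks may have gaps; tracks covering fewer than
#' 80\% of frames are flagged unusable for pose recovery.
#'
#' @slot tracks data.frame with columns frame, bead_id, u, v.
#' @slot nBeads number of distinct bead identities.
#' @slot nFrames number of frames the table spans.
#' @seealso [linkTracks()], [correspondences()]
#' @export
setClass("BeadTrackTable",
  representation(tracks = "data.frame", nBeads = "integer", nFrames = "integer")
)

setValidity("BeadTrackTable", function(object) {
  msg <- character()
  need <- c("frame", "bead_id", "u", "v")
  if (!all(need %in% names(object@tracks))) {
    msg <- c(msg, "tracks must have columns frame, bead_id, u, v")
  } else if (anyDuplicated(object@tracks[, c("frame", "bead_id")])) {
    msg <- c(msg, "each (frame, bead_id) may appear at most once")
  }
  if (length(msg)) msg else TRUE
})

#' Two-view epipolar estimate
#'
#' The fundamental matrix \eqn{F} (pixel coordinates, rank 2 enforced) and,
#' once calibrated through \eqn{E = K^T F K}, the essential matrix \eqn{E}
#' (two equal non-zero singular values enforced), with the RMS Sampson
#' distance of the correspondences used.
#'
#' @slot F 3x3 fundamental matrix (rank 2).
#' @slot E 3x3 essential matrix, or a matrix of NA before calibration.
#' @slot residual RMS Sampson distance (pixels).
#' @slot nPoints number of correspondences used.
#' @seealso [estimateFundamental()], [essentialFromFundamental()]
#' @export
setClass("EpipolarEstimate",
  representation(F = "matrix", E = "matrix", residual = "numeric", nPoints = "integer")
)

#' Candidate pose set
#'
#' The four (R, T) transformation pairs produced by decomposing an essential
#' matrix: two rotations, each with the two opposite unit translations. One
#' is physically correct; [selectCandidate()] disambiguates.
#'
#' @slot candidates list of exactly 4 [Pose-class] objects (unit translations).
#' @seealso [decomposeEssential()], [selectCandidate()]
#' @export
setClass("CandidateSet", representation(candidates = "list"))

setValidity("CandidateSet", function(object) {
  if (length(object@candidates) != 4L) return("exactly 4 candidates required")
  if (!all(vapply(object@candidates, function(p) is(p, "Pose"), logical(1)))) {
    return("candidates must be Pose objects")
  }
  TRUE
})

#' Recovered pose chain
#'
#' Per-frame poses recovered from bead tracks: \code{relative[[k]]} is the
#' sample-frame rigid step from frame k-1 to frame k, and
#' \code{absolute[[k]]} the accumulated pose of frame k-1 relative to frame
#' 0 (\code{absolute[[1]]} is the identity). \code{scale} is the world-units-
#' per-unit-translation factor fixed by [fixTranslationScale()], and
#' \code{diagnostics} records per-pair Sampson residual, per-pair scale,
#' selected candidate index and correspondence count.
#'
#' @slot relative list of N-1 [Pose-class] (frame k -> k+1 steps).
#' @slot absolute list of N [Pose-class] (frame 0 -> k), absolute[[1]] = identity.
#' @slot scale numeric global translation scale.
#' @slot diagnostics data.frame of per-pair diagnostics.
#' @seealso [recoverPoseChain()]
#' @export
setClass("PoseChain",
  representation(
    relative = "list",
    absolute = "list",
    scale = "numeric",
    diagnostics = "data.frame"
  )
)

setValidity("PoseChain", function(object) {
  msg <- character()
  if (length(object@absolute) != length(object@relative) + 1L) {
    msg <- c(msg, "absolute must contain one more pose than relative")
  }
  if (length(object@absolute)) {
    p0 <- object@absolute[[1L]]
    if (max(abs(p0@rotation - diag(3))) > 1e-9 || max(abs(p0@translation)) > 1e-9) {
      msg <- c(msg, "absolute[[1]] must be the identity pose")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Reconstruction volume grid
#'
#' Accumulator for back-projected rays, with the same world mapping
#' convention as [PhantomVolume-class]. Choose the grid large enough to
#' contain all back-projected rays of the sample region.
#'
#' @slot voxels 3D accumulator array.
#' @slot voxelSize world units per voxel.
#' @slot origin numeric(3), world coordinate of voxel (0,0,0) centre.
#' @slot nFramesSummed number of frames accumulated so far.
#' @seealso [volumeGrid()], [backprojectFrame()], [floptReconstruct()]
#' @export
setClass("VolumeGrid",
  representation(
    voxels = "array",
    voxelSize = "numeric",
    origin = "numeric",
    nFramesSummed = "integer"
  )
)

setValidity("VolumeGrid", function(object) {
  msg <- character()
  if (length(dim(object@voxels)) != 3L) msg <- c(msg, "voxels must be a 3D array")
  if (any(!is.finite(object@voxels))) msg <- c(msg, "voxel values must be finite")
  if (object@voxelSize <= 0) msg <- c(msg, "voxelSize must be positive")
  if (length(msg)) msg else TRUE
})
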