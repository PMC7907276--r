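# Generics, accessors and show methods. Slots are never accessed directly by
# user code; these accessors are the supported surface.

#' @name accessors
#' @title Accessors for flopt S4 containers
#' @param object an flopt S4 object.
#' @param x an flopt S4 object.
#' @param k 1-based frame index.
#' @param ... ignored.
#' @description Read-only accessors for the package's S4 classes.
NULL

#' @rdname accessors
#' @export
setGeneric("focalLength", function(object) standardGeneric("focalLength"))
#' @rdname accessors
#' @export
setGeneric("principalPoint", function(object) standardGeneric("principalPoint"))
#' @rdname accessors
#' @export
setGeneric("pixelPitch", function(object) standardGeneric("pixelPitch"))
#' @rdname accessors
#' @export
setGeneric("imageSize", function(object) standardGeneric("imageSize"))
#' @rdname accessors
#' @export
setGeneric("standoff", function(object) standardGeneric("standoff"))
#' @rdname accessors
#' @export
setGeneric("rotation", function(object) standardGeneric("rotation"))
#' @rdname accessors
#' @export
setGeneric("translation", function(object) standardGeneric("translation"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("getFrame", function(object, k) standardGeneric("getFrame"))
#' @rdname accessors
#' @export
setGeneric("camera", function(object) standardGeneric("camera"))
#' @rdname accessors
#' @export
setGeneric("groundTruthPoses", function(object) standardGeneric("groundTruthPoses"))
#' @rdname accessors
#' @export
setGeneric("groundTruthTracks", function(object) standardGeneric("groundTruthTracks"))
#' @rdname accessors
#' @export
setGeneric("beadPositions", function(object) standardGeneric("beadPositions"))
#' @rdname accessors
#' @export
setGeneric("voxels", function(object) standardGeneric("voxels"))
#' @rdname accessors
#' @export
setGeneric("voxelSize", function(object) standardGeneric("voxelSize"))
#' @rdname accessors
#' @export
setGeneric("gridOrigin", function(object) standardGeneric("gridOrigin"))
#' @rdname accessors
#' @export
setGeneric("relativePoses", function(object) standardGeneric("relativePoses"))
#' @rdname accessors
#' @export
setGeneric("absolutePoses", function(object) standardGeneric("absolutePoses"))
#' @rdname accessors
#' @export
setGeneric("chainDiagnostics", function(object) standardGeneric("chainDiagnostics"))
#' @rdname accessors
#' @export
setGeneric("fundamentalMatrix", function(object) standardGeneric("fundamentalMatrix"))
#' @rdname accessors
#' @export
setGeneric("essentialMatrix", function(object) standardGeneric("essentialMatrix"))
#' @rdname accessors
#' @export
setGeneric("sampsonResidual", function(object) standardGeneric("sampsonResidual"))
#' @rdname accessors
#' @export
setGeneric("candidates", function(object) standardGeneric("candidates"))
#' @rdname accessors
#' @export
setGeneric("sinogramRows", function(object) standardGeneric("sinogramRows"))
#' @rdname accessors
#' @export
setGeneric("sinogramAngles", function(object) standardGeneric("sinogramAngles"))

#' Convert a pose to its 4x4 homogeneous matrix
#'
#' @param object a [Pose-class].
#' @return 4x4 matrix \code{[R | T; 0 0 0 1]} (row-major reading).
#' @seealso [poseFromMatrix()]
#' @export
setGeneric("asHomogeneous", function(object) standardGeneric("asHomogeneous"))

setMethod("focalLength", "CameraModel", function(object) object@focalLength)
setMethod("principalPoint", "CameraModel", function(object) object@principalPoint)
setMethod("pixelPitch", "CameraModel", function(object) object@pixelPitch)
setMethod("imageSize", "CameraModel", function(object) object@imageSize)
setMethod("standoff", "CameraModel", function(object) object@standoff)

setMethod("rotation", "Pose", function(object) object@rotation)
setMethod("translation", "Pose", function(object) object@translation)
setMethod("asHomogeneous", "Pose", function(object) {
  rbind(cbind(object@rotation, object@translation), c(0, 0, 0, 1))
})

setMethod("nFrames", "MotionModel", function(object) object@nFrames)
setMethod("nFrames", "ProjectionStack", function(object) dim(object@frames)[3L])
setMethod("nFrames", "BeadTrackTable", function(object) object@nFrames)

setMethod("getFrame", "ProjectionStack", function(object, k) object@frames[, , k])
setMethod("camera", "ProjectionStack", function(object) object@camera)
setMethod("groundTruthPoses", "ProjectionStack", function(object) object@groundTruthPoses)
setMethod("groundTruthTracks", "ProjectionStack", function(object) object@groundTruthTracks)

setMethod("beadPositions", "BeadSet", function(object) object@positions)

setMethod("voxels", "PhantomVolume", function(object) object@voxels)
setMethod("voxelSize", "PhantomVolume", function(object) object@voxelSize)
setMethod("gridOrigin", "PhantomVolume", function(object) object@origin)
setMethod("voxels", "VolumeGrid", function(object) object@voxels)
setMethod("voxelSize", "VolumeGrid", function(object) object@voxelSize)
setMethod("gridOrigin", "VolumeGrid", function(object) object@origin)

setMethod("relativePoses", "PoseChain", function(object) object@relative)
setMethod("absolutePoses", "PoseChain", function(object) object@absolute)
setMethod("chainDiagnostics", "PoseChain", function(object) object@diagnostics)

setMethod("fundamentalMatrix", "EpipolarEstimate", function(object) object@F)
setMethod("essentialMatrix", "EpipolarEstimate", function(object) object@E)
setMethod("sampsonResidual", "EpipolarEstimate", function(object) object@residual)
setMethod("candidates", "CandidateSet", function(object) object@candidates)

setMethod("sinogramRows", "Sinogram", function(object) object@rows)
setMethod("sinogramAngles", "Sinogram", function(object) object@angles)

#' @rdname accessors
#' @export
setMethod("as.data.frame", "BeadTrackTable", function(x, ...) x@tracks)

setMethod("show", "CameraModel", function(object) {
  cat("CameraModel: f =", object@focalLength,
      "| pitch =", object@pixelPitch,
      "| principal point = (", paste(object@principalPoint, collapse = ", "), ")",
      "| image", object@imageSize[1L], "x", object@imageSize[2L], "px",
      "| standoff =", object@standoff, "\n")
})

setMethod("show", "Pose", function(object) {
  cat("Pose [R | T]:\n")
  print(round(cbind(object@rotation, object@translation), 6))
})

setMethod("show", "ProjectionStack", function(object) {
  d <- dim(object@frames)
  cat("ProjectionStack:", d[3L], "frames of", d[1L], "x", d[2L], "px;",
      if (length(object@groundTruthPoses)) "with" else "without",
      "ground-truth poses\n")
})

setMethod("show", "Sinogram", function(object) {
  cat("Sinogram:", nrow(object@rows), "angles x", ncol(object@rows),
      "detector px (row", object@rowIndex, ")\n")
})

setMethod("show", "BeadTrackTable", function(object) {
  cat("BeadTrackTable:", object@nBeads, "beads over", object@nFrames,
      "frames (", nrow(object@tracks), "localisations )\n")
})

setMethod("show", "PoseChain", function(object) {
  cat("PoseChain:", length(object@relative), "relative steps, scale =",
      signif(object@scale, 6), "\n")
  if (nrow(object@diagnostics)) {
    cat("  mean Sampson residual:",
        signif(mean(object@diagnostics$residual), 4), "px\n")
  }
})

setMethod("show", "EpipolarEstimate", function(object) {
  cat("EpipolarEstimate from", object@nPoints, "points; RMS Sampson residual",
      signif(object@residual, 4), "px\n")
})

setMethod("show", "VolumeGrid", function(object) {
  d <- dim(object@voxels)
  cat("VolumeGrid:", paste(d, collapse = " x "), "voxels, voxelSize",
      object@voxelSize, ";", object@nFramesSummed, "frames summed\n")
})

setMethod("show", "MotionModel", function(object) {
  cat("MotionModel:", object@nFrames, "frames over", signif(object@totalAngle, 6),
      "rad; drift", paste(signif(object@driftVelocity, 4), collapse = ","),
      "per frame; precession", signif(object@precessionRate, 4), "rad/frame\n")
})

setMethod("show", "BeadSet", function(object) {
  cat("BeadSet:", nrow(object@positions), "beads, sigma", object@radius,
      "(world units), amplitude", object@amplitude, "\n")
})
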