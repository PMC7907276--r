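# Camera model and rigid-transform algebra. Conventions (shared by every
# module, see ?flopt): world Z vertical = nominal rotation axis; camera at
# (0, standoff, 0) looking down -Y with X_c = +X, Y_c = +Z, Z_c = -Y;
# 0-based pixels with centres at integer coordinates; poses map sample to
# world coordinates.

#' Construct a camera model
#'
#' @param focalLength focal length in world units (> 0).
#' @param imageSize integer(2) c(width, height) in pixels.
#' @param pixelPitch world units per pixel (> 0).
#' @param principalPoint numeric(2) in pixels; defaults to the image centre
#'   \code{(width-1)/2, (height-1)/2} under the 0-based pixel convention.
#' @param standoff camera-to-rotation-axis distance in world units; defaults
#'   to \code{focalLength} (unit magnification at the rotation axis plane).
#' @return a [CameraModel-class].
#' @examples
#' cam <- cameraModel(focalLength = 3200, imageSize = c(64, 64))
#' intrinsicMatrix(cam)
#' @export
cameraModel <- function(focalLength, imageSize, pixelPitch = 1,
                        principalPoint = (imageSize - 1) / 2,
                        standoff = focalLength) {
  new("CameraModel",
      focalLength = as.numeric(focalLength),
      principalPoint = as.numeric(principalPoint),
      pixelPitch = as.numeric(pixelPitch),
      imageSize = as.integer(imageSize),
      standoff = as.numeric(standoff))
}

#' Default weak-perspective OPT camera for a sample of given diameter
#'
#' OPT optics are close to telecentric; projections are therefore rendered
#' and analysed with a pinhole camera whose focal length is large relative
#' to the sample (50 sample diameters by default), i.e. a weak-perspective
#' regime that keeps the epipolar relations well-posed.
#'
#' @param sampleDiameter sample extent in world units.
#' @param imageSize integer(2) c(width, height) in pixels.
#' @param pixelPitch world units per pixel.
#' @param focalFactor focal length as a multiple of the sample diameter.
#' @param principalPoint optional numeric(2) principal point override.
#' @return a [CameraModel-class].
#' @export
defaultCamera <- function(sampleDiameter, imageSize = c(64L, 64L),
                          pixelPitch = 1, focalFactor = 50,
                          principalPoint = NULL) {
  f <- focalFactor * sampleDiameter
  if (is.null(principalPoint)) principalPoint <- (imageSize - 1) / 2
  cameraModel(f, imageSize, pixelPitch, principalPoint, standoff = f)
}

#' Intrinsic matrix K
#'
#' Upper-triangular matrix mapping camera-frame coordinates to homogeneous
#' pixel coordinates: \code{w ~ K X_c} with \code{K = [f/pitch 0 u0; 0
#' f/pitch v0; 0 0 1]}. Equivalently it converts image-plane coordinates to
#' camera pixel coordinates.
#'
#' @param camera a [CameraModel-class].
#' @return 3x3 numeric matrix.
#' @export
intrinsicMatrix <- function(camera) {
  stopifnot(is(camera, "CameraModel"))
  fpx <- camera@focalLength / camera@pixelPitch
  matrix(c(fpx, 0, camera@principalPoint[1L],
           0, fpx, camera@principalPoint[2L],
           0, 0, 1), 3L, 3L, byrow = TRUE)
}

#' Construct a pose
#'
#' @param rotation 3x3 proper orthonormal matrix (default identity).
#' @param translation numeric(3) (default zero).
#' @return a [Pose-class].
#' @export
pose <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  new("Pose", rotation = rotation, translation = as.numeric(translation))
}

#' @rdname pose
#' @export
identityPose <- function() pose()

#' Rotation about an arbitrary axis
#'
#' Rodrigues rotation by \code{angle} radians about unit vector \code{axis}.
#'
#' @param axis 3-vector (normalised internally).
#' @param angle radians.
#' @return 3x3 rotation matrix.
#' @export
rotationAboutAxis <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3L], a[2L],
                a[3L], 0, -a[1L],
                -a[2L], a[1L], 0), 3L, 3L, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Pose from a 4x4 homogeneous matrix
#'
#' Inverse of [asHomogeneous()]; the round trip is exact.
#'
#' @param m 4x4 matrix \code{[R | T; 0 0 0 1]}.
#' @return a [Pose-class].
#' @export
poseFromMatrix <- function(m) {
  stopifnot(is.matrix(m), all(dim(m) == c(4L, 4L)))
  if (max(abs(m[4L, ] - c(0, 0, 0, 1))) > 1e-12) {
    stop("bottom row of a homogeneous rigid transform must be (0, 0, 0, 1)")
  }
  pose(m[1:3, 1:3, drop = FALSE], m[1:3, 4L])
}

#' Compose two poses
#'
#' Returns the pose equal to applying \code{poseB} first and then
#' \code{poseA}; the homogeneous-matrix product of the two.
#'
#' @param poseA,poseB [Pose-class] objects.
#' @return a [Pose-class].
#' @export
composePose <- function(poseA, poseB) {
  stopifnot(is(poseA, "Pose"), is(poseB, "Pose"))
  validObject(poseA); validObject(poseB)
  pose(poseA@rotation %*% poseB@rotation,
       as.numeric(poseA@rotation %*% poseB@translation) + poseA@translation)
}

#' Invert a pose
#'
#' \code{composePose(invertPose(p), p)} is the identity; the result has
#' rotation \eqn{R^T} and translation \eqn{-R^T T}.
#'
#' @param p a [Pose-class].
#' @return a [Pose-class].
#' @export
invertPose <- function(p) {
  stopifnot(is(p, "Pose"))
  validObject(p)
  Rt <- t(p@rotation)
  pose(Rt, -as.numeric(Rt %*% p@translation))
}

#' Nearest proper rotation (polar decomposition)
#'
#' Projects a nearly-orthonormal matrix back onto SO(3); applied after long
#' decomposition/composition chains to remove floating-point drift.
#'
#' @param R 3x3 matrix.
#' @return 3x3 proper rotation.
#' @export
orthonormalize <- function(R) {
  s <- svd(R)
  D <- diag(c(1, 1, sign(det(s$u %*% t(s$v)))))
  s$u %*% D %*% t(s$v)
}

#' Re-orthonormalise a pose's rotation
#'
#' @param p a [Pose-class] whose rotation may carry float drift.
#' @return a [Pose-class] with the nearest proper rotation.
#' @export
orthonormalizePose <- function(p) pose(orthonormalize(p@rotation), p@translation)

#' Pinhole projection of camera-frame points
#'
#' Projects points expressed in the camera frame onto the image plane:
#' \eqn{x = f X_c / Z_c}, \eqn{y = f Y_c / Z_c}. The homogeneous ray to an
#' image point is \eqn{p = (x, y, f)}.
#'
#' @param camera a [CameraModel-class].
#' @param pointsCameraFrame numeric(3) or n x 3 matrix of camera-frame
#'   points; all must have \eqn{Z_c > 0} (in front of the camera).
#' @return n x 2 matrix of image-plane coordinates (world units).
#' @export
projectPoint <- function(camera, pointsCameraFrame) {
  stopifnot(is(camera, "CameraModel"))
  p <- rbind(pointsCameraFrame)
  if (ncol(p) != 3L) stop("points must be 3-vectors")
  if (any(p[, 3L] <= 0)) stop("point behind camera: Z_c must be > 0")
  f <- camera@focalLength
  cbind(x = f * p[, 1L] / p[, 3L], y = f * p[, 2L] / p[, 3L])
}

#' Image-plane to pixel coordinates and back
#'
#' \code{imageToPixel} maps image-plane coordinates (world units) to 0-based
#' pixel coordinates \eqn{w = (x/\mathrm{pitch} + u_0, y/\mathrm{pitch} +
#' v_0)}; \code{pixelToImage} is its exact inverse.
#'
#' @param camera a [CameraModel-class].
#' @param pts numeric(2) or n x 2 matrix.
#' @return n x 2 matrix (pixels for \code{imageToPixel}, image-plane units
#'   for \code{pixelToImage}).
#' @export
imageToPixel <- function(camera, pts) {
  stopifnot(is(camera, "CameraModel"))
  p <- rbind(pts)
  cbind(u = p[, 1L] / camera@pixelPitch + camera@principalPoint[1L],
        v = p[, 2L] / camera@pixelPitch + camera@principalPoint[2L])
}

#' @rdname imageToPixel
#' @export
pixelToImage <- function(camera, pts) {
  stopifnot(is(camera, "CameraModel"))
  p <- rbind(pts)
  cbind(x = (p[, 1L] - camera@principalPoint[1L]) * camera@pixelPitch,
        y = (p[, 2L] - camera@principalPoint[2L]) * camera@pixelPitch)
}

#' Camera extrinsic pose
#'
#' The fixed world-to-camera transform of the package's acquisition
#' geometry: camera centre at \eqn{(0, d, 0)} (d = stand-off), optical axis
#' along world \eqn{-Y}, image u axis along world \eqn{+X} and v axis along
#' world \eqn{+Z}. Returns the pose G with \eqn{X_c = R_g X + t_g}.
#'
#' @param camera a [CameraModel-class].
#' @return a [Pose-class] mapping world to camera coordinates.
#' @export
cameraExtrinsic <- function(camera) {
  stopifnot(is(camera, "CameraModel"))
  Rg <- matrix(c(1, 0, 0,
                 0, 0, 1,
                 0, -1, 0), 3L, 3L, byrow = TRUE)
  C <- c(0, camera@standoff, 0)
  pose(Rg, -as.numeric(Rg %*% C))
}

#' Project world points through the full camera chain
#'
#' World points -> camera frame (extrinsic) -> image plane (pinhole) ->
#' pixels. If \code{samplePose} is given, points are first mapped from the
#' sample frame to the world frame.
#'
#' @param camera a [CameraModel-class].
#' @param points numeric(3) or n x 3 matrix.
#' @param samplePose optional [Pose-class] applied to the points first.
#' @return n x 2 matrix of 0-based pixel coordinates.
#' @export
worldToPixel <- function(camera, points, samplePose = NULL) {
  p <- rbind(points)
  if (!is.null(samplePose)) {
    p <- t(samplePose@rotation %*% t(p) + samplePose@translation)
  }
  G <- cameraExtrinsic(camera)
  pc <- t(G@rotation %*% t(p) + G@translation)
  imageToPixel(camera, projectPoint(camera, pc))
}

# camera-relative step M (X_{c,k+1} = M X_{c,k}) from a sample-frame step
# dP (P_{k+1} = dP P_k):  M = G dP G^-1
.sampleStepToCameraStep <- function(dP, G) {
  composePose(composePose(G, dP), invertPose(G))
}

.cameraStepToSampleStep <- function(M, G) {
  composePose(composePose(invertPose(G), M), G)
}
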