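# Shared fixtures: all built in code, deterministic under fixed seeds.

smallCam <- function(size = 64L, ...) defaultCamera(size, imageSize = c(size, size), ...)

randomPose <- function(seed = 1L) {
  set.seed(seed)
  pose(orthonormalize(matrix(rnorm(9L), 3L)), rnorm(3L))
}

# exact projected bead tracks for a motion model (the noise-free oracle the
# detection/linking output is compared against)
exactTracks <- function(beads, poses, cam) {
  do.call(rbind, lapply(seq_along(poses), function(k) {
    px <- worldToPixel(cam, beadPositions(beads), poses[[k]])
    data.frame(frame = k - 1L, bead_id = seq_len(nrow(px)) - 1L,
               u = px[, 1L], v = px[, 2L])
  }))
}

# correspondences synthesised from a known camera-relative pose: random 3D
# points in front of camera A, imaged in both views
syntheticPairs <- function(M, cam, n = 10L, seed = 1L, depth = standoff(cam),
                          spread = 20) {
  set.seed(seed)
  X <- cbind(runif(n, -spread, spread), runif(n, -spread, spread),
             depth + runif(n, -spread, spread))
  XB <- t(rotation(M) %*% t(X) + translation(M))
  wA <- imageToPixel(cam, projectPoint(cam, X))
  wB <- imageToPixel(cam, projectPoint(cam, XB))
  data.frame(ua = wA[, 1L], va = wA[, 2L], ub = wB[, 1L], vb = wB[, 2L])
}

# camera-relative step corresponding to a sample rotation step (the motion
# a turntable acquisition produces between adjacent frames)
turntableStep <- function(cam, angle, drift = c(0, 0, 0)) {
  G <- cameraExtrinsic(cam)
  dP <- pose(rotationAboutAxis(c(0, 0, 1), angle), drift)
  composePose(composePose(G, dP), invertPose(G))
}
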