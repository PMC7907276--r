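# Analytic sinogram builders used as oracles, independent of the simulator.
discSinogram <- function(nAngles, L, R) {
  s <- (seq_len(L) - 1) - (L - 1) / 2
  line <- ifelse(abs(s) < R, 2 * sqrt(pmax(R^2 - s^2, 0)), 0)
  new("Sinogram", rows = matrix(line, nAngles, L, byrow = TRUE),
      angles = (seq_len(nAngles) - 1) * 2 * pi / nAngles, rowIndex = 0L)
}

pointSinogram <- function(nAngles, L, x, y, driftPerFrame = 0) {
  th <- (seq_len(nAngles) - 1) * 2 * pi / nAngles
  rows <- matrix(0, nAngles, L)
  for (k in seq_len(nAngles)) {
    s <- x * cos(th[k]) - y * sin(th[k]) + (k - 1) * driftPerFrame
    u <- s + (L - 1) / 2
    i <- floor(u)
    if (i >= 0 && i <= L - 2) {
      rows[k, i + 1L] <- 1 - (u - i)
      rows[k, i + 2L] <- u - i
    }
  }
  new("Sinogram", rows = rows, angles = th, rowIndex = 0L)
}

test_that("back-projection smears pixels along their realigned rays", {
  cam <- smallCam(32L)
  grid <- volumeGrid(32L)
  # a single bright pixel produces a near-constant ray along the axis
  fr <- matrix(0, 32, 32)
  fr[16, 21] <- 1
  out <- backprojectFrame(fr, identityPose(), cam, grid)
  v <- voxels(out)
  ray <- v[21, , 16]   # x = u, smeared along world Y, z = v
  expect_gt(min(ray[5:28]), 0.2)
  expect_lt(max(abs(v[, , c(1:13, 19:32)])), 0.3)
  # uniform frame -> uniform slab in the interior
  outU <- backprojectFrame(matrix(1, 32, 32), identityPose(), cam,
                           volumeGrid(32L))
  inner <- voxels(outU)[8:24, 8:24, 8:24]
  expect_lt(diff(range(inner)), 1e-6)
  expect_error(backprojectFrame(fr, pose(), cam, "nope"))
})

test_that("forward projection and realigned back-projection agree", {
  cam <- smallCam(32L)
  S <- 32L
  spike <- array(0, c(S, S, S))
  spike[20, 12, 18] <- 1
  vol <- new("PhantomVolume", voxels = spike, voxelSize = 1,
             origin = rep(-(S - 1) / 2, 3L))
  P <- pose(rotationAboutAxis(c(0, 0, 1), 0.7), c(1, 0, -2))
  fr <- renderProjection(vol, NULL, P, cam, step = 0.25)
  out <- backprojectFrame(fr, P, cam, volumeGrid(32L))
  v <- voxels(out)
  # the maximal-intensity ray passes within one voxel of the source point:
  # the source voxel's value is close to the global maximum
  expect_gt(max(v[19:21, 11:13, 17:19]), 0.7 * max(v))
})

test_that("ramp filter has the Ram-Lak structure", {
  # a constant line is killed (away from the finite-support edges, where
  # zero-padding necessarily rings)
  const <- matrix(3, 4, 33)
  expect_lt(max(abs(rampFilter(const)[, 9:25])) / 3, 0.01)
  # impulse response: positive centre, symmetric negative odd lobes,
  # near-zero even lobes (the discrete Ram-Lak kernel)
  imp <- matrix(0, 1, 64)
  imp[1, 33] <- 1
  h <- rampFilter(imp)[1, ]
  expect_gt(h[33], 0)
  expect_lt(h[32], 0)
  expect_lt(h[34], 0)
  expect_equal(h[32], h[34], tolerance = 1e-9)
  expect_lt(abs(h[35]) / h[33], 0.02)
  expect_lt(abs(mean(h)), 1e-3)
  expect_error(rampFilter(matrix(1, 3, 1)), ">= 2")
})

test_that("the Radon baseline reconstructs analytic phantoms", {
  # constant disc: uniform inside within 5%
  rec <- radonReconstruct(discSinogram(180L, 64L, 20))
  ax <- (seq_len(64) - 1) - 31.5
  inside <- outer(ax^2, ax^2, `+`) < (0.8 * 20)^2
  vals <- rec[inside]
  expect_lt((max(vals) - min(vals)) / mean(vals), 0.05)
  # point phantom localised within 1 px
  recP <- radonReconstruct(pointSinogram(64L, 64L, x = 9, y = -5))
  peak <- which(recP == max(recP), arr.ind = TRUE)[1L, ]
  expect_lte(abs((peak[1L] - 1) - 31.5 - 9), 1)
  expect_lte(abs((peak[2L] - 1) - 31.5 - (-5)), 1)
  # filtered point: FWHM of the peak profile no wider than 2 px
  prof <- recP[, peak[2L]]
  expect_lte(sum(prof > max(prof) / 2), 2L)
  # helical drift visibly degrades the baseline
  phantom <- matrix(0, 64, 64)
  phantom[41, 27] <- 1
  rec0 <- radonReconstruct(pointSinogram(64L, 64L, 9, -5, 0))
  recD <- radonReconstruct(pointSinogram(64L, 64L, 9, -5, 0.5))
  corr0 <- cor(as.numeric(rec0), as.numeric(phantom))
  corrD <- cor(as.numeric(recD), as.numeric(phantom))
  expect_gt(corr0 - corrD, 0.1)
})

test_that("pose-corrected reconstruction sums realigned frames linearly", {
  cam <- smallCam(32L)
  beads <- placeBeads(5, 10, seed = 8, radius = 1)
  model <- motionModel(nFrames = 8L)
  stack <- simulateAcquisition(NULL, beads, model, cam)
  # a single-frame stack reconstructs to exactly that back-projection
  one <- new("ProjectionStack", frames = stack@frames[, , 1L, drop = FALSE],
             camera = cam, groundTruthPoses = groundTruthPoses(stack)[1L],
             groundTruthTracks = data.frame(frame = integer(),
                                            bead_id = integer(),
                                            u = numeric(), v = numeric()))
  direct <- backprojectFrame(getFrame(stack, 1L),
                             groundTruthPoses(stack)[[1L]], cam,
                             volumeGrid(48L))
  viaRec <- floptReconstruct(one, grid = volumeGrid(48L), filtered = FALSE)
  expect_equal(voxels(viaRec), voxels(direct), tolerance = 1e-12)
  expect_error(floptReconstruct(one, poses = groundTruthPoses(stack)),
               "one pose per frame")
  # linearity in the projection data
  stack2 <- stack
  stack2@frames <- 2 * stack2@frames
  r1 <- floptReconstruct(stack, grid = volumeGrid(48L))
  r2 <- floptReconstruct(stack2, grid = volumeGrid(48L))
  expect_equal(voxels(r2), 2 * voxels(r1), tolerance = 1e-9)
})

test_that("with ideal poses the two reconstructions agree", {
  # equivalence in the ideal limit: ground-truth poses, zero drift,
  # filtering on -> flOPT mid-plane and the Radon baseline correlate >=.98
  volume <- makeTestcardVolume(64)
  cam <- smallCam()
  stack <- simulateAcquisition(volume, NULL, motionModel(nFrames = 64L), cam)
  vol <- floptReconstruct(stack, grid = volumeGrid(96L), filtered = TRUE)
  sliceF <- cropCenter(midplaneSlice(vol), 64L)
  sliceR <- radonReconstruct(buildSinogram(stack), filtered = TRUE, cam = cam)
  expect_gt(correlation2d(sliceR, sliceF), 0.98)
  # and reconstruction quality grows with the number of frames summed
  corrs <- vapply(c(8L, 16L, 32L, 64L), function(m) {
    sub <- new("ProjectionStack",
               frames = stack@frames[, , seq_len(m), drop = FALSE],
               camera = cam,
               groundTruthPoses = groundTruthPoses(stack)[seq_len(m)],
               groundTruthTracks = data.frame(frame = integer(),
                                              bead_id = integer(),
                                              u = numeric(), v = numeric()))
    v <- floptReconstruct(sub, grid = volumeGrid(96L), filtered = TRUE)
    correlation2d(midplaneSlice(volume), cropCenter(midplaneSlice(v), 64L))
  }, numeric(1L))
  expect_true(all(diff(corrs) > -0.005))
  expect_gt(corrs[4L], corrs[1L])
})
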