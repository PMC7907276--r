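test_that("testcard volume embeds the two orthogonal planes correctly", {
  z <- matrix(0, 64, 64)
  expect_equal(sum(voxels(makeTestcardVolume(64, z, z))), 0)
  one <- matrix(1, 64, 64)
  vol <- makeTestcardVolume(64, one, one)
  # brute-force voxel count oracle for the overlay embedding: two 64x64
  # planes sharing one 64-voxel line counted once
  oracle <- local({
    v <- array(0, c(64, 64, 64))
    for (i in 1:64) for (j in 1:64) v[i, j, 33] <- 1
    for (j in 1:64) for (k in 1:64) v[33, j, k] <- max(v[33, j, k], 1)
    sum(v)
  })
  expect_equal(sum(voxels(vol)), oracle)
  expect_equal(oracle, 2 * 64^2 - 64)
  # mid-plane slice returns sliceA wherever sliceB is zero
  a <- testcardEllipses(64)
  b <- testcardGrid(64)
  vol2 <- makeTestcardVolume(64, a, b)
  mid <- midplaneSlice(vol2)
  untouched <- row(a) != 33
  expect_equal(mid[untouched], a[untouched])
})

test_that("testcard construction validates and resamples inputs", {
  expect_error(makeTestcardVolume(32, matrix(-1, 32, 32)), "negative")
  expect_warning(v <- makeTestcardVolume(32, matrix(0.5, 16, 24),
                                         matrix(0, 32, 32)),
                 "non-square")
  expect_equal(dim(voxels(v)), c(32L, 32L, 32L))
})

test_that("bead placement is deterministic, contained and separated", {
  b1 <- placeBeads(5, 20, seed = 3)
  b2 <- placeBeads(5, 20, seed = 3)
  expect_identical(beadPositions(b1), beadPositions(b2))
  pos <- beadPositions(placeBeads(8, 20, seed = 1))
  expect_true(all(sqrt(rowSums(pos^2)) <= 20))
  # all-pairs O(n^2) distance oracle
  minSep <- 4 * 1.5
  for (i in 1:7) for (j in (i + 1):8) {
    expect_gte(sqrt(sum((pos[i, ] - pos[j, ])^2)), minSep)
  }
  posX <- beadPositions(placeBeads(8, 24, seed = 2, excludeSlab = 4))
  expect_true(all(abs(posX[, 3L]) >= 4))
  expect_error(placeBeads(80, 10, seed = 1), "fewer beads")
})

test_that("motion sequences follow the analytic corruption model", {
  ms <- motionSequence(motionModel(nFrames = 4L))
  expect_equal(rotation(ms[[1L]]), diag(3))
  expect_equal(rotation(ms[[2L]]), rotationAboutAxis(c(0, 0, 1), pi / 2),
               tolerance = 1e-12)
  expect_equal(rotation(ms[[3L]]), rotationAboutAxis(c(0, 0, 1), pi),
               tolerance = 1e-12)
  for (p in ms) expect_equal(translation(p), c(0, 0, 0))
  # drift: frame k translation has X component k*v
  msd <- motionSequence(motionModel(nFrames = 6L, driftVelocity = c(0.25, 0, 0)))
  expect_equal(vapply(msd, function(p) translation(p)[1L], numeric(1L)),
               (0:5) * 0.25)
  # the acquisition-protocol default: 128 angles over 2*pi
  m <- motionModel()
  expect_identical(nFrames(m), 128L)
  ms128 <- motionSequence(m)
  expect_length(ms128, 128L)
  expect_equal(rotation(ms128[[2L]]),
               rotationAboutAxis(c(0, 0, 1), 2 * pi / 128), tolerance = 1e-12)
  # jittered sequences are bit-identical for a fixed seed
  mj <- motionModel(nFrames = 8L, jitterSigmaTranslation = 0.2,
                    jitterSigmaAngle = 0.01, seed = 11L)
  expect_identical(lapply(motionSequence(mj), asHomogeneous),
                   lapply(motionSequence(mj), asHomogeneous))
})

test_that("rendered projections honour the geometry", {
  cam <- smallCam()
  # uniform ball: any pure rotation leaves the projection unchanged
  S <- 32L
  ax <- seq_len(S) - (S + 1) / 2
  r2 <- outer(ax^2, ax^2, `+`)
  ball <- array(0, c(S, S, S))
  # radially symmetric blob with a smooth profile (a hard edge measures
  # voxel-grid aliasing, not the renderer's rotational symmetry)
  for (k in seq_len(S)) {
    ball[, , k] <- exp(-(r2 + ax[k]^2) / (2 * 5^2))
  }
  vol <- new("PhantomVolume", voxels = ball, voxelSize = 1,
             origin = rep(-(S - 1) / 2, 3L))
  f0 <- renderProjection(vol, NULL, identityPose(), cam, step = 0.25)
  fr <- renderProjection(vol, NULL,
                         pose(rotationAboutAxis(c(0, 0, 1), 1.1)), cam,
                         step = 0.25)
  expect_lt(sqrt(mean((fr - f0)^2)) / max(f0), 1e-3)
  # a single bright voxel projects to a spot at its projected position
  spike <- array(0, c(S, S, S))
  spike[20, 9, 25] <- 1
  volS <- new("PhantomVolume", voxels = spike, voxelSize = 1,
              origin = rep(-(S - 1) / 2, 3L))
  fs <- renderProjection(volS, NULL, identityPose(), cam, step = 0.25)
  wpos <- c(20 - 1, 9 - 1, 25 - 1) - (S - 1) / 2
  px <- worldToPixel(cam, wpos)
  peak <- which(fs == max(fs), arr.ind = TRUE)
  expect_lt(abs((peak[1L, 2L] - 1) - px[1L, 1L]), 1.0)
  expect_lt(abs((peak[1L, 1L] - 1) - px[1L, 2L]), 1.0)
  # total intensity is conserved under rotation to within 1%
  sums <- vapply(seq(0, 2 * pi, length.out = 9L)[1:8], function(th) {
    sum(renderProjection(vol, NULL, pose(rotationAboutAxis(c(0, 0, 1), th)),
                         cam))
  }, numeric(1L))
  expect_lt(diff(range(sums)) / mean(sums), 0.01)
})

test_that("simulated acquisitions carry exact ground truth", {
  cam <- smallCam()
  beads <- placeBeads(5, 16, seed = 2)
  model <- motionModel(nFrames = 32L)
  stack <- simulateAcquisition(NULL, beads, model, cam)
  # frame 1 equals a direct render at the first pose
  expect_identical(getFrame(stack, 1L),
                   renderProjection(NULL, beads, motionSequence(model)[[1L]],
                                    cam))
  # an ideal-rotation bead track is an ellipse in the image plane:
  # fit a general conic by least squares and check the residual
  tr <- groundTruthTracks(stack)
  t0 <- tr[tr$bead_id == 0L, ]
  D <- cbind(t0$u^2, t0$u * t0$v, t0$v^2, t0$u, t0$v, 1)
  conic <- svd(D)$v[, 6L]
  expect_lt(max(abs(D %*% conic)), 1e-6)
  # helical drift: the track X-centroid advances linearly with frame
  # (compared against the drift-free acquisition to cancel the rotation)
  modelD <- motionModel(nFrames = 16L, driftVelocity = c(0.5, 0, 0))
  model0 <- motionModel(nFrames = 16L)
  trD <- groundTruthTracks(simulateAcquisition(NULL, beads, modelD, cam))
  tr0 <- groundTruthTracks(simulateAcquisition(NULL, beads, model0, cam))
  cx <- tapply(trD$u, trD$frame, mean) - tapply(tr0$u, tr0$frame, mean)
  expect_equal(as.numeric(cx), (0:15) * 0.5, tolerance = 0.02)
})

test_that("sinograms stack one detector row per frame", {
  cam <- smallCam()
  S <- 64L
  # point phantom on the rotation axis: constant-position trace
  spike <- array(0, c(S, S, S))
  spike[33, 33, 33] <- 1   # world (0.5, 0.5, 0.5), near the axis
  vol <- new("PhantomVolume", voxels = spike, voxelSize = 1,
             origin = rep(-(S - 1) / 2, 3L))
  stack <- simulateAcquisition(vol, NULL, motionModel(nFrames = 16L), cam)
  sino <- buildSinogram(stack)
  expect_error(buildSinogram(stack, rowIndex = 64L), "rowIndex")
  expect_equal(nrow(sinogramRows(sino)), 16L)
  peaks <- apply(sinogramRows(sino), 1L, which.max)
  expect_lte(diff(range(peaks)), 2L)
  # off-axis point: sinusoidal trace whose amplitude recovers the radius
  spike2 <- array(0, c(S, S, S))
  spike2[46, 33, 33] <- 1   # radius ~ 12.5 in X
  vol2 <- new("PhantomVolume", voxels = spike2, voxelSize = 1,
              origin = rep(-(S - 1) / 2, 3L))
  n <- 32L
  stack2 <- simulateAcquisition(vol2, NULL, motionModel(nFrames = n), cam)
  sino2 <- buildSinogram(stack2)
  # sub-pixel peak position by centroid around the max
  tracepos <- apply(sinogramRows(sino2), 1L, function(r) {
    i <- which.max(r)
    idx <- max(1, i - 2):min(length(r), i + 2)
    sum(idx * r[idx]) / sum(r[idx]) - 1
  })
  th <- sinogramAngles(sino2)
  radius <- sqrt(sum((c(46, 33) - 1 - (S - 1) / 2)^2))
  fit <- lm(tracepos ~ cos(th) + sin(th))
  amp <- sqrt(sum(coef(fit)[2:3]^2))
  expect_lt(abs(amp - radius), 0.5)
  # X drift adds a linear ramp to the trace (tilted sinogram)
  stack3 <- simulateAcquisition(vol2, NULL,
                                motionModel(nFrames = n,
                                            driftVelocity = c(0.4, 0, 0)),
                                cam)
  tracepos3 <- apply(sinogramRows(buildSinogram(stack3)), 1L, function(r) {
    i <- which.max(r)
    idx <- max(1, i - 2):min(length(r), i + 2)
    sum(idx * r[idx]) / sum(r[idx]) - 1
  })
  k <- 0:(n - 1)
  fit3 <- lm(tracepos3 ~ k + cos(th) + sin(th))
  expect_equal(unname(coef(fit3)["k"]), 0.4, tolerance = 0.05)
})

test_that("acquisition simulation is deterministic", {
  cam <- smallCam(32L)
  beads <- placeBeads(5, 14, seed = 9)
  model <- motionModel(nFrames = 4L, jitterSigmaTranslation = 0.1, seed = 5L)
  s1 <- simulateAcquisition(NULL, beads, model, cam)
  s2 <- simulateAcquisition(NULL, beads, model, cam)
  expect_identical(s1@frames, s2@frames)
  expect_identical(groundTruthTracks(s1), groundTruthTracks(s2))
})
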