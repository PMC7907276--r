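# Acquisition simulator: testcard phantom with fiducial beads, corrupted
# motion sequences, projection frames and sinograms, all with exact ground
# truth attached. Purely geometric line integrals; no physical optics.

#' Procedural testcard images
#'
#' Built-in grayscale testcards so phantom construction never depends on
#' external image downloads: \code{testcardEllipses()} is a Shepp-Logan-like
#' nested-ellipse phantom and \code{testcardGrid()} a checker/grating card.
#' Both are normalised to [0, 1] and masked to the inscribed circle (radius
#' 0.45 of the side) so the object stays inside the detector under rotation.
#'
#' @param size image side length in pixels.
#' @return size x size numeric matrix in [0, 1].
#' @export
testcardEllipses <- function(size = 64L) {
  s <- as.integer(size)
  ax <- (seq_len(s) - (s + 1) / 2) / (s / 2)  # [-1, 1)
  X <- matrix(ax, s, s)
  Y <- matrix(ax, s, s, byrow = TRUE)
  ell <- function(cx, cy, a, b, phi, val) {
    xr <- (X - cx) * cos(phi) + (Y - cy) * sin(phi)
    yr <- -(X - cx) * sin(phi) + (Y - cy) * cos(phi)
    val * ((xr / a)^2 + (yr / b)^2 <= 1)
  }
  img <- ell(0, 0, 0.82, 0.86, 0, 0.6) +
    ell(0, 0, 0.70, 0.76, 0, -0.25) +
    ell(0.28, 0.1, 0.16, 0.32, -0.3, 0.45) +
    ell(-0.28, 0.1, 0.16, 0.32, 0.3, 0.35) +
    ell(0, -0.35, 0.30, 0.16, 0, 0.3) +
    ell(0, 0.42, 0.08, 0.08, 0, 0.5) +
    ell(0.12, -0.38, 0.04, 0.04, 0, 0.4)
  img[img < 0] <- 0
  img <- img * ((X^2 + Y^2) <= 0.9^2)
  if (max(img) > 0) img <- img / max(img)
  img
}

#' @rdname testcardEllipses
#' @export
testcardGrid <- function(size = 64L) {
  s <- as.integer(size)
  ax <- (seq_len(s) - (s + 1) / 2) / (s / 2)
  X <- matrix(ax, s, s)
  Y <- matrix(ax, s, s, byrow = TRUE)
  block <- max(2L, round(s / 8))
  checker <- (((row(X) - 1) %/% block + (col(X) - 1) %/% block) %% 2)
  grating <- 0.5 + 0.5 * sin(2 * pi * 4 * X)
  img <- 0.6 * checker + 0.4 * grating
  img <- img * ((X^2 + Y^2) <= 0.9^2)
  img / max(img)
}

#' Build a testcard phantom volume from two orthogonal images
#'
#' Embeds \code{sliceA} in the horizontal mid-plane (constant Z, image axes
#' mapping to world X and Y) and \code{sliceB} in the orthogonal vertical
#' mid-plane (constant X, image axes mapping to world Y and Z), superposed
#' by maximum where the two planes intersect. All other voxels are zero and
#' the grid is cubic and centred on the world origin.
#'
#' @param size voxel count per side.
#' @param sliceA,sliceB grayscale matrices with intensities in [0, 1];
#'   non-square inputs are bilinearly resampled (with a warning).
#' @param voxelSize world units per voxel.
#' @return a [PhantomVolume-class].
#' @export
makeTestcardVolume <- function(size = 64L,
                               sliceA = testcardEllipses(size),
                               sliceB = testcardGrid(size),
                               voxelSize = 1) {
  size <- as.integer(size)
  fix <- function(img, name) {
    if (any(img < 0)) stop(name, " has negative intensities")
    if (nrow(img) != size || ncol(img) != size) {
      if (nrow(img) != ncol(img)) {
        warning(name, " is non-square; resampling to ", size, " x ", size)
      }
      img <- resizeBilinear(img, size, size)
      img[img < 0] <- 0
    }
    img
  }
  a <- fix(sliceA, "sliceA")
  b <- fix(sliceB, "sliceB")
  vox <- array(0, dim = c(size, size, size))
  mid <- size %/% 2L + 1L  # 0-based index floor(size/2)
  vox[, , mid] <- a                       # world (X, Y) plane at Z = z_mid
  vox[mid, , ] <- pmax(vox[mid, , ], b)   # world (Y, Z) plane at X = x_mid
  new("PhantomVolume", voxels = vox, voxelSize = voxelSize,
      origin = rep(-(size - 1) / 2 * voxelSize, 3L))
}

#' Extract the horizontal mid-plane slice of a volume
#'
#' Returns the constant-Z mid-plane (the plane [makeTestcardVolume()] embeds
#' \code{sliceA} in) as a matrix indexed (X, Y) — the plane the evaluation
#' metrics compare against reconstructions.
#'
#' @param vol a [PhantomVolume-class] or [VolumeGrid-class].
#' @return numeric matrix.
#' @export
midplaneSlice <- function(vol) {
  v <- voxels(vol)
  v[, , dim(v)[3L] %/% 2L + 1L]
}

#' Disperse fiducial beads in the sample
#'
#' Beads are sampled uniformly in a ball of \code{sampleRadius} about the
#' origin and rejection-resampled until every pair is at least
#' \code{4 * radius} apart (so the rendered spots remain separable).
#' Optionally a slab \code{|Z| < excludeSlab} is kept bead-free, which
#' protects the measured testcard mid-plane from bead streaks. Deterministic
#' for a fixed seed.
#'
#' @param nBeads number of beads (>= 5 for pose-recovery scenarios).
#' @param sampleRadius ball radius, world units.
#' @param seed RNG seed.
#' @param radius rendered Gaussian sigma of a bead, world units.
#' @param amplitude rendered peak intensity of a bead.
#' @param excludeSlab half-width of a bead-free slab about Z = 0 (world
#'   units, default 0 = none).
#' @param minAxialSep minimum pairwise separation along the rotation axis
#'   (world units). Under rotation about Z every bead's image height is
#'   (nearly) constant, so beads at distinct heights never cross in the
#'   image plane and their spots stay separable at every angle — the
#'   standard fiducial-layout practice in marker-based tomographic
#'   alignment. Heights are drawn from jittered strata spanning the
#'   available Z range (one bead per stratum); with \code{minAxialSep = 0}
#'   beads are instead sampled uniformly in the ball with pure rejection.
#' @return a [BeadSet-class].
#' @export
placeBeads <- function(nBeads, sampleRadius, seed = 1L, radius = 1.5,
                       amplitude = 100, excludeSlab = 0,
                       minAxialSep = 3 * radius) {
  stopifnot(nBeads >= 1L, sampleRadius > 0)
  minSep <- 4 * radius
  withLocalSeed(seed, {
    pos <- matrix(NA_real_, nBeads, 3L)
    if (minAxialSep > 0) {
      # stratified heights: one bead per Z stratum, margin minAxialSep/2 at
      # both stratum ends guarantees pairwise axial separation
      span <- 2 * (sampleRadius - excludeSlab)
      w <- span / nBeads
      if (w < minAxialSep) {
        stop("cannot give ", nBeads, " beads an axial separation of ",
             minAxialSep, " within a Z range of ", span, "; try fewer beads")
      }
      zc <- (seq_len(nBeads) - 1L) * w +
        runif(nBeads, minAxialSep / 2, w - minAxialSep / 2)
      # map concatenated coordinate through [-R, -slab] u [slab, R]
      z <- ifelse(zc < span / 2, -sampleRadius + zc,
                  excludeSlab + (zc - span / 2))
      z <- z[sample.int(nBeads)]  # bead ids not ordered by height
      for (b in seq_len(nBeads)) {
        rmax <- sqrt(max(sampleRadius^2 - z[b]^2, (2 * radius)^2))
        tries <- 0L
        repeat {
          if (tries >= 1e4) {
            stop("could not place ", nBeads, " beads with separation ",
                 minSep, " in radius ", sampleRadius, "; try fewer beads")
          }
          tries <- tries + 1L
          xy <- runif(2L, -rmax, rmax)
          if (sum(xy^2) > rmax^2) next
          p <- c(xy, z[b])
          if (b > 1L) {
            d2 <- colSums((t(pos[seq_len(b - 1L), , drop = FALSE]) - p)^2)
            if (min(d2) < minSep^2) next
          }
          pos[b, ] <- p
          break
        }
      }
    } else {
      placed <- 0L
      tries <- 0L
      while (placed < nBeads) {
        if (tries >= 1e4) {
          stop("could not place ", nBeads, " beads with separation ", minSep,
               " in radius ", sampleRadius, "; try fewer beads")
        }
        tries <- tries + 1L
        p <- runif(3L, -sampleRadius, sampleRadius)
        if (sum(p^2) > sampleRadius^2) next
        if (excludeSlab > 0 && abs(p[3L]) < excludeSlab) next
        if (placed > 0L) {
          d2 <- colSums((t(pos[seq_len(placed), , drop = FALSE]) - p)^2)
          if (min(d2) < minSep^2) next
        }
        placed <- placed + 1L
        pos[placed, ] <- p
      }
    }
    new("BeadSet", positions = pos, amplitude = amplitude, radius = radius)
  })
}

#' Construct a motion model
#'
#' @param nFrames number of frames (>= 2); the standard acquisition
#'   protocol is 128 angles over \eqn{2\pi}, the default.
#' @param totalAngle total rotation in radians.
#' @param axis nominal rotation axis (unit 3-vector, default world Z).
#' @param driftVelocity systematic drift, world units per frame.
#' @param precessionRate axis tip about the camera's horizontal axis,
#'   radians per frame.
#' @param jitterSigmaTranslation sd of random per-frame translation.
#' @param jitterSigmaAngle sd of random per-frame rotation angle (radians).
#' @param seed RNG seed for the jitter stream.
#' @return a [MotionModel-class].
#' @export
motionModel <- function(nFrames = 128L, totalAngle = 2 * pi,
                        axis = c(0, 0, 1), driftVelocity = c(0, 0, 0),
                        precessionRate = 0, jitterSigmaTranslation = 0,
                        jitterSigmaAngle = 0, seed = 1L) {
  new("MotionModel",
      nFrames = as.integer(nFrames), totalAngle = totalAngle,
      axis = axis / sqrt(sum(axis^2)), driftVelocity = as.numeric(driftVelocity),
      precessionRate = precessionRate,
      jitterSigmaTranslation = jitterSigmaTranslation,
      jitterSigmaAngle = jitterSigmaAngle, seed = as.integer(seed))
}

#' Generate the per-frame pose sequence of an acquisition
#'
#' Frame k (0-based) has pose
#' \code{jitter o drift(k) o precession(k) o axisRotation(k)}: a rotation by
#' \code{k * totalAngle / nFrames} about the nominal axis, the axis tipped
#' by \code{precessionRate * k} about the camera's horizontal axis (world
#' X), a translation \code{k * driftVelocity}, and optional random jitter.
#' With all corruption terms zero this is the ideal equal-step Radon
#' geometry. Deterministic (bit-identical) for a fixed seed.
#'
#' @param model a [MotionModel-class].
#' @return list of \code{nFrames} [Pose-class] objects.
#' @export
motionSequence <- function(model) {
  stopifnot(is(model, "MotionModel"))
  validObject(model)
  n <- model@nFrames
  dtheta <- model@totalAngle / n
  jitter <- model@jitterSigmaTranslation > 0 || model@jitterSigmaAngle > 0
  jitters <- if (jitter) {
    withLocalSeed(model@seed, {
      lapply(seq_len(n), function(k) {
        ax <- rnorm(3L)
        ax <- ax / sqrt(sum(ax^2))
        ang <- rnorm(1L, 0, model@jitterSigmaAngle)
        Tj <- rnorm(3L, 0, model@jitterSigmaTranslation)
        list(R = if (model@jitterSigmaAngle > 0) rotationAboutAxis(ax, ang) else diag(3),
             T = if (model@jitterSigmaTranslation > 0) Tj else c(0, 0, 0))
      })
    })
  } else NULL
  lapply(seq_len(n), function(kk) {
    k <- kk - 1L
    Rk <- rotationAboutAxis(model@axis, k * dtheta)
    if (model@precessionRate != 0) {
      Rk <- rotationAboutAxis(c(1, 0, 0), model@precessionRate * k) %*% Rk
    }
    Tk <- k * model@driftVelocity
    if (jitter) {
      j <- jitters[[kk]]
      Rk <- j$R %*% Rk
      Tk <- as.numeric(j$R %*% Tk) + j$T
    }
    pose(orthonormalize(Rk), Tk)
  })
}

# Gaussian spot rendering: adds the beads (projected through the pose and
# camera) to a frame as analytic Gaussian spots. Returns list(frame, tracks).
.renderBeads <- function(frame, beads, samplePose, cam) {
  px <- worldToPixel(cam, beads@positions, samplePose)
  sigma <- beads@radius / cam@pixelPitch
  H <- nrow(frame); W <- ncol(frame)
  us <- seq_len(W) - 1; vs <- seq_len(H) - 1
  for (b in seq_len(nrow(px))) {
    du2 <- (us - px[b, 1L])^2
    dv2 <- (vs - px[b, 2L])^2
    frame <- frame + beads@amplitude * outer(exp(-dv2 / (2 * sigma^2)),
                                             exp(-du2 / (2 * sigma^2)))
  }
  list(frame = frame, centers = px)
}

#' Render one projection frame
#'
#' Line integrals of the posed volume along the camera's pinhole rays
#' (weak-perspective ray casting with trilinear sampling), plus analytically
#' rendered Gaussian spots at the projected bead centres. Either component
#' may be omitted (\code{NULL}).
#'
#' @param volume a [PhantomVolume-class] or NULL for bead-only frames.
#' @param beads a [BeadSet-class] or NULL.
#' @param samplePose the [Pose-class] of the sample for this frame.
#' @param cam a [CameraModel-class].
#' @param step ray sampling interval in units of the voxel size.
#' @return H x W numeric matrix of non-negative intensities.
#' @export
renderProjection <- function(volume, beads, samplePose, cam, step = 0.5) {
  stopifnot(is(cam, "CameraModel"), is(samplePose, "Pose"))
  validObject(samplePose)
  W <- cam@imageSize[1L]; H <- cam@imageSize[2L]
  G <- cameraExtrinsic(cam)
  if (!is.null(volume)) {
    stopifnot(is(volume, "PhantomVolume"))
    frame <- .raycastRender(as.numeric(volume@voxels), dim(volume@voxels),
                            volume@voxelSize, volume@origin,
                            samplePose@rotation, samplePose@translation,
                            G@rotation, G@translation,
                            cam@focalLength, cam@pixelPitch,
                            cam@principalPoint[1L], cam@principalPoint[2L],
                            W, H, step * volume@voxelSize)
  } else {
    frame <- matrix(0, H, W)
  }
  if (!is.null(beads)) {
    px <- worldToPixel(cam, beads@positions, samplePose)
    margin <- 3 * beads@radius / cam@pixelPitch
    if (any(px[, 1L] < -margin | px[, 1L] > W - 1 + margin |
            px[, 2L] < -margin | px[, 2L] > H - 1 + margin)) {
      warning("bead(s) outside the camera field of view; spots clipped")
    }
    frame <- .renderBeads(frame, beads, samplePose, cam)$frame
  }
  frame
}

#' Simulate a full OPT acquisition
#'
#' Renders every frame of the motion sequence and attaches the ground-truth
#' poses and the exact projected bead centres as a ground-truth track table.
#' Optional Poisson shot noise and Gaussian read noise can be applied
#' (both off by default; the geometric simulation is noise-free).
#'
#' @param volume a [PhantomVolume-class] or NULL.
#' @param beads a [BeadSet-class] or NULL.
#' @param model a [MotionModel-class].
#' @param cam a [CameraModel-class].
#' @param step ray sampling interval (voxel units).
#' @param poissonNoise logical; apply Poisson noise to frame intensities.
#' @param readNoiseSigma sd of additive Gaussian read noise (0 = none).
#' @param noiseSeed RNG seed for the noise streams.
#' @return a [ProjectionStack-class] with ground truth attached.
#' @export
simulateAcquisition <- function(volume, beads, model, cam, step = 0.5,
                                poissonNoise = FALSE, readNoiseSigma = 0,
                                noiseSeed = 1L) {
  stopifnot(is(model, "MotionModel"), is(cam, "CameraModel"))
  poses <- motionSequence(model)
  W <- cam@imageSize[1L]; H <- cam@imageSize[2L]
  n <- model@nFrames
  frames <- array(0, dim = c(H, W, n))
  tracks <- vector("list", n)
  for (k in seq_len(n)) {
    frames[, , k] <- renderProjection(volume, beads, poses[[k]], cam, step)
    if (!is.null(beads)) {
      px <- worldToPixel(cam, beads@positions, poses[[k]])
      tracks[[k]] <- data.frame(frame = k - 1L,
                                bead_id = seq_len(nrow(px)) - 1L,
                                u = px[, 1L], v = px[, 2L])
    }
  }
  if (poissonNoise || readNoiseSigma > 0) {
    frames <- withLocalSeed(noiseSeed, {
      f <- frames
      if (poissonNoise) f[] <- rpois(length(f), lambda = pmax(f, 0))
      if (readNoiseSigma > 0) f <- f + rnorm(length(f), 0, readNoiseSigma)
      f[f < 0] <- 0
      f
    })
  }
  gt <- if (is.null(beads)) {
    data.frame(frame = integer(), bead_id = integer(),
               u = numeric(), v = numeric())
  } else {
    do.call(rbind, tracks)
  }
  new("ProjectionStack", frames = frames, camera = cam,
      groundTruthPoses = poses, groundTruthTracks = gt)
}

#' Assemble a sinogram from one detector row of every frame
#'
#' Row k of the sinogram is pixel row \code{rowIndex} (0-based) of frame k;
#' the nominal (ideal, equal-step) acquisition angles are attached for the
#' Radon baseline.
#'
#' @param stack a [ProjectionStack-class].
#' @param rowIndex 0-based image row; defaults to the row nearest the
#'   principal point (the world Z = 0 plane).
#' @param totalAngle total nominal rotation covered by the stack (radians).
#' @return a [Sinogram-class].
#' @export
buildSinogram <- function(stack, rowIndex = NULL, totalAngle = 2 * pi) {
  stopifnot(is(stack, "ProjectionStack"))
  H <- dim(stack@frames)[1L]
  if (is.null(rowIndex)) rowIndex <- as.integer(round(stack@camera@principalPoint[2L]))
  if (rowIndex < 0L || rowIndex >= H) {
    stop("rowIndex must be in [0, ", H - 1L, "]")
  }
  n <- nFrames(stack)
  rows <- t(stack@frames[rowIndex + 1L, , ])
  new("Sinogram", rows = rows,
      angles = (seq_len(n) - 1L) * totalAngle / n,
      rowIndex = as.integer(rowIndex))
}
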