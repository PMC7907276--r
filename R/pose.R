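# Epipolar pose recovery: fundamental-matrix estimation from bead
# correspondences, essential-matrix decomposition into the four candidate
# (R, T) pairs, continuity-based candidate selection, translation-scale
# fixing and chaining into absolute per-frame poses.
#
# Correspondence convention: a pair (pA, pB) couples frame k (A) with frame
# k+1 (B); the constraint is pB' F pA = 0 in pixel homogeneous coordinates
# and pB' E pA = 0 in normalised coordinates, with X_B = R X_A + t and
# E = [t]x R.

.crossMatrix <- function(t) {
  matrix(c(0, -t[3L], t[2L],
           t[3L], 0, -t[1L],
           -t[2L], t[1L], 0), 3L, 3L, byrow = TRUE)
}

#' Essential matrix of a known relative pose
#'
#' \eqn{E = [t]_x R} for the relative pose \eqn{X_B = R X_A + t}; the
#' ground-truth construction used to validate the decomposition.
#'
#' @param p a [Pose-class] (relative camera pose A -> B).
#' @return 3x3 essential matrix.
#' @export
essentialFromPose <- function(p) {
  stopifnot(is(p, "Pose"))
  .crossMatrix(p@translation) %*% p@rotation
}

#' Sampson distance of correspondences under a fundamental matrix
#'
#' First-order geometric distance to the epipolar constraint, in the units
#' of the point coordinates (pixels when \code{F} acts on pixel
#' coordinates).
#'
#' @param F 3x3 fundamental (or essential) matrix.
#' @param ptsA,ptsB n x 2 matrices of corresponding points; the constraint
#'   is \code{pB' F pA = 0}.
#' @return numeric vector of per-point Sampson distances.
#' @export
sampsonDistance <- function(F, ptsA, ptsB) {
  pA <- rbind(t(rbind(ptsA)), 1)
  pB <- rbind(t(rbind(ptsB)), 1)
  FA <- F %*% pA          # epipolar lines in image B
  FtB <- t(F) %*% pB      # epipolar lines in image A
  num <- colSums(pB * FA)
  den <- FA[1L, ]^2 + FA[2L, ]^2 + FtB[1L, ]^2 + FtB[2L, ]^2
  abs(num) / sqrt(pmax(den, .Machine$double.xmin))
}

# Hartley conditioning: translate centroid to origin, scale RMS radius to
# sqrt(2). Returns the 3x3 similarity.
.hartleyTransform <- function(pts) {
  ctr <- colMeans(pts)
  rms <- sqrt(mean(rowSums(sweep(pts, 2L, ctr)^2)))
  s <- if (rms > 0) sqrt(2) / rms else 1
  matrix(c(s, 0, -s * ctr[1L],
           0, s, -s * ctr[2L],
           0, 0, 1), 3L, 3L, byrow = TRUE)
}

#' Estimate the fundamental matrix from 8+ correspondences
#'
#' Normalised eight-point algorithm: both point sets are Hartley-conditioned
#' (centroid at the origin, RMS radius \eqn{\sqrt 2}), the linear epipolar
#' system is solved by SVD, rank 2 is enforced by zeroing the smallest
#' singular value, and the conditioning is undone. The residual reported is
#' the RMS Sampson distance in pixels.
#'
#' @param pairs data.frame with columns ua, va, ub, vb (pixel coordinates;
#'   the constraint couples \code{(ub, vb)' F (ua, va)}), or an n x 4 matrix
#'   in that column order. At least 8 non-degenerate pairs required.
#' @return an [EpipolarEstimate-class] (essential slot unset).
#' @export
estimateFundamental <- function(pairs) {
  p <- as.matrix(as.data.frame(pairs)[, c("ua", "va", "ub", "vb")])
  n <- nrow(p)
  if (n < 8L) {
    stop("fundamental-matrix estimation requires >= 8 correspondences, got ",
         n, " (with 5-7 beads use the direct essential path in recoverPoseChain)")
  }
  TA <- .hartleyTransform(p[, 1:2])
  TB <- .hartleyTransform(p[, 3:4])
  hA <- TA %*% rbind(t(p[, 1:2]), 1)
  hB <- TB %*% rbind(t(p[, 3:4]), 1)
  # columns ordered F11 F12 F13 F21 ... F33 with row = kron(pB, pA)
  A <- cbind(hB[1L, ] * t(hA), hB[2L, ] * t(hA), t(hA))
  sv <- svd(A, nu = 0, nv = 9L)
  if (sv$d[8L] / sv$d[1L] < 1e-12) {
    stop("degenerate correspondence geometry (collinear or coincident points)")
  }
  Fh <- matrix(sv$v[, 9L], 3L, 3L, byrow = TRUE)
  s <- svd(Fh)
  Fh <- s$u %*% diag(c(s$d[1:2], 0)) %*% t(s$v)
  F <- t(TB) %*% Fh %*% TA
  F <- F / sqrt(sum(F^2))
  res <- sqrt(mean(sampsonDistance(F, p[, 1:2], p[, 3:4])^2))
  new("EpipolarEstimate", F = F, E = matrix(NA_real_, 3L, 3L),
      residual = res, nPoints = as.integer(n))
}

#' Calibrate a fundamental matrix into an essential matrix
#'
#' \eqn{E = K^T F K} (same camera in both views), followed by projection
#' onto the essential manifold: singular values set to (s, s, 0) with s the
#' mean of the two largest.
#'
#' @param est an [EpipolarEstimate-class] with F set, or a 3x3 F matrix.
#' @param camera a [CameraModel-class].
#' @return an [EpipolarEstimate-class] with both F and E set.
#' @export
essentialFromFundamental <- function(est, camera) {
  stopifnot(is(camera, "CameraModel"))
  F <- if (is(est, "EpipolarEstimate")) est@F else est
  K <- intrinsicMatrix(camera)
  if (abs(det(K)) < .Machine$double.eps) stop("singular intrinsic matrix")
  E <- t(K) %*% F %*% K
  s <- svd(E)
  sig <- mean(s$d[1:2])
  E <- s$u %*% diag(c(sig, sig, 0)) %*% t(s$v)
  E <- E / sqrt(sum(E^2))
  if (is(est, "EpipolarEstimate")) {
    new("EpipolarEstimate", F = est@F, E = E, residual = est@residual,
        nPoints = est@nPoints)
  } else {
    new("EpipolarEstimate", F = F, E = E, residual = NA_real_, nPoints = 0L)
  }
}

#' Decompose an essential matrix into the four candidate poses
#'
#' SVD-based factorisation: rotations \eqn{U W V^T} and \eqn{U W^T V^T}
#' (determinant-corrected so both are proper) with translations \eqn{\pm
#' u_3} (unit-normalised). Exactly one candidate places the scene in front
#' of both cameras; see [selectCandidate()].
#'
#' @param E 3x3 essential matrix, or an [EpipolarEstimate-class] with E set.
#' @return a [CandidateSet-class] of four unit-translation poses.
#' @export
decomposeEssential <- function(E) {
  if (is(E, "EpipolarEstimate")) E <- E@E
  if (max(abs(E)) < 1e-12) {
    stop("zero essential matrix: no relative motion between the views")
  }
  s <- svd(E)
  U <- s$u; V <- s$v
  if (det(U) < 0) U <- -U
  if (det(V) < 0) V <- -V
  W <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3L, 3L, byrow = TRUE)
  R1 <- orthonormalize(U %*% W %*% t(V))
  R2 <- orthonormalize(U %*% t(W) %*% t(V))
  t1 <- U[, 3L]
  t1 <- t1 / sqrt(sum(t1^2))
  new("CandidateSet", candidates = list(
    pose(R1, t1), pose(R1, -t1), pose(R2, t1), pose(R2, -t1)))
}

#' Linear two-view triangulation
#'
#' DLT triangulation of corresponding normalised image points under the
#' relative pose \code{X_B = R X_A + t}; returns the 3D points in the A
#' camera frame (at the scale of \code{t}).
#'
#' @param relPose [Pose-class] relative pose A -> B.
#' @param ptsA,ptsB n x 2 normalised image coordinates.
#' @return n x 3 matrix of triangulated points.
#' @export
triangulatePoints <- function(relPose, ptsA, ptsB) {
  R <- relPose@rotation; tt <- relPose@translation
  P2 <- cbind(R, tt)
  n <- nrow(ptsA)
  out <- matrix(NA_real_, n, 3L)
  for (i in seq_len(n)) {
    A <- rbind(
      c(-1, 0, ptsA[i, 1L], 0),
      c(0, -1, ptsA[i, 2L], 0),
      ptsB[i, 1L] * P2[3L, ] - P2[1L, ],
      ptsB[i, 2L] * P2[3L, ] - P2[2L, ])
    v <- svd(A)$v[, 4L]
    out[i, ] <- v[1:3] / v[4L]
  }
  out
}

# number of triangulated points with positive depth in both views
.cheiralityCount <- function(relPose, ptsA, ptsB) {
  X <- triangulatePoints(relPose, ptsA, ptsB)
  XB <- t(relPose@rotation %*% t(X) + relPose@translation)
  sum(X[, 3L] > 0 & XB[, 3L] > 0)
}

# augmented [R | T] with T unit-normalised (scale is undetermined at
# selection time); zero translations are left zero
.augmentedUnit <- function(p) {
  tt <- p@translation
  nrm <- sqrt(sum(tt^2))
  if (nrm > 1e-12) tt <- tt / nrm
  cbind(p@rotation, tt)
}

#' Select the physical candidate pose by continuity
#'
#' Returns the candidate minimising the sum of squared element-wise
#' differences of the augmented \eqn{[R | T]} matrices against the
#' reference — the previously selected pose, or for the first frame pair an
#' ideal pose composed from a-priori knowledge of the likely rotation step.
#' Translations are unit-normalised before comparison. Near-ties are broken
#' by the positive-depth (cheirality) count when correspondences are
#' supplied.
#'
#' @param candSet a [CandidateSet-class].
#' @param reference a [Pose-class] reference (camera-relative convention).
#' @param ptsA,ptsB optional n x 2 normalised correspondences for the
#'   cheirality tie-break.
#' @return the selected [Pose-class] (unit translation).
#' @export
selectCandidate <- function(candSet, reference, ptsA = NULL, ptsB = NULL) {
  stopifnot(is(candSet, "CandidateSet"), is(reference, "Pose"))
  ref <- .augmentedUnit(reference)
  obj <- vapply(candSet@candidates,
                function(p) sum((.augmentedUnit(p) - ref)^2), numeric(1L))
  ord <- order(obj)
  best <- ord[1L]
  if (!is.null(ptsA) && length(ord) > 1L &&
      obj[ord[2L]] - obj[ord[1L]] < 1e-9) {
    tied <- ord[obj[ord] - obj[ord[1L]] < 1e-9]
    counts <- vapply(candSet@candidates[tied], .cheiralityCount,
                     numeric(1L), ptsA = ptsA, ptsB = ptsB)
    best <- tied[which.max(counts)]
  }
  candSet@candidates[[best]]
}

# Levenberg-Marquardt least squares on the Sampson residuals over the
# (rotation, unit translation) parameterisation, from a given starting
# pose. Returns the refined pose and its RMS residual (normalised coords).
.lmPose <- function(ptsA, ptsB, init) {
  R0 <- init@rotation
  t0 <- init@translation
  if (sqrt(sum(t0^2)) < 1e-9) t0 <- c(1, 0, 0)
  t0 <- t0 / sqrt(sum(t0^2))
  mkpose <- function(par) {
    ang <- sqrt(sum(par[1:3]^2))
    R <- if (ang > 0) R0 %*% rotationAboutAxis(par[1:3], ang) else R0
    tt <- t0 + par[4:6]
    tt <- tt / sqrt(sum(tt^2))
    list(R = R, t = tt)
  }
  resfun <- function(par) {
    p <- mkpose(par)
    sampsonDistance(.crossMatrix(p$t) %*% p$R, ptsA, ptsB)
  }
  fit <- suppressWarnings(
    minpack.lm::nls.lm(par = rep(0, 6L), fn = resfun,
                       control = minpack.lm::nls.lm.control(maxiter = 200)))
  p <- mkpose(fit$par)
  list(pose = pose(orthonormalize(p$R), p$t),
       rms = sqrt(mean(fit$fvec^2)))
}

# Direct essential-matrix estimation for 5-7 correspondences: nonlinear
# least squares (Levenberg-Marquardt) on the Sampson residuals over the
# 5-DOF (rotation, unit translation) parameterisation, initialised from the
# a-priori/previous reference pose. An approximation relative to the
# well-posed >= 8 point path; used only when fewer than 8 beads are shared.
.estimateEssentialDirect <- function(ptsA, ptsB, init) {
  ref <- init
  nrm <- sqrt(sum(ref@translation^2))
  if (nrm > 1e-9) ref <- pose(ref@rotation, ref@translation / nrm)
  fit <- .lmPose(ptsA, ptsB, ref)
  E <- .crossMatrix(fit$pose@translation) %*% fit$pose@rotation
  E / sqrt(sum(E^2))
}

# Refine a relative pose as a *sample step* dP = (dR, dT) with the camera
# orbit built in: the camera-relative transform is M = G dP G^-1, whose
# translation is the (large, calibration-determined) orbit of the camera
# about the rotation axis plus the (small) sample translation. Estimating
# in this parameterisation removes the bas-relief degeneracy of narrow-
# field two-view geometry — camera tilt can no longer trade against an
# arbitrary baseline — and makes the translation scale observable.
# Residuals are pixel-unit Sampson distances plus weak anchors of the step
# rotation and translation to the reference step. The anchors implement a
# causal smoothness prior: stage motion changes slowly between adjacent
# pairs (constant drift, slow precession), whereas per-pair noise in this
# narrow-field geometry projects almost freely onto the quasi-degenerate
# bas-relief direction. Weights are pixel-residual units per radian / per
# world unit, set so genuine frame-to-frame motion changes (~1e-3-1e-4)
# cost far less than the tracking-noise floor while noise-driven
# excursions (~1e-2 and beyond) are suppressed.
# Returns list(pose = dP, rms of the data residuals).
.lmSampleStep <- function(ptsA, ptsB, initStep, G, fpx,
                          anchor = initStep, rotAnchorWeight = 30,
                          transAnchorWeight = 1) {
  R0 <- initStep@rotation
  T0 <- initStep@translation
  RaT <- t(anchor@rotation)
  Ta <- anchor@translation
  mkstep <- function(par) {
    ang <- sqrt(sum(par[1:3]^2))
    R <- if (ang > 0) R0 %*% rotationAboutAxis(par[1:3], ang) else R0
    pose(R, T0 + par[4:6])
  }
  resfun <- function(par) {
    dP <- mkstep(par)
    M <- .sampleStepToCameraStep(dP, G)
    tt <- M@translation
    nrm <- sqrt(sum(tt^2))
    if (nrm < 1e-12) return(rep(1e6, nrow(ptsA) + 6L))
    E <- .crossMatrix(tt / nrm) %*% M@rotation
    # rotation deviation from the anchor as a rotation vector (skew part)
    D <- RaT %*% dP@rotation
    rv <- 0.5 * c(D[3L, 2L] - D[2L, 3L], D[1L, 3L] - D[3L, 1L],
                  D[2L, 1L] - D[1L, 2L])
    c(fpx * sampsonDistance(E, ptsA, ptsB),
      rotAnchorWeight * rv,
      transAnchorWeight * (dP@translation - Ta))
  }
  fit <- suppressWarnings(
    minpack.lm::nls.lm(par = rep(0, 6L), fn = resfun,
                       control = minpack.lm::nls.lm.control(maxiter = 200)))
  n <- nrow(ptsA)
  list(pose = orthonormalizePose(mkstep(fit$par)),
       rms = sqrt(mean(fit$fvec[seq_len(n)]^2)),
       objective = fit$deviance)
}

# Convert a selected camera-relative candidate (unit translation) to a
# sample step, fixing its baseline from the orbit structure: the scale is
# chosen so the translation matches the camera orbit implied by the
# candidate's rotation (sample translations are small by comparison).
.candidateToSampleStep <- function(sel, G) {
  Rg <- G@rotation
  tg <- G@translation
  # camera-frame orbit translation of a pure sample step dR: tg - R_M tg
  orbit <- as.numeric(tg - sel@rotation %*% tg)
  b <- sum(sel@translation * orbit)
  .cameraStepToSampleStep(pose(sel@rotation, sel@translation * b), G)
}

#' Element-wise percentage recovery error of a pose
#'
#' For each matrix element pair (x = recovered, y = truth) the error is
#' \eqn{|x - y| / (2 (|x| + |y|))} with 0/0 defined as 0, averaged over the
#' 9 rotation elements and (separately) the 3 translation components, times
#' 100.
#'
#' @param recovered,truth [Pose-class] objects in the same convention.
#' @return named numeric: \code{c(R = \%, T = \%)}.
#' @export
matrixRecoveryError <- function(recovered, truth) {
  el <- function(x, y) {
    den <- 2 * (abs(x) + abs(y))
    e <- abs(x - y) / den
    e[den == 0] <- 0
    mean(e) * 100
  }
  c(R = el(recovered@rotation, truth@rotation),
    T = el(recovered@translation, truth@translation))
}

# normalised coordinates of pixel points: K^-1 (u, v, 1)
.normalizePoints <- function(camera, u, v) {
  Kinv <- solve(intrinsicMatrix(camera))
  h <- Kinv %*% rbind(u, v, 1)
  cbind(h[1L, ] / h[3L, ], h[2L, ] / h[3L, ])
}

#' Fix the translation scale of a recovered pose chain
#'
#' An essential matrix determines each pair's translation only up to scale.
#' The relative per-pair scales are pinned by rigidity of the bead cloud:
#' beads triangulated from each adjacent pair must form the same rigid set,
#' so each pair's scale is chosen to equalise the RMS pairwise bead
#' distance with the first pair's. The absolute gauge is fixed from the
#' calibrated camera stand-off: the mean triangulated bead depth of the
#' first pair is set equal to the camera-to-rotation-axis distance. A
#' rigidity residual per pair is reported in the diagnostics; a spread of
#' per-pair cloud sizes above 10\% triggers a warning.
#'
#' Three absolute gauges are available:
#' \describe{
#'   \item{"motionModel" (default)}{The accumulated sample translation
#'     trajectory is affine in the global scale; the scale is chosen by
#'     linear least squares so the trajectory best fits the a-priori
#'     motion model (constant-velocity drift, i.e. translation linear in
#'     the frame index). An erroneous scale leaks the large camera-orbit
#'     baseline into the sample trajectory as a spurious circular
#'     component, which is orthogonal to a linear drift over a full turn —
#'     so this gauge is well conditioned even under strong drift.}
#'   \item{"nominalStep"}{Mean per-pair camera baseline set to
#'     \eqn{2 d \sin(\Delta\theta/2)}, the orbit baseline of the a-priori
#'     nominal rotation step at the calibrated stand-off \eqn{d}. Biased by
#'     the component of drift along the baseline.}
#'   \item{"depth"}{Mean triangulated bead depth of the first pair set to
#'     the stand-off; inherits the (random) offset of the bead centroid
#'     from the rotation axis.}
#' }
#'
#' @param chain a [PoseChain-class] (any current translation scale).
#' @param table the [BeadTrackTable-class] the chain was recovered from.
#' @param cam the [CameraModel-class].
#' @param gauge absolute-scale gauge, see Details.
#' @param nominalStepAngle a-priori nominal rotation step (radians),
#'   required for the "nominalStep" gauge.
#' @return the rescaled [PoseChain-class].
#' @export
fixTranslationScale <- function(chain, table, cam,
                                gauge = c("motionModel", "nominalStep", "depth"),
                                nominalStepAngle = NULL) {
  gauge <- match.arg(gauge)
  stopifnot(is(chain, "PoseChain"), is(table, "BeadTrackTable"),
            is(cam, "CameraModel"))
  G <- cameraExtrinsic(cam)
  nRel <- length(chain@relative)
  clouds <- vector("list", nRel)
  ids <- vector("list", nRel)
  rho <- numeric(nRel)
  depth1 <- NA_real_
  for (k in seq_len(nRel)) {
    M <- .sampleStepToCameraStep(chain@relative[[k]], G)
    tt <- M@translation
    nrm <- sqrt(sum(tt^2))
    if (nrm < 1e-12) stop("zero relative translation in pair ", k)
    Mu <- pose(M@rotation, tt / nrm)
    co <- correspondences(table, k - 1L, k)
    pA <- .normalizePoints(cam, co$ua, co$va)
    pB <- .normalizePoints(cam, co$ub, co$vb)
    X <- triangulatePoints(Mu, pA, pB)
    clouds[[k]] <- X
    ids[[k]] <- co$bead_id
    rho[k] <- sqrt(mean(dist(X)^2))
    if (k == 1L) depth1 <- mean(X[, 3L])
  }
  # relative per-pair baselines from bead-cloud rigidity: s_k ~ 1 / rho_k
  relScale <- rho[1L] / rho
  sizeGauge <- switch(gauge,
    depth = (cam@standoff / depth1) * rho[1L],
    nominalStep = {
      if (is.null(nominalStepAngle)) {
        stop("nominalStepAngle required for the nominalStep gauge")
      }
      2 * cam@standoff * sin(nominalStepAngle / 2) / mean(1 / rho)
    },
    motionModel = {
      # accumulated sample translation is affine in the global scale
      # lambda: T_k(lambda) = A_k + lambda B_k; fit T_k ~ k*v + c
      G2 <- cameraExtrinsic(cam)
      Rg <- G2@rotation; tg <- G2@translation
      A <- matrix(0, nRel + 1L, 3L)
      B <- matrix(0, nRel + 1L, 3L)
      for (k in seq_len(nRel)) {
        M <- .sampleStepToCameraStep(chain@relative[[k]], G2)
        tt <- M@translation
        th <- tt / sqrt(sum(tt^2))
        RdQ <- t(Rg) %*% M@rotation %*% Rg
        u <- as.numeric(t(Rg) %*% (M@rotation %*% tg - tg))
        w <- as.numeric(t(Rg) %*% (relScale[k] * th))
        A[k + 1L, ] <- as.numeric(RdQ %*% A[k, ]) + u
        B[k + 1L, ] <- as.numeric(RdQ %*% B[k, ]) + w
      }
      kk <- rep(0:nRel, 3L)
      comp <- rep(1:3, each = nRel + 1L)
      X <- cbind(-as.numeric(B),
                 (comp == 1) * kk, (comp == 2) * kk, (comp == 3) * kk,
                 comp == 1, comp == 2, comp == 3)
      lambda <- qr.solve(X, as.numeric(A))[1L]
      lambda * rho[1L]  # sizeGauge such that pairScale[1] = lambda
    })
  pairScale <- sizeGauge / rho
  # rigidity: compare each pair's scaled pairwise-distance set to pair 1's
  rigidity <- vapply(seq_len(nRel), function(k) {
    common <- intersect(ids[[1L]], ids[[k]])
    if (length(common) < 3L) return(NA_real_)
    d1 <- dist(clouds[[1L]][match(common, ids[[1L]]), , drop = FALSE]) * pairScale[1L]
    dk <- dist(clouds[[k]][match(common, ids[[k]]), , drop = FALSE]) * pairScale[k]
    sqrt(mean((dk - d1)^2)) / sqrt(mean(d1^2))
  }, numeric(1L))
  if (any(rigidity > 0.1, na.rm = TRUE)) {
    bad <- which(rigidity > 0.1)
    warning("inconsistent translation scales across pairs (rigidity residual > 10% for pair(s) ",
            paste(head(bad, 5L), collapse = ", "),
            "); per-pair scales: ", paste(signif(pairScale[bad], 4), collapse = ", "))
  }
  relative <- lapply(seq_len(nRel), function(k) {
    M <- .sampleStepToCameraStep(chain@relative[[k]], G)
    tt <- M@translation
    Mu <- pose(M@rotation, tt / sqrt(sum(tt^2)) * pairScale[k])
    orthonormalizePose(.cameraStepToSampleStep(Mu, G))
  })
  diag_ <- chain@diagnostics
  if (nrow(diag_) == nRel) {
    diag_$pairScale <- pairScale
    diag_$rigidity <- rigidity
  }
  .accumulateChain(relative, pairScale[1L], diag_)
}

.accumulateChain <- function(relative, scale, diagnostics) {
  n <- length(relative)
  absolute <- vector("list", n + 1L)
  absolute[[1L]] <- identityPose()
  for (k in seq_len(n)) {
    absolute[[k + 1L]] <- orthonormalizePose(
      composePose(relative[[k]], absolute[[k]]))
  }
  new("PoseChain", relative = relative, absolute = absolute,
      scale = scale, diagnostics = diagnostics)
}

#' Recover the per-frame pose chain from bead tracks
#'
#' The full pose-recovery pipeline. For each adjacent frame pair:
#' correspondences -> fundamental matrix (normalised eight-point when >= 8
#' beads are shared; direct essential least squares for 5-7) -> essential
#' matrix via \eqn{E = K^T F K} -> four-candidate decomposition ->
#' continuity selection (the reference is the previously selected pose; the
#' first pair is compared against an ideal step composed from a-priori
#' knowledge of the likely rotation angle). Translation scale is then fixed
#' through the triangulated bead cloud ([fixTranslationScale()]) and the
#' relative steps accumulated into absolute poses. All poses are expressed
#' in the sample-to-world convention of [motionSequence()], so recovered
#' and ground-truth chains are directly comparable.
#'
#' @param table a [BeadTrackTable-class].
#' @param cam a [CameraModel-class].
#' @param idealStep [Pose-class]: the a-priori expected sample step between
#'   adjacent frames, e.g. \code{pose(rotationAboutAxis(c(0,0,1), 2*pi/n))}.
#' @param minCoverage minimum track coverage for a bead to be used.
#' @param fixScale logical; fix the translation scale (default TRUE).
#' @param scaleGauge absolute-scale gauge, see [fixTranslationScale()].
#' @param refine logical; polish the selected candidate by
#'   Levenberg-Marquardt least squares on the Sampson residuals (the
#'   standard two-view refinement). With noisy tracks the linear
#'   eight-point solution is strongly perturbed in this narrow-field
#'   geometry; refinement pulls it back to the maximum-likelihood pose. The
#'   refinement initialised from the previous pair's pose is used instead
#'   whenever it attains a lower residual.
#' @return a [PoseChain-class] with per-pair diagnostics.
#' @export
recoverPoseChain <- function(table, cam, idealStep, minCoverage = 0.8,
                             fixScale = TRUE, scaleGauge = "motionModel",
                             refine = TRUE) {
  stopifnot(is(table, "BeadTrackTable"), is(cam, "CameraModel"),
            is(idealStep, "Pose"))
  ids <- usableBeadIds(table, minCoverage)
  if (length(ids) < 5L) {
    stop("only ", length(ids), " usable bead tracks; pose recovery requires ",
         "5 or more fiducial markers covering >= ", round(minCoverage * 100),
         "% of frames")
  }
  tr <- table@tracks
  sub <- beadTrackTable(tr[tr$bead_id %in% ids, ], nFrames = table@nFrames)
  n <- table@nFrames
  if (n < 2L) stop("at least 2 frames required")
  G <- cameraExtrinsic(cam)
  K <- intrinsicMatrix(cam)
  fpx <- cam@focalLength / cam@pixelPitch
  ref <- .sampleStepToCameraStep(idealStep, G)
  refStep <- idealStep
  relative <- vector("list", n - 1L)
  diags <- vector("list", n - 1L)
  # first pass: correspondences and epipolar estimates for every pair (the
  # estimation residuals yield the track-noise level that calibrates the
  # smoothness-prior weights of the refinement)
  pairData <- vector("list", n - 1L)
  for (k in seq_len(n - 1L)) {
    co <- tryCatch(correspondences(sub, k - 1L, k), error = function(e) {
      stop("pose recovery failed for frame pair (", k - 1L, ", ", k, "): ",
           conditionMessage(e), call. = FALSE)
    })
    pA <- .normalizePoints(cam, co$ua, co$va)
    pB <- .normalizePoints(cam, co$ub, co$vb)
    est <- if (nrow(co) >= 8L) {
      e <- tryCatch(estimateFundamental(co), error = function(err) {
        stop("pose recovery failed for frame pair (", k - 1L, ", ", k, "): ",
             conditionMessage(err), call. = FALSE)
      })
      essentialFromFundamental(e, cam)
    } else NULL
    pairData[[k]] <- list(co = co, pA = pA, pB = pB, est = est)
  }
  resids <- vapply(pairData, function(d) {
    if (is.null(d$est)) NA_real_ else d$est@residual
  }, numeric(1L))
  # robust track-noise scale (px); the eight-point residual underestimates
  # the per-coordinate noise slightly, hence the factor 2
  noiseSigma <- 2 * median(resids, na.rm = TRUE)
  if (!is.finite(noiseSigma)) noiseSigma <- 0.05
  # prior sds of genuine frame-to-frame motion deviation: ~1.5 mrad of
  # step-rotation deviation from the nominal step, ~1 world unit of
  # translation change between consecutive steps (stage drift of a few
  # pixels per frame must remain recoverable)
  wR <- noiseSigma / 1.5e-3
  wT <- noiseSigma / 1.0
  for (k in seq_len(n - 1L)) {
    co <- pairData[[k]]$co
    pA <- pairData[[k]]$pA
    pB <- pairData[[k]]$pB
    est <- pairData[[k]]$est
    if (is.null(est)) {
      E <- .estimateEssentialDirect(pA, pB, ref)
      F <- t(solve(K)) %*% E %*% solve(K)
      res <- sqrt(mean(sampsonDistance(F, cbind(co$ua, co$va),
                                       cbind(co$ub, co$vb))^2))
      est <- new("EpipolarEstimate", F = F, E = E, residual = res,
                 nPoints = nrow(co))
    }
    cands <- decomposeEssential(est@E)
    sel <- selectCandidate(cands, ref, pA, pB)
    idx <- which(vapply(cands@candidates, function(p) {
      identical(p@rotation, sel@rotation) &&
        identical(p@translation, sel@translation)
    }, logical(1L)))[1L]
    if (refine) {
      # the anchor blends the a-priori nominal step (rotation) with the
      # previous translation estimate (drift persists between pairs);
      # anchoring rotation to the *estimate* instead would feed estimation
      # noise back into itself
      anchorStep <- pose(idealStep@rotation, refStep@translation)
      fitSel <- .lmSampleStep(pA, pB, .candidateToSampleStep(sel, G), G, fpx,
                              anchor = anchorStep, rotAnchorWeight = wR,
                              transAnchorWeight = wT)
      fitRef <- .lmSampleStep(pA, pB, refStep, G, fpx, anchor = anchorStep,
                              rotAnchorWeight = wR, transAnchorWeight = wT)
      fit <- if (fitRef$objective < fitSel$objective) fitRef else fitSel
      relative[[k]] <- fit$pose
      diags[[k]] <- data.frame(pair = k - 1L, nPoints = est@nPoints,
                               residual = est@residual, candidate = idx,
                               refinedResidual = fit$rms,
                               pairScale = NA_real_, rigidity = NA_real_)
      refStep <- fit$pose
      ref <- .sampleStepToCameraStep(fit$pose, G)
    } else {
      relative[[k]] <- orthonormalizePose(.cameraStepToSampleStep(sel, G))
      diags[[k]] <- data.frame(pair = k - 1L, nPoints = est@nPoints,
                               residual = est@residual, candidate = idx,
                               refinedResidual = NA_real_,
                               pairScale = NA_real_, rigidity = NA_real_)
      ref <- sel
    }
  }
  chain <- .accumulateChain(relative, 1, do.call(rbind, diags))
  if (fixScale) {
    stepAngle <- acos(pmin(pmax((sum(diag(idealStep@rotation)) - 1) / 2, -1), 1))
    chain <- fixTranslationScale(chain, sub, cam, gauge = scaleGauge,
                                 nominalStepAngle = stepAngle)
  }
  chain
}

# rotation vector (axis * angle) of a rotation matrix
.rotationVector <- function(R) {
  ang <- acos(pmin(pmax((sum(diag(R)) - 1) / 2, -1), 1))
  if (ang < 1e-12) return(c(0, 0, 0))
  ax <- c(R[3L, 2L] - R[2L, 3L], R[1L, 3L] - R[3L, 1L], R[2L, 1L] - R[1L, 2L])
  nrm <- sqrt(sum(ax^2))
  if (nrm < 1e-12) {
    # angle near pi: take axis from the symmetric part
    ax <- sqrt(pmax(diag(R) + 1, 0) / 2)
    ax <- ax / sqrt(sum(ax^2))
    return(ang * ax)
  }
  ang * ax / nrm
}

#' Regularise a recovered chain onto the smooth acquisition model
#'
#' Per-pair two-view estimates in this narrow-field geometry carry noise
#' that accumulates along the chain as a random walk. An OPT acquisition,
#' however, is smooth: uniform rotation steps with (at most) slow axis
#' precession and constant-velocity drift. This filter regresses the
#' recovered chain onto that model — each component of the per-pair step
#' rotation vector is fitted linearly in the frame index (capturing the
#' constant step and linear precession), and the absolute translation
#' trajectory is fitted as proportional to the frame index (constant
#' velocity, zero at frame 0) — and rebuilds the chain from the fits.
#' Per-frame random jitter, if present, is smoothed away; do not apply the
#' filter when jitter itself is the quantity of interest.
#'
#' @param chain a recovered [PoseChain-class].
#' @return the smoothed [PoseChain-class].
#' @export
smoothChain <- function(chain) {
  stopifnot(is(chain, "PoseChain"))
  n <- length(chain@relative)
  if (n < 4L) return(chain)
  W <- t(vapply(chain@relative, function(p) .rotationVector(p@rotation),
                numeric(3L)))
  k <- seq_len(n) - 1
  X <- cbind(1, k)
  Wfit <- X %*% qr.solve(X, W)
  Tabs <- t(vapply(chain@absolute, function(p) p@translation, numeric(3L)))
  kk <- 0:n
  vel <- qr.solve(matrix(kk, ncol = 1L), Tabs)
  Tfit <- matrix(kk, ncol = 1L) %*% vel
  absoluteR <- vector("list", n + 1L)
  absoluteR[[1L]] <- diag(3)
  for (i in seq_len(n)) {
    w <- Wfit[i, ]
    Rstep <- rotationAboutAxis(if (sum(w^2) > 0) w else c(1, 0, 0),
                               sqrt(sum(w^2)))
    absoluteR[[i + 1L]] <- orthonormalize(Rstep %*% absoluteR[[i]])
  }
  absolute <- lapply(seq_len(n + 1L), function(i) {
    pose(absoluteR[[i]], Tfit[i, ])
  })
  relative <- lapply(seq_len(n), function(i) {
    composePose(absolute[[i + 1L]], invertPose(absolute[[i]]))
  })
  new("PoseChain", relative = relative, absolute = absolute,
      scale = chain@scale, diagnostics = chain@diagnostics)
}

#' Absolute per-frame translations from the bead map
#'
#' Two-view epipolar constraints cannot observe a translation component
#' parallel to the camera baseline — for a turntable acquisition that is
#' exactly the direction a systematic lateral drift lives in. The absolute
#' information is in where the bead constellation is imaged. With the
#' camera extrinsic calibrated and the chain's rotations held fixed, the
#' translation trajectory is re-estimated globally from the bead
#' reprojection residuals under the constant-velocity motion model:
#' unknowns are the drift velocity \eqn{v} (translation of frame k is
#' \eqn{k v}) and a rigid offset \eqn{\delta} of the triangulated bead
#' map (the gauge the relative chain cannot fix). Over a full turn the
#' rotating signature of a map offset is separable from the linear drift,
#' and a frame-0 depth offset appears as a lateral offset a quarter turn
#' later, so every component is well observed. The bead map itself comes
#' from two-view triangulation of the first adjacent pair and is optionally
#' re-triangulated from all frames once the trajectory is known. Structure
#' and rotations are not jointly re-optimised.
#'
#' @param chain a recovered (and usually [smoothChain()]-ed)
#'   [PoseChain-class].
#' @param table the [BeadTrackTable-class].
#' @param cam the [CameraModel-class].
#' @param minCoverage minimum track coverage for a bead to be used.
#' @param iterations map/trajectory alternations (the first uses the
#'   two-view map, later ones re-triangulate from all frames).
#' @return the [PoseChain-class] with updated translations.
#' @export
refineTranslations <- function(chain, table, cam, minCoverage = 0.8,
                               iterations = 2L) {
  stopifnot(is(chain, "PoseChain"), is(table, "BeadTrackTable"),
            is(cam, "CameraModel"))
  ids <- usableBeadIds(table, minCoverage)
  tr <- table@tracks
  tr <- tr[tr$bead_id %in% ids, ]
  n <- length(chain@absolute)
  G <- cameraExtrinsic(cam)
  Rg <- G@rotation; tg <- G@translation
  fpx <- cam@focalLength / cam@pixelPitch
  norm <- .normalizePoints(cam, tr$u, tr$v)
  tr$xn <- norm[, 1L]; tr$yn <- norm[, 2L]
  # bead map from the first adjacent pair: its relative pose is locally
  # accurate even when the accumulated chain carries drift error
  M1 <- .sampleStepToCameraStep(chain@relative[[1L]], G)
  a0 <- tr[tr$frame == 0L, ]
  a1 <- tr[tr$frame == 1L, ]
  common <- intersect(a0$bead_id, a1$bead_id)
  if (length(common) < 3L) stop("need >= 3 beads visible in frames 0 and 1")
  Xc0 <- triangulatePoints(M1,
                           cbind(a0$xn[match(common, a0$bead_id)],
                                 a0$yn[match(common, a0$bead_id)]),
                           cbind(a1$xn[match(common, a1$bead_id)],
                                 a1$yn[match(common, a1$bead_id)]))
  ids <- common
  tr <- tr[tr$bead_id %in% ids, ]
  smap <- t(t(Xc0 %*% Rg) - as.numeric(t(Rg) %*% tg))  # Rg^T (Xc - tg)
  obsFrames <- sort(unique(tr$frame))
  obsFrames <- obsFrames[obsFrames < n]
  obsList <- lapply(obsFrames, function(f) {
    ob <- tr[tr$frame == f, ]
    list(k = f, idx = match(ob$bead_id, ids), obs = cbind(ob$xn, ob$yn))
  })
  rots <- lapply(chain@absolute, function(p) p@rotation)
  # initial drift velocity from the chain trajectory
  Tabs <- t(vapply(chain@absolute, function(p) p@translation, numeric(3L)))
  v0 <- as.numeric(qr.solve(matrix(0:(n - 1L), ncol = 1L), Tabs))
  par0 <- c(v0, 0, 0, 0)
  resfun <- function(par) {
    v <- par[1:3]; delta <- par[4:6]
    unlist(lapply(obsList, function(o) {
      S <- sweep(smap[o$idx, , drop = FALSE], 2L, delta, `+`)
      Tk <- o$k * v
      Xc <- t(Rg %*% (rots[[o$k + 1L]] %*% t(S) + Tk) + tg)
      fpx * as.numeric(Xc[, 1:2] / Xc[, 3L] - o$obs)
    }))
  }
  for (it in seq_len(iterations)) {
    fit <- suppressWarnings(
      minpack.lm::nls.lm(par = par0, fn = resfun,
                         control = minpack.lm::nls.lm.control(maxiter = 200)))
    par0 <- fit$par
    if (it < iterations) {
      # re-triangulate the map from all frames at the fitted trajectory
      v <- par0[1:3]
      Ms <- lapply(seq_len(n), function(k) {
        cbind(Rg %*% rots[[k]], as.numeric(Rg %*% ((k - 1L) * v)) + tg)
      })
      for (i in seq_along(ids)) {
        ob <- tr[tr$bead_id == ids[i] & tr$frame < n, ]
        A <- do.call(rbind, lapply(seq_len(nrow(ob)), function(j) {
          M <- Ms[[ob$frame[j] + 1L]]
          rbind(ob$xn[j] * M[3L, ] - M[1L, ],
                ob$yn[j] * M[3L, ] - M[2L, ])
        }))
        vv <- svd(A)$v[, 4L]
        cand <- vv[1:3] / vv[4L]
        if (all(is.finite(cand)) && sqrt(sum(cand^2)) < 0.25 * cam@standoff) {
          smap[i, ] <- cand
        }
      }
      par0[4:6] <- 0
    }
  }
  v <- par0[1:3]
  absolute <- lapply(seq_len(n), function(k) {
    pose(rots[[k]], (k - 1L) * v)
  })
  relative <- lapply(seq_len(n - 1L), function(k) {
    composePose(absolute[[k + 1L]], invertPose(absolute[[k]]))
  })
  new("PoseChain", relative = relative, absolute = absolute,
      scale = chain@scale, diagnostics = chain@diagnostics)
}

#' Per-pair recovery errors of a pose chain against ground truth
#'
#' Compares, for every adjacent frame pair, the recovered relative
#' transform with the ground-truth one in the convention the decomposition
#' itself produces: the camera-relative rotation and the unit-normalised
#' translation direction (the essential matrix determines no translation
#' scale, so directions are what the factorisation is accountable for).
#' Errors use the element-wise percentage formula of
#' [matrixRecoveryError()].
#'
#' @param chain a recovered [PoseChain-class].
#' @param truthPoses list of ground-truth sample poses (one per frame).
#' @param cam the [CameraModel-class].
#' @return 2 x (n-1) matrix with rows R and T (percent).
#' @export
relativePoseErrors <- function(chain, truthPoses, cam) {
  G <- cameraExtrinsic(cam)
  unitT <- function(p) {
    tt <- p@translation
    nrm <- sqrt(sum(tt^2))
    if (nrm > 1e-12) tt <- tt / nrm
    pose(p@rotation, tt)
  }
  n <- length(truthPoses)
  stopifnot(length(chain@relative) == n - 1L)
  vapply(seq_len(n - 1L), function(k) {
    dTrue <- composePose(truthPoses[[k + 1L]], invertPose(truthPoses[[k]]))
    Mtrue <- unitT(.sampleStepToCameraStep(dTrue, G))
    Mrec <- unitT(.sampleStepToCameraStep(chain@relative[[k]], G))
    matrixRecoveryError(Mrec, Mtrue)
  }, numeric(2L))
}
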