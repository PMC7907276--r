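# Sub-pixel fiducial detection and frame-to-frame linking (the
# correspondence step). Beads are bright punctate spots; centres are refined
# by 2D Gaussian least squares, which is robust to noise and gives the
# sub-pixel precision the epipolar estimation needs.

# 3x3-neighbourhood local maxima of a matrix, returned as (row, col) indices.
.localMaxima <- function(m) {
  H <- nrow(m); W <- ncol(m)
  if (H < 3L || W < 3L) return(cbind(row = integer(), col = integer()))
  c0 <- m[2:(H - 1), 2:(W - 1)]
  ok <- c0 >= m[1:(H - 2), 2:(W - 1)] & c0 >= m[3:H, 2:(W - 1)] &
    c0 >= m[2:(H - 1), 1:(W - 2)] & c0 >= m[2:(H - 1), 3:W] &
    c0 >= m[1:(H - 2), 1:(W - 2)] & c0 >= m[1:(H - 2), 3:W] &
    c0 >= m[3:H, 1:(W - 2)] & c0 >= m[3:H, 3:W]
  idx <- which(ok, arr.ind = TRUE)
  cbind(row = idx[, 1L] + 1L, col = idx[, 2L] + 1L)
}

# Least-squares fit of A*exp(-r^2/(2 s^2)) + b over a window around a peak.
# Pixels nearer to another candidate peak than to this one are excluded, so
# neighbouring spots do not bias the fit. Returns NULL when the fit is
# implausible (sigma way off, tiny amplitude).
.fitGaussian <- function(frame, rowPeak, colPeak, expectedSigma,
                         otherPeaks = NULL) {
  H <- nrow(frame); W <- ncol(frame)
  w <- max(2L, as.integer(ceiling(3 * expectedSigma)))
  rows <- max(1L, rowPeak - w):min(H, rowPeak + w)
  cols <- max(1L, colPeak - w):min(W, colPeak + w)
  if (length(rows) < 4L || length(cols) < 4L) return(NULL)
  z <- frame[rows, cols]
  v <- rep(rows - 1, times = length(cols))  # 0-based pixel coords
  u <- rep(cols - 1, each = length(rows))
  zv <- as.numeric(z)
  if (!is.null(otherPeaks) && nrow(otherPeaks)) {
    dSelf <- (v - (rowPeak - 1))^2 + (u - (colPeak - 1))^2
    dOther <- rep(Inf, length(u))
    for (i in seq_len(nrow(otherPeaks))) {
      dOther <- pmin(dOther, (v - (otherPeaks[i, 1L] - 1))^2 +
                       (u - (otherPeaks[i, 2L] - 1))^2)
    }
    keep <- dSelf <= dOther
    if (sum(keep) < 8L) return(NULL)
    u <- u[keep]; v <- v[keep]; zv <- zv[keep]
  }
  b0 <- min(zv)
  du <- u - (colPeak - 1)
  dv <- v - (rowPeak - 1)
  # model: Gaussian spot on a locally linear background (a plane handles
  # the smooth projection texture underneath a bead without biasing the
  # centre the way a constant offset does)
  p0 <- c(A = max(zv) - b0, u0 = colPeak - 1, v0 = rowPeak - 1,
          s = expectedSigma, b = b0, gu = 0, gv = 0)
  res <- function(p) {
    zv - (p[1L] * exp(-((u - p[2L])^2 + (v - p[3L])^2) / (2 * p[4L]^2)) +
            p[5L] + p[6L] * du + p[7L] * dv)
  }
  fit <- tryCatch(
    suppressWarnings(minpack.lm::nls.lm(par = p0, fn = res,
                       lower = c(0, colPeak - 1 - w, rowPeak - 1 - w,
                                 0.2 * expectedSigma, -Inf, -Inf, -Inf),
                       upper = c(Inf, colPeak - 1 + w, rowPeak - 1 + w,
                                 5 * expectedSigma, Inf, Inf, Inf),
                       control = minpack.lm::nls.lm.control(maxiter = 60))),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  p <- fit$par
  if (p[1L] <= 0 || p[4L] < 0.75 * expectedSigma || p[4L] > 1.5 * expectedSigma) {
    return(NULL)
  }
  data.frame(u = p[2L], v = p[3L], amplitude = p[1L], sigma = p[4L],
             residual = sqrt(mean(res(p)^2)))
}

#' Detect fiducial beads in one frame with sub-pixel precision
#'
#' Candidate peaks are 3x3 local maxima exceeding \code{median + thresholdSigma
#' * MAD} of the (optionally high-pass filtered) frame; each is refined by a
#' 2D Gaussian least-squares fit in a window of half-width
#' \code{3 * expectedSigma}. Duplicates within \code{2 * expectedSigma} are
#' merged, keeping the lower-residual fit. High-pass pre-filtering (frame
#' minus a broad box blur) suppresses the smooth testcard projection
#' background so only punctate spots trigger detection.
#'
#' @param frame numeric matrix (grayscale image, rows = v).
#' @param thresholdSigma detection threshold in robust background sigmas.
#' @param expectedSigma expected spot sigma in pixels.
#' @param highpass logical, subtract a broad box-blurred background before
#'   peak finding (the Gaussian refinement always runs on the raw frame with
#'   a local offset term).
#' @return data.frame with columns u, v (0-based sub-pixel centre),
#'   amplitude, sigma, residual; zero rows if nothing is found (a
#'   zero-variance frame is not an error).
#' @export
detectBeads <- function(frame, thresholdSigma = 8, expectedSigma = 1.5,
                        highpass = TRUE) {
  stopifnot(is.matrix(frame))
  empty <- data.frame(u = numeric(), v = numeric(), amplitude = numeric(),
                      sigma = numeric(), residual = numeric())
  if (sd(frame) == 0) return(empty)
  det_img <- if (highpass) {
    w <- 2L * as.integer(ceiling(4 * expectedSigma)) + 1L
    frame - boxBlur(frame, w)
  } else frame
  thr <- median(det_img) + thresholdSigma * max(mad(det_img), 1e-12)
  peaks <- .localMaxima(det_img)
  if (nrow(peaks)) peaks <- peaks[det_img[peaks] > thr, , drop = FALSE]
  if (!nrow(peaks)) return(empty)
  fits <- do.call(rbind, lapply(seq_len(nrow(peaks)), function(i) {
    .fitGaussian(frame, peaks[i, 1L], peaks[i, 2L], expectedSigma,
                 otherPeaks = peaks[-i, , drop = FALSE])
  }))
  if (is.null(fits) || !nrow(fits)) return(empty)
  # merge duplicates within 2 * expectedSigma, keeping the lower residual
  fits <- fits[order(fits$residual), , drop = FALSE]
  keep <- rep(TRUE, nrow(fits))
  for (i in seq_len(nrow(fits))) {
    if (!keep[i]) next
    if (i < nrow(fits)) {
      later <- (i + 1L):nrow(fits)
      d2 <- (fits$u[later] - fits$u[i])^2 + (fits$v[later] - fits$v[i])^2
      keep[later][d2 < (2 * expectedSigma)^2] <- FALSE
    }
  }
  fits <- fits[keep, , drop = FALSE]
  H <- nrow(frame); W <- ncol(frame)
  fits <- fits[fits$u >= 0 & fits$u <= W - 1 & fits$v >= 0 & fits$v <= H - 1, ,
               drop = FALSE]
  rownames(fits) <- NULL
  fits
}

#' Link per-frame detections into identity-consistent tracks
#'
#' Greedy mutual-nearest-neighbour linking from frame k to k+1 with
#' constant-velocity prediction (predicted position = last position + last
#' displacement). Links beyond \code{maxStep} pixels of the prediction are
#' rejected; when two detections claim the same track the nearer wins and
#' the other starts a new track. A bead missing from a frame may be
#' re-acquired within \code{2 * maxStep} of its prediction for up to
#' \code{maxGap} frames, after which the track closes. Track ids are
#' assigned in the first frame's detection order.
#'
#' @param detectionsPerFrame list (one per frame) of data.frames as returned
#'   by [detectBeads()].
#' @param maxStep maximum frame-to-frame displacement from the predicted
#'   position, pixels.
#' @param maxGap maximum number of consecutive missed frames.
#' @return a [BeadTrackTable-class]; tracks covering fewer than 80\% of the
#'   frames are flagged in its \code{usable} attribute-free helper
#'   [usableBeadIds()].
#' @export
linkTracks <- function(detectionsPerFrame, maxStep = 10, maxGap = 2L) {
  nF <- length(detectionsPerFrame)
  if (nF < 2L) stop("at least 2 frames required for linking")
  rows <- list()
  nextId <- 0L
  active <- list()  # id, last (u,v), prev (u,v or NULL), lastFrame, miss
  for (k in seq_len(nF)) {
    det <- detectionsPerFrame[[k]]
    nd <- if (is.null(det)) 0L else nrow(det)
    linkedDet <- rep(FALSE, nd)
    if (length(active) && nd) {
      pred <- t(vapply(active, function(a) {
        if (is.null(a$prev)) a$last else a$last + (a$last - a$prev)
      }, numeric(2L)))
      lim <- vapply(active, function(a) if (a$miss > 0L) 2 * maxStep else maxStep,
                    numeric(1L))
      D <- outer(pred[, 1L], det$u, "-")^2 + outer(pred[, 2L], det$v, "-")^2
      D[D > matrix(lim^2, nrow(D), ncol(D))] <- Inf
      # repeated global-minimum pairing = mutual nearest neighbours
      while (any(is.finite(D))) {
        ij <- arrayInd(which.min(D), dim(D))
        a <- ij[1L]; d <- ij[2L]
        tr <- active[[a]]
        rows[[length(rows) + 1L]] <- data.frame(
          frame = k - 1L, bead_id = tr$id, u = det$u[d], v = det$v[d])
        # after a gap the stale velocity is dropped (prediction = position)
        active[[a]]["prev"] <- if (tr$miss > 0L) list(NULL) else list(tr$last)
        active[[a]]$last <- c(det$u[d], det$v[d])
        active[[a]]$lastFrame <- k
        active[[a]]$miss <- 0L
        linkedDet[d] <- TRUE
        D[a, ] <- Inf
        D[, d] <- Inf
      }
    }
    # unmatched detections found a new track each
    if (nd) {
      for (d in which(!linkedDet)) {
        active[[length(active) + 1L]] <- list(
          id = nextId, last = c(det$u[d], det$v[d]), prev = NULL,
          lastFrame = k, miss = 0L)
        rows[[length(rows) + 1L]] <- data.frame(
          frame = k - 1L, bead_id = nextId, u = det$u[d], v = det$v[d])
        nextId <- nextId + 1L
      }
    }
    # age unmatched tracks; close those exceeding the gap allowance
    if (length(active)) {
      stillOpen <- logical(length(active))
      for (a in seq_along(active)) {
        if (active[[a]]$lastFrame < k) active[[a]]$miss <- active[[a]]$miss + 1L
        stillOpen[a] <- active[[a]]$miss <= maxGap
      }
      active <- active[stillOpen]
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(frame = integer(), bead_id = integer(), u = numeric(), v = numeric())
  }
  tab <- tab[order(tab$frame, tab$bead_id), ]
  rownames(tab) <- NULL
  beadTrackTable(tab, nFrames = nF)
}

#' Construct a bead track table from a (frame, bead_id, u, v) data.frame
#'
#' @param tracks data.frame with columns frame, bead_id, u, v (0-based
#'   frames, floating-point pixel coordinates).
#' @param nFrames number of frames the table spans (default: max frame + 1).
#' @return a [BeadTrackTable-class].
#' @export
beadTrackTable <- function(tracks, nFrames = NULL) {
  if (is.null(nFrames)) {
    nFrames <- if (nrow(tracks)) max(tracks$frame) + 1L else 0L
  }
  new("BeadTrackTable", tracks = tracks,
      nBeads = length(unique(tracks$bead_id)),
      nFrames = as.integer(nFrames))
}

#' Bead ids whose tracks are usable for pose recovery
#'
#' A track is usable when it covers at least \code{minCoverage} of the
#' frames (gaps allowed).
#'
#' @param table a [BeadTrackTable-class].
#' @param minCoverage minimum fraction of frames covered.
#' @return integer vector of bead ids.
#' @export
usableBeadIds <- function(table, minCoverage = 0.8) {
  stopifnot(is(table, "BeadTrackTable"))
  counts <- table(table@tracks$bead_id)
  as.integer(names(counts)[counts >= minCoverage * table@nFrames])
}

#' Paired bead coordinates between two frames
#'
#' Returns the pixel coordinates of every bead detected in \emph{both}
#' frames, ordered by bead id — the correspondence set the epipolar
#' estimation consumes. Fewer than 5 common beads is an error (the method
#' requires 5 or more fiducial markers).
#'
#' @param table a [BeadTrackTable-class].
#' @param frameA,frameB 0-based frame indices.
#' @return data.frame with columns bead_id, ua, va, ub, vb.
#' @export
correspondences <- function(table, frameA, frameB) {
  stopifnot(is(table, "BeadTrackTable"))
  tr <- table@tracks
  a <- tr[tr$frame == frameA, ]
  b <- tr[tr$frame == frameB, ]
  if (!nrow(a) || !nrow(b)) {
    stop("frames ", frameA, " and/or ", frameB, " not present in track table")
  }
  m <- merge(a, b, by = "bead_id", suffixes = c("_a", "_b"))
  if (nrow(m) < 5L) {
    stop("only ", nrow(m), " beads common to frames ", frameA, " and ",
         frameB, "; pose recovery requires 5 or more fiducial markers")
  }
  m <- m[order(m$bead_id), ]
  data.frame(bead_id = m$bead_id, ua = m$u_a, va = m$v_a,
             ub = m$u_b, vb = m$v_b)
}
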