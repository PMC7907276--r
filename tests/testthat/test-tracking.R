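renderSpots <- function(centers, size = 64L, sigma = 1.5, amplitude = 100) {
  fr <- matrix(0, size, size)
  us <- seq_len(size) - 1
  for (i in seq_len(nrow(centers))) {
    fr <- fr + amplitude * outer(exp(-(us - centers[i, 2L])^2 / (2 * sigma^2)),
                                 exp(-(us - centers[i, 1L])^2 / (2 * sigma^2)))
  }
  fr
}

test_that("bead detection is sub-pixel accurate on clean spots", {
  expect_identical(nrow(detectBeads(matrix(0, 32, 32))), 0L)
  d <- detectBeads(renderSpots(rbind(c(20.3, 41.7))), highpass = FALSE)
  expect_identical(nrow(d), 1L)
  expect_lt(abs(d$u - 20.3), 0.05)
  expect_lt(abs(d$v - 41.7), 0.05)
  expect_equal(d$sigma, 1.5, tolerance = 0.05)
  two <- renderSpots(rbind(c(20, 30), c(30, 30)))
  d2 <- detectBeads(two, highpass = FALSE)
  expect_identical(nrow(d2), 2L)
  d2 <- d2[order(d2$u), ]
  expect_lt(abs(d2$u[1L] - 20), 0.1)
  expect_lt(abs(d2$u[2L] - 30), 0.1)
  expect_lt(max(abs(d2$v - 30)), 0.1)
})

test_that("detection count is non-increasing in the threshold", {
  set.seed(4)
  fr <- renderSpots(cbind(runif(6, 8, 56), runif(6, 8, 56)),
                    amplitude = 50) +
    matrix(abs(rnorm(64 * 64, 0, 2)), 64, 64)
  counts <- vapply(c(2, 5, 10, 20, 50),
                   function(th) nrow(detectBeads(fr, thresholdSigma = th,
                                                 highpass = FALSE)),
                   integer(1L))
  expect_true(all(diff(counts) <= 0L))
})

test_that("linking preserves identities and handles track loss", {
  # static beads: zero displacement, ids preserved in detection order
  det <- data.frame(u = c(10, 30, 50), v = c(12, 32, 52),
                    amplitude = 1, sigma = 1.5, residual = 0)
  tab <- linkTracks(replicate(10, det, simplify = FALSE))
  tr <- as.data.frame(tab)
  expect_identical(sort(unique(tr$bead_id)), 0:2)
  for (id in 0:2) {
    t1 <- tr[tr$bead_id == id, ]
    expect_identical(nrow(t1), 10L)
    expect_equal(diff(t1$u), rep(0, 9L))
    expect_equal(t1$u[1L], det$u[id + 1L])
  }
  # one bead leaving the field of view: its track ends, others continue
  dets <- lapply(0:9, function(k) {
    d <- data.frame(u = c(10 + 5 * k, 30, 50), v = c(12, 32, 52),
                    amplitude = 1, sigma = 1.5, residual = 0)
    d[d$u <= 60, ]
  })
  tab2 <- linkTracks(dets, maxStep = 8)
  tr2 <- as.data.frame(tab2)
  expect_identical(nrow(tr2[tr2$bead_id == 0L, ]), sum(10 + 5 * (0:9) <= 60))
  expect_identical(nrow(tr2[tr2$bead_id == 1L, ]), 10L)
  expect_identical(nrow(tr2[tr2$bead_id == 2L, ]), 10L)
})

test_that("detect-and-link reproduces ground-truth tracks on ideal rotation", {
  cam <- smallCam()
  beads <- placeBeads(8, 20, seed = 1)
  model <- motionModel(nFrames = 32L)
  stack <- simulateAcquisition(NULL, beads, model, cam)
  dets <- lapply(seq_len(32L), function(k)
    detectBeads(getFrame(stack, k), highpass = FALSE))
  tab <- linkTracks(dets)
  gt <- groundTruthTracks(stack)
  expect_identical(length(usableBeadIds(tab)), 8L)
  # match recovered tracks to ground-truth beads via frame-0 positions,
  # then require sub-quarter-pixel agreement and zero identity swaps
  rec <- as.data.frame(tab)
  rec0 <- rec[rec$frame == 0L, ]
  gt0 <- gt[gt$frame == 0L, ]
  err2 <- 0
  nmatched <- 0L
  for (i in seq_len(nrow(gt0))) {
    j <- which.min((rec0$u - gt0$u[i])^2 + (rec0$v - gt0$v[i])^2)
    rid <- rec0$bead_id[j]
    rtr <- rec[rec$bead_id == rid, ]
    gtr <- gt[gt$bead_id == gt0$bead_id[i], ]
    m <- merge(rtr, gtr, by = "frame")
    expect_identical(nrow(m), 32L)  # no gaps, no swaps
    err2 <- err2 + sum((m$u.x - m$u.y)^2 + (m$v.x - m$v.y)^2)
    nmatched <- nmatched + nrow(m)
  }
  expect_lt(sqrt(err2 / nmatched), 0.25)
})

test_that("correspondences pair beads seen in both frames", {
  gt <- exactTracks(placeBeads(8, 20, seed = 1),
                    motionSequence(motionModel(nFrames = 16L)), smallCam())
  tab <- beadTrackTable(gt, nFrames = 16L)
  self <- correspondences(tab, 3L, 3L)
  expect_identical(self$ua, self$ub)
  expect_identical(self$va, self$vb)
  adj <- correspondences(tab, 0L, 1L)
  expect_identical(nrow(adj), 8L)
  expect_identical(adj$bead_id, sort(adj$bead_id))
  # fewer than 5 shared beads is an error naming the frames
  sub <- gt[!(gt$bead_id %in% 0:3 & gt$frame == 1L), ]
  expect_error(correspondences(beadTrackTable(sub, 16L), 0L, 1L),
               "5 or more")
  expect_error(correspondences(tab, 0L, 99L), "not present")
})
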