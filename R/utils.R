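# Internal helpers: local RNG scoping, small image utilities.

# Run code with a local RNG seed, restoring the caller's RNG state so that
# simulator determinism never leaks into (or depends on) the session RNG.
withLocalSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Separable box blur with edge replication; w is the (odd) window width.
boxBlur <- function(img, w) {
  if (w <= 1L) return(img)
  h <- (w - 1L) %/% 2L
  blur1 <- function(m) {
    n <- nrow(m)
    idx <- pmin(pmax(seq_len(n + 2L * h) - h, 1L), n)
    cs <- apply(m[idx, , drop = FALSE], 2L, cumsum)
    (cs[seq_len(n) + 2L * h, , drop = FALSE] -
       rbind(0, cs)[seq_len(n) + 0L, , drop = FALSE]) / (2L * h + 1L)
  }
  t(blur1(t(blur1(img))))
}

#' Normalise a matrix to [0, 1] by its own range
#'
#' Convenience rescaling used before intensity-based metrics when the test
#' image has an arbitrary scale (e.g. a reconstruction).
#'
#' @param m numeric matrix with a non-zero range.
#' @return matrix rescaled to [0, 1].
#' @export
rescale01 <- function(m) {
  r <- range(m)
  if (r[2L] - r[1L] <= 0) stop("cannot rescale a constant image")
  (m - r[1L]) / (r[2L] - r[1L])
}

#' Central square crop of a matrix
#'
#' @param m numeric matrix.
#' @param s crop side length (<= both dimensions).
#' @return s x s matrix.
#' @export
cropCenter <- function(m, s) {
  r0 <- floor((nrow(m) - s) / 2)
  c0 <- floor((ncol(m) - s) / 2)
  m[r0 + seq_len(s), c0 + seq_len(s), drop = FALSE]
}

# Bilinear resample of a matrix to ny x nx (used for testcard input images).
resizeBilinear <- function(img, ny, nx) {
  sy <- (nrow(img) - 1) / max(ny - 1, 1L)
  sx <- (ncol(img) - 1) / max(nx - 1, 1L)
  y <- (seq_len(ny) - 1) * sy + 1
  x <- (seq_len(nx) - 1) * sx + 1
  y0 <- pmin(floor(y), nrow(img) - 1L); x0 <- pmin(floor(x), ncol(img) - 1L)
  fy <- y - y0; fx <- x - x0
  a <- img[y0, x0, drop = FALSE]; b <- img[y0 + 1L, x0, drop = FALSE]
  c_ <- img[y0, x0 + 1L, drop = FALSE]; d <- img[y0 + 1L, x0 + 1L, drop = FALSE]
  a * outer(1 - fy, 1 - fx) + b * outer(fy, 1 - fx) +
    c_ * outer(1 - fy, fx) + d * outer(fy, fx)
}
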