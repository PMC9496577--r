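#' Planar homography utilities
#'
#' A projective homography between two planes is the transform family a
#' camera imposes when photographing a flat plate: four point
#' correspondences (8 constraints) determine its 8 degrees of freedom
#' exactly. `fit_homography()` uses the normalized direct linear transform;
#' with exactly four non-collinear correspondences the fit is exact up to
#' floating point.
#'
#' @param src,dst `n x 2` matrices of corresponding points (`n >= 4`).
#' @return `fit_homography()`: a 3x3 matrix `H` (normalized so `H[3,3] = 1`)
#'   mapping `src` to `dst`; `apply_homography()`: an `n x 2` matrix.
#' @export
fit_homography <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  if (nrow(src) < 4L || nrow(dst) != nrow(src))
    stop("need at least 4 point correspondences")
  if (any_collinear_triple(src) || any_collinear_triple(dst))
    stop("degenerate fiducial geometry: three points are collinear")
  ns <- normalize_pts(src); nd <- normalize_pts(dst)
  s <- ns$pts; d <- nd$pts
  n <- nrow(s)
  A <- matrix(0, 2L * n, 9L)
  for (i in seq_len(n)) {
    x <- s[i, 1]; y <- s[i, 2]; u <- d[i, 1]; v <- d[i, 2]
    A[2 * i - 1, ] <- c(-x, -y, -1, 0, 0, 0, u * x, u * y, u)
    A[2 * i, ]     <- c(0, 0, 0, -x, -y, -1, v * x, v * y, v)
  }
  e <- eigen(crossprod(A), symmetric = TRUE)
  h <- e$vectors[, 9L]          # null-space direction: smallest eigenvalue
  H <- matrix(h, 3L, 3L, byrow = TRUE)
  H <- solve(nd$T) %*% H %*% ns$T
  if (abs(H[3L, 3L]) < .Machine$double.eps * 100)
    stop("degenerate homography (vanishing scale)")
  H / H[3L, 3L]
}

#' @rdname fit_homography
#' @param H 3x3 homography matrix.
#' @param pts `n x 2` matrix of points.
#' @export
apply_homography <- function(H, pts) {
  pts <- rbind(t(as.matrix(pts)), 1)
  out <- H %*% pts
  w <- out[3L, ]
  if (any(abs(w) < .Machine$double.eps * 100))
    stop("point maps to infinity under homography")
  cbind(out[1L, ] / w, out[2L, ] / w)
}

# Hartley normalization: translate centroid to origin, scale mean distance
# to sqrt(2). Returns normalized points and the 3x3 transform used.
normalize_pts <- function(pts) {
  ctr <- colMeans(pts)
  d <- sqrt(rowSums(sweep(pts, 2L, ctr)^2))
  s <- if (mean(d) > 0) sqrt(2) / mean(d) else 1
  T <- matrix(c(s, 0, -s * ctr[1], 0, s, -s * ctr[2], 0, 0, 1), 3L, 3L, byrow = TRUE)
  list(pts = cbind((pts[, 1] - ctr[1]) * s, (pts[, 2] - ctr[2]) * s), T = T)
}

any_collinear_triple <- function(pts, tol = 1e-8) {
  n <- nrow(pts)
  combs <- utils::combn(n, 3L)
  span <- max(dist(pts))
  for (k in seq_len(ncol(combs))) {
    p <- pts[combs[, k], ]
    cross <- (p[2, 1] - p[1, 1]) * (p[3, 2] - p[1, 2]) -
             (p[2, 2] - p[1, 2]) * (p[3, 1] - p[1, 1])
    if (abs(cross) < tol * span^2) return(TRUE)
  }
  FALSE
}

# Bilinear sample a plate image at pixel coordinates (x, y); pixel centres
# at half-integers. Returns n x 3 matrix, NA where a required neighbour is
# outside the image or is itself NA.
sample_bilinear <- function(img, x, y) {
  d <- dim(img); H <- d[1]; W <- d[2]
  u <- x + 0.5; v <- y + 0.5          # continuous column/row index space
  c0 <- floor(u); r0 <- floor(v)
  dx <- u - c0; dy <- v - r0
  c1 <- ifelse(dx > 0, c0 + 1, c0)
  r1 <- ifelse(dy > 0, r0 + 1, r0)
  ok <- c0 >= 1 & c1 <= W & r0 >= 1 & r1 <= H
  out <- matrix(NA_real_, length(x), 3L)
  if (!any(ok)) return(out)
  c0 <- c0[ok]; c1 <- c1[ok]; r0 <- r0[ok]; r1 <- r1[ok]
  dxo <- dx[ok]; dyo <- dy[ok]
  for (ch in 1:3) {
    plane <- img[, , ch]
    i00 <- plane[cbind(r0, c0)]; i01 <- plane[cbind(r0, c1)]
    i10 <- plane[cbind(r1, c0)]; i11 <- plane[cbind(r1, c1)]
    out[ok, ch] <- (1 - dyo) * ((1 - dxo) * i00 + dxo * i01) +
                   dyo * ((1 - dxo) * i10 + dxo * i11)
  }
  out
}
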