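# Closed-form least-squares rigid-body superposition of 3-D point sets.
# Shared by the pharmacophore matcher (feature-point fitting) and the
# ensemble RMSF machinery (iterated mean-structure superposition).

#' Least-squares rigid superposition of two point sets
#'
#' Finds the proper rotation `R` and translation `t` minimising the RMSD
#' between the moving points `P` (one row per point) and the fixed points `Q`
#' under the transform `x %*% R + t`, using the SVD of the cross-covariance
#' matrix. Reflections are rejected: the returned rotation always has
#' determinant +1.
#'
#' @param p Numeric matrix, n x 3, the moving point set.
#' @param q Numeric matrix, n x 3, the fixed (target) point set, row i of `p`
#'   corresponding to row i of `q`.
#' @return List with `rotation` (3 x 3, det +1), `translation` (length 3),
#'   `rmsd` (Angstrom) and `transformed` (the superposed copy of `p`).
#' @examples
#' p <- matrix(rnorm(15), ncol = 3)
#' th <- 0.7
#' rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
#' fit <- superpose_points(p %*% rot + 2, p)
#' fit$rmsd  # ~0: a rigid motion is recovered exactly
#' @export
superpose_points <- function(p, q) {
  p <- as.matrix(p); q <- as.matrix(q)
  if (!all(dim(p) == dim(q)) || ncol(p) != 3L)
    stop_dynappi("point sets must be matched n x 3 matrices", "dynappi_shape_error")
  if (nrow(p) < 1L)
    stop_dynappi("empty point set", "dynappi_shape_error")
  cp <- colMeans(p); cq <- colMeans(q)
  pc <- sweep(p, 2, cp); qc <- sweep(q, 2, cq)
  h <- crossprod(pc, qc)              # 3x3 cross-covariance
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1                  # degenerate (collinear) sets: pick proper branch
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  tr <- as.numeric(cq - cp %*% rot)
  moved <- sweep(p %*% rot, 2, tr, `+`)
  list(rotation = rot, translation = tr,
       rmsd = rmsd_points(moved, q), transformed = moved)
}

#' Coordinate RMSD between two matched point sets (no superposition)
#'
#' @param a,b Matched n x 3 coordinate matrices.
#' @return Root-mean-square deviation in the same length unit as the input.
#' @export
rmsd_points <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b)))
    stop_dynappi("point sets must have identical dimensions", "dynappi_shape_error")
  sqrt(mean(rowSums((a - b)^2)))
}

# internal: uniform random proper rotation (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  r <- qr.Q(qr_) %*% diag(sign(diag(qr.R(qr_))))
  if (det(r) < 0) r[, 1] <- -r[, 1]
  r
}
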