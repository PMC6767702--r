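# Small geometry helpers shared across modules.

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n == 0) stop("cannot normalize a zero vector")
  v / n
}

#' Apply a rigid motion to 3D points
#'
#' Rotates and translates a point matrix: \code{x \%*\% t(R) + t}. Useful for
#' testing that classification and distance results are invariant under a
#' change of the stack's coordinate frame.
#'
#' @param x n x 3 matrix of points, or a length-3 vector.
#' @param rotation 3 x 3 rotation matrix (orthonormal, det +1).
#' @param translation length-3 numeric vector.
#' @return transformed points, same shape as the input.
#' @export
apply_rigid <- function(x, rotation = diag(3), translation = c(0, 0, 0)) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 3)
  out <- x %*% t(rotation) + matrix(translation, nrow(x), 3, byrow = TRUE)
  if (vec) out <- drop(out)
  out
}

#' Random rotation matrix
#'
#' Draws a rotation uniformly from SO(3) (QR of a Gaussian matrix with sign
#' correction). Intended for invariance tests.
#'
#' @return a 3 x 3 rotation matrix.
#' @export
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  d <- sign(diag(qr.R(qr_)))
  d[d == 0] <- 1
  q <- q %*% diag(d)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# mean +/- SEM summary for a numeric vector; SEM is NA for n < 2.
mean_sem <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  list(mean = if (n) mean(x) else NA_real_,
       sem = if (n > 1) stats::sd(x) / sqrt(n) else NA_real_,
       n = n)
}
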