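#' @keywords internal
"_PACKAGE"

## Centralized unit conversion: 1 mmHg = 0.133322 kPa.
MMHG_KPA <- 0.133322

#' Convert pressures between mmHg and kPa
#'
#' The package computes wall stress in kPa and reports hemodynamic pressures
#' in mmHg; all conversions go through these two helpers (1 mmHg =
#' 0.133322 kPa).
#'
#' @param p numeric vector of pressures.
#' @return numeric vector in the target unit.
#' @export
mmhg_to_kpa <- function(p) p * MMHG_KPA

#' @rdname mmhg_to_kpa
#' @export
kpa_to_mmhg <- function(p) p / MMHG_KPA

## ---- vectorised 3x3 tensor algebra ------------------------------------
## 3x3 matrices stored row-wise as n x 9 matrices, column index = 3*(i-1)+j
## for entry (i,j).  Keeps hot loops (quadrature-point stress evaluation)
## free of per-point %*% calls.

m3_idx <- function(i, j) 3L * (i - 1L) + j

m3_from_mat <- function(M) matrix(t(M), nrow = 1L)

m3_identity <- function(n) {
  out <- matrix(0, n, 9L)
  out[, c(1L, 5L, 9L)] <- 1
  out
}

## hot path: unrolled with literal column indices
m3_mult <- function(A, B) {
  out <- matrix(0, nrow(A), 9L)
  out[, 1L] <- A[, 1L] * B[, 1L] + A[, 2L] * B[, 4L] + A[, 3L] * B[, 7L]
  out[, 2L] <- A[, 1L] * B[, 2L] + A[, 2L] * B[, 5L] + A[, 3L] * B[, 8L]
  out[, 3L] <- A[, 1L] * B[, 3L] + A[, 2L] * B[, 6L] + A[, 3L] * B[, 9L]
  out[, 4L] <- A[, 4L] * B[, 1L] + A[, 5L] * B[, 4L] + A[, 6L] * B[, 7L]
  out[, 5L] <- A[, 4L] * B[, 2L] + A[, 5L] * B[, 5L] + A[, 6L] * B[, 8L]
  out[, 6L] <- A[, 4L] * B[, 3L] + A[, 5L] * B[, 6L] + A[, 6L] * B[, 9L]
  out[, 7L] <- A[, 7L] * B[, 1L] + A[, 8L] * B[, 4L] + A[, 9L] * B[, 7L]
  out[, 8L] <- A[, 7L] * B[, 2L] + A[, 8L] * B[, 5L] + A[, 9L] * B[, 8L]
  out[, 9L] <- A[, 7L] * B[, 3L] + A[, 8L] * B[, 6L] + A[, 9L] * B[, 9L]
  out
}

m3_t <- function(A) A[, c(1L, 4L, 7L, 2L, 5L, 8L, 3L, 6L, 9L), drop = FALSE]

m3_det <- function(A) {
  A[, 1] * (A[, 5] * A[, 9] - A[, 6] * A[, 8]) -
    A[, 2] * (A[, 4] * A[, 9] - A[, 6] * A[, 7]) +
    A[, 3] * (A[, 4] * A[, 8] - A[, 5] * A[, 7])
}

m3_inv <- function(A) {
  d <- m3_det(A)
  out <- matrix(0, nrow(A), 9L)
  out[, 1] <-  (A[, 5] * A[, 9] - A[, 6] * A[, 8]) / d
  out[, 2] <- -(A[, 2] * A[, 9] - A[, 3] * A[, 8]) / d
  out[, 3] <-  (A[, 2] * A[, 6] - A[, 3] * A[, 5]) / d
  out[, 4] <- -(A[, 4] * A[, 9] - A[, 6] * A[, 7]) / d
  out[, 5] <-  (A[, 1] * A[, 9] - A[, 3] * A[, 7]) / d
  out[, 6] <- -(A[, 1] * A[, 6] - A[, 3] * A[, 4]) / d
  out[, 7] <-  (A[, 4] * A[, 8] - A[, 5] * A[, 7]) / d
  out[, 8] <- -(A[, 1] * A[, 8] - A[, 2] * A[, 7]) / d
  out[, 9] <-  (A[, 1] * A[, 5] - A[, 2] * A[, 4]) / d
  out
}

m3_trace <- function(A) A[, 1] + A[, 5] + A[, 9]

## u' A v for n x 3 vectors u, v and n x 9 matrices A
m3_quad <- function(A, u, v) {
  u[, 1L] * (A[, 1L] * v[, 1L] + A[, 2L] * v[, 2L] + A[, 3L] * v[, 3L]) +
    u[, 2L] * (A[, 4L] * v[, 1L] + A[, 5L] * v[, 2L] + A[, 6L] * v[, 3L]) +
    u[, 3L] * (A[, 7L] * v[, 1L] + A[, 8L] * v[, 2L] + A[, 9L] * v[, 3L])
}

## outer products u v' as n x 9
m3_outer <- function(u, v) {
  out <- matrix(0, nrow(u), 9L)
  out[, 1L] <- u[, 1L] * v[, 1L]; out[, 2L] <- u[, 1L] * v[, 2L]
  out[, 3L] <- u[, 1L] * v[, 3L]; out[, 4L] <- u[, 2L] * v[, 1L]
  out[, 5L] <- u[, 2L] * v[, 2L]; out[, 6L] <- u[, 2L] * v[, 3L]
  out[, 7L] <- u[, 3L] * v[, 1L]; out[, 8L] <- u[, 3L] * v[, 2L]
  out[, 9L] <- u[, 3L] * v[, 3L]
  out
}

## double contraction A : B
m3_ddot <- function(A, B) rowSums(A * B)

## apply n x 9 matrix to n x 3 vector
m3_vec <- function(A, v) {
  out <- matrix(0, nrow(A), 3L)
  out[, 1L] <- A[, 1L] * v[, 1L] + A[, 2L] * v[, 2L] + A[, 3L] * v[, 3L]
  out[, 2L] <- A[, 4L] * v[, 1L] + A[, 5L] * v[, 2L] + A[, 6L] * v[, 3L]
  out[, 3L] <- A[, 7L] * v[, 1L] + A[, 8L] * v[, 2L] + A[, 9L] * v[, 3L]
  out
}

## ---- quaternions (w, x, y, z) ------------------------------------------

quat_from_rotmat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] >= R[2, 2] && R[1, 1] >= R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] >= R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  q / sqrt(sum(q^2))
}

rotmat_from_quat <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

## random rotation matrix (uniform via quaternion)
random_rotation <- function() {
  q <- stats::rnorm(4)
  rotmat_from_quat(q)
}

## Gauss-Legendre nodes/weights on [a, b]
gauss_legendre <- function(n, a = -1, b = 1) {
  gl <- pracma::gaussLegendre(n, a, b)
  list(x = gl$x, w = gl$w)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

unit3 <- function(v) v / sqrt(sum(v^2))
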