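# Quaternion utilities and the deterministic quasi-uniform orientation set
# used for exhaustive rigid-body sampling.

# radical-inverse (van der Corput) sequence in the given base
radical_inverse <- function(i, base) {
  f <- 1
  r <- 0
  while (any(i > 0)) {
    f <- f / base
    r <- r + f * (i %% base)
    i <- i %/% base
  }
  r
}

#' Deterministic quasi-uniform rotation set
#'
#' Unit quaternions from Shoemake's subgroup-algorithm map applied to a
#' 3-dimensional Halton sequence (bases 2, 3, 5), giving a low-discrepancy
#' cover of SO(3). `offset` shifts the start of the sequence so different
#' runs can use disjoint orientation sets while staying fully deterministic.
#'
#' @param n number of rotations.
#' @param offset start index offset into the Halton sequence (default 0).
#' @return n x 4 matrix of unit quaternions (w, x, y, z rows sum-square 1).
#' @export
rotation_set <- function(n, offset = 0) {
  i <- seq_len(n) + offset
  u1 <- radical_inverse(i, 2)
  u2 <- radical_inverse(i, 3)
  u3 <- radical_inverse(i, 5)
  q <- cbind(
    sqrt(1 - u1) * sin(2 * pi * u2),
    sqrt(1 - u1) * cos(2 * pi * u2),
    sqrt(u1) * sin(2 * pi * u3),
    sqrt(u1) * cos(2 * pi * u3)
  )
  q / sqrt(rowSums(q^2))
}

#' Rotation matrix from a unit quaternion
#' @param q length-4 numeric (w, x, y, z), need not be exactly unit.
#' @return 3 x 3 proper rotation matrix.
#' @export
quat_to_mat <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3)  # column-major: columns are images of the basis vectors
}

#' Unit quaternion from a rotation matrix
#' @param R 3 x 3 proper rotation matrix.
#' @return length-4 unit quaternion (w, x, y, z), w >= 0.
#' @export
mat_to_quat <- function(R) {
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
  q <- q / sqrt(sum(q^2))
  if (q[1] < 0) q <- -q
  q
}
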