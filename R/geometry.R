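# Small-angle cutoff below which exp/log use their series limits.
.SO3_EPS <- 1e-7

#' Rodrigues exponential map on SO(3)
#'
#' Maps an axis-angle vector (radians times unit axis) to a rotation matrix.
#' The rotation angle is the Euclidean norm of the input; the zero vector maps
#' to the identity via the series limit.
#'
#' @param omega Numeric 3-vector, axis-angle (rotation angle = `sqrt(sum(omega^2))`).
#' @return A 3x3 rotation matrix.
#' @seealso [so3_log()] for the inverse map.
#' @export
#' @examples
#' so3_exp(c(pi / 2, 0, 0))
so3_exp <- function(omega) {
  stopifnot(length(omega) == 3L, all(is.finite(omega)))
  theta <- sqrt(sum(omega^2))
  K <- .hat(omega)
  if (theta < .SO3_EPS) {
    # second-order series: I + K + K^2/2
    return(diag(3) + K + 0.5 * (K %*% K))
  }
  diag(3) + (sin(theta) / theta) * K +
    ((1 - cos(theta)) / theta^2) * (K %*% K)
}

#' Principal logarithm on SO(3)
#'
#' Inverse of [so3_exp()]: returns the axis-angle vector with angle in
#' `[0, pi]`. Rotations with angle near `pi` are resolved through the
#' eigenvector of the symmetric part, which is the numerically stable branch.
#'
#' @param R A 3x3 rotation matrix.
#' @return Numeric 3-vector (principal axis-angle).
#' @export
so3_log <- function(R) {
  .check_rotation(R)
  ct <- (sum(diag(R)) - 1) / 2
  ct <- min(1, max(-1, ct))
  theta <- acos(ct)
  if (theta < .SO3_EPS) {
    # series limit: vee of the skew part
    return(.vee(R - t(R)) / 2)
  }
  if (pi - theta < 1e-5) {
    # near half-turn: axis from the dominant eigenvector of (R + I)/2
    B <- (R + diag(3)) / 2
    ax <- sqrt(pmax(diag(B), 0))
    k <- which.max(ax)
    axis <- B[, k] / ax[k]
    axis <- axis / sqrt(sum(axis^2))
    # fix the sign deterministically from the skew part when informative,
    # otherwise first nonzero component positive
    sk <- .vee(R - t(R)) / 2
    s <- sum(sk * axis)
    if (abs(s) > 1e-12 && s < 0) axis <- -axis
    if (abs(s) <= 1e-12) {
      nz <- which(abs(axis) > 1e-12)[1]
      if (axis[nz] < 0) axis <- -axis
    }
    return(theta * axis)
  }
  (theta / (2 * sin(theta))) * .vee(R - t(R))
}

.hat <- function(v) {
  matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
}

.vee <- function(K) c(K[3, 2], K[1, 3], K[2, 1])

.check_rotation <- function(R, tol = 1e-6) {
  if (!is.matrix(R) || any(dim(R) != c(3L, 3L)) || !all(is.finite(R))) {
    stop("not a 3x3 finite matrix")
  }
  if (max(abs(crossprod(R) - diag(3))) > tol) stop("matrix is not orthonormal")
  if (abs(det(R) - 1) > tol) stop("matrix is not a proper rotation (det != +1)")
  invisible(TRUE)
}

#' Draw a Haar-uniform rotation
#'
#' Samples from the rotation-invariant (Haar) distribution on SO(3) by
#' normalizing a 4D Gaussian to a unit quaternion. Uses R's global RNG stream,
#' so `set.seed()` gives reproducible draws.
#'
#' @param n Number of rotations; if 1 (default) a single matrix is returned,
#'   otherwise a list.
#' @return A 3x3 rotation matrix, or a list of them.
#' @export
sample_uniform_rotation <- function(n = 1L) {
  draw1 <- function() {
    q <- stats::rnorm(4)
    q <- q / sqrt(sum(q^2))
    quat_to_rotmat(q)
  }
  if (n == 1L) draw1() else replicate(n, draw1(), simplify = FALSE)
}

#' Convert a unit quaternion to a rotation matrix
#' @param q Numeric 4-vector (w, x, y, z); normalized internally.
#' @return 3x3 rotation matrix.
#' @keywords internal
quat_to_rotmat <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3)
}

#' Convert a rotation matrix to a unit quaternion (w, x, y, z)
#'
#' Shepperd's method: picks the numerically largest component first. The sign
#' is fixed so that w >= 0.
#' @param R 3x3 rotation matrix.
#' @return Numeric 4-vector.
#' @keywords internal
rotmat_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] > R[3, 3]) {
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


#' Geodesic interpolation between two rotations
#'
#' Point on the SO(3) geodesic from `R0` (at `t = 0`) to `R1` (at `t = 1`),
#' computed in the right-translated convention
#' `R1 %*% so3_exp((1 - t) * so3_log(t(R1) %*% R0))`.
#' When `t(R1) %*% R0` is a half-turn the geodesic is non-unique; the
#' principal branch of [so3_log()] is used and a warning is emitted.
#'
#' @param R0,R1 3x3 rotation matrices (endpoints).
#' @param t Scalar in `[0, 1]`.
#' @return 3x3 rotation matrix.
#' @export
geodesic_rotation <- function(R0, R1, t) {
  stopifnot(t >= 0, t <= 1)
  A <- crossprod(R1, R0)          # t(R1) %*% R0
  w <- so3_log(A)
  if (pi - sqrt(sum(w^2)) < 1e-6) {
    warning("geodesic endpoints differ by a half-turn; principal branch used")
  }
  R1 %*% so3_exp((1 - t) * w)
}

#' Optimal rigid superposition (Kabsch)
#'
#' Finds the proper rotation `Q` and translation `v` minimizing the RMSD of
#' `Q %*% mobile + v` onto `reference` over the masked points. Reflections are
#' excluded (determinant forced to +1).
#'
#' @param mobile,reference Numeric matrices of shape n x 3.
#' @param mask Optional logical vector of length n; defaults to all points.
#' @return A list with elements `rotation` (3x3), `translation` (3-vector) and
#'   `rmsd` (post-alignment RMSD over masked points, in the units of the
#'   input coordinates).
#' @export
kabsch_align <- function(mobile, reference, mask = NULL) {
  stopifnot(is.matrix(mobile), is.matrix(reference),
            ncol(mobile) == 3L, ncol(reference) == 3L)
  if (nrow(mobile) != nrow(reference)) stop("point counts differ")
  if (is.null(mask)) mask <- rep(TRUE, nrow(mobile))
  m <- mobile[mask, , drop = FALSE]
  r <- reference[mask, , drop = FALSE]
  if (nrow(m) < 3L) stop("need at least 3 masked points")
  cm <- colMeans(m); cr <- colMeans(r)
  mc <- sweep(m, 2, cm); rc <- sweep(r, 2, cr)
  H <- crossprod(mc, rc)              # 3x3 covariance
  sv <- svd(H)
  if (sv$d[2] < 1e-10) stop("masked points are (near-)collinear")
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  Q <- sv$v %*% D %*% t(sv$u)
  v <- cr - as.vector(Q %*% cm)
  aligned <- t(Q %*% t(m)) + matrix(v, nrow(m), 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((aligned - r)^2)))
  list(rotation = Q, translation = v, rmsd = rmsd)
}

#' Apply a rigid transform to coordinates
#' @param coords n x 3 matrix.
#' @param tf List with `rotation` and `translation` as from [kabsch_align()].
#' @return Transformed n x 3 matrix.
#' @export
apply_transform <- function(coords, tf) {
  t(tf$rotation %*% t(coords)) +
    matrix(tf$translation, nrow(coords), 3, byrow = TRUE)
}

#' Compose two rigid transforms: first `a`, then `b`
#' @keywords internal
compose_transform <- function(b, a) {
  list(rotation = b$rotation %*% a$rotation,
       translation = as.vector(b$rotation %*% a$translation) + b$translation)
}

#' Per-residue backbone frames
#'
#' Builds an orthonormal frame per residue by Gram-Schmidt on the N/CA/C
#' atoms: e1 along CA->C, e2 the CA->N direction orthogonalized against e1,
#' e3 = e1 x e2. The frame origin is the CA position. Residues missing any of
#' N/CA/C, or with collinear N/CA/C, are masked invalid (the latter with a
#' warning).
#'
#' @param chain A `ChainStructure` (see [chain_structure()]).
#' @return List with `rotations` (list of 3x3 matrices or NULL), `origins`
#'   (L x 3 matrix) and `valid` (logical vector).
#' @export
backbone_frames <- function(chain) {
  L <- chain_length(chain)
  rot <- vector("list", L)
  org <- matrix(NA_real_, L, 3)
  valid <- rep(FALSE, L)
  for (i in seq_len(L)) {
    if (!all(chain$atom_mask[i, c("N", "CA", "C")])) next
    n <- chain$coords[i, "N", ]; ca <- chain$coords[i, "CA", ]
    cc <- chain$coords[i, "C", ]
    e1 <- cc - ca
    n1 <- sqrt(sum(e1^2))
    u <- n - ca
    if (n1 < 1e-8) next
    e1 <- e1 / n1
    e2 <- u - sum(u * e1) * e1
    n2 <- sqrt(sum(e2^2))
    if (n2 < 1e-8) {
      warning(sprintf("degenerate backbone geometry at residue %d; frame masked", i))
      next
    }
    e2 <- e2 / n2
    e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
            e1[3] * e2[1] - e1[1] * e2[3],
            e1[1] * e2[2] - e1[2] * e2[1])
    rot[[i]] <- cbind(e1, e2, e3, deparse.level = 0)
    org[i, ] <- ca
    valid[i] <- TRUE
  }
  list(rotations = rot, origins = org, valid = valid)
}
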