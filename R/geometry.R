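## Small rigid-geometry toolkit shared by the surface, pose and Procrustes code.

#' Extract the coordinate matrix of a structure
#'
#' @param x a `protein_structure` (or an n x 3 numeric matrix, returned as is).
#' @return numeric matrix with columns x, y, z.
#' @export
coords <- function(x) {
  if (is.matrix(x)) {
    stopifnot(ncol(x) == 3)
    return(x)
  }
  if (!inherits(x, "protein_structure"))
    stop("expected a protein_structure or an n x 3 matrix")
  as.matrix(x$atoms[, c("x", "y", "z")])
}

centroid <- function(x) colMeans(coords(x))

#' Apply a rigid (or improper) transform to a structure
#'
#' Coordinates are mapped as `x %*% t(rotation) + shift`.
#'
#' @param s a `protein_structure`.
#' @param rotation 3 x 3 orthogonal matrix (det +1 or -1).
#' @param shift length-3 translation, applied after rotation.
#' @return the transformed `protein_structure`.
#' @export
transform_structure <- function(s, rotation = diag(3), shift = c(0, 0, 0)) {
  xyz <- coords(s) %*% t(rotation)
  xyz <- sweep(xyz, 2, shift, "+")
  s$atoms$x <- xyz[, 1]
  s$atoms$y <- xyz[, 2]
  s$atoms$z <- xyz[, 3]
  s
}

#' Optimal superposition of paired point sets (Kabsch)
#'
#' Finds rotation `R` and translation `t` minimising the weighted sum of
#' squared distances between `mobile %*% t(R) + t` and `target`.  With
#' `allow_reflection = TRUE` the determinant of `R` may be -1 when the
#' improper fit is better; otherwise `R` is a proper rotation.
#'
#' @param mobile,target n x 3 matrices of corresponding points.
#' @param weights optional nonnegative per-point weights.
#' @param allow_reflection permit an improper (mirror) fit.
#' @return list with `rotation`, `shift`, `rmsd` (weighted), and `fitted`.
#' @export
kabsch <- function(mobile, target, weights = NULL, allow_reflection = FALSE) {
  P <- as.matrix(mobile); Q <- as.matrix(target)
  stopifnot(nrow(P) == nrow(Q), ncol(P) == 3, ncol(Q) == 3)
  n <- nrow(P)
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights >= 0), sum(weights) > 0)
  w <- weights / sum(weights)
  cp <- colSums(P * w); cq <- colSums(Q * w)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  H <- crossprod(P0 * w, Q0)                  # 3x3 cross-covariance
  sv <- svd(H)
  R_proper <- sv$v %*% diag(c(1, 1, sign(det(sv$v %*% t(sv$u))))) %*% t(sv$u)
  if (allow_reflection) {
    R_raw <- sv$v %*% t(sv$u)                 # unconstrained optimum
    R <- R_raw
  } else {
    R <- R_proper
  }
  shift <- cq - as.vector(R %*% cp)
  fitted <- sweep(P %*% t(R), 2, shift, "+")
  dev <- fitted - Q
  rmsd <- sqrt(sum(w * rowSums(dev^2)))
  list(rotation = R, shift = shift, rmsd = rmsd, fitted = fitted)
}

#' Random proper rotation (uniform) from a seeded RNG state
#' @keywords internal
random_rotation <- function() {
  M <- matrix(stats::rnorm(9), 3, 3)
  qr_ <- qr(M)
  Q <- qr.Q(qr_)
  d <- sign(diag(qr.R(qr_)))
  Q <- Q %*% diag(d)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
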