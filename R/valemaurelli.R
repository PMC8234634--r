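#' Vale-Maurelli intermediate correlation
#'
#' When two non-normal marginals are produced by Fleishman polynomials of
#' correlated standard normals, the correlation of the transformed pair
#' differs from the normal-scale correlation. For polynomials
#' (a_i, b_i, c_i, d_i) and (a_j, b_j, c_j, d_j) the transformed correlation
#' is a cubic in the normal-scale correlation rho_Z:
#' \deqn{\rho_Y = \rho_Z (b_i b_j + 3 b_i d_j + 3 d_i b_j + 9 d_i d_j)
#'   + 2 \rho_Z^2 c_i c_j + 6 \rho_Z^3 d_i d_j.}
#' `intermediate_correlation` inverts this relation: given the target
#' `rho_target` on the outcome scale it returns the rho_Z to use when drawing
#' the underlying multivariate normal.
#'
#' @param rho_target target correlation of the transformed pair, in [-1, 1].
#' @param coef_i,coef_j `fleishman_coef` objects for the two marginals.
#' @return the real root in [-1, 1] nearest `rho_target` (root-finding
#'   tolerance 1e-10). Errors if the target is unattainable for these
#'   marginals (no real root in [-1, 1]).
#' @export
intermediate_correlation <- function(rho_target, coef_i, coef_j) {
  assert_scalar(rho_target)
  stopifnot(abs(rho_target) <= 1, inherits(coef_i, "fleishman_coef"),
            inherits(coef_j, "fleishman_coef"))
  A <- vm_cubic_A(coef_i, coef_j)
  B <- 2 * coef_i$c * coef_j$c
  C <- 6 * coef_i$d * coef_j$d
  # roots of C r^3 + B r^2 + A r - rho_target = 0
  roots <- polyroot(c(-rho_target, A, B, C))
  real <- Re(roots[abs(Im(roots)) < 1e-7])
  real <- real[real >= -1 - 1e-10 & real <= 1 + 1e-10]
  if (length(real) == 0) {
    stop(sprintf(
      "target correlation %.4f unattainable for these Fleishman marginals",
      rho_target), call. = FALSE)
  }
  r <- real[which.min(abs(real - rho_target))]
  max(-1, min(1, r))
}

vm_cubic_A <- function(coef_i, coef_j) {
  coef_i$b * coef_j$b + 3 * coef_i$b * coef_j$d +
    3 * coef_i$d * coef_j$b + 9 * coef_i$d * coef_j$d
}

# Vectorized inversion of the Vale-Maurelli cubic for a whole matrix of
# targets. Newton iteration runs on all p(p-1)/2 pairs simultaneously;
# the few pairs that fail to converge fall back to the scalar polyroot path.
vm_intermediate_matrix <- function(target, coefs) {
  p <- ncol(target)
  b <- vapply(coefs, `[[`, numeric(1), "b")
  c_ <- vapply(coefs, `[[`, numeric(1), "c")
  d <- vapply(coefs, `[[`, numeric(1), "d")
  A <- outer(b, b) + 3 * outer(b, d) + 3 * outer(d, b) + 9 * outer(d, d)
  B <- 2 * outer(c_, c_)
  C <- 6 * outer(d, d)
  r <- target
  for (it in 1:100) {
    f <- A * r + B * r^2 + C * r^3 - target
    g <- A + 2 * B * r + 3 * C * r^2
    step <- f / g
    step[!is.finite(step)] <- 0
    r <- r - step
    r[r > 1] <- 1
    r[r < -1] <- -1
    if (max(abs(f)) < 1e-12) break
  }
  resid <- abs(A * r + B * r^2 + C * r^3 - target)
  bad <- which(resid > 1e-10 & row(target) < col(target), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    for (k in seq_len(nrow(bad))) {
      i <- bad[k, 1]; j <- bad[k, 2]
      r[i, j] <- r[j, i] <- intermediate_correlation(
        target[i, j], coefs[[i]], coefs[[j]])
    }
  }
  diag(r) <- 1
  (r + t(r)) / 2
}

#' Nearest correlation matrix
#'
#' Pairwise Vale-Maurelli inversion can leave the intermediate normal-scale
#' matrix indefinite. This repairs it to the nearest (Frobenius norm)
#' correlation matrix with minimum eigenvalue at least `eig_floor`,
#' delegating to the alternating-projections method of `Matrix::nearPD`.
#' A matrix that already satisfies the floor is returned unchanged.
#'
#' @param matrix symmetric matrix with unit diagonal.
#' @param eig_floor smallest admissible eigenvalue (default 1e-8).
#' @return a correlation matrix (symmetric, unit diagonal, eigenvalues >=
#'   `eig_floor`).
#' @export
nearest_correlation <- function(matrix, eig_floor = 1e-8) {
  if (!isSymmetric(unname(matrix), tol = 1e-8)) {
    stop("input matrix must be symmetric", call. = FALSE)
  }
  dn <- dimnames(matrix)
  m <- (unname(matrix) + t(unname(matrix))) / 2
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) >= eig_floor) {
    return(matrix)
  }
  fixed <- as.matrix(Matrix::nearPD(m, corr = TRUE, eig.tol = 1e-10,
                                    conv.tol = 1e-10, maxit = 200)$mat)
  ev2 <- eigen(fixed, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev2) < eig_floor) {
    # blend toward identity just enough to clear the floor
    w <- (eig_floor - min(ev2)) / (1 - min(ev2))
    fixed <- (1 - w) * fixed + w * diag(nrow(fixed))
  }
  fixed <- (fixed + t(fixed)) / 2
  diag(fixed) <- 1
  dimnames(fixed) <- dn
  fixed
}
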