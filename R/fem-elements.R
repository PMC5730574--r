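# Element stiffness matrices: 4- and 10-node tetrahedra (isotropic linear
# elasticity, Voigt order xx, yy, zz, xy, yz, zx with engineering shear) and
# shear-deformable (Timoshenko) beams.

elastic_D <- function(E, nu) {
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lam
  diag(D)[1:3] <- lam + 2 * mu
  diag(D)[4:6] <- mu
  D
}

# gradients of the barycentric coordinates of a tet: 4 x 3 matrix a, with
# grad(L_i) = a[i, ]; also returns the volume
tet_geometry <- function(corners) {
  Tm <- cbind(1, corners)          # 4 x 4, rows (1, x, y, z)
  vol <- det(Tm[2:4, 2:4] - matrix(Tm[1, 2:4], 3, 3, byrow = TRUE)) / 6
  if (!is.finite(vol) || abs(vol) < 1e-14) {
    abort("degenerate tetrahedral element (zero volume)", class = "nucmorph_fem_error")
  }
  if (vol < 0) abort("inverted tetrahedral element", class = "nucmorph_fem_error")
  A <- solve(Tm)                   # columns: coefficients of L_i
  list(grads = t(A[2:4, ]), vol = vol)
}

strain_B <- function(dN) {
  # dN: n x 3 shape-function gradients -> B: 6 x 3n
  n <- nrow(dN)
  B <- matrix(0, 6, 3 * n)
  ix <- 3 * (seq_len(n) - 1)
  B[1, ix + 1] <- dN[, 1]
  B[2, ix + 2] <- dN[, 2]
  B[3, ix + 3] <- dN[, 3]
  B[4, ix + 1] <- dN[, 2]; B[4, ix + 2] <- dN[, 1]
  B[5, ix + 2] <- dN[, 3]; B[5, ix + 3] <- dN[, 2]
  B[6, ix + 1] <- dN[, 3]; B[6, ix + 3] <- dN[, 1]
  B
}

# 4-point Gauss rule for the 10-node tet (degree-2 exact)
tet4pt <- local({
  a <- 0.5854101966249685; b <- 0.1381966011250105
  rbind(c(a, b, b, b), c(b, a, b, b), c(b, b, a, b), c(b, b, b, a))
})

tet10_dshape <- function(L, grads) {
  # gradients of the 10 quadratic shape functions; grads = grad(L_i) (4 x 3)
  dn <- matrix(0, 10, 3)
  for (i in 1:4) dn[i, ] <- (4 * L[i] - 1) * grads[i, ]
  ed <- rbind(c(1, 2), c(2, 3), c(3, 1), c(1, 4), c(2, 4), c(3, 4))
  for (k in 1:6) {
    i <- ed[k, 1]; j <- ed[k, 2]
    dn[4 + k, ] <- 4 * (L[i] * grads[j, ] + L[j] * grads[i, ])
  }
  dn
}

#' Tetrahedral element stiffness matrix
#'
#' Constant-strain 4-node or quadratic 10-node tetrahedron for isotropic
#' linear elasticity. The matrix is symmetric positive-semidefinite with
#' exactly six rigid-body zero-energy modes, and both orders pass the
#' constant-strain patch test.
#'
#' @param corners Node coordinates: `4 x 3` (linear) or `10 x 3` (quadratic;
#'   corners then midsides of edges 12, 23, 31, 14, 24, 34).
#' @param E Young's modulus (Pa).
#' @param nu Poisson ratio.
#' @return The `12 x 12` or `30 x 30` stiffness matrix (Pa um, i.e. pN/um).
#' @export
tet_stiffness <- function(corners, E, nu) {
  check_that(is.matrix(corners) && ncol(corners) == 3 &&
               nrow(corners) %in% c(4L, 10L), "corners", "must be 4 x 3 or 10 x 3")
  check_that(E > 0, "E", "must be > 0")
  check_that(nu >= 0 && nu < 0.5, "nu", "must be in [0, 0.5)")
  D <- elastic_D(E, nu)
  g <- tet_geometry(corners[1:4, , drop = FALSE])
  if (nrow(corners) == 4) {
    B <- strain_B(g$grads)
    return(g$vol * crossprod(B, D %*% B))
  }
  K <- matrix(0, 30, 30)
  for (q in 1:4) {
    B <- strain_B(tet10_dshape(tet4pt[q, ], g$grads))
    K <- K + (g$vol / 4) * crossprod(B, D %*% B)
  }
  K
}

# exact (interdependent-interpolation) 2-node Timoshenko space-frame element
# in local coordinates, 12 x 12, DOFs (ux uy uz rx ry rz) per node, x = axis
beam2_local <- function(L, E, G, A, I, kappa, J) {
  phi <- 12 * E * I / (kappa * G * A * L^2)
  K <- matrix(0, 12, 12)
  add <- function(idx, m) K[idx, idx] <<- K[idx, idx] + m
  add(c(1, 7), E * A / L * matrix(c(1, -1, -1, 1), 2))
  add(c(4, 10), G * J / L * matrix(c(1, -1, -1, 1), 2))
  cb <- E * I / ((1 + phi) * L^3)
  kb <- function(s) {
    # s = +1 for bending in x-y (uy, rz), -1 for x-z (uz, ry)
    cb * matrix(c(12, s * 6 * L, -12, s * 6 * L,
                  s * 6 * L, (4 + phi) * L^2, -s * 6 * L, (2 - phi) * L^2,
                  -12, -s * 6 * L, 12, -s * 6 * L,
                  s * 6 * L, (2 - phi) * L^2, -s * 6 * L, (4 + phi) * L^2),
                4, 4, byrow = TRUE)
  }
  add(c(2, 6, 8, 12), kb(+1))
  add(c(3, 5, 9, 11), kb(-1))
  K
}

# rotation matrix whose first row is the unit axis direction
beam_frame <- function(d) {
  ex <- d / sqrt(sum(d^2))
  up <- if (abs(ex[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  ey <- c(up[2] * ex[3] - up[3] * ex[2], up[3] * ex[1] - up[1] * ex[3],
          up[1] * ex[2] - up[2] * ex[1])
  ey <- ey / sqrt(sum(ey^2))
  ez <- c(ex[2] * ey[3] - ex[3] * ey[2], ex[3] * ey[1] - ex[1] * ey[3],
          ex[1] * ey[2] - ex[2] * ey[1])
  rbind(ex, ey, ez)
}

# global-coordinate stiffness of a 2-node segment from p1 to p2
beam2_global <- function(p1, p2, E, G, A, I, kappa, J) {
  d <- p2 - p1
  L <- sqrt(sum(d^2))
  check_that(L > 0, "beam", "zero-length segment")
  Rm <- beam_frame(d)
  T12 <- matrix(0, 12, 12)
  for (b in 0:3) T12[3 * b + 1:3, 3 * b + 1:3] <- Rm
  crossprod(T12, beam2_local(L, E, G, A, I, kappa, J) %*% T12)
}

#' Three-node Timoshenko beam stiffness (straight, local coordinates)
#'
#' A shear-deformable 3-node line element assembled from two exact
#' (interdependent-interpolation) two-node Timoshenko halves, hence free of
#' shear locking and nodally exact for end loads: a cantilever reproduces
#' the closed form \eqn{PL^3/(3EI) + PL/(\kappa G A)} and axial loading gives
#' \eqn{PL/(EA)} exactly. Includes axial, torsional and two bending planes.
#'
#' @param L Element length (end to end).
#' @param E Young's modulus; `G` shear modulus; `A` cross-section area; `I`
#'   second moment of area (both bending planes); `kappa` shear correction;
#'   `J` torsion constant (default `2 I`, the circular section value).
#' @param G,A,I,kappa,J See above.
#' @return `18 x 18` stiffness, DOFs (ux uy uz rx ry rz) at end-1, middle,
#'   end-2; local x along the axis.
#' @export
timoshenko_beam_stiffness <- function(L, E, G, A, I, kappa = 0.9, J = 2 * I) {
  for (nm in c("L", "E", "G", "A", "I", "kappa", "J")) {
    check_that(get(nm) > 0, nm, "must be > 0")
  }
  kh <- beam2_local(L / 2, E, G, A, I, kappa, J)
  K <- matrix(0, 18, 18)
  i1 <- 1:12; i2 <- 7:18
  K[i1, i1] <- K[i1, i1] + kh
  K[i2, i2] <- K[i2, i2] + kh
  K
}
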