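.lr_cache <- new.env(parent = emptyenv())

#' Euler angles and dimer geometry
#'
#' Orientations use passive z-y-z Euler angles \eqn{(\alpha, \beta,
#' \gamma)}: the molecule-fixed axes are obtained from the dimer-fixed axes
#' by \eqn{R_z(\alpha) R_y(\beta) R_z(\gamma)}, so a site at molecule-fixed
#' position \eqn{\mathbf r} sits at \eqn{R_z(\alpha)R_y(\beta)R_z(\gamma)
#' \mathbf r} in the dimer frame.  \eqn{\alpha} is the azimuth and
#' \eqn{\beta \in [0, \pi]} the polar angle of the molecular z-axis.
#'
#' @param alpha,beta,gamma angles in radians.
#' @return \code{euler_angles()} returns a list of class
#'   \code{euler_angles}.
#' @export
euler_angles <- function(alpha = 0, beta = 0, gamma = 0) {
  stopifnot(is.finite(alpha), is.finite(beta), is.finite(gamma))
  structure(list(alpha = alpha %% (2 * pi), beta = beta,
                 gamma = gamma %% (2 * pi)),
            class = "euler_angles")
}

#' @rdname euler_angles
#' @param omega an \code{euler_angles} object.
#' @return \code{euler_to_matrix()} returns the 3x3 rotation matrix
#'   \eqn{R_z(\alpha) R_y(\beta) R_z(\gamma)} acting on Cartesian
#'   coordinates.
#' @export
euler_to_matrix <- function(omega) {
  rz <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  ry <- function(b) matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3, 3)
  rz(omega$alpha) %*% ry(omega$beta) %*% rz(omega$gamma)
}

#' Dimer geometry
#'
#' The dimer-fixed frame has its origin at molecule A's centre of mass and
#' its z-axis pointing at molecule B's centre of mass.  Only the azimuth
#' difference \eqn{\alpha = \alpha_A - \alpha_B} is physical; the free
#' angle set depends on the shapes of the two molecules (atoms contribute
#' no angles, linear molecules no \eqn{\gamma}).
#'
#' @param R centre-of-mass separation, bohr; must be positive.
#' @param alpha azimuth difference \eqn{\alpha_A - \alpha_B} (radians).
#' @param beta_A,beta_B,gamma_A,gamma_B remaining Euler angles (radians).
#' @return a list of class \code{dimer_geometry} with fields \code{R},
#'   \code{omega_A} and \code{omega_B}.
#' @export
dimer_geometry <- function(R, alpha = 0, beta_A = 0, beta_B = 0,
                           gamma_A = 0, gamma_B = 0) {
  if (!is.numeric(R) || length(R) != 1L || !is.finite(R) || R <= 0)
    stop("R must be a positive separation")
  structure(list(R = R,
                 omega_A = euler_angles(alpha, beta_A, gamma_A),
                 omega_B = euler_angles(0, beta_B, gamma_B)),
            class = "dimer_geometry")
}

## well-spread unit vectors (Fibonacci sphere), used as sample points for
## the polynomial construction of rotation blocks
.fib_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  rho <- sqrt(pmax(0, 1 - z^2))
  cbind(rho * cos(phi), rho * sin(phi), z)
}

.rank_sample <- function(l) {
  key <- paste0("samp", l)
  if (!is.null(.lr_cache[[key]])) return(.lr_cache[[key]])
  pts <- .fib_sphere(2L * l + 7L)
  Y <- t(apply(pts, 1L, function(p) solid_harmonics_all(p, l)[[l + 1L]]))
  if (l == 0L) Y <- matrix(Y, ncol = 1L)
  pin <- solve(crossprod(Y), t(Y))  # least-squares inverse, exact here
  val <- list(pts = pts, pinv = pin)
  .lr_cache[[key]] <- val
  val
}

#' Rank-l representation matrix of an orthogonal operation
#'
#' Matrix \eqn{\Delta^l(g)} through which the \code{2l + 1} real rank-l
#' multipole components transform when the charge distribution is moved by
#' the (proper or improper) orthogonal operation \code{g}:
#' \eqn{S_t(g\mathbf r) = \sum_{t'} \Delta^l_{tt'}(g) S_{t'}(\mathbf r)}.
#' Computed by evaluating the solid harmonics on a fixed well-conditioned
#' set of directions and solving the (exactly determined) linear system, so
#' improper operations automatically carry the parity factor
#' \eqn{(-1)^l}.  The result is orthogonal and the map is a group
#' homomorphism.
#'
#' @param l rank.
#' @param g 3x3 orthogonal matrix.
#' @return a \code{(2l+1) x (2l+1)} orthogonal matrix.
#' @export
rotation_block <- function(l, g) {
  if (l == 0L) return(matrix(1, 1L, 1L))
  sm <- .rank_sample(l)
  Yg <- t(apply(sm$pts %*% t(g), 1L, function(p) solid_harmonics_all(p, l)[[l + 1L]]))
  t(sm$pinv %*% Yg)
}

#' Real Wigner rotation matrix
#'
#' Rotation matrix of the real rank-l multipole components for a z-y-z
#' Euler rotation: multipoles expressed in molecule-fixed axes are carried
#' to the dimer-fixed frame by \code{rotation_matrix_real(l, omega)}.
#' At zero angles it is the identity; at \code{l = 1} it equals the 3x3
#' Cartesian rotation in the \code{(z, x, y)} component ordering.
#'
#' @param l rank (\code{l >= 0}).
#' @param omega an [euler_angles()] object.
#' @return a \code{(2l+1) x (2l+1)} orthogonal matrix.
#' @export
rotation_matrix_real <- function(l, omega) {
  stopifnot(l >= 0L)
  rotation_block(l, euler_to_matrix(omega))
}

## zyz Euler angles of a proper rotation matrix (inverse of
## euler_to_matrix); beta in [0, pi], degenerate beta handled by putting
## the whole z-rotation into alpha
.matrix_to_euler <- function(g) {
  b <- acos(max(-1, min(1, g[3, 3])))
  if (abs(sin(b)) > 1e-12) {
    a <- atan2(g[2, 3], g[1, 3])
    c <- atan2(g[3, 2], -g[3, 1])
  } else {
    a <- atan2(g[2, 1], g[1, 1]) * sign(g[3, 3])
    c <- 0
  }
  euler_angles(a, b, c)
}

## exchange-transformed geometry: the dimer frame is flipped by a C2
## rotation about x (z -> -z, so it points from B's to A's centre of
## mass) and the two orientations swap roles
.exchange_geometry <- function(geom) {
  Fx <- diag(c(1, -1, -1))
  oa <- .matrix_to_euler(Fx %*% euler_to_matrix(geom$omega_B))
  ob <- .matrix_to_euler(Fx %*% euler_to_matrix(geom$omega_A))
  g <- dimer_geometry(geom$R)
  g$omega_A <- oa
  g$omega_B <- ob
  g
}
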