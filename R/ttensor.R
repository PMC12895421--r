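## Interaction T-tensors in the real spherical-tensor basis.
##
## In the dimer frame (z-axis from A's to B's centre of mass) the coupling
## matrix X between the dimer-frame multipole components of the two
## molecules is diagonal in m' (only m_a' = -m_b' survives because the
## irregular harmonic on the z-axis is nonzero only at M = 0):
##
##   X_c[ma', mb'] = (-1)^la sqrt((2la+2lb+1)! / ((2la)!(2lb)!))
##                   * threeJ(la, lb, la+lb; ma', mb', -(ma'+mb'))
##                   * delta(ma' + mb', 0) / R^(la+lb+1)
##
## The real-basis T block for molecule-frame multipoles is then
##   T = W_A' X_real W_B / R^(la+lb+1)
## with W the real rotation matrices of the two orientations and X_real the
## complex X transformed to the cosine/sine basis (it is exactly real).

## unitary complex->real transform: q_real = .u_real(l) %*% q_complex,
## complex components ordered m = -l..l
.u_real <- function(l) {
  n <- 2L * l + 1L
  U <- matrix(0 + 0i, n, n)
  idx <- function(m) m + l + 1L  # complex column for projection m
  U[1L, idx(0L)] <- 1
  for (m in seq_len(l)) {
    U[2L * m, idx(m)]       <- (-1)^m / sqrt(2)
    U[2L * m, idx(-m)]      <- 1 / sqrt(2)
    U[2L * m + 1L, idx(m)]  <- (-1)^m / (1i * sqrt(2))
    U[2L * m + 1L, idx(-m)] <- -1 / (1i * sqrt(2))
  }
  U
}

## real-basis X matrix at R = 1 for rank pair (la, lb); cached
.x0_real <- function(la, lb) {
  key <- paste0("x0_", la, "_", lb)
  if (!is.null(.lr_cache[[key]])) return(.lr_cache[[key]])
  L <- la + lb
  na <- 2L * la + 1L; nb <- 2L * lb + 1L
  pref <- (-1)^la * exp(0.5 * (lgamma(2 * L + 2) - lgamma(2 * la + 1) -
                               lgamma(2 * lb + 1)))
  Xc <- matrix(0 + 0i, na, nb)
  for (ma in -la:la) {
    mb <- -ma
    if (abs(mb) <= lb)
      Xc[ma + la + 1L, mb + lb + 1L] <- pref * wigner3j(la, lb, L, ma, mb, 0)
  }
  Ua <- .u_real(la); Ub <- .u_real(lb)
  Xr <- Conj(Ua) %*% Xc %*% Conj(t(Ub))
  if (max(abs(Im(Xr))) > 1e-12) stop("internal: X block not real")
  Xr <- Re(Xr)
  .lr_cache[[key]] <- Xr
  Xr
}

#' T-tensor block for a rank pair
#'
#' The full \code{(2la+1) x (2lb+1)} matrix of interaction T-tensor
#' components \eqn{T_{t,u}} coupling molecule-frame real multipole
#' components of rank \code{la} on A with rank \code{lb} on B at a given
#' dimer geometry; it carries all distance and orientation dependence and
#' scales as \eqn{R^{-(l_a+l_b+1)}}.  Atomic units.
#'
#' @param la,lb ranks of the two molecules' components.
#' @param geom a [dimer_geometry()].
#' @return a numeric matrix, rows ordered as [rank_labels()] of \code{la},
#'   columns as of \code{lb}.
#' @export
t_tensor_block <- function(la, lb, geom) {
  if (geom$R <= 0) stop("R must be positive")
  WA <- rotation_matrix_real(la, geom$omega_A)
  WB <- rotation_matrix_real(lb, geom$omega_B)
  (t(WA) %*% .x0_real(la, lb) %*% WB) / geom$R^(la + lb + 1L)
}

#' Single T-tensor component (production path)
#'
#' @param ta,tb Stone component labels for molecules A and B.
#' @param geom a [dimer_geometry()].
#' @return the T-tensor value (atomic units).
#' @examples
#' t_tensor("00", "00", dimer_geometry(5))   # 1/R
#' t_tensor("10", "10", dimer_geometry(5))   # -2/R^3
#' @export
t_tensor <- function(ta, tb, geom) {
  a <- lr_label(ta); b <- lr_label(tb)
  t_tensor_block(a$l, b$l, geom)[.label_index(a), .label_index(b)]
}

## ---- independent direct evaluation through complex Wigner D matrices ----

## Wigner small-d matrix, rows m' = -l..l, cols m = -l..l,
## d^l_{m'm}(beta) by Wigner's sum formula
.wigner_d <- function(l, beta) {
  n <- 2L * l + 1L
  d <- matrix(0, n, n)
  cb <- cos(beta / 2); sb <- sin(beta / 2)
  lf <- lgamma
  for (mp in -l:l) for (m in -l:l) {
    smin <- max(0L, m - mp)
    smax <- min(l + m, l - mp)
    if (smax < smin) next
    acc <- 0
    for (s in smin:smax) {
      lnum <- 0.5 * (lf(l + mp + 1) + lf(l - mp + 1) + lf(l + m + 1) + lf(l - m + 1))
      lden <- lf(l + m - s + 1) + lf(s + 1) + lf(mp - m + s + 1) + lf(l - mp - s + 1)
      acc <- acc + (-1)^(mp - m + s) * exp(lnum - lden) *
        cb^(2 * l + m - mp - 2 * s) * sb^(mp - m + 2 * s)
    }
    d[mp + l + 1L, m + l + 1L] <- acc
  }
  d
}

## complex Wigner D matrix, D^l_{m'm}(alpha, beta, gamma) =
## exp(-i m' alpha) d^l_{m'm}(beta) exp(-i m gamma)
.wigner_D <- function(l, alpha, beta, gamma) {
  d <- .wigner_d(l, beta)
  m <- -l:l
  exp(-1i * m * alpha) * d * rep(exp(-1i * m * gamma), each = 2L * l + 1L)
}

#' Direct T-tensor evaluation (reference path)
#'
#' Literal contraction of the dimer-frame coupling matrix with two complex
#' Wigner rotation matrices, transformed to the real basis at the end.
#' Serves as the independent reference for [t_tensor()]; the two paths
#' agree to better than 1e-10 relative.
#'
#' @inheritParams t_tensor
#' @return the T-tensor value (atomic units).
#' @export
t_tensor_direct <- function(ta, tb, geom) {
  a <- lr_label(ta); b <- lr_label(tb)
  if (geom$R <= 0) stop("R must be positive")
  la <- a$l; lb <- b$l
  L <- la + lb
  pref <- (-1)^la * exp(0.5 * (lgamma(2 * L + 2) - lgamma(2 * la + 1) -
                               lgamma(2 * lb + 1)))
  Xc <- matrix(0 + 0i, 2L * la + 1L, 2L * lb + 1L)
  for (ma in -la:la) {
    mb <- -ma
    if (abs(mb) <= lb)
      Xc[ma + la + 1L, mb + lb + 1L] <- pref * wigner3j(la, lb, L, ma, mb, 0)
  }
  oA <- geom$omega_A; oB <- geom$omega_B
  ## multipoles transform to the dimer frame with D(Omega^-1) per the
  ## molecule-frame convention; as matrices this is the conjugate transpose
  DA <- Conj(t(.wigner_D(la, oA$alpha, oA$beta, oA$gamma)))
  DB <- Conj(t(.wigner_D(lb, oB$alpha, oB$beta, oB$gamma)))
  Tc <- DA %*% Xc %*% t(DB)
  Ua <- .u_real(la); Ub <- .u_real(lb)
  Tr <- Conj(Ua) %*% Tc %*% Conj(t(Ub))
  Tr <- Re(Tr)[.label_index(a), .label_index(b)]
  Tr / geom$R^(L + 1L)
}

#' Exact Coulomb interaction of two rigid point-charge fragments
#'
#' Pairwise Coulomb sum \eqn{\sum_{a,b} q_a q_b / r_{ab}} between the sites
#' of molecule A (rotated by its Euler angles, origin at the dimer origin)
#' and molecule B (rotated, then shifted by \eqn{R} along z).  This is the
#' exact quantity the truncated electrostatic multipole series converges
#' to at large separation, and serves as the validation oracle for the
#' whole tensor machinery.
#'
#' @param sitesA,sitesB lists of [atom_site()] objects (molecule-fixed
#'   coordinates, bohr).
#' @param geom a [dimer_geometry()].
#' @return interaction energy in hartree.
#' @export
coulomb_oracle <- function(sitesA, sitesB, geom) {
  gA <- euler_to_matrix(geom$omega_A)
  gB <- euler_to_matrix(geom$omega_B)
  pa <- t(vapply(sitesA, function(s) as.numeric(gA %*% s$position), numeric(3)))
  pb <- t(vapply(sitesB, function(s) as.numeric(gB %*% s$position), numeric(3)))
  pb[, 3] <- pb[, 3] + geom$R
  qa <- vapply(sitesA, `[[`, numeric(1), "charge")
  qb <- vapply(sitesB, `[[`, numeric(1), "charge")
  e <- 0
  for (i in seq_along(qa)) {
    d2 <- (pb[, 1] - pa[i, 1])^2 + (pb[, 2] - pa[i, 2])^2 + (pb[, 3] - pa[i, 3])^2
    if (any(d2 < 1e-20)) stop("coincident inter-fragment sites")
    e <- e + sum(qa[i] * qb / sqrt(d2))
  }
  e
}
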