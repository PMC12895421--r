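#' Real regular solid harmonics and point-charge multipoles
#'
#' The moment kernels are the real regular solid harmonics
#' \eqn{S_{lm}(\mathbf r) = r^l \sqrt{4\pi/(2l+1)}\, Y_{lm}} brought to the
#' cosine/sine real form, normalised so that
#' \code{10} \eqn{\mapsto z}, \code{11c} \eqn{\mapsto x},
#' \code{11s} \eqn{\mapsto y}, and \code{00} \eqn{\mapsto 1}.  The real
#' combinations are
#' \eqn{S_{lmc} = ((-1)^m S_{l,m} + S_{l,-m})/\sqrt 2} and
#' \eqn{S_{lms} = ((-1)^m S_{l,m} - S_{l,-m})/(i\sqrt 2)} with the
#' Condon--Shortley phase carried by the complex harmonics, which makes all
#' multipoles of a real charge distribution real.  Evaluation uses the
#' standard stable three-term recursion in \eqn{(z, r^2)} with the
#' \eqn{\rho^m \cos m\varphi} factors built by Cartesian recursion, exact
#' for these polynomial kernels.
#'
#' @param label a Stone component label string (see [lr_label()]).
#' @param position numeric 3-vector, molecule-fixed frame.
#' @return the (real) value of the solid harmonic at \code{position}.
#' @examples
#' real_solid_harmonic("20", c(0, 0, 2))  # 4 = d^2
#' @export
real_solid_harmonic <- function(label, position) {
  lab <- lr_label(label)
  stopifnot(length(position) == 3L, all(is.finite(position)))
  sh <- solid_harmonics_all(position, lab$l)
  sh[[lab$l + 1L]][.label_index(lab)]
}

#' @rdname real_solid_harmonic
#' @param lmax highest rank to evaluate.
#' @return \code{solid_harmonics_all()} returns a list of length
#'   \code{lmax + 1}; element \code{l + 1} is the numeric vector of the
#'   \code{2l + 1} rank-\code{l} components in [rank_labels()] order.
#' @export
solid_harmonics_all <- function(position, lmax) {
  x <- position[1]; y <- position[2]; z <- position[3]
  r2 <- x * x + y * y + z * z
  out <- vector("list", lmax + 1L)
  out[[1L]] <- 1
  if (lmax == 0L) return(out)
  ## Pi[l + 1, m + 1] = r^l P_l^m(cos theta) / sin(theta)^m  (no CS phase)
  Pi <- matrix(0, lmax + 1L, lmax + 1L)
  Pi[1L, 1L] <- 1
  for (m in 0:lmax) {
    if (m > 0L) Pi[m + 1L, m + 1L] <- (2 * m - 1) * Pi[m, m]  # (2m-1)!!
    if (m + 1L <= lmax)
      Pi[m + 2L, m + 1L] <- (2 * m + 1) * z * Pi[m + 1L, m + 1L]
    if (m + 2L <= lmax) for (l in (m + 2L):lmax) {
      Pi[l + 1L, m + 1L] <- ((2 * l - 1) * z * Pi[l, m + 1L] -
                             (l - 1 + m) * r2 * Pi[l - 1L, m + 1L]) / (l - m)
    }
  }
  ## A_m = rho^m cos(m phi), B_m = rho^m sin(m phi)
  A <- numeric(lmax + 1L); B <- numeric(lmax + 1L)
  A[1L] <- 1; B[1L] <- 0
  for (m in seq_len(lmax)) {
    A[m + 1L] <- A[m] * x - B[m] * y
    B[m + 1L] <- A[m] * y + B[m] * x
  }
  for (l in seq_len(lmax)) {
    v <- numeric(2L * l + 1L)
    v[1L] <- Pi[l + 1L, 1L]
    for (m in seq_len(l)) {
      nlm <- sqrt(2 * exp(lgamma(l - m + 1) - lgamma(l + m + 1)))
      v[2L * m]      <- nlm * Pi[l + 1L, m + 1L] * A[m + 1L]
      v[2L * m + 1L] <- nlm * Pi[l + 1L, m + 1L] * B[m + 1L]
    }
    out[[l + 1L]] <- v
  }
  out
}

#' Multipole moments of a point-charge distribution
#'
#' Charge-weighted sum of real regular solid harmonics over a set of sites,
#' \eqn{Q_t = \sum_i q_i S_t(\mathbf r_i)}; the \code{00} component is the
#' total charge.
#'
#' @param sites a list of sites created with [atom_site()].
#' @param label a Stone component label string.
#' @return the multipole component (atomic units).
#' @export
multipole_of_point_charges <- function(sites, label) {
  stopifnot(length(sites) >= 1L)
  lab <- lr_label(label)
  s <- 0
  for (site in sites) {
    sh <- solid_harmonics_all(site$position, lab$l)
    s <- s + site$charge * sh[[lab$l + 1L]][.label_index(lab)]
  }
  s
}

#' All multipole components of a point-charge distribution up to a rank
#'
#' @inheritParams multipole_of_point_charges
#' @param lmax highest rank.
#' @return list per rank (as in [solid_harmonics_all()]) of component values.
#' @export
multipoles_of_point_charges <- function(sites, lmax) {
  stopifnot(length(sites) >= 1L)
  acc <- lapply(0:lmax, function(l) numeric(2L * l + 1L))
  for (site in sites) {
    sh <- solid_harmonics_all(site$position, lmax)
    for (l in 0:lmax)
      acc[[l + 1L]] <- acc[[l + 1L]] + site$charge * sh[[l + 1L]]
  }
  acc
}

#' A charged site in the molecule-fixed frame
#'
#' @param charge signed charge in units of e.
#' @param position numeric 3-vector (bohr unless stated otherwise by the
#'   caller; all internal computation is in atomic units).
#' @return a list of class \code{atom_site}.
#' @export
atom_site <- function(charge, position) {
  stopifnot(is.numeric(charge), length(charge) == 1L, is.finite(charge),
            is.numeric(position), length(position) == 3L,
            all(is.finite(position)))
  structure(list(charge = charge, position = as.numeric(position)),
            class = "atom_site")
}
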