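#' Declare a molecule (rigid monomer)
#'
#' A monomer is declared by its point group (in the package's orientation
#' conventions), its net charge, and optionally its atomic sites (needed
#' for the LeRoy anisotropy filter and for point-charge oracles).  The
#' shape class (atom / linear / nonlinear) is derived from the point
#' group: \code{Cinfv} and \code{Dinfh} are linear, \code{"atom"} is an
#' atom, everything else is nonlinear.
#'
#' @param name display name.
#' @param point_group either a family label (\code{"Cnv"} with \code{n}
#'   given) or a concrete one (\code{"C3v"}, \code{"D6h"}, \code{"Td"},
#'   \code{"Ih"}, \code{"Cinfv"}, \code{"Dinfh"}, \code{"atom"}, ...).
#' @param n axis order for the C/D/S families.
#' @param charge net charge in units of e; pins the \code{00} multipole.
#' @param sites optional list of [atom_site()] objects; an atom defaults to
#'   a single site of its net charge at the origin.
#' @return an object of class \code{lr_molecule}.
#' @examples
#' h2 <- lr_molecule("H2", "Dinfh")
#' cfp <- lr_molecule("CF+", "Cinfv", charge = 1)
#' @export
lr_molecule <- function(name, point_group, n = NULL, charge = 0,
                        sites = NULL) {
  cg <- .canon_group(point_group)
  if (!is.null(cg$n)) n <- cg$n
  pg <- cg$label
  if (pg %in% .n_groups && (is.null(n) || n < 2L))
    stop("point group ", pg, " needs an axis order n >= 2")
  shape <- if (pg == "atom") "atom"
           else if (pg %in% c("Cinfv", "Dinfh")) "linear"
           else "nonlinear"
  if (pg == "atom" && is.null(sites))
    sites <- list(atom_site(charge, c(0, 0, 0)))
  if (!is.null(sites)) {
    stopifnot(all(vapply(sites, inherits, logical(1), "atom_site")))
  }
  structure(list(name = name, point_group = pg, n = if (is.null(n)) NA_integer_ else as.integer(n),
                 charge = charge, shape = shape, sites = sites),
            class = "lr_molecule")
}

#' @export
print.lr_molecule <- function(x, ...) {
  pg <- .pretty_group(x)
  cat(sprintf("<lr_molecule> %s  point group %s  charge %+g  (%s)\n",
              x$name, pg, x$charge, x$shape))
  if (!is.null(x$sites)) cat("  ", length(x$sites), "atomic sites\n")
  invisible(x)
}

.pretty_group <- function(mol) {
  if (mol$point_group %in% .n_groups)
    sub("n", mol$n, mol$point_group, fixed = TRUE)
  else mol$point_group
}

#' Declare a two-molecule system
#'
#' @param molA,molB [lr_molecule()] objects; A is the fragment at the
#'   dimer-frame origin.
#' @param relation \code{"distinct"}, \code{"identical"} (exchange
#'   symmetry is enforced, coefficient sets tied equal) or
#'   \code{"chiral_partners"} (coefficients tied through the numeric image
#'   of a mirror operation).
#' @return an object of class \code{lr_system}.
#' @export
lr_system <- function(molA, molB, relation = c("distinct", "identical",
                                               "chiral_partners")) {
  relation <- match.arg(relation)
  stopifnot(inherits(molA, "lr_molecule"), inherits(molB, "lr_molecule"))
  if (relation != "distinct") {
    same <- identical(molA$point_group, molB$point_group) &&
      identical(molA$n, molB$n) && identical(molA$charge, molB$charge)
    if (!same)
      stop("relation '", relation,
           "' requires equal point groups and charges")
  }
  structure(list(molA = molA, molB = molB, relation = relation),
            class = "lr_system")
}

#' @export
print.lr_system <- function(x, ...) {
  cat(sprintf("<lr_system> %s (%s) -- %s (%s), %s, dimensionality %dD\n",
              x$molA$name, .pretty_group(x$molA),
              x$molB$name, .pretty_group(x$molB),
              x$relation, system_dimension(x)))
  invisible(x)
}

#' Intermolecular dimensionality and free angle set
#'
#' The free angular coordinates depend only on the shapes of the two
#' molecules: atoms contribute no angles, linear molecules no
#' \eqn{\gamma}, and the azimuth difference \eqn{\alpha} exists once both
#' molecules are nonatomic.  Together with \eqn{R} this gives 1D
#' (atom--atom) through 6D (two nonlinear molecules).
#'
#' @param sys an [lr_system()].
#' @return \code{free_angles()}: character vector drawn from
#'   \code{c("alpha", "beta_A", "beta_B", "gamma_A", "gamma_B")};
#'   \code{system_dimension()}: integer 1..6.
#' @export
free_angles <- function(sys) {
  a <- sys$molA$shape; b <- sys$molB$shape
  ang <- character()
  if (a != "atom" && b != "atom") ang <- c(ang, "alpha")
  if (a != "atom") ang <- c(ang, "beta_A")
  if (b != "atom") ang <- c(ang, "beta_B")
  if (a == "nonlinear") ang <- c(ang, "gamma_A")
  if (b == "nonlinear") ang <- c(ang, "gamma_B")
  ang[order(match(ang, c("alpha", "beta_A", "beta_B", "gamma_A", "gamma_B")))]
}

#' @rdname free_angles
#' @export
system_dimension <- function(sys) 1L + length(free_angles(sys))
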