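#' Interaction-energy dataset
#'
#' Scattered interaction energies versus intermolecular coordinates.
#' Internally geometries are stored in bohr/radians and energies in
#' hartree; the \code{units} field records the I/O units the data came
#' from (or should be written in).
#'
#' @param geoms data frame with column \code{R} and any of \code{alpha},
#'   \code{beta_A}, \code{beta_B}, \code{gamma_A}, \code{gamma_B}
#'   (bohr / radians).
#' @param energy numeric vector of energies (hartree), finite.
#' @param units list with \code{distance}, \code{angle}, \code{energy}
#'   I/O unit names.
#' @param provenance free-text description.
#' @return an object of class \code{lr_dataset}.
#' @export
lr_dataset <- function(geoms, energy,
                       units = list(distance = "angstrom", angle = "deg",
                                    energy = "cm1"),
                       provenance = "") {
  stopifnot(is.data.frame(geoms), "R" %in% names(geoms),
            nrow(geoms) == length(energy), all(is.finite(energy)),
            all(geoms$R > 0))
  structure(list(geoms = geoms, energy = as.numeric(energy), units = units,
                 provenance = provenance),
            class = "lr_dataset")
}

#' @export
print.lr_dataset <- function(x, ...) {
  cat(sprintf("<lr_dataset> %d points, R in [%.3g, %.3g] bohr, E in [%.3g, %.3g] hartree\n",
              nrow(x$geoms), min(x$geoms$R), max(x$geoms$R),
              min(x$energy), max(x$energy)))
  if (nzchar(x$provenance)) cat(" ", x$provenance, "\n")
  invisible(x)
}

#' Length of a dataset
#' @param x an [lr_dataset()].
#' @export
length.lr_dataset <- function(x) nrow(x$geoms)

#' Random symmetry-respecting coefficient set
#'
#' Draws a ground-truth coefficient set for a system: nonzero values only
#' on symmetry-allowed entries, with magnitudes decaying by rank (scale
#' \code{decay^l}, by default \eqn{2^{-l}}, so leading terms dominate the
#' way physically realistic multipole series do), exchange/chiral
#' constraints applied exactly, and the leading multipole coordinate of
#' molecule A oriented non-negative (the package's gauge convention).
#' Reproducible per seed.
#'
#' @param sys an [lr_system()].
#' @param caps per-interaction expansion caps (see [assemble_terms()]).
#' @param seed integer seed.
#' @param decay per-rank magnitude decay factor.
#' @param asym_scale standard deviation of the asymptote draw (hartree).
#' @return an [lr_coefficients()] object.
#' @export
random_coefficients <- function(sys, caps, seed = 1L, decay = 0.5,
                                asym_scale = 1e-4) {
  ex <- lr_expansion(sys, caps)
  tie <- .tie_map(ex)
  set.seed(seed)
  thf <- stats::setNames(numeric(length(tie$free_names)), tie$free_names)
  for (i in seq_along(thf)) {
    nm <- tie$free_names[i]
    if (nm == "E_asym") { thf[i] <- stats::rnorm(1, 0, asym_scale); next }
    p <- strsplit(nm, ".", fixed = TRUE)[[1]]
    sc <- switch(substr(p[1], 1, 1),
      Q = decay^as.integer(p[2]),
      a = decay^sum(as.integer(strsplit(p[2], "_")[[1]])),
      D = decay^sum(as.integer(unlist(strsplit(strsplit(p[2], "|",
                                                        fixed = TRUE)[[1]],
                                               "_")))))
    thf[i] <- stats::rnorm(1, 0, 1) * sc
    ## polarizabilities: keep the always-allowed isotropic-type entries
    ## comfortably away from zero so induction has realistic weight
    if (substr(nm, 1, 1) == "a" && p[3] == "1") thf[i] <- thf[i] + sc
  }
  ## gauge: leading free multipole coordinate of A non-negative
  qa <- grep("^QA\\.", tie$free_names)
  if (length(qa) > 0L && thf[qa[1L]] < 0) {
    qf <- grep("^Q[AB]\\.", tie$free_names)
    thf[qf] <- -thf[qf]
  }
  lr_coefficients(ex, as.numeric(tie$Tmat %*% thf + tie$offset))
}

#' Synthetic scattered-energy dataset from a known model
#'
#' Samples geometries uniformly in \eqn{R} over \code{R_range} and
#' uniformly over the free angle subset of the system's dimensionality
#' class (azimuths and \eqn{\gamma} uniform on the circle, \eqn{\cos\beta}
#' uniform so orientations are unbiased on the sphere), evaluates the
#' forward model and adds i.i.d. Gaussian noise.
#'
#' @param coeffs an [lr_coefficients()] ground-truth set.
#' @param n number of points.
#' @param R_range length-2 vector (bohr), inside the long-range regime.
#' @param noise_sigma Gaussian noise s.d. (hartree).
#' @param seed integer seed.
#' @param n_outliers number of points additionally perturbed by
#'   \code{outlier_size} times their local interaction energy.
#' @param outlier_size multiplier for injected outliers.
#' @return an [lr_dataset()] (internal units), with the true model energy
#'   kept in attribute \code{"model_energy"}.
#' @export
synthetic_dataset <- function(coeffs, n, R_range = c(15, 60),
                              noise_sigma = 0, seed = 1L,
                              n_outliers = 0L, outlier_size = 10) {
  stopifnot(inherits(coeffs, "lr_coefficients"), n >= 1L,
            length(R_range) == 2L, R_range[1] > 0)
  sys <- coeffs$expansion$sys
  ang <- free_angles(sys)
  set.seed(seed)
  df <- data.frame(R = stats::runif(n, R_range[1], R_range[2]))
  for (a in ang) {
    df[[a]] <- if (grepl("^beta", a)) acos(stats::runif(n, -1, 1))
               else stats::runif(n, 0, 2 * pi)
  }
  e_model <- evaluate_energy(coeffs, df)
  e <- e_model + stats::rnorm(n, 0, noise_sigma)
  if (n_outliers > 0L) {
    idx <- sample.int(n, n_outliers)
    easym <- coeffs$theta[["E_asym"]]
    e[idx] <- e[idx] + outlier_size * (e_model[idx] - easym)
  }
  out <- lr_dataset(df, e,
                    units = list(distance = "bohr", angle = "rad",
                                 energy = "hartree"),
                    provenance = sprintf("synthetic (seed %d, sigma %g)",
                                         seed, noise_sigma))
  attr(out, "model_energy") <- e_model
  out
}

#' Random point-charge model with exact point-group symmetry
#'
#' Draws random charged sites and symmetrizes them over the group orbit,
#' yielding a charge distribution exactly invariant under the group;
#' its multipoles vanish on every non-allowed component, which makes it
#' the oracle for the symmetry machinery.  For linear groups the sites
#' are drawn on the z-axis (mirrored for \code{Dinfh}); an atom is a
#' single site at the origin.
#'
#' @param mol an [lr_molecule()] (or group label).
#' @param n_sites number of random seed sites before symmetrization.
#' @param seed integer seed.
#' @param spread length scale of the site positions (bohr).
#' @return a list of [atom_site()] objects.
#' @export
symmetric_point_charge_model <- function(mol, n_sites = 3L, seed = 1L,
                                         spread = 1) {
  if (!inherits(mol, "lr_molecule")) mol <- lr_molecule("m", mol)
  set.seed(seed)
  pg <- mol$point_group
  sites <- list()
  if (pg == "atom") {
    return(list(atom_site(stats::runif(1, -1, 1), c(0, 0, 0))))
  }
  if (pg %in% c("Cinfv", "Dinfh")) {
    for (i in seq_len(n_sites)) {
      q <- stats::runif(1, -1, 1); z <- stats::runif(1, -1, 1) * spread
      sites[[length(sites) + 1L]] <- atom_site(q, c(0, 0, z))
      if (pg == "Dinfh" && abs(z) > 0)
        sites[[length(sites) + 1L]] <- atom_site(q, c(0, 0, -z))
    }
    return(sites)
  }
  els <- group_elements(mol)
  for (i in seq_len(n_sites)) {
    q <- stats::runif(1, -1, 1)
    p <- stats::runif(3, -1, 1) * spread
    for (g in els)
      sites[[length(sites) + 1L]] <- atom_site(q, as.numeric(g %*% p))
  }
  sites
}
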