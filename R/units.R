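#' Physical constants and unit conversion
#'
#' All internal computation is carried out in Hartree atomic units
#' (lengths in bohr, energies in hartree, charges in e, with
#' \eqn{4\pi\epsilon_0 = 1}) and angles in radians.  Files and user-facing
#' interfaces default to the spectroscopic conventions common in studies of
#' van der Waals complexes: distances in angstrom, energies in
#' \eqn{\mathrm{cm}^{-1}}, angles in degrees.
#'
#' @format A named list with elements
#' \describe{
#'   \item{hartree_cm1}{\eqn{\mathrm{cm}^{-1}} per hartree.}
#'   \item{bohr_angstrom}{angstrom per bohr.}
#' }
#' @export
lr_constants <- list(
  hartree_cm1   = 219474.6313632,
  bohr_angstrom = 0.529177210903
)

.length_to_bohr <- function(x, unit) {
  switch(unit,
    bohr     = x,
    au       = x,
    angstrom = x / lr_constants$bohr_angstrom,
    stop("unknown length unit: ", unit)
  )
}

.length_from_bohr <- function(x, unit) {
  switch(unit,
    bohr     = x,
    au       = x,
    angstrom = x * lr_constants$bohr_angstrom,
    stop("unknown length unit: ", unit)
  )
}

.energy_to_hartree <- function(x, unit) {
  switch(unit,
    hartree = x,
    au      = x,
    cm1     = x / lr_constants$hartree_cm1,
    stop("unknown energy unit: ", unit)
  )
}

.energy_from_hartree <- function(x, unit) {
  switch(unit,
    hartree = x,
    au      = x,
    cm1     = x * lr_constants$hartree_cm1,
    stop("unknown energy unit: ", unit)
  )
}

.angle_to_rad <- function(x, unit) {
  switch(unit,
    rad     = x,
    radians = x,
    deg     = x * pi / 180,
    degrees = x * pi / 180,
    stop("unknown angle unit: ", unit)
  )
}

.angle_from_rad <- function(x, unit) {
  switch(unit,
    rad     = x,
    radians = x,
    deg     = x * 180 / pi,
    degrees = x * 180 / pi,
    stop("unknown angle unit: ", unit)
  )
}
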