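## Dataset files, the LeRoy anisotropy filter, and coefficient
## serialization.
##
## File dialect: whitespace-separated numeric columns, '#' comment lines,
## an optional single header line (auto-detected).  The column order is
## fixed by the system's dimensionality class:
##   R  [alpha]  [beta_A]  [beta_B]  [gamma_A]  [gamma_B]  E
## with exactly the free angle subset present (atoms contribute no
## angles, linear molecules no gamma).  Default units: distances in
## angstrom, angles in degrees, energies in cm-1.

.default_units <- function() list(distance = "angstrom", angle = "deg",
                                  energy = "cm1")

#' Read a scattered-energy dataset
#'
#' @param path file path.
#' @param sys an [lr_system()]; fixes the expected column count.
#' @param units list with \code{distance}, \code{angle}, \code{energy}
#'   (defaults angstrom / deg / cm1).
#' @return an [lr_dataset()] in internal atomic units.
#' @export
read_dataset <- function(path, sys, units = .default_units()) {
  stopifnot(file.exists(path), inherits(sys, "lr_system"))
  ang <- free_angles(sys)
  ncol_exp <- 2L + length(ang)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) {
    warning("empty dataset file: ", path)
    geoms <- data.frame(R = numeric())
    for (a in ang) geoms[[a]] <- numeric()
    return(lr_dataset(geoms, numeric(), units,
                      provenance = paste("read from", path)))
  }
  parse_row <- function(s) strsplit(trimws(s), "\\s+")[[1]]
  first <- parse_row(lines[1L])
  start <- 1L
  if (any(is.na(suppressWarnings(as.numeric(first))))) start <- 2L # header
  rows <- lapply(lines[seq(start, length(lines))], parse_row)
  nc <- lengths(rows)
  if (any(nc != ncol_exp))
    stop("expected ", ncol_exp, " columns (R, ",
         paste(c(ang, "E"), collapse = ", "), ") for this ",
         system_dimension(sys), "D system; line ",
         lineno[which(nc != ncol_exp)[1L] + start - 1L], " has ",
         nc[which(nc != ncol_exp)[1L]])
  vals <- suppressWarnings(vapply(rows, as.numeric, numeric(ncol_exp)))
  if (anyNA(vals)) {
    bad <- which(colSums(is.na(vals)) > 0)[1L]
    stop("non-numeric field at line ", lineno[bad + start - 1L], " of ", path)
  }
  vals <- t(vals)
  geoms <- data.frame(R = .length_to_bohr(vals[, 1L], units$distance))
  for (i in seq_along(ang))
    geoms[[ang[i]]] <- .angle_to_rad(vals[, 1L + i], units$angle)
  energy <- .energy_to_hartree(vals[, ncol_exp], units$energy)
  lr_dataset(geoms, energy, units, provenance = paste("read from", path))
}

#' Write a dataset in the package's file dialect
#'
#' @param data an [lr_dataset()].
#' @param path output path.
#' @param sys an [lr_system()] (column order check).
#' @param units output units (defaults to the dataset's own).
#' @return \code{path}, invisibly.
#' @export
write_dataset <- function(data, path, sys, units = data$units) {
  ang <- free_angles(sys)
  stopifnot(all(ang %in% names(data$geoms)))
  m <- cbind(.length_from_bohr(data$geoms$R, units$distance))
  for (a in ang) m <- cbind(m, .angle_from_rad(data$geoms[[a]], units$angle))
  m <- cbind(m, .energy_from_hartree(data$energy, units$energy))
  hdr <- sprintf("# R(%s) %s E(%s)", units$distance,
                 paste(sprintf("%s(%s)", ang, units$angle), collapse = " "),
                 units$energy)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(format(m, digits = 17, trim = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' LeRoy anisotropy filter
#'
#' Admits a data point into the long-range fitting set when the minimal
#' distance over all inter-fragment atom pairs (sites placed by each
#' molecule's Euler rotation and the centre-of-mass separation) is at
#' least \code{d_min}; the boundary is inclusive.  This carves out the
#' negligible-overlap region for strongly anisotropic molecules, beyond a
#' simple radial cutoff.
#'
#' @param data an [lr_dataset()].
#' @param sys an [lr_system()]; both molecules must carry sites.
#' @param d_min threshold distance (bohr).
#' @return logical admission mask, with the per-point minimal pair
#'   distance in attribute \code{"min_dist"}.
#' @export
leroy_filter <- function(data, sys, d_min) {
  if (is.null(sys$molA$sites) || is.null(sys$molB$sites))
    stop("leroy_filter needs atomic sites on both molecules")
  pa <- t(vapply(sys$molA$sites, `[[`, numeric(3), "position"))
  pb <- t(vapply(sys$molB$sites, `[[`, numeric(3), "position"))
  geoms <- .geoms_from_frame(data$geoms)
  dmin <- vapply(geoms, function(g) {
    ra <- pa %*% t(euler_to_matrix(g$omega_A))
    rb <- pb %*% t(euler_to_matrix(g$omega_B))
    rb[, 3L] <- rb[, 3L] + g$R
    min(vapply(seq_len(nrow(ra)), function(i)
      min(sqrt((rb[, 1L] - ra[i, 1L])^2 + (rb[, 2L] - ra[i, 2L])^2 +
               (rb[, 3L] - ra[i, 3L])^2)), numeric(1)))
  }, numeric(1))
  mask <- dmin >= d_min
  attr(mask, "min_dist") <- dmin
  mask
}

#' Subset a dataset
#' @param data an [lr_dataset()].
#' @param keep logical or integer index.
#' @return the subset [lr_dataset()].
#' @export
subset_dataset <- function(data, keep) {
  lr_dataset(data$geoms[keep, , drop = FALSE], data$energy[keep],
             data$units, data$provenance)
}

## ---- coefficient serialization -----------------------------------------

.COEF_FORMAT <- "longrangefit-coefficients-1"

#' Serialize / restore a coefficient set
#'
#' Coefficients are written as a JSON document carrying the format
#' version, the system declaration, the caps, the deterministic term
#' table and every named coefficient; \code{read_coefficients} rebuilds
#' the expansion and verifies that each required coefficient is present,
#' so \code{read(write(x))} is the identity.
#'
#' @param coeffs an [lr_coefficients()] (or [lr_fit()]).
#' @param path file path.
#' @return \code{write_coefficients}: \code{path}, invisibly;
#'   \code{read_coefficients}: an [lr_coefficients()].
#' @export
write_coefficients <- function(coeffs, path) {
  if (inherits(coeffs, "lr_fit")) coeffs <- coeffs$coefficients
  ex <- coeffs$expansion
  molrec <- function(m) {
    rec <- list(name = m$name, point_group = m$point_group,
                charge = m$charge)
    if (!is.na(m$n)) rec$n <- m$n
    rec
  }
  doc <- list(
    format = .COEF_FORMAT,
    units = list(energy = "hartree", distance = "bohr", angle = "rad"),
    system = list(molA = molrec(ex$sys$molA), molB = molrec(ex$sys$molB),
                  relation = ex$sys$relation),
    caps = as.list(ex$caps),
    terms = ex$terms[, c("interaction", "order", "labels")],
    coefficients = as.list(coeffs$theta)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_coefficients
#' @export
read_coefficients <- function(path) {
  doc <- jsonlite::read_json(path)
  if (!identical(doc$format, .COEF_FORMAT))
    stop("unsupported coefficient file format: ",
         if (is.null(doc$format)) "<missing>" else doc$format)
  mk <- function(m) lr_molecule(m$name, m$point_group,
                                n = if (length(m[["n"]]) == 1L) m[["n"]]
                                    else NULL,
                                charge = m$charge)
  sys <- lr_system(mk(doc$system$molA), mk(doc$system$molB),
                   doc$system$relation)
  caps <- unlist(doc$caps)
  ex <- lr_expansion(sys, caps)
  vals <- doc$coefficients
  missing <- setdiff(ex$names, names(vals))
  if (length(missing) > 0L)
    stop("coefficient file is missing required entr",
         if (length(missing) == 1L) "y: " else "ies: ",
         paste(missing, collapse = ", "))
  lr_coefficients(ex, vapply(ex$names, function(nm) as.numeric(vals[[nm]]),
                             numeric(1)))
}
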