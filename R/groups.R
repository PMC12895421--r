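## Point-group machinery: generators in the package's orientation
## conventions, group closure, and cached element lists.
##
## Orientation conventions (molecule-fixed frame): the principal rotation
## axis lies along z; a C2 axis along x where the group has one; sigma_h is
## the xy plane; for Cs the mirror is the xy plane; cubic groups carry
## their C3 axis along (1,1,1); icosahedral groups their C5 axis along
## (1, -phi, 0) with phi the golden ratio.  Continuous groups (Cinfv,
## Dinfh) and atoms are handled analytically, not by enumeration.

.rot_axis <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  c1 <- cos(angle); s1 <- sin(angle)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) * c1 + s1 * K + (1 - c1) * (u %o% u)
}

.rotz <- function(a) .rot_axis(c(0, 0, 1), a)
.sigma_xy <- diag(c(1, 1, -1))
.sigma_xz <- diag(c(1, -1, 1))
.c2x <- diag(c(1, -1, -1))
.golden <- (1 + sqrt(5)) / 2

.finite_groups <- c("C1", "Cs", "Ci", "Cn", "Cnh", "Cnv", "Dn", "Dnh",
                    "Dnd", "S2n", "T", "Th", "Td", "O", "Oh", "I", "Ih")
.continuous_groups <- c("Cinfv", "Dinfh", "atom")
.n_groups <- c("Cn", "Cnh", "Cnv", "Dn", "Dnh", "Dnd", "S2n")

.group_generators <- function(point_group, n = NULL) {
  need_n <- point_group %in% .n_groups
  if (need_n) {
    if (is.null(n) || n < 2L) stop("point group ", point_group,
                                   " needs an axis order n >= 2")
    n <- as.integer(n)
  }
  cz  <- if (need_n) .rotz(2 * pi / n) else NULL
  c3d <- .rot_axis(c(1, 1, 1), 2 * pi / 3)
  c5i <- .rot_axis(c(1, -.golden, 0), 2 * pi / 5)
  switch(point_group,
    C1  = list(),
    Cs  = list(.sigma_xy),
    Ci  = list(-diag(3)),
    Cn  = list(cz),
    Cnh = list(cz, .sigma_xy),
    Cnv = list(cz, .sigma_xz),
    Dn  = list(cz, .c2x),
    ## Dnh: principal axis, C2(x) and the S_n roto-reflection about z
    Dnh = list(cz, .c2x, .sigma_xy %*% cz),
    ## Dnd: the roto-reflection axis of D_nd has order 2n
    Dnd = list(cz, .c2x, .sigma_xy %*% .rotz(pi / n)),
    S2n = list(.sigma_xy %*% .rotz(pi / n)),
    T   = list(.rotz(pi), c3d),
    Th  = list(.rotz(pi), .sigma_xy, c3d),
    Td  = list(.sigma_xy %*% .rotz(pi / 2), c3d),
    O   = list(.rotz(pi / 2), c3d),
    Oh  = list(.rotz(pi / 2), .sigma_xy, c3d),
    I   = list(.rotz(pi), c3d, c5i),
    Ih  = list(.rotz(pi), .sigma_xy, c3d, c5i),
    stop("unknown point group label: ", point_group)
  )
}

.mat_key <- function(m) paste(sprintf("%.9f", round(m, 9) + 0), collapse = ",")

## closure of a generator set to a full finite group (fixed-point iteration
## with a matrix-hash tolerance of 1e-9)
.group_closure <- function(gens) {
  elems <- list(diag(3))
  seen <- new.env(parent = emptyenv())
  assign(.mat_key(diag(3)), TRUE, envir = seen)
  frontier <- list(diag(3))
  while (length(frontier) > 0L) {
    nxt <- list()
    for (f in frontier) for (g in gens) {
      h <- g %*% f
      k <- .mat_key(h)
      if (is.null(seen[[k]])) {
        seen[[k]] <- TRUE
        elems[[length(elems) + 1L]] <- h
        nxt[[length(nxt) + 1L]] <- h
      }
    }
    frontier <- nxt
    if (length(elems) > 1000L) stop("group closure did not terminate")
  }
  elems
}

#' Elements of a molecular point group
#'
#' Enumerates the finite point group in the package's orientation
#' conventions by closing the generator set.  Continuous groups
#' (\code{Cinfv}, \code{Dinfh}) and atoms cannot be enumerated and raise an
#' error; their invariant subspaces are obtained analytically by
#' [invariant_basis()].
#'
#' @param spec an [lr_molecule()] (or a bare group label string).
#' @param n axis order when \code{spec} is a bare label of a C/D/S family
#'   group.
#' @return a list of 3x3 orthogonal matrices including the identity.
#' @examples
#' length(group_elements("Td"))   # 24
#' length(group_elements("C2v", n = 2))  # 4
#' @export
group_elements <- function(spec, n = NULL) {
  if (inherits(spec, "lr_molecule")) {
    pg <- spec$point_group; n <- spec$n
  } else {
    pg <- .canon_group(spec)
    if (!is.null(pg$n)) n <- pg$n
    pg <- pg$label
  }
  if (pg %in% .continuous_groups)
    stop("continuous group ", pg, " is handled analytically, not enumerated")
  key <- paste0("grp_", pg, "_", if (is.null(n)) "" else n)
  if (!is.null(.lr_cache[[key]])) return(.lr_cache[[key]])
  out <- .group_closure(.group_generators(pg, n))
  .lr_cache[[key]] <- out
  out
}

## accept both family labels ("Cnv" with n given) and concrete ones ("C3v")
.canon_group <- function(label) {
  if (label %in% c(.finite_groups, .continuous_groups))
    return(list(label = label, n = NULL))
  m <- regmatches(label, regexec("^([CDS])([0-9]+)([a-z]*)$", label))[[1]]
  if (length(m) == 0L) stop("unknown point group label: ", label)
  fam <- paste0(m[2], "n", m[4])
  nn <- as.integer(m[3])
  fam <- sub("nn", "n", fam)
  if (fam == "Sn") { # S2n family: S4 -> n = 2
    if (nn %% 2L != 0L) stop("S groups must have even order: ", label)
    return(list(label = "S2n", n = nn %/% 2L))
  }
  if (!fam %in% .n_groups) stop("unknown point group label: ", label)
  if (nn == 1L) {
    ## C1v = Cs-like edge cases are not supported; require n >= 2
    stop("axis order must be >= 2 in ", label)
  }
  list(label = fam, n = nn)
}
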