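## Assembly of the system-specific expansion: every symmetry-allowed term
## of the electrostatic (Q_t Q_u T_{t,u}), induction
## (-1/2 alpha_{t;t'} Q_u Q_u' T_{t,u} T_{t',u'}) and dispersion
## (-D_{t,u;t',u'} T_{t,u} T_{t',u'}) series with inverse-power order up
## to the per-interaction caps.  Terms are grouped by rank: one term is a
## rank tuple whose symmetry-allowed component combinations all share the
## same coefficients structure; the double sums over components are
## evaluated in full (no cross terms are dropped).

.norm_caps <- function(caps) {
  if (length(caps) == 1L && is.null(names(caps)))
    caps <- c(elec = caps, ind = caps, disp = caps)
  stopifnot(all(c("elec", "ind", "disp") %in% names(caps)))
  caps <- caps[c("elec", "ind", "disp")]
  if (any(caps > 15)) stop("expansion orders beyond 15 are not supported")
  if (any(caps < 0)) stop("caps must be non-negative")
  storage.mode(caps) <- "integer"
  caps
}

#' Assemble the symmetry-adapted term list of a system
#'
#' Enumerates every symmetry-allowed term with inverse-power order at most
#' the per-interaction caps, in a deterministic ordering (interaction,
#' order, then lexicographic rank labels).  Electrostatic terms are rank
#' pairs \code{(la, lb)} of order \code{la + lb + 1}; induction and
#' dispersion terms are rank quadruples of order equal to the sum of their
#' two T-tensor orders.  Terms whose only possible coefficient vanishes
#' identically (e.g. charge terms of a neutral molecule) are omitted.
#'
#' @param sys an [lr_system()].
#' @param caps either a single order or a named vector
#'   \code{c(elec =, ind =, disp =)}, each at most 15.
#' @return an object of class \code{lr_terms}: a list with the system, the
#'   caps and a data frame \code{table} of terms.
#' @examples
#' sys <- lr_system(lr_molecule("CF+", "Cinfv", charge = 1),
#'                  lr_molecule("H2", "Dinfh"))
#' tt <- assemble_terms(sys, caps = 6)
#' subset(tt$table, interaction == "electrostatic")
#' @export
assemble_terms <- function(sys, caps) {
  caps <- .norm_caps(caps)
  rA <- .active_ranks(sys$molA, 14L)
  rB <- .active_ranks(sys$molB, 14L)
  rows <- list()
  add <- function(interaction, order, labels, key) {
    rows[[length(rows) + 1L]] <<- data.frame(
      interaction = interaction, order = order, labels = labels, key = key,
      stringsAsFactors = FALSE)
  }
  ## electrostatic
  for (la in rA) for (lb in rB) {
    n <- la + lb + 1L
    if (n <= caps[["elec"]])
      add("electrostatic", n, sprintf("Q%d(A).Q%d(B)", la, lb),
          sprintf("E.%d.%d", la, lb))
  }
  ## induction (alpha on one side, squared moments on the other)
  for (side in c("A", "B")) {
    pol <- if (side == "A") sys$molA else sys$molB
    src <- if (side == "A") rB else rA
    oth <- if (side == "A") "B" else "A"
    if (length(src) == 0L) next
    capi <- caps[["ind"]]
    if (capi >= 4L) for (blk in .active_blocks(pol, capi - 2L - 2L * min(src))) {
      l1 <- blk[1]; l2 <- blk[2]
      for (lu in src) for (lu2 in src[src >= lu]) {
        n <- l1 + lu + l2 + lu2 + 2L
        if (n <= capi)
          add(paste0("induction_", side), n,
              sprintf("alpha%d,%d(%s).Q%d(%s).Q%d(%s)", l1, l2, side,
                      lu, oth, lu2, oth),
              sprintf("I%s.%d_%d.%d.%d", side, l1, l2, lu, lu2))
      }
    }
  }
  ## dispersion
  capd <- caps[["disp"]]
  if (capd >= 6L) {
    bA <- .active_blocks(sys$molA, capd - 4L)
    bB <- .active_blocks(sys$molB, capd - 4L)
    for (a in bA) for (b in bB) {
      n <- a[1] + a[2] + b[1] + b[2] + 2L
      if (n <= capd)
        add("dispersion", n,
            sprintf("D[%d,%d(A);%d,%d(B)]", a[1], a[2], b[1], b[2]),
            sprintf("D.%d_%d.%d_%d", a[1], a[2], b[1], b[2]))
    }
  }
  tab <- if (length(rows) == 0L)
    data.frame(interaction = character(), order = integer(),
               labels = character(), key = character(),
               stringsAsFactors = FALSE)
  else do.call(rbind, rows)
  ord <- order(match(tab$interaction, c("electrostatic", "induction_A",
                                        "induction_B", "dispersion")),
               tab$order, tab$key)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(sys = sys, caps = caps, table = tab), class = "lr_terms")
}

#' @export
print.lr_terms <- function(x, ...) {
  cat(sprintf("<lr_terms> %s -- %s, caps elec/ind/disp = %d/%d/%d, %d terms\n",
              x$sys$molA$name, x$sys$molB$name,
              x$caps[["elec"]], x$caps[["ind"]], x$caps[["disp"]],
              nrow(x$table)))
  invisible(x)
}

#' Interaction term table by order
#'
#' Renders, for one interaction type, the table of orders 1..15 with the
#' active (symmetry-allowed) terms of the system, mirroring the
#' order-by-order way the expansion is introduced into a fit.
#'
#' @param sys an [lr_system()].
#' @param interaction \code{"electrostatic"}, \code{"induction"} or
#'   \code{"dispersion"}.
#' @param max_order highest order row (default 15).
#' @return a data frame with columns \code{order}, \code{active} and
#'   \code{terms} (comma-separated term labels, \code{""} where none).
#' @export
render_term_table <- function(sys, interaction = c("electrostatic",
                                                   "induction", "dispersion"),
                              max_order = 15L) {
  interaction <- match.arg(interaction)
  tt <- assemble_terms(sys, caps = c(elec = max_order, ind = max_order,
                                     disp = max_order))
  tab <- tt$table
  keep <- if (interaction == "induction")
    tab$interaction %in% c("induction_A", "induction_B")
  else tab$interaction == interaction
  tab <- tab[keep, , drop = FALSE]
  out <- data.frame(order = seq_len(max_order), active = FALSE,
                    terms = "", stringsAsFactors = FALSE)
  for (n in seq_len(max_order)) {
    lab <- tab$labels[tab$order == n]
    if (length(lab) > 0L) {
      out$active[n] <- TRUE
      out$terms[n] <- paste(lab, collapse = ", ")
    }
  }
  out
}

#' Coefficient-count comparison of the two tensor representations
#'
#' Total number of electrostatic expansion coefficients of both molecules
#' through a given order for a symmetry-free charged pair: the Cartesian
#' form needs \eqn{2\sum_{p<n} 3^p = 3^n - 1} components (every rank-p
#' Cartesian tensor has \eqn{3^p}), the spherical form only
#' \eqn{2\sum_{l<n}(2l+1) = 2n^2}.
#'
#' @param order expansion order, 1..15.
#' @return integer count.
#' @examples
#' cartesian_coefficient_count(6)  # 728
#' spherical_coefficient_count(6)  # 72
#' @export
cartesian_coefficient_count <- function(order) {
  if (order < 1 || order > 15) stop("order must be in 1..15")
  as.integer(3^order - 1)
}

#' @rdname cartesian_coefficient_count
#' @export
spherical_coefficient_count <- function(order) {
  if (order < 1 || order > 15) stop("order must be in 1..15")
  as.integer(2 * order^2)
}
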