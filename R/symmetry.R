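## Symmetry adaptation: surviving multipole components, polarizability
## patterns, and leading interaction orders per point group.

.mol_key <- function(mol) paste0(mol$point_group, "_", mol$n)

## deterministic basis orientation: first sizeable entry of each column is
## positive, columns ordered by the row index of that entry (SVD leaves
## both the sign and the order of degenerate singular vectors arbitrary)
.canon_cols <- function(B) {
  if (ncol(B) == 0L) return(B)
  lead <- integer(ncol(B))
  for (k in seq_len(ncol(B))) {
    i <- which(abs(B[, k]) > 1e-7)[1L]
    if (B[i, k] < 0) B[, k] <- -B[, k]
    lead[k] <- i
  }
  B[, order(lead), drop = FALSE]
}

#' Totally symmetric multipole subspace of a point group
#'
#' Orthonormal basis of the rank-l real multipole components left invariant
#' by every operation of the molecule's point group: the column space of
#' the group-averaged projector \eqn{P_l = |G|^{-1}\sum_g \Delta^l(g)},
#' with improper operations carrying the parity factor \eqn{(-1)^l}
#' automatically (see [rotation_block()]).  Continuous groups follow the
#' analytic rules: \code{Cinfv} keeps only \eqn{m = 0}; \code{Dinfh}
#' keeps \eqn{m = 0} at even l; an atom keeps rank 0 only.  Rank via
#' singular values with threshold 1e-8.
#'
#' @param spec an [lr_molecule()].
#' @param l rank, 0..15.
#' @return a \code{(2l+1) x d} matrix whose orthonormal columns span the
#'   invariant subspace (\code{d = 0} allowed); rows in [rank_labels()]
#'   order.
#' @export
invariant_basis <- function(spec, l) {
  stopifnot(inherits(spec, "lr_molecule"), l >= 0L, l <= 15L)
  n <- 2L * l + 1L
  pg <- spec$point_group
  if (pg == "atom") {
    return(if (l == 0L) matrix(1, 1L, 1L) else matrix(0, n, 0L))
  }
  if (pg == "Cinfv") {
    B <- matrix(0, n, 1L); B[1L, 1L] <- 1
    return(B)
  }
  if (pg == "Dinfh") {
    if (l %% 2L != 0L) return(matrix(0, n, 0L))
    B <- matrix(0, n, 1L); B[1L, 1L] <- 1
    return(B)
  }
  key <- paste0("inv_", .mol_key(spec), "_", l)
  if (!is.null(.lr_cache[[key]])) return(.lr_cache[[key]])
  els <- group_elements(spec)
  P <- matrix(0, n, n)
  for (g in els) P <- P + rotation_block(l, g)
  P <- P / length(els)
  sv <- svd(P)
  d <- sum(sv$d > 1e-8)
  B <- if (d == 0L) matrix(0, n, 0L)
       else .canon_cols(sv$u[, seq_len(d), drop = FALSE])
  .lr_cache[[key]] <- B
  B
}

#' Allowed multipole components up to a rank
#'
#' @param spec an [lr_molecule()].
#' @param l_max highest rank (\code{<= 15}).
#' @return named list \code{"0" ... "l_max"} of invariant bases (see
#'   [invariant_basis()]); rank 0 is always present, its value pinned to
#'   the molecular charge (zero for neutral molecules).
#' @export
allowed_multipoles <- function(spec, l_max) {
  stopifnot(l_max <= 15L)
  out <- lapply(0:l_max, function(l) invariant_basis(spec, l))
  names(out) <- as.character(0:l_max)
  out
}

## ranks at which the molecule can carry a nonzero multipole coefficient
## (rank 0 only when charged)
.active_ranks <- function(spec, l_max) {
  r <- integer()
  if (spec$charge != 0) r <- 0L
  for (l in seq_len(l_max)) if (ncol(invariant_basis(spec, l)) > 0L)
    r <- c(r, l)
  r
}

## orthonormal symmetrizer-projected invariant basis for the (l1, l2)
## polarizability block: matrices M (2l1+1) x (2l2+1); symmetric when
## l1 == l2.  Blocks are stored for l1 <= l2; the (l2, l1) block is the
## transpose.
.pattern_block <- function(spec, l1, l2) {
  stopifnot(l1 <= l2)
  key <- paste0("pat_", .mol_key(spec), "_", l1, "_", l2)
  if (!is.null(.lr_cache[[key]])) return(.lr_cache[[key]])
  n1 <- 2L * l1 + 1L; n2 <- 2L * l2 + 1L
  pg <- spec$point_group
  mats <- list()
  if (pg == "atom") {
    if (l1 == l2) mats <- list(diag(n1) / sqrt(n1))
  } else if (pg %in% c("Cinfv", "Dinfh")) {
    if (pg == "Cinfv" || (l1 + l2) %% 2L == 0L) {
      for (m in 0:l1) {
        M <- matrix(0, n1, n2)
        if (m == 0L) M[1L, 1L] <- 1
        else {
          M[2L * m, 2L * m] <- 1 / sqrt(2)
          M[2L * m + 1L, 2L * m + 1L] <- 1 / sqrt(2)
        }
        mats[[length(mats) + 1L]] <- M
      }
    }
  } else {
    els <- group_elements(spec)
    P <- matrix(0, n1 * n2, n1 * n2)
    for (g in els) {
      D1 <- rotation_block(l1, g); D2 <- rotation_block(l2, g)
      P <- P + kronecker(D2, D1)   # vec(D1 %*% M %*% t(D2)) = (D2 x D1) vec(M)
    }
    P <- P / length(els)
    if (l1 == l2) {
      ## restrict to symmetric matrices (alpha_{t;t'} = alpha_{t';t})
      Sym <- matrix(0, n1 * n1, n1 * n1)
      idx <- function(i, j) (j - 1L) * n1 + i
      for (i in seq_len(n1)) for (j in seq_len(n1)) {
        Sym[idx(i, j), idx(i, j)] <- Sym[idx(i, j), idx(i, j)] + 0.5
        Sym[idx(i, j), idx(j, i)] <- Sym[idx(i, j), idx(j, i)] + 0.5
      }
      P <- P %*% Sym
    }
    sv <- svd(P)
    d <- sum(sv$d > 1e-8)
    if (d > 0L) {
      Bc <- .canon_cols(sv$u[, seq_len(d), drop = FALSE])
      mats <- lapply(seq_len(d), function(k) matrix(Bc[, k], n1, n2))
    }
  }
  .lr_cache[[key]] <- mats
  mats
}

#' Symmetry-allowed polarizability pattern
#'
#' Invariant basis of the polarizability blocks
#' \eqn{\alpha_{t;t'}} with \eqn{t} of rank \code{l1} and \eqn{t'} of rank
#' \code{l2 >= l1}: the totally symmetric subspace of the (symmetrized,
#' when \code{l1 = l2}) tensor product of the two rank representations.
#' An atom's dipole block has the single isotropic invariant; a linear
#' molecule's dipole block has two (parallel and perpendicular).
#'
#' @param spec an [lr_molecule()].
#' @param l_max highest rank entering any block.
#' @return named list over blocks \code{"l1_l2"} (\code{l1 <= l2}); each
#'   element is a list of orthonormal basis matrices of dimension
#'   \code{(2 l1 + 1) x (2 l2 + 1)}.
#' @export
polarizability_pattern <- function(spec, l_max) {
  stopifnot(l_max <= 14L)
  out <- list()
  for (l1 in 1:l_max) for (l2 in l1:l_max) {
    m <- .pattern_block(spec, l1, l2)
    if (length(m) > 0L) out[[paste0(l1, "_", l2)]] <- m
  }
  out
}

## polarizability blocks (unordered {l1,l2}, l1 <= l2) with at least one
## invariant; rank 0 is excluded (a monopole does not polarize)
.active_blocks <- function(spec, lsum_max) {
  blocks <- list()
  l1 <- 1L
  while (l1 + l1 <= lsum_max) {
    for (l2 in l1:(lsum_max - l1)) {
      if (length(.pattern_block(spec, l1, l2)) > 0L)
        blocks[[length(blocks) + 1L]] <- c(l1, l2)
    }
    l1 <- l1 + 1L
  }
  blocks
}

#' Leading interaction order of a system
#'
#' The smallest inverse-power order \eqn{n} (term \eqn{\propto R^{-n}})
#' with at least one symmetry-allowed term of the requested interaction:
#' \eqn{n = l_a + l_b + 1} for electrostatics and the sum of the two
#' T-tensor orders for induction and dispersion.  Returns \code{Inf} when
#' no term is allowed through 15th order.
#'
#' @param sys an [lr_system()].
#' @param interaction \code{"electrostatic"}, \code{"induction"} or
#'   \code{"dispersion"}.
#' @return integer order, or \code{Inf}.
#' @examples
#' co <- lr_molecule("CO", "Cinfv")
#' leading_order(lr_system(co, co, "identical"), "electrostatic")  # 3
#' @export
leading_order <- function(sys, interaction = c("electrostatic", "induction",
                                               "dispersion")) {
  interaction <- match.arg(interaction)
  lmax <- 14L
  rA <- .active_ranks(sys$molA, lmax)
  rB <- .active_ranks(sys$molB, lmax)
  if (interaction == "electrostatic") {
    if (length(rA) == 0L || length(rB) == 0L) return(Inf)
    n <- min(rA) + min(rB) + 1L
    return(if (n <= 15L) n else Inf)
  }
  best <- Inf
  if (interaction == "induction") {
    ## alpha on one molecule, squared permanent moments on the other
    for (side in 1:2) {
      pol <- if (side == 1L) sys$molA else sys$molB
      src <- if (side == 1L) rB else rA
      if (length(src) == 0L) next
      blks <- .active_blocks(pol, 13L)
      lu <- min(src)
      for (b in blks)
        best <- min(best, b[1] + lu + 1L + b[2] + lu + 1L)
    }
  } else {
    bA <- .active_blocks(sys$molA, 13L)
    bB <- .active_blocks(sys$molB, 13L)
    for (a in bA) for (b in bB)
      best <- min(best, a[1] + b[1] + 1L + a[2] + b[2] + 1L)
  }
  if (best <= 15) best else Inf
}

#' Exchange constraints between the two coefficient sets
#'
#' For \code{relation = "identical"} the coefficient blocks of molecule B
#' are tied equal to those of A.  For \code{"chiral_partners"} they are
#' tied through the numeric image of the \eqn{\sigma_{xz}} mirror: each
#' rank-l coefficient vector of B is \eqn{\Delta^l(\sigma_{xz})} applied to
#' A's (so s-type components change sign), and polarizability blocks map
#' as \eqn{\Delta^{l_1} \alpha \Delta^{l_2 T}}; all maps are computed
#' numerically from [rotation_block()], never hand-derived.  A distinct
#' system has no constraints.
#'
#' @param sys an [lr_system()].
#' @param l_max highest rank for which maps are returned.
#' @return a list with \code{type} and, for tied systems, per-rank
#'   component maps \code{mult[[l + 1]]} ((2l+1) square matrices with
#'   \code{Q_B = map \%*\% Q_A}).
#' @export
exchange_constraints <- function(sys, l_max = 8L) {
  if (sys$relation == "distinct")
    return(list(type = "distinct", mult = list()))
  mirror <- .sigma_xz
  mult <- lapply(0:l_max, function(l) {
    if (sys$relation == "identical") diag(2L * l + 1L)
    else rotation_block(l, mirror)
  })
  list(type = sys$relation, mult = mult)
}
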