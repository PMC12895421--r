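## Energy evaluation of an assembled expansion.
##
## All geometry dependence sits in the T-tensor blocks, which are
## precomputed once per geometry set ("design"); evaluating the model for
## a new coefficient vector is then cheap linear algebra, which is what
## makes the staged nonlinear fits fast.

.as_geom_list <- function(geoms) {
  if (inherits(geoms, "dimer_geometry")) return(list(geoms))
  if (is.data.frame(geoms)) return(.geoms_from_frame(geoms))
  stopifnot(is.list(geoms), all(vapply(geoms, inherits, logical(1),
                                       "dimer_geometry")))
  geoms
}

## data frame (R, alpha, beta_A, beta_B, gamma_A, gamma_B; radians, bohr)
## -> list of dimer_geometry
.geoms_from_frame <- function(df) {
  g <- function(nm) if (nm %in% names(df)) df[[nm]] else rep(0, nrow(df))
  al <- g("alpha"); bA <- g("beta_A"); bB <- g("beta_B")
  gA <- g("gamma_A"); gB <- g("gamma_B")
  lapply(seq_len(nrow(df)), function(i)
    dimer_geometry(df$R[i], al[i], bA[i], bB[i], gA[i], gB[i]))
}

## ordered rank-pair enumeration helpers ---------------------------------

.ordered_pairs <- function(blk) {
  if (blk[1] == blk[2]) list(list(r = blk, tp = FALSE))
  else list(list(r = blk, tp = FALSE), list(r = rev(blk), tp = TRUE))
}

## Precompute the per-point T-tensor blocks and the dispersion regressors
## for a geometry set.  `expansion` fixes which rank pairs are needed.
lr_design <- function(expansion, geoms) {
  geoms <- if (is.data.frame(geoms)) .geoms_from_frame(geoms) else .as_geom_list(geoms)
  N <- length(geoms)
  lay <- expansion
  tab <- lay$terms

  ## enumerate contributions
  elec <- list()
  for (i in which(tab$interaction == "electrostatic")) {
    p <- strsplit(tab$key[i], ".", fixed = TRUE)[[1]]
    elec[[length(elec) + 1L]] <- list(la = as.integer(p[2]),
                                      lb = as.integer(p[3]),
                                      order = tab$order[i])
  }
  ind <- list()
  for (i in which(tab$interaction %in% c("induction_A", "induction_B"))) {
    p <- strsplit(tab$key[i], ".", fixed = TRUE)[[1]]
    side <- substr(p[1], 2, 2)
    blk <- as.integer(strsplit(p[2], "_")[[1]])
    lu <- as.integer(p[3]); lu2 <- as.integer(p[4])
    ## ordered enumeration of the double sums: (la1, lu) x (la2, lu2)
    op <- .ordered_pairs(blk)
    mom <- if (lu == lu2) list(c(lu, lu2)) else list(c(lu, lu2), c(lu2, lu))
    for (o in op) for (m in mom)
      ind[[length(ind) + 1L]] <- list(side = side, blk = blk, tp = o$tp,
                                      la1 = o$r[1], la2 = o$r[2],
                                      lu1 = m[1], lu2 = m[2],
                                      order = tab$order[i])
  }
  disp <- list()
  for (i in which(tab$interaction == "dispersion")) {
    p <- strsplit(tab$key[i], ".", fixed = TRUE)[[1]]
    disp[[length(disp) + 1L]] <-
      list(blkA = as.integer(strsplit(p[2], "_")[[1]]),
           blkB = as.integer(strsplit(p[3], "_")[[1]]),
           key = paste(p[2], p[3], sep = "|"), order = tab$order[i])
  }

  ## rank pairs needed
  pairs <- new.env(parent = emptyenv())
  addpair <- function(la, lb) assign(paste0(la, "_", lb), c(la, lb), envir = pairs)
  for (e in elec) addpair(e$la, e$lb)
  for (e in ind) {
    if (e$side == "A") { addpair(e$la1, e$lu1); addpair(e$la2, e$lu2) }
    else { addpair(e$lu1, e$la1); addpair(e$lu2, e$la2) }
  }
  for (e in disp) {
    for (oa in .ordered_pairs(e$blkA)) for (ob in .ordered_pairs(e$blkB)) {
      addpair(oa$r[1], ob$r[1]); addpair(oa$r[2], ob$r[2])
    }
  }
  pair_list <- as.list(pairs)

  ## per-point rotation matrices per rank, then T blocks
  ranksA <- sort(unique(vapply(pair_list, `[`, integer(1), 1L)))
  ranksB <- sort(unique(vapply(pair_list, `[`, integer(1), 2L)))
  M <- lapply(pair_list, function(p)
    matrix(0, N, (2L * p[1] + 1L) * (2L * p[2] + 1L)))
  for (i in seq_len(N)) {
    gm <- geoms[[i]]
    WA <- lapply(ranksA, function(l) rotation_matrix_real(l, gm$omega_A))
    names(WA) <- as.character(ranksA)
    WB <- lapply(ranksB, function(l) rotation_matrix_real(l, gm$omega_B))
    names(WB) <- as.character(ranksB)
    for (k in names(pair_list)) {
      p <- pair_list[[k]]
      Tb <- (t(WA[[as.character(p[1])]]) %*% .x0_real(p[1], p[2]) %*%
             WB[[as.character(p[2])]]) / gm$R^(p[1] + p[2] + 1L)
      M[[k]][i, ] <- as.vector(Tb)
    }
  }

  ## dispersion regressor matrix, one column per D parameter, annotated
  ## with the term order
  d_par <- grep("^D\\.", lay$names, value = TRUE)
  Fd <- matrix(0, N, length(d_par))
  colnames(Fd) <- d_par
  d_order <- stats::setNames(rep(Inf, length(d_par)), d_par)
  for (e in disp) {
    patA <- lay$patDA[[e$key]]; patB <- lay$patDB[[e$key]]
    for (kk in seq_along(patA)) for (j in seq_along(patB)) {
      nm <- sprintf("D.%s.%d.%d", e$key, kk, j)
      col <- numeric(N)
      for (oa in .ordered_pairs(e$blkA)) for (ob in .ordered_pairs(e$blkB)) {
        Mk <- if (oa$tp) t(patA[[kk]]) else patA[[kk]]
        Mj <- if (ob$tp) t(patB[[j]]) else patB[[j]]
        M1 <- M[[paste0(oa$r[1], "_", ob$r[1])]]
        M2 <- M[[paste0(oa$r[2], "_", ob$r[2])]]
        col <- col + rowSums(M1 * (M2 %*% t(kronecker(Mj, Mk))))
      }
      Fd[, nm] <- -col
      d_order[nm] <- e$order
    }
  }

  structure(list(expansion = lay, N = N, geoms = geoms, M = M,
                 elec = elec, ind = ind, Fd = Fd, d_order = d_order),
            class = "lr_design")
}

## model energies for a full parameter vector; caps may be lowered below
## the expansion caps to evaluate an intermediate stage
.design_energy <- function(design, theta, caps = NULL) {
  lay <- design$expansion
  if (is.null(caps)) caps <- lay$caps else caps <- .norm_caps(caps)
  cf <- lr_coefficients(lay, theta)
  theta <- cf$theta
  qA <- multipole_components(cf, "A")
  qB <- multipole_components(cf, "B")
  e <- rep(theta[["E_asym"]], design$N)
  for (b in design$elec) {
    if (b$order > caps[["elec"]]) next
    va <- qA[[as.character(b$la)]]; vb <- qB[[as.character(b$lb)]]
    if (is.null(va) || is.null(vb)) next
    e <- e + design$M[[paste0(b$la, "_", b$lb)]] %*% as.vector(outer(va, vb))
  }
  ## induction: V blocks (T %*% Q_other) cached per (pair, source rank)
  Vcache <- new.env(parent = emptyenv())
  getV <- function(la, lu, side) {
    key <- paste0(la, "_", lu, "_", side)
    v <- Vcache[[key]]
    if (!is.null(v)) return(v)
    q <- if (side == "A") qB[[as.character(lu)]] else qA[[as.character(lu)]]
    na <- 2L * la + 1L
    v <- design$M[[paste0(la, "_", lu)]] %*% kronecker(q, diag(na))
    Vcache[[key]] <- v
    v
  }
  for (tm in design$ind) {
    if (tm$order > caps[["ind"]]) next
    Ab <- .alpha_block_matrix(cf, tm$side, .block_key(tm$blk))
    if (tm$tp) Ab <- t(Ab)
    if (tm$side == "A") {
      V1 <- getV(tm$la1, tm$lu1, "A"); V2 <- getV(tm$la2, tm$lu2, "A")
    } else {
      ## alpha on B: moments of A; T blocks are indexed (rank_A, rank_B),
      ## so the contraction runs through t(T)
      V1 <- .getVB(design, qA, tm$la1, tm$lu1, Vcache)
      V2 <- .getVB(design, qA, tm$la2, tm$lu2, Vcache)
    }
    e <- e - 0.5 * rowSums((V1 %*% Ab) * V2)
  }
  if (ncol(design$Fd) > 0L) {
    use <- design$d_order <= caps[["disp"]]
    if (any(use))
      e <- e + design$Fd[, use, drop = FALSE] %*% theta[colnames(design$Fd)[use]]
  }
  as.numeric(e)
}

## V for alpha-on-B terms: rows of T belong to molecule A's component, so
## V[i, u] = sum_t T_i[t, u] qA_t  with (t in rank lu of A, u in rank la of B)
.getVB <- function(design, qA, la, lu, Vcache) {
  key <- paste0("B", la, "_", lu)
  v <- Vcache[[key]]
  if (!is.null(v)) return(v)
  q <- qA[[as.character(lu)]]
  na <- 2L * lu + 1L; nb <- 2L * la + 1L
  ## stored block is (lu, la): vec index t + (u-1)*na
  v <- design$M[[paste0(lu, "_", la)]] %*% kronecker(diag(nb), q)
  Vcache[[key]] <- v
  v
}

#' Evaluate the expansion energy at geometries
#'
#' \eqn{E(\mathbf{x}) = E_{asym} + E_{elec} + E_{ind} + E_{disp}} with the
#' electrostatic terms \eqn{+Q_t Q_u T_{t,u}}, induction
#' \eqn{-\tfrac12 \alpha_{t;t'} Q_u Q_{u'} T_{t,u}T_{t',u'}} (both
#' molecules) and dispersion \eqn{-D_{t,u;t',u'} T_{t,u}T_{t',u'}}, all
#' double sums taken in full.  Atomic units.
#'
#' @param coeffs an [lr_coefficients()] object.
#' @param geoms a [dimer_geometry()], a list of them, or a data frame with
#'   columns \code{R} (bohr) and any of \code{alpha, beta_A, beta_B,
#'   gamma_A, gamma_B} (radians).
#' @param caps optional caps at most the expansion's, to evaluate a
#'   truncated stage.
#' @return numeric vector of energies (hartree).
#' @export
evaluate_energy <- function(coeffs, geoms, caps = NULL) {
  stopifnot(inherits(coeffs, "lr_coefficients"))
  des <- lr_design(coeffs$expansion, geoms)
  .design_energy(des, coeffs$theta, caps)
}
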