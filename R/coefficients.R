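## Coefficient layout: the free parameters of a system-specific expansion.
##
## Internally every coefficient lives in symmetry-adapted coordinates:
## a rank-l multipole is d_l numbers multiplying the orthonormal columns
## of the invariant basis (so cubic-group "components" that are fixed
## linear combinations, e.g. the rank-4 (40)/(44c) mix of O_h, are one
## free number); a polarizability block {l1, l2} is its coordinates on
## the invariant pattern matrices; a dispersion block pair carries one
## coefficient per (pattern_A, pattern_B) combination.  The rank-0
## multipole is always pinned to the molecular charge and is never a
## parameter.

.block_key <- function(b) paste0(b[1], "_", b[2])

.build_layout <- function(terms) {
  sys <- terms$sys; tab <- terms$table
  parse_key <- function(k) strsplit(k, ".", fixed = TRUE)[[1]]
  qA_ranks <- integer(); qB_ranks <- integer()
  aA_blocks <- list(); aB_blocks <- list()
  d_blocks <- list()
  for (i in seq_len(nrow(tab))) {
    p <- parse_key(tab$key[i])
    switch(substr(p[1], 1, 1),
      E = {
        qA_ranks <- union(qA_ranks, as.integer(p[2]))
        qB_ranks <- union(qB_ranks, as.integer(p[3]))
      },
      I = {
        blk <- as.integer(strsplit(p[2], "_")[[1]])
        if (p[1] == "IA") {
          aA_blocks[[.block_key(blk)]] <- blk
          qB_ranks <- union(qB_ranks, as.integer(p[3]))
          qB_ranks <- union(qB_ranks, as.integer(p[4]))
        } else {
          aB_blocks[[.block_key(blk)]] <- blk
          qA_ranks <- union(qA_ranks, as.integer(p[3]))
          qA_ranks <- union(qA_ranks, as.integer(p[4]))
        }
      },
      D = {
        d_blocks[[paste(p[2], p[3], sep = "|")]] <-
          list(a = as.integer(strsplit(p[2], "_")[[1]]),
               b = as.integer(strsplit(p[3], "_")[[1]]))
      })
  }
  qA_ranks <- sort(setdiff(qA_ranks, 0L))
  qB_ranks <- sort(setdiff(qB_ranks, 0L))
  sk <- function(keys) if (is.null(keys)) character() else sort(keys)
  aA_blocks <- aA_blocks[sk(names(aA_blocks))]
  aB_blocks <- aB_blocks[sk(names(aB_blocks))]
  d_blocks <- d_blocks[sk(names(d_blocks))]

  basisA <- lapply(qA_ranks, function(l) invariant_basis(sys$molA, l))
  basisB <- lapply(qB_ranks, function(l) invariant_basis(sys$molB, l))
  names(basisA) <- as.character(qA_ranks)
  names(basisB) <- as.character(qB_ranks)
  patA <- lapply(aA_blocks, function(b) .pattern_block(sys$molA, b[1], b[2]))
  patB <- lapply(aB_blocks, function(b) .pattern_block(sys$molB, b[1], b[2]))
  patDA <- lapply(d_blocks, function(p) .pattern_block(sys$molA, p$a[1], p$a[2]))
  patDB <- lapply(d_blocks, function(p) .pattern_block(sys$molB, p$b[1], p$b[2]))

  nm <- "E_asym"
  sec <- data.frame(name = "E_asym", section = "asym", stringsAsFactors = FALSE)
  addn <- function(names, section) {
    sec <<- rbind(sec, data.frame(name = names, section = section,
                                  stringsAsFactors = FALSE))
  }
  for (i in seq_along(qA_ranks)) {
    d <- ncol(basisA[[i]])
    if (d > 0L) addn(sprintf("QA.%d.%d", qA_ranks[i], seq_len(d)), "qA")
  }
  for (i in seq_along(qB_ranks)) {
    d <- ncol(basisB[[i]])
    if (d > 0L) addn(sprintf("QB.%d.%d", qB_ranks[i], seq_len(d)), "qB")
  }
  for (k in names(aA_blocks))
    addn(sprintf("aA.%s.%d", k, seq_along(patA[[k]])), "aA")
  for (k in names(aB_blocks))
    addn(sprintf("aB.%s.%d", k, seq_along(patB[[k]])), "aB")
  for (k in names(d_blocks)) {
    nk <- length(patDA[[k]]); nj <- length(patDB[[k]])
    for (j in seq_len(nj)) for (kk in seq_len(nk))
      addn(sprintf("D.%s.%d.%d", k, kk, j), "d")
  }
  sec <- sec[-1L, , drop = FALSE]
  names_full <- c("E_asym", sec$name)
  list(sys = sys, caps = terms$caps, terms = tab,
       qA_ranks = qA_ranks, qB_ranks = qB_ranks,
       basisA = basisA, basisB = basisB,
       aA_blocks = aA_blocks, aB_blocks = aB_blocks, d_blocks = d_blocks,
       patA = patA, patB = patB, patDA = patDA, patDB = patDB,
       names = names_full,
       section = c("asym", sec$section))
}

#' System-specific expansion with its parameter layout
#'
#' Binds the term list of [assemble_terms()] to the symmetry-adapted
#' coefficient layout: invariant multipole bases per rank, polarizability
#' pattern bases per block, dispersion pattern products, and the full
#' named parameter vector.
#'
#' @inheritParams assemble_terms
#' @return an object of class \code{lr_expansion}.
#' @export
lr_expansion <- function(sys, caps) {
  terms <- assemble_terms(sys, caps)
  lay <- .build_layout(terms)
  structure(lay, class = "lr_expansion")
}

#' @export
print.lr_expansion <- function(x, ...) {
  cat(sprintf("<lr_expansion> %s -- %s, caps %d/%d/%d, %d terms, %d parameters\n",
              x$sys$molA$name, x$sys$molB$name, x$caps[["elec"]],
              x$caps[["ind"]], x$caps[["disp"]], nrow(x$terms),
              length(x$names)))
  invisible(x)
}

#' Coefficient set of an expansion
#'
#' Wraps a full parameter vector (asymptotic energy, multipole coordinates,
#' polarizability and dispersion coefficients) for a given expansion.
#' Component-space views are available through [multipole_components()].
#'
#' @param expansion an [lr_expansion()].
#' @param theta full numeric parameter vector in \code{expansion$names}
#'   order (recycled zeros allowed), or a named vector whose names are a
#'   subset of the layout names.
#' @return an object of class \code{lr_coefficients}.
#' @export
lr_coefficients <- function(expansion, theta = 0) {
  n <- length(expansion$names)
  if (!is.null(names(theta))) {
    bad <- setdiff(names(theta), expansion$names)
    if (length(bad) > 0L)
      stop("unknown coefficient name(s): ", paste(bad, collapse = ", "))
    th <- stats::setNames(numeric(n), expansion$names)
    th[names(theta)] <- theta
  } else {
    th <- stats::setNames(rep_len(as.numeric(theta), n), expansion$names)
  }
  structure(list(expansion = expansion, theta = th),
            class = "lr_coefficients")
}

#' @export
print.lr_coefficients <- function(x, digits = 6, ...) {
  cat("<lr_coefficients>\n")
  cat("  E_asym =", format(x$theta[["E_asym"]], digits = digits), "hartree\n")
  for (side in c("A", "B")) {
    q <- multipole_components(x, side)
    for (l in names(q)) {
      v <- q[[l]]
      nz <- which(abs(v) > 0)
      if (length(nz) > 0L)
        cat(sprintf("  Q%s [%s]: %s\n", side, l,
                    paste(sprintf("%s=%s", rank_labels(as.integer(l))[nz],
                                  format(v[nz], digits = digits)),
                          collapse = ", ")))
    }
  }
  np <- grep("^(aA|aB|D)\\.", names(x$theta), value = TRUE)
  nz <- np[abs(x$theta[np]) > 0]
  if (length(nz) > 0L) {
    cat("  nonzero polarizability/dispersion entries:", length(nz), "\n")
    show <- utils::head(nz, 8L)
    for (nm in show)
      cat(sprintf("    %s = %s\n", nm, format(x$theta[[nm]], digits = digits)))
    if (length(nz) > 8L) cat("    ...\n")
  }
  invisible(x)
}

#' Multipole components of a coefficient set
#'
#' Reconstructs the real component values \eqn{Q_t} of one molecule from
#' its symmetry-adapted coordinates (rank 0 is the pinned charge).
#'
#' @param coeffs an [lr_coefficients()] (or [lr_fit()]) object.
#' @param mol \code{"A"} or \code{"B"}.
#' @return named list rank -> numeric vector of the \code{2l + 1}
#'   components in [rank_labels()] order.
#' @export
multipole_components <- function(coeffs, mol = c("A", "B")) {
  mol <- match.arg(mol)
  if (inherits(coeffs, "lr_fit")) coeffs <- coeffs$coefficients
  lay <- coeffs$expansion
  ranks <- if (mol == "A") lay$qA_ranks else lay$qB_ranks
  basis <- if (mol == "A") lay$basisA else lay$basisB
  ch <- if (mol == "A") lay$sys$molA$charge else lay$sys$molB$charge
  out <- list("0" = ch)
  for (l in ranks) {
    B <- basis[[as.character(l)]]
    cf <- coeffs$theta[sprintf("Q%s.%d.%d", mol, l, seq_len(ncol(B)))]
    out[[as.character(l)]] <- as.numeric(B %*% cf)
  }
  out
}

## assembled polarizability block matrix {l1,l2} of one molecule (zero
## matrix if the block carries no parameters)
.alpha_block_matrix <- function(coeffs, mol, blk_key) {
  lay <- coeffs$expansion
  pat <- if (mol == "A") lay$patA[[blk_key]] else lay$patB[[blk_key]]
  blk <- if (mol == "A") lay$aA_blocks[[blk_key]] else lay$aB_blocks[[blk_key]]
  M <- matrix(0, 2L * blk[1] + 1L, 2L * blk[2] + 1L)
  for (k in seq_along(pat)) {
    M <- M + coeffs$theta[[sprintf("a%s.%s.%d", mol, blk_key, k)]] * pat[[k]]
  }
  M
}

## ---- linear tying: exchange constraints and fixed coefficients ----------

## theta_full = Tmat %*% theta_free + offset
.tie_map <- function(expansion, fixed = NULL) {
  nms <- expansion$names
  n <- length(nms)
  Tm <- diag(n); rownames(Tm) <- nms
  offset <- stats::setNames(numeric(n), nms)
  drop <- logical(n)

  if (expansion$sys$relation != "distinct") {
    lmax_needed <- max(c(expansion$qA_ranks, expansion$qB_ranks, 1L,
                         unlist(expansion$aA_blocks),
                         unlist(expansion$aB_blocks),
                         unlist(expansion$d_blocks)))
    ex <- exchange_constraints(expansion$sys, l_max = lmax_needed)
    ## multipoles: coords of B from coords of A through the component map
    ## (exact identity for identical molecules, so the tied blocks are
    ## bitwise equal)
    for (l in expansion$qB_ranks) {
      BA <- expansion$basisA[[as.character(l)]]
      BB <- expansion$basisB[[as.character(l)]]
      S <- if (ex$type == "identical") diag(ncol(BB))
           else t(BB) %*% ex$mult[[l + 1L]] %*% BA
      rB <- sprintf("QB.%d.%d", l, seq_len(ncol(BB)))
      rA <- sprintf("QA.%d.%d", l, seq_len(ncol(BA)))
      Tm[rB, ] <- 0
      Tm[rB, match(rA, nms)] <- S
      drop[match(rB, nms)] <- TRUE
    }
    ## polarizability blocks: map each A pattern matrix through the mirror
    for (k in names(expansion$aB_blocks)) {
      blk <- expansion$aB_blocks[[k]]
      patA <- expansion$patA[[k]]; patB <- expansion$patB[[k]]
      if (ex$type == "identical") {
        P <- diag(length(patB))
      } else {
        P <- matrix(0, length(patB), length(patA))
        for (i in seq_along(patA)) {
          img <- ex$mult[[blk[1] + 1L]] %*% patA[[i]] %*% t(ex$mult[[blk[2] + 1L]])
          for (j in seq_along(patB)) P[j, i] <- sum(img * patB[[j]])
        }
      }
      rB <- sprintf("aB.%s.%d", k, seq_along(patB))
      rA <- sprintf("aA.%s.%d", k, seq_along(patA))
      Tm[rB, ] <- 0
      Tm[rB, match(rA, nms)] <- P
      drop[match(rB, nms)] <- TRUE
    }
    ## dispersion: exchange symmetry requires the coefficient tensor to be
    ## symmetric under swapping the two molecules; for chiral partners the
    ## mirror additionally acts on the B-side pattern indices with a sign
    ## (the mirror's diagonal image on each pattern basis), giving
    ##   d^{(b,a)}_{jk} = s_A(k) s_B(j) d^{(a,b)}_{kj}
    dk <- names(expansion$d_blocks)
    for (k in dk) {
      p <- expansion$d_blocks[[k]]
      partner <- paste(.block_key(p$b), .block_key(p$a), sep = "|")
      if (!partner %in% dk || k > partner) next
      sA <- .pattern_sign(expansion$sys$molA, p$a, ex)
      sB <- .pattern_sign(expansion$sys$molB, p$b, ex)
      nk <- length(expansion$patDA[[k]]); nj <- length(expansion$patDB[[k]])
      for (kk in seq_len(nk)) for (j in seq_len(nj)) {
        tgt <- sprintf("D.%s.%d.%d", partner, j, kk)
        src <- sprintf("D.%s.%d.%d", k, kk, j)
        if (tgt == src) next
        if (k == partner && j < kk) next  # keep the upper wedge free
        Tm[tgt, ] <- 0
        Tm[tgt, match(src, nms)] <- sA[kk] * sB[j]
        drop[match(tgt, nms)] <- TRUE
      }
    }
  }

  if (!is.null(fixed) && length(fixed) > 0L) {
    fx <- .resolve_fixed(expansion, fixed)
    for (nm in names(fx)) {
      i <- match(nm, nms)
      if (is.na(i)) stop("fixed coefficient '", nm, "' not in the layout")
      if (drop[i]) stop("coefficient '", nm, "' is tied by exchange symmetry; ",
                        "fix its molecule-A partner instead")
      Tm[i, ] <- 0
      offset[i] <- fx[[nm]]
      drop[i] <- TRUE
    }
  }

  free <- !drop
  ## columns for dropped params carry no information
  Tmat <- Tm[, free, drop = FALSE]
  colnames(Tmat) <- nms[free]
  list(Tmat = Tmat, offset = offset, free_names = nms[free])
}

## diagonal sign image of the mirror on a pattern basis; identity for
## identical molecules.  Non-diagonal images (no pattern basis aligned
## with the mirror) are not supported for dispersion ties.
.pattern_sign <- function(mol, blk, ex) {
  pat <- .pattern_block(mol, blk[1], blk[2])
  if (ex$type == "identical") return(rep(1, length(pat)))
  P <- matrix(0, length(pat), length(pat))
  for (i in seq_along(pat)) {
    img <- ex$mult[[blk[1] + 1L]] %*% pat[[i]] %*% t(ex$mult[[blk[2] + 1L]])
    for (j in seq_along(pat)) P[j, i] <- sum(img * pat[[j]])
  }
  if (max(abs(P - diag(diag(P)))) > 1e-9)
    stop("chiral dispersion tie: mirror image of the pattern basis is not ",
         "diagonal for block ", .block_key(blk))
  sign(diag(P))
}

## resolve user-facing fixed-coefficient names; Stone labels are accepted
## where the invariant basis column is that single component (e.g. "QB.20"
## for a linear molecule)
.resolve_fixed <- function(expansion, fixed) {
  out <- list()
  for (nm in names(fixed)) {
    if (nm %in% expansion$names) { out[[nm]] <- fixed[[nm]]; next }
    m <- regmatches(nm, regexec("^Q([AB])\\.([0-9]+[0-9][cs]?)$", nm))[[1]]
    if (length(m) == 0L) stop("unknown coefficient name: ", nm)
    side <- m[2]; lab <- lr_label(m[3])
    basis <- if (side == "A") expansion$basisA else expansion$basisB
    B <- basis[[as.character(lab$l)]]
    if (is.null(B)) stop("rank ", lab$l, " carries no parameters here")
    idx <- .label_index(lab)
    hit <- which(abs(abs(B[idx, ]) - 1) < 1e-9)
    if (length(hit) != 1L)
      stop("component ", nm, " is not a pure basis direction; fix the ",
           "symmetry-adapted coordinate instead")
    out[[sprintf("Q%s.%d.%d", side, lab$l, hit)]] <- fixed[[nm]] * sign(B[idx, hit])
  }
  out
}
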