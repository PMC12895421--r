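## Standalone evaluator export.
##
## The fitted model is flattened to component level: a list of single-T
## terms (electrostatics, coefficient Q_t^A Q_u^B) and T-product terms
## (induction and dispersion, with the -1/2 alpha Q Q and -D weights
## already folded in).  The flattened list plus the asymptote is the
## normative machine-readable artifact; a self-contained Fortran source
## evaluating it (atomic units, no external dependencies) is templated
## from the same data.

.EXPORT_FORMAT <- "longrangefit-evaluator-1"

#' Flatten a coefficient set to component-level terms
#'
#' @param coeffs an [lr_coefficients()] (or [lr_fit()]).
#' @param drop_tol entries with absolute coefficient at or below this are
#'   dropped (default 0: keep everything nonzero).
#' @return list with \code{E_asym}, \code{singles} (data frame la, ia,
#'   lb, ib, coef, order; component indices 1-based in [rank_labels()]
#'   order) and \code{pairs} (two label quadruples and coef).
#' @export
flatten_model <- function(coeffs, drop_tol = 0) {
  if (inherits(coeffs, "lr_fit")) coeffs <- coeffs$coefficients
  ex <- coeffs$expansion
  cf <- coeffs
  qA <- multipole_components(cf, "A")
  qB <- multipole_components(cf, "B")
  singles <- list()
  for (i in which(ex$terms$interaction == "electrostatic")) {
    p <- strsplit(ex$terms$key[i], ".", fixed = TRUE)[[1]]
    la <- as.integer(p[2]); lb <- as.integer(p[3])
    C <- outer(qA[[as.character(la)]], qB[[as.character(lb)]])
    nz <- which(abs(C) > drop_tol, arr.ind = TRUE)
    for (r in seq_len(nrow(nz)))
      singles[[length(singles) + 1L]] <-
        c(la, nz[r, 1L], lb, nz[r, 2L], C[nz[r, , drop = FALSE]],
          la + lb + 1L)
  }
  ## pair terms accumulated under a canonical key
  acc <- new.env(parent = emptyenv())
  addp <- function(la1, ia1, lb1, ib1, la2, ia2, lb2, ib2, coef) {
    if (coef == 0) return()
    k1 <- sprintf("%02d%02d%02d%02d", la1, ia1, lb1, ib1)
    k2 <- sprintf("%02d%02d%02d%02d", la2, ia2, lb2, ib2)
    if (k2 < k1) { tmp <- k1; k1 <- k2; k2 <- tmp }
    key <- paste0(k1, k2)
    prev <- acc[[key]]
    acc[[key]] <- if (is.null(prev)) coef else prev + coef
  }
  ## induction, full ordered double sums (mirrors the design enumeration)
  tab <- ex$terms
  for (i in which(tab$interaction %in% c("induction_A", "induction_B"))) {
    p <- strsplit(tab$key[i], ".", fixed = TRUE)[[1]]
    side <- substr(p[1], 2, 2)
    blk <- as.integer(strsplit(p[2], "_")[[1]])
    lu <- as.integer(p[3]); lu2 <- as.integer(p[4])
    Ablk <- .alpha_block_matrix(cf, side, .block_key(blk))
    qs <- if (side == "A") qB else qA
    op <- .ordered_pairs(blk)
    mom <- if (lu == lu2) list(c(lu, lu2)) else list(c(lu, lu2), c(lu2, lu))
    for (o in op) for (m in mom) {
      M <- if (o$tp) t(Ablk) else Ablk
      q1 <- qs[[as.character(m[1])]]; q2 <- qs[[as.character(m[2])]]
      for (t1 in seq_len(nrow(M))) for (t2 in seq_len(ncol(M))) {
        if (M[t1, t2] == 0) next
        for (u1 in seq_along(q1)) for (u2 in seq_along(q2)) {
          w <- -0.5 * M[t1, t2] * q1[u1] * q2[u2]
          if (side == "A")
            addp(o$r[1], t1, m[1], u1, o$r[2], t2, m[2], u2, w)
          else
            addp(m[1], u1, o$r[1], t1, m[2], u2, o$r[2], t2, w)
        }
      }
    }
  }
  ## dispersion
  for (i in which(tab$interaction == "dispersion")) {
    p <- strsplit(tab$key[i], ".", fixed = TRUE)[[1]]
    key <- paste(p[2], p[3], sep = "|")
    blkA <- as.integer(strsplit(p[2], "_")[[1]])
    blkB <- as.integer(strsplit(p[3], "_")[[1]])
    patA <- ex$patDA[[key]]; patB <- ex$patDB[[key]]
    for (kk in seq_along(patA)) for (j in seq_along(patB)) {
      d <- cf$theta[[sprintf("D.%s.%d.%d", key, kk, j)]]
      if (d == 0) next
      for (oa in .ordered_pairs(blkA)) for (ob in .ordered_pairs(blkB)) {
        Mk <- if (oa$tp) t(patA[[kk]]) else patA[[kk]]
        Mj <- if (ob$tp) t(patB[[j]]) else patB[[j]]
        for (t1 in seq_len(nrow(Mk))) for (t2 in seq_len(ncol(Mk)))
          for (u1 in seq_len(nrow(Mj))) for (u2 in seq_len(ncol(Mj))) {
            w <- -d * Mk[t1, t2] * Mj[u1, u2]
            if (w != 0)
              addp(oa$r[1], t1, ob$r[1], u1, oa$r[2], t2, ob$r[2], u2, w)
          }
      }
    }
  }
  keys <- sort(ls(acc))
  pairs <- matrix(0, length(keys), 9L)
  for (i in seq_along(keys)) {
    k <- keys[i]
    v <- as.integer(substring(k, seq(1, 15, 2), seq(2, 16, 2)))
    pairs[i, 1:8] <- v
    pairs[i, 9L] <- acc[[k]]
  }
  if (length(keys) > 0L)
    pairs <- pairs[abs(pairs[, 9L]) > drop_tol, , drop = FALSE]
  singles_df <- if (length(singles) > 0L) {
    m <- do.call(rbind, singles)
    data.frame(la = m[, 1L], ia = m[, 2L], lb = m[, 3L], ib = m[, 4L],
               coef = m[, 5L], order = m[, 6L])
  } else data.frame(la = integer(), ia = integer(), lb = integer(),
                    ib = integer(), coef = numeric(), order = integer())
  pairs_df <- data.frame(la1 = as.integer(pairs[, 1L]), ia1 = as.integer(pairs[, 2L]),
                         lb1 = as.integer(pairs[, 3L]), ib1 = as.integer(pairs[, 4L]),
                         la2 = as.integer(pairs[, 5L]), ia2 = as.integer(pairs[, 6L]),
                         lb2 = as.integer(pairs[, 7L]), ib2 = as.integer(pairs[, 8L]),
                         coef = pairs[, 9L])
  pairs_df$order <- pairs_df$la1 + pairs_df$lb1 + pairs_df$la2 +
    pairs_df$lb2 + 2L
  list(E_asym = cf$theta[["E_asym"]], singles = singles_df,
       pairs = pairs_df)
}

#' Evaluate a flattened term list
#'
#' Direct re-evaluation of the exported component-level term list through
#' the T-tensors; matches [evaluate_energy()] on the originating
#' coefficient set to machine precision and serves as the parity check
#' for exported evaluators.
#'
#' @param flat result of [flatten_model()].
#' @param geom a [dimer_geometry()].
#' @return energy (hartree).
#' @export
evaluate_flat <- function(flat, geom) {
  Tcache <- new.env(parent = emptyenv())
  getT <- function(la, lb) {
    k <- paste0(la, "_", lb)
    v <- Tcache[[k]]
    if (is.null(v)) { v <- t_tensor_block(la, lb, geom); Tcache[[k]] <- v }
    v
  }
  e <- flat$E_asym
  s <- flat$singles
  for (i in seq_len(nrow(s)))
    e <- e + s$coef[i] * getT(s$la[i], s$lb[i])[s$ia[i], s$ib[i]]
  p <- flat$pairs
  for (i in seq_len(nrow(p)))
    e <- e + p$coef[i] * getT(p$la1[i], p$lb1[i])[p$ia1[i], p$ib1[i]] *
      getT(p$la2[i], p$lb2[i])[p$ia2[i], p$ib2[i]]
  e
}

#' Export a standalone evaluator of the fitted potential
#'
#' Writes (a) \code{<path>.json}, the machine-readable flattened term +
#' coefficient file (the normative artifact), and (b) \code{<path>.f90},
#' a self-contained Fortran module with a function
#' \code{lr_energy(R, alpha, beta_a, beta_b, gamma_a, gamma_b)} returning
#' the energy in hartree for coordinates in bohr and radians (unused
#' angles are simply passed as 0).  The source has no external
#' dependencies and can be dropped into scattering or dynamics codes.
#'
#' @param coeffs an [lr_coefficients()] (or [lr_fit()]).
#' @param path output path prefix (no extension).
#' @return named character vector of the two file paths, invisibly.
#' @export
export_evaluator <- function(coeffs, path) {
  if (inherits(coeffs, "lr_fit")) coeffs <- coeffs$coefficients
  flat <- flatten_model(coeffs)
  jp <- paste0(path, ".json")
  fp <- paste0(path, ".f90")
  molrec <- function(m) {
    rec <- list(name = m$name, point_group = m$point_group,
                charge = m$charge)
    if (!is.na(m$n)) rec$n <- m$n
    rec
  }
  jsonlite::write_json(list(
    format = .EXPORT_FORMAT,
    units = list(energy = "hartree", distance = "bohr", angle = "rad"),
    system = list(molA = molrec(coeffs$expansion$sys$molA),
                  molB = molrec(coeffs$expansion$sys$molB),
                  relation = coeffs$expansion$sys$relation),
    E_asym = flat$E_asym, singles = flat$singles, pairs = flat$pairs),
    jp, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  writeLines(.fortran_source(flat), fp)
  invisible(c(terms = jp, source = fp))
}

## ---- Fortran templating -------------------------------------------------

.fnum <- function(x) paste0(sprintf("%.17e", x), "_dp")

.fortran_source <- function(flat) {
  s <- flat$singles; p <- flat$pairs
  lma <- max(0L, s$la, p$la1, p$la2)
  lmb <- max(0L, s$lb, p$lb1, p$lb2)
  ## rank pairs used and their X0 matrices
  pu <- unique(rbind(cbind(s$la, s$lb), cbind(p$la1, p$lb1),
                     cbind(p$la2, p$lb2)))
  x0_lines <- character()
  for (r in seq_len(nrow(pu))) {
    la <- pu[r, 1L]; lb <- pu[r, 2L]
    X <- .x0_real(la, lb)
    x0_lines <- c(x0_lines,
                  sprintf("    pair_used(%d, %d) = .true.", la, lb))
    nz <- which(X != 0, arr.ind = TRUE)
    for (k in seq_len(nrow(nz)))
      x0_lines <- c(x0_lines,
        sprintf("    x0(%d, %d, %d, %d) = %s", la, lb, nz[k, 1L], nz[k, 2L],
                .fnum(X[nz[k, , drop = FALSE]])))
  }
  s_lines <- character()
  for (i in seq_len(nrow(s)))
    s_lines <- c(s_lines,
      sprintf("    sdat(:, %d) = (/ %d, %d, %d, %d /)", i,
              s$la[i], s$ia[i], s$lb[i], s$ib[i]),
      sprintf("    scof(%d) = %s", i, .fnum(s$coef[i])))
  p_lines <- character()
  for (i in seq_len(nrow(p)))
    p_lines <- c(p_lines,
      sprintf("    pdat(:, %d) = (/ %d, %d, %d, %d, %d, %d, %d, %d /)", i,
              p$la1[i], p$ia1[i], p$lb1[i], p$ib1[i],
              p$la2[i], p$ia2[i], p$lb2[i], p$ib2[i]),
      sprintf("    pcof(%d) = %s", i, .fnum(p$coef[i])))

  c(sprintf("! Long-range interaction energy evaluator (generated)."),
    sprintf("! Coordinates: R in bohr, angles in radians; energy in hartree."),
    sprintf("! Unused angles of lower-dimensional systems are passed as 0."),
    "module lr_potential",
    "  implicit none",
    "  private",
    "  public :: lr_energy",
    "  integer, parameter :: dp = kind(1.0d0)",
    sprintf("  real(dp), parameter :: easym = %s", .fnum(flat$E_asym)),
    sprintf("  integer, parameter :: lma = %d, lmb = %d", lma, lmb),
    sprintf("  integer, parameter :: ns = %d, npr = %d", nrow(s), nrow(p)),
    "  integer :: sdat(4, max(ns, 1)), pdat(8, max(npr, 1))",
    "  real(dp) :: scof(max(ns, 1)), pcof(max(npr, 1))",
    "  real(dp) :: x0(0:lma, 0:lmb, 2*lma+1, 2*lmb+1)",
    "  logical :: pair_used(0:lma, 0:lmb)",
    "  logical :: init_done = .false.",
    "contains",
    "",
    "  function lr_energy(r, alpha, beta_a, beta_b, gamma_a, gamma_b) result(e)",
    "    real(dp), intent(in) :: r, alpha, beta_a, beta_b, gamma_a, gamma_b",
    "    real(dp) :: e",
    "    real(dp) :: wa(2*lma+1, 2*lma+1, 0:lma)",
    "    real(dp) :: wb(2*lmb+1, 2*lmb+1, 0:lmb)",
    "    real(dp) :: tb(2*lma+1, 2*lmb+1, 0:lma, 0:lmb)",
    "    integer :: l, la, lb, i",
    "    if (.not. init_done) call init()",
    "    do l = 0, lma",
    "      call realrot(l, alpha, beta_a, gamma_a, wa(1:2*l+1, 1:2*l+1, l))",
    "    end do",
    "    do l = 0, lmb",
    "      call realrot(l, 0.0_dp, beta_b, gamma_b, wb(1:2*l+1, 1:2*l+1, l))",
    "    end do",
    "    do la = 0, lma",
    "      do lb = 0, lmb",
    "        if (pair_used(la, lb)) then",
    "          tb(1:2*la+1, 1:2*lb+1, la, lb) = matmul( &",
    "            transpose(wa(1:2*la+1, 1:2*la+1, la)), &",
    "            matmul(x0(la, lb, 1:2*la+1, 1:2*lb+1), &",
    "                   wb(1:2*lb+1, 1:2*lb+1, lb))) / r**(la+lb+1)",
    "        end if",
    "      end do",
    "    end do",
    "    e = easym",
    "    do i = 1, ns",
    "      e = e + scof(i) * tb(sdat(2,i), sdat(4,i), sdat(1,i), sdat(3,i))",
    "    end do",
    "    do i = 1, npr",
    "      e = e + pcof(i) * tb(pdat(2,i), pdat(4,i), pdat(1,i), pdat(3,i)) &",
    "                      * tb(pdat(6,i), pdat(8,i), pdat(5,i), pdat(7,i))",
    "    end do",
    "  end function lr_energy",
    "",
    "  subroutine realrot(l, a, b, g, w)",
    "    integer, intent(in) :: l",
    "    real(dp), intent(in) :: a, b, g",
    "    real(dp), intent(out) :: w(2*l+1, 2*l+1)",
    "    complex(dp) :: dm(2*l+1, 2*l+1), u(2*l+1, 2*l+1)",
    "    real(dp) :: dl(2*l+1, 2*l+1)",
    "    complex(dp), parameter :: ii = (0.0_dp, 1.0_dp)",
    "    real(dp), parameter :: rh = 0.70710678118654752_dp",
    "    integer :: mp, m",
    "    call smalld(l, b, dl)",
    "    do mp = -l, l",
    "      do m = -l, l",
    "        dm(mp+l+1, m+l+1) = exp(-ii*mp*a) * dl(mp+l+1, m+l+1) * exp(-ii*m*g)",
    "      end do",
    "    end do",
    "    u = (0.0_dp, 0.0_dp)",
    "    u(1, l+1) = (1.0_dp, 0.0_dp)",
    "    do m = 1, l",
    "      u(2*m, l+1+m) = (-1)**m * rh",
    "      u(2*m, l+1-m) = rh",
    "      u(2*m+1, l+1+m) = -ii * (-1)**m * rh",
    "      u(2*m+1, l+1-m) = ii * rh",
    "    end do",
    "    w = real(matmul(u, matmul(conjg(dm), conjg(transpose(u)))), dp)",
    "  end subroutine realrot",
    "",
    "  subroutine smalld(l, beta, d)",
    "    integer, intent(in) :: l",
    "    real(dp), intent(in) :: beta",
    "    real(dp), intent(out) :: d(2*l+1, 2*l+1)",
    "    integer :: mp, m, s, smin, smax",
    "    real(dp) :: cb, sb, acc, lnum, lden",
    "    cb = cos(beta / 2); sb = sin(beta / 2)",
    "    do mp = -l, l",
    "      do m = -l, l",
    "        smin = max(0, m - mp)",
    "        smax = min(l + m, l - mp)",
    "        acc = 0.0_dp",
    "        do s = smin, smax",
    "          lnum = 0.5_dp * (lf(l+mp) + lf(l-mp) + lf(l+m) + lf(l-m))",
    "          lden = lf(l+m-s) + lf(s) + lf(mp-m+s) + lf(l-mp-s)",
    "          acc = acc + (-1)**(mp-m+s) * exp(lnum - lden) &",
    "                * cb**(2*l+m-mp-2*s) * sb**(mp-m+2*s)",
    "        end do",
    "        d(mp+l+1, m+l+1) = acc",
    "      end do",
    "    end do",
    "  end subroutine smalld",
    "",
    "  function lf(n) result(v)",
    "    integer, intent(in) :: n",
    "    real(dp) :: v",
    "    v = log_gamma(real(n, dp) + 1.0_dp)",
    "  end function lf",
    "",
    "  subroutine init()",
    "    x0 = 0.0_dp",
    "    pair_used = .false.",
    x0_lines,
    s_lines,
    p_lines,
    "    init_done = .true.",
    "  end subroutine init",
    "",
    "end module lr_potential")
}
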