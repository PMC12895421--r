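#' Wigner 3-j symbol
#'
#' Evaluates the Wigner 3-j symbol
#' \eqn{\begin{pmatrix} j_1 & j_2 & j_3 \\ m_1 & m_2 & m_3 \end{pmatrix}}
#' by the Racah sum formula with log-factorials.  Returns 0 when the
#' selection rules (\eqn{m_1+m_2+m_3 = 0}, triangle inequality) are not
#' met.  Integer angular momenta only; exact enough (about 1e-14 relative)
#' for the rank range used here (j up to 30).
#'
#' @param j1,j2,j3 non-negative integer angular momenta.
#' @param m1,m2,m3 integer projections, \code{abs(m) <= j}.
#' @return the 3-j value as a double.
#' @examples
#' wigner3j(1, 1, 2, 0, 0, 0)   # sqrt(2/15)
#' wigner3j(1, 1, 1, 0, 0, 0)   # 0 (odd sum with all m = 0)
#' @export
wigner3j <- function(j1, j2, j3, m1, m2, m3) {
  if (j1 < 0 || j2 < 0 || j3 < 0) stop("negative angular momentum")
  if (abs(m1) > j1 || abs(m2) > j2 || abs(m3) > j3)
    stop("projection exceeds its angular momentum")
  if (m1 + m2 + m3 != 0) return(0)
  if (j3 < abs(j1 - j2) || j3 > j1 + j2) return(0)
  ## Racah formula
  lf <- lgamma  # lgamma(n + 1) = log(n!)
  delta <- 0.5 * (lf(j1 + j2 - j3 + 1) + lf(j1 - j2 + j3 + 1) +
                  lf(-j1 + j2 + j3 + 1) - lf(j1 + j2 + j3 + 2))
  pref <- 0.5 * (lf(j1 + m1 + 1) + lf(j1 - m1 + 1) +
                 lf(j2 + m2 + 1) + lf(j2 - m2 + 1) +
                 lf(j3 + m3 + 1) + lf(j3 - m3 + 1))
  kmin <- max(0, j2 - j3 - m1, j1 - j3 + m2)
  kmax <- min(j1 + j2 - j3, j1 - m1, j2 + m2)
  if (kmax < kmin) return(0)
  s <- 0
  for (k in kmin:kmax) {
    lterm <- lf(k + 1) + lf(j1 + j2 - j3 - k + 1) + lf(j1 - m1 - k + 1) +
      lf(j2 + m2 - k + 1) + lf(j3 - j2 + m1 + k + 1) + lf(j3 - j1 - m2 + k + 1)
    s <- s + (-1)^k * exp(delta + pref - lterm)
  }
  (-1)^(j1 - j2 - m3) * s
}
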