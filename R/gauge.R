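#' Align the multiplicative gauge of a fitted coefficient set
#'
#' For two distinct neutral molecules only the products of A- and B-side
#' multipoles are determined by the data: rescaling all of A's multipoles
#' by \eqn{s} and all of B's by \eqn{1/s} (with \eqn{\alpha^A \to s^2
#' \alpha^A}, \eqn{\alpha^B \to \alpha^B / s^2}) leaves every model energy
#' unchanged.  This helper picks the \eqn{s} that best matches a
#' reference set (least squares on the A-side multipole coordinates,
#' sign included), so coefficient sets can be compared one-to-one.
#' Charged or constrained systems are already anchored and return
#' unchanged (\eqn{s = 1}).
#'
#' @param coeffs an [lr_coefficients()] (or [lr_fit()]).
#' @param reference the [lr_coefficients()] to align to (same expansion
#'   layout).
#' @return an [lr_coefficients()] in the reference gauge, with the factor
#'   in attribute \code{"gauge_s"}.
#' @export
gauge_align <- function(coeffs, reference) {
  if (inherits(coeffs, "lr_fit")) coeffs <- coeffs$coefficients
  stopifnot(inherits(coeffs, "lr_coefficients"),
            inherits(reference, "lr_coefficients"))
  th <- coeffs$theta; tr <- reference$theta
  stopifnot(identical(names(th), names(tr)))
  qa <- grep("^QA\\.", names(th))
  s <- 1
  anchored <- coeffs$expansion$sys$molA$charge != 0 ||
    coeffs$expansion$sys$molB$charge != 0 ||
    coeffs$expansion$sys$relation != "distinct"
  if (!anchored && length(qa) > 0L && sum(th[qa]^2) > 0) {
    s <- sum(th[qa] * tr[qa]) / sum(th[qa]^2)
    if (s == 0) s <- 1
  }
  th[qa] <- th[qa] * s
  qb <- grep("^QB\\.", names(th)); th[qb] <- th[qb] / s
  aa <- grep("^aA\\.", names(th)); th[aa] <- th[aa] * s^2
  ab <- grep("^aB\\.", names(th)); th[ab] <- th[ab] / s^2
  out <- lr_coefficients(coeffs$expansion, as.numeric(th))
  attr(out, "gauge_s") <- s
  out
}
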