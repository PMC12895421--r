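#' Stone angular-momentum component labels
#'
#' A real spherical multipole component is indexed by a Stone label
#' \code{t = lm} or \code{t = lmc} / \code{lms}: rank \code{l}, projection
#' \code{m} and, for \code{m >= 1}, a \code{c} (cosine) or \code{s} (sine)
#' phase selecting the two real combinations of the \eqn{\pm m} complex
#' components.  Labels are handled as plain strings ("00", "10", "11c",
#' "21s", ...).  Within one rank the components are ordered
#' \code{l0, l1c, l1s, l2c, l2s, ..., llc, lls}, giving \code{2l + 1}
#' components at rank \code{l}.
#'
#' @param label a label string such as \code{"21c"}.
#' @return \code{lr_label()} returns a list with integer fields \code{l},
#'   \code{m} and character \code{phase} (\code{""} for \code{m = 0}).
#' @examples
#' lr_label("21c")
#' rank_labels(2)
#' @export
lr_label <- function(label) {
  stopifnot(is.character(label), length(label) == 1L)
  m0 <- regmatches(label, regexec("^([0-9]{1,2})([0-9])([cs]?)$", label))[[1]]
  if (length(m0) == 0L)
    stop("malformed component label: '", label, "'")
  ## two-digit ranks ("100" = l=10, m=0) need a second pass: try the longest
  ## rank match that leaves a valid m <= l
  cand <- regmatches(label, regexec("^([0-9]+?)([0-9])([cs]?)$", label))[[1]]
  l <- as.integer(cand[2]); m <- as.integer(cand[3]); phase <- cand[4]
  if (m > l) { # e.g. "111c": l=11 impossible split, retry greedy
    cand <- regmatches(label, regexec("^([0-9]+)([0-9])([cs]?)$", label))[[1]]
    l <- as.integer(cand[2]); m <- as.integer(cand[3]); phase <- cand[4]
  }
  if (is.na(l) || is.na(m) || m > l)
    stop("malformed component label: '", label, "'")
  if (m == 0L && nzchar(phase))
    stop("label '", label, "': m = 0 components carry no c/s phase")
  if (m > 0L && !nzchar(phase))
    stop("label '", label, "': m >= 1 components need a c or s phase")
  if (l > 15L) stop("ranks above 15 are not supported")
  list(l = l, m = m, phase = phase)
}

#' @rdname lr_label
#' @param l integer rank (0..15).
#' @export
rank_labels <- function(l) {
  stopifnot(l >= 0L, l <= 15L)
  out <- as.character(l * 10L)
  if (l == 0L) return("00")
  out <- paste0(l, "0")
  for (m in seq_len(l)) out <- c(out, paste0(l, m, "c"), paste0(l, m, "s"))
  out
}

## position of a component inside its rank block (1-based):
## m = 0 -> 1, (m, c) -> 2m, (m, s) -> 2m + 1
.label_index <- function(lab) {
  if (lab$m == 0L) 1L else if (lab$phase == "c") 2L * lab$m else 2L * lab$m + 1L
}

## index -> (m, phase) within a rank
.index_m_phase <- function(i) {
  if (i == 1L) list(m = 0L, phase = "")
  else if (i %% 2L == 0L) list(m = i %/% 2L, phase = "c")
  else list(m = i %/% 2L, phase = "s")
}
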