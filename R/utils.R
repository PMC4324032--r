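#' Signed distance on a circular chromosome
#'
#' Shortest signed displacement from `from` to `to` on a circle of length
#' `len`, mapped into `(-len/2, len/2]`.  Positive values mean `to` lies
#' clockwise (increasing coordinate) of `from`.
#'
#' @param from,to 1-based positions (vectors recycle).
#' @param len chromosome length in bp.
#' @return Numeric vector of signed distances.
#' @export
circ_signed_dist <- function(from, to, len) {
  d <- (to - from) %% len
  ifelse(d > len / 2, d - len, d)
}

#' Absolute circular distance
#'
#' @inheritParams circ_signed_dist
#' @return Numeric vector of non-negative distances (at most `len/2`).
#' @export
circ_dist <- function(from, to, len) {
  abs(circ_signed_dist(from, to, len))
}

# Wrap a 1-based coordinate onto [1, len].
wrap_pos <- function(pos, len) {
  ((pos - 1) %% len) + 1
}

# Evaluate a polynomial given coefficients in increasing power order.
eval_poly <- function(coeffs, x) {
  out <- rep(0, length(x))
  for (k in seq_along(coeffs)) out <- out + coeffs[k] * x^(k - 1)
  out
}

# Reverse complement of a plain character DNA string (keeps N).
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
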