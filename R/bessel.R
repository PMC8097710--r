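#' Modified Bessel function of the first kind, integer order
#'
#' `I_nu(z)` for non-negative integer order and non-negative real argument.
#' These values are the sideband amplitudes of the exponential-modulation
#' expansion: the base tone carries `I_0(M')` and the k-th sideband pair
#' carries `I_k(M')`. Evaluation delegates to [base::besselI()]; the power
#' series `(z/2)^nu * sum_k z^(2k) / (2^(2k) k! (nu+k)!)` is kept in the test
#' suite as an independent oracle.
#'
#' @param order Non-negative integer order `nu` (vectorized).
#' @param argument Non-negative real argument `z` (vectorized).
#' @return `I_order(argument)`, recycled to the common length.
#' @examples
#' modified_bessel_i(0, 0)            # 1
#' modified_bessel_i(5, 4.0)          # ~0.50472
#' @export
modified_bessel_i <- function(order, argument) {
  if (!is.numeric(order) || any(is.na(order)) ||
      any(order < 0) || any(order != floor(order)))
    stop_domain("'order' must be non-negative integer(s)")
  if (!is.numeric(argument) || any(is.na(argument)) || any(argument < 0))
    stop_domain("'argument' must be non-negative real(s)")
  n <- max(length(order), length(argument))
  order <- rep_len(order, n)
  argument <- rep_len(argument, n)
  vapply(seq_len(n), function(i) besselI(argument[i], order[i]), numeric(1))
}
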