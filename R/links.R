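#' Complementary log-log link utilities
#'
#' The cloglog link \eqn{g(u) = \log(-\log(1-u))} maps (0,1) onto the real
#' line; its inverse is \eqn{h(u) = 1 - \exp(-\exp(u))} with derivative
#' \eqn{h'(u) = e^u (1 - h(u))}.  These are the transforms used throughout
#' the package for CIF regression.
#'
#' @param u numeric vector; for `cloglog` values in (0,1), otherwise real.
#' @return numeric vector of the same length.
#' @examples
#' cloglog_inv(cloglog(0.3))  # 0.3
#' @export
cloglog <- function(u) log(-log(1 - u))

#' @rdname cloglog
#' @export
cloglog_inv <- function(u) 1 - exp(-exp(u))

#' @rdname cloglog
#' @export
cloglog_inv_deriv <- function(u) exp(u) * exp(-exp(u))
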