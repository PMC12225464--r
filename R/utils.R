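#' @importFrom rlang %||% abort warn .data
#' @importFrom stats plogis qlogis qnorm pnorm runif rbinom var quantile sd cor
#' @importFrom utils head
NULL

# inverse-logit / logit under their conventional names
inv_logit <- function(x) plogis(x)
logit <- function(p) qlogis(p)

#' Pipe operator
#'
#' Re-export of the magrittr-style pipe from dplyr.
#'
#' @name %>%
#' @rdname pipe
#' @keywords internal
#' @export
#' @importFrom dplyr %>%
#' @usage lhs \%>\% rhs
NULL

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  invisible(x)
}

# stable log(1 - exp(x)) for x <= 0, used for log(1 - v*p) given log(v*p)
log1m_exp <- function(x) {
  ifelse(x > -log(2), log(-expm1(x)), log1p(-exp(x)))
}
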