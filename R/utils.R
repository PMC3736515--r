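#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round half away from zero
#'
#' Reported percentages and kappa values are rounded half-up (0.45 -> 0.5),
#' matching how the published tables round. Applied only at output time,
#' never inside a computation.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

abort_npm <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "npmagree_error")))
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)
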