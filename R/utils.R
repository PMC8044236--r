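`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; printed tables here use the
#' conventional half-up rule.
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# 0/1 integer check used by label and decision validators
is_binary <- function(x) {
  is.numeric(x) && !anyNA(x) && all(x %in% c(0, 1))
}

stop_mutafuse <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "mutafuse_error")))
}

utils::globalVariables(c("fpr", "tpr", "model", "importance", "feature"))
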