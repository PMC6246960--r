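#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Fixed-point rounding with ties going up (0.125 -> 0.13 at 2 digits),
#' matching how contingency-table percentages are conventionally printed.
#' Base R's `round()` rounds half to even, which would print 9/28 as 32.14
#' either way but disagrees on exact .xx5 ties.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half-up to `digits` places.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("ctdna_config_error", "error")))
}

stop_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("ctdna_input_error", "error")))
}

check_proportion_map <- function(p, what) {
  if (length(p) == 0 || is.null(names(p)) || any(!nzchar(names(p))))
    stop_config(what, " must be a named numeric vector of proportions")
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop_config(what, " proportions must be non-negative and sum to 1 (got sum ",
                format(sum(p), digits = 12), ")")
  invisible(p)
}

## Draws categories for n samples from a named proportion map.
draw_categories <- function(n, p) {
  if (n == 0) return(character(0))
  sample(names(p), n, replace = TRUE, prob = p)
}

## Log-uniform draw on [lo, hi], lo > 0.
rlogunif <- function(n, lo, hi) {
  exp(stats::runif(n, log(lo), log(hi)))
}

empty_df <- function(proto) {
  proto[0, , drop = FALSE]
}
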