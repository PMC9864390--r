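#' @importFrom rlang %||% abort .data
#' @importFrom stats predict quantile rbinom rnorm rpois runif setNames
#' @importFrom utils head tail
NULL

# Round half away from zero (printed tables use conventional half-up rounding,
# not the IEEE banker's rounding of base round()).
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  trunc(abs(x) * m + 0.5) / m * sign(x)
}

# TRUE for each code that starts with at least one of the prefixes.
# "I25.1" matches prefix "I25"; "E78.0" matches "E78.0" but not "E78.1".
matches_prefix <- function(codes, prefixes) {
  if (length(prefixes) == 0L) return(rep(FALSE, length(codes)))
  out <- rep(FALSE, length(codes))
  for (p in prefixes) out <- out | startsWith(codes, p)
  out
}

as_iso_date <- function(x) {
  if (inherits(x, "Date")) return(x)
  as.Date(x, format = "%Y-%m-%d")
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) abort(msg)
  invisible(TRUE)
}
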