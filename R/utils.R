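# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
log_sum_exp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' @noRd
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

#' Two-sided normal p-value from an estimate and its standard error.
#' @noRd
z_pvalue <- function(beta, se) {
  2 * stats::pnorm(-abs(beta / se))
}

#' Normal-theory 95% confidence limits.
#' @noRd
ci95 <- function(beta, se) {
  z <- stats::qnorm(0.975)
  c(beta - z * se, beta + z * se)
}

# Messages routed through one gate so pipeline runs can silence them.
mrt_message <- function(..., quiet = getOption("mrtriad.quiet", FALSE)) {
  if (!isTRUE(quiet)) message(...)
  invisible(NULL)
}
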