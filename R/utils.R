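# shared helpers: rounding and p-value formatting conventions used in reports

#' Round half away from zero
#'
#' Commercial ("round half up") rounding, as used for all reported
#' percentages; base [round()] rounds half to even, which would print
#' 76.45 as 76.4.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Format a p-value for reporting
#'
#' p-values that would print as "0.000" at three decimals are rendered
#' as "< 0.0005" so a small probability is never displayed as zero.
#'
#' @param p numeric p-value in \[0, 1\].
#' @return character scalar.
#' @export
format_pvalue <- function(p) {
  stopifnot(is.numeric(p), length(p) == 1L, p >= 0, p <= 1)
  if (p < 5e-4) "< 0.0005" else sprintf("%.3f", p)
}

# internal: stop with a formatted message
.fail <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# longest run of TRUE in a logical vector
.longest_run <- function(flags) {
  if (!any(flags)) return(0L)
  r <- rle(flags)
  max(r$lengths[r$values])
}
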