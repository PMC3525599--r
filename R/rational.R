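# Exact rational handling for the density threshold gamma (and the degree
# fraction lambda).  Thresholds are parsed from decimal strings into
# integer fractions so that all feasibility comparisons reduce to integer
# comparisons; a floating-point threshold would misclassify boundary cases
# such as ceiling(0.85 * 10) evaluated as ceiling(8.5000000000000018).

gcd2 <- function(a, b) {
  while (b > 0) { t <- a %% b; a <- b; b <- t }
  a
}

#' Exact rational threshold
#'
#' Parses a decimal number (given as a string such as `"0.85"`, or as a
#' numeric scalar, which is first formatted back to its shortest decimal
#' representation) into an exact integer fraction.  Used internally for
#' the edge-density threshold gamma and the degree fraction lambda so
#' that quasi-clique membership is decided by integer arithmetic.
#'
#' @param x a scalar numeric or a decimal string, e.g. `"0.85"`.
#' @return an object of class `qc_rational` with fields `num`, `den`
#'   and `value` (`num/den` as numeric).
#' @examples
#' qc_rational("0.85")
#' @export
qc_rational <- function(x) {
  if (inherits(x, "qc_rational")) return(x)
  if (is.numeric(x)) {
    stopifnot(length(x) == 1L, is.finite(x))
    x <- format(x, digits = 15, scientific = FALSE, trim = TRUE)
  }
  stopifnot(is.character(x), length(x) == 1L)
  if (!grepl("^[0-9]*\\.?[0-9]+$", x))
    stop("not a plain decimal number: '", x, "'")
  parts <- strsplit(x, ".", fixed = TRUE)[[1]]
  frac <- if (length(parts) == 2L) parts[2] else ""
  if (nchar(frac) > 12)
    stop("decimal '", x, "' has too many digits for exact arithmetic")
  den <- 10^nchar(frac)
  num <- as.numeric(paste0(parts[1], frac))
  g <- gcd2(num, den)
  structure(list(num = num / g, den = den / g, value = num / den),
            class = "qc_rational")
}

#' @export
print.qc_rational <- function(x, ...) {
  cat(sprintf("<qc_rational> %g/%g = %g\n", x$num, x$den, x$value))
  invisible(x)
}

# ceiling(r * m) for a qc_rational r and a nonnegative integer m, exactly
ceil_times <- function(r, m) {
  tot <- r$num * m
  q <- tot %/% r$den
  q + ((tot %% r$den) > 0)
}
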