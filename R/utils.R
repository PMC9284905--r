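# Shared numeric helpers.

#' Round half away from zero
#'
#' Rounding used for the gram quantization of DXA mass queries and for the
#' integer-percent presentation of diagnostic metrics. Unlike [base::round()],
#' which rounds half to even, halves are carried away from zero (2.5 -> 3,
#' -2.5 -> -3), matching how scanner output and clinical tables are printed.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Numeric vector, rounded.
#' @examples
#' round_half_away(c(2.5, -2.5, 69.51))
#' @export
round_half_away <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

# quantize a mass in grams the way the scanner reports it
quantize_grams <- function(x) round_half_away(x)

# fraction -> rounded integer percent (presentation scale used in reports)
as_percent <- function(x) round_half_away(100 * x)

# area of an ellipse slab between vertical lines x1, x2 (centre at 0,
# semi-axes a horizontal, b vertical); closed form via the circle antiderivative
ellipse_slab_area <- function(a, b, x1, x2) {
  if (a <= 0 || b <= 0) {
    return(rep(0, length(x1)))
  }
  f <- function(u) {
    u <- pmax(-1, pmin(1, u))
    (u * sqrt(pmax(0, 1 - u^2)) + asin(u)) / 2
  }
  2 * a * b * (f(x2 / a) - f(x1 / a))
}

stop_domain <- function(msg, class) {
  abort(msg, class = c(class, "vatmets_error"))
}

check_positive <- function(x, name) {
  if (any(!is.finite(x) | x <= 0)) {
    stop_domain(paste0("`", name, "` must be positive and finite."),
                "vatmets_domain_error")
  }
  invisible(x)
}
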