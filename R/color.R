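# sRGB (IEC 61966-2-1, D65) -> CIELab, vectorized over pixels.
# Authored here so per-frame region conversions stay cheap; agreement with
# grDevices::convertColor is asserted in the test suite.

.srgb_m <- matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041
), nrow = 3, byrow = TRUE)

.d65_white <- c(X = 0.95047, Y = 1.00000, Z = 1.08883)

#' Convert sRGB pixels to CIELab
#'
#' Converts 8-bit sRGB values (D65 white point) to CIE L*a*b*.  The a*
#' component is the green(-)/red(+) opponent axis used as the respiration
#' signal substrate.
#'
#' @param rgb numeric matrix with 3 columns (R, G, B) on the 0--255 scale,
#'   or a length-3 vector for a single pixel.
#' @return matrix with columns `L`, `a`, `b`.
#' @examples
#' srgb_to_lab(c(128, 128, 128))  # neutral gray: a* = b* = 0
#' @export
srgb_to_lab <- function(rgb) {
  if (is.null(dim(rgb))) rgb <- matrix(rgb, ncol = 3L, byrow = TRUE)
  if (ncol(rgb) != 3L) stop("`rgb` must have 3 columns", call. = FALSE)
  v <- rgb / 255
  # inverse companding (piecewise gamma)
  lin <- ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
  xyz <- lin %*% t(.srgb_m)
  tt <- sweep(xyz, 2L, .d65_white, "/")
  eps <- (6 / 29)^3
  f <- ifelse(tt > eps, tt^(1 / 3), tt / (3 * (6 / 29)^2) + 4 / 29)
  out <- cbind(
    L = 116 * f[, 2L] - 16,
    a = 500 * (f[, 1L] - f[, 2L]),
    b = 200 * (f[, 2L] - f[, 3L])
  )
  out
}
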