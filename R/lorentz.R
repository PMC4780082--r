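# Area-parameterized Lorentzian line shape and band-model evaluation.

#' Lorentzian band profile (area parameterization)
#'
#' \deqn{y(x) = \frac{2A}{\pi}\,\frac{w}{4(x-x_c)^2 + w^2}}
#'
#' with center \eqn{x_c}, signed area \eqn{A} (the integral over the real
#' line) and full width at half maximum \eqn{w}. The peak value is
#' \eqn{2A/(\pi w)} at \eqn{x = x_c}. The area form keeps a unity
#' positive/negative area-ratio constraint between paired bands well defined.
#'
#' @param x wavenumber(s), cm^-1.
#' @param xc band center, cm^-1.
#' @param A signed band area, absorbance * cm^-1.
#' @param w FWHM, cm^-1 (> 0).
#' @return numeric absorbance values, same length as \code{x}.
#' @export
#' @examples
#' lorentzian(1700, xc = 1700, A = pi / 2, w = 1)  # peak value 1
lorentzian <- function(x, xc, A, w) {
  if (w <= 0) stop("FWHM must be positive")
  (2 * A / pi) * w / (4 * (x - xc)^2 + w^2)
}

#' Evaluate a sum-of-Lorentzians band model on a grid
#'
#' @param bands data frame with columns \code{xc}, \code{A}, \code{w} (one row
#'   per band), or a list of such rows.
#' @param grid wavenumber axis, cm^-1.
#' @return an [ir_spectrum] with the summed model trace.
#' @export
model_eval <- function(bands, grid) {
  bands <- .as_band_frame(bands)
  if (!nrow(bands)) stop("empty band list")
  y <- rep(0, length(grid))
  for (i in seq_len(nrow(bands))) {
    y <- y + lorentzian(grid, bands$xc[i], bands$A[i], bands$w[i])
  }
  ir_spectrum(grid, y)
}

.as_band_frame <- function(bands) {
  if (is.data.frame(bands)) {
    stopifnot(all(c("xc", "A", "w") %in% names(bands)))
    return(bands)
  }
  if (is.list(bands)) {
    return(do.call(rbind, lapply(bands, function(b)
      data.frame(xc = b$xc, A = b$A, w = b$w))))
  }
  stop("bands must be a data frame or list with xc, A, w")
}

# Partial derivatives of the Lorentzian wrt its three parameters.
.lor_grad <- function(x, xc, A, w) {
  dx <- x - xc
  D <- 4 * dx^2 + w^2
  list(
    dA  = (2 / pi) * w / D,
    dxc = (2 * A / pi) * w * 8 * dx / D^2,
    dw  = (2 * A / pi) * (4 * dx^2 - w^2) / D^2
  )
}
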