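# Scaling of difference spectra, double differences, band integrals.
#
# Scientific context: light-minus-dark FTIR difference spectra of an
# unlabelled and a 15N-labelled protein sample differ in overall amplitude
# (path length, concentration). The unlabelled trace is therefore scaled onto
# the labelled one by least squares over a spectral window that labelling
# leaves untouched, and the double difference s*unlabelled - labelled then
# isolates the bands that move on labelling.

# Put two spectra on the common grid: intersection span, grid of `ref`.
.common_grid <- function(a, ref) {
  lo <- max(min(a$axis), min(ref$axis))
  hi <- min(max(a$axis), max(ref$axis))
  if (hi <= lo) stop("spectra do not overlap")
  grid <- ref$axis[ref$axis >= lo & ref$axis <= hi]
  if (length(grid) < 2L) stop("overlap of spectra contains fewer than 2 grid points")
  grid
}

#' Least-squares amplitude scale between two spectra
#'
#' The multiplicative factor \code{s} minimizing \code{sum((s*a - b)^2)} over
#' the window \code{w}, i.e. \code{s = sum(a*b)/sum(a^2)} on the common grid
#' (grid of \code{b} restricted to the overlap). No additive offset is fitted:
#' difference spectra are already baseline-referenced and an offset would
#' absorb genuine broad signals.
#'
#' @param a spectrum to be scaled (e.g. the unlabelled difference spectrum).
#' @param b reference spectrum (e.g. the labelled difference spectrum).
#' @param w scaling window, typically 1500-1200 cm^-1 where isotope labelling
#'   has no effect.
#' @return scalar scale factor.
#' @export
scale_factor <- function(a, b, w) {
  stopifnot(inherits(a, "ir_spectrum"), inherits(b, "ir_spectrum"))
  w <- as_window(w)
  grid <- .common_grid(a, b)
  grid <- grid[grid >= w$lo & grid <= w$hi]
  if (length(grid) < 2L) stop("scaling window not covered by both spectra")
  av <- resample(a, grid)$values
  bv <- resample(b, grid)$values
  den <- sum(av * av)
  if (den == 0) stop("degenerate reference: sum(a^2) = 0 on the scaling window")
  sum(av * bv) / den
}

#' Double-difference spectrum between isotopomers
#'
#' Scales the unlabelled difference spectrum onto the labelled one over
#' \code{scaling_window} (see [scale_factor()]) and returns
#' \code{s*unlabelled - labelled} on the common grid (the labelled spectrum's
#' grid over the overlap) -- the "unlabelled minus labelled" sign convention,
#' under which a band of the unlabelled species appears positive and its
#' isotope-shifted counterpart negative.
#'
#' @param unlabelled,labelled [ir_spectrum] difference spectra.
#' @param scaling_window window for the amplitude scaling (default
#'   1500-1200 cm^-1).
#' @return an [ir_spectrum]; the applied scale is in \code{meta$scale_factor}.
#' @export
double_difference <- function(unlabelled, labelled,
                              scaling_window = wn_window(1500, 1200)) {
  s <- scale_factor(unlabelled, labelled, scaling_window)
  grid <- .common_grid(unlabelled, labelled)
  u <- resample(unlabelled, grid)$values
  l <- resample(labelled, grid)$values
  ir_spectrum(grid, s * u - l,
              meta = list(scale_factor = s,
                          scaling_window = c(as_window(scaling_window)$hi,
                                             as_window(scaling_window)$lo)))
}

#' Band intensity integral over a window
#'
#' Trapezoidal integral of \code{|values|} over the window, in
#' cm^-1 * absorbance. The absolute value is integrated because signed
#' integrals of difference bands largely cancel; band intensity comparisons
#' (e.g. of the amide I region 1695-1615 cm^-1 across proteins) need the
#' magnitude.
#'
#' @param s an [ir_spectrum].
#' @param w integration window.
#' @param absolute integrate \code{|values|} (default) or signed values.
#' @return scalar integral.
#' @export
band_integral <- function(s, w, absolute = TRUE) {
  cs <- crop(s, w)
  x <- rev(cs$axis); y <- rev(cs$values)    # ascending for the trapezoid sum
  if (absolute) y <- abs(y)
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Normalize a spectrum on a reference band
#'
#' Divides the whole spectrum by the absolute value at the local extremum
#' nearest \code{center} inside the window \code{w} -- e.g. scaling difference
#' spectra of different proteins on the flavin C4=O stretch before comparing
#' amide I intensities.
#'
#' @param s an [ir_spectrum].
#' @param center nominal band position, cm^-1.
#' @param w search window containing the band.
#' @return an [ir_spectrum]; normalization position and value recorded in
#'   \code{meta}.
#' @export
normalize_on_band <- function(s, center, w) {
  cs <- crop(s, w)
  v <- cs$values; n <- length(v)
  # local extrema of |v| in the window interior, plus window edges as fallback
  is_ext <- logical(n)
  for (i in 2:(n - 1)) {
    is_ext[i] <- (v[i] - v[i - 1]) * (v[i + 1] - v[i]) <= 0
  }
  idx <- which(is_ext)
  if (!length(idx)) stop("no local extremum found in the window")
  pick <- idx[which.min(abs(cs$axis[idx] - center))]
  ref <- abs(v[pick])
  if (ref == 0) stop("extremum value is zero; cannot normalize")
  ir_spectrum(s$axis, s$values / ref,
              meta = c(s$meta, list(norm_position = cs$axis[pick],
                                    norm_value = v[pick])))
}
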