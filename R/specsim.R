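# Stick-spectrum convolution and computed difference / double-difference
# spectra for theory-experiment comparison.

#' Stick spectrum
#'
#' Discrete computed lines before line-shape convolution: positions in cm^-1
#' (IR) or cm^-1 transition energies (UV-vis), intensities in km/mol or
#' oscillator strength.
#'
#' @param positions numeric line positions.
#' @param intensities numeric line intensities, non-negative.
#' @return object of class \code{stick_spectrum}.
#' @export
stick_spectrum <- function(positions, intensities) {
  if (length(positions) != length(intensities))
    stop("positions and intensities must have equal length")
  if (any(intensities < 0)) stop("stick intensities must be non-negative")
  structure(list(positions = as.numeric(positions),
                 intensities = as.numeric(intensities)),
            class = "stick_spectrum")
}

#' Convolve IR sticks with Lorentzians
#'
#' Sum of area-normalized Lorentzians centered at the stick positions and
#' scaled by the intensities, so the integrated band area equals the stick
#' intensity. Default FWHM 8 cm^-1 (7 cm^-1 is the usual choice for
#' double-difference comparisons).
#'
#' @param sticks a [stick_spectrum()] (or a list/data frame with
#'   \code{positions}, \code{intensities}).
#' @param fwhm Lorentzian FWHM, cm^-1.
#' @param grid output wavenumber axis (default 1 cm^-1 over 1800-1200).
#' @return an [ir_spectrum].
#' @export
convolve_ir <- function(sticks, fwhm = 8, grid = seq(1800, 1200, by = -1)) {
  if (fwhm <= 0) stop("FWHM must be positive")
  pos <- sticks$positions; int <- sticks$intensities
  y <- rep(0, length(grid))
  if (!length(pos)) {
    warning("empty stick spectrum; returning zero spectrum")
    return(ir_spectrum(grid, y))
  }
  for (i in seq_along(pos)) {
    y <- y + lorentzian(grid, pos[i], int[i], fwhm)
  }
  ir_spectrum(grid, y)
}

#' Convolve electronic states with Gaussians on the energy axis
#'
#' Each state (transition energy in cm^-1, oscillator strength) becomes a
#' Gaussian of the given FWHM on the energy axis; the curve is then evaluated
#' on a wavelength grid in nm via E = 1e7/lambda. The Gaussian is applied in
#' energy (the FWHM is stated in cm^-1), not in wavelength, so a single state
#' peaks exactly at 1e7/E0 nm.
#'
#' @param states a [stick_spectrum()] with positions = transition energies in
#'   cm^-1.
#' @param fwhm Gaussian FWHM on the energy axis, cm^-1 (default 3000).
#' @param grid output wavelength axis in nm (default 1 nm over 300-550).
#' @return list with \code{wavelength} (nm) and \code{values} plus class
#'   \code{uvvis_spectrum}; also usable as a data frame via
#'   \code{as.data.frame}.
#' @export
convolve_uvvis <- function(states, fwhm = 3000, grid = seq(300, 550, by = 1)) {
  if (fwhm <= 0) stop("FWHM must be positive")
  if (any(states$positions <= 0)) stop("transition energies must be positive")
  if (any(grid <= 0)) stop("wavelength grid must be positive")
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  E <- 1e7 / grid
  y <- rep(0, length(grid))
  for (i in seq_along(states$positions)) {
    y <- y + states$intensities[i] *
      exp(-(E - states$positions[i])^2 / (2 * sigma^2))
  }
  structure(list(wavelength = grid, values = y), class = "uvvis_spectrum")
}

#' @export
as.data.frame.uvvis_spectrum <- function(x, ...)
  data.frame(wavelength_nm = x$wavelength, value = x$values)

#' Computed light-minus-dark difference spectrum
#'
#' @param light,dark [ir_spectrum]s on a common grid.
#' @return an [ir_spectrum], \code{light - dark}.
#' @export
computed_difference <- function(light, dark) {
  stopifnot(inherits(light, "ir_spectrum"), inherits(dark, "ir_spectrum"))
  if (length(light$axis) != length(dark$axis) ||
      max(abs(light$axis - dark$axis)) > 1e-9)
    stop("spectra must share one grid; resample first")
  ir_spectrum(light$axis, light$values - dark$values)
}

#' Computed double-difference spectrum from four stick sets
#'
#' \code{(light_u - dark_u) - (light_l - dark_l)}, each term convolved with
#' Lorentzians of the given FWHM: the theoretical counterpart of the
#' experimental unlabelled-minus-labelled double difference, built from the
#' stick spectra of the four isotopomer/state combinations. When intensities
#' are isotope-independent the integral of the result is (near) zero.
#'
#' @param dark_u,dark_l,light_u,light_l [stick_spectrum()]s for
#'   unlabelled/labelled dark and light states.
#' @param fwhm Lorentzian FWHM, cm^-1 (default 7 for double-difference
#'   comparisons).
#' @param grid output axis.
#' @return an [ir_spectrum].
#' @export
computed_double_difference <- function(dark_u, dark_l, light_u, light_l,
                                       fwhm = 7,
                                       grid = seq(1800, 1200, by = -1)) {
  du <- convolve_ir(dark_u, fwhm, grid)
  dl <- convolve_ir(dark_l, fwhm, grid)
  lu <- convolve_ir(light_u, fwhm, grid)
  ll <- convolve_ir(light_l, fwhm, grid)
  ir_spectrum(grid, (lu$values - du$values) - (ll$values - dl$values))
}

#' Pearson similarity of two spectra over a window
#'
#' Correlation of values over the window after resampling both spectra onto
#' the common grid; quantifies a theory-experiment band-pattern comparison.
#'
#' @param a,b [ir_spectrum]s.
#' @param w comparison window.
#' @return Pearson correlation coefficient.
#' @export
spectral_similarity <- function(a, b, w) {
  w <- as_window(w)
  grid <- .common_grid(a, b)
  grid <- grid[grid >= w$lo & grid <= w$hi]
  if (length(grid) < 3L) stop("window too narrow for a correlation")
  av <- resample(a, grid)$values
  bv <- resample(b, grid)$values
  if (stats::sd(av) == 0 || stats::sd(bv) == 0)
    stop("zero variance in the comparison window")
  stats::cor(av, bv)
}
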