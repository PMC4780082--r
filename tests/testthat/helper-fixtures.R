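# Shared fixtures, built in code at test time.

# The three-pair deconvolution truth: flavin C4=O light-state pair,
# dark-state C=O pair (positive lobe at the lower wavenumber), hidden C=N
# pair; unity area ratios, one shared 7 cm^-1 FWHM.
truth_bands <- function(w = 7, areas = c(1, 1.3, 0.8)) {
  data.frame(xc = c(1697, 1689, 1660, 1667, 1691, 1672),
             A = c(areas[1], -areas[1], areas[2], -areas[2],
                   areas[3], -areas[3]),
             w = w)
}

noiseless_dd <- function(step = 0.5, w = 7, areas = c(1, 1.3, 0.8)) {
  model_eval(truth_bands(w, areas), seq(1700, 1650, by = -step))
}

# Diatomic with explicit masses and a single stretch constant chosen so the
# harmonic frequency equals `freq` cm^-1 (closed form, used as an oracle).
diatomic_hessian <- function(m1, m2, freq = 1691) {
  mu <- 1 / (1 / m1 + 1 / m2)
  freq_cm_unit <- 5140.487144  # cm^-1 per sqrt(hartree/(bohr^2 amu)), CODATA
  k <- mu * (freq / freq_cm_unit)^2
  H <- matrix(0, 6, 6)
  # atoms on the z axis: only z-z couplings
  H[3, 3] <- H[6, 6] <- k
  H[3, 6] <- H[6, 3] <- -k
  mol <- molecule(c("C", "N"), rbind(c(0, 0, 0), c(0, 0, 1.2)),
                  masses = c(m1, m2))
  list(mol = mol, H = H, k = k, mu = mu)
}

expect_spectrum_equal <- function(a, b, tol = 1e-9) {
  expect_equal(a$axis, b$axis, tolerance = tol)
  expect_equal(a$values, b$values, tolerance = tol)
}
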