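test_that("the generator is deterministic under a fixed seed", {
  d <- experiment_design(seed = 42)
  p1 <- synth_difference_pair(d)
  p2 <- synth_difference_pair(d)
  expect_identical(p1$unlabelled$values, p2$unlabelled$values)
  expect_identical(p1$labelled$values, p2$labelled$values)

  p3 <- synth_difference_pair(experiment_design(seed = 43))
  expect_false(identical(p1$unlabelled$values, p3$unlabelled$values))
})

test_that("incorporation limits: p = 0 reproduces the unlabelled bands, p = 1 shifts fully", {
  d0 <- experiment_design(incorporation = 0, noise_sd = 0)
  p0 <- synth_difference_pair(d0)
  expect_equal(p0$labelled$values, p0$unlabelled$values, tolerance = 1e-12)

  bm <- data.frame(label = "one", dark_center = 1680, dark_area = 5e-3,
                   light_center = 1700, light_area = 5e-3,
                   shift_dark = 7, shift_light = 7, w = 8)
  d1 <- experiment_design(incorporation = 1, noise_sd = 0, band_model = bm)
  p1 <- synth_difference_pair(d1)
  grid <- p1$labelled$axis
  expected <- model_eval(data.frame(xc = c(1673, 1693), A = c(-5e-3, 5e-3),
                                    w = 8), grid)
  expect_equal(p1$labelled$values, expected$values, tolerance = 1e-12)
})

test_that("lower incorporation weakens the double difference", {
  amp <- function(p, seed) {
    pair <- synth_difference_pair(
      experiment_design(incorporation = p, noise_sd = 1e-6, seed = seed))
    dd <- double_difference(pair$unlabelled, pair$labelled)
    max(abs(crop(dd, c(1650, 1705))$values))
  }
  expect_lt(amp(0.58, 5), amp(0.75, 5))
  expect_lt(amp(0.30, 6), amp(0.58, 6))
})

test_that("a p = 0 pair leaves only noise in the double difference", {
  d <- experiment_design(incorporation = 0, noise_sd = 2e-5, seed = 9)
  pair <- synth_difference_pair(d)
  dd <- double_difference(pair$unlabelled, pair$labelled)
  resid <- crop(dd, c(1240, 1540))$values   # away from any band structure
  expect_lt(abs(mean(resid)), 1e-5)
  expect_equal(sd(resid), sqrt(2) * 2e-5, tolerance = 0.25)
})

test_that("toy force fields produce physically admissible Hessians", {
  for (m in list(toy_co_oscillator(1700), amide_surrogate(),
                 imidate_surrogate("pcm"), imidate_surrogate("hbond"))) {
    H <- m$hessian
    expect_lt(max(abs(H - t(H))), 1e-12)
    ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-10 * max(abs(ev)))   # positive semidefinite
    nm <- normal_modes(m$mol, H)
    expect_true(all(nm$frequencies > -1))        # no imaginary vibrations
  }
  expect_error(toy_force_field(c("C", "O"),
                               rbind(c(0, 0, 0), c(1.2, 0, 0)),
                               bonds = data.frame(i = 1, j = 2, k = -1)),
               "positive")
})

test_that("the single C=O toy oscillator lands on its design frequency", {
  co <- toy_co_oscillator(1700)
  nm <- normal_modes(co$mol, co$hessian)
  expect_lt(abs(max(nm$frequencies) - 1700), 0.5)
  I <- ir_intensities(nm, co$dipole_derivatives)
  expect_gt(I[which.max(nm$frequencies)], 0)
})

test_that("coupling tames the diatomic isotope-shift bound", {
  # an uncoupled C-N oscillator at the same frequency shows the full
  # reduced-mass shift; the coupled imidic surrogate stays well below it
  d <- diatomic_hessian(12, 14.0030740048, freq = 1691)
  nm14 <- normal_modes(d$mol, d$H)
  nm15 <- normal_modes(d$mol, d$H, iso = isotope_pattern(`2` = "15N"))
  shift_diatomic <- max(nm14$frequencies) - max(nm15$frequencies)
  expect_equal(shift_diatomic, 26.2, tolerance = 0.1)

  m <- imidate_surrogate("pcm")
  nmu <- normal_modes(m$mol, m$hessian, scale = 0.965)
  nml <- normal_modes(m$mol, m$hessian, iso = isotope_pattern(N3 = "15N"),
                      scale = 0.965)
  pr <- suppressWarnings(pair_modes(nmu, nml))
  pt <- ped(nmu, m$hessian, m$mol, m$coords)
  cn_mode <- pt$summary$mode[which.max(pt$ped[, "r(C1-N3)"])]
  cn_shift <- pr$shift[pr$mode_a == cn_mode]
  expect_gt(cn_shift, 13); expect_lt(cn_shift, 16.5)
  expect_lt(cn_shift, shift_diatomic)
})

test_that("fixture suite is byte-stable per seed and self-consistent", {
  d1 <- tempfile(); d2 <- tempfile(); d3 <- tempfile()
  f1 <- fixture_suite(seed = 17, dir = d1)
  f2 <- fixture_suite(seed = 17, dir = d2)
  f3 <- fixture_suite(seed = 18, dir = d3)
  md5 <- function(fs) unname(tools::md5sum(fs))
  expect_identical(md5(f1), md5(f2))
  # different seed: different spectra, identical Hessian files
  csvs <- grepl("blrb|blrp1", basename(f1))
  expect_false(any(md5(f1[csvs]) == md5(f3[csvs])))
  expect_identical(md5(f1[!csvs]), md5(f3[!csvs]))

  # regenerated fixtures pass the core invariants after a file round trip
  h <- read_hessian(file.path(d1, "synthetic_acetamide_vff.punch"),
                    format = "gamess_punch", n_atoms = 9)
  mol <- read_xyz(file.path(d1, "synthetic_acetamide_vff.xyz"))
  nm <- normal_modes(mol, h$hessian)
  expect_identical(nm$zero_mode_count, 6L)
  s <- read_spectrum(file.path(d1, "synthetic_blrb_unlabelled.csv"))
  expect_gt(length(s$axis), 500)
  expect_true(all(diff(s$axis) < 0))
})
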