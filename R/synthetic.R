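# Synthetic stand-ins for the study's raw data: (i) paired
# unlabelled/labelled FTIR difference spectra with band structure, noise,
# baseline drift and partial isotope incorporation; (ii) toy
# valence-force-field molecules yielding Cartesian Hessians and dipole
# derivatives with tunable C=O / C=N / N-H-bend couplings.
#
# Partial incorporation is modelled as a linear mixture of the unshifted and
# shifted band sets (dilute, non-interacting isotopomers add linearly in
# absorbance).

#' Design of a synthetic isotope-editing FTIR experiment
#'
#' The band model is a table of difference-band triples: each row is one
#' molecular species with a dark-state band (entering the light-minus-dark
#' difference spectrum negatively) and a light-state band (positive), both
#' downshifted on isotope labelling by the row's shift(s). Labelling is
#' incomplete: a fraction \code{incorporation} of molecules carries the
#' label.
#'
#' The default band model emulates a BlrB-like BLUF domain: the flavin C4=O
#' difference band (dark 1710, light 1697 cm^-1; light-state shift 8 cm^-1 on
#' labelling, dark 5), the glutamine dark-state C=O at 1667 (shift 7) whose
#' light-state counterpart is the imidic C=N at 1691 (shift 19), amide I
#' bands at 1641/1623 (label-insensitive), and label-insensitive fingerprint
#' bands below 1500 cm^-1 that carry the amplitude scaling between samples.
#'
#' @param incorporation fraction of labelled molecules in [0, 1] (0.75 for a
#'   BlrB-like, 0.58 for a BlrP1-like sample).
#' @param noise_sd white-noise standard deviation, absorbance units.
#' @param drift polynomial drift coefficients (constant, linear, quadratic)
#'   on the axis rescaled to [-1, 1]; absorbance units.
#' @param seed integer RNG seed for reproducible noise.
#' @param band_model optional replacement band table (columns
#'   \code{label, dark_center, dark_area, light_center, light_area,
#'   shift_dark, shift_light, w}).
#' @param amide_scale multiplier on the amide I band areas (smaller
#'   conformational change -> smaller amide I difference bands).
#' @param gain overall amplitude factor applied to the labelled sample
#'   (path-length/concentration mismatch removed later by scaling).
#' @return object of class \code{experiment_design}.
#' @export
experiment_design <- function(incorporation = 0.75, noise_sd = 1e-5,
                              drift = c(0, 0, 0), seed = 1,
                              band_model = NULL, amide_scale = 1, gain = 1) {
  if (incorporation < 0 || incorporation > 1)
    stop("incorporation must be in [0, 1]")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (is.null(band_model)) {
    band_model <- data.frame(
      label = c("flavin_C4O", "gln_CO_to_CN", "amide_I", "amide_I_b",
                "fp_1455", "fp_1400", "fp_1305", "fp_1248"),
      dark_center  = c(1710, 1667, 1641, 1657, 1455, 1400, 1305, 1248),
      dark_area    = c(7e-3, 6e-3, 8e-3 * amide_scale, 4e-3 * amide_scale,
                       4e-3, 3e-3, 3.5e-3, 2.5e-3),
      light_center = c(1697, 1691, 1623, 1634, 1448, 1392, 1298, 1257),
      light_area   = c(8e-3, 4e-3, 9e-3 * amide_scale, 4.5e-3 * amide_scale,
                       4e-3, 3e-3, 3.5e-3, 2.5e-3),
      shift_dark   = c(5, 7, 0, 0, 0, 0, 0, 0),
      shift_light  = c(8, 19, 0, 0, 0, 0, 0, 0),
      w            = c(9, 9, 14, 14, 12, 12, 12, 12))
  }
  structure(list(band_model = band_model, incorporation = incorporation,
                 noise_sd = noise_sd, drift = drift, seed = seed,
                 gain = gain),
            class = "experiment_design")
}

.design_bands <- function(bm, shifted = FALSE) {
  dark_c <- bm$dark_center - if (shifted) bm$shift_dark else 0
  light_c <- bm$light_center - if (shifted) bm$shift_light else 0
  data.frame(xc = c(dark_c, light_c),
             A = c(-bm$dark_area, bm$light_area),
             w = c(bm$w, bm$w))
}

.drift_trace <- function(coefs, axis) {
  t <- 2 * (axis - mean(range(axis))) / diff(range(axis))
  out <- rep(0, length(axis))
  for (k in seq_along(coefs)) out <- out + coefs[k] * t^(k - 1)
  out
}

#' Generate a synthetic unlabelled/labelled difference-spectrum pair
#'
#' The unlabelled trace is the sum of the design's difference bands plus
#' white noise and polynomial drift; the labelled trace mixes the unshifted
#' band set (weight \code{1 - p}) with the isotope-shifted set (weight
#' \code{p = incorporation}), with its own independent noise and drift, and
#' an overall \code{gain}. Seeded and reproducible: the same design yields
#' bit-identical spectra.
#'
#' @param design an [experiment_design()].
#' @param grid wavenumber axis (default 1 cm^-1 over 1750-1200).
#' @return list with elements \code{unlabelled} and \code{labelled}
#'   ([ir_spectrum]s).
#' @export
synth_difference_pair <- function(design,
                                  grid = seq(1750, 1200, by = -1)) {
  stopifnot(inherits(design, "experiment_design"))
  p <- design$incorporation
  bm <- design$band_model
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(design$seed)
  base_u <- model_eval(.design_bands(bm, shifted = FALSE), grid)$values
  base_s <- model_eval(.design_bands(bm, shifted = TRUE), grid)$values
  u <- base_u + stats::rnorm(length(grid), 0, design$noise_sd) +
    .drift_trace(design$drift, grid)
  l <- design$gain * ((1 - p) * base_u + p * base_s) +
    stats::rnorm(length(grid), 0, design$noise_sd) +
    .drift_trace(design$drift, grid)
  list(
    unlabelled = ir_spectrum(grid, u,
                             meta = list(sample = "unlabelled", seed = design$seed)),
    labelled = ir_spectrum(grid, l,
                           meta = list(sample = "labelled",
                                       incorporation = p, seed = design$seed)))
}

# --- toy valence force fields ----------------------------------------------

#' Define a toy valence force field
#'
#' A molecular fragment with explicit internal-coordinate force constants:
#' stretches in mdyn/A, bends and torsions in mdyn*A/rad^2, stretch-bend
#' couplings in mdyn/rad, stretch-stretch couplings in mdyn/A. Bond dipole
#' derivatives (effective bond charges, e) supply a 3 x 3N dipole-derivative
#' matrix via the bond-dipole model mu = sum_b q_b (r_j - r_i).
#'
#' @param elements element symbols.
#' @param coordinates N x 3 matrix, Angstrom.
#' @param bonds data frame \code{i, j, k} (force constant mdyn/A) and
#'   optional \code{q} (bond charge, e; default 0.3).
#' @param angles optional data frame \code{i, j, k, kb} (j central,
#'   mdyn*A/rad^2); default: all bonded triples with \code{kb = 0.6}.
#' @param torsions optional data frame \code{i, j, k, l, kt}; default: all
#'   bonded quadruples with \code{kt = 0.05}.
#' @param couplings optional data frame \code{s, t, k}: indices into the
#'   internal-coordinate list (bonds first, then angles, then torsions) and
#'   the off-diagonal constant (units inferred from the coordinate kinds).
#' @return object of class \code{toy_force_field}.
#' @export
toy_force_field <- function(elements, coordinates, bonds, angles = NULL,
                            torsions = NULL, couplings = NULL) {
  mol <- molecule(elements, coordinates)
  if (any(bonds$k <= 0)) stop("stretch constants must be positive")
  if (is.null(bonds$q)) bonds$q <- 0.3
  n <- length(elements)
  bonded <- matrix(FALSE, n, n)
  for (r in seq_len(nrow(bonds))) bonded[bonds$i[r], bonds$j[r]] <-
    bonded[bonds$j[r], bonds$i[r]] <- TRUE
  if (is.null(angles)) {
    rows <- list()
    for (j in 1:n) {
      nb <- which(bonded[j, ])
      if (length(nb) < 2) next
      for (a in 1:(length(nb) - 1)) for (b in (a + 1):length(nb))
        rows[[length(rows) + 1L]] <- data.frame(i = nb[a], j = j, k = nb[b],
                                                kb = 0.6)
    }
    angles <- if (length(rows)) do.call(rbind, rows) else
      data.frame(i = integer(0), j = integer(0), k = integer(0),
                 kb = numeric(0))
  }
  if (is.null(torsions)) {
    rows <- list()
    for (j in 1:n) for (k in 1:n) {
      if (k <= j || !bonded[j, k]) next
      for (i in which(bonded[j, ] & seq_len(n) != k))
        for (l in which(bonded[k, ] & seq_len(n) != j)) {
          if (i == l) next
          rows[[length(rows) + 1L]] <- data.frame(i = i, j = j, k = k, l = l,
                                                  kt = 0.05)
        }
    }
    torsions <- if (length(rows)) do.call(rbind, rows) else
      data.frame(i = integer(0), j = integer(0), k = integer(0),
                 l = integer(0), kt = numeric(0))
  }
  structure(list(mol = mol, bonds = bonds, angles = angles,
                 torsions = torsions, couplings = couplings),
            class = "toy_force_field")
}

#' Build molecule, Hessian and dipole derivatives from a toy force field
#'
#' Assembles the Cartesian Hessian as \eqn{B^T F B} at the reference geometry
#' (B the Wilson matrix in atomic-unit coordinates, F the internal
#' force-constant matrix converted to hartree-based units) and the dipole
#' derivatives from the bond-dipole model. The result is positive
#' semidefinite whenever F is, so all frequencies are real and the six
#' rigid-body modes are exactly zero.
#'
#' @param ff a [toy_force_field()].
#' @return list: \code{mol} ([molecule()]), \code{hessian} (3N x 3N,
#'   hartree/bohr^2), \code{dipole_derivatives} (3 x 3N, e),
#'   \code{coords} (the internal-coordinate table), \code{F_int}
#'   (internal force constants, atomic units).
#' @export
toy_molecule <- function(ff) {
  stopifnot(inherits(ff, "toy_force_field"))
  mol <- ff$mol
  n <- length(mol$elements)
  lab <- function(i) paste0(mol$elements[i], i)
  rows <- list()
  for (r in seq_len(nrow(ff$bonds)))
    rows[[length(rows) + 1L]] <- data.frame(
      kind = "bond", i = ff$bonds$i[r], j = ff$bonds$j[r], k = NA_integer_,
      l = NA_integer_,
      label = sprintf("r(%s-%s)", lab(ff$bonds$i[r]), lab(ff$bonds$j[r])))
  for (r in seq_len(nrow(ff$angles)))
    rows[[length(rows) + 1L]] <- data.frame(
      kind = "angle", i = ff$angles$i[r], j = ff$angles$j[r],
      k = ff$angles$k[r], l = NA_integer_,
      label = sprintf("a(%s-%s-%s)", lab(ff$angles$i[r]),
                      lab(ff$angles$j[r]), lab(ff$angles$k[r])))
  for (r in seq_len(nrow(ff$torsions)))
    rows[[length(rows) + 1L]] <- data.frame(
      kind = "torsion", i = ff$torsions$i[r], j = ff$torsions$j[r],
      k = ff$torsions$k[r], l = ff$torsions$l[r],
      label = sprintf("t(%s-%s-%s-%s)", lab(ff$torsions$i[r]),
                      lab(ff$torsions$j[r]), lab(ff$torsions$k[r]),
                      lab(ff$torsions$l[r])))
  coords <- do.call(rbind, rows)
  rownames(coords) <- NULL
  class(coords) <- c("internal_coords", "data.frame")

  kinds <- coords$kind
  kdiag <- c(ff$bonds$k * .CONST$mdynA_to_au,
             ff$angles$kb * .CONST$mdynAA_to_au,
             ff$torsions$kt * .CONST$mdynAA_to_au)
  F <- diag(kdiag, nrow = nrow(coords))
  if (!is.null(ff$couplings)) {
    for (r in seq_len(nrow(ff$couplings))) {
      s <- ff$couplings$s[r]; t <- ff$couplings$t[r]
      kin <- sort(c(kinds[s], kinds[t]))
      conv <- if (all(kin == "bond")) .CONST$mdynA_to_au
              else if (kin[1] == "bond") .CONST$mdyn_to_au
              else .CONST$mdynAA_to_au
      F[s, t] <- F[t, s] <- ff$couplings$k[r] * conv
    }
  }
  B <- b_matrix(mol, coords, coordinates = mol$coordinates * .CONST$ang_to_bohr)
  H <- t(B) %*% F %*% B
  H <- (H + t(H)) / 2

  D <- matrix(0, 3, 3 * n)
  for (r in seq_len(nrow(ff$bonds))) {
    i <- ff$bonds$i[r]; j <- ff$bonds$j[r]; q <- ff$bonds$q[r]
    for (al in 1:3) {
      D[al, 3 * (j - 1) + al] <- D[al, 3 * (j - 1) + al] + q
      D[al, 3 * (i - 1) + al] <- D[al, 3 * (i - 1) + al] - q
    }
  }
  list(mol = mol, hessian = H, dipole_derivatives = D, coords = coords,
       F_int = F)
}

# --- z-matrix style geometry construction ----------------------------------

# Place atom at distance r from A, angle theta (deg) to B, dihedral phi (deg)
# to C (NERF construction).
.place_atom <- function(A, B, C, r, theta, phi) {
  th <- theta * pi / 180; ph <- phi * pi / 180
  bc <- A - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - C
  n <- .cross(ab, bc); n <- n / sqrt(sum(n^2))
  m <- .cross(n, bc)
  d <- c(-r * cos(th), r * sin(th) * cos(ph), r * sin(th) * sin(ph))
  A + d[1] * bc + d[2] * m + d[3] * n
}

.zmat_geometry <- function(zmat) {
  # zmat: list of rows list(el, ref = c(a, b, c), r, theta, phi)
  n <- length(zmat)
  xyz <- matrix(0, n, 3)
  el <- character(n)
  for (i in seq_len(n)) {
    z <- zmat[[i]]
    el[i] <- z$el
    if (i == 1) {
      xyz[i, ] <- c(0, 0, 0)
    } else if (i == 2) {
      xyz[i, ] <- c(z$r, 0, 0)
    } else if (i == 3) {
      th <- z$theta * pi / 180
      a <- z$ref[1]; b <- z$ref[2]
      dir <- if (a == 2) -1 else 1  # bend back toward/away along x
      base <- xyz[a, ]
      sgn <- if (xyz[a, 1] > xyz[b, 1]) -1 else 1
      xyz[i, ] <- base + c(sgn * z$r * cos(th), z$r * sin(th), 0)
    } else {
      xyz[i, ] <- .place_atom(xyz[z$ref[1], ], xyz[z$ref[2], ],
                              xyz[z$ref[3], ], z$r, z$theta, z$phi)
    }
  }
  list(elements = el, coordinates = xyz)
}

#' Write the canonical synthetic test-fixture files
#'
#' Generates, under \code{dir}, the full set of synthetic fixtures the test
#' suite and examples consume: paired unlabelled/labelled difference spectra
#' for a BlrB-like (75\% incorporation) and a BlrP1-like (58\% incorporation,
#' smaller amide I changes) sample as CSV; XYZ geometries and punch-format
#' Hessians/dipole derivatives for the three valence-force-field surrogates
#' ([amide_surrogate()], [imidate_surrogate()] both variants); and a stick
#' table of the amide surrogate's paired unlabelled/15N frequencies and IR
#' intensities. All files are plain text, prefixed \code{synthetic_}, and
#' byte-stable for a given seed.
#'
#' @param seed integer seed for the spectral noise.
#' @param dir output directory (created if needed).
#' @return character vector of the written file paths, invisibly.
#' @export
fixture_suite <- function(seed = 1, dir = tempfile("isovib_fixtures_")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- character(0)
  wf <- function(name) { p <- file.path(dir, name); out <<- c(out, p); p }

  blrb <- synth_difference_pair(experiment_design(incorporation = 0.75,
                                                  seed = seed))
  blrp1 <- synth_difference_pair(experiment_design(incorporation = 0.58,
                                                   amide_scale = 0.45,
                                                   seed = seed + 1L))
  write_spectrum(blrb$unlabelled, wf("synthetic_blrb_unlabelled.csv"))
  write_spectrum(blrb$labelled, wf("synthetic_blrb_labelled.csv"))
  write_spectrum(blrp1$unlabelled, wf("synthetic_blrp1_unlabelled.csv"))
  write_spectrum(blrp1$labelled, wf("synthetic_blrp1_labelled.csv"))

  mols <- list(synthetic_acetamide_vff = amide_surrogate(),
               synthetic_imidate_pcm_vff = imidate_surrogate("pcm"),
               synthetic_imidate_hb_vff = imidate_surrogate("hbond"))
  for (nm in names(mols)) {
    m <- mols[[nm]]
    write_xyz(m$mol, wf(paste0(nm, ".xyz")),
              comment = paste("synthetic valence-force-field surrogate:", nm))
    write_hessian(m$hessian, wf(paste0(nm, ".punch")),
                  format = "gamess_punch",
                  dipole_derivatives = m$dipole_derivatives)
  }

  a <- mols[[1]]
  tab <- isotope_shift_table(
    a$mol, a$hessian,
    patterns = list(unlabelled = isotope_pattern(),
                    labelled_15N = isotope_pattern(N3 = "15N")),
    D = a$dipole_derivatives, scale = 0.965)
  con <- file(wf("synthetic_acetamide_sticks.csv"), "w")
  writeLines("mode,freq_unlabelled,intensity_unlabelled,freq_labelled,intensity_labelled", con)
  writeLines(sprintf("%d,%.6f,%.6f,%.6f,%.6f", tab$mode_a, tab$freq_a,
                     tab$intensity_a, tab$freq_b, tab$intensity_b), con)
  close(con)
  invisible(out)
}
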