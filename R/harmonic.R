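# Harmonic vibrational analysis: mass-weighted eigenproblem, Eckart
# projection, isotope substitution, IR intensities, isotopomer mode pairing.

#' Isotope substitution pattern
#'
#' Per-atom mass overrides, e.g. a 15N at the glutamine side-chain amide
#' nitrogen or deuterium at water hydrogens. Atoms not listed keep the
#' molecule's default masses.
#'
#' @param ... named overrides: names are atom indices (as strings) or in the
#'   form \code{"N4"} (element symbol + 1-based atom index), values are masses
#'   in amu or isotope labels such as \code{"15N"}, \code{"2H"}.
#' @return object of class \code{isotope_pattern} (named numeric vector of
#'   atom-index -> mass).
#' @export
#' @examples
#' isotope_pattern(N4 = "15N")           # atom 4 (a nitrogen) becomes 15N
#' isotope_pattern(`3` = 15.0001088989)  # explicit mass for atom 3
isotope_pattern <- function(...) {
  spec <- list(...)
  if (!length(spec)) return(structure(numeric(0), class = "isotope_pattern"))
  idx <- vapply(names(spec), function(nm) {
    digits <- gsub("[^0-9]", "", nm)
    if (!nzchar(digits)) stop("cannot find an atom index in '", nm, "'")
    as.integer(digits)
  }, 0L)
  mass <- vapply(spec, function(v) {
    if (is.character(v)) atomic_mass(v) else as.numeric(v)
  }, 0)
  if (any(mass <= 0)) stop("isotope masses must be positive")
  structure(stats::setNames(mass, idx), class = "isotope_pattern")
}

.apply_isotopes <- function(mol, iso) {
  m <- mol$masses
  if (!is.null(iso) && length(iso)) {
    idx <- as.integer(names(iso))
    if (any(idx < 1L | idx > length(m)))
      stop("isotope pattern indexes atoms outside the molecule")
    m[idx] <- as.numeric(iso)
  }
  m
}

# Orthonormal basis of the 6 (5 for linear) rigid-body directions in
# mass-weighted Cartesian coordinates at the given geometry.
.rigid_body_basis <- function(coords, masses) {
  n <- nrow(coords)
  com <- colSums(coords * masses) / sum(masses)
  rc <- sweep(coords, 2, com)
  sq <- sqrt(masses)
  V <- matrix(0, 3 * n, 6)
  for (k in 1:3) V[seq(k, 3 * n, by = 3), k] <- sq            # translations
  for (k in 1:3) {                                            # rotations
    ax <- c(0, 0, 0); ax[k] <- 1
    for (i in seq_len(n)) {
      V[(3 * i - 2):(3 * i), 3 + k] <- sq[i] *
        c(ax[2] * rc[i, 3] - ax[3] * rc[i, 2],
          ax[3] * rc[i, 1] - ax[1] * rc[i, 3],
          ax[1] * rc[i, 2] - ax[2] * rc[i, 1])
    }
  }
  # drop null rotations (linear molecules) and orthonormalize
  keep <- sqrt(colSums(V^2)) > 1e-8 * max(sqrt(colSums(V^2)))
  V <- V[, keep, drop = FALSE]
  qr_ <- qr(V)
  Q <- qr.Q(qr_)
  rank <- qr_$rank
  Q[, seq_len(rank), drop = FALSE]
}

#' Harmonic normal modes from a Cartesian Hessian
#'
#' Diagonalizes the mass-weighted Hessian \eqn{M^{-1/2} H M^{-1/2}}. With
#' \code{project = TRUE} the six rigid-body directions (five for linear
#' molecules) are removed first by Eckart projection -- explicit construction
#' of the translation/rotation vectors at the input geometry, orthonormalization
#' and projection of the mass-weighted Hessian -- so that exactly six (five)
#' near-zero frequencies remain. Frequencies are
#' \eqn{\tilde\nu_i = \mathrm{sign}(\lambda_i)\sqrt{|\lambda_i|}} converted to
#' cm^-1; imaginary modes appear as negative numbers. Computed frequencies may
#' additionally be scaled by an empirical factor (0.965 for
#' B3LYP/6-31G(d,p)-grade Hessians of hydrogen-bonded amide systems);
#' \code{frequencies} holds the scaled values, \code{frequencies_unscaled} the
#' raw ones.
#'
#' Mode vectors are returned both mass-weighted (orthonormal, matrix
#' \code{modes_mw}) and Cartesian (\code{displacements}, columns
#' \eqn{M^{-1/2}\ell_i}); the sign convention makes the largest-magnitude
#' component of each mass-weighted vector positive.
#'
#' @param mol a [molecule()].
#' @param H 3N x 3N Cartesian Hessian, hartree/bohr^2.
#' @param iso optional [isotope_pattern()].
#' @param project remove rigid-body modes by Eckart projection (default TRUE).
#' @param scale frequency scaling factor applied to \code{frequencies}
#'   (default 1; use 0.965 for B3LYP/6-31G(d,p) Hessians).
#' @param sym_tol relative Hessian symmetry tolerance.
#' @return object of class \code{normal_modes}: scaled and unscaled
#'   frequencies (cm^-1, descending), mass-weighted and Cartesian mode
#'   vectors, reduced masses (amu), masses used, the zero-mode count and
#'   geometry bookkeeping.
#' @export
normal_modes <- function(mol, H, iso = NULL, project = TRUE, scale = 1,
                         sym_tol = 1e-8) {
  stopifnot(inherits(mol, "molecule"))
  n <- length(mol$elements)
  if (!is.matrix(H) || nrow(H) != 3 * n || ncol(H) != 3 * n)
    stop("Hessian must be ", 3 * n, " x ", 3 * n)
  rel_asym <- max(abs(H - t(H))) / max(abs(H), .Machine$double.eps)
  if (rel_asym > sym_tol)
    stop("Hessian relative asymmetry ", signif(rel_asym, 3),
         " exceeds tolerance; symmetrize on read")
  H <- (H + t(H)) / 2
  masses <- .apply_isotopes(mol, iso)
  sq <- rep(sqrt(masses), each = 3L)
  Hmw <- H / outer(sq, sq)

  n_rigid <- 0L
  if (project) {
    Q <- .rigid_body_basis(mol$coordinates, masses)
    n_rigid <- ncol(Q)
    P <- diag(3 * n) - Q %*% t(Q)
    Hmw <- P %*% Hmw %*% P
    Hmw <- (Hmw + t(Hmw)) / 2
  }

  eig <- eigen(Hmw, symmetric = TRUE)
  lambda <- eig$values              # descending
  L <- eig$vectors
  # sign convention: largest-magnitude component positive
  for (j in seq_len(ncol(L))) {
    k <- which.max(abs(L[, j]))
    if (L[k, j] < 0) L[, j] <- -L[, j]
  }
  freq <- sign(lambda) * sqrt(abs(lambda)) * .CONST$freq_cm
  cart <- L / sq                     # columns M^{-1/2} l_i
  red_mass <- 1 / colSums(cart^2)    # amu (l_i normalized)
  zero_ct <- sum(abs(freq) < 1)

  structure(list(
    frequencies = scale * freq,
    frequencies_unscaled = freq,
    scale = scale,
    modes_mw = L,
    displacements = cart,
    reduced_masses = red_mass,
    masses = masses,
    coordinates = mol$coordinates,
    elements = mol$elements,
    zero_mode_count = zero_ct,
    n_rigid_projected = n_rigid,
    projected = project,
    trace_premass = sum(diag(H) / rep(masses, each = 3L))),
    class = "normal_modes")
}

#' @export
print.normal_modes <- function(x, ...) {
  nv <- length(x$frequencies) - x$zero_mode_count
  cat(sprintf("<normal_modes> %d atoms, %d vibrations (+%d rigid-body)\n",
              length(x$elements), nv, x$zero_mode_count))
  vib <- x$frequencies[abs(x$frequencies) >= 1]
  cat("  frequencies (cm^-1):",
      paste(sprintf("%.1f", utils::head(vib, 12)), collapse = " "),
      if (length(vib) > 12) "...\n" else "\n")
  invisible(x)
}

#' Infrared intensities from dipole derivatives
#'
#' \eqn{I_i \propto |\,\partial\mu/\partial Q_i\,|^2} with
#' \eqn{\partial\mu/\partial Q_i = D\,M^{-1/2}\ell_i} (D the 3 x 3N dipole
#' derivative matrix in atomic units, \eqn{\ell_i} the mass-weighted
#' normalized mode); converted to km/mol with the standard constant
#' (974.88 km/mol per (e amu^-1/2)^2).
#'
#' @param modes a [normal_modes()] object.
#' @param D 3 x 3N dipole-derivative matrix, atomic units.
#' @return numeric vector of intensities, km/mol, one per mode.
#' @export
ir_intensities <- function(modes, D) {
  if (is.null(D))
    stop("dipole derivatives missing; use the intensity-free workflow ",
         "(frequencies and shifts only)")
  if (!is.matrix(D) || nrow(D) != 3L || ncol(D) != nrow(modes$modes_mw))
    stop("dipole derivatives must be 3 x 3N")
  dmudQ <- D %*% modes$displacements      # 3 x nmodes, e / sqrt(amu)
  .CONST$ir_kmmol * colSums(dmudQ^2)
}

#' Pair normal modes of two isotopomers
#'
#' Greedy maximum-overlap assignment between the vibrational modes of two
#' isotopomers of the same molecule. Overlaps are
#' \eqn{|\langle \ell_i^a, \ell_i^b\rangle|} computed in the mass-weighted
#' metric of the first (reference, typically unlabelled) isotopomer; at
#' \eqn{\Delta m = 1} amu this metric choice is immaterial. Pairs are assigned
#' in order of decreasing overlap, each mode used at most once. If the best
#' and second-best overlap for a reference mode agree within
#' \code{ambiguity_tol}, a warning names both candidates. Rigid-body modes
#' (|freq| < 1 cm^-1) and imaginary modes are excluded by default.
#'
#' @param a,b [normal_modes()] of the same molecule/Hessian under different
#'   isotope patterns; \code{a} is the reference.
#' @param include_imaginary keep imaginary (negative) modes (default FALSE).
#' @param ambiguity_tol overlap gap below which a pairing is flagged
#'   ambiguous (default 0.05).
#' @return data frame of class \code{mode_pairing}: reference and partner mode
#'   indices, frequencies (scaled), \code{shift = freq_a - freq_b} (cm^-1,
#'   positive = downshift on labelling when b is the heavier isotopomer) and
#'   the overlap.
#' @export
pair_modes <- function(a, b, include_imaginary = FALSE, ambiguity_tol = 0.05) {
  stopifnot(inherits(a, "normal_modes"), inherits(b, "normal_modes"))
  if (nrow(a$modes_mw) != nrow(b$modes_mw))
    stop("isotopomers disagree on system size")
  sel <- function(m) {
    keep <- abs(m$frequencies_unscaled) >= 1
    if (!include_imaginary) keep <- keep & m$frequencies_unscaled > 0
    which(keep)
  }
  ia <- sel(a); ib <- sel(b)
  # overlap in the reference mass metric: <x_a, M_a x_b> on Cartesian vectors
  Ma <- rep(a$masses, each = 3L)
  Xa <- a$displacements[, ia, drop = FALSE]
  Xb <- b$displacements[, ib, drop = FALSE]
  Xa <- sweep(Xa, 1, sqrt(Ma), `*`); Xb <- sweep(Xb, 1, sqrt(Ma), `*`)
  Xa <- sweep(Xa, 2, sqrt(colSums(Xa^2)), `/`)
  Xb <- sweep(Xb, 2, sqrt(colSums(Xb^2)), `/`)
  S <- abs(crossprod(Xa, Xb))                  # |overlap|, rows a, cols b
  pairs <- data.frame(mode_a = integer(0), mode_b = integer(0),
                      freq_a = numeric(0), freq_b = numeric(0),
                      shift = numeric(0), overlap = numeric(0),
                      ambiguous = logical(0))
  Swork <- S
  while (any(is.finite(Swork)) && nrow(pairs) < min(length(ia), length(ib))) {
    k <- arrayInd(which.max(Swork), dim(Swork))
    i <- k[1]; j <- k[2]
    ov <- Swork[i, j]
    if (!is.finite(ov)) break
    alt <- sort(Swork[i, is.finite(Swork[i, ])], decreasing = TRUE)
    amb <- length(alt) > 1 && (alt[1] - alt[2]) < ambiguity_tol
    if (amb) {
      j2 <- order(Swork[i, ], decreasing = TRUE)[2]
      warning(sprintf(
        "ambiguous pairing for reference mode %d (%.1f cm^-1): partners %d (overlap %.3f) and %d (overlap %.3f)",
        ia[i], a$frequencies[ia[i]], ib[j], alt[1], ib[j2], alt[2]))
    }
    pairs <- rbind(pairs, data.frame(
      mode_a = ia[i], mode_b = ib[j],
      freq_a = a$frequencies[ia[i]], freq_b = b$frequencies[ib[j]],
      shift = a$frequencies[ia[i]] - b$frequencies[ib[j]],
      overlap = ov, ambiguous = amb))
    Swork[i, ] <- -Inf; Swork[, j] <- -Inf
  }
  pairs <- pairs[order(-pairs$freq_a), ]
  rownames(pairs) <- NULL
  class(pairs) <- c("mode_pairing", "data.frame")
  pairs
}

#' Isotope shift table across several isotope patterns
#'
#' Runs [normal_modes()] for every pattern and pairs each against the first
#' (reference) pattern, collecting scaled frequencies, shifts, overlaps and
#' (when dipole derivatives are given) IR intensities. This is the table that
#' feeds simulated difference and double-difference spectra.
#'
#' @param mol a [molecule()].
#' @param H Cartesian Hessian.
#' @param patterns list of at least two [isotope_pattern()]s (use
#'   \code{isotope_pattern()} for the unlabelled reference).
#' @param D optional 3 x 3N dipole-derivative matrix.
#' @param scale frequency scaling factor.
#' @param project Eckart projection flag.
#' @return data frame: pattern index and name, reference mode index,
#'   frequencies of reference and pattern, shift, overlap, and intensities.
#' @export
isotope_shift_table <- function(mol, H, patterns, D = NULL, scale = 1,
                                project = TRUE) {
  if (length(patterns) < 2L) stop("need at least two isotope patterns")
  nm <- lapply(patterns, function(p)
    normal_modes(mol, H, iso = p, project = project, scale = scale))
  ref <- nm[[1]]
  iref <- NULL
  if (!is.null(D)) iref <- ir_intensities(ref, D)
  out <- list()
  pnames <- names(patterns) %||% paste0("pattern", seq_along(patterns))
  if (is.null(names(patterns))) names(patterns) <- pnames
  for (k in seq_along(patterns)[-1]) {
    pr <- pair_modes(ref, nm[[k]])
    df <- data.frame(pattern = pnames[k], pr, stringsAsFactors = FALSE)
    if (!is.null(D)) {
      ik <- ir_intensities(nm[[k]], D)
      df$intensity_a <- iref[pr$mode_a]
      df$intensity_b <- ik[pr$mode_b]
    }
    out[[length(out) + 1L]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
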