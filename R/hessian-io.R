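# Geometry and Hessian / dipole-derivative file I/O.
#
# Interchange formats: standard XYZ for geometries; a GAMESS/Firefly-style
# punch dialect for Hessians ($HESS block, rows emitted in blocks of five
# values prefixed by the row index modulo 100 and a running block index) and
# dipole derivatives ($DIPDR block, one line of three values -- d mu_x, d
# mu_y, d mu_z -- per Cartesian coordinate); and a plain whitespace matrix
# with a one-line header.

#' Construct a molecule
#'
#' @param elements character vector of element symbols.
#' @param coordinates N x 3 numeric matrix, Angstrom.
#' @param masses optional atomic masses, amu; defaults to
#'   most-abundant-isotope masses via [atomic_mass()].
#' @return object of class \code{molecule}.
#' @export
molecule <- function(elements, coordinates, masses = NULL) {
  coordinates <- as.matrix(coordinates)
  if (ncol(coordinates) != 3L) stop("coordinates must be N x 3")
  if (length(elements) != nrow(coordinates))
    stop("elements and coordinates disagree on atom count")
  if (nrow(coordinates) < 2L) stop("a molecule needs at least 2 atoms")
  if (!all(is.finite(coordinates))) stop("coordinates must be finite")
  masses <- masses %||% atomic_mass(elements)
  if (any(masses <= 0)) stop("masses must be positive")
  structure(list(elements = as.character(elements),
                 coordinates = unname(coordinates),
                 masses = as.numeric(masses)),
            class = "molecule")
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule> %d atoms: %s\n", length(x$elements),
              paste(x$elements, collapse = " ")))
  invisible(x)
}

#' Read / write XYZ geometry files
#'
#' Standard XYZ: atom count, comment line, then one \code{element x y z} line
#' per atom (Angstrom).
#'
#' @param path file path.
#' @return [molecule()] for \code{read_xyz}; \code{path} invisibly for
#'   \code{write_xyz}.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("parse error in ", path, " at line 1: expected atom count")
  if (length(lines) < n + 2L) stop("truncated XYZ file: ", path)
  el <- character(n); xyz <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    toks <- strsplit(trimws(lines[i + 2L]), "[\t ]+")[[1]]
    if (length(toks) < 4L)
      stop("parse error in ", path, " at line ", i + 2L)
    el[i] <- toks[1]
    xyz[i, ] <- as.numeric(toks[2:4])
  }
  molecule(el, xyz)
}

#' @param mol a [molecule()].
#' @param comment comment line for the file.
#' @rdname read_xyz
#' @export
write_xyz <- function(mol, path, comment = "") {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(as.character(length(mol$elements)), comment), con)
  writeLines(sprintf("%-3s %18.12f %18.12f %18.12f", mol$elements,
                     mol$coordinates[, 1], mol$coordinates[, 2],
                     mol$coordinates[, 3]), con)
  invisible(path)
}

#' Read a Cartesian Hessian (and dipole derivatives) from file
#'
#' \code{gamess_punch}: parses \code{$HESS} (3N x 3N, hartree/bohr^2, rows in
#' blocks of five values each prefixed with the row index modulo 100 and a
#' block counter) and, when present, \code{$DIPDR} (3N lines of three values;
#' returned as the 3 x 3N matrix \eqn{\partial\mu_\alpha/\partial x_j} in
#' atomic units). \code{plain_matrix}: a header line \code{nrow ncol} followed
#' by whitespace-separated rows. The Hessian is symmetrized as
#' \eqn{(H + H^T)/2}; asymmetry beyond \code{tol} raises an error, smaller
#' asymmetry a warning.
#'
#' @param path file path.
#' @param format \code{"gamess_punch"} or \code{"plain_matrix"}.
#' @param n_atoms expected atom count (checked when given).
#' @param tol relative symmetry tolerance (default 1e-6).
#' @return list with \code{hessian} (3N x 3N) and \code{dipole_derivatives}
#'   (3 x 3N or NULL).
#' @export
read_hessian <- function(path, format = c("gamess_punch", "plain_matrix"),
                         n_atoms = NULL, tol = 1e-6) {
  format <- match.arg(format)
  if (format == "plain_matrix") {
    lines <- readLines(path, warn = FALSE)
    hdr <- as.integer(strsplit(trimws(lines[1]), "[\t ]+")[[1]])
    if (length(hdr) != 2L || anyNA(hdr))
      stop("parse error in ", path, ": header must be 'nrow ncol'")
    vals <- as.numeric(unlist(strsplit(trimws(lines[-1]), "[\t ]+")))
    vals <- vals[!is.na(vals)]
    if (length(vals) != hdr[1] * hdr[2])
      stop("dimension mismatch in ", path, ": expected ", hdr[1] * hdr[2],
           " values, found ", length(vals))
    H <- matrix(vals, hdr[1], hdr[2], byrow = TRUE)
    D <- NULL
  } else {
    lines <- readLines(path, warn = FALSE)
    H <- .parse_punch_hess(lines, path)
    D <- .parse_punch_dipdr(lines)
  }
  if (nrow(H) != ncol(H)) stop("Hessian must be square, got ",
                               nrow(H), " x ", ncol(H))
  if (nrow(H) %% 3L != 0L) stop("Hessian dimension not a multiple of 3")
  if (!is.null(n_atoms) && nrow(H) != 3L * n_atoms)
    stop("Hessian dimension ", nrow(H), " does not match ", n_atoms, " atoms")
  asym <- max(abs(H - t(H))) / max(abs(H), .Machine$double.eps)
  if (asym > tol)
    stop("Hessian asymmetry ", signif(asym, 3), " exceeds tolerance ", tol)
  if (asym > 1e-12)
    warning("Hessian symmetrized (relative asymmetry ", signif(asym, 3), ")")
  H <- (H + t(H)) / 2
  if (!is.null(D) && !is.null(n_atoms) && ncol(D) != 3L * n_atoms)
    stop("dipole-derivative dimension mismatch")
  list(hessian = H, dipole_derivatives = D)
}

.parse_punch_hess <- function(lines, path) {
  i0 <- grep("^ ?\\$HESS", lines)
  if (!length(i0)) stop("no $HESS block in ", path)
  iend <- grep("^ ?\\$END", lines)
  iend <- iend[iend > i0[1]][1]
  if (is.na(iend)) stop("unterminated $HESS block in ", path)
  body <- lines[(i0[1] + 1L):(iend - 1L)]
  body <- body[!grepl("^ ?ENERGY", body)]
  body <- trimws(body); body <- body[nzchar(body)]
  blocks <- list()
  for (ln in body) {
    # two leading integer fields (row index mod 100, block counter), then
    # up to five values
    toks <- strsplit(ln, "[\t ]+")[[1]]
    if (length(toks) < 3L)
      stop("parse error in $HESS of ", path, ": '", ln, "'")
    irow <- suppressWarnings(as.integer(toks[1]))
    vals <- suppressWarnings(as.numeric(toks[-(1:2)]))
    if (is.na(irow) || anyNA(vals))
      stop("parse error in $HESS of ", path, ": '", ln, "'")
    blocks[[length(blocks) + 1L]] <- list(irow = irow, vals = vals)
  }
  nvals <- sum(vapply(blocks, function(b) length(b$vals), 0L))
  dim <- round(sqrt(nvals))
  if (dim * dim != nvals)
    stop("$HESS of ", path, " does not contain a square matrix (",
         nvals, " values)")
  H <- matrix(0, dim, dim)
  row <- 1L; col <- 1L
  for (b in blocks) {
    if (b$irow != (row %% 100L))
      stop("row index mismatch in $HESS of ", path,
           ": expected ", row %% 100L, ", found ", b$irow)
    k <- length(b$vals)
    if (col + k - 1L > dim) stop("overfull row ", row, " in $HESS of ", path)
    H[row, col:(col + k - 1L)] <- b$vals
    col <- col + k
    if (col > dim) { col <- 1L; row <- row + 1L }
  }
  if (row != dim + 1L) stop("incomplete $HESS block in ", path)
  H
}

.parse_punch_dipdr <- function(lines) {
  i0 <- grep("^ ?\\$DIPDR", lines)
  if (!length(i0)) return(NULL)
  iend <- grep("^ ?\\$END", lines)
  iend <- iend[iend > i0[1]][1]
  body <- trimws(lines[(i0[1] + 1L):(iend - 1L)])
  body <- body[nzchar(body)]
  vals <- lapply(body, function(ln) as.numeric(strsplit(ln, "[\t ]+")[[1]]))
  if (any(vapply(vals, length, 0L) != 3L))
    stop("each $DIPDR line must hold three values")
  M <- do.call(rbind, vals)       # 3N x 3: rows = Cartesian coords
  t(M)                            # 3 x 3N
}

#' Write a Hessian (and dipole derivatives) to file
#'
#' @param H 3N x 3N Cartesian Hessian, hartree/bohr^2.
#' @param path output path.
#' @param format \code{"gamess_punch"} or \code{"plain_matrix"}.
#' @param dipole_derivatives optional 3 x 3N matrix for a \code{$DIPDR} block
#'   (punch format only).
#' @return \code{path}, invisibly.
#' @export
write_hessian <- function(H, path, format = c("gamess_punch", "plain_matrix"),
                          dipole_derivatives = NULL) {
  format <- match.arg(format)
  con <- file(path, "w"); on.exit(close(con))
  if (format == "plain_matrix") {
    writeLines(sprintf("%d %d", nrow(H), ncol(H)), con)
    for (i in seq_len(nrow(H)))
      writeLines(paste(sprintf("%.15e", H[i, ]), collapse = " "), con)
  } else {
    writeLines(" $HESS", con)
    writeLines("ENERGY IS 0.0000000000 E(NUC) IS 0.0000000000", con)
    dim <- nrow(H)
    for (i in seq_len(dim)) {
      blocks <- split(H[i, ], ceiling(seq_len(dim) / 5))
      for (b in seq_along(blocks)) {
        writeLines(sprintf("%3d %3d %s", i %% 100L, b %% 1000L,
                           paste(sprintf("% .10e", blocks[[b]]),
                                 collapse = " ")), con)
      }
    }
    writeLines(" $END", con)
    if (!is.null(dipole_derivatives)) {
      writeLines(" $DIPDR", con)
      M <- t(dipole_derivatives)    # 3N x 3
      for (i in seq_len(nrow(M)))
        writeLines(paste(sprintf("% .10e", M[i, ]), collapse = " "), con)
      writeLines(" $END", con)
    }
  }
  invisible(path)
}
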