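# Internal coordinates, Wilson B matrix, potential energy distribution.
#
# PED convention: diagonal-element convention. With s_i = B x_i the internal
# displacement of mode i and F the internal force-constant matrix
# (F = A' H A, A = M^-1 B' (B M^-1 B')^+), the contribution of coordinate s
# to mode i is F_ss s_si^2, normalized over coordinates within the mode.
# Off-diagonal coupling is not folded into the entries; the ratio of the
# diagonal sum to the full lambda_i is reported separately per mode.

#' Generate internal coordinates automatically
#'
#' Bonds by the covalent-radius criterion \code{r < factor * (rA + rB)},
#' angles over all bonded triples, torsions over all bonded quadruples.
#' Near-linear angles (above \code{linear_tol} degrees) are dropped with a
#' warning, as are torsions around them. Disconnected atoms give a warning,
#' not an error.
#'
#' @param mol a [molecule()].
#' @param factor covalent-radius bond factor (default 1.3).
#' @param linear_tol angle (degrees) beyond which a bend is considered
#'   degenerate (default 175).
#' @return data frame of class \code{internal_coords}: \code{kind} (bond,
#'   angle, torsion), atom indices \code{i,j,k,l} (NA where unused) and a
#'   \code{label} such as \code{"r(C2-O3)"}.
#' @export
auto_internal_coords <- function(mol, factor = 1.3, linear_tol = 175) {
  stopifnot(inherits(mol, "molecule"))
  n <- length(mol$elements)
  xyz <- mol$coordinates
  rad <- vapply(mol$elements, function(e) {
    base <- gsub("[0-9]", "", e)
    if (!base %in% names(.COVRAD)) stop("no covalent radius for '", e, "'")
    .COVRAD[[base]]
  }, 0)
  bonded <- matrix(FALSE, n, n)
  rows <- list()
  lab <- function(i) paste0(mol$elements[i], i)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (r < factor * (rad[i] + rad[j])) {
      bonded[i, j] <- bonded[j, i] <- TRUE
      rows[[length(rows) + 1L]] <- data.frame(
        kind = "bond", i = i, j = j, k = NA_integer_, l = NA_integer_,
        label = sprintf("r(%s-%s)", lab(i), lab(j)))
    }
  }
  if (any(rowSums(bonded) == 0))
    warning("disconnected atom(s): ",
            paste(which(rowSums(bonded) == 0), collapse = ", "))
  ang_deg <- function(i, j, k) {
    u <- xyz[i, ] - xyz[j, ]; v <- xyz[k, ] - xyz[j, ]
    cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
    acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  }
  ok_angle <- function(i, j, k) ang_deg(i, j, k) < linear_tol
  for (j in 1:n) {
    nb <- which(bonded[j, ])
    if (length(nb) < 2) next
    for (a in 1:(length(nb) - 1)) for (b in (a + 1):length(nb)) {
      i <- nb[a]; k <- nb[b]
      if (!ok_angle(i, j, k)) {
        warning(sprintf("dropping near-linear angle %s-%s-%s",
                        lab(i), lab(j), lab(k)))
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        kind = "angle", i = i, j = j, k = k, l = NA_integer_,
        label = sprintf("a(%s-%s-%s)", lab(i), lab(j), lab(k)))
    }
  }
  for (j in 1:n) for (k in 1:n) {
    if (k <= j || !bonded[j, k]) next
    for (i in which(bonded[j, ] & seq_len(n) != k))
      for (l in which(bonded[k, ] & seq_len(n) != j)) {
        if (i == l) next
        if (!ok_angle(i, j, k) || !ok_angle(j, k, l)) next
        rows[[length(rows) + 1L]] <- data.frame(
          kind = "torsion", i = i, j = j, k = k, l = l,
          label = sprintf("t(%s-%s-%s-%s)", lab(i), lab(j), lab(k), lab(l)))
      }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("internal_coords", "data.frame")
  out
}

# value + analytic Cartesian gradient of one internal coordinate
.int_coord_grad <- function(kind, idx, xyz) {
  n <- nrow(xyz)
  g <- matrix(0, n, 3)
  if (kind == "bond") {
    i <- idx[1]; j <- idx[2]
    d <- xyz[j, ] - xyz[i, ]; r <- sqrt(sum(d^2))
    if (r < 1e-10) stop("coincident atoms in bond")
    u <- d / r
    g[i, ] <- -u; g[j, ] <- u
    val <- r
  } else if (kind == "angle") {
    i <- idx[1]; j <- idx[2]; k <- idx[3]
    u <- xyz[i, ] - xyz[j, ]; v <- xyz[k, ] - xyz[j, ]
    r1 <- sqrt(sum(u^2)); r2 <- sqrt(sum(v^2))
    u <- u / r1; v <- v / r2
    ct <- pmin(pmax(sum(u * v), -1), 1)
    st <- sqrt(1 - ct^2)
    if (st < 1e-8) stop("degenerate (collinear) angle at atoms ",
                        paste(idx[1:3], collapse = "-"))
    gi <- (ct * u - v) / (r1 * st)
    gk <- (ct * v - u) / (r2 * st)
    g[i, ] <- gi; g[k, ] <- gk; g[j, ] <- -(gi + gk)
    val <- acos(ct)
  } else {                     # torsion
    i <- idx[1]; j <- idx[2]; k <- idx[3]; l <- idx[4]
    F_ <- xyz[i, ] - xyz[j, ]
    G_ <- xyz[j, ] - xyz[k, ]
    H_ <- xyz[l, ] - xyz[k, ]
    A_ <- .cross(F_, G_); B_ <- .cross(H_, G_)
    a2 <- sum(A_^2); b2 <- sum(B_^2); gn <- sqrt(sum(G_^2))
    if (a2 < 1e-16 || b2 < 1e-16)
      stop("degenerate torsion at atoms ", paste(idx, collapse = "-"))
    val <- atan2(sum(.cross(B_, A_) * G_) / gn, sum(A_ * B_))
    p1 <- -(gn / a2) * A_
    p4 <- (gn / b2) * B_
    fg <- sum(F_ * G_); hg <- sum(H_ * G_)
    g[i, ] <- p1
    g[l, ] <- p4
    g[j, ] <- -p1 - (fg / gn^2) * p1 - (hg / gn^2) * p4
    g[k, ] <- -p4 + (fg / gn^2) * p1 + (hg / gn^2) * p4
  }
  list(value = val, grad = as.vector(t(g)))
}

.cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

#' Wilson B matrix
#'
#' Analytic derivatives \eqn{\partial q_s/\partial x} of each internal
#' coordinate with respect to the Cartesian coordinates, one row per
#' coordinate (bond rows dimensionless, angle/torsion rows rad per length
#' unit of \code{coordinates}).
#'
#' @param mol a [molecule()].
#' @param coords an \code{internal_coords} table ([auto_internal_coords()]).
#' @param coordinates optional coordinate matrix overriding
#'   \code{mol$coordinates} (e.g. in bohr for use against a Hessian in
#'   atomic units).
#' @return n_int x 3N numeric matrix with \code{coords$label} as row names.
#' @export
b_matrix <- function(mol, coords, coordinates = NULL) {
  xyz <- coordinates %||% mol$coordinates
  B <- matrix(0, nrow(coords), 3 * nrow(xyz),
              dimnames = list(coords$label, NULL))
  for (s in seq_len(nrow(coords))) {
    idx <- unlist(coords[s, c("i", "j", "k", "l")])
    idx <- idx[!is.na(idx)]
    res <- tryCatch(
      .int_coord_grad(coords$kind[s], idx, xyz),
      error = function(e) stop("B-matrix row for ", coords$label[s], ": ",
                               conditionMessage(e)))
    B[s, ] <- res$grad
  }
  B
}

#' Potential energy distribution of normal modes
#'
#' Decomposes each vibrational mode over the internal coordinates using the
#' diagonal-element convention (see the package vignette): internal force
#' constants \eqn{F = A^T H A} with \eqn{A = M^{-1}B^T(BM^{-1}B^T)^+},
#' internal mode displacements \eqn{s_i = B x_i}, entries
#' \eqn{F_{ss} s_{si}^2} normalized per mode. Redundant coordinate sets are
#' handled through the pseudo-inverse; a rank check verifies the coordinates
#' span the vibrational space.
#'
#' @param modes a [normal_modes()] object (from the same molecule and
#'   Hessian).
#' @param H the Cartesian Hessian, hartree/bohr^2.
#' @param mol the [molecule()].
#' @param coords an \code{internal_coords} table.
#' @return object of class \code{ped_table}: \code{ped} (modes x coordinates
#'   matrix of fractional contributions), \code{summary} data frame (mode
#'   index, frequency, dominant coordinate and its fraction, diagonal
#'   fraction of lambda), and the coordinate table.
#' @export
ped <- function(modes, H, mol, coords) {
  stopifnot(inherits(modes, "normal_modes"), inherits(mol, "molecule"))
  n3 <- 3 * length(mol$elements)
  xyz_bohr <- mol$coordinates * .CONST$ang_to_bohr
  B <- b_matrix(mol, coords, coordinates = xyz_bohr)
  minv <- rep(1 / modes$masses, each = 3L)
  # rank check on B M^-1/2: internal coordinates must span the vibrations
  sv <- svd(sweep(B, 2, sqrt(minv), `*`))$d
  n_vib <- sum(abs(modes$frequencies_unscaled) >= 1)
  rank <- sum(sv > max(sv) * 1e-10)
  if (rank < n_vib) {
    missing <- character(0)
    if (!any(coords$kind == "torsion")) missing <- c(missing, "torsions")
    if (!any(coords$kind == "angle")) missing <- c(missing, "angles")
    stop("internal coordinates rank ", rank, " < ", n_vib,
         " vibrational modes",
         if (length(missing)) paste0("; consider adding ",
                                     paste(missing, collapse = ", ")))
  }
  G <- B %*% (minv * t(B))                      # B M^-1 B'
  A <- (minv * t(B)) %*% .pinv(G)               # M^-1 B' (B M^-1 B')^+
  Fint <- t(A) %*% H %*% A
  vib <- which(abs(modes$frequencies_unscaled) >= 1)
  lambda <- sign(modes$frequencies_unscaled) *
    (modes$frequencies_unscaled / .CONST$freq_cm)^2
  P <- matrix(0, length(vib), nrow(coords),
              dimnames = list(NULL, coords$label))
  diag_frac <- numeric(length(vib))
  Fss <- diag(Fint)
  for (t in seq_along(vib)) {
    i <- vib[t]
    s <- as.vector(B %*% modes$displacements[, i])
    contrib <- Fss * s^2
    tot <- sum(contrib)
    if (tot <= 0) { P[t, ] <- 0; next }
    P[t, ] <- contrib / tot
    diag_frac[t] <- tot / abs(lambda[i])
  }
  dom <- apply(P, 1, which.max)
  summary <- data.frame(
    mode = vib,
    frequency = modes$frequencies[vib],
    dominant = coords$label[dom],
    dominant_fraction = P[cbind(seq_along(vib), dom)],
    diag_fraction = diag_frac)
  structure(list(ped = P, summary = summary, coords = coords),
            class = "ped_table")
}

.pinv <- function(M, tol = 1e-10) {
  s <- svd(M)
  keep <- s$d > max(s$d) * tol
  s$v[, keep, drop = FALSE] %*% (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' @export
print.ped_table <- function(x, ...) {
  cat(sprintf("<ped_table> %d modes x %d internal coordinates\n",
              nrow(x$ped), ncol(x$ped)))
  print(utils::head(x$summary, 15), digits = 4)
  invisible(x)
}

#' Classify modes as C=O-like or C=N-like from PED and isotope shift
#'
#' Combines PED dominance with the 15N isotope shift: a mode is labelled
#' \code{"C=O"} when its shift magnitude is at most \code{small} cm^-1 AND
#' its dominant internal coordinate matches \code{co_pattern}; \code{"C=N"}
#' when the shift is at least \code{large} cm^-1 AND the dominant coordinate
#' matches \code{cn_pattern}. Everything else -- intermediate shifts or
#' conflicting evidence -- is labelled \code{"ambiguous"}, never silently
#' forced.
#'
#' @param ped_table a [ped()] result for the reference isotopomer.
#' @param shift_table a [pair_modes()] or [isotope_shift_table()] result
#'   (columns \code{mode_a}, \code{shift}).
#' @param rules list with \code{co_pattern}, \code{cn_pattern} (regular
#'   expressions matched against dominant coordinate labels) and thresholds
#'   \code{small}, \code{large} in cm^-1 (defaults 3 and 10).
#' @return data frame: mode, frequency, shift, dominant coordinate, label.
#' @export
assign_band <- function(ped_table, shift_table,
                        rules = list(co_pattern = "r\\(C[0-9]*-O",
                                     cn_pattern = "r\\(C[0-9]*-N",
                                     small = 3, large = 10)) {
  stopifnot(inherits(ped_table, "ped_table"))
  small <- rules$small %||% 3
  large <- rules$large %||% 10
  sm <- ped_table$summary
  out <- merge(sm, shift_table[, c("mode_a", "shift")],
               by.x = "mode", by.y = "mode_a")
  lab <- character(nrow(out))
  for (r in seq_len(nrow(out))) {
    is_co <- grepl(rules$co_pattern, out$dominant[r])
    is_cn <- grepl(rules$cn_pattern, out$dominant[r])
    sh <- abs(out$shift[r])
    lab[r] <- if (sh <= small && is_co) "C=O"
              else if (sh >= large && is_cn) "C=N"
              else "ambiguous"
  }
  data.frame(mode = out$mode, frequency = out$frequency, shift = out$shift,
             dominant = out$dominant, label = lab)
}
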