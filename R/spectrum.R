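# Spectrum container and file I/O (JCAMP-DX 4.24 subset + two-column CSV).

#' Construct an infrared spectrum
#'
#' A spectrum is a sampled absorbance (or delta-absorbance) trace on a strictly
#' monotone wavenumber axis. On construction the axis is normalized to the
#' FTIR display convention, descending wavenumber; the input ordering is
#' recorded in \code{meta$input_order}.
#'
#' @param axis numeric, wavenumbers in cm^-1, strictly monotone (either
#'   direction; stored descending).
#' @param values numeric, absorbance; same length as \code{axis}, all finite.
#' @param meta named list of free-form labels (sample, isotopomer, ...).
#' @return object of class \code{ir_spectrum} with elements \code{axis},
#'   \code{values}, \code{meta}.
#' @export
#' @examples
#' s <- ir_spectrum(c(1700, 1699, 1698), c(0.1, 0.2, 0.15))
#' s$axis
ir_spectrum <- function(axis, values, meta = list()) {
  axis <- as.numeric(axis); values <- as.numeric(values)
  if (length(axis) != length(values))
    stop("axis and values must have equal length")
  if (length(axis) < 2L) stop("a spectrum needs at least 2 points")
  if (!all(is.finite(axis)) || !all(is.finite(values)))
    stop("axis and values must be finite")
  d <- diff(axis)
  if (all(d > 0)) {
    meta$input_order <- meta$input_order %||% "ascending"
    axis <- rev(axis); values <- rev(values)
  } else if (all(d < 0)) {
    meta$input_order <- meta$input_order %||% "descending"
  } else {
    stop("axis must be strictly monotone")
  }
  structure(list(axis = axis, values = values, meta = meta),
            class = "ir_spectrum")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ir_spectrum <- function(x, ...) {
  cat(sprintf("<ir_spectrum> %d points, %.1f .. %.1f cm^-1\n",
              length(x$axis), x$axis[1], x$axis[length(x$axis)]))
  if (length(x$meta)) {
    keep <- setdiff(names(x$meta), "input_order")
    for (k in keep) cat(sprintf("  %s: %s\n", k, format(x$meta[[k]])[1]))
  }
  invisible(x)
}

#' @export
as.data.frame.ir_spectrum <- function(x, ...) {
  data.frame(wavenumber = x$axis, absorbance = x$values)
}

#' @export
plot.ir_spectrum <- function(x, ..., xlab = expression(tilde(nu) / cm^-1),
                             ylab = "absorbance") {
  plot(x$axis, x$values, type = "l", xlim = rev(range(x$axis)),
       xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Wavenumber window
#'
#' Inclusive wavenumber interval \code{[lo, hi]} in cm^-1. Most functions also
#' accept a plain length-2 numeric in either order.
#'
#' @param hi upper bound, cm^-1.
#' @param lo lower bound, cm^-1; must satisfy \code{hi > lo}.
#' @return object of class \code{wn_window}.
#' @export
#' @examples
#' wn_window(1700, 1650)
wn_window <- function(hi, lo) {
  if (!is.finite(hi) || !is.finite(lo) || hi <= lo)
    stop("window requires finite hi > lo")
  structure(list(hi = hi, lo = lo), class = "wn_window")
}

as_window <- function(w) {
  if (inherits(w, "wn_window")) return(w)
  if (is.numeric(w) && length(w) == 2L) return(wn_window(max(w), min(w)))
  stop("not a window: supply wn_window(hi, lo) or a length-2 numeric")
}

#' Read a spectrum from file
#'
#' Supports a JCAMP-DX 4.24 subset (\code{##XYDATA=(X++(Y..Y))} in AFFN form
#' and \code{##XYPOINTS=(XY..XY)}) and two-column CSV with header
#' \code{wavenumber_cm-1,absorbance}. The axis is normalized to descending
#' wavenumber; the ordering found in the file is kept in
#' \code{meta$input_order}.
#'
#' @param path file path.
#' @param format \code{"auto"} (by extension), \code{"jcamp"} or \code{"csv"}.
#' @return an [ir_spectrum].
#' @seealso [write_spectrum()]
#' @export
read_spectrum <- function(path, format = c("auto", "jcamp", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(jdx|dx|jcm|jcamp)$", tolower(path))) "jcamp" else "csv"
  }
  if (format == "csv") .read_spectrum_csv(path) else .read_spectrum_jcamp(path)
}

.read_spectrum_csv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty file: ", path)
  start <- 1L
  if (grepl("[A-Za-z]", lines[1])) start <- 2L  # header row
  n <- length(lines) - start + 1L
  if (n < 2L) stop("need at least two data rows in ", path)
  ax <- numeric(n); val <- numeric(n)
  for (i in seq_len(n)) {
    ln <- lines[start + i - 1L]
    parts <- strsplit(ln, "[,;\t ]+")[[1]]
    parts <- parts[nzchar(parts)]
    x <- suppressWarnings(as.numeric(parts))
    if (length(x) < 2L || anyNA(x[1:2]))
      stop("parse error in ", path, " at line ", start + i - 1L, ": '", ln, "'")
    ax[i] <- x[1]; val[i] <- x[2]
  }
  ir_spectrum(ax, val, meta = list(source = path, format = "csv"))
}

.jcamp_field <- function(lines, key) {
  hit <- grep(paste0("^##", key, "="), lines, value = TRUE)
  if (!length(hit)) return(NULL)
  sub(paste0("^##", key, "="), "", hit[1])
}

.read_spectrum_jcamp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  i_xy <- grep("^##XYDATA=", lines)
  i_xp <- grep("^##XYPOINTS=", lines)
  i_end <- grep("^##END", lines)
  if (!length(i_end)) i_end <- length(lines) + 1L
  if (length(i_xy)) {
    xf <- as.numeric(.jcamp_field(lines, "XFACTOR") %||% "1")
    yf <- as.numeric(.jcamp_field(lines, "YFACTOR") %||% "1")
    dx <- as.numeric(.jcamp_field(lines, "DELTAX") %||% NA)
    body <- lines[(i_xy[1] + 1L):(i_end[1] - 1L)]
    body <- body[nzchar(trimws(body)) & !grepl("^##", body)]
    ax <- numeric(0); val <- numeric(0)
    for (k in seq_along(body)) {
      toks <- strsplit(trimws(body[k]), "[,\t ]+")[[1]]
      num <- suppressWarnings(as.numeric(toks))
      if (anyNA(num))
        stop("parse error in ", path, " (XYDATA line ", k, "): '", body[k], "'")
      if (length(num) < 2L) next
      x0 <- num[1] * xf
      ys <- num[-1] * yf
      if (is.na(dx)) stop("XYDATA without ##DELTAX= in ", path)
      ax <- c(ax, x0 + dx * xf * (seq_along(ys) - 1))
      val <- c(val, ys)
    }
    if (length(ax) < 2L) stop("no XYDATA points parsed from ", path)
    return(ir_spectrum(ax, val, meta = list(source = path, format = "jcamp")))
  }
  if (length(i_xp)) {
    body <- lines[(i_xp[1] + 1L):(i_end[1] - 1L)]
    body <- body[nzchar(trimws(body)) & !grepl("^##", body)]
    toks <- unlist(strsplit(trimws(body), "[;,\t ]+"))
    toks <- toks[nzchar(toks)]
    num <- suppressWarnings(as.numeric(toks))
    if (anyNA(num)) {
      bad <- which(is.na(num))[1]
      stop("parse error in ", path, " (XYPOINTS token ", bad, ")")
    }
    if (length(num) %% 2L != 0L) stop("odd token count in XYPOINTS of ", path)
    ax <- num[seq(1, length(num), by = 2)]
    val <- num[seq(2, length(num), by = 2)]
    return(ir_spectrum(ax, val, meta = list(source = path, format = "jcamp")))
  }
  stop("no ##XYDATA= or ##XYPOINTS= block found in ", path)
}

#' Write a spectrum to file
#'
#' CSV uses the header \code{wavenumber_cm-1,absorbance}; JCAMP-DX is written
#' as an \code{##XYPOINTS=(XY..XY)} record in AFFN with full double precision,
#' so that a write/read round trip reproduces axis and values to better than
#' 1e-9.
#'
#' @param s an [ir_spectrum].
#' @param path output path.
#' @param format \code{"auto"} (by extension), \code{"jcamp"} or \code{"csv"}.
#' @param title title record for JCAMP output.
#' @return \code{path}, invisibly.
#' @export
write_spectrum <- function(s, path, format = c("auto", "jcamp", "csv"),
                           title = "isovib spectrum") {
  stopifnot(inherits(s, "ir_spectrum"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(jdx|dx|jcm|jcamp)$", tolower(path))) "jcamp" else "csv"
  }
  if (format == "csv") {
    con <- file(path, "w"); on.exit(close(con))
    writeLines("wavenumber_cm-1,absorbance", con)
    writeLines(sprintf("%.10g,%.12g", s$axis, s$values), con)
  } else {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(c(
      paste0("##TITLE=", title),
      "##JCAMP-DX=4.24",
      "##DATA TYPE=INFRARED SPECTRUM",
      "##XUNITS=1/CM",
      "##YUNITS=ABSORBANCE",
      sprintf("##NPOINTS=%d", length(s$axis)),
      sprintf("##FIRSTX=%.10g", s$axis[1]),
      sprintf("##LASTX=%.10g", s$axis[length(s$axis)]),
      "##XYPOINTS=(XY..XY)"), con)
    writeLines(sprintf("%.12g, %.14g", s$axis, s$values), con)
    writeLines("##END=", con)
  }
  invisible(path)
}

#' Resample a spectrum onto a new wavenumber grid
#'
#' Linear interpolation; exact where the grid hits existing axis points.
#' Extrapolation is refused. Linear (not spline) interpolation is used so that
#' subsequent subtraction of two resampled traces cannot pick up overshoot
#' artifacts.
#'
#' @param s an [ir_spectrum].
#' @param grid numeric wavenumber axis within the span of \code{s}.
#' @return an [ir_spectrum] on \code{grid} (stored descending).
#' @export
resample <- function(s, grid) {
  stopifnot(inherits(s, "ir_spectrum"))
  grid <- as.numeric(grid)
  lo <- min(s$axis); hi <- max(s$axis)
  eps <- 1e-9 * max(abs(c(lo, hi)), 1)
  if (any(grid < lo - eps | grid > hi + eps))
    stop("grid extends outside the spectrum span [", lo, ", ", hi, "]")
  grid <- pmin(pmax(grid, lo), hi)
  grid <- sort(unique(grid), decreasing = TRUE)
  y <- stats::approx(rev(s$axis), rev(s$values), xout = grid,
                     method = "linear", ties = "ordered")$y
  if (length(grid) == 1L) {
    # degenerate single-point query: return a minimal spectrum-like object
    return(structure(list(axis = grid, values = y, meta = s$meta),
                     class = "ir_spectrum"))
  }
  ir_spectrum(grid, y, meta = s$meta)
}

#' Crop a spectrum to a wavenumber window
#'
#' Keeps points with \code{lo <= wavenumber <= hi}, bounds inclusive,
#' preserving order.
#'
#' @param s an [ir_spectrum].
#' @param w a [wn_window()] or length-2 numeric.
#' @return an [ir_spectrum].
#' @export
crop <- function(s, w) {
  stopifnot(inherits(s, "ir_spectrum"))
  w <- as_window(w)
  keep <- s$axis >= w$lo & s$axis <= w$hi
  if (sum(keep) < 2L)
    stop("crop window [", w$lo, ", ", w$hi, "] retains fewer than 2 points")
  ir_spectrum(s$axis[keep], s$values[keep], meta = s$meta)
}
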