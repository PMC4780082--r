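# Constrained sum-of-Lorentzians deconvolution of double-difference spectra.
#
# The model: each isotope-edited difference band contributes a pair of
# Lorentzians of opposite sign whose areas are tied to be equal in magnitude
# (the oscillator strength is taken to be independent of the labelling), and
# all bands share one FWHM. Centers and areas may be fixed individually, so
# the deconvolution of a BLUF double difference -- six Lorentzians, four
# experimentally determined centers fixed, one area fixed, unity area ratios,
# one shared width -- has exactly five free parameters.

#' Declare a band pair for the deconvolution model
#'
#' A pair is one positive and one negative Lorentzian with equal area
#' magnitude (unity area-ratio constraint, applied by reparameterization:
#' the pair carries a single area parameter).
#'
#' @param pos center of the positive band, cm^-1.
#' @param neg center of the negative band, cm^-1.
#' @param area starting area magnitude (absorbance * cm^-1).
#' @param fix_centers logical, length 1 or 2 (positive band, negative band):
#'   keep the center(s) fixed during fitting.
#' @param fix_area keep the pair area fixed.
#' @param label band-pair label used in reports.
#' @return an object of class \code{band_pair}.
#' @export
#' @examples
#' band_pair(1697, 1689, area = 1, fix_centers = TRUE, fix_area = TRUE)
band_pair <- function(pos, neg, area, fix_centers = FALSE, fix_area = FALSE,
                      label = NULL) {
  if (length(fix_centers) == 1L) fix_centers <- rep(fix_centers, 2L)
  if (area <= 0) stop("pair area magnitude must be positive")
  structure(list(pos = pos, neg = neg, area = area,
                 fix_centers = fix_centers, fix_area = fix_area,
                 label = label %||% sprintf("%.0f/%.0f", pos, neg)),
            class = "band_pair")
}

#' Declare an unpaired band
#'
#' @param xc center, cm^-1.
#' @param area signed starting area.
#' @param fix_center,fix_area fix the respective parameter during fitting.
#' @param label band label.
#' @return an object of class \code{single_band}.
#' @export
single_band <- function(xc, area, fix_center = FALSE, fix_area = FALSE,
                        label = NULL) {
  if (area == 0) stop("band area must be nonzero")
  structure(list(xc = xc, area = area, fix_center = fix_center,
                 fix_area = fix_area, label = label %||% sprintf("%.0f", xc)),
            class = "single_band")
}

#' Assemble a deconvolution configuration
#'
#' Collects band pairs and single bands, the fit window, the width model and
#' optimizer settings into a configuration for [fit_bands()].
#'
#' @param ... [band_pair()] and/or [single_band()] objects.
#' @param window fit window ([wn_window()] or length-2 numeric).
#' @param fwhm starting FWHM, cm^-1 (shared or per band).
#' @param shared_fwhm all bands share one FWHM parameter (default TRUE).
#' @param fix_fwhm keep the (shared) FWHM fixed.
#' @param n_starts number of multistart optimizations (the first uses the
#'   nominal starting values, the rest perturb them).
#' @param center_jitter max center perturbation of free centers across
#'   multistarts, cm^-1.
#' @param area_jitter max relative area perturbation.
#' @param fwhm_jitter max relative FWHM perturbation.
#' @param max_iter optimizer iteration cap per start.
#' @return an object of class \code{fit_config}.
#' @export
fit_config <- function(..., window, fwhm = 7, shared_fwhm = TRUE,
                       fix_fwhm = FALSE, n_starts = 8, center_jitter = 3,
                       area_jitter = 0.5, fwhm_jitter = 0.5, max_iter = 200) {
  parts <- list(...)
  if (!length(parts)) stop("at least one band_pair or single_band is required")
  rows <- list()
  pair_id <- 0L
  for (p in parts) {
    if (inherits(p, "band_pair")) {
      pair_id <- pair_id + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        label = p$label, pair = pair_id, role = "pos", xc0 = p$pos,
        A0 = p$area, fix_center = p$fix_centers[1], fix_area = p$fix_area)
      rows[[length(rows) + 1L]] <- data.frame(
        label = p$label, pair = pair_id, role = "neg", xc0 = p$neg,
        A0 = -p$area, fix_center = p$fix_centers[2], fix_area = p$fix_area)
    } else if (inherits(p, "single_band")) {
      rows[[length(rows) + 1L]] <- data.frame(
        label = p$label, pair = NA_integer_, role = "single", xc0 = p$xc,
        A0 = p$area, fix_center = p$fix_center, fix_area = p$fix_area)
    } else stop("arguments must be band_pair() or single_band() objects")
  }
  bands <- do.call(rbind, rows)
  if (fwhm <= 0) stop("starting FWHM must be positive")
  cfg <- structure(list(bands = bands, window = as_window(window),
                        fwhm = fwhm, shared_fwhm = shared_fwhm,
                        fix_fwhm = fix_fwhm, n_starts = n_starts,
                        center_jitter = center_jitter,
                        area_jitter = area_jitter, fwhm_jitter = fwhm_jitter,
                        max_iter = max_iter),
                   class = "fit_config")
  if (count_free_parameters(cfg) < 0L) stop("over-constrained configuration")
  cfg
}

#' Six-Lorentzian configuration for a BLUF double-difference spectrum
#'
#' The deconvolution model for the 1650-1700 cm^-1 region of the BlrB-type
#' double difference: three band pairs with unity area ratios and one shared
#' FWHM. The four experimentally resolved centers (1697/1689 and 1667/1660
#' cm^-1; the latter pair has its positive lobe at the lower wavenumber) and
#' the area of the 1697 cm^-1 pair are fixed, leaving five free parameters:
#' the two centers of the hidden pair, two pair areas, and the shared width.
#'
#' @param hidden_start starting centers (positive, negative) of the hidden
#'   band pair, cm^-1.
#' @param areas starting area magnitudes of the three pairs (flavin C4=O
#'   light-state pair, dark-state C=O pair, hidden C=N pair).
#' @param fwhm starting shared FWHM, cm^-1.
#' @param window fit window, cm^-1.
#' @param ... passed on to [fit_config()].
#' @return a \code{fit_config}.
#' @export
#' @examples
#' cfg <- bluf_dd_config()
#' count_free_parameters(cfg)  # 5
bluf_dd_config <- function(hidden_start = c(1691, 1672), areas = c(1, 1.3, 0.8),
                           fwhm = 7, window = c(1650, 1700), ...) {
  fit_config(
    band_pair(1697, 1689, area = areas[1], fix_centers = TRUE,
              fix_area = TRUE, label = "flavin_C4O_light"),
    band_pair(1660, 1667, area = areas[2], fix_centers = TRUE,
              label = "dark_CO"),
    band_pair(hidden_start[1], hidden_start[2], area = areas[3],
              label = "hidden_CN"),
    window = window, fwhm = fwhm, shared_fwhm = TRUE, ...)
}

#' Count the free parameters of a deconvolution configuration
#'
#' Three parameters per band (center, area, width), minus one per fixed
#' center, one per fixed area, one per unity-area pair, and \code{n - 1} when
#' all \code{n} bands share one FWHM (minus one more if the shared width is
#' itself fixed).
#'
#' @param cfg a [fit_config()].
#' @return integer count.
#' @export
count_free_parameters <- function(cfg) {
  stopifnot(inherits(cfg, "fit_config"))
  b <- cfg$bands
  n <- nrow(b)
  n_pairs <- length(unique(b$pair[!is.na(b$pair)]))
  # each pair's two areas carry one fix_area flag; count fixed areas once per
  # pair and once per fixed single band
  fixed_areas <- 0L
  for (pid in unique(b$pair[!is.na(b$pair)])) {
    if (any(b$fix_area[which(b$pair == pid)])) fixed_areas <- fixed_areas + 1L
  }
  fixed_areas <- fixed_areas + sum(b$fix_area[is.na(b$pair)])
  free <- 3L * n - sum(b$fix_center) - fixed_areas - n_pairs
  if (cfg$shared_fwhm) free <- free - (n - 1L) - as.integer(cfg$fix_fwhm)
  free
}

# --- parameter vector <-> band table ---------------------------------------

.param_skeleton <- function(cfg) {
  b <- cfg$bands
  nm <- character(0)
  for (i in seq_len(nrow(b))) {
    if (!b$fix_center[i])
      nm <- c(nm, paste0("center.", b$label[i],
                         if (b$role[i] == "single") "" else paste0(".", b$role[i])))
  }
  done_pairs <- integer(0)
  for (i in seq_len(nrow(b))) {
    if (!is.na(b$pair[i])) {
      if (b$pair[i] %in% done_pairs) next
      done_pairs <- c(done_pairs, b$pair[i])
      if (!any(b$fix_area[b$pair == b$pair[i]]))
        nm <- c(nm, paste0("area.", b$label[i]))
    } else if (!b$fix_area[i]) {
      nm <- c(nm, paste0("area.", b$label[i]))
    }
  }
  if (cfg$shared_fwhm) {
    if (!cfg$fix_fwhm) nm <- c(nm, "fwhm")
  } else {
    nm <- c(nm, paste0("fwhm.", b$label, ifelse(b$role == "single", "",
                                                paste0(".", b$role))))
  }
  nm
}

.start_values <- function(cfg) {
  b <- cfg$bands
  nm <- .param_skeleton(cfg)
  th <- numeric(length(nm)); names(th) <- nm
  for (i in seq_len(nrow(b))) {
    key <- paste0("center.", b$label[i],
                  if (b$role[i] == "single") "" else paste0(".", b$role[i]))
    if (key %in% nm) th[key] <- b$xc0[i]
    akey <- paste0("area.", b$label[i])
    if (akey %in% nm) th[akey] <- abs(b$A0[i]) * if (b$role[i] == "single")
      sign(b$A0[i]) else 1
  }
  if ("fwhm" %in% nm) th["fwhm"] <- cfg$fwhm
  wkeys <- grep("^fwhm\\.", nm, value = TRUE)
  th[wkeys] <- cfg$fwhm
  th
}

# Expand a parameter vector into the full band table (xc, A, w per band).
.assemble_bands <- function(cfg, theta) {
  b <- cfg$bands
  xc <- b$xc0; A <- b$A0; w <- rep(cfg$fwhm, nrow(b))
  for (i in seq_len(nrow(b))) {
    ckey <- paste0("center.", b$label[i],
                   if (b$role[i] == "single") "" else paste0(".", b$role[i]))
    if (ckey %in% names(theta)) xc[i] <- theta[[ckey]]
    akey <- paste0("area.", b$label[i])
    if (akey %in% names(theta)) {
      a <- theta[[akey]]
      A[i] <- switch(b$role[i], pos = a, neg = -a, single = a)
    }
    if (cfg$shared_fwhm) {
      if ("fwhm" %in% names(theta)) w[i] <- theta[["fwhm"]]
    } else {
      wkey <- paste0("fwhm.", b$label[i],
                     if (b$role[i] == "single") "" else paste0(".", b$role[i]))
      if (wkey %in% names(theta)) w[i] <- theta[[wkey]]
    }
  }
  data.frame(label = b$label, pair = b$pair, role = b$role,
             xc = xc, A = A, w = w)
}

.model_values <- function(cfg, theta, x) {
  bd <- .assemble_bands(cfg, theta)
  y <- rep(0, length(x))
  for (i in seq_len(nrow(bd))) y <- y + lorentzian(x, bd$xc[i], bd$A[i], bd$w[i])
  y
}

.model_jacobian <- function(cfg, theta, x) {
  bd <- .assemble_bands(cfg, theta)
  J <- matrix(0, length(x), length(theta),
              dimnames = list(NULL, names(theta)))
  for (i in seq_len(nrow(bd))) {
    g <- .lor_grad(x, bd$xc[i], bd$A[i], bd$w[i])
    ckey <- paste0("center.", bd$label[i],
                   if (bd$role[i] == "single") "" else paste0(".", bd$role[i]))
    if (ckey %in% names(theta)) J[, ckey] <- J[, ckey] + g$dxc
    akey <- paste0("area.", bd$label[i])
    if (akey %in% names(theta)) {
      s <- switch(bd$role[i], pos = 1, neg = -1, single = 1)
      J[, akey] <- J[, akey] + s * g$dA
    }
    if (cfg$shared_fwhm) {
      if ("fwhm" %in% names(theta)) J[, "fwhm"] <- J[, "fwhm"] + g$dw
    } else {
      wkey <- paste0("fwhm.", bd$label[i],
                     if (bd$role[i] == "single") "" else paste0(".", bd$role[i]))
      if (wkey %in% names(theta)) J[, wkey] <- J[, wkey] + g$dw
    }
  }
  J
}

# --- the fit ----------------------------------------------------------------

#' Fit a constrained sum-of-Lorentzians model to a double-difference spectrum
#'
#' Least-squares deconvolution over the configuration's window. Constraints
#' (fixed centers and areas, unity pair ratios, one shared FWHM) are applied
#' by exact reparameterization, so only the genuinely free parameters are
#' optimized, by Levenberg-Marquardt with the analytic Jacobian and a seeded
#' multistart over perturbed starting values (the hidden-pair centers overlap
#' fixed bands and single starts can stall in local minima).
#'
#' @param dd the double-difference [ir_spectrum] (see [double_difference()]).
#' @param cfg a [fit_config()], e.g. [bluf_dd_config()].
#' @param seed integer seed for the multistart perturbations (optional; when
#'   missing the current RNG stream is used).
#' @return an object of class \code{bandfit}; see [summary.bandfit()],
#'   [coef.bandfit()], [predict.bandfit()], [plot.bandfit()].
#' @export
#' @examples
#' truth <- data.frame(xc = c(1697, 1689, 1660, 1667, 1691, 1672),
#'                     A = c(1, -1, 1.3, -1.3, 0.8, -0.8), w = 7)
#' dd <- model_eval(truth, seq(1700, 1650, by = -0.5))
#' fit <- fit_bands(dd, bluf_dd_config(), seed = 1)
#' coef(fit)["fwhm"]
fit_bands <- function(dd, cfg, seed = NULL) {
  stopifnot(inherits(dd, "ir_spectrum"), inherits(cfg, "fit_config"))
  p <- count_free_parameters(cfg)
  if (p <= 0L) stop("configuration has no free parameters")
  ddw <- crop(dd, cfg$window)
  x <- ddw$axis; yobs <- ddw$values
  if (length(x) <= p)
    stop("fewer data points in the window than free parameters")
  theta0 <- .start_values(cfg)

  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old_seed <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }

  ctrl <- minpack.lm::nls.lm.control(maxiter = cfg$max_iter, ftol = 1e-14,
                                     ptol = 1e-14)
  lower <- rep(-Inf, length(theta0)); upper <- rep(Inf, length(theta0))
  names(lower) <- names(upper) <- names(theta0)
  wk <- grepl("^fwhm", names(theta0))
  lower[wk] <- 1e-2
  ak <- grepl("^area\\.", names(theta0))
  # pair areas are magnitudes; singles keep their sign freedom
  pair_labels <- unique(cfg$bands$label[!is.na(cfg$bands$pair)])
  ak_pair <- names(theta0) %in% paste0("area.", pair_labels)
  lower[ak_pair] <- 0

  runs <- vector("list", cfg$n_starts)
  for (k in seq_len(cfg$n_starts)) {
    th <- theta0
    if (k > 1L) {
      ck <- grepl("^center\\.", names(th))
      th[ck] <- th[ck] + stats::runif(sum(ck), -cfg$center_jitter,
                                      cfg$center_jitter)
      th[ak] <- th[ak] * (1 + stats::runif(sum(ak), -cfg$area_jitter,
                                           cfg$area_jitter))
      th[wk] <- th[wk] * (1 + stats::runif(sum(wk), 0, cfg$fwhm_jitter))
    }
    res <- tryCatch(
      minpack.lm::nls.lm(
        par = th,
        fn = function(par) .model_values(cfg, par, x) - yobs,
        jac = function(par) .model_jacobian(cfg, par, x),
        lower = lower, upper = upper, control = ctrl),
      error = function(e) NULL)
    runs[[k]] <- res
  }
  ok <- !vapply(runs, is.null, logical(1))
  if (!any(ok)) stop("all multistart optimizations failed")
  rss <- vapply(runs, function(r) if (is.null(r)) Inf else r$deviance, 0)
  best <- which.min(rss)
  fitres <- runs[[best]]
  theta <- stats::coef(fitres)

  bands <- .assemble_bands(cfg, theta)
  # canonicalize: a pair area driven to its zero bound with both centers free
  # keeps role labels meaningful; report as-is otherwise
  fittedv <- .model_values(cfg, theta, x)
  resid <- yobs - fittedv
  n <- length(x)
  J <- .model_jacobian(cfg, theta, x)
  vcov <- tryCatch({
    s2 <- sum(resid^2) / max(n - p, 1L)
    s2 * solve(crossprod(J))
  }, error = function(e) matrix(NA_real_, p, p))
  se <- sqrt(pmax(diag(vcov), 0))
  names(se) <- names(theta)

  structure(list(
    bands = bands, coefficients = theta, se = se, vcov = vcov,
    free_parameter_count = p, residual_rms = sqrt(mean(resid^2)),
    rss = sum(resid^2), converged = fitres$info %in% 1:4,
    info = fitres$info, message = fitres$message,
    data = ddw, fitted.values = fittedv, residuals = resid,
    config = cfg, multistart = data.frame(start = seq_along(rss), rss = rss),
    best_start = best, call = match.call()),
    class = "bandfit")
}

#' @export
print.bandfit <- function(x, ...) {
  cat("Constrained Lorentzian band fit\n")
  cat(sprintf("  %d bands, %d free parameters, %d points in window [%g, %g] cm^-1\n",
              nrow(x$bands), x$free_parameter_count, length(x$data$axis),
              x$config$window$lo, x$config$window$hi))
  cat(sprintf("  residual rms %.3g, converged: %s\n", x$residual_rms,
              x$converged))
  print(x$bands, digits = 6)
  invisible(x)
}

#' Summarize a band fit
#'
#' @param object a \code{bandfit}.
#' @param ... unused.
#' @return a \code{summary.bandfit} with the band table, free-parameter
#'   estimates and standard errors.
#' @export
summary.bandfit <- function(object, ...) {
  tab <- cbind(estimate = object$coefficients, std_error = object$se)
  structure(list(bands = object$bands, coefficients = tab,
                 free_parameter_count = object$free_parameter_count,
                 residual_rms = object$residual_rms,
                 converged = object$converged,
                 multistart = object$multistart),
            class = "summary.bandfit")
}

#' @export
print.summary.bandfit <- function(x, ...) {
  cat("Constrained Lorentzian band fit\n\nBands:\n")
  print(x$bands, digits = 6)
  cat(sprintf("\nFree parameters (%d):\n", x$free_parameter_count))
  print(x$coefficients, digits = 5)
  cat(sprintf("\nresidual rms: %.4g; converged: %s; best of %d starts\n",
              x$residual_rms, x$converged, nrow(x$multistart)))
  invisible(x)
}

#' @export
coef.bandfit <- function(object, ...) object$coefficients

#' @export
vcov.bandfit <- function(object, ...) object$vcov

#' @export
fitted.bandfit <- function(object, ...) object$fitted.values

#' @export
residuals.bandfit <- function(object, ...) object$residuals

#' @export
deviance.bandfit <- function(object, ...) object$rss

#' @export
df.residual.bandfit <- function(object, ...)
  length(object$data$axis) - object$free_parameter_count

#' @export
nobs.bandfit <- function(object, ...) length(object$data$axis)

#' Evaluate a fitted band model
#'
#' @param object a \code{bandfit}.
#' @param newdata optional wavenumber grid (numeric) or [ir_spectrum] whose
#'   axis is used; defaults to the fitted window grid.
#' @param ... unused.
#' @return an [ir_spectrum] of model values.
#' @export
predict.bandfit <- function(object, newdata = NULL, ...) {
  grid <- if (is.null(newdata)) object$data$axis
          else if (inherits(newdata, "ir_spectrum")) newdata$axis
          else as.numeric(newdata)
  model_eval(object$bands, grid)
}

#' Plot a band fit: data, model and components
#'
#' @param x a \code{bandfit}.
#' @param components draw the individual Lorentzians.
#' @param ... passed to \code{plot}.
#' @export
plot.bandfit <- function(x, components = TRUE, ...) {
  s <- x$data
  plot(s$axis, s$values, type = "l", xlim = rev(range(s$axis)),
       xlab = expression(tilde(nu) / cm^-1), ylab = expression(Delta * Delta * A),
       ...)
  graphics::lines(s$axis, x$fitted.values, col = "red")
  if (components) {
    for (i in seq_len(nrow(x$bands))) {
      graphics::lines(s$axis, lorentzian(s$axis, x$bands$xc[i], x$bands$A[i],
                                         x$bands$w[i]),
                      col = "grey50", lty = 2)
    }
  }
  invisible(x)
}

#' Simulate noisy replicates from a fitted band model
#'
#' Draws Gaussian noise of standard deviation \code{noise_sd} (default: the
#' fit's residual rms) around the fitted model on the fitted grid.
#'
#' @param object a \code{bandfit}.
#' @param nsim number of replicates.
#' @param seed optional RNG seed.
#' @param noise_sd noise standard deviation, absorbance.
#' @param ... unused.
#' @return a list of [ir_spectrum] replicates.
#' @export
simulate.bandfit <- function(object, nsim = 1, seed = NULL, noise_sd = NULL,
                             ...) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old_seed <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  sd <- noise_sd %||% object$residual_rms
  grid <- object$data$axis
  mu <- object$fitted.values
  lapply(seq_len(nsim), function(i)
    ir_spectrum(grid, mu + stats::rnorm(length(grid), 0, sd)))
}
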