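# Detection and photon-based molecule counting of S-layer crystal puncta.

#' Detect candidate puncta above a robust background threshold
#'
#' Estimates the background as the median and MAD-derived SD of a
#' user-supplied off-cell region (or of the whole image when `NULL`), and
#' returns one candidate per local intensity maximum whose peak exceeds
#' `mean + threshold_sd * SD` (default 10 SD, far enough in the Poisson tail
#' that pure-noise images yield essentially no false positives).
#'
#' @param image Numeric matrix in photon units.
#' @param background_region Logical mask (same shape) or `NULL`.
#' @param threshold_sd Detection threshold in background SDs (default 10).
#' @param min_separation_px Local maxima closer than this are merged into the
#'   brighter one.
#' @return data.frame `x_px`, `y_px` (0-based pixel coordinates), `peak`
#'   (photons), `threshold` attribute.
#' @export
detect_puncta <- function(image, background_region = NULL, threshold_sd = 10,
                          min_separation_px = 2) {
  stopifnot(is.matrix(image))
  bg_vals <- if (is.null(background_region)) image else image[background_region]
  bg_mean <- median(bg_vals)
  bg_sd <- mad(bg_vals)
  if (bg_sd == 0) bg_sd <- sd(bg_vals)
  if (!is.finite(bg_sd) || bg_sd == 0) {
    stop("degenerate background: SD = 0", call. = FALSE)
  }
  thr <- bg_mean + threshold_sd * bg_sd
  above <- image > thr
  if (!any(above)) {
    out <- data.frame(x_px = numeric(), y_px = numeric(), peak = numeric())
    attr(out, "threshold") <- thr
    return(out)
  }
  # local maxima: pixel >= its 8 neighbours
  ny <- nrow(image); nx <- ncol(image)
  pad <- matrix(-Inf, ny + 2, nx + 2)
  pad[2:(ny + 1), 2:(nx + 1)] <- image
  is_max <- above
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    nb <- pad[2:(ny + 1) + dy, 2:(nx + 1) + dx]
    is_max <- is_max & (image >= nb)
  }
  idx <- which(is_max)
  o <- order(image[idx], decreasing = TRUE)
  idx <- idx[o]
  ys <- (idx - 1) %% ny
  xs <- (idx - 1) %/% ny
  keep <- rep(TRUE, length(idx))
  for (i in seq_along(idx)) {
    if (!keep[i]) next
    if (i < length(idx)) {
      later <- (i + 1):length(idx)
      d2 <- (xs[later] - xs[i])^2 + (ys[later] - ys[i])^2
      keep[later][d2 < min_separation_px^2] <- FALSE
    }
  }
  out <- data.frame(x_px = xs[keep], y_px = ys[keep],
                    peak = image[idx[keep]])
  attr(out, "threshold") <- thr
  out
}

# Least-squares Gaussian spot fit in a window around (x0, y0) (0-based px).
# Returns NULL on failure. symmetric = TRUE forces sx = sy.
fit_gaussian_spot <- function(image, x0, y0, sigma_px = 2, symmetric = FALSE,
                              window_px = NULL) {
  ny <- nrow(image); nx <- ncol(image)
  if (is.null(window_px)) window_px <- max(5L, ceiling(4 * sigma_px))
  c0 <- round(x0); r0 <- round(y0)
  cs <- max(0, c0 - window_px):min(nx - 1, c0 + window_px)
  rs <- max(0, r0 - window_px):min(ny - 1, r0 + window_px)
  sub <- image[rs + 1, cs + 1, drop = FALSE]
  df <- data.frame(
    x = rep(cs, each = length(rs)),
    y = rep(rs, length(cs)),
    z = as.numeric(sub)
  )
  A0 <- max(df$z) - min(df$z)
  start <- if (symmetric) {
    list(A = A0, x0 = x0, y0 = y0, s = sigma_px, b = min(df$z))
  } else {
    list(A = A0, x0 = x0, y0 = y0, sx = sigma_px, sy = sigma_px,
         b = min(df$z))
  }
  form <- if (symmetric) {
    z ~ b + A * exp(-((x - x0)^2 + (y - y0)^2) / (2 * s^2))
  } else {
    z ~ b + A * exp(-((x - x0)^2 / (2 * sx^2) + (y - y0)^2 / (2 * sy^2)))
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = df, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL
  )
  if (is.null(fit)) return(NULL)
  cf <- as.list(coef(fit))
  if (symmetric) { cf$sx <- cf$s; cf$sy <- cf$s }
  cf$converged <- fit$convInfo$isConv
  cf
}

#' Fit an asymmetric Gaussian to a candidate punctum
#'
#' Non-linear least squares fit of an axis-aligned elliptical Gaussian
#' (amplitude, center, sigma_x, sigma_y, constant offset) in a window around
#' the candidate. The integrated photon count is the analytic integral
#' `2 * pi * A * sigma_x * sigma_y` (in pixel units), excluding the offset.
#' Fits that fail to converge, have non-positive amplitude, or widths outside
#' `sigma_range` times the nominal PSF sigma (out-of-focus spots) are
#' rejected with a reason.
#'
#' @param image Numeric matrix (photons).
#' @param candidate One row of [detect_puncta()] output (or a list with
#'   `x_px`, `y_px`).
#' @param pixel_size_nm Pixel size.
#' @param psf_fwhm_nm Nominal PSF FWHM; sets the starting width and the
#'   in-focus acceptance range.
#' @param sigma_range In-focus acceptance interval as multiples of the
#'   nominal PSF sigma (default `c(0.5, 2)`).
#' @param min_amplitude_sd Reject fits whose amplitude is below this multiple
#'   of the residual SD (offset-only windows).
#' @return A list of class `"punctum"` with `center_nm`, `widths_nm`,
#'   `amplitude`, `local_offset`, `integrated_photons`, `molecules = NA`;
#'   or `NULL` with attribute-free message via `attr(,"reason")` when
#'   rejected — specifically, a list of class `"punctum_rejection"`.
#' @export
fit_punctum <- function(image, candidate, pixel_size_nm = 20,
                        psf_fwhm_nm = 60, sigma_range = c(0.5, 2),
                        min_amplitude_sd = 3) {
  sigma_px <- psf_fwhm_nm / 2.3548 / pixel_size_nm
  cf <- fit_gaussian_spot(image, candidate$x_px[1], candidate$y_px[1],
                          sigma_px = sigma_px, symmetric = FALSE)
  reject <- function(reason) {
    structure(list(reason = reason, candidate = candidate),
              class = "punctum_rejection")
  }
  if (is.null(cf) || !isTRUE(cf$converged)) return(reject("fit did not converge"))
  cf$sx <- abs(cf$sx); cf$sy <- abs(cf$sy)
  win <- max(5L, ceiling(4 * sigma_px))
  if (cf$sx > win || cf$sy > win) return(reject("width exceeds fit window"))
  if (cf$sx < sigma_range[1] * sigma_px || cf$sx > sigma_range[2] * sigma_px ||
      cf$sy < sigma_range[1] * sigma_px || cf$sy > sigma_range[2] * sigma_px) {
    return(reject("width outside in-focus range"))
  }
  if (cf$A <= 0) return(reject("non-positive amplitude"))
  # offset-only guard: amplitude must clear the local residual noise
  local_sd <- mad(image[max(1, round(candidate$y_px[1]) - win):
                          min(nrow(image), round(candidate$y_px[1]) + win),
                        max(1, round(candidate$x_px[1]) - win):
                          min(ncol(image), round(candidate$x_px[1]) + win)])
  if (local_sd > 0 && cf$A < min_amplitude_sd * local_sd) {
    return(reject("amplitude indistinguishable from offset"))
  }
  structure(
    list(center_nm = c(x = cf$x0, y = cf$y0) * pixel_size_nm,
         widths_nm = c(sx = cf$sx, sy = cf$sy) * pixel_size_nm,
         amplitude = cf$A, local_offset = cf$b,
         integrated_photons = 2 * pi * cf$A * cf$sx * cf$sy,
         molecules = NA_real_),
    class = "punctum"
  )
}

#' Calibrate photons per molecule and the photobleaching correction
#'
#' From paired fields of isolated single molecules imaged in confocal-like
#' and STED-like modes: the photons-per-molecule calibration is the median
#' integrated photon count of single molecules in the STED-mode field (median
#' is robust against rare unresolved doubles; the mean is available), and the
#' photobleaching correction factor is the ratio of molecules detected in the
#' confocal mode to those surviving in the STED mode of the same field.
#'
#' @param sted_image,confocal_image Numeric matrices (photons) of the same
#'   field.
#' @param pixel_size_nm,psf_fwhm_nm Imaging parameters of the STED channel
#'   (confocal detection uses 3x the FWHM).
#' @param threshold_sd Detection threshold (SDs above background).
#' @param statistic `"median"` (default) or `"mean"` photons per molecule.
#' @return A list of class `"counting_calibration"`:
#'   `photons_per_molecule`, `bleach_correction` (>= 1 in practice),
#'   `labeling_efficiency` (set to 1; supply the measured in vitro value via
#'   [counting_calibration()]), `n_sted`, `n_confocal`.
#' @export
calibrate_photons_per_molecule <- function(sted_image, confocal_image,
                                           pixel_size_nm = 20,
                                           psf_fwhm_nm = 60,
                                           threshold_sd = 10,
                                           statistic = c("median", "mean")) {
  statistic <- match.arg(statistic)
  cand_sted <- detect_puncta(sted_image, NULL, threshold_sd,
                             min_separation_px = psf_fwhm_nm / pixel_size_nm)
  cand_conf <- detect_puncta(confocal_image, NULL, threshold_sd,
                             min_separation_px = 3 * psf_fwhm_nm / pixel_size_nm)
  if (nrow(cand_sted) < 10L) {
    stop("fewer than 10 isolated molecules detected: calibration unstable",
         call. = FALSE)
  }
  photons <- vapply(seq_len(nrow(cand_sted)), function(i) {
    p <- fit_punctum(sted_image, cand_sted[i, ], pixel_size_nm, psf_fwhm_nm)
    if (inherits(p, "punctum")) p$integrated_photons else NA_real_
  }, numeric(1))
  photons <- photons[is.finite(photons)]
  if (length(photons) < 10L) {
    stop("fewer than 10 isolated molecules fitted: calibration unstable",
         call. = FALSE)
  }
  mu <- if (statistic == "median") median(photons) else mean(photons)
  counting_calibration(
    photons_per_molecule = mu,
    bleach_correction = nrow(cand_conf) / nrow(cand_sted),
    labeling_efficiency = 1,
    n_sted = nrow(cand_sted), n_confocal = nrow(cand_conf)
  )
}

#' Counting calibration container
#'
#' @param photons_per_molecule Mean/median detected photons per labeled
#'   molecule (mu).
#' @param bleach_correction Photobleaching correction factor
#'   (confocal/STED detection ratio, >= 1 when STED bleaches).
#' @param labeling_efficiency In vitro dye labeling efficiency, in (0, 1]
#'   (measured values range from 0.5 to 0.9).
#' @param n_sted,n_confocal Numbers of molecules behind the calibration.
#' @return List of class `"counting_calibration"`.
#' @export
counting_calibration <- function(photons_per_molecule,
                                 bleach_correction = 1,
                                 labeling_efficiency = 1,
                                 n_sted = NA_integer_,
                                 n_confocal = NA_integer_) {
  check_scalar(photons_per_molecule, "photons_per_molecule",
               min = .Machine$double.eps)
  check_scalar(bleach_correction, "bleach_correction",
               min = .Machine$double.eps)
  if (labeling_efficiency <= 0 || labeling_efficiency > 1) {
    stop("`labeling_efficiency` must be in (0, 1]", call. = FALSE)
  }
  structure(
    list(photons_per_molecule = photons_per_molecule,
         bleach_correction = bleach_correction,
         labeling_efficiency = labeling_efficiency,
         n_sted = n_sted, n_confocal = n_confocal),
    class = "counting_calibration"
  )
}

#' Molecules per punctum
#'
#' `molecules = integrated_photons / mu * bleach_correction /
#' labeling_efficiency`: linear in the integrated photons and the bleaching
#' correction, inverse in the photons-per-molecule calibration and the
#' labeling efficiency.
#'
#' @param punctum A [fit_punctum()] result (or a number of photons).
#' @param calibration A [counting_calibration()].
#' @return The punctum with `molecules` filled in (or the bare number when a
#'   photon count was supplied).
#' @export
molecules_per_punctum <- function(punctum, calibration) {
  stopifnot(inherits(calibration, "counting_calibration"))
  photons <- if (inherits(punctum, "punctum")) {
    punctum$integrated_photons
  } else {
    as.numeric(punctum)
  }
  m <- photons / calibration$photons_per_molecule *
    calibration$bleach_correction / calibration$labeling_efficiency
  if (inherits(punctum, "punctum")) {
    punctum$molecules <- m
    punctum
  } else {
    m
  }
}

#' Detect, fit and count all puncta in an image
#'
#' @param image Numeric matrix (photons).
#' @param calibration A [counting_calibration()].
#' @param background_region Optional logical mask for background estimation.
#' @param pixel_size_nm,psf_fwhm_nm,threshold_sd See [detect_puncta()] and
#'   [fit_punctum()].
#' @return data.frame with one row per accepted punctum: `id`, `x_nm`,
#'   `y_nm`, `sigx_nm`, `sigy_nm`, `photons`, `molecules`; rejected
#'   candidates are tallied in attribute `"n_rejected"`.
#' @export
count_puncta <- function(image, calibration, background_region = NULL,
                         pixel_size_nm = 20, psf_fwhm_nm = 60,
                         threshold_sd = 10) {
  cand <- detect_puncta(image, background_region, threshold_sd,
                        min_separation_px = psf_fwhm_nm / pixel_size_nm)
  rows <- list(); n_rej <- 0L
  for (i in seq_len(nrow(cand))) {
    p <- fit_punctum(image, cand[i, ], pixel_size_nm, psf_fwhm_nm)
    if (!inherits(p, "punctum")) { n_rej <- n_rej + 1L; next }
    p <- molecules_per_punctum(p, calibration)
    rows[[length(rows) + 1L]] <- data.frame(
      id = length(rows) + 1L,
      x_nm = p$center_nm[["x"]], y_nm = p$center_nm[["y"]],
      sigx_nm = p$widths_nm[["sx"]], sigy_nm = p$widths_nm[["sy"]],
      photons = p$integrated_photons, molecules = p$molecules
    )
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(id = integer(), x_nm = numeric(), y_nm = numeric(),
               sigx_nm = numeric(), sigy_nm = numeric(),
               photons = numeric(), molecules = numeric())
  }
  attr(out, "n_rejected") <- n_rej
  out
}
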