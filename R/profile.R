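# Binary cell profile analysis: register, orient, fit axis, outline,
# binarize, project onto 40 axial bins, and aggregate across cells with
# Wilson score confidence bands.

#' Container for one cell's registered image channels
#'
#' @param transmitted Transmitted-light image (numeric matrix, photons/pixel;
#'   rows = y increasing downward, columns = x, pixel centers at 0-based
#'   integer coordinates).
#' @param channel_a,channel_b Fluorescence channels (same shape as
#'   `transmitted`; `channel_b` may be `NULL`).
#' @param pixel_size_nm Pixel size in nm.
#' @param stalk_side `"left"`, `"right"` or `"unknown"`: which side the stalk
#'   is on (supplied by metadata; cells arrive pre-cropped, one per record).
#' @return A list of class `"cell_record"` with additional slots filled by the
#'   pipeline: `orientation_applied` (degrees), `shifts` (registration),
#'   `axis` (a `cell_axis`), `outline_mask`.
#' @export
cell_record <- function(transmitted, channel_a, channel_b = NULL,
                        pixel_size_nm = 20,
                        stalk_side = c("unknown", "left", "right")) {
  stalk_side <- match.arg(stalk_side)
  stopifnot(is.matrix(transmitted), is.matrix(channel_a))
  if (!all(dim(channel_a) == dim(transmitted)) ||
      (!is.null(channel_b) && !all(dim(channel_b) == dim(transmitted)))) {
    stop("all channels must share the transmitted image's shape",
         call. = FALSE)
  }
  check_scalar(pixel_size_nm, "pixel_size_nm", min = .Machine$double.eps)
  structure(
    list(transmitted = transmitted, channel_a = channel_a,
         channel_b = channel_b, pixel_size_nm = pixel_size_nm,
         stalk_side = stalk_side, orientation_applied = 0,
         shifts = NULL, axis = NULL, outline_mask = NULL),
    class = "cell_record"
  )
}

#' Register fluorescence channels to the transmitted-light image
#'
#' Corrects sample drift between channels by translating each fluorescence
#' channel by the integer-pixel shift maximizing its cross-correlation with
#' the gradient magnitude of the transmitted image.
#'
#' @param record A [cell_record()].
#' @param max_shift_px Maximum shift searched in each direction.
#' @return The record with channels translated; applied shifts stored in
#'   `record$shifts` (a list with `a`, `b`, each `c(dx, dy)` in pixels and a
#'   `reliable` flag which is `FALSE` when the correlation peak lies on the
#'   search border).
#' @export
register_channels <- function(record, max_shift_px = 10L) {
  stopifnot(inherits(record, "cell_record"))
  ref <- gradient_magnitude(record$transmitted)
  shifts <- list()
  for (nm in c("a", "b")) {
    ch <- record[[paste0("channel_", nm)]]
    if (is.null(ch)) next
    s <- best_integer_shift(ref, ch, max_shift_px)
    record[[paste0("channel_", nm)]] <- translate_image(ch, s$dx, s$dy)
    shifts[[nm]] <- c(dx = s$dx, dy = s$dy, reliable = s$reliable)
  }
  record$shifts <- shifts
  record
}

gradient_magnitude <- function(img) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, byrow = TRUE)
  gx <- as.matrix(EBImage::filter2(img, kx))
  gy <- as.matrix(EBImage::filter2(img, t(kx)))
  sqrt(gx^2 + gy^2)
}

# Cross-correlation over all integer shifts within +/- max_shift via FFT;
# returns the shift (dx = columns, dy = rows) to apply to `img` so it best
# matches `ref`.
best_integer_shift <- function(ref, img, max_shift_px) {
  a <- ref - mean(ref)
  b <- img - mean(img)
  cc <- Re(fft(fft(a) * Conj(fft(b)), inverse = TRUE))
  ny <- nrow(a); nx <- ncol(a)
  dys <- seq(-max_shift_px, max_shift_px)
  dxs <- seq(-max_shift_px, max_shift_px)
  sub <- cc[(dys %% ny) + 1, (dxs %% nx) + 1, drop = FALSE]
  best <- arrayInd(which.max(sub), dim(sub))
  dy <- dys[best[1]]; dx <- dxs[best[2]]
  reliable <- best[1] > 1 && best[1] < length(dys) &&
    best[2] > 1 && best[2] < length(dxs)
  list(dx = dx, dy = dy, reliable = reliable)
}

translate_image <- function(img, dx, dy) {
  out <- matrix(0, nrow(img), ncol(img))
  src_rows <- seq_len(nrow(img)) - dy
  src_cols <- seq_len(ncol(img)) - dx
  ok_r <- src_rows >= 1 & src_rows <= nrow(img)
  ok_c <- src_cols >= 1 & src_cols <= ncol(img)
  out[which(ok_r), which(ok_c)] <- img[src_rows[ok_r], src_cols[ok_c]]
  out
}

# Bilinear rotation of an image about its center by `deg` degrees
# (positive = counter-clockwise in standard x-right / y-up terms, i.e. the
# cell's long-axis angle measured from the x axis is reduced by `deg`).
rotate_image <- function(img, deg) {
  th <- deg * pi / 180
  ny <- nrow(img); nx <- ncol(img)
  cy <- (ny - 1) / 2; cx <- (nx - 1) / 2
  # output pixel (r, c) samples input at the inverse-rotated location
  co <- cos(th); si <- sin(th)
  cgrid <- rep(seq_len(nx) - 1 - cx, each = ny)
  rgrid <- rep(seq_len(ny) - 1 - cy, nx)
  xs <- co * cgrid - si * rgrid + cx
  ys <- si * cgrid + co * rgrid + cy
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  val <- numeric(length(xs))
  get <- function(r, c) {
    ok <- r >= 0 & r <= ny - 1 & c >= 0 & c <= nx - 1
    v <- numeric(length(r))
    v[ok] <- img[cbind(r[ok] + 1, c[ok] + 1)]
    v
  }
  val <- (1 - fx) * (1 - fy) * get(y0, x0) +
    fx * (1 - fy) * get(y0, x0 + 1) +
    (1 - fx) * fy * get(y0 + 1, x0) +
    fx * fy * get(y0 + 1, x0 + 1)
  matrix(val, ny, nx)
}

# Discrete Radon scan: for each angle, bin the intensity-weighted coordinate
# perpendicular to the integration direction into 1-px bins and score the
# spread of the projection profile by its energy (sum of squared bin values).
# Total intensity is angle-invariant, so the energy is maximal exactly when
# the mass concentrates into the fewest bins — integration along the long
# axis. (The raw profile variance shares that continuum maximizer but is
# non-monotone under 1-px binning, so the energy is used as the score.)
radon_profile_variance <- function(img, angles_deg) {
  idx <- which(img > 0)
  w <- img[idx]
  ny <- nrow(img)
  y <- ((idx - 1) %% ny)
  x <- ((idx - 1) %/% ny)
  vapply(angles_deg, function(a) {
    th <- a * pi / 180
    t <- x * sin(th) + y * cos(th) # coordinate perpendicular to direction a
    b <- floor(t - min(t)) + 1
    sum(rowsum(w, b)^2)
  }, numeric(1))
}

#' Orient a cell horizontally with the stalk on the left
#'
#' Finds the cell's long-axis angle as the angle of maximal Radon projection
#' variance of the transmitted-light image, rotates the record so the axis is
#' horizontal, and mirrors it when the declared stalk side is `"right"` so
#' that the stalk ends up on the left.
#'
#' @param record A [cell_record()].
#' @param stalk_side Overrides `record$stalk_side` if given.
#' @param coarse_step_deg,fine_step_deg Angle-scan resolution.
#' @return The rotated record; `orientation_applied` holds the rotation in
#'   degrees and `mirrored` whether a horizontal flip was applied.
#' @export
orient_cell <- function(record, stalk_side = NULL,
                        coarse_step_deg = 2, fine_step_deg = 0.25) {
  stopifnot(inherits(record, "cell_record"))
  if (!is.null(stalk_side)) record$stalk_side <- stalk_side
  img <- record$transmitted
  coarse <- seq(0, 180 - coarse_step_deg, by = coarse_step_deg)
  v <- radon_profile_variance(img, coarse)
  if (max(v) < 1.2 * median(v)) {
    stop("no dominant orientation: object is nearly isotropic", call. = FALSE)
  }
  a0 <- coarse[which.max(v)]
  fine <- seq(a0 - coarse_step_deg, a0 + coarse_step_deg, by = fine_step_deg)
  vf <- radon_profile_variance(img, fine)
  best <- fine[which.max(vf)]
  # the projection energy peaks when integrating along the long axis, whose
  # angle from the x axis (y down) is -best; rotate it away
  rot <- ((-best + 90) %% 180) - 90
  for (nm in c("transmitted", "channel_a", "channel_b")) {
    if (!is.null(record[[nm]])) record[[nm]] <- rotate_image(record[[nm]], rot)
  }
  record$orientation_applied <- rot
  record$mirrored <- identical(record$stalk_side, "right")
  if (record$mirrored) {
    for (nm in c("transmitted", "channel_a", "channel_b")) {
      if (!is.null(record[[nm]])) {
        record[[nm]] <- record[[nm]][, rev(seq_len(ncol(record[[nm]])))]
      }
    }
    record$stalk_side <- "left"
  }
  record
}

#' Fit the cell axis through per-column transmitted-light maxima
#'
#' For an oriented (horizontal) cell, takes the row of maximal
#' transmitted-light intensity in each column crossing the cell and fits a
#' second-order polynomial through them; for long cells (above
#' `spline_threshold_um`, e.g. filamentous cells after division inhibition)
#' a smoothing spline is used instead. The axis is returned with a normalized
#' arc-length parameterization.
#'
#' @param record An oriented [cell_record()].
#' @param spline_threshold_um Cell length above which a smoothing spline
#'   replaces the polynomial (default 6).
#' @param min_intensity_frac Columns whose maximum is below this fraction of
#'   the global maximum are outside the cell and ignored entirely.
#' @param fit_intensity_frac Only columns at least this bright contribute
#'   points to the fit: near-full-thickness columns of the cell body track
#'   the midline, whereas columns crossing the polar caps would flatten the
#'   fitted curvature. The fitted axis is still evaluated over the whole
#'   usable span.
#' @param n_samples Number of points in the densely sampled axis polyline.
#' @return A list of class `"cell_axis"`: `model_kind` (`"poly2"` or
#'   `"smoothing_spline"`), `coefficients` (poly2 only), `x_px`, `y_px`
#'   (dense polyline, 0-based pixel coordinates), `u` (normalized arc
#'   length), `length_um`.
#' @export
fit_cell_axis <- function(record, spline_threshold_um = 6,
                          min_intensity_frac = 0.3,
                          fit_intensity_frac = 0.9, n_samples = 1000L) {
  stopifnot(inherits(record, "cell_record"))
  img <- as.matrix(EBImage::gblur(record$transmitted, sigma = 1))
  peak <- max(img)
  col_max <- apply(img, 2, max)
  usable <- which(col_max >= min_intensity_frac * peak)
  fit_cols <- which(col_max >= fit_intensity_frac * peak)
  if (length(fit_cols) < 6L) fit_cols <- usable
  if (length(usable) < 6L) {
    stop("fewer than 6 usable columns for the axis fit", call. = FALSE)
  }
  xs <- fit_cols - 1 # 0-based
  ys <- apply(img[, fit_cols, drop = FALSE], 2, which.max) - 1
  length_um <- (max(usable) - min(usable)) * record$pixel_size_nm / 1000
  xfine <- seq(min(usable) - 1, max(usable) - 1, length.out = n_samples)
  if (length_um > spline_threshold_um) {
    fit <- smooth.spline(xs, ys)
    yfine <- predict(fit, xfine)$y
    kind <- "smoothing_spline"
    coefs <- NULL
  } else {
    fit <- lm(y ~ x + I(x^2), data = data.frame(x = xs, y = ys))
    coefs <- unname(coef(fit)) # intercept, linear, quadratic
    yfine <- coefs[1] + coefs[2] * xfine + coefs[3] * xfine^2
    kind <- "poly2"
  }
  arc <- c(0, cumsum(sqrt(diff(xfine)^2 + diff(yfine)^2)))
  axis <- structure(
    list(model_kind = kind, coefficients = coefs,
         x_px = xfine, y_px = yfine, u = arc / max(arc),
         length_um = length_um),
    class = "cell_axis"
  )
  axis
}

#' Build the 200 nm cell outline band
#'
#' Defines the band mask within which S-layer presence is scored: a band of
#' nominal width 200 nm centered on the cell boundary. In `complete_layer`
#' mode (cells with a mostly complete S-layer) the boundary is found by Otsu
#' thresholding of the max-normalized sum of the two fluorescence channels; in
#' `incomplete_layer` mode (de novo assembly, partial layers) it is the
#' maximum-gradient contour of the transmitted-light image.
#'
#' @param record An oriented [cell_record()]; `incomplete_layer` mode needs
#'   `record$axis` (see [fit_cell_axis()]) since gradient rays are cast from
#'   the axis.
#' @param mode `"complete_layer"` or `"incomplete_layer"`.
#' @param band_width_nm Band width (default 200).
#' @param boundary_offset_nm Complete-layer mode only: how far the
#'   thresholded fluorescence boundary lies outside the cell surface (about
#'   one PSF half-width plus the layer half-thickness); the mask is eroded by
#'   this much so the band is centered on the surface itself.
#' @return The logical band mask. Attribute `"boundary"` holds the 1-px
#'   contour it was grown from.
#' @export
make_outline <- function(record, mode = c("complete_layer",
                                          "incomplete_layer"),
                         band_width_nm = 200, boundary_offset_nm = 50) {
  stopifnot(inherits(record, "cell_record"))
  mode <- match.arg(mode)
  px <- record$pixel_size_nm
  if (mode == "complete_layer") {
    if (max(record$channel_a) <= 0) {
      stop("empty boundary after thresholding", call. = FALSE)
    }
    s <- record$channel_a / max(record$channel_a)
    if (!is.null(record$channel_b) && max(record$channel_b) > 0) {
      s <- s + record$channel_b / max(record$channel_b)
    }
    s <- as.matrix(EBImage::gblur(s, sigma = 1))
    mask <- s > otsu_threshold(s)
    if (!any(mask)) stop("empty boundary after thresholding", call. = FALSE)
    lab <- EBImage::bwlabel(mask)
    mask <- lab == which.max(tabulate(lab[lab > 0]))
    mask <- as.matrix(EBImage::fillHull(EBImage::Image(mask * 1))) > 0
    ero <- round(boundary_offset_nm / px)
    if (ero >= 1) {
      mask <- as.matrix(EBImage::erode(
        EBImage::Image(mask * 1),
        EBImage::makeBrush(2L * ero + 1L, shape = "disc"))) > 0
    }
    if (!any(mask)) stop("empty boundary after thresholding", call. = FALSE)
    contour <- mask & !shrink_mask(mask)
  } else {
    if (is.null(record$axis)) {
      stop("incomplete_layer mode needs a fitted cell axis", call. = FALSE)
    }
    contour <- max_gradient_contour(record)
    if (!any(contour)) {
      stop("empty boundary after thresholding", call. = FALSE)
    }
  }
  half_px <- band_width_nm / px / 2
  dist_to_contour <- as.matrix(EBImage::distmap(
    EBImage::Image((!contour) * 1)))
  band <- dist_to_contour <= half_px
  attr(band, "boundary") <- contour
  attr(band, "mode") <- mode
  band
}

# Contour of maximal transmitted-light gradient around the cell axis: rays
# are cast perpendicular to the axis (plus radial fans beyond the two axis
# ends to cover the poles) and the gradient-magnitude maximum along each ray
# is marked.
max_gradient_contour <- function(record, max_reach_px = NULL) {
  img <- as.matrix(EBImage::gblur(record$transmitted, sigma = 1))
  gm <- gradient_magnitude(img)
  if (max(gm) <= 0) return(matrix(FALSE, nrow(img), ncol(img)))
  ax <- record$axis
  ny <- nrow(img); nx <- ncol(img)
  if (is.null(max_reach_px)) max_reach_px <- max(ny, nx) / 3
  # subsample the dense axis polyline to ~1 px spacing
  keep <- unique(round(seq(1, length(ax$x_px),
                           length.out = max(ax$x_px) - min(ax$x_px) + 1)))
  axp <- cbind(ax$x_px[keep], ax$y_px[keep])
  n <- nrow(axp)
  tang <- rbind(axp[2, ] - axp[1, ],
                axp[pmin(seq_len(n) + 1, n), ] - axp[pmax(seq_len(n) - 1, 1), ])
  tang <- tang[-1, , drop = FALSE]
  tang <- tang / sqrt(rowSums(tang^2))
  dirs <- rbind(cbind(-tang[, 2], tang[, 1]), cbind(tang[, 2], -tang[, 1]))
  origins <- rbind(axp, axp)
  # polar fans beyond the axis ends
  fan <- function(origin, tangent) {
    th <- atan2(tangent[2], tangent[1]) + seq(-80, 80, by = 8) * pi / 180
    list(o = matrix(origin, length(th), 2, byrow = TRUE),
         d = cbind(cos(th), sin(th)))
  }
  f1 <- fan(axp[1, ], axp[1, ] - axp[2, ])
  f2 <- fan(axp[n, ], axp[n, ] - axp[n - 1, ])
  origins <- rbind(origins, f1$o, f2$o)
  dirs <- rbind(dirs, f1$d, f2$d)
  steps <- seq(1, max_reach_px, by = 0.5)
  contour <- matrix(FALSE, ny, nx)
  gm_at <- function(x, y) {
    ok <- x >= 0 & x <= nx - 1 & y >= 0 & y <= ny - 1
    v <- rep(0, length(x))
    v[ok] <- gm[cbind(round(y[ok]) + 1, round(x[ok]) + 1)]
    v
  }
  for (i in seq_len(nrow(origins))) {
    xs <- origins[i, 1] + dirs[i, 1] * steps
    ys <- origins[i, 2] + dirs[i, 2] * steps
    v <- gm_at(xs, ys)
    if (max(v) <= 0) next
    j <- which.max(v)
    contour[round(ys[j]) + 1, round(xs[j]) + 1] <- TRUE
  }
  contour
}

shrink_mask <- function(mask) {
  as.matrix(EBImage::erode(EBImage::Image(mask * 1),
                           EBImage::makeBrush(3, shape = "box"))) > 0
}

#' Binarize an S-layer fluorescence channel within the outline band
#'
#' Smooths the channel with a Gaussian of sigma 0.9 pixels (18 nm at
#' 20 nm/px) and applies a binary intensity threshold, intersected with the
#' outline band. The default threshold is Otsu's, computed from smoothed
#' intensities within a dilated outline (parameter-free, reproducible); a
#' fixed quantile of those intensities can be used instead.
#'
#' @param channel Fluorescence image matrix.
#' @param outline_mask Band mask from [make_outline()].
#' @param sigma_px Smoothing sigma in pixels (default 0.9).
#' @param method `"otsu"` or `"quantile"`.
#' @param quantile_level Quantile for `method = "quantile"`.
#' @return Logical mask of S-layer-positive pixels (empty masks are allowed:
#'   unlabeled cells exist in de novo assembly experiments).
#' @export
binarize_layer <- function(channel, outline_mask, sigma_px = 0.9,
                           method = c("otsu", "quantile"),
                           quantile_level = 0.5) {
  method <- match.arg(method)
  stopifnot(is.matrix(channel), is.logical(outline_mask),
            all(dim(channel) == dim(outline_mask)))
  sm <- as.matrix(EBImage::gblur(channel, sigma = sigma_px))
  region <- as.matrix(EBImage::dilate(
    EBImage::Image(outline_mask * 1),
    EBImage::makeBrush(7, shape = "disc"))) > 0
  vals <- sm[region]
  thr <- if (method == "otsu") otsu_threshold(vals) else {
    quantile(vals, quantile_level)
  }
  sm > thr & outline_mask
}

#' Project a binary layer mask onto the cell axis
#'
#' Assigns every positive pixel to the axial bin of its nearest axis point
#' (normalized arc length, half-open bins `[i/n, (i+1)/n)`, last bin closed)
#' and to the upper or lower cell half by the sign of its offset from the
#' axis (pixels exactly on the axis count as upper). A bin is positive iff at
#' least one pixel lands in it.
#'
#' @param layer_mask Logical mask from [binarize_layer()].
#' @param axis A [fit_cell_axis()] result.
#' @param n_bins Number of equi-length bins (default 40).
#' @param channel Optional channel label carried through.
#' @return A list of class `"binary_profile"`: `n_bins`, `upper`, `lower`
#'   (logical vectors), `channel`.
#' @export
project_profile <- function(layer_mask, axis, n_bins = 40L, channel = NA) {
  stopifnot(is.logical(layer_mask), inherits(axis, "cell_axis"))
  check_scalar(n_bins, "n_bins", min = 1)
  n_bins <- as.integer(n_bins)
  upper <- logical(n_bins)
  lower <- logical(n_bins)
  idx <- which(layer_mask)
  if (length(idx)) {
    ny <- nrow(layer_mask)
    pyx <- cbind(((idx - 1) %/% ny), ((idx - 1) %% ny)) # x, y (0-based)
    poly <- cbind(axis$x_px, axis$y_px)
    near <- nearest_polyline_point(pyx, poly)
    u <- axis$u[near$index]
    bin <- pmin(floor(u * n_bins), n_bins - 1L) + 1L
    # side by signed cross product of (tangent, pixel - axis point);
    # tangent taken along increasing x so "upper" = smaller row index
    i <- near$index
    i2 <- pmin(i + 1L, length(axis$x_px))
    i1 <- pmax(i - 1L, 1L)
    tx <- axis$x_px[i2] - axis$x_px[i1]
    ty <- axis$y_px[i2] - axis$y_px[i1]
    cross <- tx * (pyx[, 2] - axis$y_px[i]) - ty * (pyx[, 1] - axis$x_px[i])
    is_upper <- cross <= 0 # ties (on-axis pixels) assigned to upper
    upper[unique(bin[is_upper])] <- TRUE
    lower[unique(bin[!is_upper])] <- TRUE
  }
  structure(list(n_bins = n_bins, upper = upper, lower = lower,
                 channel = channel),
            class = "binary_profile")
}

#' Population fraction profile with Wilson confidence bands
#'
#' Combines the upper and lower half-profiles of all cells: per bin,
#' `k` positive half-profiles out of `n = 2 x n_cells` binomial observations
#' give the fraction of the population carrying S-layer at that axial
#' position, with a 95% Wilson score interval.
#'
#' @param profiles List of [project_profile()] results (one per cell; each
#'   contributes its upper and lower half).
#' @param conf Confidence level (default 0.95).
#' @return A data.frame of class `"population_profile"`: `bin`, `u_mid`,
#'   `k`, `n`, `fraction`, `ci_low`, `ci_high`; attribute `n_cells`.
#' @export
population_fraction <- function(profiles, conf = 0.95) {
  if (inherits(profiles, "binary_profile")) profiles <- list(profiles)
  if (!length(profiles)) stop("empty profile collection", call. = FALSE)
  nb <- unique(vapply(profiles, function(p) p$n_bins, integer(1)))
  if (length(nb) != 1L) stop("profiles disagree on n_bins", call. = FALSE)
  k <- Reduce(`+`, lapply(profiles, function(p) p$upper + p$lower))
  n <- 2L * length(profiles)
  wi <- wilson_interval(k, n, conf)
  res <- data.frame(bin = seq_len(nb), u_mid = (seq_len(nb) - 0.5) / nb,
                    k = k, n = n, fraction = wi$fraction,
                    ci_low = wi$low, ci_high = wi$high)
  attr(res, "n_cells") <- length(profiles)
  class(res) <- c("population_profile", "data.frame")
  res
}

#' @export
plot.population_profile <- function(x, ...) {
  plot(x$u_mid, x$fraction, type = "l", ylim = c(0, 1), lwd = 2,
       xlab = "normalized position along cell axis",
       ylab = "fraction of cells with S-layer", ...)
  polygon(c(x$u_mid, rev(x$u_mid)), c(x$ci_low, rev(x$ci_high)),
          col = gray(0.5, 0.3), border = NA)
  invisible(x)
}

#' Run the whole profile pipeline on one cell record
#'
#' Convenience wrapper: register, orient, fit the axis, build the outline,
#' binarize each fluorescence channel and project it into axial bins.
#'
#' @param record A [cell_record()].
#' @param mode Outline mode, see [make_outline()].
#' @param n_bins Number of axial bins.
#' @param register Whether to run channel registration first.
#' @return List with the processed `record`, the `axis`, `outline`, binary
#'   masks and a list `profiles` with one [project_profile()] result per
#'   channel.
#' @export
profile_cell <- function(record, mode = "complete_layer", n_bins = 40L,
                         register = TRUE) {
  if (register) record <- register_channels(record)
  record <- orient_cell(record)
  axis <- fit_cell_axis(record)
  record$axis <- axis
  outline <- make_outline(record, mode)
  record$outline_mask <- outline
  profiles <- list()
  masks <- list()
  for (nm in c("a", "b")) {
    ch <- record[[paste0("channel_", nm)]]
    if (is.null(ch)) next
    m <- binarize_layer(ch, outline)
    masks[[nm]] <- m
    profiles[[nm]] <- project_profile(m, axis, n_bins, channel = nm)
  }
  list(record = record, axis = axis, outline = outline,
       masks = masks, profiles = profiles)
}
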