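#' Link localizations into tracks by greedy nearest-neighbor association
#'
#' Frame-to-frame linking: each new localization is matched to the nearest
#' active track end within `max_step`, matches assigned greedily in order of
#' increasing distance (ties broken by lower localization index, so the result
#' is deterministic for a given input order). Detection gaps up to `max_gap`
#' frames are bridged; unmatched localizations start new tracks.
#'
#' @param localizations data.frame with columns `frame`, `x_nm`, `y_nm`
#'   (optionally `z_nm`, `t_s`).
#' @param max_step Maximum allowed step between linked localizations, nm.
#' @param max_gap Maximum number of missed frames bridged (0 = none).
#'
#' @return The input data.frame with a `track_id` column added, ordered by
#'   track then frame.
#' @export
link_localizations <- function(localizations, max_step = 500, max_gap = 1L) {
  stopifnot(is.data.frame(localizations),
            all(c("frame", "x_nm", "y_nm") %in% names(localizations)))
  check_scalar(max_step, "max_step", min = 0)
  check_scalar(max_gap, "max_gap", min = 0)
  axes <- intersect(c("x_nm", "y_nm", "z_nm"), names(localizations))
  locs <- localizations[order(localizations$frame), , drop = FALSE]
  locs$.row <- seq_len(nrow(locs))
  locs$track_id <- NA_integer_
  # active track state: id, last frame, last position
  act_id <- integer(0)
  act_frame <- integer(0)
  act_pos <- matrix(numeric(0), 0, length(axes))
  next_id <- 1L
  for (f in sort(unique(locs$frame))) {
    rows <- which(locs$frame == f)
    keep <- act_frame >= f - 1L - max_gap
    act_id <- act_id[keep]; act_frame <- act_frame[keep]
    act_pos <- act_pos[keep, , drop = FALSE]
    assigned_loc <- rep(FALSE, length(rows))
    used_track <- rep(FALSE, length(act_id))
    if (length(act_id) && length(rows)) {
      p <- as.matrix(locs[rows, axes, drop = FALSE])
      d <- sqrt(outer(rowSums(p^2), rowSums(act_pos^2), "+") -
                  2 * p %*% t(act_pos))
      cand <- which(d <= max_step, arr.ind = TRUE)
      if (nrow(cand)) {
        ord <- order(d[cand], cand[, 1]) # distance, then lower loc index
        for (k in ord) {
          i <- cand[k, 1]; j <- cand[k, 2]
          if (assigned_loc[i] || used_track[j]) next
          assigned_loc[i] <- TRUE
          used_track[j] <- TRUE
          locs$track_id[rows[i]] <- act_id[j]
          act_frame[j] <- f
          act_pos[j, ] <- p[i, ]
        }
      }
    }
    new_rows <- rows[!assigned_loc]
    if (length(new_rows)) {
      ids <- seq.int(next_id, length.out = length(new_rows))
      locs$track_id[new_rows] <- ids
      next_id <- next_id + length(new_rows)
      act_id <- c(act_id, ids)
      act_frame <- c(act_frame, rep(f, length(new_rows)))
      act_pos <- rbind(act_pos,
                       as.matrix(locs[new_rows, axes, drop = FALSE]))
    }
  }
  locs <- locs[order(locs$track_id, locs$frame), ]
  locs$.row <- NULL
  rownames(locs) <- NULL
  locs
}

#' Sliding-window RMSD of a track
#'
#' For every full window of `window` consecutive frames, computes the root
#' mean squared deviation of the positions from the window's mean position.
#' Bound molecules give RMSD near the localization precision; freely diffusing
#' ones give much larger values. The value is assigned to the window's center
#' frame.
#'
#' @param track Single-track data.frame with `frame`, `t_s`, `x_nm`, `y_nm`
#'   (and optionally `z_nm`; all present position axes are used).
#' @param window Window length in frames (default 20, i.e. 1 s at 20 frames/s).
#'
#' @return data.frame with columns `frame`, `t_s`, `rmsd_nm`, one row per full
#'   window; zero rows if the track is shorter than `window`.
#' @examples
#' trk <- data.frame(frame = 1:40, t_s = (0:39) * 0.05,
#'                   x_nm = rep(c(0, 100), 20), y_nm = 0)
#' head(sliding_rmsd(trk)) # alternating +/-100 nm in x: RMSD = 50 nm
#' @export
sliding_rmsd <- function(track, window = 20L) {
  stopifnot(is.data.frame(track), all(c("frame", "t_s") %in% names(track)))
  check_scalar(window, "window", min = 2)
  window <- as.integer(window)
  axes <- intersect(c("x_nm", "y_nm", "z_nm"), names(track))
  track <- track[order(track$frame), ]
  n <- nrow(track)
  if (n < window) {
    return(data.frame(frame = integer(), t_s = numeric(), rmsd_nm = numeric()))
  }
  pos <- as.matrix(track[, axes, drop = FALSE])
  n_win <- n - window + 1L
  rmsd2 <- numeric(n_win)
  for (a in seq_len(ncol(pos))) {
    cs <- cumsum(c(0, pos[, a]))
    cs2 <- cumsum(c(0, pos[, a]^2))
    s <- cs[(window + 1L):(n + 1L)] - cs[1:n_win]
    s2 <- cs2[(window + 1L):(n + 1L)] - cs2[1:n_win]
    rmsd2 <- rmsd2 + s2 / window - (s / window)^2
  }
  center <- seq_len(n_win) + (window - 1L) %/% 2L
  data.frame(
    frame = track$frame[center],
    t_s = track$t_s[center],
    rmsd_nm = sqrt(pmax(rmsd2, 0))
  )
}

#' Calibrate the binding RMSD threshold from pooled track RMSD values
#'
#' The pooled RMSD histogram of a cell's tracks is bimodal: a low mode set by
#' the localization precision of bound molecules and a broad tail from mobile
#' ones. A Gaussian is fitted to the histogram of the lowest-RMSD population
#' and the binding threshold is set at its mean + 2 sigma.
#'
#' The low population is delimited by the first anti-mode (valley) of a kernel
#' density estimate; when the pooled distribution has no interior valley (a
#' single population), the window is taken symmetric about the main mode
#' (mode + (mode - 1st percentile)), which spans the whole low peak. Histogram
#' bin width follows the Freedman-Diaconis rule.
#'
#' @param rmsd_values Pooled RMSD values in nm from all tracks of a cell
#'   (at least 500 values).
#' @param conf_sigma Number of sigmas above the fitted mean (default 2).
#'
#' @return A list of class `"threshold_calibration"` with `fitted_mean`,
#'   `fitted_sigma`, `threshold` (nm), `cutoff` (upper edge of the fitted
#'   population) and `n_values`.
#' @seealso [binding_defaults()] for the study's published threshold.
#' @export
calibrate_threshold <- function(rmsd_values, conf_sigma = 2) {
  rmsd_values <- rmsd_values[is.finite(rmsd_values)]
  if (length(rmsd_values) < 500L) {
    stop("need >= 500 pooled RMSD values for a stable calibration",
         call. = FALSE)
  }
  dens <- density(rmsd_values, n = 512)
  dy <- diff(dens$y)
  valleys <- which(diff(sign(dy)) == 2) + 1L
  mode_i <- which.max(dens$y)
  mode_x <- dens$x[mode_i]
  # accept only a pronounced valley after the main mode (shallow KDE wiggles
  # would truncate the low population and bias the fit)
  valley_after <- valleys[dens$x[valleys] > mode_x &
                            dens$y[valleys] < 0.7 * dens$y[mode_i]]
  cutoff <- if (length(valley_after)) {
    dens$x[valley_after[1]]
  } else {
    # unimodal: symmetric window about the mode spans the whole low peak
    mode_x + (mode_x - quantile(rmsd_values, 0.01))
  }
  low_vals <- rmsd_values[rmsd_values < cutoff]
  if (length(low_vals) < 100L) {
    stop("no resolvable low-RMSD population; supply a manual threshold",
         call. = FALSE)
  }
  h <- graphics::hist(low_vals, breaks = "FD", plot = FALSE)
  sel <- h$counts > 0
  if (sum(sel) < 5L) {
    stop("no resolvable low-RMSD population; supply a manual threshold",
         call. = FALSE)
  }
  df <- data.frame(x = h$mids[sel], y = h$counts[sel])
  start <- list(A = max(df$y), mu = mode_x, s = max(sd(low_vals), 1e-3))
  fit <- minpack.lm::nlsLM(
    y ~ A * exp(-(x - mu)^2 / (2 * s^2)), data = df, start = start,
    lower = c(A = 0, mu = 0, s = 1e-6),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  cf <- coef(fit)
  if (!is.finite(cf[["mu"]]) || cf[["s"]] <= 0) {
    stop("Gaussian fit of the low-RMSD mode failed; supply a manual threshold",
         call. = FALSE)
  }
  structure(
    list(fitted_mean = unname(cf[["mu"]]),
         fitted_sigma = unname(cf[["s"]]),
         threshold = unname(cf[["mu"]] + conf_sigma * cf[["s"]]),
         cutoff = unname(cutoff),
         n_values = length(rmsd_values)),
    class = "threshold_calibration"
  )
}

#' @export
print.threshold_calibration <- function(x, ...) {
  cat(sprintf(
    "RMSD binding threshold: %.1f nm (mean %.1f + 2 x sigma %.1f, n = %d)\n",
    x$threshold, x$fitted_mean, x$fitted_sigma, x$n_values))
  invisible(x)
}

#' Published default thresholds for bound-state classification
#'
#' The study's calibrated constants: molecules are classified bound when the
#' 20-frame (1 s) sliding-window RMSD is below 57.3 nm (2 sigma above the mean
#' of the localization-precision-limited RMSD mode), and near a nucleation
#' seed when the distance to the nearest seed is below 300 nm.
#'
#' @return list with `threshold_nm` (57.3), `proximity_nm` (300),
#'   `window_frames` (20) and `frame_interval_s` (0.05).
#' @export
binding_defaults <- function() {
  list(threshold_nm = 57.3, proximity_nm = 300,
       window_frames = 20L, frame_interval_s = 0.05)
}

#' Classify track frames as bound or unbound
#'
#' A frame is bound iff its RMSD is strictly below the threshold (unbound when
#' RMSD >= threshold, so a value exactly at the threshold is unbound).
#'
#' @param rmsd RMSD series in nm (vector, or a [sliding_rmsd()] data.frame).
#' @param threshold Binding threshold in nm (default: the published 57.3 nm,
#'   see [binding_defaults()] or [calibrate_threshold()]).
#' @return Logical vector (`NA` where RMSD is `NA`).
#' @export
classify_bound <- function(rmsd, threshold = binding_defaults()$threshold_nm) {
  if (is.data.frame(rmsd)) rmsd <- rmsd$rmsd_nm
  if (inherits(threshold, "threshold_calibration")) threshold <- threshold$threshold
  check_scalar(threshold, "threshold", min = .Machine$double.eps)
  rmsd < threshold
}

#' Locate stationary nucleation seeds
#'
#' Determines seed (small immobile S-layer crystal patch) positions either
#' from a seed-channel image (peak detection + symmetric 2D Gaussian fits) or
#' from a localization table accumulated over time (cluster means with a
#' stationarity check).
#'
#' @param x Either a numeric matrix (image, photons; rows = y, columns = x,
#'   pixel centers at 0-based integer coordinates) or a data.frame with
#'   `x_nm`, `y_nm` and optionally `frame` and `seed_id`.
#' @param pixel_size_nm Pixel size for image input.
#' @param threshold_sd Detection threshold in robust SDs above background
#'   (image input).
#' @param psf_fwhm_nm Nominal PSF FWHM (image input); fitted seeds closer than
#'   one FWHM are flagged as unresolved.
#' @param cluster_radius_nm Single-linkage clustering radius for localization
#'   input.
#' @param loc_precision_nm Localization precision; a seed whose positional SD
#'   over time exceeds twice this is flagged non-stationary.
#'
#' @return data.frame `seed_id`, `x_nm`, `y_nm`, `n` (localizations or fitted
#'   amplitude), `pos_sd_nm`, `flagged` (logical), `flag_reason`.
#' @export
locate_seeds <- function(x, pixel_size_nm = 100, threshold_sd = 10,
                         psf_fwhm_nm = 300, cluster_radius_nm = 500,
                         loc_precision_nm = 20) {
  if (is.matrix(x)) {
    locate_seeds_image(x, pixel_size_nm, threshold_sd, psf_fwhm_nm)
  } else if (is.data.frame(x)) {
    locate_seeds_locs(x, cluster_radius_nm, loc_precision_nm)
  } else {
    stop("`x` must be an image matrix or a localization data.frame",
         call. = FALSE)
  }
}

locate_seeds_image <- function(img, pixel_size_nm, threshold_sd, psf_fwhm_nm) {
  cand <- detect_puncta(img, background_region = NULL,
                        threshold_sd = threshold_sd,
                        min_separation_px = max(1, psf_fwhm_nm / pixel_size_nm / 2))
  if (!nrow(cand)) {
    return(data.frame(seed_id = integer(), x_nm = numeric(), y_nm = numeric(),
                      n = numeric(), pos_sd_nm = numeric(),
                      flagged = logical(), flag_reason = character()))
  }
  sigma_px <- psf_fwhm_nm / 2.3548 / pixel_size_nm
  fits <- lapply(seq_len(nrow(cand)), function(i) {
    fit_gaussian_spot(img, cand$x_px[i], cand$y_px[i],
                      sigma_px = sigma_px, symmetric = TRUE)
  })
  ok <- !vapply(fits, is.null, logical(1))
  fits <- fits[ok]
  if (!length(fits)) {
    return(data.frame(seed_id = integer(), x_nm = numeric(), y_nm = numeric(),
                      n = numeric(), pos_sd_nm = numeric(),
                      flagged = logical(), flag_reason = character()))
  }
  xs <- vapply(fits, function(f) f$x0, numeric(1)) * pixel_size_nm
  ys <- vapply(fits, function(f) f$y0, numeric(1)) * pixel_size_nm
  amp <- vapply(fits, function(f) f$A, numeric(1))
  flagged <- rep(FALSE, length(xs))
  reason <- rep("", length(xs))
  # a fit much wider than the PSF is likely an unresolved pair of seeds
  # (two sources d apart fit as one Gaussian of width ~ sqrt(s^2 + d^2/4))
  wide <- vapply(fits, function(f) f$sx > 1.25 * sigma_px, logical(1))
  flagged[wide] <- TRUE
  reason[wide] <- "wider than the PSF: possible unresolved seed pair"
  if (length(xs) > 1) {
    dmat <- as.matrix(stats::dist(cbind(xs, ys)))
    diag(dmat) <- Inf
    too_close <- apply(dmat, 1, min) < psf_fwhm_nm
    flagged[too_close] <- TRUE
    reason[too_close] <- "unresolved: within one PSF width of another seed"
  }
  data.frame(seed_id = seq_along(xs), x_nm = xs, y_nm = ys, n = amp,
             pos_sd_nm = NA_real_, flagged = flagged, flag_reason = reason)
}

locate_seeds_locs <- function(locs, cluster_radius_nm, loc_precision_nm) {
  stopifnot(all(c("x_nm", "y_nm") %in% names(locs)))
  if (!"seed_id" %in% names(locs)) {
    if (nrow(locs) > 1) {
      hc <- stats::hclust(stats::dist(locs[, c("x_nm", "y_nm")]),
                          method = "single")
      locs$seed_id <- stats::cutree(hc, h = cluster_radius_nm)
    } else {
      locs$seed_id <- 1L
    }
  }
  out <- lapply(split(locs, locs$seed_id), function(g) {
    sd_pos <- sqrt(mean(c(var(g$x_nm), var(g$y_nm)), na.rm = TRUE))
    if (!is.finite(sd_pos)) sd_pos <- 0
    flagged <- sd_pos > 2 * loc_precision_nm
    data.frame(
      seed_id = g$seed_id[1], x_nm = mean(g$x_nm), y_nm = mean(g$y_nm),
      n = nrow(g), pos_sd_nm = sd_pos, flagged = flagged,
      flag_reason = if (flagged) "non-stationary: positional SD > 2 x precision" else ""
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Distance to the nearest nucleation seed
#'
#' Per-frame Euclidean distance between a tracked molecule and the closest
#' seed (d_NS).
#'
#' @param track Single-track data.frame with `x_nm`, `y_nm`.
#' @param seeds data.frame with `x_nm`, `y_nm` (e.g. from [locate_seeds()]),
#'   or a 2-column matrix in nm.
#' @return Numeric vector, one value per track row.
#' @export
distance_to_nearest_seed <- function(track, seeds) {
  if (is.data.frame(seeds)) seeds <- as.matrix(seeds[, c("x_nm", "y_nm")])
  seeds <- as.matrix(seeds)
  if (nrow(seeds) < 1L) stop("need at least one seed", call. = FALSE)
  p <- as.matrix(track[, c("x_nm", "y_nm")])
  d2 <- outer(rowSums(p^2), rowSums(seeds^2), "+") - 2 * p %*% t(seeds)
  sqrt(pmax(apply(d2, 1, min), 0))
}

#' Bound-state / seed-proximity co-occupancy fractions
#'
#' Categorizes each frame where both the bound state and d_NS are defined as
#' near-and-unbound, near-and-bound, or bound-but-not-near ("near" means
#' d_NS strictly below `proximity`), and reports the fraction of total
#' classified time in each category. The three fractions plus the remainder
#' (neither bound nor near) sum to 1 exactly.
#'
#' @param bound Logical series from [classify_bound()].
#' @param d_ns Numeric series from [distance_to_nearest_seed()], same frames.
#' @param proximity Proximity threshold in nm (default: the published 300 nm).
#' @param frame_interval_s Frame interval used to report total time.
#'
#' @return A list of class `"cooccupancy_summary"`: `total_time_s`, `n_frames`,
#'   `frac_near_unbound`, `frac_near_bound`, `frac_bound_not_near`,
#'   `frac_neither`.
#' @export
cooccupancy <- function(bound, d_ns,
                        proximity = binding_defaults()$proximity_nm,
                        frame_interval_s = binding_defaults()$frame_interval_s) {
  if (length(bound) != length(d_ns)) {
    stop("`bound` and `d_ns` must be aligned on the same frames", call. = FALSE)
  }
  check_scalar(proximity, "proximity", min = 0)
  ok <- !is.na(bound) & !is.na(d_ns)
  if (!any(ok)) stop("no frames with both series defined", call. = FALSE)
  b <- bound[ok]
  near <- d_ns[ok] < proximity
  n <- length(b)
  structure(
    list(
      total_time_s = n * frame_interval_s,
      n_frames = n,
      frac_near_unbound = sum(near & !b) / n,
      frac_near_bound = sum(near & b) / n,
      frac_bound_not_near = sum(b & !near) / n,
      frac_neither = sum(!b & !near) / n
    ),
    class = "cooccupancy_summary"
  )
}

#' @export
print.cooccupancy_summary <- function(x, ...) {
  cat(sprintf("Co-occupancy over %.1f s (%d frames):\n", x$total_time_s,
              x$n_frames))
  cat(sprintf("  near seed & unbound : %.3f\n", x$frac_near_unbound))
  cat(sprintf("  near seed & bound   : %.3f\n", x$frac_near_bound))
  cat(sprintf("  bound, not near     : %.3f\n", x$frac_bound_not_near))
  cat(sprintf("  neither             : %.3f\n", x$frac_neither))
  invisible(x)
}
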