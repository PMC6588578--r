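# Synthetic two-color STED-like cell images with known label patterns.
# Images are plain numeric matrices in photons/pixel, [row = y, col = x],
# pixel centers at 0-based integer coordinates, y increasing downward.

#' Label patterns for the cell-image simulator
#'
#' Constructors describing where fluorescent label sits on the cell surface
#' shell (2D projection): uniformly along the whole outline, enriched at the
#' poles, in short crack-like features on the cell body, or as discrete
#' puncta with known molecule counts.
#'
#' @param n_emitters Number of labeled molecules to place.
#' @param polar_fraction Fraction of emitters placed within the polar arc
#'   regions (polar pattern).
#' @param pole_extent Fraction of normalized arc length at each end counted
#'   as polar (default 0.15).
#' @param n_cracks,crack_length_nm,emitters_per_crack Crack pattern geometry.
#' @param centers_nm Punctum centers, an n x 2 matrix (x_nm, y_nm) in image
#'   coordinates.
#' @param molecules Molecule count per punctum (recycled).
#' @return A list describing the pattern, class `"label_pattern"`.
#' @name label_patterns
NULL

#' @rdname label_patterns
#' @export
label_uniform <- function(n_emitters = 3000L) {
  structure(list(type = "uniform", n_emitters = as.integer(n_emitters)),
            class = "label_pattern")
}

#' @rdname label_patterns
#' @export
label_polar <- function(n_emitters = 3000L, polar_fraction = 0.8,
                        pole_extent = 0.15) {
  check_scalar(polar_fraction, "polar_fraction", min = 0, max = 1)
  check_scalar(pole_extent, "pole_extent", min = 0.01, max = 0.5)
  structure(list(type = "polar_enriched", n_emitters = as.integer(n_emitters),
                 polar_fraction = polar_fraction, pole_extent = pole_extent),
            class = "label_pattern")
}

#' @rdname label_patterns
#' @export
label_cracks <- function(n_cracks = 3L, crack_length_nm = 400,
                         emitters_per_crack = 200L) {
  structure(list(type = "crack_features", n_cracks = as.integer(n_cracks),
                 crack_length_nm = crack_length_nm,
                 emitters_per_crack = as.integer(emitters_per_crack)),
            class = "label_pattern")
}

#' @rdname label_patterns
#' @export
label_puncta <- function(centers_nm, molecules) {
  centers_nm <- matrix(as.numeric(centers_nm), ncol = 2)
  molecules <- rep_len(molecules, nrow(centers_nm))
  structure(list(type = "puncta", centers_nm = centers_nm,
                 molecules = molecules),
            class = "label_pattern")
}

#' Configuration for the cell-image simulator
#'
#' @param pixel_size_nm Pixel size: 20 for STED-like, 100 for confocal-like,
#'   163 for EMCCD-like imaging.
#' @param psf_fwhm_nm PSF FWHM per fluorescence channel, nm (recycled to the
#'   number of channels).
#' @param photons_per_molecule_mean Mean detected photons per labeled
#'   molecule.
#' @param background_mean Background, photons/pixel.
#' @param cell_geometry List: `body_length_nm` (cylindrical mid-section),
#'   `body_radius_nm`, `centerline_curvature` (1/nm, 0 = straight rod),
#'   `stalk_length_nm`, `stalk_radius_nm`.
#' @param label_pattern_a,label_pattern_b Label patterns (see
#'   [label_patterns]); `label_pattern_b = NULL` gives a single-channel image.
#' @param rotation_deg In-plane rotation of the cell (for testing
#'   orientation recovery).
#' @param shell_halfwidth_nm Half-thickness of the projected surface shell
#'   that carries the label.
#' @param margin_nm Empty margin around the cell.
#' @param poisson_noise Apply Poisson noise to the rendered channels
#'   (the noise-free expectations are always returned as ground truth).
#' @param rng_seed Integer seed for reproducibility.
#' @return A validated list of class `"image_sim_config"`.
#' @export
image_sim_config <- function(pixel_size_nm = 20,
                             psf_fwhm_nm = c(60, 80),
                             photons_per_molecule_mean = 100,
                             background_mean = 0,
                             cell_geometry = list(),
                             label_pattern_a = label_uniform(),
                             label_pattern_b = NULL,
                             rotation_deg = 0,
                             shell_halfwidth_nm = 40,
                             margin_nm = 300,
                             poisson_noise = TRUE,
                             rng_seed = NULL) {
  check_scalar(pixel_size_nm, "pixel_size_nm", min = .Machine$double.eps)
  if (any(psf_fwhm_nm <= 0)) stop("`psf_fwhm_nm` must be > 0", call. = FALSE)
  check_scalar(photons_per_molecule_mean, "photons_per_molecule_mean", min = 0)
  check_scalar(background_mean, "background_mean", min = 0)
  geom <- utils::modifyList(
    list(body_length_nm = 2400, body_radius_nm = 400,
         centerline_curvature = 0, stalk_length_nm = 0,
         stalk_radius_nm = 60),
    cell_geometry
  )
  check_scalar(geom$body_length_nm, "body_length_nm", min = 0)
  check_scalar(geom$body_radius_nm, "body_radius_nm",
               min = .Machine$double.eps)
  check_scalar(geom$centerline_curvature, "centerline_curvature", min = 0)
  check_scalar(geom$stalk_length_nm, "stalk_length_nm", min = 0)
  stopifnot(inherits(label_pattern_a, "label_pattern"),
            is.null(label_pattern_b) || inherits(label_pattern_b,
                                                 "label_pattern"))
  structure(
    list(pixel_size_nm = pixel_size_nm, psf_fwhm_nm = psf_fwhm_nm,
         photons_per_molecule_mean = photons_per_molecule_mean,
         background_mean = background_mean, cell_geometry = geom,
         label_pattern_a = label_pattern_a, label_pattern_b = label_pattern_b,
         rotation_deg = rotation_deg,
         shell_halfwidth_nm = shell_halfwidth_nm, margin_nm = margin_nm,
         poisson_noise = isTRUE(poisson_noise), rng_seed = rng_seed),
    class = "image_sim_config"
  )
}

#' Simulate a two-color cell image with known ground truth
#'
#' Renders a spherocylindrical (optionally crescent-shaped) cell:
#' a transmitted-light channel whose intensity peaks on the cell midline
#' (so the cell axis can be recovered from per-column maxima), and one or two
#' fluorescence channels in which labeled molecules on the projected surface
#' shell are rendered as PSF-convolved emitter density with Poisson noise.
#'
#' @param config An [image_sim_config()].
#' @return A list of class `"cell_image_sim"`:
#'   * `record` — a [cell_record()] (transmitted + fluorescence channels),
#'   * `truth` — ground truth: noise-free `expected_a`/`expected_b` images,
#'     per-channel label masks (`mask_a`, `mask_b`; pixels containing label),
#'     the cell `silhouette`, surface `shell` band mask, `centerline_nm`
#'     polyline, emitter tables, and for puncta patterns the punctum table.
#' @export
simulate_cell_image <- function(config) {
  stopifnot(inherits(config, "image_sim_config"))
  with_seed(config$rng_seed, simulate_cell_image_impl(config))
}

simulate_cell_image_impl <- function(config) {
  px <- config$pixel_size_nm
  g <- config$cell_geometry
  margin <- config$margin_nm + 3 * max(config$psf_fwhm_nm)
  total_len <- g$body_length_nm + 2 * g$body_radius_nm + g$stalk_length_nm
  sag <- if (g$centerline_curvature > 0) {
    R <- 1 / g$centerline_curvature
    R * (1 - cos(min(g$body_length_nm / (2 * R), pi / 2)))
  } else 0
  width_nm <- total_len + 2 * margin
  height_nm <- 2 * g$body_radius_nm + sag + 2 * margin
  # generous square-ish canvas when the cell is to be drawn rotated
  if (config$rotation_deg %% 180 != 0) {
    height_nm <- max(height_nm, width_nm)
    width_nm <- max(height_nm, width_nm)
  }
  nx <- ceiling(width_nm / px)
  ny <- ceiling(height_nm / px)

  cl <- cell_centerline(g, n = 400)
  # rotate and center (nm coordinates of the canvas: x right, y down)
  th <- config$rotation_deg * pi / 180
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  cl_xy <- sweep(cl$points, 2, colMeans(cl$points)) %*% t(rot)
  center <- c((nx - 1) / 2, (ny - 1) / 2) * px
  cl_xy <- sweep(cl_xy, 2, center, "+")
  stalk_xy <- NULL
  if (g$stalk_length_nm > 0) {
    stalk_xy <- sweep(sweep(cl$stalk, 2, colMeans(cl$points)) %*% t(rot),
                      2, center, "+")
  }

  # pixel center coordinates in nm
  xs <- (seq_len(nx) - 1) * px
  ys <- (seq_len(ny) - 1) * px
  pts <- cbind(rep(xs, each = ny), rep(ys, nx)) # row-major [y fastest]
  near <- nearest_polyline_point(pts, cl_xy)
  dmat <- matrix(near$dist, ny, nx)
  umat <- matrix(cl$u[near$index], ny, nx)
  r <- g$body_radius_nm
  silhouette <- dmat <= r
  trans <- matrix(0, ny, nx)
  inside <- silhouette
  trans[inside] <- sqrt(pmax(0, 1 - (dmat[inside] / r)^2))
  if (!is.null(stalk_xy)) {
    near_s <- nearest_polyline_point(pts, stalk_xy)
    ds <- matrix(near_s$dist, ny, nx)
    sr <- g$stalk_radius_nm
    stalk_in <- ds <= sr
    trans[stalk_in] <- pmax(trans[stalk_in],
                            0.7 * sqrt(pmax(0, 1 - (ds[stalk_in] / sr)^2)))
    silhouette <- silhouette | stalk_in
  }
  trans_peak <- 1000
  trans <- trans * trans_peak
  trans_obs <- matrix(rpois(length(trans), trans + 5), ny, nx)

  shell <- abs(dmat - r) <= config$shell_halfwidth_nm
  channels <- list(a = config$label_pattern_a, b = config$label_pattern_b)
  rendered <- list(); truth <- list()
  fwhm <- rep_len(config$psf_fwhm_nm, 2)
  for (ci in seq_along(channels)) {
    pat <- channels[[ci]]
    if (is.null(pat)) next
    nm <- names(channels)[ci]
    em <- place_emitters(pat, shell, umat, px, nx, ny)
    if (pat$type == "puncta") {
      bad <- em$emitters$x_nm < 0 | em$emitters$x_nm > (nx - 1) * px |
        em$emitters$y_nm < 0 | em$emitters$y_nm > (ny - 1) * px
      if (any(bad)) stop("puncta centers outside the image", call. = FALSE)
    }
    dens <- matrix(0, ny, nx)
    rowi <- pmin(pmax(round(em$emitters$y_nm / px), 0), ny - 1) + 1
    coli <- pmin(pmax(round(em$emitters$x_nm / px), 0), nx - 1) + 1
    for (k in seq_len(nrow(em$emitters))) {
      dens[rowi[k], coli[k]] <- dens[rowi[k], coli[k]] + 1
    }
    sigma_px <- fwhm[ci] / 2.3548 / px
    expected <- convolve_psf(dens, sigma_px) *
      config$photons_per_molecule_mean + config$background_mean
    expected <- pmax(expected, 0) # clip FFT round-off undershoot
    obs <- if (config$poisson_noise) {
      matrix(rpois(length(expected), expected), ny, nx)
    } else expected
    mask <- dens > 0
    rendered[[nm]] <- obs
    truth[[paste0("expected_", nm)]] <- expected
    truth[[paste0("mask_", nm)]] <- mask
    truth[[paste0("emitters_", nm)]] <- em$emitters
    if (!is.null(em$puncta)) truth[[paste0("puncta_", nm)]] <- em$puncta
  }

  record <- cell_record(
    transmitted = trans_obs,
    channel_a = rendered$a,
    channel_b = rendered$b,
    pixel_size_nm = px,
    stalk_side = if (g$stalk_length_nm > 0) "left" else "unknown"
  )
  truth$silhouette <- silhouette
  truth$shell <- shell
  truth$centerline_nm <- cl_xy
  truth$transmitted_expected <- trans
  structure(list(record = record, truth = truth, config = config),
            class = "cell_image_sim")
}

# Centerline polyline (nm, unrotated: x along the cell axis, y the sag
# direction), normalized arc-length u in [0,1], and stalk polyline extending
# from the left pole.
cell_centerline <- function(g, n = 400) {
  L <- g$body_length_nm
  if (g$centerline_curvature > 0 && L > 0) {
    R <- 1 / g$centerline_curvature
    s <- seq(-L / 2, L / 2, length.out = n)
    pts <- cbind(R * sin(s / R), R * (1 - cos(s / R)))
  } else {
    s <- seq(-max(L, 1e-9) / 2, max(L, 1e-9) / 2, length.out = n)
    pts <- cbind(s, 0)
  }
  arc <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  stalk <- NULL
  if (g$stalk_length_nm > 0) {
    tangent <- pts[1, ] - pts[2, ]
    tangent <- tangent / sqrt(sum(tangent^2))
    base <- pts[1, ] + tangent * g$body_radius_nm
    tip <- base + tangent * g$stalk_length_nm
    stalk <- rbind(base, tip)
  }
  list(points = pts, u = arc / max(arc), stalk = stalk)
}

# Sample emitter positions for a label pattern. `shell` is the logical band
# mask, `umat` the normalized arc-length of each pixel's nearest centerline
# point. Emitters are placed at pixel centers + sub-pixel jitter.
place_emitters <- function(pat, shell, umat, px, nx, ny) {
  idx <- which(shell)
  if (!length(idx) && pat$type != "puncta") {
    stop("empty surface shell; check geometry vs image size", call. = FALSE)
  }
  rows <- ((idx - 1) %% ny)
  cols <- ((idx - 1) %/% ny)
  u <- umat[idx]
  jit <- function(n) runif(n, -0.5, 0.5)
  sample_pixels <- function(n, w) {
    pick <- sample.int(length(idx), n, replace = TRUE, prob = w)
    data.frame(x_nm = (cols[pick] + jit(n)) * px,
               y_nm = (rows[pick] + jit(n)) * px)
  }
  puncta <- NULL
  em <- switch(pat$type,
    uniform = sample_pixels(pat$n_emitters, NULL),
    polar_enriched = {
      polar <- u < pat$pole_extent | u > 1 - pat$pole_extent
      w <- ifelse(polar,
                  pat$polar_fraction / max(sum(polar), 1),
                  (1 - pat$polar_fraction) / max(sum(!polar), 1))
      sample_pixels(pat$n_emitters, w)
    },
    crack_features = {
      body <- u > 0.2 & u < 0.8
      centers <- sample(u[body], pat$n_cracks)
      total_arc <- diff(range(u))
      halfu <- pat$crack_length_nm / 2 / 4000 # approx arc->u scale
      sel_list <- lapply(centers, function(uc) {
        w <- as.numeric(abs(u - uc) < max(halfu, 0.02))
        sample_pixels(pat$emitters_per_crack, w)
      })
      do.call(rbind, sel_list)
    },
    puncta = {
      reps <- rep(seq_len(nrow(pat$centers_nm)), pat$molecules)
      puncta <- data.frame(punctum = seq_len(nrow(pat$centers_nm)),
                           x_nm = pat$centers_nm[, 1],
                           y_nm = pat$centers_nm[, 2],
                           molecules = pat$molecules)
      data.frame(x_nm = pat$centers_nm[reps, 1],
                 y_nm = pat$centers_nm[reps, 2])
    },
    stop("unknown label pattern type", call. = FALSE)
  )
  list(emitters = em, puncta = puncta)
}

# Convolve a density image with a normalized Gaussian kernel (truncated at
# 4 sigma, renormalized, so total counts are conserved exactly).
convolve_psf <- function(img, sigma_px) {
  if (sigma_px <= 0) return(img)
  r <- max(1L, ceiling(4 * sigma_px))
  g1 <- exp(-((-r:r)^2) / (2 * sigma_px^2))
  k <- outer(g1, g1)
  k <- k / sum(k)
  as.matrix(EBImage::filter2(img, k))
}
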