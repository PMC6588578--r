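# Shared fixture builders. Everything is generated in code at test time.

# A field of PSF-rendered puncta at given centers/molecule counts.
mk_puncta_field <- function(centers, molecules, photons = 120, seed = 1,
                            fwhm = 60, bg = 1, noise = TRUE) {
  cfg <- image_sim_config(
    pixel_size_nm = 20, psf_fwhm_nm = fwhm,
    photons_per_molecule_mean = photons, background_mean = bg,
    cell_geometry = list(body_length_nm = 2400),
    label_pattern_a = label_puncta(centers, molecules),
    poisson_noise = noise, rng_seed = seed
  )
  simulate_cell_image(cfg)
}

# A labeled cell image (straight rod unless stated).
mk_cell <- function(pattern = label_uniform(4000), rotation = 0, seed = 1,
                    noise = TRUE, pattern_b = NULL, body_length = 2400,
                    stalk = 0, curvature = 0, photons = 100, bg = 0) {
  cfg <- image_sim_config(
    cell_geometry = list(body_length_nm = body_length,
                         stalk_length_nm = stalk,
                         centerline_curvature = curvature),
    label_pattern_a = pattern, label_pattern_b = pattern_b,
    rotation_deg = rotation, poisson_noise = noise,
    photons_per_molecule_mean = photons, background_mean = bg,
    rng_seed = seed
  )
  simulate_cell_image(cfg)
}

# Independent closed-form Wilson interval used as the test oracle
# (evaluated from the defining formula, kept separate from the package code).
oracle_wilson <- function(k, n, z = qnorm(0.975)) {
  p <- k / n
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z / (1 + z^2 / n) * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  c(low = max(0, centre - half), high = min(1, centre + half))
}

# Brute-force per-pixel axial projection oracle for project_profile().
oracle_project <- function(mask, axis, n_bins = 40L) {
  upper <- logical(n_bins); lower <- logical(n_bins)
  ny <- nrow(mask)
  for (idx in which(mask)) {
    px <- (idx - 1) %/% ny
    py <- (idx - 1) %% ny
    d2 <- (axis$x_px - px)^2 + (axis$y_px - py)^2
    i <- which.min(d2)
    u <- axis$u[i]
    bin <- min(floor(u * n_bins), n_bins - 1L) + 1L
    i2 <- min(i + 1L, length(axis$x_px)); i1 <- max(i - 1L, 1L)
    tx <- axis$x_px[i2] - axis$x_px[i1]
    ty <- axis$y_px[i2] - axis$y_px[i1]
    cross <- tx * (py - axis$y_px[i]) - ty * (px - axis$x_px[i])
    if (cross <= 0) upper[bin] <- TRUE else lower[bin] <- TRUE
  }
  list(upper = upper, lower = lower)
}

# O(n^2) double-loop MSD oracle.
oracle_msd <- function(track, max_lag) {
  axes <- intersect(c("x_nm", "y_nm", "z_nm"), names(track))
  pos <- as.matrix(track[, axes]) / 1000
  frames <- track$frame
  out <- data.frame(lag_frames = integer(), msd_um2 = numeric(),
                    n_pairs = integer())
  for (lag in seq_len(max_lag)) {
    d2 <- c()
    for (i in seq_along(frames)) {
      j <- which(frames == frames[i] + lag)
      if (length(j) == 1) d2 <- c(d2, sum((pos[j, ] - pos[i, ])^2))
    }
    if (length(d2)) {
      out <- rbind(out, data.frame(lag_frames = lag, msd_um2 = mean(d2),
                                   n_pairs = length(d2)))
    }
  }
  out
}
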