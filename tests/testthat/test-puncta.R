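test_that("pure-noise images yield no candidates at 10 SD", {
  set.seed(101)
  noise <- matrix(rpois(300 * 300, 10), 300)
  expect_identical(nrow(detect_puncta(noise)), 0L)
})

test_that("planted spots are detected at their location, dim ones ignored", {
  set.seed(102)
  bg <- 10
  img <- matrix(rpois(200 * 200, bg), 200)
  spot <- function(img, cx, cy, peak, s = 2.5) {
    for (r in 1:nrow(img)) for (c in 1:ncol(img)) {
      img[r, c] <- img[r, c] +
        peak * exp(-((c - 1 - cx)^2 + (r - 1 - cy)^2) / (2 * s^2))
    }
    img
  }
  sdb <- mad(img)
  img1 <- spot(img, 80, 120, 20 * sdb)
  cand <- detect_puncta(img1, min_separation_px = 5)
  expect_identical(nrow(cand), 1L)
  expect_lte(max(abs(c(cand$x_px - 80, cand$y_px - 120))), 1)

  # 5 spots above and 3 below threshold, verified against a brute-force scan
  # of the noise-free render
  centers <- cbind(x = c(30, 90, 150, 30, 90, 150, 30, 90),
                   y = c(30, 30, 30, 100, 100, 100, 170, 170))
  peaks <- c(rep(25 * sdb, 5), rep(3 * sdb, 3))
  clean <- matrix(bg, 200, 200)
  for (i in seq_len(nrow(centers))) {
    clean <- spot(clean, centers[i, 1], centers[i, 2], peaks[i])
  }
  thr <- median(img) + 10 * mad(img)
  n_above <- sum(sapply(seq_len(nrow(centers)), function(i) {
    clean[centers[i, 2] + 1, centers[i, 1] + 1] > thr
  }))
  expect_identical(n_above, 5L)
  noisy <- matrix(rpois(length(clean), clean), 200)
  # merge radius slightly above the spot FWHM (~6 px) so noise-split maxima
  # within one spot collapse to a single candidate
  cand5 <- detect_puncta(noisy, min_separation_px = 8)
  expect_identical(nrow(cand5), 5L)
})

test_that("degenerate background is rejected", {
  flat <- matrix(7, 50, 50)
  expect_error(detect_puncta(flat), "SD = 0")
})

test_that("asymmetric Gaussian fits recover parameters and photons exactly", {
  A <- 100; sx <- 4; sy <- 3 # px; 80 and 60 nm at 20 nm/px
  img <- matrix(0, 61, 61)
  for (r in 1:61) for (c in 1:61) {
    img[r, c] <- A * exp(-((c - 31)^2 / (2 * sx^2) + (r - 31)^2 / (2 * sy^2)))
  }
  p <- fit_punctum(img, list(x_px = 30, y_px = 30), pixel_size_nm = 20,
                   psf_fwhm_nm = 60, sigma_range = c(0.2, 6))
  expect_s3_class(p, "punctum")
  expect_equal(unname(p$widths_nm), c(80, 60), tolerance = 0.01)
  expect_equal(unname(p$center_nm), c(600, 600), tolerance = 1)
  expect_equal(p$integrated_photons, 2 * pi * A * sx * sy, tolerance = 0.01)
})

test_that("circular spots give equal widths and flat windows are rejected", {
  set.seed(103)
  img <- matrix(rpois(61 * 61, 5), 61)
  for (r in 1:61) for (c in 1:61) {
    img[r, c] <- img[r, c] + 300 * exp(-((c - 31)^2 + (r - 31)^2) / (2 * 3^2))
  }
  p <- fit_punctum(img, list(x_px = 30, y_px = 30), pixel_size_nm = 20,
                   psf_fwhm_nm = 60, sigma_range = c(0.2, 6))
  expect_equal(p$widths_nm[["sx"]], p$widths_nm[["sy"]], tolerance = 0.1)
  flat <- matrix(rpois(61 * 61, 20), 61)
  rej <- fit_punctum(flat, list(x_px = 30, y_px = 30), pixel_size_nm = 20,
                     psf_fwhm_nm = 60)
  expect_s3_class(rej, "punctum_rejection")
})

test_that("photon and bleaching calibration recover the generator truth", {
  gx <- seq(600, 3400, length.out = 5)
  gy <- seq(600, 1500, length.out = 4)
  centers <- as.matrix(expand.grid(gx, gy))
  sted <- mk_puncta_field(centers, 1, photons = 2000, seed = 31)
  # confocal sees 25 molecules where STED only retains 20: bleach = 1.25
  centers_conf <- rbind(centers, cbind(seq(700, 3000, length.out = 5), 1800))
  conf <- mk_puncta_field(centers_conf, 1, photons = 2000, seed = 32,
                          fwhm = 180)
  cal <- calibrate_photons_per_molecule(sted$record$channel_a,
                                        conf$record$channel_a,
                                        pixel_size_nm = 20, psf_fwhm_nm = 60)
  expect_equal(cal$bleach_correction, 1.25)
  expect_equal(cal$photons_per_molecule, 2000, tolerance = 0.05)
  # identical fields -> bleach correction 1
  cal1 <- calibrate_photons_per_molecule(sted$record$channel_a,
                                         sted$record$channel_a,
                                         pixel_size_nm = 20,
                                         psf_fwhm_nm = 60)
  expect_equal(cal1$bleach_correction, 1)
  # too few molecules -> error
  few <- mk_puncta_field(matrix(c(1000, 1000), 1), 1, photons = 2000,
                         seed = 33)
  expect_error(
    calibrate_photons_per_molecule(few$record$channel_a,
                                   few$record$channel_a,
                                   pixel_size_nm = 20, psf_fwhm_nm = 60),
    "fewer than 10")
})

test_that("molecules_per_punctum follows the correction formula", {
  expect_equal(molecules_per_punctum(5000, counting_calibration(100)), 50)
  expect_equal(molecules_per_punctum(
    5000, counting_calibration(100, labeling_efficiency = 0.5)), 100)
  expect_equal(molecules_per_punctum(
    5000, counting_calibration(100, bleach_correction = 1.2,
                               labeling_efficiency = 0.8)), 75)
  expect_error(counting_calibration(100, labeling_efficiency = 0),
               "labeling_efficiency")
  # linearity / inverse-scaling properties
  base <- molecules_per_punctum(3000, counting_calibration(150, 1.1, 0.7))
  expect_equal(molecules_per_punctum(6000, counting_calibration(150, 1.1, 0.7)),
               2 * base)
  expect_equal(molecules_per_punctum(3000, counting_calibration(150, 2.2, 0.7)),
               2 * base)
  expect_equal(molecules_per_punctum(3000, counting_calibration(300, 1.1, 0.7)),
               base / 2)
  expect_equal(molecules_per_punctum(3000, counting_calibration(150, 1.1, 0.35)),
               2 * base)
})

test_that("molecule counts of rendered puncta are recovered within 15%", {
  set.seed(104)
  nmol <- sample(10:100, 12)
  centers <- cbind(rep(seq(600, 3400, length.out = 6), 2),
                   rep(c(700, 1400), each = 6))
  sim <- mk_puncta_field(centers, nmol, photons = 120, seed = 34, bg = 2)
  cal <- counting_calibration(120)
  res <- count_puncta(sim$record$channel_a, cal, pixel_size_nm = 20,
                      psf_fwhm_nm = 60)
  expect_identical(nrow(res), length(nmol))
  truth <- sim$truth$puncta_a
  match_i <- sapply(seq_len(nrow(res)), function(i) {
    which.min((truth$x_nm - res$x_nm[i])^2 + (truth$y_nm - res$y_nm[i])^2)
  })
  rel <- abs(res$molecules - truth$molecules[match_i]) /
    truth$molecules[match_i]
  expect_lt(median(rel), 0.15)
})

test_that("detected punctum counts are monotone in planted counts", {
  cal <- counting_calibration(120)
  counts <- sapply(c(4, 8, 12), function(k) {
    centers <- cbind(rep(seq(600, 3400, length.out = 6), 2)[1:k],
                     rep(c(700, 1400), each = 6)[1:k])
    sim <- mk_puncta_field(centers, 40, photons = 120, seed = 100 + k, bg = 2)
    nrow(count_puncta(sim$record$channel_a, cal, pixel_size_nm = 20,
                      psf_fwhm_nm = 60))
  })
  expect_true(all(diff(counts) > 0))
})
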