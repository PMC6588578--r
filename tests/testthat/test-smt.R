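test_that("well-separated emitters link into pure tracks", {
  locs <- data.frame(frame = rep(1:10, each = 2),
                     x_nm = c(rbind(seq(0, 180, 20), seq(2000, 2180, 20))),
                     y_nm = 0)
  lk <- link_localizations(locs, max_step = 100)
  expect_identical(length(unique(lk$track_id)), 2L)
  for (t in split_tracks(lk)) {
    expect_identical(nrow(t), 10L)
    expect_lt(max(abs(diff(t$x_nm))), 21)
  }
})

test_that("detection gaps within max_gap are bridged", {
  locs <- data.frame(frame = c(1, 2, 4, 5), x_nm = c(0, 20, 60, 80), y_nm = 0)
  expect_identical(length(unique(
    link_localizations(locs, max_step = 100, max_gap = 1)$track_id)), 1L)
  expect_identical(length(unique(
    link_localizations(locs, max_step = 100, max_gap = 0)$track_id)), 2L)
})

test_that("linking matches the exhaustive per-frame assignment oracle", {
  # two planted tracks passing near each other; brute-force minimal total
  # distance assignment per frame over all permutations (n <= 4)
  set.seed(201)
  n <- 30
  t1 <- cbind(seq(0, 2900, by = 100), 500 + rnorm(n, 0, 10))
  t2 <- cbind(seq(2900, 0, by = -100), 560 + rnorm(n, 0, 10))
  locs <- data.frame(frame = rep(1:n, 2),
                     x_nm = c(t1[, 1], t2[, 1]),
                     y_nm = c(t1[, 2], t2[, 2]),
                     truth = rep(1:2, each = n))
  lk <- link_localizations(locs[order(locs$frame), ], max_step = 300)
  # oracle: sequential per-frame optimal matching
  oracle_id <- rep(NA_integer_, nrow(locs))
  locs_o <- locs[order(locs$frame), ]
  prev <- NULL
  next_id <- 1
  for (f in 1:n) {
    rows <- which(locs_o$frame == f)
    if (is.null(prev)) {
      oracle_id[rows] <- seq_along(rows)
      next_id <- length(rows) + 1
    } else {
      perms <- list(c(1, 2), c(2, 1))
      cost <- sapply(perms, function(p) {
        sum(sqrt((locs_o$x_nm[rows] - locs_o$x_nm[prev][p])^2 +
                   (locs_o$y_nm[rows] - locs_o$y_nm[prev][p])^2))
      })
      p <- perms[[which.min(cost)]]
      oracle_id[rows] <- oracle_id[prev][p]
    }
    prev <- rows
  }
  locs_o$oracle <- oracle_id
  merged <- merge(lk, locs_o, by = c("frame", "x_nm", "y_nm"))
  tab <- table(merged$track_id, merged$oracle)
  # one-to-one correspondence between greedy track ids and oracle ids
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
})

test_that("sliding RMSD handles degenerate and analytic cases", {
  stat <- data.frame(frame = 1:40, t_s = (0:39) * 0.05,
                     x_nm = 5, y_nm = -3)
  expect_true(all(sliding_rmsd(stat)$rmsd_nm == 0))
  alt <- data.frame(frame = 1:40, t_s = (0:39) * 0.05,
                    x_nm = rep(c(0, 100), 20), y_nm = 0)
  expect_equal(sliding_rmsd(alt)$rmsd_nm, rep(50, 21))
  short <- data.frame(frame = 1:10, t_s = (0:9) * 0.05, x_nm = 1, y_nm = 1)
  expect_identical(nrow(sliding_rmsd(short)), 0L)
})

test_that("mean RMSD of pure-noise windows matches the chi closed form", {
  # RMSD of w iid 2D Gaussian points = sigma/sqrt(w) * chi_{2(w-1)};
  # E[chi_k] = sqrt(2) * gamma((k+1)/2) / gamma(k/2)
  set.seed(202)
  sigma <- 30; w <- 20; n_win <- 1e4
  k <- 2 * (w - 1)
  expected <- sigma / sqrt(w) * sqrt(2) * exp(lgamma((k + 1) / 2) -
                                                lgamma(k / 2))
  # non-overlapping windows: take every w-th value of one long track
  n <- n_win * w
  trk <- data.frame(frame = 1:n, t_s = (1:n - 1) * 0.05,
                    x_nm = rnorm(n, 0, sigma), y_nm = rnorm(n, 0, sigma))
  r <- sliding_rmsd(trk, w)$rmsd_nm
  r_indep <- r[seq(1, length(r), by = w)]
  se <- sd(r_indep) / sqrt(length(r_indep))
  expect_lt(abs(mean(r_indep) - expected), 3 * se)
})

test_that("sliding RMSD is rigid-motion invariant and scales linearly", {
  set.seed(203)
  trk <- data.frame(frame = 1:60, t_s = (0:59) * 0.05,
                    x_nm = cumsum(rnorm(60, 0, 40)),
                    y_nm = cumsum(rnorm(60, 0, 40)))
  base <- sliding_rmsd(trk)$rmsd_nm
  th <- 0.8
  rot <- trk
  rot$x_nm <- cos(th) * trk$x_nm - sin(th) * trk$y_nm + 1e4
  rot$y_nm <- sin(th) * trk$x_nm + cos(th) * trk$y_nm - 2e3
  expect_equal(sliding_rmsd(rot)$rmsd_nm, base, tolerance = 1e-9)
  sc <- trk
  sc$x_nm <- 3 * trk$x_nm
  sc$y_nm <- 3 * trk$y_nm
  expect_equal(sliding_rmsd(sc)$rmsd_nm, 3 * base, tolerance = 1e-9)
})

test_that("threshold calibration recovers mean + 2 sigma of the low mode", {
  set.seed(204)
  v <- rnorm(4000, 30, 10)
  th <- calibrate_threshold(v[v > 0])
  expect_equal(th$threshold, 50, tolerance = 0.05)
  # bimodal mixture: threshold governed by the low mode only
  v2 <- c(rnorm(3000, 30, 10), rnorm(3000, 200, 40))
  th2 <- calibrate_threshold(v2[v2 > 0])
  expect_equal(th2$threshold, 50, tolerance = 0.06)
  expect_error(calibrate_threshold(rnorm(100, 30, 10)), "500")
})

test_that("published defaults expose 57.3 nm and 300 nm thresholds", {
  d <- binding_defaults()
  expect_identical(d$threshold_nm, 57.3)
  expect_identical(d$proximity_nm, 300)
  expect_identical(d$window_frames, 20L)
})

test_that("bound classification uses a strict inequality", {
  expect_false(classify_bound(57.3, 57.3)) # boundary value is unbound
  expect_true(classify_bound(57.29, 57.3))
  expect_true(all(classify_bound(rep(0, 5))))
  # monotonicity: inflating RMSD never converts unbound -> bound
  set.seed(205)
  r <- runif(200, 0, 120)
  b1 <- classify_bound(r)
  b2 <- classify_bound(r + runif(200, 0, 30))
  expect_false(any(!b1 & b2))
})

test_that("seed positions are recovered from images and drift is flagged", {
  # noise-free field of two seeds 6 um apart
  img <- matrix(1, 120, 120)
  ctrs <- list(c(30, 40), c(90, 80))
  for (ct in ctrs) {
    for (r in 1:120) for (c in 1:120) {
      img[r, c] <- img[r, c] +
        400 * exp(-((c - 1 - ct[1])^2 + (r - 1 - ct[2])^2) / (2 * 2.5^2))
    }
  }
  seeds <- locate_seeds(img, pixel_size_nm = 100, psf_fwhm_nm = 500)
  expect_identical(nrow(seeds), 2L)
  seeds <- seeds[order(seeds$x_nm), ]
  expect_lt(abs(seeds$x_nm[1] - 3000), 10)
  expect_lt(abs(seeds$y_nm[1] - 4000), 10)
  expect_lt(abs(seeds$x_nm[2] - 9000), 10)
  expect_false(any(seeds$flagged))
  # drifting seed localizations: 5 nm/frame
  drift <- data.frame(x_nm = cumsum(rep(5, 200)), y_nm = 0, seed_id = 1)
  expect_true(locate_seeds(drift)$flagged)
  still <- data.frame(x_nm = rnorm(200, 0, 10), y_nm = rnorm(200, 0, 10),
                      seed_id = 1)
  expect_false(locate_seeds(still, loc_precision_nm = 20)$flagged)
})

test_that("overlapping seeds within one PSF width are flagged", {
  # two sources 450 nm apart, PSF FWHM 500 nm: they merge into one blob
  # wider than the PSF, or two fits closer than one FWHM — flagged either way
  img <- matrix(1, 120, 120)
  s_px <- 500 / 2.3548 / 100
  for (ct in list(c(58, 60), c(62.5, 60))) {
    for (r in 1:120) for (c in 1:120) {
      img[r, c] <- img[r, c] +
        400 * exp(-((c - 1 - ct[1])^2 + (r - 1 - ct[2])^2) / (2 * s_px^2))
    }
  }
  seeds <- locate_seeds(img, pixel_size_nm = 100, psf_fwhm_nm = 500)
  expect_true(any(seeds$flagged))
})

test_that("distance to nearest seed matches the exhaustive oracle", {
  expect_equal(distance_to_nearest_seed(
    data.frame(x_nm = 300, y_nm = 400), matrix(0, 1, 2)), 500)
  expect_equal(distance_to_nearest_seed(
    data.frame(x_nm = 70, y_nm = -20), matrix(c(70, -20), 1)), 0)
  set.seed(206)
  seeds <- matrix(runif(6, -2000, 2000), 3)
  trk <- data.frame(x_nm = runif(100, -2000, 2000),
                    y_nm = runif(100, -2000, 2000))
  d <- distance_to_nearest_seed(trk, seeds)
  oracle <- sapply(seq_len(100), function(i) {
    min(sqrt((seeds[, 1] - trk$x_nm[i])^2 + (seeds[, 2] - trk$y_nm[i])^2))
  })
  expect_equal(d, oracle, tolerance = 1e-12)
})

test_that("co-occupancy fractions are exact and sum to one", {
  none <- cooccupancy(rep(FALSE, 100), rep(1000, 100))
  expect_equal(none$frac_near_unbound, 0)
  expect_equal(none$frac_near_bound, 0)
  expect_equal(none$frac_bound_not_near, 0)
  # bound exactly when near, 27 s of 60 s at 20 frames/s
  n <- 1200
  b <- c(rep(TRUE, 540), rep(FALSE, n - 540))
  d <- ifelse(b, 100, 1000)
  cs <- cooccupancy(b, d)
  expect_equal(cs$frac_near_bound, 0.45)
  expect_equal(cs$frac_near_unbound, 0)
  expect_equal(cs$frac_bound_not_near, 0)
  expect_equal(cs$total_time_s, 60)
  set.seed(207)
  b2 <- runif(500) < 0.3
  d2 <- runif(500, 0, 600)
  cs2 <- cooccupancy(b2, d2)
  expect_equal(cs2$frac_near_unbound + cs2$frac_near_bound +
                 cs2$frac_bound_not_near + cs2$frac_neither, 1)
  expect_error(cooccupancy(NA, NA), "defined")
})

test_that("irreversibly captured tracks classify bound at the default threshold", {
  # k_off = 0, capture radius 150 nm, localization error <= 30 nm/axis:
  # every frame whose full RMSD window lies in the bound period must be bound
  seeds <- matrix(c(0, 0), 1)
  trk <- simulate_tracks(track_sim_config(
    diffusion_coefficient = 0.05, dimensionality = 2,
    localization_error_xyz = c(30, 30), n_tracks = 6,
    n_frames_per_track = 300,
    binding = list(seed_positions = seeds, capture_radius = 150,
                   on_rate = Inf, off_rate = 0),
    start_halfwidth = 400, rng_seed = 208))
  w <- binding_defaults()$window_frames
  for (t in split_tracks(trk)) {
    rm <- sliding_rmsd(t, w)
    if (!nrow(rm)) next
    b <- classify_bound(rm)
    st <- t$true_state == "bound"
    stable_bound <- vapply(match(rm$frame, t$frame), function(i) {
      lo <- i - (w - 1) %/% 2
      all(st[lo:(lo + w - 1)])
    }, logical(1))
    expect_true(all(b[stable_bound]))
  }
})
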