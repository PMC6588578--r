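test_that("channel registration recovers planted integer and subpixel shifts", {
  sim <- mk_cell(seed = 21, noise = FALSE)
  rec <- sim$record
  shifted <- slakit:::translate_image(rec$channel_a, 3, -2)
  rec$channel_a <- shifted
  out <- register_channels(rec)
  expect_equal(unname(out$shifts$a[c("dx", "dy")]), c(-3, 2))
  expect_equal(out$channel_a, sim$record$channel_a, tolerance = 1e-9)

  # zero-shift input -> identity
  out0 <- register_channels(sim$record)
  expect_equal(unname(out0$shifts$a[c("dx", "dy")]), c(0, 0))

  # subpixel planted shift (1.4, 0) -> nearest integer shift, checked against
  # a brute-force correlation oracle over all integer shifts
  sub <- 0.6 * slakit:::translate_image(sim$record$channel_a, 1, 0) +
    0.4 * slakit:::translate_image(sim$record$channel_a, 2, 0)
  rec2 <- sim$record
  rec2$channel_a <- sub
  out2 <- register_channels(rec2)
  ref <- slakit:::gradient_magnitude(sim$record$transmitted)
  scores <- sapply(-3:3, function(dx) {
    sum(ref * slakit:::translate_image(sub, dx, 0))
  })
  expect_equal(unname(out2$shifts$a[["dx"]]), (-3:3)[which.max(scores)])
  expect_equal(unname(out2$shifts$a[["dx"]]), -1)
})

test_that("cells drawn at an angle are oriented horizontal to < 1 degree", {
  for (deg in c(30, -20, 0)) {
    sim <- mk_cell(rotation = deg, seed = 22 + deg)
    rec <- orient_cell(sim$record)
    ax <- fit_cell_axis(rec)
    slope <- coef(lm(ax$y_px ~ ax$x_px))[2]
    expect_lt(abs(atan(slope) * 180 / pi), 1)
    if (deg == 0) expect_lt(abs(rec$orientation_applied), 1)
  }
})

test_that("declared right-side stalk is mirrored to the left", {
  sim <- mk_cell(seed = 23, stalk = 700)
  rec <- sim$record
  # flip the image so the stalk is on the right, then declare it
  for (nm in c("transmitted", "channel_a")) {
    rec[[nm]] <- rec[[nm]][, rev(seq_len(ncol(rec[[nm]])))]
  }
  rec$stalk_side <- "right"
  out <- orient_cell(rec)
  expect_true(out$mirrored)
  # stalk (dimmer, thin) pixels now at minimal x: compare column sums of the
  # left and right thirds of the transmitted silhouette
  cs <- colSums(out$transmitted > 0.3 * max(out$transmitted))
  n <- length(cs)
  occupied <- which(cs > 0)
  left <- cs[occupied[1]:floor(quantile(occupied, 0.33))]
  right <- cs[ceiling(quantile(occupied, 0.67)):occupied[length(occupied)]]
  expect_lt(mean(left), mean(right))
})

test_that("nearly isotropic objects are rejected by orientation", {
  disc <- matrix(0, 101, 101)
  ctr <- 51
  for (r in 1:101) for (c in 1:101) {
    if ((r - ctr)^2 + (c - ctr)^2 < 30^2) disc[r, c] <- 100
  }
  rec <- cell_record(disc, disc, pixel_size_nm = 20)
  expect_error(orient_cell(rec), "isotropic")
})

test_that("axis fit recovers straight, parabolic and crescent centerlines", {
  # straight cell at known row
  sim <- mk_cell(seed = 24, noise = FALSE)
  rec <- sim$record
  rec$transmitted <- sim$truth$transmitted_expected
  ax <- fit_cell_axis(rec)
  expect_equal(ax$model_kind, "poly2")
  true_row <- sim$truth$centerline_nm[1, 2] / rec$pixel_size_nm
  expect_lt(abs(ax$coefficients[3]), 1e-3) # curvature ~ 0
  expect_lt(abs(ax$coefficients[1] +
                  ax$coefficients[2] * mean(ax$x_px) +
                  ax$coefficients[3] * mean(ax$x_px)^2 - true_row), 1)

  # parabolic silhouette: compare against a direct poly2 fit on the
  # generating pixels
  ny <- 120; nx <- 200
  img <- matrix(0, ny, nx)
  a <- 0.002; b <- -0.3; cc <- 70
  xs <- 30:170
  gen_y <- a * xs^2 + b * xs + cc
  for (i in seq_along(xs)) {
    rows <- round(gen_y[i]) + (-12:12)
    img[rows + 1, xs[i] + 1] <- 100 * sqrt(pmax(0, 1 - ((-12:12) / 12)^2))
  }
  recp <- cell_record(img, img, pixel_size_nm = 20)
  axp <- fit_cell_axis(recp)
  oracle <- lm(y ~ x + I(x^2), data = data.frame(x = xs, y = gen_y))
  pred_fit <- axp$coefficients[1] + axp$coefficients[2] * xs +
    axp$coefficients[3] * xs^2
  expect_lt(max(abs(pred_fit - predict(oracle))), 1)

  # crescent cell: fitted axis within 1 px of the oracle poly2 fit of the
  # ground-truth centerline, over the centerline's own x-range
  simc <- mk_cell(curvature = 1 / 3000, seed = 25, noise = FALSE)
  recc <- simc$record
  recc$transmitted <- simc$truth$transmitted_expected
  axc <- fit_cell_axis(recc)
  px <- recc$pixel_size_nm
  truth_px <- simc$truth$centerline_nm / px
  oracle_c <- lm(y ~ x + I(x^2),
                 data = data.frame(x = truth_px[, 1], y = truth_px[, 2]))
  inside <- axc$x_px >= min(truth_px[, 1]) & axc$x_px <= max(truth_px[, 1])
  pred_o <- predict(oracle_c, data.frame(x = axc$x_px[inside]))
  expect_lt(max(abs(axc$y_px[inside] - pred_o)), 1)
})

test_that("axis fit needs at least 6 usable columns", {
  img <- matrix(0, 50, 50)
  img[20:30, 12] <- 100
  expect_error(fit_cell_axis(cell_record(img, img)), "6 usable columns")
})

test_that("outline band has the nominal 200 nm width in both modes", {
  sim <- mk_cell(pattern = label_uniform(4000),
                 pattern_b = label_uniform(4000), rotation = 10, seed = 26)
  rec <- orient_cell(sim$record)
  rec$axis <- fit_cell_axis(rec)
  for (mode in c("complete_layer", "incomplete_layer")) {
    band <- make_outline(rec, mode)
    dm <- as.matrix(EBImage::distmap(EBImage::Image(band * 1)))
    # interior max distance ~ half width; 200 nm = 10 px at 20 nm/px
    expect_gte(2 * max(dm) - 1, 9)
    expect_lte(2 * max(dm) - 1, 13)
  }
})

test_that("complete and incomplete outlines agree on a fully labeled cell", {
  sim <- mk_cell(pattern = label_uniform(4000),
                 pattern_b = label_uniform(4000), rotation = 10, seed = 27)
  rec <- orient_cell(sim$record)
  rec$axis <- fit_cell_axis(rec)
  oc <- make_outline(rec, "complete_layer")
  oi <- make_outline(rec, "incomplete_layer")
  expect_gt(sum(oc & oi) / sum(oc | oi), 0.7)
})

test_that("blank images give an outline error", {
  blank <- matrix(0, 60, 60)
  rec <- cell_record(blank, blank)
  rec$axis <- structure(list(x_px = 1:10, y_px = rep(30, 10),
                             u = seq(0, 1, length.out = 10)),
                        class = "cell_axis")
  expect_error(make_outline(rec, "complete_layer"), "empty boundary")
})

test_that("binarization is empty on zero images and covers uniform label", {
  sim <- mk_cell(pattern = label_uniform(6000), noise = FALSE, seed = 28)
  rec <- sim$record
  rec$transmitted <- sim$truth$transmitted_expected
  rec <- orient_cell(rec)
  rec$axis <- fit_cell_axis(rec)
  out <- make_outline(rec, "complete_layer")
  expect_false(any(binarize_layer(matrix(0, nrow(out), ncol(out)), out)))
  m <- binarize_layer(rec$channel_a, out)
  truth_in_band <- sim$truth$mask_a & out
  expect_gte(sum(m & truth_in_band) / sum(truth_in_band), 0.99)
})

test_that("crack features are segmented with F1 > 0.8 at SNR ~ 10", {
  sim <- mk_cell(pattern = label_cracks(3, 400, 300), seed = 29,
                 photons = 150, bg = 2)
  rec <- orient_cell(sim$record)
  rec$axis <- fit_cell_axis(rec)
  out <- make_outline(rec, "incomplete_layer")
  m <- binarize_layer(rec$channel_a, out)
  t2 <- sim$truth$mask_a
  tp <- sum(m & t2); fp <- sum(m & !t2); fn <- sum(!m & t2)
  expect_gt(2 * tp / (2 * tp + fp + fn), 0.8)
})

test_that("profile projection matches the brute-force per-pixel oracle", {
  sim <- mk_cell(pattern = label_uniform(4000), seed = 30)
  res <- profile_cell(sim$record, mode = "complete_layer")
  bp <- res$profiles$a
  oracle <- oracle_project(res$masks$a, res$axis)
  expect_identical(bp$upper, oracle$upper)
  expect_identical(bp$lower, oracle$lower)
  # full-coverage mask: every bin positive in both halves
  full <- project_profile(res$outline, res$axis)
  expect_true(all(full$upper) && all(full$lower))
  # empty mask: nothing positive
  none <- project_profile(res$outline & FALSE, res$axis)
  expect_false(any(none$upper) || any(none$lower))
})

test_that("a mask confined to the first quarter of arc length fills bins 1-10", {
  sim <- mk_cell(seed = 31)
  res <- profile_cell(sim$record, mode = "complete_layer")
  ax <- res$axis
  out <- res$outline
  ny <- nrow(out)
  idx <- which(out)
  pxy <- cbind((idx - 1) %/% ny, (idx - 1) %% ny)
  u <- ax$u[slakit:::nearest_polyline_point(
    pxy, cbind(ax$x_px, ax$y_px))$index]
  mask <- matrix(FALSE, ny, ncol(out))
  mask[idx[u < 0.25]] <- TRUE
  bp <- project_profile(mask, ax)
  expect_identical(which(bp$upper | bp$lower), 1:10)
})

test_that("projection is invariant to adding pixels in already-positive bins", {
  sim <- mk_cell(seed = 32)
  res <- profile_cell(sim$record, mode = "complete_layer")
  m <- res$masks$a
  base <- project_profile(m, res$axis)
  # add back outline pixels that project into bins already positive
  out <- res$outline
  ny <- nrow(out)
  idx <- which(out & !m)
  pxy <- cbind((idx - 1) %/% ny, (idx - 1) %% ny)
  near <- slakit:::nearest_polyline_point(pxy, cbind(res$axis$x_px,
                                                     res$axis$y_px))
  u <- res$axis$u[near$index]
  bins <- pmin(floor(u * 40), 39) + 1
  addable <- idx[(base$upper[bins] & base$lower[bins])]
  m2 <- m
  m2[addable] <- TRUE
  again <- project_profile(m2, res$axis)
  expect_identical(again$upper, base$upper)
  expect_identical(again$lower, base$lower)
})

test_that("Wilson intervals match the closed-form oracle and behave", {
  # hand-checked anchor points
  w <- wilson_interval(162, 162)
  expect_equal(w$low, 0.97683, tolerance = 1e-4)
  expect_equal(w$high, 1)
  expect_equal(unname(oracle_wilson(162, 162)), c(w$low, w$high),
               tolerance = 1e-12)
  w0 <- wilson_interval(0, 162)
  expect_equal(w0$low, 0)
  expect_equal(w0$high, 1 - w$low, tolerance = 1e-12) # k = 0 mirrors k = n
  w2 <- wilson_interval(1, 2)
  expect_equal(c(w2$low, w2$high), c(0.0945, 0.9055), tolerance = 1e-3)
  expect_equal(unname(oracle_wilson(1, 2)), c(w2$low, w2$high),
               tolerance = 1e-12)
  # interval always contains k/n, lies in [0,1], and narrows with n
  for (k in c(0, 3, 7)) {
    for (n in c(10, 40, 160)) {
      wi <- wilson_interval(k, n)
      expect_true(wi$low <= k / n && k / n <= wi$high)
      expect_true(wi$low >= 0 && wi$high <= 1)
    }
  }
  widths <- sapply(c(10, 100, 1000), function(n) {
    wi <- wilson_interval(round(0.3 * n), n)
    wi$high - wi$low
  })
  expect_true(all(diff(widths) < 0))
})

test_that("population fractions pool upper and lower halves", {
  all_pos <- structure(list(n_bins = 40L, upper = rep(TRUE, 40),
                            lower = rep(TRUE, 40), channel = "a"),
                       class = "binary_profile")
  pop <- population_fraction(rep(list(all_pos), 81))
  expect_true(all(pop$fraction == 1))
  expect_true(all(pop$n == 162))
  expect_equal(pop$ci_low[1], 0.97683, tolerance = 1e-4)
  expect_equal(pop$ci_high[1], 1)
  all_neg <- structure(list(n_bins = 40L, upper = rep(FALSE, 40),
                            lower = rep(FALSE, 40), channel = "a"),
                       class = "binary_profile")
  popn <- population_fraction(rep(list(all_neg), 81))
  expect_true(all(popn$fraction == 0))
  expect_true(all(popn$ci_low == 0))
  expect_error(population_fraction(list()), "empty")
})
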