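test_that("the full-frame ROI decomposition matches the instrument geometry", {
  g <- roi_grid(c(10640, 14192), c(16, 16))
  expect_true(all(vapply(g$cols, length, integer(1)) == 887L))
  expect_true(all(vapply(g$rows, length, integer(1)) == 665L))

  g1 <- roi_grid(c(16, 16), c(16, 16))
  expect_true(all(vapply(g1$rows, length, integer(1)) == 1L))

  g2 <- roi_grid(c(16, 17), c(16, 16))
  expect_equal(length(g2$cols[[16]]), 2L)  # remainder joins the last column
  expect_true(all(vapply(g2$cols[1:15], length, integer(1)) == 1L))

  expect_error(roi_grid(c(8, 8), c(16, 16)), "larger than frame")
})

test_that("split_rois tiles the frame exactly and reassembles", {
  a <- array(seq_len(20 * 24 * 3), dim = c(20, 24, 3))
  subs <- split_rois(a, c(4, 4))
  expect_length(subs, 16L)
  total <- sum(vapply(subs, function(s) sum(as.numeric(s)), numeric(1)))
  expect_equal(total, sum(as.numeric(a)))
  expect_equal(attr(subs[[1]], "roi_index"), c(1, 1))
})

test_that("percentile contrast agrees with a brute-force quantile oracle", {
  set.seed(8)
  x <- seq(0, 40 * pi, length.out = 4001)
  frame <- matrix(100 + 50 * sin(x)[1:4000], 50, 80)
  p <- unname(stats::quantile(as.numeric(frame), c(0.05, 0.95), type = 7))
  oracle <- (p[2] - p[1]) / (p[2] + p[1])
  expect_equal(frame_contrast(frame), oracle, tolerance = 1e-12)

  for (i in 1:20) {
    f <- matrix(runif(500, 1, 100), 20, 25)
    p <- unname(stats::quantile(as.numeric(f), c(0.05, 0.95), type = 7))
    expect_equal(frame_contrast(f), (p[2] - p[1]) / (p[2] + p[1]),
                 tolerance = 1e-12)
    a <- runif(1, 0.1, 10)  # invariant under gain changes
    expect_equal(frame_contrast(a * f), frame_contrast(f), tolerance = 1e-12)
  }
})

test_that("the batched contrast kernel matches per-frame contrast exactly", {
  set.seed(14)
  sub <- array(runif(24 * 20 * 30, 10, 500), dim = c(24, 20, 30))
  cc1 <- contrast_curve(sub)
  cc2 <- vapply(1:30, function(k) frame_contrast(sub[, , k]), numeric(1))
  expect_identical(cc1, cc2)
  # integer-valued stacks take the same path
  subi <- array(sample.int(1000, 16 * 16 * 10, replace = TRUE), dim = c(16, 16, 10))
  expect_identical(contrast_curve(subi),
                   vapply(1:10, function(k) frame_contrast(subi[, , k]), numeric(1)))
})

test_that("contrast handles uniform, binary, and degenerate frames", {
  expect_equal(frame_contrast(matrix(7, 10, 10)), 0)
  half <- matrix(c(rep(0, 50), rep(5, 50)), 10, 10)
  expect_equal(frame_contrast(half), 1)
  expect_error(frame_contrast(matrix(0, 10, 10)), "undefined")
})

test_that("best focus is exact on noiseless symmetric curves", {
  z <- (0:80) * 1.0
  cc <- 0.1 + 0.6 * exp(-(z - z[41])^2 / (2 * 15^2))
  bf <- best_focus(cc, z)
  expect_true(bf$fit_ok)
  expect_equal(bf$best_focus_um, z[41], tolerance = 1e-6)
  expect_equal(bf$fit_width_um, 15, tolerance = 1e-4)
})

test_that("best focus is unbiased and precise under noise (Monte Carlo)", {
  z <- (0:80) * 1.0
  true_mu <- 40.3
  clean <- 0.12 + 0.55 * exp(-(z - true_mu)^2 / (2 * 12^2))
  set.seed(17)
  centers <- vapply(1:500, function(r) {
    best_focus(clean + rnorm(81, 0, 0.01 * max(clean)), z)$best_focus_um
  }, numeric(1))
  expect_lt(abs(mean(centers) - true_mu), 0.1)  # bias < 0.1 z-step
  expect_lt(sd(centers), 0.5)                   # spread < 0.5 z-step
})

test_that("flat or short curves are rejected", {
  expect_false(best_focus(rep(0.4, 20), 1:20)$fit_ok)
  expect_error(best_focus(c(1, 2, 3, 2), 1:4), ">= 5")
  set.seed(3)
  noisy_flat <- 0.3 + rnorm(40, 0, 0.01)
  expect_false(best_focus(noisy_flat, 1:40)$fit_ok)
})

test_that("parabolic focus surfaces are recovered within a z step", {
  c2 <- 30 / 63.5^2  # 30 um of curvature at the field corner
  fs <- function(x, y) 60 + c2 * ((x - 63.5)^2 + (y - 63.5)^2) / 2
  rs <- make_ronchi_stack(c(128, 128, 161), 16, 1, fs,
                          function(dz) 0.1 * dz, block_px = 16)
  fc <- measure_field_curvature(rs$volume, grid = c(8, 8))
  expect_true(all(fc$fit_ok))
  g <- roi_grid(c(128, 128), c(8, 8))
  truth <- outer(seq_len(8), seq_len(8), Vectorize(function(i, j)
    fs(mean(g$cols[[j]]) - 1, mean(g$rows[[i]]) - 1)))
  expect_lt(max(abs(fc$focus_um - truth)), 1)  # within one z step

  # radial profile reproduces the generating paraboloid
  prof <- fc$radial
  pred <- c2 * (prof$radius_px^2 - prof$radius_px[1]^2) / 2
  expect_lt(max(abs(prof$shift_um - pred)), 1)
})

test_that("flat surfaces give a flat radial profile referenced to zero", {
  rs <- make_ronchi_stack(c(64, 64, 41), 8, 1,
                          function(x, y) rep(20, length(x)),
                          function(dz) 0.15 * dz, block_px = 16)
  fc <- measure_field_curvature(rs$volume, grid = c(4, 4), dof_um = 7.43)
  expect_lt(max(abs(fc$radial$shift_um)), 0.2)
  expect_equal(fc$radial$shift_um[1], 0)
  expect_equal(fc$radial$shift_dof, fc$radial$shift_um / 7.43)
})

test_that("the radial profile is invariant under a 90-degree grid rotation", {
  set.seed(23)
  focus <- matrix(rnorm(64, 50, 5), 8, 8)
  p1 <- radial_average_map(focus, pixel_size_um = 1)
  p2 <- radial_average_map(t(focus)[8:1, ], pixel_size_um = 1)  # rotate 90 deg
  expect_equal(p1$shift_um, p2$shift_um, tolerance = 1e-12)
  expect_equal(p1$n, p2$n)
})

test_that("radial averaging requires at least one valid fit", {
  expect_error(radial_average_map(matrix(NA_real_, 4, 4)), "no valid")
})
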