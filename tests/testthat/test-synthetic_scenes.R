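test_that("generators are deterministic: same seed, bit-identical output", {
  a <- make_bead_phantom(c(64, 64, 24), 1, 10, fwhm_um = c(2, 2, 3),
                         noise = camera_noise_model(), seed = 99)
  b <- make_bead_phantom(c(64, 64, 24), 1, 10, fwhm_um = c(2, 2, 3),
                         noise = camera_noise_model(), seed = 99)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$truth, b$truth)

  fs <- function(x, y) 10 + 0 * x
  r1 <- make_ronchi_stack(c(32, 32, 11), 8, 2, fs, function(dz) 0.1 * dz,
                          noise = camera_noise_model(), seed = 7)
  r2 <- make_ronchi_stack(c(32, 32, 11), 8, 2, fs, function(dz) 0.1 * dz,
                          noise = camera_noise_model(), seed = 7)
  expect_identical(r1$volume$data, r2$volume$data)

  d1 <- make_dot_grid(c(300, 300), 60, 20, k1 = 1e-8,
                      noise = camera_noise_model(), seed = 3)
  d2 <- make_dot_grid(c(300, 300), 60, 20, k1 = 1e-8,
                      noise = camera_noise_model(), seed = 3)
  expect_identical(d1$image, d2$image)
})

test_that("camera noise model satisfies the photon transfer relation", {
  nm <- camera_noise_model(offset = 100, read_noise = 3, gain = 2)
  photons <- array(200, dim = c(100, 100, 100))  # 1e6 uniform samples
  counts <- apply_camera_noise(photons, nm, seed = 12)
  v <- var(as.vector(counts))
  expected <- nm$gain * (mean(counts) - nm$offset) + nm$read_noise^2
  expect_lt(abs(v / expected - 1), 0.05)
})

test_that("an empty phantom is pure noise around the offset", {
  ph <- make_bead_phantom(c(40, 40, 20), 1, 0, fwhm_um = c(2, 2, 3),
                          noise = camera_noise_model(offset = 100, read_noise = 2),
                          seed = 5)
  expect_equal(nrow(ph$truth), 0L)
  expect_lt(abs(mean(ph$volume$data) - 100), 0.5)
})

test_that("a noiseless bead's axis profiles carry the ground-truth FWHM", {
  ph <- make_bead_phantom(c(33, 33, 33), 1, 1, fwhm_um = c(2, 2, 4),
                          peak_counts = 1000, seed = 2,
                          positions_um = matrix(c(16, 16, 16), 1))
  a <- ph$volume$data
  sums <- list(x = apply(a, 2, sum), y = apply(a, 1, sum), z = apply(a, 3, sum))
  truth_sigma <- c(2, 2, 4) / (2 * sqrt(2 * log(2)))
  for (ax in 1:3) {
    cf <- oracle_fit_igauss(sums[[ax]])
    fwhm <- 2 * sqrt(2 * log(2)) * cf[["s"]]
    expect_lt(abs(fwhm / c(2, 2, 4)[ax] - 1), 0.01)
    expect_equal(cf[["mu"]], 17, tolerance = 1e-6)
  }
  # perfectly centred bead peaks at peak_counts
  expect_equal(max(a), 1000, tolerance = 1e-9)
  expect_true(abs(truth_sigma[1] - cf[["s"]] / 2) < 1)  # sanity on scale
})

test_that("over-dense bead requests are refused", {
  expect_error(
    make_bead_phantom(c(20, 20, 10), 1, 500, fwhm_um = c(3, 3, 5), seed = 1),
    "density")
})

test_that("explicit close pairs bypass placement separation", {
  ph <- make_bead_phantom(c(33, 33, 17), 1, 2, fwhm_um = c(2, 2, 3),
                          peak_counts = c(1000, 600), seed = 1,
                          positions_um = matrix(c(14, 16, 8, 18, 16, 8),
                                                2, byrow = TRUE))
  expect_equal(nrow(ph$truth), 2L)
  expect_equal(ph$truth$peak, c(1000, 600))
})

test_that("flat-focus grating stacks peak at the focal plane in every region", {
  mid <- 10 * 2  # plane 11 of 21 at 2 um steps
  rs <- make_ronchi_stack(c(64, 64, 21), 8, 2, function(x, y) rep(mid, length(x)),
                          function(dz) 0.15 * dz, block_px = 16)
  subs <- split_rois(rs$volume, c(4, 4))
  for (s in subs) {
    cc <- vapply(seq_len(dim(s)[3]), function(k) frame_contrast(s[, , k]), numeric(1))
    expect_equal(which.max(cc), 11L)
  }
  expect_true(all(rs$truth$z0_block == mid))
})

test_that("zero defocus blur yields constant contrast and no focus", {
  rs <- make_ronchi_stack(c(32, 32, 11), 8, 1, function(x, y) rep(5, length(x)),
                          function(dz) 0 * dz)
  cc <- vapply(seq_len(11), function(k) frame_contrast(rs$volume$data[, , k]),
               numeric(1))
  expect_equal(diff(range(cc)), 0)
  bf <- best_focus(cc, (0:10) * 1)
  expect_false(bf$fit_ok)
})

test_that("focus surfaces outside the scan range are refused", {
  expect_error(
    make_ronchi_stack(c(32, 32, 11), 8, 1, function(x, y) rep(50, length(x)),
                      function(dz) 0.1 * dz),
    "range")
})

test_that("dot-grid rendering places centroids on the distorted ground truth", {
  dg <- make_dot_grid(c(620, 610), 100, 40, center_px = c(301.23, 307.77))
  dots <- segment_dots(dg$image)
  tr <- dg$truth[order(dg$truth$y_true, dg$truth$x_true), ]
  expect_equal(nrow(dots), nrow(tr))
  expect_lt(max(abs(dots$x_px - tr$x_true)), 0.05)
  expect_lt(max(abs(dots$y_px - tr$y_true)), 0.05)
})

test_that("undistorted targets measure zero distortion", {
  dg <- make_dot_grid(c(900, 900), 90, 30)
  md <- measure_distortion(dg$image, 90)
  expect_lt(max(abs(md$profile$percent_distortion)), 0.02)
})

test_that("pure quadratic distortion follows the analytic forward model", {
  k1 <- 4e-9
  dg <- make_dot_grid(c(1200, 1200), 100, 40, k1 = k1)
  md <- measure_distortion(dg$image, 100)
  outer_bins <- md$profile[md$profile$radius_px > 300, ]
  pred <- 100 * k1 * outer_bins$radius_px^2
  expect_true(all(abs(outer_bins$percent_distortion / pred - 1) < 0.1))
})

test_that("distortion that pushes dots off-frame is refused", {
  expect_error(make_dot_grid(c(400, 400), 60, 20, k1 = 5e-6), "out of frame")
})
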