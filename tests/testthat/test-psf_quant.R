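test_that("pure noise yields no detections at a 10-sigma threshold", {
  ph <- make_bead_phantom(c(128, 128, 64), 1, 0, fwhm_um = c(2, 2, 3),
                          background = 50,
                          noise = camera_noise_model(offset = 100, read_noise = 2),
                          seed = 21)
  det <- detect_beads(ph$volume, min_separation_um = 5, snr_threshold = 10)
  expect_equal(nrow(det), 0L)
})

test_that("well-separated beads are all detected with no spurious hits", {
  ph <- make_bead_phantom(c(160, 160, 60), 1, 100, fwhm_um = c(2, 2, 3.5),
                          peak_counts = 800, background = 20,
                          noise = camera_noise_model(offset = 100, read_noise = 2),
                          seed = 31)
  det <- detect_beads(ph$volume, min_separation_um = 4, snr_threshold = 8)
  expect_gte(nrow(det), 99L)
  # every detection is near a true bead (no spurious maxima)
  d2true <- vapply(seq_len(nrow(det)), function(i) {
    min(sqrt((ph$truth$x_um - det$x_um[i])^2 + (ph$truth$y_um - det$y_um[i])^2 +
               (ph$truth$z_um - det$z_um[i])^2))
  }, numeric(1))
  expect_lt(max(d2true), 2)
  # deterministic (z, y, x) ordering
  expect_true(!is.unsorted(order(det$z_px, det$y_px, det$x_px)))
})

test_that("non-maximum suppression keeps the brighter of a close pair", {
  ph <- make_bead_phantom(c(33, 33, 17), 1, 2, fwhm_um = c(2, 2, 3),
                          peak_counts = c(600, 1000), seed = 1,
                          positions_um = matrix(c(13, 16, 8, 19, 16, 8),
                                                2, byrow = TRUE))
  det <- detect_beads(ph$volume, min_separation_um = 10, snr_threshold = 3)
  expect_equal(nrow(det), 1L)
  expect_equal(det$x_um, 19)  # the brighter bead
})

test_that("bead fits recover the rendered Gaussian width to 2%", {
  sigma_px <- 0.8
  fwhm_um <- 2 * sqrt(2 * log(2)) * sigma_px * 0.75
  ph <- make_bead_phantom(c(25, 25, 25), 0.75, 1,
                          fwhm_um = c(fwhm_um, fwhm_um, 2 * fwhm_um),
                          peak_counts = 2000, seed = 4,
                          positions_um = matrix(c(9.1, 8.9, 9.0), 1))
  m <- fit_bead(ph$volume, round(c(9.1, 8.9, 9.0) / 0.75) + 1, 6)
  expect_equal(m$flags, "")
  expect_lt(abs(m$fwhm_x_um / 1.413 - 1), 0.02)
  expect_lt(abs(m$fwhm_y_um / m$fwhm_x_um - 1), 0.02)  # isotropy in x/y
  expect_lt(abs(m$fwhm_z_um / (2 * fwhm_um) - 1), 0.02)
  # sub-voxel positions recovered
  expect_equal(m$x_um, 9.1, tolerance = 0.05)
  expect_equal(m$y_um, 8.9, tolerance = 0.05)
})

test_that("beads at the volume edge are flagged", {
  ph <- make_bead_phantom(c(25, 25, 13), 1, 1, fwhm_um = c(2, 2, 3),
                          seed = 1, positions_um = matrix(c(2, 2, 2), 1))
  m <- fit_bead(ph$volume, c(3, 3, 3), 6)
  expect_match(m$flags, "edge")
})

test_that("saturated beads are flagged", {
  ph <- make_bead_phantom(c(21, 21, 21), 1, 1, fwhm_um = c(2, 2, 3),
                          peak_counts = 5000, seed = 1, bit_depth = 12,
                          positions_um = matrix(c(10, 10, 10), 1))
  m <- fit_bead(ph$volume, c(11, 11, 11), 6)
  expect_match(m$flags, "saturated")
})

test_that("reported FWHMs track the voxel size (scale equivariance)", {
  ph <- make_bead_phantom(c(25, 25, 25), 1, 1, fwhm_um = c(2.4, 2.4, 4),
                          peak_counts = 1500, seed = 6,
                          positions_um = matrix(c(12, 12, 12), 1))
  v1 <- ph$volume
  v2 <- volume3d(ph$volume$data, 2)  # same data, 2 um voxels
  m1 <- fit_bead(v1, c(13, 13, 13), 6)
  m2 <- fit_bead(v2, c(13, 13, 13), 6)
  expect_equal(m2$fwhm_x_um / m1$fwhm_x_um, 2, tolerance = 1e-9)
  expect_equal(m2$fwhm_z_um / m1$fwhm_z_um, 2, tolerance = 1e-9)
  expect_equal(m2$x_um / m1$x_um, 2, tolerance = 1e-9)
})

test_that("close bead pairs are mutually flagged clumped", {
  ph <- make_bead_phantom(c(41, 41, 21), 1, 3, fwhm_um = c(2, 2, 3),
                          peak_counts = 1000, seed = 1,
                          positions_um = matrix(c(12, 20, 10,
                                                  17, 20, 10,
                                                  32, 30, 10), 3, byrow = TRUE))
  m <- measure_beads(ph$volume, min_separation_um = 3, snr_threshold = 3)
  flagged <- grepl("clumped", m$flags)
  expect_equal(sum(flagged), 2L)
})

test_that("field maps aggregate unflagged beads per (x, y) bin", {
  # spatially constant PSF model: all bins statistically equal
  ph <- make_bead_phantom(c(120, 120, 40), 1, 60, fwhm_um = c(2.2, 2.2, 3.6),
                          peak_counts = 1000, background = 10,
                          noise = camera_noise_model(offset = 100, read_noise = 1),
                          seed = 41)
  m <- measure_beads(ph$volume, min_separation_um = 4, snr_threshold = 8)
  fm <- aggregate_field_map(m, c(2, 2), extent_um = c(119, 119))
  expect_true(all(fm$n >= 1))
  expect_lt(diff(range(fm$lateral_mean)), 0.15)  # ~7% of 2.2 um
  expect_equal(sum(fm$n), sum(m$flags == ""))

  # a radially increasing model is reproduced by the bin means
  fwhm_model <- function(x, y) {
    r2 <- ((x - 90) / 90)^2 + ((y - 90) / 90)^2
    w <- 2 * (1 + 0.5 * r2)
    c(w, w, 2 * w)
  }
  ph2 <- make_bead_phantom(c(180, 180, 40), 1, 80, fwhm_um = fwhm_model,
                           peak_counts = 1500, seed = 42)
  m2 <- measure_beads(ph2$volume, min_separation_um = 5, snr_threshold = 5)
  fm2 <- aggregate_field_map(m2, c(3, 3), extent_um = c(179, 179))
  centers <- (c(0.5, 1.5, 2.5) / 3) * 179
  rel_err <- c()
  for (bx in 1:3) for (by in 1:3) {
    if (is.na(fm2$lateral_mean[by, bx])) next
    truth <- fwhm_model(centers[bx], centers[by])[1]
    rel_err <- c(rel_err, fm2$lateral_mean[by, bx] / truth - 1)
  }
  expect_lt(sqrt(mean(rel_err^2)), 0.03)
})

test_that("single-bead bins report n = 1 with zero spread; all-flagged input errors", {
  ph <- make_bead_phantom(c(25, 25, 15), 1, 1, fwhm_um = c(2, 2, 3),
                          seed = 2, positions_um = matrix(c(12, 12, 7), 1))
  m <- fit_bead(ph$volume, c(13, 13, 8), 6)
  fm <- aggregate_field_map(m, c(1, 1), extent_um = c(24, 24))
  expect_equal(fm$n[1, 1], 1)
  expect_equal(fm$lateral_sd[1, 1], 0)

  m$flags <- "edge"
  expect_error(aggregate_field_map(m, c(1, 1)), "zero usable")
})
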