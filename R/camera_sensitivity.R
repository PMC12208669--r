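#' Bead signal-to-noise ratio
#'
#' SNR is defined as the signal of the bead minus the mean background,
#' divided by the background noise: `(signal - background_mean) /
#' background_noise`. The signal is the brightest voxel within a sphere
#' around the bead (or the background-subtracted integrated intensity with
#' `mode = "integrated"`); background statistics come from a surrounding
#' spherical annulus.
#'
#' @param vol A [volume3d()].
#' @param bead_position Numeric `(x, y, z)` voxel indices (1-based).
#' @param signal_radius_px Radius (voxels) of the signal sphere.
#' @param annulus_px Length-2 `(inner, outer)` annulus radii in voxels;
#'   must contain at least 100 voxels.
#' @param exclude_positions Optional matrix (n x 3) of other bead positions
#'   (voxel indices); an error is raised if any falls within the annulus.
#' @param mode `"peak"` (default) or `"integrated"`.
#' @return One-row data frame of class `snr_measurement`: `snr`, `signal`,
#'   `background_mean`, `background_noise`, `n_annulus`.
#' @export
measure_snr <- function(vol, bead_position, signal_radius_px = 3,
                        annulus_px = c(6, 12), exclude_positions = NULL,
                        mode = c("peak", "integrated")) {
  mode <- match.arg(mode)
  stopifnot(inherits(vol, "volume3d"), length(annulus_px) == 2L,
            annulus_px[1] > signal_radius_px, annulus_px[2] > annulus_px[1])
  pos <- round(as.numeric(bead_position))
  d <- dim(vol$data)
  r_out <- ceiling(annulus_px[2])
  x0 <- max(1L, pos[1] - r_out); x1 <- min(d[2], pos[1] + r_out)
  y0 <- max(1L, pos[2] - r_out); y1 <- min(d[1], pos[2] + r_out)
  z0 <- max(1L, pos[3] - r_out); z1 <- min(d[3], pos[3] + r_out)
  roi <- vol$data[y0:y1, x0:x1, z0:z1, drop = FALSE]
  dy <- (y0:y1) - pos[2]; dx <- (x0:x1) - pos[1]; dz <- (z0:z1) - pos[3]
  dist <- sqrt(outer(outer(dy^2, dx^2, "+"), dz^2, "+"))

  if (!is.null(exclude_positions)) {
    ep <- as.matrix(exclude_positions)
    dd <- sqrt((ep[, 1] - pos[1])^2 + (ep[, 2] - pos[2])^2 + (ep[, 3] - pos[3])^2)
    if (any(dd > 1e-9 & dd <= annulus_px[2] + signal_radius_px))
      stop("annulus overlaps another bead")
  }
  ann <- roi[dist >= annulus_px[1] & dist <= annulus_px[2]]
  if (length(ann) < 100L) stop("annulus contains fewer than 100 voxels")
  bg_mean <- mean(ann)
  bg_sd <- sd(ann)
  if (bg_sd == 0) stop("background noise is zero: SNR undefined on noiseless input")
  sig_vox <- roi[dist <= signal_radius_px]
  signal <- if (mode == "peak") max(sig_vox) else sum(sig_vox - bg_mean) + bg_mean
  out <- data.frame(snr = (signal - bg_mean) / bg_sd, signal = signal,
                    background_mean = bg_mean, background_noise = bg_sd,
                    n_annulus = length(ann))
  class(out) <- c("snr_measurement", class(out))
  out
}

#' SNR as a function of imaging speed
#'
#' Simulates imaging the same bead at a series of rolling-shutter line
#' times (pixel dwell times). Expected photon counts scale linearly with
#' dwell; a camera noise model is applied; SNR is measured per
#' [measure_snr()] and paired with the voxel rate
#' `pixels_per_row / line_time`. Wide sensor rows give a longer dwell at
#' equal voxel rate, which is the mechanism this curve exposes.
#'
#' @param pixels_per_row Sensor row width in pixels.
#' @param line_times_us Numeric vector (>= 2) of line/dwell times in
#'   microseconds. Sorted ascending with a warning if unordered.
#' @param peak_flux_per_us Expected bead-peak photons per microsecond of dwell.
#' @param background_flux_per_us Expected background photons per microsecond.
#' @param noise A [camera_noise_model()].
#' @param n_replicates Phantom replicates averaged per dwell.
#' @param seed RNG seed.
#' @param dim_yxz Phantom dimensions; the bead sits at the centre.
#' @param fwhm_px Bead FWHM in voxels `(x, y, z)`.
#' @return Data frame of class `snr_curve` with `line_time_us`,
#'   `pixel_rate`, `snr` (mean over replicates), `snr_sd`; rates strictly
#'   increasing.
#' @export
snr_vs_rate <- function(pixels_per_row, line_times_us, peak_flux_per_us = 200,
                        background_flux_per_us = 20,
                        noise = camera_noise_model(), n_replicates = 5,
                        seed = 1L, dim_yxz = c(33, 33, 33),
                        fwhm_px = c(2.5, 2.5, 4)) {
  if (length(line_times_us) < 2L) stop("need >= 2 dwell times")
  if (is.unsorted(line_times_us)) {
    warning("dwell times were not monotone; sorting ascending")
    line_times_us <- sort(line_times_us)
  }
  center_um <- c((dim_yxz[2] - 1) / 2, (dim_yxz[1] - 1) / 2, (dim_yxz[3] - 1) / 2)
  rows <- lapply(seq_along(line_times_us), function(k) {
    lt <- line_times_us[k]
    snrs <- vapply(seq_len(n_replicates), function(r) {
      ph <- make_bead_phantom(dim_yxz, voxel_size_um = 1, n_beads = 1,
                              fwhm_um = fwhm_px,
                              peak_counts = peak_flux_per_us * lt,
                              background = background_flux_per_us * lt,
                              noise = noise,
                              seed = sub_seed(seed, k * 1000L + r),
                              positions_um = matrix(center_um, 1))
      m <- measure_snr(ph$volume, center_um + 1)
      m$snr
    }, numeric(1))
    data.frame(line_time_us = lt,
               pixel_rate = voxel_rate(pixels_per_row, lt),
               snr = mean(snrs), snr_sd = sd(snrs))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$pixel_rate), ]
  rownames(out) <- NULL
  class(out) <- c("snr_curve", class(out))
  out
}

#' Relative SNR between two sensor curves
#'
#' Ratio of a test curve's SNR to a reference curve's, interpolated at the
#' test curve's pixel rates (log-rate linear interpolation within the
#' reference's range).
#'
#' @param curve,reference [snr_vs_rate()] data frames.
#' @return `curve` with an added `rsnr` column (`NA` outside the
#'   reference's rate range).
#' @export
relative_snr <- function(curve, reference) {
  f <- approxfun(log(reference$pixel_rate), reference$snr)
  curve$rsnr <- curve$snr / f(log(curve$pixel_rate))
  curve
}
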