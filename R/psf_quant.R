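#' Detect bead candidates in a 3-D stack
#'
#' Finds local intensity maxima (26-connectivity) above
#' `background + snr_threshold * noise`, where the background is the volume
#' median and the noise its median absolute deviation, then applies
#' non-maximum suppression at the requested minimum physical separation
#' (brighter candidate wins). Candidates are returned ordered by (z, y, x).
#'
#' @param vol A [volume3d()] with at least 3 voxels per axis.
#' @param min_separation_um Minimum centre separation in micrometres.
#' @param snr_threshold Detection threshold in units of the noise estimate.
#' @return Data frame with voxel indices (`x_px`, `y_px`, `z_px`, 1-based),
#'   physical positions (`x_um`, `y_um`, `z_um`) and `intensity`. Empty
#'   (zero-row) when nothing is detected.
#' @export
detect_beads <- function(vol, min_separation_um, snr_threshold = 10) {
  stopifnot(inherits(vol, "volume3d"))
  d <- dim(vol$data)
  if (any(d < 3L)) stop("volume must have >= 3 voxels per axis")
  a <- vol$data
  bg <- median(a)
  noise <- mad(a)
  thr <- bg + snr_threshold * noise

  pad <- array(-Inf, dim = d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- a
  is_max <- a > thr
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0 && dy == 0 && dx == 0) next
    if (!any(is_max)) break
    nb <- pad[(2:(d[1] + 1)) + dy, (2:(d[2] + 1)) + dx, (2:(d[3] + 1)) + dz]
    is_max <- is_max & (a >= nb)
  }
  idx <- which(is_max)
  if (!length(idx))
    return(data.frame(x_px = integer(0), y_px = integer(0), z_px = integer(0),
                      x_um = numeric(0), y_um = numeric(0), z_um = numeric(0),
                      intensity = numeric(0)))
  ai <- arrayInd(idx, d)
  cand <- data.frame(x_px = ai[, 2], y_px = ai[, 1], z_px = ai[, 3],
                     intensity = a[idx])
  vs <- vol$voxel_size_um
  cand$x_um <- (cand$x_px - 1) * vs["x"]
  cand$y_um <- (cand$y_px - 1) * vs["y"]
  cand$z_um <- (cand$z_px - 1) * vs["z"]

  # non-maximum suppression, brightest first (ties broken by z, y, x)
  o <- order(-cand$intensity, cand$z_px, cand$y_px, cand$x_px)
  cand <- cand[o, ]
  keep <- logical(nrow(cand))
  kx <- ky <- kz <- numeric(0)
  for (i in seq_len(nrow(cand))) {
    if (length(kx)) {
      d2 <- (kx - cand$x_um[i])^2 + (ky - cand$y_um[i])^2 + (kz - cand$z_um[i])^2
      if (min(d2) < min_separation_um^2) next
    }
    keep[i] <- TRUE
    kx <- c(kx, cand$x_um[i]); ky <- c(ky, cand$y_um[i]); kz <- c(kz, cand$z_um[i])
  }
  out <- cand[keep, c("x_px", "y_px", "z_px", "x_um", "y_um", "z_um", "intensity")]
  out <- out[order(out$z_px, out$y_px, out$x_px), ]
  rownames(out) <- NULL
  out
}

#' Fit one bead's lateral and axial FWHM
#'
#' Extracts a region of interest around a candidate position, estimates the
#' local background as the median of the ROI's outer one-voxel shell,
#' refines the centroid, and fits the three background-subtracted 1-D
#' profiles through the centroid with a pixel-integrated Gaussian
#' (erf-difference profile, matching the cell-averaged image-formation
#' model). FWHM = 2 sqrt(2 ln 2) sigma, converted to micrometres through the
#' voxel size.
#'
#' @param vol A [volume3d()].
#' @param position Numeric `(x, y, z)` voxel indices (1-based), or a row
#'   from [detect_beads()].
#' @param roi_halfwidth_px ROI half width in voxels, scalar or `(x, y, z)`.
#' @return One-row data frame: refined `x_um`, `y_um`, `z_um`; `fwhm_x_um`,
#'   `fwhm_y_um`, `fwhm_z_um`; `peak`; `r2_x`, `r2_y`, `r2_z`; and a `flags`
#'   string (comma-separated subset of `edge`, `saturated`, `fit_failed`;
#'   empty when clean). A failed fit is flagged, never an exception.
#' @export
fit_bead <- function(vol, position, roi_halfwidth_px = 6) {
  stopifnot(inherits(vol, "volume3d"))
  if (is.data.frame(position) || is.list(position))
    position <- c(position$x_px, position$y_px, position$z_px)
  pos <- round(as.numeric(position))
  d <- dim(vol$data)
  hw <- rep(as.integer(roi_halfwidth_px), length.out = 3L)  # (x, y, z)
  flags <- character(0)

  x0 <- pos[1] - hw[1]; x1 <- pos[1] + hw[1]
  y0 <- pos[2] - hw[2]; y1 <- pos[2] + hw[2]
  z0 <- pos[3] - hw[3]; z1 <- pos[3] + hw[3]
  if (x0 < 1 || y0 < 1 || z0 < 1 || x1 > d[2] || y1 > d[1] || z1 > d[3]) {
    flags <- c(flags, "edge")
    x0 <- max(1L, x0); y0 <- max(1L, y0); z0 <- max(1L, z0)
    x1 <- min(d[2], x1); y1 <- min(d[1], y1); z1 <- min(d[3], z1)
  }
  roi <- vol$data[y0:y1, x0:x1, z0:z1, drop = FALSE]
  if (!is.null(vol$bit_depth) && any(roi >= 2^vol$bit_depth - 1))
    flags <- c(flags, "saturated")

  shell <- roi
  rd <- dim(roi)
  if (all(rd >= 3L)) shell[2:(rd[1] - 1), 2:(rd[2] - 1), 2:(rd[3] - 1)] <- NA
  bg <- median(shell, na.rm = TRUE)

  w <- pmax(roi - bg, 0)
  if (sum(w) <= 0) {
    return(bead_row(NA, NA, NA, NA, NA, NA, NA, NA, NA, NA,
                    paste(c(flags, "fit_failed"), collapse = ",")))
  }
  ys <- y0:y1; xs <- x0:x1; zs <- z0:z1
  cy <- sum(slice.index(w, 1) * w) / sum(w) + y0 - 1
  cx <- sum(slice.index(w, 2) * w) / sum(w) + x0 - 1
  cz <- sum(slice.index(w, 3) * w) / sum(w) + z0 - 1
  iy <- min(max(round(cy), y0), y1) - y0 + 1
  ix <- min(max(round(cx), x0), x1) - x0 + 1
  iz <- min(max(round(cz), z0), z1) - z0 + 1

  fx <- fit_profile_1d(xs, roi[iy, , iz], cx)
  fy <- fit_profile_1d(ys, roi[, ix, iz], cy)
  fz <- fit_profile_1d(zs, roi[iy, ix, ], cz)
  if (!fx$ok || !fy$ok || !fz$ok) flags <- c(flags, "fit_failed")

  vs <- vol$voxel_size_um
  bead_row(x_um = (fx$mu - 1) * vs["x"], y_um = (fy$mu - 1) * vs["y"],
           z_um = (fz$mu - 1) * vs["z"],
           fwhm_x = FWHM_SIGMA * fx$sigma * vs["x"],
           fwhm_y = FWHM_SIGMA * fy$sigma * vs["y"],
           fwhm_z = FWHM_SIGMA * fz$sigma * vs["z"],
           peak = max(roi), r2_x = fx$r2, r2_y = fy$r2, r2_z = fz$r2,
           flags = paste(flags, collapse = ","))
}

bead_row <- function(x_um, y_um, z_um, fwhm_x, fwhm_y, fwhm_z, peak,
                     r2_x, r2_y, r2_z, flags) {
  data.frame(x_um = as.numeric(x_um), y_um = as.numeric(y_um), z_um = as.numeric(z_um),
             fwhm_x_um = as.numeric(fwhm_x), fwhm_y_um = as.numeric(fwhm_y),
             fwhm_z_um = as.numeric(fwhm_z), peak = as.numeric(peak),
             r2_x = as.numeric(r2_x), r2_y = as.numeric(r2_y), r2_z = as.numeric(r2_z),
             flags = flags, stringsAsFactors = FALSE)
}

# Pixel-integrated Gaussian least-squares fit of a 1-D profile.
# t: coordinates (voxel indices), v: intensities, mu0: centroid start value.
fit_profile_1d <- function(t, v, mu0) {
  fail <- list(mu = NA_real_, sigma = NA_real_, r2 = NA_real_, ok = FALSE)
  if (length(t) < 5L) return(fail)
  c0 <- min(v); a0 <- max(v) - c0
  if (a0 <= 0) return(fail)
  w0 <- pmax(v - c0, 0)
  s0 <- sqrt(max(sum(w0 * (t - mu0)^2) / sum(w0), 0.1))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      v ~ A * (pnorm((t + 0.5 - mu) / sigma) - pnorm((t - 0.5 - mu) / sigma)) /
        (pnorm(0.5 / sigma) - pnorm(-0.5 / sigma)) + c,
      start = list(A = a0, mu = mu0, sigma = max(min(s0, diff(range(t)) / 2), 0.4), c = c0),
      lower = c(A = 0, mu = min(t), sigma = 0.25, c = -Inf),
      upper = c(A = Inf, mu = max(t), sigma = diff(range(t)), c = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit)) return(fail)
  p <- coef(fit)
  ss_res <- sum(residuals(fit)^2)
  ss_tot <- sum((v - mean(v))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  ok <- is.finite(p["sigma"]) && p["sigma"] > 0.25 && p["A"] > 0
  list(mu = unname(p["mu"]), sigma = unname(p["sigma"]), r2 = r2, ok = ok)
}

#' Detect and fit all beads in a stack
#'
#' Convenience pipeline: [detect_beads()], then [fit_bead()] on every
#' candidate, then mutual `clumped` flagging of bead pairs closer than
#' `clump_factor` times the mean of their mean FWHMs.
#'
#' @inheritParams detect_beads
#' @inheritParams fit_bead
#' @param clump_factor Pairs closer than `clump_factor` times the smaller
#'   of their mean FWHMs are both flagged `clumped`.
#' @return Data frame of [fit_bead()] rows.
#' @export
measure_beads <- function(vol, min_separation_um, snr_threshold = 10,
                          roi_halfwidth_px = 6, clump_factor = 3) {
  cands <- detect_beads(vol, min_separation_um, snr_threshold)
  if (!nrow(cands)) return(bead_row(numeric(0), numeric(0), numeric(0), numeric(0),
                                    numeric(0), numeric(0), numeric(0), numeric(0),
                                    numeric(0), numeric(0), character(0)))
  rows <- lapply(seq_len(nrow(cands)), function(i)
    fit_bead(vol, cands[i, ], roi_halfwidth_px))
  m <- do.call(rbind, rows)
  ok <- is.finite(m$x_um) & is.finite(m$fwhm_x_um) &
    is.finite(m$fwhm_y_um) & is.finite(m$fwhm_z_um)
  if (sum(ok) > 1L) {
    p <- as.matrix(m[ok, c("x_um", "y_um", "z_um")])
    fw <- rowMeans(m[ok, c("fwhm_x_um", "fwhm_y_um", "fwhm_z_um")])
    dm <- as.matrix(dist(p))
    # the smaller FWHM of the pair: robust when a neighbour has already
    # corrupted the other bead's width estimate
    lim <- clump_factor * outer(fw, fw, pmin)
    diag(dm) <- Inf
    clumped <- apply(dm < lim, 1, any)
    idx <- which(ok)[clumped]
    m$flags[idx] <- ifelse(m$flags[idx] == "", "clumped",
                           paste0(m$flags[idx], ",clumped"))
  }
  m
}

#' Aggregate bead measurements into a field-position map
#'
#' Bins unflagged measurements on an (x, y) grid across the field of view
#' and reports per-bin mean and standard deviation of the lateral FWHM (the
#' per-bead mean of x and y FWHM) and the axial FWHM, as in a PSF
#' field-uniformity map.
#'
#' @param measurements Data frame from [measure_beads()]/[fit_bead()].
#' @param n_bins_xy Integer length-2, bins along x and y.
#' @param extent_um Optional length-2 field extent (x, y) in micrometres;
#'   default spans the measured positions.
#' @return An object of class `psf_field_map`: lists of bin edges and
#'   matrices (`[ybin, xbin]`) `n`, `lateral_mean`, `lateral_sd`,
#'   `axial_mean`, `axial_sd`. Bins with no beads hold `NA` (never zero).
#' @export
aggregate_field_map <- function(measurements, n_bins_xy = c(8, 8), extent_um = NULL) {
  use <- measurements[measurements$flags == "" & is.finite(measurements$fwhm_x_um), ,
                      drop = FALSE]
  if (!nrow(use)) stop("zero usable beads: all measurements are flagged")
  nb <- rep(as.integer(n_bins_xy), length.out = 2L)
  if (is.null(extent_um)) extent_um <- c(max(use$x_um), max(use$y_um))
  xb <- seq(0, extent_um[1], length.out = nb[1] + 1L)
  yb <- seq(0, extent_um[2], length.out = nb[2] + 1L)
  ix <- pmin(pmax(findInterval(use$x_um, xb, rightmost.closed = TRUE), 1L), nb[1])
  iy <- pmin(pmax(findInterval(use$y_um, yb, rightmost.closed = TRUE), 1L), nb[2])
  lat <- (use$fwhm_x_um + use$fwhm_y_um) / 2
  ax <- use$fwhm_z_um
  n <- lm_ <- ls_ <- am_ <- as_ <- matrix(NA_real_, nb[2], nb[1])
  n[] <- 0
  for (b in split(seq_len(nrow(use)), interaction(iy, ix, drop = TRUE))) {
    r <- iy[b[1]]; c <- ix[b[1]]
    n[r, c] <- length(b)
    lm_[r, c] <- mean(lat[b]); ls_[r, c] <- if (length(b) > 1) sd(lat[b]) else 0
    am_[r, c] <- mean(ax[b]); as_[r, c] <- if (length(b) > 1) sd(ax[b]) else 0
  }
  structure(list(x_breaks_um = xb, y_breaks_um = yb, n = n,
                 lateral_mean = lm_, lateral_sd = ls_,
                 axial_mean = am_, axial_sd = as_),
            class = "psf_field_map")
}

#' @export
print.psf_field_map <- function(x, ...) {
  cat(sprintf("psf_field_map: %d x %d bins, %d beads; lateral FWHM %.2f um (mean), axial %.2f um\n",
              ncol(x$n), nrow(x$n), sum(x$n),
              mean(x$lateral_mean, na.rm = TRUE), mean(x$axial_mean, na.rm = TRUE)))
  invisible(x)
}
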