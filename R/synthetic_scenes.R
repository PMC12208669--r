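#' 3-D image volume with voxel-size metadata
#'
#' The common currency of all measurement pipelines: a 3-D intensity array
#' stored `[y, x, z]` (row, column, plane — the orientation produced by
#' [tiff::readTIFF()]) with per-axis physical voxel sizes. Physical
#' coordinates are pixel-centred micrometres: voxel index `i` (1-based) along
#' an axis sits at `(i - 1) * voxel_size_um` for that axis.
#'
#' @param data 3-D numeric array `[y, x, z]`; a 2-D matrix is promoted to a
#'   single-plane volume.
#' @param voxel_size_um Named numeric `c(x =, y =, z =)` voxel size in
#'   micrometres, or a scalar used for all axes.
#' @param bit_depth Optional integer (12, 14 or 16). When set, intensities
#'   must lie within `[0, 2^bit_depth - 1]`.
#' @return An object of class `volume3d`.
#' @export
volume3d <- function(data, voxel_size_um, bit_depth = NULL) {
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("data must be a 3-D array [y, x, z] or a 2-D matrix")
  if (any(dim(data) < 1L)) stop("all dimensions must be >= 1")
  if (length(voxel_size_um) == 1L)
    voxel_size_um <- c(x = voxel_size_um, y = voxel_size_um, z = voxel_size_um)
  voxel_size_um <- voxel_size_um[c("x", "y", "z")]
  if (any(is.na(voxel_size_um)) || any(voxel_size_um <= 0))
    stop("voxel_size_um must be positive, named (x, y, z) or scalar")
  if (!is.null(bit_depth)) {
    if (!bit_depth %in% c(12L, 14L, 16L)) stop("bit_depth must be 12, 14 or 16")
    if (min(data) < 0 || max(data) > 2^bit_depth - 1)
      stop("intensities exceed bit-depth range")
  }
  structure(list(data = data, voxel_size_um = voxel_size_um, bit_depth = bit_depth),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("volume3d: %d x %d x %d (y, x, z); voxel %.3g x %.3g x %.3g um%s\n",
              d[1], d[2], d[3], x$voxel_size_um["x"], x$voxel_size_um["y"],
              x$voxel_size_um["z"],
              if (is.null(x$bit_depth)) "" else sprintf("; %d-bit", x$bit_depth)))
  invisible(x)
}

#' Camera noise model
#'
#' Offset + gain x Poisson(photons) + Gaussian read noise, the standard
#' sCMOS transfer model. Applying it to a photon image satisfies the photon
#' transfer relation `var(counts) = gain * (mean(counts) - offset) +
#' read_noise^2` on a uniform patch.
#'
#' @param offset Baseline counts added to every pixel.
#' @param read_noise Read noise RMS in counts (>= 0).
#' @param gain Counts per photoelectron (> 0).
#' @return An object of class `camera_noise_model`.
#' @export
camera_noise_model <- function(offset = 100, read_noise = 2, gain = 1) {
  if (read_noise < 0) stop("read_noise must be >= 0")
  if (gain <= 0) stop("gain must be > 0")
  structure(list(offset = offset, read_noise = read_noise, gain = gain),
            class = "camera_noise_model")
}

#' Apply a camera noise model to an expected-photon image
#'
#' Shot noise (Poisson, on the photon signal), then Gaussian read noise,
#' then the fixed offset.
#'
#' @param photons Numeric array of expected photon counts (>= 0).
#' @param noise A [camera_noise_model()], or `NULL` for a noiseless ideal
#'   camera (counts = offset + gain * photons).
#' @param seed Optional RNG seed for reproducibility.
#' @return Array of counts, same shape as `photons`.
#' @export
apply_camera_noise <- function(photons, noise, seed = NULL) {
  if (is.null(noise)) return(photons)
  stopifnot(inherits(noise, "camera_noise_model"))
  if (any(photons < 0)) stop("expected photon counts must be >= 0")
  with_seed(seed, {
    n <- length(photons)
    counts <- noise$offset + noise$gain * rpois(n, lambda = as.vector(photons))
    if (noise$read_noise > 0) counts <- counts + rnorm(n, 0, noise$read_noise)
    array(counts, dim = dim(photons))
  })
}

#' Synthetic bead phantom with ground truth
#'
#' Renders sub-resolution fluorescent beads (e.g. 0.2 um microspheres in an
#' expanded hydrogel) as cell-averaged anisotropic Gaussians at sub-voxel
#' positions, optionally with a camera noise model, and returns the exact
#' positions and FWHMs as paired ground truth.
#'
#' Each bead contributes `peak * prod_axis g(i)` where `g` is the normalized
#' integral of a Gaussian over the voxel cell, so a perfectly centred bead
#' has its central voxel at `peak` photons. Beads are placed by greedy
#' rejection sampling honouring a minimum mutual separation of
#' `separation_factor` times the local FWHM; if the requested density cannot
#' be realized the generator refuses with a density error.
#'
#' @param dim_yxz Integer length-3, array dimensions `(ny, nx, nz)`.
#' @param voxel_size_um Voxel size, scalar or named `c(x=, y=, z=)` um.
#' @param n_beads Number of beads (0 gives a pure-noise/offset volume).
#' @param fwhm_um Either a length-3 numeric `(fwhm_x, fwhm_y, fwhm_z)` in um,
#'   or a function `(x_um, y_um) -> c(fwhm_x, fwhm_y, fwhm_z)` giving a
#'   field-position-dependent PSF model.
#' @param peak_counts Expected photons at the central voxel of a centred
#'   bead; scalar or one value per bead.
#' @param background Uniform background photon level.
#' @param noise A [camera_noise_model()] or `NULL`.
#' @param seed RNG seed (determinism contract: same seed, same volume).
#' @param margin_um Margin kept free of bead centres at each face; default
#'   twice the largest FWHM.
#' @param separation_factor Minimum centre separation in units of FWHM
#'   (default 3; set 0 to disable, e.g. to place deliberate close pairs).
#' @param positions_um Optional matrix (n x 3, columns x, y, z um) of bead
#'   centres, overriding random placement.
#' @param bit_depth Optional bit depth; counts are rounded and clamped.
#' @return A list with `volume` (a [volume3d()]) and `truth` (a data frame
#'   of bead positions in um, FWHMs in um, and peak photons).
#' @export
make_bead_phantom <- function(dim_yxz, voxel_size_um, n_beads, fwhm_um = c(1.5, 1.5, 3.0),
                              peak_counts = 1000, background = 0, noise = NULL,
                              seed = 1L, margin_um = NULL, separation_factor = 3,
                              positions_um = NULL, bit_depth = NULL) {
  stopifnot(length(dim_yxz) == 3L, all(dim_yxz >= 1L))
  vs <- if (length(voxel_size_um) == 1L)
    c(x = voxel_size_um, y = voxel_size_um, z = voxel_size_um) else voxel_size_um[c("x", "y", "z")]
  fwhm_fun <- if (is.function(fwhm_um)) fwhm_um else function(x, y) fwhm_um
  extent <- c(x = (dim_yxz[2] - 1) * vs["x"], y = (dim_yxz[1] - 1) * vs["y"],
              z = (dim_yxz[3] - 1) * vs["z"])
  probe <- fwhm_fun(extent[1] / 2, extent[2] / 2)
  if (any(probe <= c(vs["x"], vs["y"], vs["z"])))
    stop("FWHMs must exceed one voxel (sampling-resolvable)")
  if (is.null(margin_um)) margin_um <- 2 * max(probe)

  placed <- with_seed(seed, {
    if (!is.null(positions_um)) {
      positions_um <- as.matrix(positions_um)
      stopifnot(ncol(positions_um) == 3L)
      positions_um
    } else if (n_beads == 0L) {
      matrix(numeric(0), ncol = 3)
    } else {
      lo <- pmin(margin_um, extent / 2)
      hi <- pmax(extent - margin_um, extent / 2)
      pos <- matrix(NA_real_, n_beads, 3)
      sep_ref <- separation_factor * max(probe)
      k <- 0L; attempts <- 0L; max_attempts <- 200L * n_beads
      while (k < n_beads && attempts < max_attempts) {
        attempts <- attempts + 1L
        cand <- c(runif(1, lo[1], hi[1]), runif(1, lo[2], hi[2]), runif(1, lo[3], hi[3]))
        ok <- TRUE
        if (k > 0L && separation_factor > 0) {
          d2 <- (pos[seq_len(k), 1] - cand[1])^2 + (pos[seq_len(k), 2] - cand[2])^2 +
            (pos[seq_len(k), 3] - cand[3])^2
          ok <- min(d2) >= sep_ref^2
        }
        if (ok) { k <- k + 1L; pos[k, ] <- cand }
      }
      if (k < n_beads)
        stop("bead density too high: cannot place ", n_beads,
             " beads at >= ", separation_factor, "x FWHM separation")
      pos
    }
  })

  nb <- nrow(placed)
  fw <- if (nb) t(vapply(seq_len(nb),
                         function(i) fwhm_fun(placed[i, 1], placed[i, 2]), numeric(3)))
        else matrix(numeric(0), ncol = 3)

  vol <- array(background, dim = dim_yxz)
  peak_counts <- rep(peak_counts, length.out = max(nb, 1L))
  if (nb) {
    sigx <- fw[, 1] / (FWHM_SIGMA * vs["x"])
    sigy <- fw[, 2] / (FWHM_SIGMA * vs["y"])
    sigz <- fw[, 3] / (FWHM_SIGMA * vs["z"])
    mux <- placed[, 1] / vs["x"] + 1   # voxel-index coordinates (1-based centres)
    muy <- placed[, 2] / vs["y"] + 1
    muz <- placed[, 3] / vs["z"] + 1
    for (i in seq_len(nb)) {
      gx <- cell_gauss(dim_yxz[2], mux[i], sigx[i])
      gy <- cell_gauss(dim_yxz[1], muy[i], sigy[i])
      gz <- cell_gauss(dim_yxz[3], muz[i], sigz[i])
      if (!length(gx$idx) || !length(gy$idx) || !length(gz$idx)) next
      block <- peak_counts[i] * (gy$val %o% gx$val %o% gz$val)
      vol[gy$idx, gx$idx, gz$idx] <- vol[gy$idx, gx$idx, gz$idx] + block
    }
  }
  counts <- apply_camera_noise(vol, noise, seed = if (is.null(seed)) NULL else sub_seed(seed, 1L))
  if (!is.null(bit_depth)) counts <- pmin(pmax(round(counts), 0), 2^bit_depth - 1)
  truth <- data.frame(x_um = placed[, 1], y_um = placed[, 2], z_um = placed[, 3],
                      fwhm_x_um = fw[, 1], fwhm_y_um = fw[, 2], fwhm_z_um = fw[, 3],
                      peak = peak_counts[seq_len(nb)])
  list(volume = volume3d(counts, vs, bit_depth = bit_depth), truth = truth)
}

# FWHM of a Gaussian = 2 sqrt(2 ln 2) sigma
FWHM_SIGMA <- 2 * sqrt(2 * log(2))

# Normalized cell-integrated 1-D Gaussian profile: indices within +-5 sigma
# of mu (clipped to 1..n) and values scaled so a centred cell equals 1.
cell_gauss <- function(n, mu, sigma) {
  lo <- max(1L, floor(mu - 5 * sigma - 1))
  hi <- min(n, ceiling(mu + 5 * sigma + 1))
  if (lo > hi) return(list(idx = integer(0), val = numeric(0)))
  idx <- lo:hi
  val <- pnorm((idx + 0.5 - mu) / sigma) - pnorm((idx - 0.5 - mu) / sigma)
  list(idx = idx, val = val / (pnorm(0.5 / sigma) - pnorm(-0.5 / sigma)))
}

#' Synthetic through-focus Ronchi-ruling stack with ground truth
#'
#' Emulates scanning a binary square-wave grating (a Ronchi ruling) through
#' the focal plane of a lens whose best-focus depth varies with field
#' position. Each frame is the square wave convolved with a Gaussian whose
#' width grows with defocus `|z - z0(x, y)|`, so per-region contrast peaks
#' at the local best focus and decays symmetrically. The focus surface is
#' evaluated piecewise-constant on a rendering block grid; the exact
#' erf-form convolution is used, with a uniform-field shortcut where the
#' residual grating modulation is numerically zero (fundamental attenuation
#' below 1e-6).
#'
#' @param dim_yxz Integer length-3 `(ny, nx, nz)`: frame size and plane count.
#' @param period_px Grating period in pixels (>= 4).
#' @param z_step_um Plane spacing in micrometres; plane k (1-based) is at
#'   `(k - 1) * z_step_um`.
#' @param focus_surface Function `(x_px, y_px) -> z0_um` (vectorized),
#'   best-focus depth at 0-based pixel-centre coordinates. Must stay within
#'   the scanned range.
#' @param blur_vs_defocus Function `dz_um -> sigma_px` mapping absolute
#'   defocus to Gaussian blur width in pixels (vectorized, nonnegative).
#' @param contrast_max Grating modulation depth at perfect focus, in `[0, 1]`.
#' @param mean_level Mean photon level of the pattern.
#' @param block_px Rendering block size in pixels (focus surface resolution).
#' @param noise A [camera_noise_model()] or `NULL`.
#' @param seed RNG seed (used only when `noise` is given).
#' @param quantize Store frames as integer counts (rounded), as a real
#'   analogue-to-digital converter would; halves memory for large stacks.
#' @return A list with `volume` (a [volume3d()], voxel x/y size 1 px
#'   equivalent, z size `z_step_um`) and `truth` (the focus surface function,
#'   its values at rendering-block centres, and the z positions in um).
#' @export
make_ronchi_stack <- function(dim_yxz, period_px, z_step_um, focus_surface,
                              blur_vs_defocus, contrast_max = 0.9,
                              mean_level = 1000, block_px = 32L,
                              noise = NULL, seed = 1L, quantize = FALSE) {
  stopifnot(length(dim_yxz) == 3L, all(dim_yxz >= 1L))
  if (period_px < 4) stop("period_px must be >= 4")
  if (contrast_max < 0 || contrast_max > 1) stop("contrast_max must be in [0, 1]")
  ny <- dim_yxz[1]; nx <- dim_yxz[2]; nz <- dim_yxz[3]
  z_um <- (seq_len(nz) - 1) * z_step_um
  hi <- mean_level * (1 + contrast_max)
  lo <- mean_level * (1 - contrast_max)

  row_b <- block_ranges(ny, block_px)
  col_b <- block_ranges(nx, block_px)
  use_int <- quantize && is.null(noise)
  vol <- if (use_int) array(as.integer(round(mean_level)), dim = dim_yxz)
         else array(mean_level, dim = dim_yxz)
  z0_block <- matrix(NA_real_, length(row_b), length(col_b))
  # attenuation of the square wave fundamental; below tol the field is flat
  sigma_flat <- period_px * sqrt(log(1e6) / (2 * pi^2))

  # For an integer period the profile at integer pixels depends only on
  # (x mod period, sigma): tabulate it on a dense blur grid and interpolate
  # (grid spacing ~ sigma_flat/2048; interpolation error << photon noise).
  table_path <- period_px == round(period_px)
  if (table_path) {
    sgrid <- seq(0, sigma_flat, length.out = 2048L)
    P <- t(vapply(sgrid, function(s)
      blurred_square_wave(0:(period_px - 1), period_px, s, lo, hi),
      numeric(period_px)))
  }

  for (bi in seq_along(row_b)) {
    for (bj in seq_along(col_b)) {
      rows <- row_b[[bi]]; cols <- col_b[[bj]]
      xs <- cols - 1  # 0-based pixel-centre x
      cx <- mean(xs); cy <- mean(rows - 1)
      z0 <- focus_surface(cx, cy)
      if (z0 < min(z_um) || z0 > max(z_um))
        stop("focus surface exits the scanned z range")
      z0_block[bi, bj] <- z0
      sig <- blur_vs_defocus(abs(z_um - z0))
      if (any(sig < 0)) stop("blur_vs_defocus must be nonnegative")
      B <- matrix(mean_level, nz, length(xs))
      need <- which(sig < sigma_flat)
      if (length(need)) {
        if (table_path) {
          idx <- (xs %% period_px) + 1L
          t_ <- sig[need] / sigma_flat * 2047 + 1
          i1 <- pmin(floor(t_), 2047); w <- t_ - i1
          B[need, ] <- P[i1, idx, drop = FALSE] * (1 - w) +
            P[i1 + 1L, idx, drop = FALSE] * w
        } else {
          for (k in need)
            B[k, ] <- blurred_square_wave(xs, period_px, sig[k], lo, hi)
        }
      }
      # replicate the 1-D x-profile down the block rows: [y, x, z]
      prof <- if (use_int) as.integer(round(t(B))) else as.vector(t(B))
      vol[rows, cols, ] <- array(rep(prof, each = length(rows)),
                                 dim = c(length(rows), length(xs), nz))
    }
  }
  counts <- apply_camera_noise(vol, noise, seed = seed)
  if (quantize && !is.null(noise)) {
    counts <- round(counts)
    storage.mode(counts) <- "integer"
  }
  truth <- list(focus_surface = focus_surface, z0_block = z0_block,
                block_rows = row_b, block_cols = col_b, z_positions_um = z_um)
  list(volume = volume3d(counts, c(x = 1, y = 1, z = z_step_um)), truth = truth)
}

# Contiguous block index ranges of size `size`; remainder joins the last block.
block_ranges <- function(n, size) {
  nb <- max(1L, n %/% size)
  starts <- (seq_len(nb) - 1L) * size + 1L
  ends <- c(starts[-1L] - 1L, n)
  Map(function(s, e) s:e, starts, ends)
}

# Square wave (bright on [k*p, k*p + p/2)) convolved with Gaussian(sigma),
# evaluated at positions x; exact erf form truncated at 6 sigma.
blurred_square_wave <- function(x, period, sigma, lo, hi) {
  if (sigma == 0) return(ifelse((x %% period) < period / 2, hi, lo))
  kmin <- floor((min(x) - 6 * sigma) / period) - 1
  kmax <- ceiling((max(x) + 6 * sigma) / period) + 1
  starts <- (kmin:kmax) * period
  ends <- starts + period / 2
  b <- rowSums(pnorm(outer(x, starts, "-") / sigma) -
                 pnorm(outer(x, ends, "-") / sigma))
  lo + (hi - lo) * b
}

#' Synthetic dot-grid distortion target with ground truth
#'
#' Emulates a trans-illuminated calibration target: dark circular dots on a
#' bright background, placed on a square lattice and displaced by a radial
#' distortion model `r_d = r * (1 + k1 r^2 + k2 r^4)` about a distortion
#' centre. Dots are rendered with anti-aliased (area-coverage) edges at
#' sub-pixel positions.
#'
#' @param dim_yx Integer length-2 `(ny, nx)` image size.
#' @param spacing_px Lattice spacing in pixels (> dot diameter).
#' @param dot_diameter_px Dot diameter in pixels.
#' @param k1,k2 Radial distortion coefficients (px^-2, px^-4); positive k1
#'   is pincushion (outward displacement), negative is barrel.
#' @param center_px Optional length-2 `(x, y)` distortion centre in 0-based
#'   pixel coordinates; default image centre.
#' @param background Bright background level (photons).
#' @param dot_depth Intensity drop at the centre of a dot.
#' @param edge_sigma_px Gaussian edge-spread of the dot boundary in pixels
#'   (optical blur of the imaged target); `0` gives a hard anti-aliased
#'   disc edge.
#' @param noise A [camera_noise_model()] or `NULL`.
#' @param seed RNG seed (used only when `noise` is given).
#' @return A list with `image` (matrix `[y, x]`), `truth` (data frame of
#'   lattice indices, ideal and distorted positions, radii), `k1`, `k2`,
#'   `center_px`.
#' @export
make_dot_grid <- function(dim_yx, spacing_px, dot_diameter_px, k1 = 0, k2 = 0,
                          center_px = NULL, background = 1000, dot_depth = 900,
                          edge_sigma_px = 1, noise = NULL, seed = 1L) {
  stopifnot(length(dim_yx) == 2L)
  if (spacing_px <= dot_diameter_px) stop("spacing must exceed dot diameter")
  ny <- dim_yx[1]; nx <- dim_yx[2]
  if (is.null(center_px)) center_px <- c((nx - 1) / 2, (ny - 1) / 2)
  radius <- dot_diameter_px / 2
  margin <- radius + 2 + 3 * edge_sigma_px

  imax <- floor((nx - 1) / spacing_px); jmax <- floor((ny - 1) / spacing_px)
  g <- expand.grid(i = -imax:imax, j = -jmax:jmax, KEEP.OUT.ATTRS = FALSE)
  xi <- center_px[1] + g$i * spacing_px
  yi <- center_px[2] + g$j * spacing_px
  keep <- xi >= margin & xi <= nx - 1 - margin & yi >= margin & yi <= ny - 1 - margin
  g <- g[keep, , drop = FALSE]; xi <- xi[keep]; yi <- yi[keep]
  if (!nrow(g)) stop("no dots fit inside the image")

  r <- sqrt((xi - center_px[1])^2 + (yi - center_px[2])^2)
  scale <- 1 + k1 * r^2 + k2 * r^4
  xd <- center_px[1] + (xi - center_px[1]) * scale
  yd <- center_px[2] + (yi - center_px[2]) * scale
  if (any(xd < margin | xd > nx - 1 - margin | yd < margin | yd > ny - 1 - margin))
    stop("distortion pushes dots out of frame")

  img <- matrix(background, ny, nx)
  pad <- radius + 2 + 3 * edge_sigma_px
  for (d in seq_along(xd)) {
    c0 <- max(1L, floor(xd[d] - pad)); c1 <- min(nx, ceiling(xd[d] + pad + 1))
    r0 <- max(1L, floor(yd[d] - pad)); r1 <- min(ny, ceiling(yd[d] + pad + 1))
    xs <- (c0:c1) - 1; ys <- (r0:r1) - 1
    dist <- sqrt(outer((ys - yd[d])^2, (xs - xd[d])^2, "+"))
    cov <- if (edge_sigma_px > 0) pnorm((radius - dist) / edge_sigma_px)
           else pmin(1, pmax(0, radius - dist + 0.5))  # hard anti-aliased edge
    img[r0:r1, c0:c1] <- img[r0:r1, c0:c1] - dot_depth * cov
  }
  img <- apply_camera_noise(img, noise, seed = seed)
  truth <- data.frame(i = g$i, j = g$j, x_ideal = xi, y_ideal = yi,
                      x_true = xd, y_true = yd, r_theo = r,
                      r_true = r * scale)
  list(image = img, truth = truth, k1 = k1, k2 = k2, center_px = center_px)
}
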