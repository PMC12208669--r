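#' ROI grid decomposition of a frame
#'
#' Splits frame dimensions into a contiguous, non-overlapping grid of
#' regions of interest. Each ROI spans `floor(n / grid)` pixels per axis;
#' remainder pixels are assigned to the last row/column. A 14192 x 10640
#' frame split 16 x 16 yields 887 x 665 pixel ROIs.
#'
#' @param dim_yx Integer length-2 frame dimensions `(ny, nx)`.
#' @param grid Integer length-2 grid `(rows, cols)`, default `c(16, 16)`.
#' @return List with `rows` and `cols`: lists of 1-based index ranges.
#' @export
roi_grid <- function(dim_yx, grid = c(16, 16)) {
  stopifnot(length(dim_yx) == 2L, length(grid) == 2L)
  if (any(grid > dim_yx)) stop("grid larger than frame")
  split1 <- function(n, g) {
    size <- n %/% g
    starts <- (seq_len(g) - 1L) * size + 1L
    ends <- c(starts[-1L] - 1L, n)
    Map(function(s, e) s:e, starts, ends)
  }
  list(rows = split1(dim_yx[1], grid[1]), cols = split1(dim_yx[2], grid[2]))
}

#' Split a stack into per-ROI substacks
#'
#' @param vol A [volume3d()] (or bare 3-D array) through-focus stack.
#' @param grid Integer length-2 ROI grid, default `c(16, 16)`.
#' @return List of 3-D arrays in row-major ROI order, with attributes
#'   `roi_index` (grid row, col) and `center_px` (0-based x, y pixel centre)
#'   on each element.
#' @export
split_rois <- function(vol, grid = c(16, 16)) {
  a <- if (inherits(vol, "volume3d")) vol$data else vol
  stopifnot(is.array(a), length(dim(a)) == 3L)
  g <- roi_grid(dim(a)[1:2], grid)
  out <- list()
  for (i in seq_along(g$rows)) for (j in seq_along(g$cols)) {
    sub <- a[g$rows[[i]], g$cols[[j]], , drop = FALSE]
    attr(sub, "roi_index") <- c(i, j)
    attr(sub, "center_px") <- c(x = mean(g$cols[[j]]) - 1, y = mean(g$rows[[i]]) - 1)
    out[[length(out) + 1L]] <- sub
  }
  out
}

#' Percentile-based frame contrast
#'
#' Robust Michelson-style contrast of a frame: `C = (I95 - I5)/(I95 + I5)`
#' with the 95th and 5th intensity percentiles (type-7 linear
#' interpolation, the same definition as [stats::quantile()]). Invariant
#' under multiplicative intensity scaling.
#'
#' @param frame Numeric matrix or vector of pixel intensities.
#' @return Contrast in `[0, 1]`.
#' @export
frame_contrast <- function(frame) {
  v <- as.numeric(frame)
  if (!length(v)) stop("empty frame")
  p <- percentile7(v, c(0.05, 0.95))
  den <- p[2] + p[1]
  if (den <= 0) stop("contrast undefined: all-zero (or non-positive) frame")
  (p[2] - p[1]) / den
}

#' Contrast-versus-depth curve of a substack
#'
#' [frame_contrast()] applied to every frame of a 3-D substack, computed in
#' compiled code with exact order statistics (identical to the per-frame
#' definition to machine precision).
#'
#' @param substack 3-D array `[y, x, z]` (or [volume3d()]).
#' @return Numeric vector of per-frame contrasts.
#' @export
contrast_curve <- function(substack) {
  a <- if (inherits(substack, "volume3d")) substack$data else substack
  stopifnot(is.array(a), length(dim(a)) == 3L)
  cc <- col_contrast_cpp(matrix(a, ncol = dim(a)[3]))
  if (anyNA(cc)) stop("contrast undefined: all-zero (or non-positive) frame")
  cc
}

#' Best-focus depth from a contrast-versus-depth curve
#'
#' Fits a Gaussian with baseline, `a * exp(-(z - mu)^2 / (2 w^2)) + b`, to
#' the contrast curve by least squares; the fitted centre is the best-focus
#' depth. The fit is marked invalid (`fit_ok = FALSE`) when the curve is
#' flat (fitted peak minus baseline below 3x the residual RMS), the centre
#' falls outside the scanned range, or the fit does not converge.
#'
#' @param contrast Numeric vector of per-frame contrasts.
#' @param z_um Numeric vector of frame depths in micrometres (same length,
#'   >= 5 samples).
#' @return List with `best_focus_um`, `fit_width_um`, `fit_ok`.
#' @export
best_focus <- function(contrast, z_um) {
  if (length(contrast) != length(z_um)) stop("contrast and z_um lengths differ")
  if (length(contrast) < 5L) stop("need >= 5 z samples")
  bad <- list(best_focus_um = NA_real_, fit_width_um = NA_real_, fit_ok = FALSE)
  if (max(contrast) - min(contrast) <= 0) return(bad)
  b0 <- min(contrast); a0 <- max(contrast) - b0
  mu0 <- z_um[which.max(contrast)]
  w <- pmax(contrast - b0, 0)
  s0 <- sqrt(max(sum(w * (z_um - mu0)^2) / sum(w), diff(range(z_um)) / 1e4))
  fit <- tryCatch(
    minpack.lm::nlsLM(contrast ~ a * exp(-(z_um - mu)^2 / (2 * s^2)) + b,
                      start = list(a = a0, mu = mu0, s = s0, b = b0),
                      lower = c(a = 0, mu = min(z_um), s = 1e-9, b = -Inf),
                      upper = c(a = Inf, mu = max(z_um), s = diff(range(z_um)), b = Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(bad)
  p <- coef(fit)
  rms <- sqrt(mean(residuals(fit)^2))
  ok <- p[["a"]] >= 3 * rms &&
    p[["mu"]] >= min(z_um) && p[["mu"]] <= max(z_um)
  list(best_focus_um = unname(p[["mu"]]), fit_width_um = unname(p[["s"]]),
       fit_ok = ok)
}

#' Field-curvature map from a through-focus grating stack
#'
#' Full pipeline: split the stack into an ROI grid, compute the
#' percentile-contrast of every frame of every ROI, fit the per-ROI
#' contrast-versus-depth curve with a Gaussian to locate best focus, and
#' radially average the best-focus depths about the field centre.
#'
#' @param vol A [volume3d()] through-focus stack (z spacing taken from its
#'   voxel size unless `z_um` is given).
#' @param grid ROI grid, default `c(16, 16)`.
#' @param z_um Optional explicit frame depths (um).
#' @param pixel_size_um Lateral pixel size for radii, default from `vol`.
#' @param dof_um Optional depth of field (um) for expressing the radial
#'   profile in DoF units (see [depth_of_field()]).
#' @return Object of class `field_curvature_map`: `focus_um` (matrix of
#'   per-ROI best-focus depths, NA where invalid), `fit_ok`, `curves`
#'   (per-ROI contrast vectors), `radial` (data frame from
#'   [radial_average_map()]), plus grid geometry.
#' @export
measure_field_curvature <- function(vol, grid = c(16, 16), z_um = NULL,
                                    pixel_size_um = NULL, dof_um = NULL) {
  stopifnot(inherits(vol, "volume3d"))
  d <- dim(vol$data)
  if (is.null(z_um)) z_um <- (seq_len(d[3]) - 1) * vol$voxel_size_um["z"]
  if (is.null(pixel_size_um)) pixel_size_um <- unname(vol$voxel_size_um["x"])
  g <- roi_grid(d[1:2], grid)
  nr <- length(g$rows); nc <- length(g$cols)
  focus <- matrix(NA_real_, nr, nc)
  okm <- matrix(FALSE, nr, nc)
  # all ROI contrast curves in one pass over the stack (compiled kernel,
  # identical to frame_contrast per frame)
  cm <- roi_contrast_cpp(vol$data, dim(vol$data),
                         vapply(g$rows, min, integer(1)), vapply(g$rows, max, integer(1)),
                         vapply(g$cols, min, integer(1)), vapply(g$cols, max, integer(1)))
  if (anyNA(cm)) stop("contrast undefined: all-zero (or non-positive) frame")
  curves <- lapply(seq_len(nr * nc), function(k) cm[k, ])
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    bf <- best_focus(cm[(i - 1) * nc + j, ], z_um)
    if (bf$fit_ok) { focus[i, j] <- bf$best_focus_um; okm[i, j] <- TRUE }
  }
  radial <- radial_average_map(focus, frame_dim_yx = d[1:2],
                               pixel_size_um = pixel_size_um, dof_um = dof_um)
  structure(list(focus_um = focus, fit_ok = okm, curves = curves,
                 z_um = z_um, grid = c(nr, nc), frame_dim_yx = d[1:2],
                 pixel_size_um = pixel_size_um, dof_um = dof_um, radial = radial),
            class = "field_curvature_map")
}

#' @export
print.field_curvature_map <- function(x, ...) {
  cat(sprintf("field_curvature_map: %d x %d ROIs (%d valid fits); max |radial shift| %.2f um\n",
              x$grid[1], x$grid[2], sum(x$fit_ok),
              max(abs(x$radial$shift_um), na.rm = TRUE)))
  invisible(x)
}

#' Radially average a grid of best-focus depths
#'
#' Assigns each ROI to a concentric ring about the field centre (one ring
#' per ROI ring: 8 rings for a 16 x 16 grid), and averages the focal shift
#' relative to the innermost ring within each ring. The profile at the
#' centre is therefore 0 by construction. Optionally also expressed in
#' depth-of-field units.
#'
#' @param focus_grid Numeric matrix of per-ROI best-focus depths in um
#'   (`NA` = invalid fit).
#' @param frame_dim_yx Optional frame dimensions used to place ROI centres
#'   in pixels; when omitted, radii are in ROI units.
#' @param pixel_size_um Lateral pixel size (um) for physical radii.
#' @param dof_um Optional depth of field (um) for the `shift_dof` column.
#' @return Data frame with `ring`, `radius_px`, `radius_um` (or
#'   `radius_mm`), `shift_um`, `shift_sd_um`, `n`, and `shift_dof` when
#'   `dof_um` is given.
#' @export
radial_average_map <- function(focus_grid, frame_dim_yx = NULL,
                               pixel_size_um = 1, dof_um = NULL) {
  nr <- nrow(focus_grid); nc <- ncol(focus_grid)
  if (!any(is.finite(focus_grid))) stop("no valid focus fits")
  if (!is.null(frame_dim_yx)) {
    g <- roi_grid(frame_dim_yx, c(nr, nc))
    cy <- vapply(g$rows, mean, numeric(1)) - 1
    cx <- vapply(g$cols, mean, numeric(1)) - 1
    fx <- (frame_dim_yx[2] - 1) / 2; fy <- (frame_dim_yx[1] - 1) / 2
  } else {
    cy <- seq_len(nr); cx <- seq_len(nc)
    fx <- (nc + 1) / 2; fy <- (nr + 1) / 2
  }
  rad <- sqrt(outer((cy - fy)^2, (cx - fx)^2, "+"))
  # ring index: Chebyshev distance from the grid centre in ROI units
  ri <- abs(seq_len(nr) - (nr + 1) / 2)
  rj <- abs(seq_len(nc) - (nc + 1) / 2)
  ring <- ceiling(outer(ri, rj, pmax))
  ring[ring == 0] <- 1L   # odd grids: centre ROI belongs to ring 1

  ok <- is.finite(focus_grid)
  inner <- ring == min(ring[ok])
  ref <- mean(focus_grid[inner & ok])
  shift <- focus_grid - ref
  rings <- sort(unique(ring[ok]))
  out <- data.frame(
    ring = rings,
    radius_px = vapply(rings, function(k) mean(rad[ring == k & ok]), numeric(1)),
    shift_um = vapply(rings, function(k) mean(shift[ring == k & ok]), numeric(1)),
    shift_sd_um = vapply(rings, function(k) {
      v <- shift[ring == k & ok]; if (length(v) > 1) sd(v) else 0
    }, numeric(1)),
    n = vapply(rings, function(k) sum(ring == k & ok), numeric(1)))
  out$radius_um <- out$radius_px * pixel_size_um
  out$shift_um <- out$shift_um - out$shift_um[1]  # profile is 0 at the centre ring
  if (!is.null(dof_um)) out$shift_dof <- out$shift_um / dof_um
  attr(out, "reference_focus_um") <- ref
  out
}
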