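#' Lens specification
#'
#' Container for the static optical parameters of a detection (or excitation)
#' lens: field of view, numerical aperture, working distance, magnification,
#' and immersion-medium refractive index.
#'
#' @param fov_mm Field-of-view diameter in mm (> 0).
#' @param na Numerical aperture (0 < na < medium_ri).
#' @param magnification Lateral magnification (> 0).
#' @param wd_mm Working distance in mm (optional, informational).
#' @param medium_ri Refractive index of the immersion medium (>= 1).
#'
#' @return An object of class `lens_spec`.
#' @examples
#' lens_spec(fov_mm = 16.8, na = 0.305, magnification = 5.0, medium_ri = 1.33)
#' @export
lens_spec <- function(fov_mm, na, magnification, wd_mm = NA_real_, medium_ri = 1.0) {
  stopifnot(is.numeric(fov_mm), length(fov_mm) == 1L,
            is.numeric(na), length(na) == 1L,
            is.numeric(magnification), length(magnification) == 1L)
  if (fov_mm <= 0) stop("fov_mm must be > 0")
  if (medium_ri < 1) stop("medium_ri must be >= 1")
  if (na <= 0 || na >= medium_ri) stop("na must satisfy 0 < na < medium_ri")
  if (magnification <= 0) stop("magnification must be > 0")
  structure(list(fov_mm = fov_mm, na = na, magnification = magnification,
                 wd_mm = wd_mm, medium_ri = medium_ri),
            class = "lens_spec")
}

#' Sensor specification
#'
#' @param pixels_h Pixel count per row (horizontal, integer > 0).
#' @param pixels_v Row count (vertical, integer > 0).
#' @param pitch_um Pixel pitch in micrometres (> 0).
#' @param line_time_us Named numeric vector mapping bit-depth mode
#'   (`"12"`, `"14"`, `"16"`) to rolling-shutter row readout time in
#'   microseconds. All entries must be > 0.
#'
#' @return An object of class `sensor_spec`.
#' @examples
#' # A 151-megapixel large-format CMOS sensor
#' sensor_spec(14192, 10640, 3.76, c("12" = 15.00, "14" = 20.15, "16" = 45.44))
#' @export
sensor_spec <- function(pixels_h, pixels_v, pitch_um, line_time_us = numeric(0)) {
  if (pixels_h < 1 || pixels_v < 1 || pixels_h != round(pixels_h) || pixels_v != round(pixels_v))
    stop("pixel counts must be positive integers")
  if (pitch_um <= 0) stop("pitch_um must be > 0")
  if (length(line_time_us) && any(line_time_us <= 0))
    stop("line times must be > 0")
  structure(list(pixels_h = as.integer(pixels_h), pixels_v = as.integer(pixels_v),
                 pitch_um = pitch_um, line_time_us = line_time_us),
            class = "sensor_spec")
}

#' Tissue expansion specification
#'
#' @param factor Linear expansion factor of the hydrogel-embedded tissue
#'   (dimensionless, >= 1; 1 means no expansion).
#' @return An object of class `expansion_spec`.
#' @export
expansion_spec <- function(factor) {
  if (!is.numeric(factor) || length(factor) != 1L || factor < 1)
    stop("expansion factor must be a single number >= 1")
  structure(list(factor = factor), class = "expansion_spec")
}

#' Optical etendue of a lens
#'
#' Etendue G = (pi/4) * (FOV * NA)^2, a throughput measure proportional to
#' the number of resolvable elements of the optical system. It is quadratic
#' in the product of field-of-view diameter and numerical aperture.
#'
#' @param fov_mm Field-of-view diameter in mm (>= 0).
#' @param na Numerical aperture (>= 0).
#' @return Etendue in mm^2.
#' @examples
#' etendue(6, 0.47)    # 6.25 mm^2
#' etendue(14, 0.35)   # 18.86 mm^2
#' etendue(5, 0.6)     # 7.07 mm^2
#' @export
etendue <- function(fov_mm, na) {
  if (any(fov_mm < 0) || any(na < 0)) stop("fov_mm and na must be non-negative")
  (pi / 4) * (fov_mm * na)^2
}

#' Object-space sampling
#'
#' Physical size of one sensor pixel projected into the specimen plane.
#'
#' @param pitch_um Sensor pixel pitch in micrometres (> 0).
#' @param magnification Lateral magnification (> 0).
#' @return Micrometres per pixel at the specimen.
#' @examples
#' object_sampling(3.76, 5.0)  # 0.752 um/px
#' @export
object_sampling <- function(pitch_um, magnification) {
  if (any(pitch_um <= 0) || any(magnification <= 0))
    stop("pitch_um and magnification must be > 0")
  pitch_um / magnification
}

#' Sampling-limited resolution (Nyquist criterion)
#'
#' @param object_sampling_um Object-space sampling in micrometres per pixel.
#' @return Nyquist-limited resolution in micrometres (2x the sampling).
#' @examples
#' nyquist_resolution(object_sampling(3.76, 5.0))  # 1.504 um
#' @export
nyquist_resolution <- function(object_sampling_um) {
  if (any(object_sampling_um <= 0)) stop("sampling must be > 0")
  2 * object_sampling_um
}

#' Sensor geometry projected into the specimen plane
#'
#' @param sensor A [sensor_spec()].
#' @param lens A [lens_spec()] (its magnification is used).
#' @return A list with `fov_w_mm`, `fov_h_mm`, `diag_mm` (specimen-plane
#'   field width, height, diagonal in mm) and `megapixels`.
#' @examples
#' s <- sensor_spec(14192, 10640, 3.76)
#' l <- lens_spec(16.8, 0.305, 5.0, medium_ri = 1.33)
#' sensor_geometry(s, l)  # 10.67 x 8.00 mm, 13.3 mm diagonal, 151 MP
#' @export
sensor_geometry <- function(sensor, lens) {
  stopifnot(inherits(sensor, "sensor_spec"), inherits(lens, "lens_spec"))
  w_mm <- um_to_mm(sensor$pixels_h * sensor$pitch_um / lens$magnification)
  h_mm <- um_to_mm(sensor$pixels_v * sensor$pitch_um / lens$magnification)
  list(fov_w_mm = w_mm,
       fov_h_mm = h_mm,
       diag_mm = sqrt(w_mm^2 + h_mm^2),
       megapixels = sensor$pixels_h * sensor$pixels_v / 1e6)
}

#' Voxel (pixel) rate of a rolling-shutter sensor
#'
#' Rows are read one line time at a time, so the sustained rate is the row
#' width divided by the line time.
#'
#' @param pixels_per_row Pixels read out per row (> 0).
#' @param line_time_us Row readout time in microseconds (> 0).
#' @return Voxels per second.
#' @seealso [report_megavoxel_rate()] for the truncated integer convention.
#' @examples
#' voxel_rate(14192, 15.00)  # 946.1e6 voxels/s
#' voxel_rate(14192, 45.44)  # 312.3e6 voxels/s
#' @export
voxel_rate <- function(pixels_per_row, line_time_us) {
  if (any(pixels_per_row <= 0) || any(line_time_us <= 0))
    stop("pixels_per_row and line_time_us must be > 0")
  pixels_per_row / (line_time_us * 1e-6)
}

#' Effective resolution in native tissue units
#'
#' Physical tissue expansion enlarges the specimen before imaging, so the
#' optical resolution divided by the linear expansion factor gives the
#' effective resolution in pre-expansion (native) tissue units.
#'
#' @param optical_resolution_um Optical (or sampling-limited) resolution in
#'   micrometres, in expanded-specimen units.
#' @param expansion An [expansion_spec()] or a numeric factor >= 1.
#' @return Effective resolution in micrometres of native tissue.
#' @examples
#' effective_resolution(1.5, expansion_spec(3))  # 0.5 um
#' @export
effective_resolution <- function(optical_resolution_um, expansion) {
  f <- as_expansion_factor(expansion)
  if (any(optical_resolution_um <= 0)) stop("resolution must be > 0")
  optical_resolution_um / f
}

#' Native tissue extent for an expanded-specimen extent
#'
#' @param extent_mm Numeric vector of expanded-specimen extents in mm.
#' @param expansion An [expansion_spec()] or numeric factor >= 1.
#' @return Native extents in mm (same length as `extent_mm`); round with
#'   [round_half_up()] at 0 digits for the integer-mm report convention.
#' @examples
#' native_volume(c(200, 52, 35), 3)  # ~ 67, 17, 12 mm
#' @export
native_volume <- function(extent_mm, expansion) {
  f <- as_expansion_factor(expansion)
  if (any(extent_mm <= 0)) stop("extents must be > 0")
  extent_mm / f
}

#' Relative light-collection efficiency of two numerical apertures
#'
#' Fluorescence signal collection scales approximately with NA^2, so the
#' fold change between a reference and a test aperture is (na_ref/na_test)^2.
#'
#' @param na_ref,na_test Numerical apertures (> 0).
#' @return Fold change (dimensionless).
#' @examples
#' light_collection_ratio(1.0, 0.305)  # ~10.75: >10-fold
#' light_collection_ratio(0.5, 0.305)  # ~2.69:  2.7-fold
#' @export
light_collection_ratio <- function(na_ref, na_test) {
  if (any(na_ref <= 0) || any(na_test <= 0)) stop("numerical apertures must be > 0")
  (na_ref / na_test)^2
}

#' Depth of field
#'
#' Classical diffraction-limited depth of field, lambda * n / NA^2. Used to
#' express field curvature in instrument-relevant units.
#'
#' @param na Numerical aperture (0 < na < medium_ri).
#' @param wavelength_um Wavelength in micrometres.
#' @param medium_ri Immersion-medium refractive index.
#' @return Depth of field in micrometres.
#' @examples
#' depth_of_field(0.305, 0.520, 1.33)  # ~7.4 um
#' @export
depth_of_field <- function(na, wavelength_um, medium_ri = 1.0) {
  if (any(na <= 0) || any(na >= medium_ri)) stop("na must satisfy 0 < na < medium_ri")
  if (any(wavelength_um <= 0)) stop("wavelength must be > 0")
  wavelength_um * medium_ri / na^2
}

#' Plan a 2-D tile grid covering a specimen extent
#'
#' Computes the minimal axis-aligned grid of camera fields of view that
#' covers a rectangular specimen extent with at least the requested
#' fractional overlap between adjacent tiles. The third (z) axis is covered
#' by the stage scan, not by tiling.
#'
#' @param extent_mm_xy Length-2 numeric, specimen extent (x, y) in mm.
#' @param fov_mm_xy Length-2 numeric, camera field of view (x, y) in mm.
#' @param overlap_frac Fractional overlap in `[0, 1)`.
#' @return An object of class `tile_plan` with fields `nx`, `ny`,
#'   `step_mm` (per-axis step), `overlap_frac`, `origins` (data frame of
#'   tile lower-left corners in mm), `fov_mm_xy`, `extent_mm_xy`.
#' @examples
#' plan_tiles(c(30, 24), c(10.6, 8.0), 0)       # 3 x 3 grid
#' plan_tiles(c(10, 7), c(10.6, 8.0), 0.15)     # single tile
#' @export
plan_tiles <- function(extent_mm_xy, fov_mm_xy, overlap_frac = 0.15) {
  stopifnot(length(extent_mm_xy) == 2L, length(fov_mm_xy) == 2L)
  if (any(extent_mm_xy <= 0) || any(fov_mm_xy <= 0))
    stop("extents and FOV must be > 0")
  if (overlap_frac < 0 || overlap_frac >= 1)
    stop("overlap_frac must be in [0, 1)")
  n <- ifelse(extent_mm_xy <= fov_mm_xy, 1L,
              as.integer(ceiling((extent_mm_xy - fov_mm_xy) /
                                   (fov_mm_xy * (1 - overlap_frac)))) + 1L)
  # actual step spreads tiles evenly so the last tile ends at the extent edge
  step <- ifelse(n > 1L, (extent_mm_xy - fov_mm_xy) / (n - 1L), 0)
  ox <- if (n[1] > 1L) seq(0, extent_mm_xy[1] - fov_mm_xy[1], length.out = n[1]) else 0
  oy <- if (n[2] > 1L) seq(0, extent_mm_xy[2] - fov_mm_xy[2], length.out = n[2]) else 0
  origins <- expand.grid(x_mm = ox, y_mm = oy, KEEP.OUT.ATTRS = FALSE)
  structure(list(nx = n[1], ny = n[2], step_mm = step,
                 overlap_frac = overlap_frac, origins = origins,
                 fov_mm_xy = fov_mm_xy, extent_mm_xy = extent_mm_xy),
            class = "tile_plan")
}

#' @export
print.tile_plan <- function(x, ...) {
  cat(sprintf("tile_plan: %d x %d = %d tiles; FOV %.3g x %.3g mm; extent %.3g x %.3g mm; overlap >= %.0f%%\n",
              x$nx, x$ny, x$nx * x$ny, x$fov_mm_xy[1], x$fov_mm_xy[2],
              x$extent_mm_xy[1], x$extent_mm_xy[2], 100 * x$overlap_frac))
  invisible(x)
}

#' Full design report for a lens/sensor/expansion combination
#'
#' Evaluates the complete design calculus: etendue, specimen-plane geometry,
#' sampling and Nyquist resolution, per-bit-depth voxel rates, and (when an
#' expansion factor is given) effective resolutions and native volume.
#' Raw unrounded values are always retained; rounded report conventions are
#' applied only by the print method.
#'
#' @param lens A [lens_spec()].
#' @param sensor A [sensor_spec()].
#' @param expansion Optional [expansion_spec()] or numeric factor.
#' @param axial_resolution_um Optional optical axial resolution (um) to be
#'   converted into native units alongside the lateral one.
#' @param extent_mm Optional expanded-specimen extents (mm) for the native
#'   volume report.
#' @return A list of class `design_report`.
#' @export
design_report <- function(lens, sensor, expansion = NULL,
                          axial_resolution_um = NULL, extent_mm = NULL) {
  stopifnot(inherits(lens, "lens_spec"), inherits(sensor, "sensor_spec"))
  geom <- sensor_geometry(sensor, lens)
  samp <- object_sampling(sensor$pitch_um, lens$magnification)
  nyq <- nyquist_resolution(samp)
  rates <- if (length(sensor$line_time_us))
    vapply(sensor$line_time_us, function(lt) voxel_rate(sensor$pixels_h, lt), numeric(1))
  else numeric(0)
  rep <- list(etendue_mm2 = etendue(lens$fov_mm, lens$na),
              geometry = geom,
              sampling_um_per_px = samp,
              nyquist_um = nyq,
              voxel_rate_s = rates,
              lens = lens, sensor = sensor)
  if (!is.null(expansion)) {
    f <- as_expansion_factor(expansion)
    rep$expansion_factor <- f
    rep$effective_lateral_um <- effective_resolution(nyq, f)
    if (!is.null(axial_resolution_um))
      rep$effective_axial_um <- effective_resolution(axial_resolution_um, f)
    if (!is.null(extent_mm))
      rep$native_extent_mm <- native_volume(extent_mm, f)
  }
  class(rep) <- "design_report"
  rep
}

#' @export
print.design_report <- function(x, ...) {
  cat("Microscope design report\n")
  cat(sprintf("  etendue:          %.2f mm^2 (FOV %.3g mm, NA %.3g)\n",
              x$etendue_mm2, x$lens$fov_mm, x$lens$na))
  cat(sprintf("  camera FOV:       %.1f x %.1f mm (%.1f mm diagonal), %d MP\n",
              round_half_up(x$geometry$fov_w_mm, 1), round_half_up(x$geometry$fov_h_mm, 1),
              round_half_up(x$geometry$diag_mm, 1), round_half_up(x$geometry$megapixels, 0)))
  cat(sprintf("  sampling:         %.2f um/px; Nyquist resolution %.1f um\n",
              round_half_up(x$sampling_um_per_px, 2), round_half_up(x$nyquist_um, 1)))
  for (m in names(x$voxel_rate_s))
    cat(sprintf("  voxel rate (%s-bit): %d x 10^6 voxels/s\n", m,
                report_megavoxel_rate(x$voxel_rate_s[[m]])))
  if (!is.null(x$expansion_factor)) {
    cat(sprintf("  %gx expansion:     effective lateral resolution %.1f um\n",
                x$expansion_factor, round_half_up(x$effective_lateral_um, 1)))
    if (!is.null(x$native_extent_mm))
      cat(sprintf("  native volume:    %s mm\n",
                  paste(round_half_up(x$native_extent_mm, 0), collapse = " x ")))
  }
  invisible(x)
}

as_expansion_factor <- function(expansion) {
  f <- if (inherits(expansion, "expansion_spec")) expansion$factor else expansion
  if (!is.numeric(f) || length(f) != 1L || f < 1)
    stop("expansion factor must be a single number >= 1")
  f
}
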