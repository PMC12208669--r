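#' Read an image stack from TIFF
#'
#' Reads a 2-D or 3-D (multi-page, including BigTIFF) TIFF into a
#' [volume3d()]. A 2-D image becomes a single-plane volume. Integer
#' intensities are restored exactly for files written by [write_volume()].
#' Voxel size must be supplied explicitly when the file carries none —
#' there is no silent default.
#'
#' @param path TIFF file path.
#' @param voxel_size_um Voxel size in micrometres (scalar or named
#'   `c(x=, y=, z=)`). Required unless the file stores a resolution tag.
#' @param bit_depth Bit depth used to rescale sample values back to counts
#'   (default 16, matching [write_volume()]).
#' @return A [volume3d()].
#' @export
read_volume <- function(path, voxel_size_um = NULL, bit_depth = 16) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (is.null(voxel_size_um)) {
    info <- attributes(pages[[1]])
    if (!is.null(info$x.resolution) && info$x.resolution > 0 &&
        identical(info$resolution.unit, "cm")) {
      px_um <- 1e4 / info$x.resolution
      voxel_size_um <- c(x = px_um, y = px_um, z = px_um)
    } else {
      stop("voxel size not present in file metadata; pass voxel_size_um explicitly")
    }
  }
  maxv <- 2^bit_depth - 1
  arr <- array(0, dim = c(dim(pages[[1]])[1:2], length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- round(pages[[k]] * maxv)
  volume3d(arr, voxel_size_um, bit_depth = as.integer(bit_depth))
}

#' Write a volume to multi-page TIFF
#'
#' Counts are stored as `bit_depth`-bit samples; integer counts up to
#' `2^bit_depth - 1` round-trip exactly through [read_volume()]. Voxel size
#' is not stored in the file; supply it when reading back.
#'
#' @param vol A [volume3d()].
#' @param path Output path.
#' @param bit_depth Sample bit depth (16 recommended; sub-16-bit data are
#'   stored in a 16-bit container).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, bit_depth = 16) {
  stopifnot(inherits(vol, "volume3d"))
  maxv <- 2^bit_depth - 1
  a <- vol$data
  if (min(a) < 0 || max(a) > maxv) stop("intensities exceed the requested bit depth")
  pages <- lapply(seq_len(dim(a)[3]), function(k) a[, , k] / maxv)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                  reduce = FALSE, compression = "none")
  invisible(path)
}

#' Read lens/sensor/expansion specifications from a YAML config
#'
#' Expected top-level keys: `lens` (fov_mm, na, magnification, wd_mm,
#' medium_ri), `sensor` (pixels_h, pixels_v, pitch_um, line_time_us as a
#' bit-depth-keyed map), `expansion` (factor). Any subset may be present.
#'
#' @param path YAML file path.
#' @return List with any of `lens`, `sensor`, `expansion` spec objects.
#' @export
read_spec_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- list()
  if (!is.null(cfg$lens))
    out$lens <- do.call(lens_spec, cfg$lens)
  if (!is.null(cfg$sensor)) {
    s <- cfg$sensor
    lt <- if (is.null(s$line_time_us)) numeric(0) else unlist(s$line_time_us)
    out$sensor <- sensor_spec(s$pixels_h, s$pixels_v, s$pitch_um, lt)
  }
  if (!is.null(cfg$expansion))
    out$expansion <- expansion_spec(cfg$expansion$factor)
  out
}

#' Write a structured analysis report
#'
#' Serializes pipeline results as schema-versioned JSON with stable key
#' ordering and a provenance block (package version, seed, configuration
#' echo), so identical inputs produce byte-identical reports. Data frames
#' may additionally be written as flat CSV tables next to the JSON.
#'
#' @param results Named list of results (data frames, vectors, scalars).
#' @param path Output JSON path.
#' @param seed Seed used for the run (recorded in provenance).
#' @param config Optional configuration echo (named list).
#' @param csv_tables Logical; also write each data-frame element as
#'   `<path-stem>_<name>.csv`.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, seed = NULL, config = NULL,
                         csv_tables = FALSE) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("cannot write report: no such directory: ", dir)
  doc <- list(
    schema_version = "1.0",
    provenance = list(
      toolkit = "spimcal",
      version = as.character(utils::packageVersion("spimcal")),
      seed = seed,
      config = config),
    results = results)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null",
                       dataframe = "columns")
  if (csv_tables) {
    stem <- sub("\\.json$", "", path)
    for (nm in names(results)) {
      if (is.data.frame(results[[nm]]))
        utils::write.csv(results[[nm]], paste0(stem, "_", nm, ".csv"),
                         row.names = FALSE)
    }
  }
  invisible(path)
}
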