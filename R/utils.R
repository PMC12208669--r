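#' Unit conversions
#'
#' All internal physical lengths are micrometres; millimetres appear only at
#' the user-facing design-calculus surface. These two helpers centralize the
#' conversion.
#'
#' @param x Numeric vector.
#' @return Converted numeric vector.
#' @export
um_to_mm <- function(x) x / 1000

#' @rdname um_to_mm
#' @export
mm_to_um <- function(x) x * 1000

#' Round half away from zero
#'
#' Deterministic half-up rounding for reported values (base `round()` uses
#' round-half-to-even). Raw values are always retained alongside rounded
#' reports.
#'
#' @param x Numeric vector.
#' @param digits Decimal digits.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Integer megavoxel-rate report
#'
#' Voxel rates are reported truncated to the nearest 10^6 voxels/s.
#'
#' @param rate_s Voxel rate in voxels per second.
#' @return Integer number of megavoxels per second.
#' @export
report_megavoxel_rate <- function(rate_s) as.integer(floor(rate_s / 1e6))

# Run code with a temporary RNG seed, restoring global RNG state afterwards.
# Keeps generators deterministic without clobbering the caller's stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a deterministic 31-bit sub-seed from a base seed and an index.
sub_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(k)) %% 2147483647)
}

# Type-7 (linear interpolation) percentile of a numeric vector, the same
# definition as stats::quantile(type = 7). Implemented over a single sort so
# the contrast pipeline can call it hundreds of thousands of times.
percentile7 <- function(x, probs) {
  n <- length(x)
  if (n == 0L) stop("empty vector")
  s <- sort.int(x, method = "radix")
  h <- (n - 1) * probs + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}
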