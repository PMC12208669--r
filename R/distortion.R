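#' Segment calibration-target dots and compute sub-pixel centroids
#'
#' Global Otsu threshold on the (polarity-normalized) image, connected
#' component labelling, area filter, then intensity-weighted sub-pixel
#' centroids. Components touching the image border are excluded and counted
#' in the `rejected` attribute. Output is ordered by (y, x).
#'
#' @param image 2-D numeric matrix `[y, x]`.
#' @param polarity `"dark_on_bright"` (trans-illuminated target, default) or
#'   `"bright_on_dark"`.
#' @param min_area_px Minimum component area in pixels.
#' @return Data frame with `x_px`, `y_px` (0-based sub-pixel centroids) and
#'   `area_px`; attribute `rejected` counts border/area-filtered components.
#' @export
segment_dots <- function(image, polarity = c("dark_on_bright", "bright_on_dark"),
                         min_area_px = 9) {
  polarity <- match.arg(polarity)
  stopifnot(is.matrix(image))
  rng <- range(image)
  if (diff(rng) <= 0) stop("no dots found: image is uniform")
  fg <- (image - rng[1]) / diff(rng)
  if (polarity == "dark_on_bright") fg <- 1 - fg
  thr <- EBImage::otsu(EBImage::Image(fg))
  mask <- fg > thr
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask)))
  nlab <- max(lab)
  if (nlab == 0) stop("no dots found")

  ny <- nrow(image); nx <- ncol(image)
  idx <- which(lab > 0)
  l <- lab[idx]
  yy <- ((idx - 1) %% ny) + 1
  xx <- ((idx - 1) %/% ny) + 1
  area <- tabulate(l, nlab)
  on_border <- tapply(yy == 1 | yy == ny | xx == 1 | xx == nx, l, any)
  keep <- !on_border & area >= min_area_px
  rejected <- sum(!keep)
  if (!any(keep)) stop("no dots found (all components rejected)")

  # centroids weighted by (fg - threshold)+ over a padded bounding box: the
  # weight vanishes continuously on a circular level set of the dot profile,
  # so sub-pixel truncation does not bias the centroid
  cx <- cy <- rep(NA_real_, nlab)
  for (lb in which(keep)) {
    sel <- l == lb
    r0 <- max(1L, min(yy[sel]) - 2L); r1 <- min(ny, max(yy[sel]) + 2L)
    c0 <- max(1L, min(xx[sel]) - 2L); c1 <- min(nx, max(xx[sel]) + 2L)
    w <- pmax(fg[r0:r1, c0:c1] - thr, 0)
    w[lab[r0:r1, c0:c1] != lb & lab[r0:r1, c0:c1] != 0] <- 0  # mask other dots
    sw <- sum(w)
    cy[lb] <- sum(w * (row(w) + r0 - 2)) / sw
    cx[lb] <- sum(w * (col(w) + c0 - 2)) / sw
  }
  out <- data.frame(x_px = cx[keep], y_px = cy[keep], area_px = area[keep])
  out <- out[order(out$y_px, out$x_px), ]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  attr(out, "threshold") <- thr
  out
}

#' Match detected dot centroids to an ideal lattice
#'
#' The distortion centre is taken as the detected centroid nearest the
#' image centre; the ideal lattice is anchored on that dot and built along
#' grid axes estimated from its immediate neighbours at the nominal
#' spacing. Every centroid is assigned to its nearest lattice node;
#' assignments must be injective — when two centroids claim the same node,
#' both are flagged ambiguous and excluded from profiles.
#'
#' @param centroids Data frame from [segment_dots()] (needs >= 9 rows).
#' @param nominal_spacing_px Nominal lattice spacing in pixels.
#' @param image_dim_yx Optional image dimensions `(ny, nx)` used to locate
#'   the image centre; default uses the centroid bounding-box centre.
#' @return Data frame ordered by lattice index (j, i): measured and
#'   theoretical positions, radial distances `r_meas`/`r_theo` from the
#'   distortion centre, `percent_distortion` = `100 (r_meas - r_theo) /
#'   r_theo` (`NA` for the centre dot), and `ambiguous`. Attributes:
#'   `distortion_center`, `axes` (2 x 2 matrix of lattice basis vectors).
#' @export
match_lattice <- function(centroids, nominal_spacing_px, image_dim_yx = NULL) {
  if (nrow(centroids) < 9L) stop("need >= 9 centroids to estimate a lattice")
  p <- cbind(centroids$x_px, centroids$y_px)
  ctr <- if (!is.null(image_dim_yx))
    c((image_dim_yx[2] - 1) / 2, (image_dim_yx[1] - 1) / 2)
  else colMeans(apply(p, 2, range))
  i0 <- which.min((p[, 1] - ctr[1])^2 + (p[, 2] - ctr[2])^2)
  c0 <- p[i0, ]

  # local grid axes from the centre dot's nearest neighbours
  dvec <- sweep(p, 2, c0)
  dd <- sqrt(rowSums(dvec^2))
  near <- which(dd > 0.5 * nominal_spacing_px & dd < 1.5 * nominal_spacing_px)
  if (length(near) < 2L) stop("cannot estimate lattice axes near the centre dot")
  ax_score <- dvec[near, 1] / dd[near]
  ay_score <- dvec[near, 2] / dd[near]
  ux <- dvec[near[which.max(ax_score)], ]
  uy <- dvec[near[which.max(ay_score)], ]
  A <- cbind(ux, uy)
  if (abs(det(A)) < 0.1 * nominal_spacing_px^2)
    stop("degenerate lattice axes")

  ij <- t(round(solve(A, t(dvec))))
  theo <- sweep(ij %*% t(A), 2, c0, "+")
  dup <- duplicated(ij) | duplicated(ij, fromLast = TRUE)

  r_meas <- sqrt(rowSums(sweep(p, 2, c0)^2))
  r_theo <- sqrt(rowSums(sweep(theo, 2, c0)^2))
  out <- data.frame(x_meas = p[, 1], y_meas = p[, 2],
                    i = ij[, 1], j = ij[, 2],
                    x_theo = theo[, 1], y_theo = theo[, 2],
                    r_meas = r_meas, r_theo = r_theo,
                    percent_distortion = ifelse(r_theo > 0,
                                                100 * (r_meas - r_theo) / r_theo,
                                                NA_real_),
                    ambiguous = dup)
  out <- out[order(out$j, out$i), ]
  rownames(out) <- NULL
  attr(out, "distortion_center") <- c0
  attr(out, "axes") <- A
  out
}

#' Radially averaged percent-distortion profile
#'
#' Per-dot percent distortion (radial distance from the distortion centre,
#' measured vs theoretical, as a percentage of theoretical) averaged in
#' radial bins. Positive values indicate pincushion (outward) distortion,
#' negative barrel.
#'
#' @param assignments Data frame from [match_lattice()].
#' @param bin_width_px Radial bin width in pixels.
#' @return Data frame with `radius_px` (bin-mean theoretical radius),
#'   `percent_distortion` (mean), `sd`, `n`; only bins with `n >= 1`.
#' @export
radial_distortion_profile <- function(assignments, bin_width_px) {
  use <- assignments[!assignments$ambiguous & assignments$r_theo > 0, , drop = FALSE]
  if (!nrow(use)) stop("no off-centre dots to profile")
  bin <- floor(use$r_theo / bin_width_px)
  agg <- split(seq_len(nrow(use)), bin)
  data.frame(
    radius_px = vapply(agg, function(k) mean(use$r_theo[k]), numeric(1)),
    percent_distortion = vapply(agg, function(k) mean(use$percent_distortion[k]), numeric(1)),
    sd = vapply(agg, function(k) {
      v <- use$percent_distortion[k]; if (length(v) > 1) sd(v) else 0
    }, numeric(1)),
    n = vapply(agg, length, numeric(1)),
    row.names = NULL)
}

#' Fit a quadratic radial distortion coefficient
#'
#' Least-squares fit of the small-distortion model
#' `(r_meas - r_theo)/r_theo = c + k1 * r_theo^2` to per-dot measurements,
#' returning `k1` in px^-2. The intercept absorbs any residual global scale
#' (magnification) error of the estimated lattice, which would otherwise
#' bias `k1`; a pure scale error is not distortion.
#'
#' @param assignments Data frame from [match_lattice()].
#' @return Estimated `k1` (numeric scalar).
#' @export
fit_radial_distortion <- function(assignments) {
  use <- assignments[!assignments$ambiguous & assignments$r_theo > 0, , drop = FALSE]
  if (!nrow(use)) stop("no off-centre dots to fit")
  y <- use$percent_distortion / 100
  x <- use$r_theo^2
  unname(coef(lm(y ~ x))["x"])
}

#' Measure lens distortion from a dot-grid image
#'
#' Convenience pipeline: [segment_dots()], [match_lattice()],
#' [radial_distortion_profile()] and [fit_radial_distortion()].
#'
#' @inheritParams segment_dots
#' @inheritParams match_lattice
#' @param bin_width_px Radial bin width; default half the nominal spacing.
#' @return List of class `distortion_profile` with `dots`, `assignments`,
#'   `profile`, `k1`, `distortion_center`.
#' @export
measure_distortion <- function(image, nominal_spacing_px,
                               polarity = "dark_on_bright",
                               min_area_px = 9, bin_width_px = NULL) {
  dots <- segment_dots(image, polarity, min_area_px)
  asg <- match_lattice(dots, nominal_spacing_px, image_dim_yx = dim(image))
  if (is.null(bin_width_px)) bin_width_px <- nominal_spacing_px / 2
  prof <- radial_distortion_profile(asg, bin_width_px)
  structure(list(dots = dots, assignments = asg, profile = prof,
                 k1 = fit_radial_distortion(asg),
                 distortion_center = attr(asg, "distortion_center")),
            class = "distortion_profile")
}

#' @export
print.distortion_profile <- function(x, ...) {
  cat(sprintf("distortion_profile: %d dots, k1 = %.3g px^-2, max |distortion| %.3g%%\n",
              nrow(x$assignments), x$k1,
              max(abs(x$profile$percent_distortion))))
  invisible(x)
}
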