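# Shared fixtures: the reference instrument's lens/sensor parameters, used
# across tests as a realistic configuration.
ref_sensor <- function() sensor_spec(14192, 10640, 3.76,
                                     c("12" = 15.00, "14" = 20.15, "16" = 45.44))
ref_lens <- function() lens_spec(fov_mm = 16.8, na = 0.305, magnification = 5.0,
                                 wd_mm = 35, medium_ri = 1.33)

# 1-D interval-union coverage oracle for tile plans: checks by exhaustive
# interval arithmetic that tiles of width `fov` at `origins` cover
# [0, extent] and that adjacent tiles overlap by at least `overlap * fov`.
check_tiling_1d <- function(origins, fov, extent, overlap) {
  o <- sort(origins)
  eps <- 1e-9
  if (o[1] > eps) return(FALSE)
  if (tail(o, 1) + fov < extent - eps) return(FALSE)
  if (length(o) > 1) {
    gaps <- o[-1] - (head(o, -1) + fov)
    if (any(gaps > -overlap * fov + eps)) return(FALSE)  # need overlap, not gaps
  }
  TRUE
}

# Independent pixel-integrated-Gaussian fit of a 1-D profile (test-side
# oracle, kept separate from the package's fitting code).
oracle_fit_igauss <- function(v) {
  t <- seq_along(v)
  mu0 <- sum(t * v) / sum(v)
  fit <- minpack.lm::nlsLM(
    v ~ A * (pnorm((t + 0.5 - mu) / s) - pnorm((t - 0.5 - mu) / s)),
    start = list(A = max(v), mu = mu0, s = 1.5))
  coef(fit)
}
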