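# Shared fixtures, all generated in code.

# A smooth synthetic curve whose sector extrema sit (to ~1e-4) at
# prescribed values: narrow Gaussian bumps at the four sector centres on a
# base level solved so that the discrete mean is exactly 1.
designed_curve <- function(Fv, Ov, Rv, Lv, n = 720L, sigma = 0.4) {
  theta <- 2 * pi * (seq_len(n) - 1) / n
  ad <- function(a, b) {
    d <- abs((a - b + pi) %% (2 * pi) - pi)
    d
  }
  g <- function(centre) exp(-ad(theta, centre)^2 / (2 * sigma^2))
  cbar <- mean(g(0))           # same bump mass at every centre
  m <- (1 - (Fv + Ov + Rv + Lv) * cbar) / (1 - 4 * cbar)
  y <- m + (Ov - m) * g(0) + (Fv - m) * g(pi) +
    (Rv - m) * g(pi / 2) + (Lv - m) * g(3 * pi / 2)
  curve <- radial_curve(theta, y / mean(y), anterior_angle = pi,
                        normalized = TRUE)
  align_curve(curve)
}

# Aligned normalized curve of a phantom spec, warnings silenced.
phantom_curve <- function(spec, n_samples = 360L) {
  suppressWarnings(align_curve(normalize_curve(
    radial_profile(make_outline(spec), n_samples = n_samples))))
}

quiet_features <- function(curve) suppressWarnings(extract_features(curve))

ang_dist_test <- function(a, b) abs((a - b + pi) %% (2 * pi) - pi)

# Circle phantom whose vertices coincide with the 1-degree ray grid, so the
# sampled profile is exactly constant.
circle_spec <- function(diameter = 120, n_vertices = 720L) {
  phantom_spec(diameter, diameter, n_vertices = n_vertices)
}
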