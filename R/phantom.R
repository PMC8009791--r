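#' Parametric phantom skull specification
#'
#' Describes a synthetic cranial cross-section: an ellipse (anteroposterior
#' length by biparietal width) decorated with Gaussian bumps that mimic the
#' compensatory deformities of scaphocephaly — frontal bossing (anterior
#' midline bump), occipital bulging (posterior bump) and temporal narrowing
#' (symmetric lateral pinch). All downstream modules are testable against
#' these phantoms because every feature location and amplitude is known
#' analytically.
#'
#' The generated radius is
#' \deqn{r(\theta) = r_{ell}(\theta) + \bar{r}_{ell}\,\big[
#'   A_f g(\theta;\pi) + A_o g(\theta;0)
#'   - A_t\,(g(\theta;\pi/2) + g(\theta;-\pi/2))\big]}
#' where \eqn{g(\theta;c) = \exp(-\Delta(\theta,c)^2 / 2\sigma^2)} is a
#' periodic Gaussian bump of width `bump_sd_rad`, \eqn{\bar{r}_{ell}} is the
#' mean ellipse radius over the vertex grid, and the amplitudes are the
#' deformity dials expressed as fractions of that mean radius. The anterior
#' direction is at angle \eqn{\pi}, the posterior at angle 0 of the phantom's
#' own frame.
#'
#' @param base_length_mm Anteroposterior diameter of the base ellipse (mm).
#' @param base_width_mm Biparietal diameter of the base ellipse (mm).
#' @param frontal_bossing,occipital_bulge,temporal_narrowing Non-negative
#'   deformity amplitudes, fractions of the mean ellipse radius.
#' @param noise_sd Standard deviation of i.i.d. Gaussian radial noise per
#'   vertex (mm).
#' @param seed Integer seed; outlines are bit-identical for a given spec.
#' @param n_vertices Number of outline vertices (>= 32).
#' @param bump_sd_rad Angular width (sd) of the Gaussian bumps, radians.
#' @return An object of class `phantom_spec`.
#' @examples
#' spec <- phantom_spec(base_length_mm = 160, base_width_mm = 100,
#'                      occipital_bulge = 0.2)
#' outline <- make_outline(spec)
#' @export
phantom_spec <- function(base_length_mm = 160, base_width_mm = 100,
                         frontal_bossing = 0, occipital_bulge = 0,
                         temporal_narrowing = 0, noise_sd = 0,
                         seed = 1L, n_vertices = 256L, bump_sd_rad = 0.5) {
  stopifnot(base_length_mm > 0, base_width_mm > 0,
            frontal_bossing >= 0, occipital_bulge >= 0,
            temporal_narrowing >= 0, noise_sd >= 0,
            bump_sd_rad > 0)
  n_vertices <- as.integer(n_vertices)
  if (n_vertices < 32L) {
    stop("n_vertices must be at least 32, got ", n_vertices)
  }
  structure(list(base_length_mm = base_length_mm,
                 base_width_mm = base_width_mm,
                 frontal_bossing = frontal_bossing,
                 occipital_bulge = occipital_bulge,
                 temporal_narrowing = temporal_narrowing,
                 noise_sd = noise_sd,
                 seed = as.integer(seed),
                 n_vertices = n_vertices,
                 bump_sd_rad = bump_sd_rad),
            class = "phantom_spec")
}

# Deterministic (noise-free) phantom radius at arbitrary angles.
phantom_radius <- function(spec, theta) {
  a <- spec$base_length_mm / 2
  b <- spec$base_width_mm / 2
  r_ell <- a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
  # Mean ellipse radius over the spec's own vertex grid, so that noise-free
  # vertex radii and this function agree exactly.
  tg <- phantom_theta(spec)
  r_mean <- mean(a * b / sqrt((b * cos(tg))^2 + (a * sin(tg))^2))
  s2 <- 2 * spec$bump_sd_rad^2
  g <- function(centre) exp(-ang_dist(theta, centre)^2 / s2)
  bump <- spec$frontal_bossing * g(pi) +
    spec$occipital_bulge * g(0) -
    spec$temporal_narrowing * (g(pi / 2) + g(-pi / 2))
  r_ell + r_mean * bump
}

phantom_theta <- function(spec) {
  2 * pi * (seq_len(spec$n_vertices) - 1L) / spec$n_vertices
}

#' Generate a synthetic cranial outline
#'
#' Evaluates the phantom radius model on a uniform angular grid and returns
#' the closed polygon, counter-clockwise, in mm. With all deformity dials and
#' noise at zero the outline is an exact ellipse (a circle for equal axes).
#'
#' @param spec A [phantom_spec()].
#' @return An [outline2d()] with the anterior direction at angle \eqn{\pi}.
#' @export
make_outline <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  theta <- phantom_theta(spec)
  r <- phantom_radius(spec, theta)
  if (spec$noise_sd > 0) {
    r <- withr_seed(spec$seed, r + rnorm(length(r), 0, spec$noise_sd))
  }
  if (any(r <= 0)) {
    stop("deformity amplitudes/noise produce non-positive radius at angle(s) ",
         paste(signif(theta[r <= 0], 3), collapse = ", "),
         "; reduce temporal_narrowing or noise_sd")
  }
  outline2d(cbind(x_mm = r * cos(theta), y_mm = r * sin(theta)),
            anterior_angle = pi)
}

# Evaluate expr under a local RNG state seeded with `seed`.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

#' Generate a synthetic head volume mask
#'
#' Stacks scaled copies of the phantom outline into an ellipsoid-like binary
#' voxel grid: the slice at signed height \eqn{z} (vertical semi-axis
#' \eqn{c} = `n_slices * slice_spacing_mm / 2`) is the base outline scaled by
#' \eqn{\sqrt{1 - z^2/c^2}}. A voxel is foreground when its centre lies
#' inside the scaled outline (radial comparison against the periodic linear
#' interpolation of the vertex radii). The exact analytic volume of the
#' continuous solid, \eqn{A_{base} \cdot 4c/3} with \eqn{A_{base}} the polar
#' area of the base region, is attached as ground truth.
#'
#' @param spec A [phantom_spec()].
#' @param n_slices Number of axial slices (>= 3).
#' @param slice_spacing_mm Slice spacing (dz), mm; must be positive.
#' @param xy_spacing_mm In-plane voxel spacing, mm; defaults to
#'   `slice_spacing_mm` (isotropic voxels).
#' @return A `volume_mask`: list with `voxels` (3D 0/1 array, x-y-z),
#'   `spacing_mm`, `origin_mm` (world coordinates of voxel \[1,1,1\] centre),
#'   `start_slice`, `end_slice`, `analytic_volume_mm3` and the `spec`.
#' @examples
#' sphere <- make_volume(phantom_spec(100, 100, n_vertices = 256),
#'                       n_slices = 100, slice_spacing_mm = 1)
#' sphere$analytic_volume_mm3  # 4/3 * pi * 50^3
#' @export
make_volume <- function(spec, n_slices, slice_spacing_mm,
                        xy_spacing_mm = slice_spacing_mm) {
  stopifnot(inherits(spec, "phantom_spec"))
  n_slices <- as.integer(n_slices)
  if (n_slices < 3L) stop("n_slices must be at least 3, got ", n_slices)
  if (slice_spacing_mm <= 0 || xy_spacing_mm <= 0) {
    stop("voxel spacing must be positive")
  }
  outline <- make_outline(spec)
  v <- outline$vertices
  theta_v <- atan2(v[, 2], v[, 1]) %% (2 * pi)
  r_v <- sqrt(rowSums(v^2))
  ord <- order(theta_v)
  theta_v <- theta_v[ord]
  r_v <- r_v[ord]

  cz <- n_slices * slice_spacing_mm / 2
  z_centres <- (seq_len(n_slices) - 0.5) * slice_spacing_mm - cz

  r_max <- max(r_v)
  half <- r_max + 2 * xy_spacing_mm
  nxy <- 2L * as.integer(ceiling(half / xy_spacing_mm)) + 1L
  coord <- (seq_len(nxy) - (nxy + 1) / 2) * xy_spacing_mm
  rho <- sqrt(outer(coord^2, coord^2, `+`))
  th <- atan2(matrix(coord, nxy, nxy, byrow = TRUE),
              matrix(coord, nxy, nxy)) %% (2 * pi)
  # periodic linear interpolation of the outline radius
  r_at <- approx(c(theta_v, theta_v[1] + 2 * pi), c(r_v, r_v[1]),
                 xout = as.vector(th), rule = 2)$y
  r_at <- matrix(r_at, nxy, nxy)

  vox <- array(0L, dim = c(nxy, nxy, n_slices))
  scale_k <- sqrt(pmax(0, 1 - (z_centres / cz)^2))
  for (k in seq_len(n_slices)) {
    vox[, , k] <- 1L * (rho <= scale_k[k] * r_at)
  }

  # polar area of the radially-interpolated base region:
  # per segment integral of r(theta)^2/2 dtheta with r linear in theta
  r2 <- c(r_v, r_v[1])
  dth <- diff(c(theta_v, theta_v[1] + 2 * pi))
  a_base <- sum((r2[-length(r2)]^2 + r2[-length(r2)] * r2[-1] +
                   r2[-1]^2) / 3 * dth / 2)
  structure(list(voxels = vox,
                 spacing_mm = c(xy_spacing_mm, xy_spacing_mm,
                                slice_spacing_mm),
                 origin_mm = c(coord[1], coord[1], z_centres[1]),
                 start_slice = 1L, end_slice = n_slices,
                 analytic_volume_mm3 = a_base * 4 * cz / 3,
                 spec = spec),
            class = "volume_mask")
}

#' Construct a volume mask from a voxel array
#'
#' @param voxels 3D array, nonzero = foreground (x, y, z order).
#' @param spacing_mm Length-3 positive voxel spacing (dx, dy, dz) in mm.
#' @param origin_mm World coordinates of the centre of voxel \[1,1,1\].
#' @param start_slice,end_slice Analysis range along z (defaults: full grid).
#' @return A `volume_mask`.
#' @export
volume_mask <- function(voxels, spacing_mm, origin_mm = c(0, 0, 0),
                        start_slice = 1L, end_slice = dim(voxels)[3]) {
  stopifnot(length(dim(voxels)) == 3, length(spacing_mm) == 3)
  if (any(spacing_mm <= 0)) stop("voxel spacing must be positive")
  structure(list(voxels = 1L * (voxels != 0), spacing_mm = spacing_mm,
                 origin_mm = origin_mm,
                 start_slice = as.integer(start_slice),
                 end_slice = as.integer(end_slice),
                 analytic_volume_mm3 = NA_real_, spec = NULL),
            class = "volume_mask")
}

#' Generate a synthetic rater score table
#'
#' Simulates the visual-scoring setting: each subject has a latent true score
#' in \{0, 1, 2\} for each of the six clinical items (width, length, vertex
#' height, frontal bossing, occipital bulging, temporal narrowing); each
#' rater reports the true score with probability `agreement` and otherwise an
#' independent uniform draw from \{0, 1, 2\}. `agreement = 1` yields
#' identical raters (ICC 1); `agreement = 0` yields scores independent of the
#' subject (ICC near 0 for large cohorts).
#'
#' @param n_subjects Number of subjects.
#' @param n_raters Number of raters (>= 2).
#' @param agreement Probability in \[0, 1\] that a rater reports the latent
#'   true score.
#' @param seed Integer seed.
#' @return A `rater_table`: 3D integer array subjects x raters x 6 items
#'   with dimnames.
#' @export
make_rater_table <- function(n_subjects, n_raters, agreement, seed = 1L) {
  if (n_raters < 2L) stop("n_raters must be at least 2, got ", n_raters)
  stopifnot(n_subjects >= 1, agreement >= 0, agreement <= 1)
  items <- c("width", "length", "vertex height", "frontal bossing",
             "occipital bulging", "temporal narrowing")
  tab <- withr_seed(seed, {
    true <- matrix(sample(0:2, n_subjects * 6, replace = TRUE),
                   n_subjects, 6)
    arr <- array(NA_integer_, dim = c(n_subjects, n_raters, 6))
    for (r in seq_len(n_raters)) {
      keep <- matrix(runif(n_subjects * 6) < agreement, n_subjects, 6)
      noise <- matrix(sample(0:2, n_subjects * 6, replace = TRUE),
                      n_subjects, 6)
      arr[, r, ] <- ifelse(keep, true, noise)
    }
    arr
  })
  dimnames(tab) <- list(subject = paste0("S", seq_len(n_subjects)),
                        rater = paste0("R", seq_len(n_raters)),
                        item = items)
  structure(tab, class = c("rater_table", "array"))
}

#' Generate a synthetic normative intracranial-volume table
#'
#' A clearly synthetic stand-in for age- and sex-specific normative ICV
#' reference data (the real normative values are not shipped): a saturating
#' growth curve from roughly 400 mL at birth towards an asymptote near
#' 1100 mL by age three, females offset 7% below males, with SD at 7% of the
#' mean. Useful for exercising [normative_band()]; not for clinical use.
#'
#' @param ages_months Strictly increasing vector of ages (months).
#' @return A data.frame with columns `sex`, `age_months`, `mean_ml`, `sd_ml`.
#' @export
make_normative_table <- function(ages_months = seq(0, 36, by = 3)) {
  stopifnot(all(diff(ages_months) > 0))
  mean_m <- 380 + 720 * (1 - exp(-ages_months / 7.5))
  rbind(data.frame(sex = "male", age_months = ages_months,
                   mean_ml = mean_m, sd_ml = 0.07 * mean_m),
        data.frame(sex = "female", age_months = ages_months,
                   mean_ml = 0.93 * mean_m, sd_ml = 0.07 * 0.93 * mean_m))
}

#' Generate a deterministic cohort of phantom specs with graded severity
#'
#' Convenience sweep used in tests and examples: severity (temporal
#' narrowing, frontal bossing, occipital bulging, elongation) increases
#' smoothly across the cohort, giving untied widths and peak sums.
#'
#' @param n Cohort size.
#' @param seed Base seed; subject i uses `seed + i`.
#' @param severity Range of the deformity dials swept across the cohort.
#' @return A list of `n` [phantom_spec()] objects.
#' @export
phantom_cohort <- function(n, seed = 1L, severity = c(0, 0.25)) {
  g <- seq(severity[1], severity[2], length.out = n)
  lapply(seq_len(n), function(i) {
    phantom_spec(base_length_mm = 150 + 60 * g[i],
                 base_width_mm = 110 - 40 * g[i],
                 frontal_bossing = 0.3 * g[i],
                 occipital_bulge = 0.4 * g[i],
                 temporal_narrowing = 0.3 * g[i],
                 seed = seed + i)
  })
}
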