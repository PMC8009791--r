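#' Radial curve container
#'
#' The pipeline's central object: radius (mm, or dimensionless once
#' normalized) as a function of angular position on a uniform grid over
#' \[0, 2pi). Angles are measured in the outline's frame until
#' [align_curve()] rotates the phase origin to the occipital maximum.
#'
#' @param theta Uniform angular grid on \[0, 2pi), radians.
#' @param y Radii (mm) or normalized radii; positive.
#' @param anterior_angle Direction of anterior in the current phase frame.
#' @param normalized Logical: has [normalize_curve()] been applied?
#' @param aligned Logical: has [align_curve()] been applied?
#' @param scale_mm Normalization constant (mean radius, mm), once normalized.
#' @param alignment Circular shift applied by alignment, radians.
#' @param ray_warnings Number of rays with multiple outline crossings.
#' @return An object of class `radial_curve`.
#' @export
radial_curve <- function(theta, y, anterior_angle = 0, normalized = FALSE,
                         aligned = FALSE, scale_mm = NA_real_,
                         alignment = 0, ray_warnings = 0L) {
  stopifnot(length(theta) == length(y), all(is.finite(y)), all(y > 0))
  structure(list(theta = theta, y = y, n_samples = length(y),
                 anterior_angle = anterior_angle %% (2 * pi),
                 normalized = normalized, aligned = aligned,
                 scale_mm = scale_mm, alignment = alignment,
                 ray_warnings = as.integer(ray_warnings)),
            class = "radial_curve")
}

#' Radial distance profile of an outline about a centre
#'
#' For `n_samples` uniformly spaced angles, the distance from the centre to
#' the outline along that ray. The centre must lie strictly inside the
#' polygon; if a ray crosses the outline more than once (outline not
#' star-shaped about the centre) the outermost crossing is used and a
#' warning count is recorded on the curve.
#'
#' @param outline An [outline2d()].
#' @param center Length-2 centre point, mm; defaults to the area centroid.
#' @param n_samples Number of angular samples (default 360, i.e. 1 degree).
#' @return An unnormalized `radial_curve` in mm.
#' @export
radial_profile <- function(outline, center = outline_centroid(outline),
                           n_samples = 360L) {
  stopifnot(inherits(outline, "outline2d"), n_samples >= 8)
  v <- outline$vertices
  if (!point_in_polygon(center, v)) {
    stop("center (", paste(signif(center, 4), collapse = ", "),
         ") is not strictly inside the outline")
  }
  theta <- 2 * pi * (seq_len(n_samples) - 1L) / n_samples
  p1x <- v[, 1] - center[1]; p1y <- v[, 2] - center[2]
  ex <- c(p1x[-1], p1x[1]) - p1x
  ey <- c(p1y[-1], p1y[1]) - p1y
  dist <- numeric(n_samples)
  n_multi <- 0L
  for (i in seq_len(n_samples)) {
    dx <- cos(theta[i]); dy <- sin(theta[i])
    denom <- dx * ey - dy * ex
    t <- (p1x * dy - p1y * dx) / denom
    s <- (p1x * ey - p1y * ex) / denom
    # half-open edge interval with a small tolerance so a ray passing
    # exactly through a vertex is caught by one of its two edges
    hit <- is.finite(s) & is.finite(t) & t >= -1e-9 & t < 1 - 1e-9 & s > 0
    ns <- sum(hit)
    if (ns == 0) stop("ray at theta=", signif(theta[i], 4),
                      " does not cross the outline")
    if (ns > 1) n_multi <- n_multi + 1L
    dist[i] <- max(s[hit])
  }
  radial_curve(theta, dist, anterior_angle = outline$anterior_angle,
               ray_warnings = n_multi)
}

#' Normalize a radial curve to dimensionless units
#'
#' Divides by the circular mean radius so that the curve's mean is exactly 1
#' and the result is scale-invariant: control skulls then read about 0.85 at
#' the sides and 1.1-1.15 at occiput and forehead. The mean radius in mm is
#' retained as `scale_mm`.
#'
#' @param curve A `radial_curve` with positive radii.
#' @return A normalized `radial_curve`.
#' @export
normalize_curve <- function(curve) {
  stopifnot(inherits(curve, "radial_curve"))
  m <- mean(curve$y)
  out <- curve
  out$y <- curve$y / m
  out$normalized <- TRUE
  out$scale_mm <- if (curve$normalized) curve$scale_mm else m
  out
}

#' Align a radial curve to start at the occipital maximum
#'
#' Circularly shifts the curve so that theta = 0 sits at the maximum of the
#' posterior sector (angles within 90 degrees of the posterior direction,
#' known from the outline frame). After alignment a scaphocephalic curve
#' runs descent (from occiput), ascent (to forehead at theta = pi), descent,
#' ascent — with the patient's left side at theta = 3pi/2 and right side at
#' theta = pi/2. A flat curve (no distinguishable posterior maximum) is
#' aligned by the anatomical frame alone, with a warning.
#'
#' @param curve A normalized `radial_curve`.
#' @return An aligned `radial_curve`; `alignment` records the shift.
#' @export
align_curve <- function(curve) {
  stopifnot(inherits(curve, "radial_curve"))
  if (!curve$normalized) stop("align_curve() expects a normalized curve")
  posterior <- (curve$anterior_angle + pi) %% (2 * pi)
  sector <- ang_dist(curve$theta, posterior) <= pi / 2
  ys <- curve$y[sector]
  if (diff(range(curve$y)) < 1e-9) {
    warning("flat curve: aligned by anatomical frame alone")
    shift_angle <- posterior
  } else {
    shift_angle <- curve$theta[sector][which.max(ys)]
  }
  idx <- which.min(ang_dist(curve$theta, shift_angle))
  n <- curve$n_samples
  ord <- ((seq_len(n) - 1 + idx - 1) %% n) + 1
  out <- curve
  out$y <- curve$y[ord]
  out$alignment <- curve$theta[idx]
  out$anterior_angle <- (curve$anterior_angle - curve$theta[idx]) %% (2 * pi)
  out$aligned <- TRUE
  out
}

#' Periodic moving-average smoothing of a radial curve
#'
#' Optional preprocessing for noisy real outlines (phantom curves are smooth
#' and do not need it); off by default throughout the pipeline and recorded
#' in provenance when used.
#'
#' @param curve A `radial_curve`.
#' @param window Odd window length in samples (default 5).
#' @export
smooth_curve <- function(curve, window = 5L) {
  stopifnot(inherits(curve, "radial_curve"), window %% 2 == 1, window >= 3)
  n <- curve$n_samples
  half <- (window - 1L) %/% 2L
  ypad <- c(tail(curve$y, half), curve$y, head(curve$y, half))
  out <- curve
  out$y <- as.numeric(stats::filter(ypad, rep(1 / window, window),
                                    sides = 2))[half + seq_len(n)]
  out
}
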