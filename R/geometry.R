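#' Closed 2D cranial outline
#'
#' A simple closed polygon in mm, stored counter-clockwise, with a record of
#' where the anatomical anterior direction points in the outline's own frame
#' (an angle in radians; the patient's left is 90 degrees counter-clockwise
#' from anterior, as seen from above). Phantom outlines use
#' `anterior_angle = pi`; outlines sliced from a head volume use the
#' landmark-derived frame with anterior along +x (`anterior_angle = 0`).
#'
#' @param vertices Two-column numeric matrix (x_mm, y_mm), >= 32 rows, not
#'   repeating the first vertex.
#' @param anterior_angle Direction of the anterior axis, radians.
#' @return An object of class `outline2d`.
#' @export
outline2d <- function(vertices, anterior_angle = 0) {
  vertices <- as.matrix(vertices)
  stopifnot(ncol(vertices) == 2, is.numeric(vertices))
  if (nrow(vertices) > 1 &&
      isTRUE(all.equal(vertices[1, ], vertices[nrow(vertices), ],
                       check.attributes = FALSE))) {
    vertices <- vertices[-nrow(vertices), , drop = FALSE]
  }
  if (nrow(vertices) < 32) {
    stop("outline must have at least 32 vertices, got ", nrow(vertices))
  }
  if (signed_area(vertices) < 0) {            # enforce CCW orientation
    vertices <- vertices[nrow(vertices):1, , drop = FALSE]
  }
  colnames(vertices) <- c("x_mm", "y_mm")
  structure(list(vertices = vertices, closed = TRUE,
                 anterior_angle = anterior_angle %% (2 * pi)),
            class = "outline2d")
}

# Shoelace signed area (CCW positive).
signed_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Polygon area of an outline (mm^2)
#' @param outline An [outline2d()].
#' @export
outline_area <- function(outline) abs(signed_area(outline$vertices))

#' Area centroid of a closed outline
#'
#' Centroid of the enclosed region via the shoelace moment formula — not the
#' vertex mean, which is biased wherever vertex density is non-uniform.
#'
#' @param outline An [outline2d()] or a two-column vertex matrix.
#' @return Named numeric vector `c(x_mm, y_mm)`.
#' @export
outline_centroid <- function(outline) {
  v <- if (inherits(outline, "outline2d")) outline$vertices else
    as.matrix(outline)
  a <- signed_area(v)
  if (abs(a) < 1e-12) stop("zero-area polygon: centroid undefined")
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  c(x_mm = sum((x + xn) * cr) / (6 * a),
    y_mm = sum((y + yn) * cr) / (6 * a))
}

#' Rotate an outline in-plane
#'
#' Rigid rotation about the origin; the recorded anterior direction rotates
#' with the vertices, so downstream alignment is unaffected.
#'
#' @param outline An [outline2d()].
#' @param angle_rad Rotation angle, radians (counter-clockwise).
#' @export
rotate_outline <- function(outline, angle_rad) {
  rot <- matrix(c(cos(angle_rad), sin(angle_rad),
                  -sin(angle_rad), cos(angle_rad)), 2, 2)
  outline2d(outline$vertices %*% t(rot),
            anterior_angle = outline$anterior_angle + angle_rad)
}

# Even-odd ray-crossing point-in-polygon test for one point.
point_in_polygon <- function(pt, v) {
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cross_edge <- ((y > pt[2]) != (yn > pt[2]))
  xi <- x + (pt[2] - y) / (yn - y) * (xn - x)
  sum(cross_edge & xi > pt[1], na.rm = TRUE) %% 2 == 1
}

#' Landmark set for the cranial reference plane
#'
#' @param left_porion,left_exocanthion,right_exocanthion Length-3 numeric
#'   vectors, mm. The three points must be non-collinear.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(left_porion, left_exocanthion, right_exocanthion) {
  lm <- list(left_porion = as.numeric(left_porion),
             left_exocanthion = as.numeric(left_exocanthion),
             right_exocanthion = as.numeric(right_exocanthion))
  stopifnot(all(vapply(lm, length, 1L) == 3))
  class(lm) <- "landmark_set"
  lm
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Construct the cranial reference plane from external landmarks
#'
#' The plane through the left porion and both exocanthia is translated
#' `offset_mm` (default 40 mm) along its normal towards the cranial vertex.
#' The normal is `cross(right_exocanthion - porion, left_exocanthion -
#' porion)` normalized, which points cranially for an anatomically posed
#' landmark set; when `head` (a `volume_mask`) is supplied, the normal is
#' flipped if needed so that it points towards the head's foreground centre
#' of mass. The in-plane frame has the anterior axis along the projection of
#' porion-to-exocanthion-midpoint, and the left axis completing a
#' right-handed frame (left = normal x anterior).
#'
#' @param lm A [landmark_set()].
#' @param offset_mm Height of the cutting plane above the landmark plane, mm.
#' @param head Optional `volume_mask` used to orient the normal.
#' @return A `reference_plane`: list with unit `normal`, `origin` (on the
#'   offset plane, above the landmark centroid), unit in-plane axes
#'   `anterior` and `left`, and `offset_mm`.
#' @export
plane_from_landmarks <- function(lm, offset_mm = 40, head = NULL) {
  stopifnot(inherits(lm, "landmark_set"))
  p <- lm$left_porion
  v1 <- lm$right_exocanthion - p
  v2 <- lm$left_exocanthion - p
  n <- cross3(v1, v2)
  nn <- sqrt(sum(n^2))
  scale <- max(sqrt(sum(v1^2)), sqrt(sum(v2^2)))
  if (nn < 1e-9 * scale^2) {
    stop("landmarks are collinear (triangle area ~ 0): porion ",
         paste(signif(p, 4), collapse = ","), "; exocanthia span a line")
  }
  n <- n / nn
  centroid <- (lm$left_porion + lm$left_exocanthion +
                 lm$right_exocanthion) / 3
  if (!is.null(head)) {
    stopifnot(inherits(head, "volume_mask"))
    com <- mask_centre_of_mass(head)
    if (sum((com - centroid) * n) < 0) n <- -n
  }
  mid_exo <- (lm$left_exocanthion + lm$right_exocanthion) / 2
  ant <- mid_exo - p
  ant <- ant - sum(ant * n) * n
  an <- sqrt(sum(ant^2))
  if (an < 1e-9 * scale) stop("degenerate anterior axis")
  ant <- ant / an
  structure(list(origin = centroid + offset_mm * n, normal = n,
                 anterior = ant, left = cross3(n, ant),
                 offset_mm = offset_mm),
            class = "reference_plane")
}

#' Construct a reference plane directly
#'
#' @param origin Point on the plane, mm.
#' @param normal Plane normal (normalized internally).
#' @param anterior In-plane anterior direction (projected and normalized).
#' @export
reference_plane <- function(origin, normal, anterior) {
  n <- normal / sqrt(sum(normal^2))
  a <- anterior - sum(anterior * n) * n
  a <- a / sqrt(sum(a^2))
  structure(list(origin = as.numeric(origin), normal = n, anterior = a,
                 left = cross3(n, a), offset_mm = NA_real_),
            class = "reference_plane")
}

mask_centre_of_mass <- function(mask) {
  idx <- which(mask$voxels != 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty volume mask")
  colMeans((idx - 1) * rep(mask$spacing_mm, each = nrow(idx))) +
    mask$origin_mm
}

# Trilinear interpolation of a voxel grid at world points (n x 3);
# points outside the grid evaluate to 0 (background).
trilinear_sample <- function(mask, pts) {
  d <- dim(mask$voxels)
  f <- sweep(sweep(pts, 2, mask$origin_mm), 2, mask$spacing_mm, `/`) + 1
  out <- numeric(nrow(pts))
  i0 <- floor(f)
  w <- f - i0
  for (corner in 0:7) {
    off <- c(corner %% 2, (corner %/% 2) %% 2, corner %/% 4)
    ii <- sweep(i0, 2, off, `+`)
    wt <- (if (off[1] == 1) w[, 1] else 1 - w[, 1]) *
      (if (off[2] == 1) w[, 2] else 1 - w[, 2]) *
      (if (off[3] == 1) w[, 3] else 1 - w[, 3])
    ok <- ii[, 1] >= 1 & ii[, 1] <= d[1] &
      ii[, 2] >= 1 & ii[, 2] <= d[2] &
      ii[, 3] >= 1 & ii[, 3] <= d[3] & wt > 0
    if (any(ok)) {
      out[ok] <- out[ok] + wt[ok] * mask$voxels[ii[ok, , drop = FALSE]]
    }
  }
  out
}

#' Extract the cranial cross-section outline on a reference plane
#'
#' Resamples the head volume on the plane (trilinear interpolation on a
#' uniform in-plane grid) and traces the 0.5 iso-level by marching squares,
#' giving sub-voxel accuracy. Among the closed iso-contours, the
#' largest-area loop is returned — at vault height the cranial cross-section
#' dominates any satellite loops. In-plane coordinates: x along the plane's
#' anterior axis, y along its left axis (so `anterior_angle = 0`).
#'
#' @param head A `volume_mask`.
#' @param plane A `reference_plane`.
#' @param resolution_mm In-plane sampling step; defaults to the smallest
#'   voxel spacing.
#' @return An [outline2d()].
#' @export
slice_outline <- function(head, plane, resolution_mm = NULL) {
  stopifnot(inherits(head, "volume_mask"), inherits(plane, "reference_plane"))
  res <- resolution_mm %||% min(head$spacing_mm)
  d <- dim(head$voxels)
  # project the volume's corners onto the plane axes to bound the grid
  ext <- (d - 1) * head$spacing_mm
  corners <- as.matrix(expand.grid(c(0, ext[1]), c(0, ext[2]),
                                   c(0, ext[3])))
  corners <- sweep(corners, 2, head$origin_mm, `+`)
  rel <- sweep(corners, 2, plane$origin)
  u_rng <- range(rel %*% plane$anterior)
  v_rng <- range(rel %*% plane$left)
  u <- seq(u_rng[1], u_rng[2], by = res)
  v <- seq(v_rng[1], v_rng[2], by = res)
  pts <- cbind(rep(u, times = length(v)) %o% plane$anterior +
                 rep(v, each = length(u)) %o% plane$left)
  pts <- sweep(pts, 2, plane$origin, `+`)
  z <- matrix(trilinear_sample(head, pts), length(u), length(v))
  cl <- contourLines(u, v, z, levels = 0.5)
  closed <- Filter(function(cc) {
    length(cc$x) > 3 && cc$x[1] == cc$x[length(cc$x)] &&
      cc$y[1] == cc$y[length(cc$y)]
  }, cl)
  if (length(closed) == 0) {
    stop("plane does not intersect the head in a closed loop (",
         length(cl), " open/degenerate contour(s) found)")
  }
  areas <- vapply(closed, function(cc) {
    abs(signed_area(cbind(cc$x, cc$y)[-length(cc$x), , drop = FALSE]))
  }, 1.0)
  if (max(areas) < (2 * res)^2) {
    stop("largest intersection loop has near-zero area (tangent plane?)")
  }
  best <- closed[[which.max(areas)]]
  outline2d(cbind(best$x, best$y)[-length(best$x), , drop = FALSE],
            anterior_angle = 0)
}
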