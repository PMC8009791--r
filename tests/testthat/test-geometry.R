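# anatomically posed landmark set in a patient-oriented frame
# (x right, y anterior, z cranial), landmark plane at z = 0
lm_flat <- landmark_set(left_porion = c(-70, 0, 0),
                        left_exocanthion = c(-30, 80, 0),
                        right_exocanthion = c(30, 80, 0))

test_that("reference plane from flat landmarks is axis aligned", {
  pl <- plane_from_landmarks(lm_flat, offset_mm = 40)
  expect_equal(pl$normal, c(0, 0, 1), tolerance = 1e-12)
  expect_equal(pl$origin[3], 40, tolerance = 1e-12)
  # anterior axis points from porion towards the exocanthion midpoint
  expect_gt(sum(pl$anterior * c(0, 1, 0)), 0.5)
  expect_equal(sqrt(sum(pl$anterior^2)), 1, tolerance = 1e-12)
  expect_equal(sum(pl$anterior * pl$left), 0, tolerance = 1e-12)

  pl0 <- plane_from_landmarks(lm_flat, offset_mm = 0)
  expect_equal(pl0$origin[3], 0, tolerance = 1e-12)
})

test_that("plane construction is equivariant under rigid rotation", {
  set.seed(11)
  ang <- runif(3, -pi, pi)
  rx <- matrix(c(1, 0, 0, 0, cos(ang[1]), sin(ang[1]),
                 0, -sin(ang[1]), cos(ang[1])), 3, 3)
  rz <- matrix(c(cos(ang[3]), sin(ang[3]), 0,
                 -sin(ang[3]), cos(ang[3]), 0, 0, 0, 1), 3, 3)
  rot <- rx %*% rz
  lm_rot <- landmark_set(rot %*% lm_flat$left_porion,
                         rot %*% lm_flat$left_exocanthion,
                         rot %*% lm_flat$right_exocanthion)
  pl <- plane_from_landmarks(lm_flat, offset_mm = 40)
  pl_rot <- plane_from_landmarks(lm_rot, offset_mm = 40)
  expect_equal(pl_rot$normal, as.numeric(rot %*% pl$normal),
               tolerance = 1e-9)
  expect_equal(pl_rot$origin, as.numeric(rot %*% pl$origin),
               tolerance = 1e-9)
  expect_equal(pl_rot$anterior, as.numeric(rot %*% pl$anterior),
               tolerance = 1e-9)
})

test_that("collinear landmarks are rejected", {
  expect_error(plane_from_landmarks(
    landmark_set(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))), "collinear")
})

test_that("slicing a sphere through its centre recovers the great circle", {
  sphere <- make_volume(phantom_spec(120, 120), n_slices = 120,
                        slice_spacing_mm = 1)
  pl <- reference_plane(origin = c(0, 0, 0), normal = c(0, 0, 1),
                        anterior = c(1, 0, 0))
  outl <- slice_outline(sphere, pl)
  expect_equal(outline_area(outl), pi * 60^2, tolerance = 0.005)
  radii <- sqrt(rowSums(sweep(outl$vertices, 2,
                              outline_centroid(outl))^2))
  expect_equal(mean(radii), 60, tolerance = 0.01)

  tangent <- reference_plane(origin = c(0, 0, 70), normal = c(0, 0, 1),
                             anterior = c(1, 0, 0))
  expect_error(slice_outline(sphere, tangent), "closed loop")
})

test_that("phantom ellipsoid mid-plane outline matches the spec axes", {
  vol <- make_volume(phantom_spec(160, 100), n_slices = 60,
                     slice_spacing_mm = 2)
  pl <- reference_plane(origin = c(0, 0, 0), normal = c(0, 0, 1),
                        anterior = c(1, 0, 0))
  outl <- slice_outline(vol, pl)
  ext <- outline_extents(outl)
  # agreement within one voxel (2 mm spacing)
  expect_lt(abs(ext[["length_mm"]] - 160), 2.05)
  expect_lt(abs(ext[["width_mm"]] - 100), 2.05)
})

test_that("area centroid is exact, equivariant, and not the vertex mean", {
  # unit square, edges densified to satisfy the vertex-count invariant
  t <- seq(0, 1, length.out = 9)[-9]
  square <- rbind(cbind(t, 0), cbind(1, t), cbind(1 - t, 1), cbind(0, 1 - t))
  expect_equal(unname(outline_centroid(outline2d(square))), c(0.5, 0.5),
               tolerance = 1e-12)

  # circle with an offset centre
  th <- seq(0, 2 * pi, length.out = 181)[-181]
  circ <- outline2d(cbind(3 + 10 * cos(th), -2 + 10 * sin(th)))
  expect_equal(unname(outline_centroid(circ)), c(3, -2), tolerance = 1e-6)

  # asymmetric polygon vs Monte-Carlo rejection sampling oracle
  thb <- seq(0, 2 * pi, length.out = 65)[-65]
  blob <- outline2d(cbind((0.2 + 0.1 * cos(3 * thb)) * cos(thb),
                          (0.2 + 0.05 * sin(2 * thb)) * sin(thb)))
  set.seed(99)
  n_mc <- 2e6
  xr <- range(blob$vertices[, 1]); yr <- range(blob$vertices[, 2])
  px <- runif(n_mc, xr[1], xr[2]); py <- runif(n_mc, yr[1], yr[2])
  v <- blob$vertices
  inside <- {
    x <- v[, 1]; y <- v[, 2]
    xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
    cnt <- rep(0L, n_mc)
    for (e in seq_along(x)) {
      cross <- ((y[e] > py) != (yn[e] > py))
      xi <- x[e] + (py - y[e]) / (yn[e] - y[e]) * (xn[e] - x[e])
      cnt <- cnt + as.integer(cross & xi > px)
    }
    cnt %% 2L == 1L
  }
  mc <- c(mean(px[inside]), mean(py[inside]))
  expect_lt(max(abs(unname(outline_centroid(blob)) - mc)), 1e-3)

  # rigid-motion equivariance
  cen <- outline_centroid(blob)
  rot <- rotate_outline(blob, 0.7)
  rmat <- matrix(c(cos(0.7), sin(0.7), -sin(0.7), cos(0.7)), 2, 2)
  expect_equal(unname(outline_centroid(rot)),
               as.numeric(rmat %*% cen), tolerance = 1e-9)

  # non-uniform vertex density: vertex mean is biased, area centroid is not
  dense_edge <- rbind(cbind(seq(0, 1, length.out = 60), 0),
                      cbind(1, c(0.25, 0.5, 0.75, 1)),
                      cbind(c(0.75, 0.5, 0.25, 0), 1),
                      cbind(0, c(0.75, 0.5, 0.25)))
  dens <- outline2d(dense_edge)
  expect_equal(unname(outline_centroid(dens)), c(0.5, 0.5),
               tolerance = 1e-9)
  expect_gt(abs(mean(dense_edge[, 2]) - 0.5), 0.2)

  degenerate <- cbind(seq(0, 1, length.out = 40), 0)
  expect_error(outline_centroid(degenerate), "zero-area")
})
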