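test_that("features from a designed curve reproduce prescribed extrema", {
  curve <- designed_curve(Fv = 1.18, Ov = 1.24, Rv = 0.79, Lv = 0.79)
  ft <- quiet_features(curve)
  expect_equal(ft$F, 1.18, tolerance = 1e-3)
  expect_equal(ft$O, 1.24, tolerance = 1e-3)
  expect_equal(ft$R, 0.79, tolerance = 1e-3)
  expect_equal(ft$L, 0.79, tolerance = 1e-3)
  expect_equal(round(ft$width, 2), 0.79)
  expect_equal(round(ft$diff_occiput_sides, 2), 0.45)
  expect_equal(round(ft$diff_forehead_sides, 2), 0.39)
  expect_equal(round(ft$diff_forehead_occiput, 2), 0.06)
  # extrema positions at the sector centres
  expect_lt(ang_dist_test(ft$XF, pi), 0.05)
  expect_lt(ang_dist_test(ft$XO, 0), 0.05)
})

test_that("a flat curve yields unit extrema and zero differences", {
  const <- suppressWarnings(align_curve(normalize_curve(
    radial_profile(make_outline(circle_spec())))))
  ft <- quiet_features(const)
  expect_equal(c(ft$F, ft$O, ft$R, ft$L), rep(1, 4), tolerance = 1e-6)
  expect_equal(ft$diff_occiput_sides, 0, tolerance = 1e-6)
  expect_equal(ft$diff_forehead_sides, 0, tolerance = 1e-6)
  expect_equal(ft$diff_forehead_occiput, 0, tolerance = 1e-6)
  expect_true(all(is.na(c(ft$Do, ft$Af, ft$Df, ft$Ao))))
})

test_that("peak heights match the generator amplitudes", {
  spec <- phantom_spec(150, 110, frontal_bossing = 0.12,
                       occipital_bulge = 0.2)
  # profile about the generator's own centre so the oracle applies exactly
  curve <- suppressWarnings(align_curve(normalize_curve(
    radial_profile(make_outline(spec), center = c(0, 0)))))
  ft <- quiet_features(curve)
  # independent evaluation of the generator model + normalization on the
  # same 1-degree ray grid
  a <- 75; b <- 55; sig <- 0.5
  tg <- 2 * pi * (0:359) / 360
  tv <- 2 * pi * (seq_len(spec$n_vertices) - 1) / spec$n_vertices
  r_mean_ell <- mean(a * b / sqrt((b * cos(tv))^2 + (a * sin(tv))^2))
  ad <- function(t, c) abs((t - c + pi) %% (2 * pi) - pi)
  r_full <- a * b / sqrt((b * cos(tg))^2 + (a * sin(tg))^2) +
    r_mean_ell * (0.12 * exp(-ad(tg, pi)^2 / (2 * sig^2)) +
                    0.2 * exp(-ad(tg, 0)^2 / (2 * sig^2)))
  expect_equal(ft$O, max(r_full[ad(tg, 0) < pi / 4]) / mean(r_full),
               tolerance = 1e-3)
  expect_equal(ft$F, max(r_full[ad(tg, pi) < pi / 4]) / mean(r_full),
               tolerance = 1e-3)
})

test_that("derived differences satisfy their algebraic identities", {
  for (g in seq(0, 0.25, length.out = 5)) {
    ft <- quiet_features(phantom_curve(
      phantom_spec(150 + 60 * g, 110 - 40 * g, frontal_bossing = 0.3 * g,
                   occipital_bulge = 0.4 * g,
                   temporal_narrowing = 0.3 * g)))
    expect_equal(ft$diff_occiput_sides + ft$width, ft$O, tolerance = 1e-12)
    expect_equal(ft$diff_forehead_sides + ft$width, ft$F,
                 tolerance = 1e-12)
    expect_equal(ft$width, (ft$R + ft$L) / 2, tolerance = 1e-12)
  }
})

test_that("the occipital dial monotonically drives O and its difference", {
  vals <- t(vapply(seq(0.05, 0.25, length.out = 5), function(ob) {
    ft <- quiet_features(phantom_curve(
      phantom_spec(150, 110, occipital_bulge = ob)))
    c(ft$O, ft$diff_occiput_sides)
  }, c(0, 0)))
  expect_true(all(diff(vals[, 1]) > 0))
  expect_true(all(diff(vals[, 2]) > 0))
})

test_that("abruptness signs follow descent/ascent order on a phantom sweep", {
  for (g in seq(0.1, 0.3, length.out = 5)) {
    ft <- quiet_features(phantom_curve(
      phantom_spec(150 + 80 * g, 110 - 50 * g, frontal_bossing = 0.3 * g,
                   occipital_bulge = 0.4 * g,
                   temporal_narrowing = 0.3 * g)))
    slopes <- c(ft$Do, ft$Af, ft$Df, ft$Ao)
    defined <- !is.na(slopes)
    expect_true(all(slopes[defined & c(TRUE, FALSE, TRUE, FALSE)] <= 0))
    expect_true(all(slopes[defined & c(FALSE, TRUE, FALSE, TRUE)] >= 0))
  }
})

test_that("abruptness of a hand-built piecewise-linear curve is exact", {
  # descent from 1.2 at theta 0 to 0.8 at theta 1; crossings of 1.1 and
  # 0.9 at 0.25 and 0.75, so slope = -0.2 / 0.5 = -0.4
  n <- 720L
  th <- 2 * pi * (seq_len(n) - 1) / n
  knots_t <- c(0, 1, pi, pi + 1, 2 * pi)
  knots_y <- c(1.2, 0.8, 1.2, 0.8, 1.2)
  y <- approx(knots_t, knots_y, xout = th)$y
  curve <- suppressWarnings(align_curve(normalize_curve(
    radial_curve(th, y, anterior_angle = pi))))
  ab <- abruptness(curve)
  expect_equal(ab["Do", "slope"], -0.4, tolerance = 1e-3)
  expect_equal(ab["Do", "delta_theta"], 0.5, tolerance = 1e-3)
  # ascent spans 0.8 -> 1.2 over (pi - 1): crossings half-way apart
  expect_equal(ab["Af", "slope"], 0.2 / (0.5 * (pi - 1)), tolerance = 1e-3)
  expect_true(all(ab$reason == ""))
})

test_that("abruptness is stable under 10x angular refinement", {
  spec <- phantom_spec(170, 95, frontal_bossing = 0.12,
                       occipital_bulge = 0.18, temporal_narrowing = 0.1)
  coarse <- abruptness(phantom_curve(spec, n_samples = 360))
  fine <- abruptness(phantom_curve(spec, n_samples = 3600))
  expect_equal(coarse$slope, fine$slope, tolerance = 1e-3)
})

test_that("segments that never reach a threshold report a reason, not a number", {
  mild <- phantom_curve(phantom_spec(150, 135))  # near-round: y stays near 1
  ab <- abruptness(mild)
  expect_true(any(is.na(ab$slope)))
  expect_true(all(ab$reason[is.na(ab$slope)] != ""))
})

test_that("features bind into a tidy per-subject data.frame", {
  specs <- phantom_cohort(3)
  fts <- lapply(specs, function(s) quiet_features(phantom_curve(s)))
  df <- features_df(fts, subject_ids = c("a", "b", "c"))
  expect_equal(nrow(df), 3)
  expect_identical(df$subject, c("a", "b", "c"))
  expect_true(all(c("F", "O", "R", "L", "width", "Do") %in% names(df)))
})
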