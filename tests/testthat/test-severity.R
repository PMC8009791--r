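test_that("two-subject ranking gives the narrower, longer skull the top score", {
  a <- derive_features(F = 1.20, O = 1.25, R = 0.75, L = 0.75)
  b <- derive_features(F = 1.12, O = 1.15, R = 0.85, L = 0.84)
  rk <- ucsq_score(list(a, b), subject_ids = c("A", "B"))
  expect_equal(rk$ucsq[rk$subject == "A"], 4)
  expect_equal(rk$ucsq[rk$subject == "B"], 2)
})

test_that("ties share average ranks and rank sums are conserved", {
  fts <- list(derive_features(F = 1.2, O = 1.2, R = 0.80, L = 0.80),
              derive_features(F = 1.1, O = 1.3, R = 0.82, L = 0.78),
              derive_features(F = 1.15, O = 1.18, R = 0.9, L = 0.9))
  rk <- ucsq_score(fts)   # subjects 1 and 2 tie on width 1.60
  expect_equal(sort(rk$rank_width), c(1, 2.5, 2.5))
  expect_equal(sum(rk$rank_width), 6)
  expect_equal(sum(rk$rank_peaks), 6)
})

test_that("cohort mean rank score is always N + 1", {
  for (n in c(5, 12, 21)) {
    specs <- phantom_cohort(n)
    fts <- lapply(specs, function(s) quiet_features(phantom_curve(s)))
    rk <- ucsq_score(fts)
    expect_equal(mean(rk$ucsq), n + 1, tolerance = 1e-12)
    expect_true(all(rk$ucsq >= 2 & rk$ucsq <= 2 * n))
  }
  expect_error(ucsq_score(list(derive_features(1.1, 1.1, 0.9, 0.9))),
               "at least 2")
})

test_that("severity index follows the control-reference formula", {
  table1 <- derive_features(F = 1.18, O = 1.24, R = 0.79, L = 0.79)
  si <- severity_index(table1)
  expect_equal(si$value, (1.24 - 1.1) + (1.18 - 1.15) + (1.70 - 1.58),
               tolerance = 1e-12)
  expect_equal(round(si$value, 2), 0.29)
  expect_equal(as.character(si$class), "moderate")
  expect_equal(unname(si$components),
               c(0.14, 0.03, 0.12), tolerance = 1e-12)

  control <- derive_features(F = 1.15, O = 1.10, R = 0.85, L = 0.85)
  si0 <- severity_index(control)
  expect_equal(si0$value, 0, tolerance = 1e-12)
  expect_equal(as.character(si0$class), "mild")
})

test_that("class boundaries are right-closed at 0.20 and 0.35", {
  expect_equal(as.character(severity_class(0.20)), "moderate")
  expect_equal(as.character(severity_class(0.35)), "severe")
  expect_equal(as.character(severity_class(0.1999999)), "mild")
  expect_equal(as.character(severity_class(0.3499999)), "moderate")
})

test_that("severity index decreases as the phantom gets wider", {
  widths <- seq(95, 125, length.out = 5)
  vals <- vapply(widths, function(w) {
    ft <- quiet_features(phantom_curve(
      phantom_spec(160, w, frontal_bossing = 0.1, occipital_bulge = 0.1)))
    severity_index(ft)$value
  }, 1.0)
  expect_true(all(diff(vals) < 0))
})

test_that("traditional cranial index is width over length times 100", {
  expect_equal(ci_traditional(100, 125), 80)
  expect_equal(ci_traditional(117, 117), 100)
  expect_error(ci_traditional(-1, 10), "positive")
  ell <- make_outline(phantom_spec(160, 100))
  ext <- outline_extents(ell)
  expect_equal(ci_traditional(ext[["width_mm"]], ext[["length_mm"]]),
               62.5, tolerance = 0.005)
})

test_that("curve cranial index matches its closed form", {
  table1 <- derive_features(F = 1.18, O = 1.24, R = 0.79, L = 0.79)
  expect_equal(ci_curve(table1), 100 * 1.58 / 2.42, tolerance = 1e-12)
  expect_equal(round(ci_curve(table1), 2), 65.29)
  flat <- derive_features(F = 1, O = 1, R = 1, L = 1)
  expect_equal(ci_curve(flat), 100)
})

test_that("curve CI underestimates and tracks the traditional CI", {
  set.seed(3)
  cis <- t(vapply(seq_len(50), function(i) {
    g <- (i - 1) / 49
    spec <- phantom_spec(150 + 55 * g, 118 - 38 * g,
                         frontal_bossing = 0.12 * g,
                         occipital_bulge = 0.15 * g,
                         temporal_narrowing = 0.1 * g,
                         seed = i)
    outl <- make_outline(spec)
    ext <- outline_extents(outl)
    ft <- quiet_features(phantom_curve(spec))
    c(trad = ci_traditional(ext[["width_mm"]], ext[["length_mm"]]),
      curve = ci_curve(ft))
  }, c(trad = 0, curve = 0)))
  expect_gt(diff(range(cis[, "trad"])), 15)      # sweep spans CI ~60-80
  expect_gt(stats::cor(cis[, "trad"], cis[, "curve"]), 0.9)
  deformed <- cis[11:50, ]
  expect_true(all(deformed[, "curve"] < deformed[, "trad"]))
})

test_that("severity summary bundles the three layers", {
  spec <- phantom_spec(170, 95, frontal_bossing = 0.1,
                       occipital_bulge = 0.15, temporal_narrowing = 0.1)
  ft <- quiet_features(phantom_curve(spec))
  ext <- outline_extents(make_outline(spec))
  s <- severity_summary(ft, ext[["width_mm"]], ext[["length_mm"]])
  expect_true(s$severity_index > 0)
  expect_true(s$severity_class %in% c("mild", "moderate", "severe"))
  expect_lt(s$ci_curve, s$ci_traditional)
})
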