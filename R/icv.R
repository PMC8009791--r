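#' Intracranial volume from a binary mask
#'
#' Cavalieri-style estimate: the foreground area of each analyzed axial
#' slice (voxel count times in-plane voxel area) is summed and multiplied by
#' the slice spacing. The analysis range `start_slice..end_slice` is the
#' caller's responsibility (just above the foramen magnum to just beneath
#' the vertex). For an axis-aligned binary grid this is algebraically
#' identical to counting voxels times the voxel volume, which is kept
#' available as the `voxel_count` cross-check method.
#'
#' @param mask A `volume_mask` (see [make_volume()], [volume_mask()]).
#' @param method `"slice_area_sum"` (default) or `"voxel_count"`.
#' @param normative Optional normative table (data.frame `sex`,
#'   `age_months`, `mean_ml`, `sd_ml`) for SD-band classification.
#' @param age_months,sex Required when `normative` is given.
#' @param at_mean_tolerance Passed to [normative_band()].
#' @return An `icv_result`: list with `icv_ml`, `method`, `slice_areas_mm2`
#'   and `band` (NA without a normative table).
#' @export
icv_from_mask <- function(mask, method = c("slice_area_sum", "voxel_count"),
                          normative = NULL, age_months = NULL, sex = NULL,
                          at_mean_tolerance = 0.05) {
  stopifnot(inherits(mask, "volume_mask"))
  method <- match.arg(method)
  nz <- dim(mask$voxels)[3]
  s0 <- mask$start_slice
  s1 <- mask$end_slice
  if (s0 < 1 || s1 > nz || s1 < s0) {
    stop("empty or out-of-range analysis slice range [", s0, ", ", s1,
         "] for a grid of ", nz, " slices")
  }
  dx <- mask$spacing_mm[1]; dy <- mask$spacing_mm[2]
  dz <- mask$spacing_mm[3]
  counts <- vapply(s0:s1, function(k) sum(mask$voxels[, , k] != 0), 1.0)
  areas <- counts * dx * dy
  vol_mm3 <- switch(method,
    slice_area_sum = sum(areas * dz),
    voxel_count = sum(counts) * dx * dy * dz)
  band <- NA_character_
  if (!is.null(normative)) {
    band <- normative_band(vol_mm3 / 1000, age_months, sex, normative,
                           at_mean_tolerance)
  }
  structure(list(icv_ml = vol_mm3 / 1000, method = method,
                 slice_areas_mm2 = areas, band = band),
            class = "icv_result")
}

# The seven SD-band labels, from lowest to highest volume.
icv_band_labels <- c("< - 2 SD", "- 1 to - 2 SD", "Mean to - 1 SD",
                     "At mean", "Mean to + 1 SD", "+ 1 to + 2 SD",
                     "> + 2 SD")

#' Classify an intracranial volume against a normative table
#'
#' The age- and sex-specific normative mean and SD are linearly interpolated
#' at the subject's age (no extrapolation outside the table's age range) and
#' the volume is placed in one of seven SD bands by its z-score: below -2
#' SD, -1 to -2 SD, mean to -1 SD, at mean (|z| below `at_mean_tolerance`),
#' mean to +1 SD, +1 to +2 SD, above +2 SD. Band boundaries at |z| = 1 and 2
#' belong to the inner band.
#'
#' @param icv_ml Intracranial volume, mL.
#' @param age_months Age in months; must lie within the table's range for
#'   the subject's sex.
#' @param sex Sex label matching the table's `sex` column.
#' @param table Normative data.frame: `sex`, `age_months` (strictly
#'   increasing per sex), `mean_ml`, `sd_ml` (> 0).
#' @param at_mean_tolerance Half-width of the "At mean" band in z units.
#' @return A character band label.
#' @export
normative_band <- function(icv_ml, age_months, sex, table,
                           at_mean_tolerance = 0.05) {
  validate_normative(table)
  rows <- table[table$sex == sex, ]
  if (nrow(rows) == 0) stop("no normative rows for sex '", sex, "'")
  if (age_months < min(rows$age_months) ||
      age_months > max(rows$age_months)) {
    stop("age ", age_months, " months outside normative range [",
         min(rows$age_months), ", ", max(rows$age_months),
         "] for sex '", sex, "'; no extrapolation")
  }
  m <- approx(rows$age_months, rows$mean_ml, xout = age_months)$y
  s <- approx(rows$age_months, rows$sd_ml, xout = age_months)$y
  z <- (icv_ml - m) / s
  if (abs(z) < at_mean_tolerance) return(icv_band_labels[4])
  if (z > 2) return(icv_band_labels[7])
  if (z > 1) return(icv_band_labels[6])
  if (z >= 0) return(icv_band_labels[5])
  if (z >= -1) return(icv_band_labels[3])
  if (z >= -2) return(icv_band_labels[2])
  icv_band_labels[1]
}

validate_normative <- function(table) {
  need <- c("sex", "age_months", "mean_ml", "sd_ml")
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols) > 0) {
    stop("normative table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (sx in unique(table$sex)) {
    ages <- table$age_months[table$sex == sx]
    if (any(diff(ages) <= 0)) {
      stop("normative ages for sex '", sx,
           "' are not strictly increasing")
    }
  }
  if (any(table$sd_ml <= 0)) stop("normative sd_ml must be positive")
  invisible(table)
}

#' Fill interior holes of a binary mask, slice by slice
#'
#' Simple preprocessing for masks with small segmentation defects: any
#' background voxel not connected (4-connectivity within its slice) to the
#' slice border is turned into foreground.
#'
#' @param mask A `volume_mask`.
#' @return The mask with in-slice holes filled.
#' @export
fill_mask_holes <- function(mask) {
  stopifnot(inherits(mask, "volume_mask"))
  d <- dim(mask$voxels)
  for (k in seq_len(d[3])) {
    sl <- mask$voxels[, , k] != 0
    outside <- flood_from_border(sl)
    mask$voxels[, , k] <- 1L * (sl | !outside)
  }
  mask
}

# Flood-fill background from the slice border; returns logical matrix of
# background voxels reachable from the border.
flood_from_border <- function(fg) {
  nr <- nrow(fg); nc <- ncol(fg)
  reach <- matrix(FALSE, nr, nc)
  seed <- !fg
  seed[2:(nr - 1), 2:(nc - 1)] <- FALSE
  frontier <- which(seed)
  reach[frontier] <- TRUE
  while (length(frontier) > 0) {
    r <- ((frontier - 1) %% nr) + 1
    cc <- ((frontier - 1) %/% nr) + 1
    nb <- rbind(cbind(r - 1, cc), cbind(r + 1, cc),
                cbind(r, cc - 1), cbind(r, cc + 1))
    ok <- nb[, 1] >= 1 & nb[, 1] <= nr & nb[, 2] >= 1 & nb[, 2] <= nc
    nb <- nb[ok, , drop = FALSE]
    lin <- nb[, 1] + (nb[, 2] - 1) * nr
    new <- lin[!reach[lin] & !fg[lin]]
    new <- unique(new)
    reach[new] <- TRUE
    frontier <- new
  }
  reach
}
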