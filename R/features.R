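#' Extract the curve variables from an aligned radial curve
#'
#' Reads off the standard scaphocephaly curve variables: the maxima of
#' forehead (F) and occiput (O), the minima of the right (R) and left (L)
#' sides, their angular positions, the skull width as the mean of both sides
#' (R/2 + L/2), the differences occiput-minus-sides, forehead-minus-sides
#' and forehead-minus-occiput, and the four abruptness slopes of the
#' descents and ascents (via [abruptness()]).
#'
#' Search sectors are the four quadrants of the aligned curve: occiput
#' centred on theta = 0, forehead on pi, right side on pi/2, left side on
#' 3pi/2. If a sector's extremum falls on its boundary a warning is raised
#' (possible misalignment). `diff_forehead_occiput` is the absolute
#' difference |F - O| (the per-subject magnitude convention); the signed
#' value F - O is retained as `diff_forehead_occiput_signed`.
#'
#' @param curve An aligned, normalized `radial_curve`.
#' @return An object of class `curve_features`: a list with elements `F`,
#'   `O`, `R`, `L`, `XF`, `XR`, `XL`, `XO`, `width`, `diff_occiput_sides`,
#'   `diff_forehead_sides`, `diff_forehead_occiput`,
#'   `diff_forehead_occiput_signed`, `Do`, `Af`, `Df`, `Ao` (abruptness
#'   slopes, NA when undefined) and `abruptness_detail`.
#' @export
extract_features <- function(curve) {
  stopifnot(inherits(curve, "radial_curve"))
  if (!curve$normalized || !curve$aligned) {
    stop("extract_features() expects a normalized, aligned curve")
  }
  if (!all(is.finite(curve$y))) stop("curve contains non-finite values")
  th <- curve$theta
  y <- curve$y
  sector <- function(centre) ang_dist(th, centre) <= pi / 4
  pick <- function(centre, what) {
    in_sec <- sector(centre)
    idx <- which(in_sec)[if (what == "max") which.max(y[in_sec]) else
      which.min(y[in_sec])]
    # boundary check: extremum at the edge of its search quadrant
    if (ang_dist(th[idx], centre) > pi / 4 - 2 * pi / curve$n_samples &&
        diff(range(y)) > 1e-9) {
      warning(sprintf(
        "extremum of sector centred %.2f rad lies on the sector boundary%s",
        centre, " (possible misalignment)"))
    }
    list(value = y[idx], theta = th[idx], idx = idx)
  }
  o <- pick(0, "max")
  f <- pick(pi, "max")
  r <- pick(pi / 2, "min")
  l <- pick(3 * pi / 2, "min")
  ab <- abruptness(curve)
  out <- derive_features(F = f$value, O = o$value, R = r$value, L = l$value,
                         XF = f$theta, XR = r$theta, XL = l$theta,
                         XO = o$theta)
  out[c("Do", "Af", "Df", "Ao")] <-
    as.list(ab[c("Do", "Af", "Df", "Ao"), "slope"])
  out$abruptness_detail <- ab
  out
}

#' Construct curve features from raw extrema
#'
#' Computes the derived variables exactly from the four extrema; used
#' internally by [extract_features()] and handy for working directly with
#' published summary values.
#'
#' @param F,O Maxima of forehead and occiput (normalized units).
#' @param R,L Minima of the right and left side troughs.
#' @param XF,XR,XL,XO Angular positions of the extrema, radians.
#' @return A `curve_features` object (abruptness slots NA).
#' @export
derive_features <- function(F, O, R, L, XF = NA_real_, XR = NA_real_,
                            XL = NA_real_, XO = NA_real_) {
  stopifnot(R > 0, L > 0)
  width <- R / 2 + L / 2
  structure(list(F = F, O = O, R = R, L = L,
                 XF = XF, XR = XR, XL = XL, XO = XO,
                 width = width,
                 diff_occiput_sides = O - width,
                 diff_forehead_sides = F - width,
                 diff_forehead_occiput = abs(F - O),
                 diff_forehead_occiput_signed = F - O,
                 Do = NA_real_, Af = NA_real_, Df = NA_real_,
                 Ao = NA_real_,
                 abruptness_detail = NULL),
            class = "curve_features")
}

#' Abruptness of the curve's descents and ascents
#'
#' The aligned curve of a scaphocephalic skull has four monotone segments:
#' descent from the occiput (Do, the first descent), ascent to the forehead
#' (Af, first ascent), descent from the forehead (Df, second descent) and
#' ascent back to the occiput (Ao, second ascent). Each abruptness is the
#' slope between the curve heights 1.1 and 0.9: delta-y of +/-0.2 divided by
#' the angular distance between the linearly interpolated crossings of those
#' two levels within the segment (radians). Descents are negative, ascents
#' positive. A segment that never reaches one of the two levels yields NA
#' with a reason code — never an extrapolated value. When a level is crossed
#' several times within a segment (ripple), the crossing nearest that
#' level's end of the segment is used (1.1 nearest the peak, 0.9 nearest the
#' trough), so the slope spans the whole shoulder of the transition.
#'
#' @param curve An aligned, normalized `radial_curve`.
#' @param lower,upper The two reference heights (defaults 0.9 and 1.1).
#' @return A data.frame with one row per segment (`Do`, `Af`, `Df`, `Ao`):
#'   `slope` (per radian), `delta_theta` (radians), `theta_upper`,
#'   `theta_lower` (crossing positions) and `reason` (why undefined, or "").
#' @export
abruptness <- function(curve, lower = 0.9, upper = 1.1) {
  stopifnot(inherits(curve, "radial_curve"))
  if (!curve$normalized || !curve$aligned) {
    stop("abruptness() expects a normalized, aligned curve")
  }
  th <- curve$theta
  y <- curve$y
  n <- curve$n_samples
  sec_extremum <- function(centre, what) {
    in_sec <- ang_dist(th, centre) <= pi / 4
    which(in_sec)[if (what == "max") which.max(y[in_sec]) else
      which.min(y[in_sec])]
  }
  iO <- sec_extremum(0, "max")
  iR <- sec_extremum(pi / 2, "min")
  iF <- sec_extremum(pi, "max")
  iL <- sec_extremum(3 * pi / 2, "min")
  # unwrap one full period starting at the occipital maximum
  ord <- ((seq_len(n + 1) - 1 + iO - 1) %% n) + 1
  thu <- th[iO] + 2 * pi * (seq_len(n + 1) - 1) / n
  yu <- y[ord]
  pos <- function(i) ((i - iO) %% n) + 1  # position of sample i in unwrap
  segs <- list(Do = c(1, pos(iR)), Af = c(pos(iR), pos(iF)),
               Df = c(pos(iF), pos(iL)), Ao = c(pos(iL), n + 1))
  signs <- c(Do = -1, Af = 1, Df = -1, Ao = 1)
  res <- data.frame(segment = names(segs), slope = NA_real_,
                    delta_theta = NA_real_, theta_upper = NA_real_,
                    theta_lower = NA_real_, reason = "",
                    stringsAsFactors = FALSE)
  rownames(res) <- res$segment
  for (s in names(segs)) {
    i1 <- segs[[s]][1]; i2 <- segs[[s]][2]
    if (i2 <= i1) {
      res[s, "reason"] <- "degenerate segment"
      next
    }
    ts <- thu[i1:i2]; ys <- yu[i1:i2]
    if (max(ys) < upper) {
      res[s, "reason"] <- sprintf("segment never reaches %.2f", upper)
      next
    }
    if (min(ys) > lower) {
      res[s, "reason"] <- sprintf("segment never reaches %.2f", lower)
      next
    }
    # peak end: start for descents, end for ascents
    peak_at_start <- signs[s] < 0
    t_up <- crossing_near_end(ts, ys, upper, from_start = peak_at_start)
    t_lo <- crossing_near_end(ts, ys, lower, from_start = !peak_at_start)
    dth <- abs(t_lo - t_up)
    res[s, "theta_upper"] <- t_up
    res[s, "theta_lower"] <- t_lo
    res[s, "delta_theta"] <- dth
    res[s, "slope"] <- signs[s] * (upper - lower) / dth
  }
  res
}

# Linearly interpolated crossing of `level`, nearest the start (or end) of
# the segment. A sample exactly on the level counts as a crossing at that
# sample (first touching sample wins).
crossing_near_end <- function(ts, ys, level, from_start) {
  d <- ys - level
  touch <- which(d == 0)
  lo <- which(d[-length(d)] * d[-1] < 0)
  cand_t <- c(ts[touch],
              ts[lo] + (level - ys[lo]) / (ys[lo + 1] - ys[lo]) *
                (ts[lo + 1] - ts[lo]))
  if (length(cand_t) == 0) return(NA_real_)
  if (from_start) min(cand_t) else max(cand_t)
}

#' @export
print.curve_features <- function(x, ...) {
  cat("Curve features (normalized units):\n")
  cat(sprintf("  F = %.3f  O = %.3f  R = %.3f  L = %.3f\n",
              x$F, x$O, x$R, x$L))
  cat(sprintf("  width (R/2 + L/2)      = %.3f\n", x$width))
  cat(sprintf("  O - R/2 - L/2          = %.3f\n", x$diff_occiput_sides))
  cat(sprintf("  F - R/2 - L/2          = %.3f\n", x$diff_forehead_sides))
  cat(sprintf("  |F - O|                = %.3f\n", x$diff_forehead_occiput))
  cat(sprintf("  abruptness Do=%.3f Af=%.3f Df=%.3f Ao=%.3f\n",
              x$Do, x$Af, x$Df, x$Ao))
  invisible(x)
}

#' Bind curve features into a data.frame
#'
#' @param features A list of `curve_features` (one per subject).
#' @param subject_ids Optional subject identifiers.
#' @return A data.frame with one row per subject and the Table-style
#'   variable columns.
#' @export
features_df <- function(features, subject_ids = NULL) {
  if (inherits(features, "curve_features")) features <- list(features)
  cols <- c("F", "O", "R", "L", "XF", "XR", "XL", "width",
            "diff_occiput_sides", "diff_forehead_sides",
            "diff_forehead_occiput", "diff_forehead_occiput_signed",
            "Do", "Af", "Df", "Ao")
  df <- do.call(rbind, lapply(features, function(f) {
    as.data.frame(f[cols])
  }))
  df <- cbind(subject = subject_ids %||% seq_len(nrow(df)), df)
  rownames(df) <- NULL
  df
}
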