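#' Cohort rank-sum severity score (UCSQ)
#'
#' Ranks every subject in a cohort on two axes: skull width (R + L; the
#' narrower the skull, the higher the rank number) and the summed peaks
#' F + O (the higher the sum, the higher the rank). Ranks run 1..N with ties
#' receiving the average rank, and the per-subject score is the sum of the
#' two ranks, so it spans 2..2N and the cohort mean is always N + 1 (22.00
#' for a cohort of 21). The score is only defined relative to its cohort.
#'
#' @param cohort A data.frame with columns `F`, `O`, `R`, `L` (one row per
#'   subject, e.g. from [features_df()]) or a list of `curve_features`.
#' @param subject_ids Optional identifiers; taken from a `subject` column if
#'   present.
#' @return A `cohort_ranking` data.frame: `subject`, `width_sum` (R + L),
#'   `peak_sum` (F + O), `rank_width`, `rank_peaks`, `ucsq`.
#' @export
ucsq_score <- function(cohort, subject_ids = NULL) {
  if (is.list(cohort) && !is.data.frame(cohort)) {
    cohort <- features_df(cohort, subject_ids)
  }
  stopifnot(all(c("F", "O", "R", "L") %in% names(cohort)))
  n <- nrow(cohort)
  if (n < 2) stop("rank score undefined for a cohort of ", n,
                  " subject(s); need at least 2")
  width_sum <- cohort$R + cohort$L
  peak_sum <- cohort$F + cohort$O
  rank_width <- rank(-width_sum, ties.method = "average")
  rank_peaks <- rank(peak_sum, ties.method = "average")
  out <- data.frame(
    subject = subject_ids %||% cohort$subject %||% seq_len(n),
    width_sum = width_sum, peak_sum = peak_sum,
    rank_width = rank_width, rank_peaks = rank_peaks,
    ucsq = rank_width + rank_peaks)
  class(out) <- c("cohort_ranking", "data.frame")
  out
}

#' Explicit severity index with mild/moderate/severe classes
#'
#' Measures how far a skull deviates from the control reference values
#' (occiput 1.1, forehead 1.15, width of skull 1.70 where "width of skull"
#' is the sum R + L, i.e. 2 x 0.85 for both sides):
#' \deqn{(O - 1.1) + (F - 1.15) + (1.70 - (R + L))}
#' Classes: mild below 0.20, moderate at or above 0.20 and below 0.35,
#' severe at or above 0.35 (boundaries right-closed on the severe side, per
#' the published ">=" cut-offs). Components may be negative; the formula is
#' applied literally and each component is reported.
#'
#' @param features A `curve_features` object, or a list/data.frame with
#'   `F`, `O`, `R`, `L`.
#' @param cutoffs Length-2 increasing cut-offs (default `c(0.20, 0.35)`).
#' @param reference Control reference values: occiput, forehead, width sum.
#' @return A list: `value`, `class` (factor mild/moderate/severe) and
#'   `components` (named numeric length 3).
#' @export
severity_index <- function(features, cutoffs = c(0.20, 0.35),
                           reference = c(occiput = 1.1, forehead = 1.15,
                                         width_sum = 1.70)) {
  stopifnot(length(cutoffs) == 2, diff(cutoffs) > 0)
  comp <- c(occiput = features$O - reference[["occiput"]],
            forehead = features$F - reference[["forehead"]],
            width = reference[["width_sum"]] - (features$R + features$L))
  value <- sum(comp)
  cls <- severity_class(value, cutoffs)
  list(value = value, class = cls, components = comp)
}

#' Severity class from an index value
#'
#' @param value Severity index value(s).
#' @param cutoffs Length-2 increasing cut-offs; values at or above a
#'   cut-off fall in the more severe class.
#' @return Factor with levels mild, moderate, severe.
#' @export
severity_class <- function(value, cutoffs = c(0.20, 0.35)) {
  factor(ifelse(value >= cutoffs[2], "severe",
                ifelse(value >= cutoffs[1], "moderate", "mild")),
         levels = c("mild", "moderate", "severe"))
}

#' Traditional cranial index
#'
#' Biparietal diameter (maximum skull width) over occipitofrontal diameter
#' (maximum skull length) times 100. Values below about 75 indicate the
#' long, narrow head of scaphocephaly.
#'
#' @param width_mm,length_mm Maximum cranial width and length, mm (> 0).
#' @return The cranial index in percent.
#' @examples
#' ci_traditional(100, 125)  # 80
#' @export
ci_traditional <- function(width_mm, length_mm) {
  if (any(width_mm <= 0) || any(length_mm <= 0)) {
    stop("width and length must be positive")
  }
  width_mm / length_mm * 100
}

#' Cranial index derived from the radial curve
#'
#' The curve analogue of the cranial index: width is twice the mean of both
#' side troughs (R + L) and length is the forehead maximum plus the occiput
#' maximum, so CI = 100 (R + L) / (F + O). Because the curve is taken 4 cm
#' above the landmark plane rather than at the widest/longest level, this
#' tends to sit slightly below the traditional index.
#'
#' @param features A `curve_features` (or anything with `F`, `O`, `R`, `L`).
#' @return The curve-derived cranial index in percent.
#' @export
ci_curve <- function(features) {
  100 * (features$R + features$L) / (features$F + features$O)
}

#' Maximum in-plane width and length of an outline
#'
#' Extents of the outline along the anterior axis (length) and perpendicular
#' to it (width), for feeding [ci_traditional()] from a cross-section.
#'
#' @param outline An [outline2d()].
#' @return Named numeric vector `c(width_mm, length_mm)`.
#' @export
outline_extents <- function(outline) {
  a <- outline$anterior_angle
  axis_a <- c(cos(a), sin(a))
  axis_l <- c(-sin(a), cos(a))
  v <- outline$vertices
  c(width_mm = diff(range(v %*% axis_l)),
    length_mm = diff(range(v %*% axis_a)))
}

#' Full severity summary for one subject
#'
#' Bundles the three severity layers for one subject's features; the
#' rank-sum score is added by [ucsq_score()] at cohort level.
#'
#' @param features A `curve_features`.
#' @param width_mm,length_mm Optional maximum cranial width/length (mm) for
#'   the traditional CI; skipped when absent.
#' @param cutoffs Severity cut-offs, see [severity_index()].
#' @return A one-row data.frame: `severity_index`, `severity_class`,
#'   `ci_curve`, `ci_traditional` (NA when extents not given).
#' @export
severity_summary <- function(features, width_mm = NULL, length_mm = NULL,
                             cutoffs = c(0.20, 0.35)) {
  si <- severity_index(features, cutoffs)
  data.frame(
    severity_index = si$value,
    severity_class = as.character(si$class),
    ci_curve = ci_curve(features),
    ci_traditional = if (is.null(width_mm) || is.null(length_mm))
      NA_real_ else ci_traditional(width_mm, length_mm))
}
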