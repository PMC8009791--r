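#' Aggregate visual scores across raters
#'
#' For each subject, the score of each of the six clinical items is averaged
#' over raters, and the six averages are summed into the overall visual
#' assessment, which runs from 0 (normal skull) to 12 (all items severely
#' deformed for every rater).
#'
#' @param table A `rater_table` (3D array subjects x raters x items, scores
#'   in 0..2) from [make_rater_table()] or [read_rater_csv()].
#' @return A data.frame: `subject`, one column per item (rater means) and
#'   `overall`.
#' @export
aggregate_visual <- function(table) {
  stopifnot(length(dim(table)) == 3)
  if (anyNA(table)) {
    idx <- which(is.na(table), arr.ind = TRUE)
    dn <- dimnames(table)
    lab <- apply(idx, 1, function(i) {
      paste0("(", dn[[1]][i[1]] %||% i[1], ", ", dn[[2]][i[2]] %||% i[2],
             ", ", dn[[3]][i[3]] %||% i[3], ")")
    })
    stop("missing rater scores at: ", paste(lab, collapse = "; "))
  }
  item_means <- apply(table, c(1, 3), mean)
  out <- data.frame(subject = dimnames(table)[[1]] %||%
                      seq_len(dim(table)[1]),
                    item_means, check.names = FALSE)
  out$overall <- rowSums(item_means)
  rownames(out) <- NULL
  out
}

#' Intraclass correlation ICC(A,k): two-way random, absolute agreement,
#' average measures
#'
#' Interrater reliability of the average of k raters under a two-way random
#' effects model with absolute agreement:
#' \deqn{ICC(A,k) = \frac{MS_S - MS_E}{MS_S + (MS_R - MS_E)/n}}
#' where \eqn{MS_S}, \eqn{MS_R} and \eqn{MS_E} are the subject, rater and
#' residual mean squares of the two-way ANOVA decomposition and n the number
#' of subjects. 1 means perfect reliability, 0 poor reliability. The result
#' carries the Landis-Koch label: poor (below 0.20), fair, moderate, good,
#' excellent (0.80 and above); bins are lower-inclusive with edges at 0.20,
#' 0.40, 0.60, 0.80.
#'
#' @param grid Numeric matrix, subjects in rows, raters in columns (at least
#'   2 of each).
#' @return An `icc_result`: list with `icc` (NA when between-subject
#'   variance is zero), `model` descriptor, `label`, and the mean squares.
#' @export
icc_a_k <- function(grid) {
  grid <- as.matrix(grid)
  n <- nrow(grid)
  k <- ncol(grid)
  if (n < 2 || k < 2) stop("need at least 2 subjects and 2 raters")
  if (anyNA(grid)) stop("grid contains missing values")
  grand <- mean(grid)
  row_m <- rowMeans(grid)
  col_m <- colMeans(grid)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((grid - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  ms_rows <- ss_rows / (n - 1)
  ms_cols <- ss_cols / (k - 1)
  ms_err <- ss_err / ((n - 1) * (k - 1))
  denom <- ms_rows + (ms_cols - ms_err) / n
  icc <- if (ms_rows < 1e-12 * (1 + abs(grand))) {
    NA_real_                      # no between-subject variance
  } else {
    (ms_rows - ms_err) / denom
  }
  structure(list(icc = icc,
                 model = "two-way random, absolute agreement, average measures",
                 label = if (is.na(icc)) NA_character_ else
                   landis_koch_label(icc),
                 ms_subjects = ms_rows, ms_raters = ms_cols,
                 ms_error = ms_err, n_subjects = n, n_raters = k),
            class = "icc_result")
}

#' Landis-Koch reliability label
#'
#' @param icc ICC value; values in \[0, 1\] expected.
#' @param edges Lower-inclusive bin edges.
#' @return "poor", "fair", "moderate", "good" or "excellent".
#' @export
landis_koch_label <- function(icc, edges = c(0.20, 0.40, 0.60, 0.80)) {
  labels <- c("poor", "fair", "moderate", "good", "excellent")
  labels[findInterval(icc, edges) + 1]
}

#' Pearson correlation with p-value and strength label
#'
#' Product-moment correlation with a two-sided p-value from the t transform
#' \eqn{t = r\sqrt{(n-2)/(1-r^2)}}, labelled by the conventional strength
#' scale on |r|: negligible (below 0.30), low, moderate, high, very high
#' (0.90 and above); bins lower-inclusive with edges at 0.30, 0.50, 0.70,
#' 0.90.
#'
#' @param x,y Numeric vectors of equal length (at least 3), each with
#'   nonzero variance.
#' @return A `correlation_result`: list with `r`, `p`, `n`, `label`.
#' @export
pearson_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant input: correlation undefined")
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  r <- unname(ct$estimate)
  structure(list(r = r, p = ct$p.value, n = length(x),
                 label = correlation_label(r)),
            class = "correlation_result")
}

#' Correlation strength label on |r|
#'
#' @param r Correlation coefficient.
#' @param edges Lower-inclusive bin edges on |r|.
#' @return "negligible", "low", "moderate", "high" or "very high".
#' @export
correlation_label <- function(r, edges = c(0.30, 0.50, 0.70, 0.90)) {
  labels <- c("negligible", "low", "moderate", "high", "very high")
  labels[findInterval(abs(r), edges) + 1]
}

#' Correlation matrix of curve variables against visual scores
#'
#' Pearson r, p and strength label of every feature column against the
#' overall visual score, mirroring the study's correlation table structure.
#'
#' @param features A features data.frame (see [features_df()]).
#' @param visual The output of [aggregate_visual()] (row order matching).
#' @param columns Feature columns to correlate.
#' @return A data.frame: `variable`, `r`, `p`, `n`, `label`.
#' @export
correlate_features_visual <- function(features, visual,
                                      columns = c("F", "O", "width",
                                                  "diff_forehead_occiput",
                                                  "Do", "Df", "Af", "Ao")) {
  stopifnot(nrow(features) == nrow(visual))
  rows <- lapply(columns, function(cn) {
    xs <- features[[cn]]
    ok <- is.finite(xs) & is.finite(visual$overall)
    if (sum(ok) < 3) {
      return(data.frame(variable = cn, r = NA_real_, p = NA_real_,
                        n = sum(ok), label = NA_character_))
    }
    pc <- pearson_cor(xs[ok], visual$overall[ok])
    data.frame(variable = cn, r = pc$r, p = pc$p, n = pc$n,
               label = pc$label)
  })
  do.call(rbind, rows)
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(A,%d) = %s [%s], model: %s\n", x$n_raters,
              if (is.na(x$icc)) "undefined (no between-subject variance)"
              else sprintf("%.4f", x$icc),
              x$label %||% "NA", x$model))
  invisible(x)
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.4f (n = %d, p = %.4g): %s correlation\n",
              x$r, x$n, x$p, x$label))
  invisible(x)
}
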