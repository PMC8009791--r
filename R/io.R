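#' Read and write cranial outlines as CSV
#'
#' Outline CSV files have exactly two columns, `x_mm` and `y_mm`, one vertex
#' per row, in order, without repeating the first vertex. Values are written
#' with full precision.
#'
#' @param outline An [outline2d()].
#' @param path File path.
#' @param anterior_angle Frame information for [read_outline_csv()] (not
#'   stored in the CSV itself).
#' @return `read_outline_csv()` returns an [outline2d()];
#'   `write_outline_csv()` returns the path invisibly.
#' @export
write_outline_csv <- function(outline, path) {
  stopifnot(inherits(outline, "outline2d"))
  df <- as.data.frame(outline$vertices)
  write.csv(format_full(df), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_outline_csv
#' @export
read_outline_csv <- function(path, anterior_angle = 0) {
  df <- read.csv(path)
  if (!identical(names(df), c("x_mm", "y_mm"))) {
    unexpected <- setdiff(names(df), c("x_mm", "y_mm"))
    stop("outline CSV must have exactly columns x_mm, y_mm; found: ",
         paste(names(df), collapse = ", "),
         if (length(unexpected)) paste0(" (unexpected: ",
                                        paste(unexpected, collapse = ", "),
                                        ")"))
  }
  outline2d(as.matrix(df), anterior_angle = anterior_angle)
}

# Render all numeric columns with 15 significant digits for lossless
# round-trips through text.
format_full <- function(df) {
  for (cn in names(df)) {
    if (is.numeric(df[[cn]])) df[[cn]] <- formatC(df[[cn]], digits = 15,
                                                  format = "g")
  }
  df
}

#' Read and write the landmark JSON file
#'
#' Format: `{"left_porion": [x,y,z], "left_exocanthion": [x,y,z],
#' "right_exocanthion": [x,y,z]}`, coordinates in mm in a right-handed
#' patient-oriented system (x towards patient right, y anterior, z cranial).
#'
#' @param lm A [landmark_set()].
#' @param path File path.
#' @export
write_landmarks_json <- function(lm, path) {
  stopifnot(inherits(lm, "landmark_set"))
  jsonlite::write_json(unclass(lm), path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_landmarks_json
#' @export
read_landmarks_json <- function(path) {
  if (!file.exists(path)) stop("landmark file not found: ", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("left_porion", "left_exocanthion", "right_exocanthion")
  missing_f <- setdiff(need, names(j))
  if (length(missing_f)) {
    stop("landmark JSON missing field(s): ",
         paste(missing_f, collapse = ", "))
  }
  landmark_set(j$left_porion, j$left_exocanthion, j$right_exocanthion)
}

#' Read and write radial curves as CSV with a JSON sidecar
#'
#' The CSV holds columns `theta_rad` and `y`; the sidecar
#' (`<path>.json`) records `n_samples`, the alignment shift, the
#' normalization constant in mm, flags and the smoothing setting, so a curve
#' round-trips losslessly.
#'
#' @param curve A `radial_curve`.
#' @param path CSV file path (sidecar written next to it).
#' @param smoothing Smoothing setting to record in provenance.
#' @export
write_curve_csv <- function(curve, path, smoothing = "none") {
  stopifnot(inherits(curve, "radial_curve"))
  df <- data.frame(theta_rad = curve$theta, y = curve$y)
  write.csv(format_full(df), path, row.names = FALSE, quote = FALSE)
  meta <- list(n_samples = curve$n_samples,
               anterior_angle = curve$anterior_angle,
               normalized = curve$normalized, aligned = curve$aligned,
               scale_mm = curve$scale_mm, alignment = curve$alignment,
               ray_warnings = curve$ray_warnings, smoothing = smoothing)
  jsonlite::write_json(meta, paste0(path, ".json"), digits = NA,
                       auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_curve_csv
#' @export
read_curve_csv <- function(path) {
  df <- read.csv(path)
  if (!identical(names(df), c("theta_rad", "y"))) {
    stop("curve CSV must have exactly columns theta_rad, y; found: ",
         paste(names(df), collapse = ", "))
  }
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) {
    jsonlite::read_json(sidecar, simplifyVector = TRUE)
  } else list()
  radial_curve(df$theta_rad, df$y,
               anterior_angle = meta$anterior_angle %||% 0,
               normalized = isTRUE(meta$normalized),
               aligned = isTRUE(meta$aligned),
               scale_mm = meta$scale_mm %||% NA_real_,
               alignment = meta$alignment %||% 0,
               ray_warnings = meta$ray_warnings %||% 0L)
}

#' Read and write feature tables as CSV
#'
#' One row per subject; columns are the curve-variable names plus the
#' extremum positions and abruptness slopes (empty cells where an
#' abruptness is undefined).
#'
#' @param df A features data.frame (see [features_df()]).
#' @param path File path.
#' @export
write_features_csv <- function(df, path) {
  write.csv(format_full(df), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  df <- read.csv(path)
  need <- c("F", "O", "R", "L")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("features CSV missing column(s): ",
                         paste(miss, collapse = ", "))
  df
}

#' Read and write rater tables as long CSV
#'
#' Long format with columns `subject`, `rater`, `item`, `score`; scores are
#' integers in 0..2. [read_rater_csv()] reshapes to the subjects x raters x
#' items array used by [aggregate_visual()] and [icc_a_k()].
#'
#' @param table A `rater_table` array.
#' @param path File path.
#' @export
write_rater_csv <- function(table, path) {
  stopifnot(length(dim(table)) == 3)
  dn <- dimnames(table)
  long <- expand.grid(subject = dn[[1]], rater = dn[[2]], item = dn[[3]],
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  long$score <- as.vector(table)
  write.csv(long, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_rater_csv
#' @export
read_rater_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "rater", "item", "score")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("rater CSV missing column(s): ",
                         paste(miss, collapse = ", "))
  subjects <- unique(df$subject)
  raters <- unique(df$rater)
  items <- unique(df$item)
  arr <- array(NA_integer_,
               dim = c(length(subjects), length(raters), length(items)),
               dimnames = list(subject = subjects, rater = raters,
                               item = items))
  arr[cbind(match(df$subject, subjects), match(df$rater, raters),
            match(df$item, items))] <- df$score
  structure(arr, class = c("rater_table", "array"))
}

#' Read and write normative ICV tables as CSV
#'
#' Columns `sex`, `age_months`, `mean_ml`, `sd_ml`; ages must be strictly
#' increasing within each sex and SDs positive (validated on read).
#'
#' @param table Normative data.frame.
#' @param path File path.
#' @export
write_normative_csv <- function(table, path) {
  validate_normative(table)
  write.csv(format_full(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_normative_csv
#' @export
read_normative_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_normative(df)
  df
}

#' Read and write volume masks
#'
#' Preferred format is NIfTI (via the RNifti package when available); the
#' documented fallback is a raw little-endian uint8 voxel file plus a JSON
#' header (`<path>.json`) holding `dim`, `spacing_mm`, `origin_mm` and the
#' slice analysis range.
#'
#' @param mask A `volume_mask`.
#' @param path Output path; `.nii`/`.nii.gz` selects NIfTI, anything else
#'   the raw + JSON pair.
#' @export
write_volume <- function(mask, path) {
  stopifnot(inherits(mask, "volume_mask"))
  if (grepl("\\.nii(\\.gz)?$", path)) {
    if (!requireNamespace("RNifti", quietly = TRUE)) {
      stop("RNifti not available; use the raw + JSON format instead")
    }
    img <- RNifti::asNifti(mask$voxels)
    RNifti::pixdim(img) <- mask$spacing_mm
    RNifti::writeNifti(img, path)
  } else {
    writeBin(as.raw(as.vector(mask$voxels != 0)), path)
    jsonlite::write_json(list(dim = dim(mask$voxels),
                              spacing_mm = mask$spacing_mm,
                              origin_mm = mask$origin_mm,
                              start_slice = mask$start_slice,
                              end_slice = mask$end_slice,
                              dtype = "uint8"),
                         paste0(path, ".json"), digits = NA,
                         auto_unbox = TRUE)
  }
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    if (!requireNamespace("RNifti", quietly = TRUE)) {
      stop("RNifti not available; use the raw + JSON format instead")
    }
    img <- RNifti::readNifti(path)
    volume_mask(array(as.integer(img != 0), dim = dim(img)),
                spacing_mm = RNifti::pixdim(img)[1:3])
  } else {
    hdr_path <- paste0(path, ".json")
    if (!file.exists(hdr_path)) stop("volume header not found: ", hdr_path)
    hdr <- jsonlite::read_json(hdr_path, simplifyVector = TRUE)
    vox <- readBin(path, "raw", n = prod(hdr$dim))
    volume_mask(array(as.integer(vox != 0), dim = hdr$dim),
                spacing_mm = hdr$spacing_mm,
                origin_mm = hdr$origin_mm %||% c(0, 0, 0),
                start_slice = hdr$start_slice %||% 1L,
                end_slice = hdr$end_slice %||% hdr$dim[3])
  }
}
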