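#' Pipeline configuration
#'
#' Collects the tunable parameters of the whole pipeline with the package
#' defaults: 360 angular samples (1 degree), no smoothing, 40 mm plane
#' offset, severity cut-offs 0.20/0.35 and an "At mean" z tolerance of 0.05.
#' A config round-trips losslessly through its JSON representation.
#'
#' @param n_samples Angular samples of the radial curve.
#' @param smoothing Apply periodic moving-average smoothing to curves?
#' @param smooth_window Smoothing window (odd, samples).
#' @param offset_mm Reference-plane height above the landmark plane, mm.
#' @param cutoffs Severity-index class cut-offs.
#' @param at_mean_tolerance "At mean" half-width in z units.
#' @param seed Seed for any stochastic step.
#' @param output_dir Where [run_pipeline()] writes its outputs.
#' @return A `run_config` list.
#' @export
run_config <- function(n_samples = 360L, smoothing = FALSE,
                       smooth_window = 5L, offset_mm = 40,
                       cutoffs = c(0.20, 0.35), at_mean_tolerance = 0.05,
                       seed = 1L, output_dir = ".") {
  stopifnot(n_samples >= 8, smooth_window %% 2 == 1, offset_mm >= 0,
            length(cutoffs) == 2, diff(cutoffs) > 0, at_mean_tolerance > 0)
  structure(list(n_samples = as.integer(n_samples),
                 smoothing = isTRUE(smoothing),
                 smooth_window = as.integer(smooth_window),
                 offset_mm = offset_mm, cutoffs = cutoffs,
                 at_mean_tolerance = at_mean_tolerance,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "run_config")
}

#' @rdname run_config
#' @param path JSON file path.
#' @export
write_config_json <- function(config, path) {
  jsonlite::write_json(unclass(config), path, digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @param config A `run_config`.
#' @export
read_config_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, j)
}

#' Run the full quantification pipeline
#'
#' Takes one or more subjects — each either an outline (object or CSV path)
#' or a head volume plus landmark file — and produces, per subject, the
#' aligned normalized curve, the curve features, and the severity summary;
#' with two or more subjects the cohort rank-sum score is added. Outputs
#' are written under `config$output_dir`: `curve_<id>.csv` (+ sidecars),
#' `features.csv`, `severity.csv` and `provenance.json` (config, package
#' version, per-subject warnings). Any stage error is propagated with the
#' stage name and subject id; results of completed subjects are retained
#' and listed in the provenance manifest.
#'
#' @param subjects A list; each element is a list with either `outline` (an
#'   [outline2d()] or CSV path; optional `anterior_angle`) or `volume` (a
#'   `volume_mask` or path readable by [read_volume()]) plus `landmarks` (a
#'   [landmark_set()] or JSON path). An optional `id` names the subject.
#' @param config A [run_config()].
#' @return Invisibly, a list with `features` (data.frame), `severity`
#'   (data.frame incl. cohort ranks when available), `curves` (list) and
#'   `provenance`.
#' @export
run_pipeline <- function(subjects, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  curves <- list()
  feats <- list()
  sev_rows <- list()
  warns <- list()
  ids <- character(0)
  for (i in seq_along(subjects)) {
    sub <- subjects[[i]]
    id <- sub$id %||% paste0("subject", i)
    stage <- "input"
    res <- tryCatch({
      outline <- resolve_outline(sub, config)
      stage <- "curve"
      wmsgs <- character(0)
      curve <- withCallingHandlers({
        prof <- radial_profile(outline, n_samples = config$n_samples)
        prof <- if (config$smoothing) {
          smooth_curve(prof, config$smooth_window)
        } else prof
        align_curve(normalize_curve(prof))
      }, warning = function(w) {
        wmsgs <<- c(wmsgs, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
      stage <- "features"
      ft <- suppressWarnings(extract_features(curve))
      stage <- "severity"
      ext <- outline_extents(outline)
      sev <- severity_summary(ft, width_mm = ext[["width_mm"]],
                              length_mm = ext[["length_mm"]],
                              cutoffs = config$cutoffs)
      list(curve = curve, features = ft, severity = sev, warnings = wmsgs)
    }, error = function(e) {
      stop("pipeline stage '", stage, "' failed for subject '", id, "': ",
           conditionMessage(e), call. = FALSE)
    })
    ids <- c(ids, id)
    curves[[id]] <- res$curve
    feats[[id]] <- res$features
    sev_rows[[id]] <- cbind(subject = id, res$severity)
    warns[[id]] <- res$warnings
    write_curve_csv(res$curve,
                    file.path(config$output_dir,
                              paste0("curve_", id, ".csv")),
                    smoothing = if (config$smoothing)
                      paste0("moving_average_w", config$smooth_window)
                    else "none")
  }
  fdf <- features_df(feats, subject_ids = ids)
  sdf <- do.call(rbind, sev_rows)
  rownames(sdf) <- NULL
  if (length(ids) >= 2) {
    ranking <- ucsq_score(fdf)
    sdf$ucsq <- ranking$ucsq[match(sdf$subject, ranking$subject)]
    sdf$rank_width <- ranking$rank_width[match(sdf$subject,
                                               ranking$subject)]
    sdf$rank_peaks <- ranking$rank_peaks[match(sdf$subject,
                                               ranking$subject)]
  }
  write_features_csv(fdf, file.path(config$output_dir, "features.csv"))
  write_features_csv(sdf, file.path(config$output_dir, "severity.csv"))
  prov <- list(config = unclass(config),
               package_version = as.character(
                 utils::packageVersion("cranioquant")),
               subjects = ids, warnings = warns,
               created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(prov, file.path(config$output_dir,
                                       "provenance.json"),
                       digits = NA, auto_unbox = TRUE, null = "null")
  invisible(list(features = fdf, severity = sdf, curves = curves,
                 provenance = prov))
}

resolve_outline <- function(sub, config) {
  if (!is.null(sub$outline)) {
    if (inherits(sub$outline, "outline2d")) return(sub$outline)
    return(read_outline_csv(sub$outline,
                            anterior_angle = sub$anterior_angle %||% 0))
  }
  if (!is.null(sub$volume)) {
    vol <- if (inherits(sub$volume, "volume_mask")) sub$volume else
      read_volume(sub$volume)
    if (is.null(sub$landmarks)) {
      stop("volume input requires a 'landmarks' entry ",
           "(landmark_set or JSON path)")
    }
    lm <- if (inherits(sub$landmarks, "landmark_set")) sub$landmarks else
      read_landmarks_json(sub$landmarks)
    plane <- plane_from_landmarks(lm, offset_mm = config$offset_mm,
                                  head = vol)
    return(slice_outline(vol, plane))
  }
  stop("subject must provide either 'outline' or 'volume' + 'landmarks'")
}
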