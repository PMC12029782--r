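## End-to-end workflow: segment (reference segmenter or imported
## predictions) -> confidence filter -> per-class masks -> quantification
## -> report. The report object carries per-plate measurements plus any
## per-plate failures; tidy() and glance() expose them broom-style.

#' Pipeline configuration
#'
#' Defaults reproduce the standardized imaging setup: 1746 px frames of an
#' 11 cm dish and a 0.30 confidence threshold on imported predictions.
#'
#' @param image_width_px calibration image width (px).
#' @param dish_diameter_cm dish diameter (cm).
#' @param method `"reference"` (classical segmenter) or `"import"` (read
#'   predictions from YOLO-seg files named in the manifest).
#' @param confidence_threshold threshold for [filter_by_confidence()].
#' @param mode Ef mode passed to [analyze_plate()].
#' @param seed integer seed for any stochastic stage.
#' @param out_dir optional directory for mask PNG dumps and CSV reports.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(image_width_px = 1746, dish_diameter_cm = 11,
                            method = c("reference", "import"),
                            confidence_threshold = 0.30,
                            mode = c("area_px", "area_cm2", "diameter_cm"),
                            seed = 1L, out_dir = NULL) {
  structure(list(image_width_px = image_width_px,
                 dish_diameter_cm = dish_diameter_cm,
                 method = match.arg(method),
                 confidence_threshold = confidence_threshold,
                 mode = match.arg(mode),
                 seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Any field of [pipeline_config()] may appear in the file; missing fields
#' keep their defaults.
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    abort(sprintf("unknown config fields: %s", paste(unknown, collapse = ", ")))
  }
  do.call(pipeline_config, vals)
}

#' Run the plate-analysis workflow
#'
#' `plates` is a manifest tibble with a `plate` identifier column and, per
#' plate, one of: an `image` column (file path or in-memory numeric matrix
#' in a list-column) segmented per `config$method`, with a `pred` column of
#' YOLO-seg prediction paths when `method = "import"`; or `colony_mask` /
#' `halo_mask` columns (logical matrices in list-columns, or mask-image
#' paths) quantified directly. A failing plate is recorded in the report
#' and the run continues.
#'
#' @param plates the plate manifest tibble.
#' @param config a [pipeline_config()].
#' @param manual_ef optional tibble with columns `plate` and `ef_manual`
#'   (reference measurements); adds relative differences to the report.
#' @return an object of class `plate_report`: a list with `measurements`
#'   (one row per analyzed plate), `errors`, `config`. Supports [tidy()],
#'   [glance()] and [autoplot()].
#' @export
run_plate_analysis <- function(plates, config = pipeline_config(),
                               manual_ef = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!nrow(plates)) abort("empty run: the plate manifest has no rows.")
  if (!"plate" %in% names(plates)) {
    plates$plate <- paste0("plate_", seq_len(nrow(plates)))
  }
  cal <- calibration(config$image_width_px, config$dish_diameter_cm)
  meas <- list(); errs <- list()
  for (i in seq_len(nrow(plates))) {
    res <- tryCatch(
      analyze_one_plate(plates[i, ], config, cal),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      errs[[length(errs) + 1L]] <- tibble(plate = plates$plate[i],
                                          error = conditionMessage(res))
    } else {
      meas[[length(meas) + 1L]] <-
        dplyr::bind_cols(tibble(plate = plates$plate[i]), res)
    }
  }
  if (!length(meas)) abort("empty run: no plate could be analyzed.")
  measurements <- dplyr::bind_rows(meas)
  if (!is.null(manual_ef)) {
    measurements <- dplyr::left_join(measurements, manual_ef, by = "plate")
    measurements$rel_diff_pct <- ifelse(
      is.na(measurements$ef_manual), NA_real_,
      relative_difference_pct(measurements$ef, measurements$ef_manual))
  }
  report <- structure(list(measurements = measurements,
                           errors = dplyr::bind_rows(errs),
                           config = config),
                      class = "plate_report")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(measurements,
              file.path(config$out_dir, "measurements.csv"),
              row.names = FALSE)
  }
  report
}

analyze_one_plate <- function(row, config, cal) {
  has <- function(col) col %in% names(row) && !is.null(row[[col]][[1]])
  if (has("colony_mask") && has("halo_mask")) {
    cm <- load_mask(row$colony_mask[[1]])
    hm <- load_mask(row$halo_mask[[1]])
    return(analyze_plate(cm, hm, cal, config$mode))
  }
  if (!has("image")) {
    abort("plate has neither an image nor a colony/halo mask pair.")
  }
  img <- row$image[[1]]
  if (is.character(img)) img <- read_plate_image(img)
  if (config$method == "reference") {
    seg <- segment_reference(img)
    ann <- filter_by_confidence(seg$annotations, config$confidence_threshold)
  } else {
    if (!has("pred")) abort("method 'import' needs a `pred` column.")
    ann <- read_yolo_seg(row$pred[[1]])
    ann <- filter_by_confidence(ann, config$confidence_threshold)
  }
  masks <- polygons_to_masks(ann, dim(img))
  if (!length(masks$BAC)) abort("no colony detected after filtering.")
  if (!length(masks$AS)) abort("no solubilization region detected.")
  cm <- Reduce(`|`, masks$BAC)
  hm <- Reduce(`|`, masks$AS)
  analyze_plate(cm, hm, cal, config$mode)
}

load_mask <- function(x) {
  if (is.character(x)) return(read_plate_image(x) > 0.5)
  check_mask(x)
  x
}

#' @export
print.plate_report <- function(x, ...) {
  cat(sprintf("<plate_report: %d plate(s) analyzed, %d failed>\n",
              nrow(x$measurements), nrow(x$errors)))
  print(x$measurements)
  invisible(x)
}

#' Tidy a plate report into per-plate measurements
#'
#' @param x a `plate_report`.
#' @param ... unused.
#' @return the per-plate measurement tibble.
#' @method tidy plate_report
#' @export
tidy.plate_report <- function(x, ...) x$measurements

#' One-row summary of a plate report
#'
#' @param x a `plate_report`.
#' @param ... unused.
#' @return a one-row tibble: plate counts, mean / min / max Ef, and (when
#'   manual references were supplied) mean and max relative difference.
#' @method glance plate_report
#' @export
glance.plate_report <- function(x, ...) {
  m <- x$measurements
  out <- tibble(n_plates = nrow(m), n_failed = nrow(x$errors),
                mean_ef = mean(m$ef), min_ef = min(m$ef), max_ef = max(m$ef))
  if ("rel_diff_pct" %in% names(m) && any(!is.na(m$rel_diff_pct))) {
    out$mean_rel_diff_pct <- mean(m$rel_diff_pct, na.rm = TRUE)
    out$max_rel_diff_pct <- max(m$rel_diff_pct, na.rm = TRUE)
  }
  out
}

#' Compare automated and manual efficiency measurements
#'
#' Joins automated and manual Ef values by plate identifier, computes the
#' per-plate relative difference, and summarizes. Unpaired entries are kept
#' in the comparison table (flagged `paired = FALSE`) but excluded from the
#' summary statistics.
#'
#' @param automated tibble with columns `plate` and `ef`.
#' @param manual tibble with columns `plate` and `ef_manual`.
#' @return a list with `comparison` (per-plate tibble) and `summary`
#'   (one-row tibble with `n_pairs`, `mean_rel_diff_pct`,
#'   `max_rel_diff_pct`).
#' @export
run_validation <- function(automated, manual) {
  comp <- dplyr::full_join(automated[, c("plate", "ef")], manual,
                           by = "plate")
  comp$paired <- !is.na(comp$ef) & !is.na(comp$ef_manual)
  comp$rel_diff_pct <- ifelse(
    comp$paired, relative_difference_pct(comp$ef, comp$ef_manual), NA_real_)
  paired <- comp[comp$paired, ]
  if (!nrow(paired)) abort("no paired automated/manual measurements.")
  list(comparison = comp,
       summary = tibble(n_pairs = nrow(paired),
                        mean_rel_diff_pct = mean(paired$rel_diff_pct),
                        max_rel_diff_pct = max(paired$rel_diff_pct)))
}
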