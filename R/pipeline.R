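# Orchestration: configuration, per-file measurement runs, segmentation
# evaluation tables and expert comparisons; the CLI is a thin wrapper over
# these functions.

#' Run configuration
#'
#' @param method `"tda"`, `"tda_dl"` or `"both"`.
#' @param threshold Positive decision cut-off.
#' @param clahe Apply CLAHE preprocessing to images before measurement
#'   overlays (measurement itself runs on masks and is unaffected).
#' @param clahe_clip,clahe_tiles CLAHE parameters.
#' @param label_aliases Accepted labelme labels per region.
#' @param output_dir Directory for CSV/JSON/overlay outputs (`NULL`: none).
#' @param seed Integer seed recorded in the manifest.
#' @param verbosity 0 silent, 1 progress messages.
#' @export
run_config <- function(method = c("both", "tda", "tda_dl"), threshold = 0.08,
                       clahe = FALSE, clahe_clip = 2, clahe_tiles = c(8, 8),
                       label_aliases = default_label_aliases(),
                       output_dir = NULL, seed = 1L, verbosity = 1L) {
  method <- match.arg(method)
  stopifnot(threshold > 0)
  structure(list(method = method, threshold = threshold, clahe = isTRUE(clahe),
                 clahe_clip = clahe_clip, clahe_tiles = clahe_tiles,
                 label_aliases = label_aliases, output_dir = output_dir,
                 seed = as.integer(seed), verbosity = verbosity),
            class = "run_config")
}

#' Read a plain key=value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment. Recognized keys
#' match the arguments of [run_config()]; CLI flags override file values.
#'
#' @param path Config file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  lines <- sub("#.*$", "", readLines(path, warn = FALSE))
  lines <- trimws(lines[grepl("=", lines)])
  kv <- lapply(strsplit(lines, "=", fixed = TRUE), trimws)
  vals <- stats::setNames(lapply(kv, function(x) paste(x[-1], collapse = "=")),
                          vapply(kv, `[[`, "", 1))
  args <- list()
  if (!is.null(vals$method)) args$method <- vals$method
  if (!is.null(vals$threshold)) args$threshold <- as.numeric(vals$threshold)
  if (!is.null(vals$clahe)) args$clahe <- tolower(vals$clahe) %in% c("true", "on", "1", "yes")
  if (!is.null(vals$clahe_clip)) args$clahe_clip <- as.numeric(vals$clahe_clip)
  if (!is.null(vals$output_dir)) args$output_dir <- vals$output_dir
  if (!is.null(vals$seed)) args$seed <- as.integer(vals$seed)
  do.call(run_config, args)
}

# Prepare an inferred mask pair for measurement: drop speckle components
# and strip any overlap (inferred instances may collide; the alignment and
# canal geometry need disjoint inputs).
prepare_mask_pair <- function(apical, coronal) {
  apical <- clean_mask(apical)
  coronal <- clean_mask(coronal)
  overlap <- apical & coronal
  if (any(overlap)) {
    apical[overlap] <- FALSE
    coronal[overlap] <- FALSE
  }
  list(apical = apical, coronal = coronal)
}

#' Measure one mask pair
#'
#' Aligns the instances and runs the requested engine(s).
#'
#' @param apical,coronal Logical instance masks.
#' @param method `"tda"`, `"tda_dl"` or `"both"`.
#' @param threshold Decision cut-off.
#' @param clean Apply [prepare_mask_pair()] (largest component + overlap
#'   strip) before aligning.
#' @param skeleton_backend Optional TDA-DL skeleton backend.
#' @return Named list of `i3m_result` objects (one per requested method).
#' @export
measure_masks <- function(apical, coronal, method = c("both", "tda", "tda_dl"),
                          threshold = 0.08, clean = TRUE, skeleton_backend = NULL) {
  method <- match.arg(method)
  if (clean) {
    pair <- prepare_mask_pair(apical, coronal)
    apical <- pair$apical; coronal <- pair$coronal
  }
  aligned <- align_vertical(apical, coronal)
  out <- list()
  if (method %in% c("both", "tda")) {
    out$tda <- i3m_result(measure_tda(aligned), threshold)
  }
  if (method %in% c("both", "tda_dl")) {
    out$tda_dl <- i3m_result(measure_tda_dl(aligned, skeleton_backend = skeleton_backend),
                             threshold)
  }
  out
}

#' Measure a batch of annotations
#'
#' Accepts labelme JSON paths, [tooth_annotation()] objects or
#' `phantom_tooth` objects; measures each with the configured method(s) and
#' returns a tidy table. When `config$output_dir` is set, writes
#' `measurements.csv`, a JSON `report.json`, per-tooth overlay PNGs and a
#' reproducibility `manifest.json`. Unreadable or unmeasurable inputs are
#' recorded per file (`error` column) and do not stop the run.
#'
#' @param inputs Character vector of paths, or a list of annotations or
#'   phantoms.
#' @param config A [run_config()].
#' @return Tibble with one row per tooth and method; the `error` column is
#'   `NA` for successes. The attribute `n_failed` carries the failure count.
#' @export
run_measure <- function(inputs, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  rows <- list()
  n_failed <- 0L
  for (i in seq_along(inputs)) {
    input <- if (is.list(inputs) && !inherits(inputs, "tooth_annotation")) inputs[[i]] else inputs[i]
    parsed <- tryCatch(as_measurement_input(input, config), error = function(e) e)
    if (inherits(parsed, "error")) {
      n_failed <- n_failed + 1L
      rows[[length(rows) + 1L]] <- measurement_error_row(input_id(input, i), parsed)
      next
    }
    res <- tryCatch(
      measure_masks(parsed$apical, parsed$coronal, method = config$method,
                    threshold = config$threshold),
      error = function(e) e)
    if (inherits(res, "error")) {
      n_failed <- n_failed + 1L
      rows[[length(rows) + 1L]] <- measurement_error_row(parsed$source_id, res)
      next
    }
    for (r in res) {
      rows[[length(rows) + 1L]] <- dplyr::mutate(tidy(r),
                                                 source_id = parsed$source_id,
                                                 error = NA_character_)
    }
    if (!is.null(config$output_dir)) {
      write_overlays(parsed, res, config)
    }
    if (config$verbosity > 0) {
      message(sprintf("[%d/%d] %s: %s", i, length(inputs), parsed$source_id,
                      paste(vapply(res, function(r) sprintf("%s I3M=%.4f %s",
                                                            r$measurement$method, r$i3m, r$decision),
                                   ""), collapse = "; ")))
    }
  }
  out <- dplyr::relocate(dplyr::bind_rows(rows), "source_id")
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(out, file.path(config$output_dir, "measurements.csv"))
    jsonlite::write_json(out, file.path(config$output_dir, "report.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    write_manifest(config)
  }
  attr(out, "n_failed") <- n_failed
  out
}

input_id <- function(input, i) {
  if (is.character(input)) sub("\\.[A-Za-z]+$", "", basename(input))
  else if (inherits(input, "tooth_annotation")) input$source_id
  else sprintf("input_%03d", i)
}

as_measurement_input <- function(input, config) {
  if (is.character(input)) input <- read_labelme(input, config$label_aliases)
  if (inherits(input, "tooth_annotation")) {
    masks <- annotation_masks(input)
    img <- if (config$clahe) {
      clahe_enhance(input$image, config$clahe_clip, config$clahe_tiles)
    } else input$image
    return(list(apical = masks$apical, coronal = masks$coronal,
                image = img, source_id = input$source_id))
  }
  if (inherits(input, "phantom_tooth")) {
    return(list(apical = input$apical_mask, coronal = input$coronal_mask,
                image = input$image,
                source_id = sprintf("phantom_seed%d", input$spec$seed)))
  }
  abort_annotation_schema("unsupported input type")
}

measurement_error_row <- function(id, cond) {
  tibble::tibble(source_id = id, method = NA_character_, a_px = NA_real_,
                 b_px = NA_real_, c_px = NA_real_, i3m = NA_real_,
                 threshold = NA_real_, decision = NA_character_,
                 error = class(cond)[1])
}

write_manifest <- function(config) {
  manifest <- list(
    package = "i3m",
    version = as.character(utils::packageVersion("i3m")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC"),
    config = config[c("method", "threshold", "clahe", "clahe_clip", "seed")])
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

write_overlays <- function(parsed, results, config) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  for (r in results) {
    path <- file.path(config$output_dir,
                      sprintf("%s_%s.png", parsed$source_id,
                              tolower(r$measurement$method)))
    png::writePNG(overlay_rgb(parsed$image, parsed$apical, parsed$coronal,
                              r$measurement), path)
  }
}

#' Evaluate inferred instance masks against ground truth
#'
#' Per-region IoU table (coronal, apical, overall = union of both).
#'
#' @param truth,inferred Lists with logical masks `apical` and `coronal`.
#' @return Tibble with one row per region.
#' @export
evaluate_segmentation <- function(truth, inferred) {
  dplyr::bind_rows(
    tidy(segmentation_eval(truth$coronal, inferred$coronal, "coronal")),
    tidy(segmentation_eval(truth$apical, inferred$apical, "apical")),
    tidy(segmentation_eval(truth$apical | truth$coronal,
                           inferred$apical | inferred$coronal, "overall")))
}

#' Compare computed measurements against an expert table
#'
#' Joins a [run_measure()] table with an expert CSV (columns `source_id`,
#' `i3m` and optionally `decision`) and runs the statistics battery per
#' method.
#'
#' @param measured Tibble from [run_measure()].
#' @param expert Tibble/data frame with expert values.
#' @param threshold Decision cut-off for decisions derived from scores.
#' @return Named list of `i3m_comparison` objects, one per method present.
#' @export
compare_to_expert <- function(measured, expert, threshold = 0.08) {
  stopifnot(all(c("source_id", "i3m") %in% names(expert)))
  measured <- measured[!is.na(measured$i3m), ]
  out <- list()
  for (m in unique(measured$method)) {
    sub <- dplyr::inner_join(measured[measured$method == m, ],
                             tibble::as_tibble(expert),
                             by = "source_id", suffix = c("", "_expert"))
    if (nrow(sub) < 3L) next
    out[[m]] <- compare_scores(
      sub$i3m, sub$i3m_expert,
      decisions = classify_age(sub$i3m, threshold),
      reference_decisions = if ("decision_expert" %in% names(sub)) {
        sub$decision_expert
      } else if ("decision" %in% names(expert)) {
        sub$decision
      } else NULL,
      threshold = threshold)
  }
  out
}
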