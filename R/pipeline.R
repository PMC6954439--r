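#' Assemble a run configuration
#'
#' Collects every tunable of the pipeline in one validated object. Values
#' come from (in increasing precedence) package defaults, a YAML config
#' file, and direct arguments. Defaults equal the published values where
#' a value is printed (2.5 µm rolling ball, 1 µm LoG scale, 2.5 µm CLAHE
#' kernel, 11 µm filament extension, 0.6 µm punctum radius).
#'
#' @param config_file Optional path to a flat YAML key-value file; keys
#'   match the argument names of \code{\link{preprocess_params}},
#'   \code{\link{classification_rules}}, plus \code{min_area_um2},
#'   \code{pixel_size_um}, \code{projection} and \code{yen_bins}.
#' @param ... Direct overrides of the same keys.
#' @return An object of class \code{run_config}.
#' @export
run_config <- function(config_file = NULL, ...) {
  vals <- list()
  if (!is.null(config_file)) {
    if (!file.exists(config_file)) stop("config file not found: ", config_file)
    vals <- yaml::read_yaml(config_file)
    if (!is.list(vals)) stop("config file must be a key-value mapping")
  }
  dots <- list(...)
  vals[names(dots)] <- dots
  take <- function(key, default) vals[[key]] %||% default
  pp <- preprocess_params(
    rolling_ball_um = take("rolling_ball_um", 2.5),
    log_scale_um = take("log_scale_um", 1.0),
    clahe_kernel_um = take("clahe_kernel_um", 2.5),
    clahe_clip = take("clahe_clip", 0.01))
  rules <- classification_rules(
    filament_min_extension_um = take("filament_min_extension_um", 11),
    round_radius_um = take("round_radius_um", 0.6),
    round_min_circularity = take("round_min_circularity", 0.8),
    round_max_ar = take("round_max_ar", 2.0),
    swollen_min_solidity = take("swollen_min_solidity", 0.9),
    radius_feature = take("radius_feature", "equivalent"))
  known <- c("rolling_ball_um", "log_scale_um", "clahe_kernel_um",
             "clahe_clip", "filament_min_extension_um", "round_radius_um",
             "round_min_circularity", "round_max_ar", "swollen_min_solidity",
             "radius_feature", "min_area_um2", "pixel_size_um",
             "projection", "yen_bins", "seed")
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  structure(list(
    preprocess = pp,
    rules = rules,
    min_area_um2 = take("min_area_um2", 0.25),
    pixel_size_um = take("pixel_size_um", NULL),
    projection = take("projection", "max"),
    yen_bins = take("yen_bins", 256L),
    seed = take("seed", 1L)
  ), class = "run_config")
}

# Flat named list of every parameter actually used, for the run manifest.
config_manifest <- function(config) {
  c(unclass(config$preprocess),
    unclass(config$rules),
    list(min_area_um2 = config$min_area_um2,
         pixel_size_um = config$pixel_size_um,
         projection = config$projection,
         yen_bins = config$yen_bins))
}

#' Analyse one cell of one image
#'
#' The per-cell unit of the pipeline: mask the projected image to the
#' cell, preprocess, threshold with Yen's criterion, segment, measure the
#' six features, classify and summarize.
#'
#' @param image A projected \code{\link{calibrated_image}}.
#' @param region The cell's \code{\link{cell_region}}.
#' @param config A \code{\link{run_config}}.
#' @return List with \code{objects} (classified feature table),
#'   \code{summary} (a \code{cell_summary}), \code{threshold} and the
#'   segmented \code{segments}.
#' @export
analyze_cell <- function(image, region, config = run_config()) {
  masked <- apply_cell_region(image, region)
  pre <- preprocess_image(masked, config$preprocess)
  # threshold from in-cell pixels only: the analysis is scoped per
  # outlined cell, and out-of-cell zeros would distort the histogram
  thr <- yen_threshold(matrix(pre$pixels[region$mask], ncol = 1L),
                       n_bins = config$yen_bins)
  segs <- segment_objects(pre, thr, min_area_um2 = config$min_area_um2,
                          cell_id = region$cell_id)
  feats <- measure_objects(segs, image$pixel_size)
  feats <- classify_cell(segs, feats, config$rules)
  list(objects = feats, summary = summarize_cell(feats, region$cell_id),
       threshold = thr, segments = segs)
}

#' Analyse one image file end to end
#'
#' Loads the stack, Z-projects it, resolves cell regions and runs
#' \code{\link{analyze_cell}} for each cell.
#'
#' @param image_path Path to a TIFF stack or image.
#' @param regions_path Optional path to a label mask or ImageJ ROI file;
#'   when omitted the whole image is treated as one cell.
#' @param config A \code{\link{run_config}}.
#' @return List with \code{objects} (combined table), \code{summaries}
#'   (list of \code{cell_summary}) and \code{image} (the projection).
#' @export
analyze_image <- function(image_path, regions_path = NULL,
                          config = run_config()) {
  stack <- load_stack(image_path,
                      pixel_size_override = config$pixel_size_um)
  img <- z_project(stack, method = config$projection)
  regions <- if (is.null(regions_path)) {
    list(cell_region(matrix(TRUE, nrow(img$pixels), ncol(img$pixels)),
                     cell_id = tools::file_path_sans_ext(basename(image_path))))
  } else {
    read_cell_regions(regions_path, dim = dim(img$pixels))
  }
  results <- lapply(regions, function(rg) analyze_cell(img, rg, config))
  objects <- do.call(rbind, lapply(results, `[[`, "objects"))
  list(objects = objects,
       summaries = lapply(results, `[[`, "summary"),
       image = img)
}

#' Batch-process a set of images
#'
#' Runs \code{\link{analyze_image}} over a table of inputs, skipping (and
#' logging) images that fail, aggregates per-cell summaries into group
#' statistics, writes \code{objects.csv}, \code{cells.csv},
#' \code{groups.csv} and a JSON run manifest recording every parameter
#' actually used.
#'
#' @param inputs Data frame with columns \code{image} (path), optional
#'   \code{regions} (path or NA) and optional \code{group}.
#' @param out_dir Output directory.
#' @param config A \code{\link{run_config}}.
#' @return List with \code{objects}, \code{summaries}, \code{groups},
#'   \code{errors} (per-image failure messages) and \code{paths}.
#' @export
run_batch <- function(inputs, out_dir, config = run_config()) {
  if (nrow(inputs) == 0L) stop("no input images")
  if (is.null(inputs$regions)) inputs$regions <- NA_character_
  if (is.null(inputs$group)) inputs$group <- "all"
  all_objects <- list(); all_summaries <- list()
  group_of <- character(0L); errors <- character(0L)
  for (i in seq_len(nrow(inputs))) {
    res <- tryCatch(
      analyze_image(inputs$image[i],
                    regions_path = if (is.na(inputs$regions[i])) NULL
                                   else inputs$regions[i],
                    config = config),
      error = function(e) e)
    if (inherits(res, "error")) {
      msg <- sprintf("%s: %s", inputs$image[i], conditionMessage(res))
      message("skipping ", msg)
      errors <- c(errors, msg)
      next
    }
    all_objects[[length(all_objects) + 1L]] <- res$objects
    for (s in res$summaries) {
      all_summaries[[length(all_summaries) + 1L]] <- s
      group_of[s$cell_id] <- inputs$group[i]
    }
  }
  if (length(all_summaries) == 0L)
    stop("all inputs failed:\n", paste(errors, collapse = "\n"))
  objects <- do.call(rbind, all_objects)
  groups <- aggregate_cells(all_summaries, group_of)
  paths <- write_results(objects, all_summaries, groups, out_dir)
  manifest <- file.path(out_dir, "run_manifest.json")
  jsonlite::write_json(
    list(parameters = config_manifest(config),
         inputs = inputs, n_cells = length(all_summaries),
         n_objects = nrow(objects), errors = errors),
    manifest, auto_unbox = TRUE, digits = NA, null = "null")
  list(objects = objects, summaries = all_summaries, groups = groups,
       errors = errors, paths = c(paths, manifest))
}
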