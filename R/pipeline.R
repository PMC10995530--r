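#' Default run configuration
#'
#' One validated configuration object covering every tunable parameter
#' of the pipeline, serialized into every report for provenance. A YAML
#' config file and per-call overrides are merged with last-writer-wins
#' precedence: defaults < file < overrides.
#'
#' @param file optional YAML file of settings.
#' @param ... named overrides of individual settings.
#' @return A `run_config` list.
#' @export
run_config <- function(file = NULL, ...) {
  cfg <- list(
    threshold_fraction = 0.40,
    closing_radius_mm = NULL,   # NULL = 2 x max voxel spacing
    keep_largest = TRUE,
    apply_closing = TRUE,
    gl_lower = 0, gl_upper = 60, gl_levels = 192L,
    sphere_volume_cm3 = 1.0,
    fallback_diameter_mm = 12,
    diameter_method = "r_eq",
    surface_method = "mesh",
    filter_sigma_mm = NULL,
    target_spacing_mm = NULL,
    maxstat_minprop = 0.10,
    maxstat_permutations = 1000L,
    seed = 1L)
  if (!is.null(file)) {
    got <- yaml::read_yaml(file)
    unknown <- setdiff(names(got), names(cfg))
    if (length(unknown) > 0L)
      stop("unknown config settings: ", paste(unknown, collapse = ", "))
    cfg[names(got)] <- got
  }
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0L)
    stop("unknown config settings: ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

validate_config <- function(cfg) {
  stopifnot(cfg$threshold_fraction > 0, cfg$threshold_fraction < 1,
            is.null(cfg$closing_radius_mm) || cfg$closing_radius_mm >= 0,
            cfg$gl_upper > cfg$gl_lower, cfg$gl_levels >= 1,
            cfg$sphere_volume_cm3 > 0, cfg$fallback_diameter_mm >= 0,
            cfg$maxstat_minprop >= 0, cfg$maxstat_minprop < 0.5,
            cfg$maxstat_permutations >= 0)
  invisible(cfg)
}

config_provenance <- function(cfg) {
  js <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, null = "null")
  tf <- tempfile()
  writeLines(js, tf)
  h <- substr(unname(tools::md5sum(tf)), 1, 8)
  unlink(tf)
  list(config_json = as.character(js), config_hash = h,
       package_version = as.character(utils::packageVersion("pethotspot")))
}

write_report_json <- function(payload, path, cfg) {
  payload$provenance <- config_provenance(cfg)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

seg_params_from_config <- function(cfg) {
  segmentation_params(threshold_fraction = cfg$threshold_fraction,
                      closing_radius_mm = cfg$closing_radius_mm,
                      keep_largest = cfg$keep_largest)
}

feat_params_from_config <- function(cfg) {
  feature_params(
    discretization = discretization_params(cfg$gl_lower, cfg$gl_upper,
                                           cfg$gl_levels),
    sphere_volume_cm3 = cfg$sphere_volume_cm3,
    fallback_diameter_mm = cfg$fallback_diameter_mm,
    diameter_method = cfg$diameter_method,
    surface_method = cfg$surface_method)
}

#' Run the extraction pipeline on one lesion
#'
#' Reads a PET volume and a seed VOI (or final mask), applies the
#' configured preprocessing (optional gaussian postfilter, optional
#' resampling), segments (40%-of-SUVmax isocontour, optional closing)
#' unless the mask is declared final, extracts the full feature vector
#' and writes one CSV row with provenance columns (config hash,
#' fallback flag).
#'
#' @param pet_path NIfTI PET volume in SUV units.
#' @param mask_path NIfTI seed VOI (or final mask).
#' @param out_csv output CSV path.
#' @param config a [run_config()].
#' @param mask_is_final skip segmentation and use the mask as the VOI.
#' @param id subject/lesion identifier written into the row.
#' @return Invisibly, the one-row data frame written to `out_csv`.
#' @export
run_extract <- function(pet_path, mask_path, out_csv,
                        config = run_config(), mask_is_final = FALSE,
                        id = "lesion") {
  vol <- read_volume(pet_path)
  roi <- read_mask(mask_path)
  if (!is.null(config$filter_sigma_mm))
    vol <- gaussian_filter(vol, config$filter_sigma_mm)
  if (!is.null(config$target_spacing_mm)) {
    vol <- resample_volume(vol, config$target_spacing_mm, mode = "linear")
    roi <- resample_volume(roi, config$target_spacing_mm, mode = "nearest")
  }
  if (mask_is_final) {
    mask <- roi
  } else {
    mask <- threshold_segment(vol, roi, seg_params_from_config(config))
    if (isTRUE(config$apply_closing)) {
      r <- config$closing_radius_mm
      if (is.null(r)) r <- 2 * max(vol$spacing)
      mask <- close_mask(mask, r)
    }
  }
  fv <- extract_features(vol, mask, feat_params_from_config(config))
  df <- as.data.frame(fv)
  prov <- config_provenance(config)
  df <- cbind(data.frame(id = id), df)
  df$config_hash <- prov$config_hash
  df$package_version <- prov$package_version
  dir.create(dirname(out_csv), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(df, out_csv, row.names = FALSE)
  invisible(df)
}

#' Run the robustness comparison between two feature tables
#'
#' Reads two CSVs of the same subjects under two conditions and writes
#' the per-feature Bland-Altman report ([robustness_report()]) as CSV
#' plus a JSON report embedding the configuration.
#'
#' @param csv_a,csv_b feature CSVs (same subject order).
#' @param out_prefix output path prefix (writes `<prefix>.csv` and
#'   `<prefix>.json`).
#' @param config a [run_config()].
#' @param features optional feature subset.
#' @return Invisibly, the report data frame.
#' @export
run_robustness <- function(csv_a, csv_b, out_prefix,
                           config = run_config(), features = NULL) {
  ta <- utils::read.csv(csv_a)
  tb <- utils::read.csv(csv_b)
  rep <- robustness_report(ta, tb, features = features)
  dir.create(dirname(out_prefix), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(rep, paste0(out_prefix, ".csv"), row.names = FALSE)
  write_report_json(list(report = rep), paste0(out_prefix, ".json"), config)
  invisible(rep)
}

#' Run the Spearman correlogram
#'
#' @param csv feature CSV (numeric feature columns; `id`-like columns
#'   are dropped).
#' @param out_prefix writes `<prefix>_matrix.csv` (absolute Spearman
#'   correlations) and `<prefix>_order.csv` (clustered feature order).
#' @param config a [run_config()].
#' @return Invisibly, the [spearman_matrix()] object.
#' @export
run_correlogram <- function(csv, out_prefix, config = run_config()) {
  tab <- utils::read.csv(csv)
  num <- tab[vapply(tab, is.numeric, logical(1))]
  num <- num[setdiff(names(num), c("id"))]
  sm <- spearman_matrix(num)
  dir.create(dirname(out_prefix), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(sm$r_abs), paste0(out_prefix, "_matrix.csv"))
  utils::write.csv(data.frame(position = seq_along(sm$order),
                              feature = colnames(sm$r)[sm$order]),
                   paste0(out_prefix, "_order.csv"), row.names = FALSE)
  invisible(sm)
}

#' Run the per-feature survival screening
#'
#' Reads a cohort CSV (`id`, `time_months`, `event`, feature columns),
#' runs [maxstat_cutoff()] per feature and writes the screening table
#' (cutoff, permutation p-value, direction, C-index) as CSV and JSON.
#'
#' @param csv cohort CSV.
#' @param out_prefix output path prefix.
#' @param config a [run_config()] (`maxstat_minprop`,
#'   `maxstat_permutations`, `seed`).
#' @param features features to screen (default: all numeric columns
#'   except id/time/event).
#' @return Invisibly, the screening data frame.
#' @export
run_survival <- function(csv, out_prefix, config = run_config(),
                         features = NULL) {
  tab <- utils::read.csv(csv)
  if (is.null(features)) {
    features <- setdiff(names(tab)[vapply(tab, is.numeric, logical(1))],
                        c("id", "time_months", "time", "event"))
  }
  res <- survival_table(tab, features, minprop = config$maxstat_minprop,
                        n_perm = config$maxstat_permutations,
                        seed = config$seed)
  dir.create(dirname(out_prefix), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(res, paste0(out_prefix, ".csv"), row.names = FALSE)
  write_report_json(list(table = res), paste0(out_prefix, ".json"), config)
  invisible(res)
}

#' Simulate a phantom or cohort to files
#'
#' `run_simulate_phantom()` writes the phantom volume and seed VOI as
#' NIfTI plus the ground truth as JSON; `run_simulate_cohort()` writes
#' the cohort CSV.
#'
#' @param spec a [phantom_spec()] / [cohort_spec()].
#' @param out_prefix output path prefix.
#' @param config a [run_config()] (recorded in the ground-truth JSON).
#' @return Invisibly, the phantom / cohort object.
#' @export
run_simulate_phantom <- function(spec, out_prefix, config = run_config()) {
  ph <- make_phantom(spec)
  dir.create(dirname(out_prefix), recursive = TRUE, showWarnings = FALSE)
  write_volume(ph$volume, paste0(out_prefix, "_pet.nii.gz"))
  write_volume(ph$seed, paste0(out_prefix, "_seed.nii.gz"))
  truth <- ph$truth
  truth$spec <- unclass(truth$spec)
  write_report_json(list(truth = truth), paste0(out_prefix, "_truth.json"),
                    config)
  invisible(ph)
}

#' @rdname run_simulate_phantom
#' @export
run_simulate_cohort <- function(spec, out_prefix, config = run_config()) {
  co <- simulate_cohort(spec)
  dir.create(dirname(out_prefix), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(co, paste0(out_prefix, ".csv"), row.names = FALSE)
  invisible(co)
}
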