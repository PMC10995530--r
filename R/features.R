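#' Feature extraction parameters
#'
#' @param discretization a [discretization_params()] for the texture
#'   features.
#' @param sphere_volume_cm3 SUVpeak sphere volume (cm^3).
#' @param fallback_diameter_mm lesion diameter below which SUVpeak (and
#'   the peak-based displacement features) cannot be measured and are
#'   replaced by their SUVmax-based counterparts; default 12 mm.
#' @param diameter_method how the fallback "diameter" is measured:
#'   `"r_eq"` (default, `2 * R_eq`) or `"feret"` (maximal 3D distance
#'   between boundary voxel centers).
#' @param surface_method surface estimator for [sphericity()].
#' @return A `feature_params` object.
#' @export
feature_params <- function(discretization = discretization_params(),
                           sphere_volume_cm3 = 1.0,
                           fallback_diameter_mm = 12,
                           diameter_method = c("r_eq", "feret"),
                           surface_method = c("mesh", "voxel_faces")) {
  structure(list(discretization = discretization,
                 sphere_volume_cm3 = sphere_volume_cm3,
                 fallback_diameter_mm = fallback_diameter_mm,
                 diameter_method = match.arg(diameter_method),
                 surface_method = match.arg(surface_method)),
            class = "feature_params")
}

#' Extract the full per-lesion feature vector
#'
#' Computes the 17 per-lesion biomarkers from a PET volume and its
#' segmented lesion mask: the conventional features SUVmin, SUVmax,
#' SUVpeak, SUVmean, MTV (cm^3), TLG (= MTV x SUVmean), sphericity; the
#' displacement biomarkers NHOCmax, NHOCpeak, NHOPmax, NHOPpeak; and six
#' texture features from the discretized VOI (GLCM joint entropy log10
#' and inverse difference moment, GLRLM short/long run emphasis, GLSZM
#' low/high gray-level zone emphasis).
#'
#' Small-lesion fallback: when the lesion diameter is below
#' `fallback_diameter_mm` (too small to host the SUVpeak sphere), the
#' peak-based entries are copied from the max-based ones and
#' `peak_fallback_used` is set.
#'
#' @param vol a [suv_volume()].
#' @param mask the segmented, non-empty [lesion_mask()].
#' @param params a [feature_params()].
#' @return A `feature_vector` (named list; see
#'   [as.data.frame.feature_vector()] for the tabular form).
#' @export
extract_features <- function(vol, mask, params = feature_params()) {
  stopifnot(inherits(vol, "suv_volume"), inherits(mask, "lesion_mask"),
            inherits(params, "feature_params"))
  check_same_geometry(vol, mask)
  if (!any(mask$values)) stop("mask is empty")
  geom <- lesion_geometry(mask)
  inm <- vol$values[mask$values]
  loc_max <- locate_suv_max(vol, mask)

  diam <- switch(params$diameter_method,
                 r_eq = 2 * geom$r_eq_mm,
                 feret = feret_diameter(geom))
  fallback <- diam < params$fallback_diameter_mm
  if (fallback) {
    loc_peak <- loc_max
    suv_peak <- loc_max$value
  } else {
    loc_peak <- locate_suv_peak(vol, mask, params$sphere_volume_cm3)
    suv_peak <- loc_peak$value
  }

  dv <- discretize(vol, mask, params$discretization)
  gl <- glcm_features(glcm(dv))
  rl <- glrlm_features(dv)
  sz <- glszm_features(dv)

  structure(list(
    suv_min = min(inm), suv_max = loc_max$value, suv_peak = suv_peak,
    suv_mean = mean(inm),
    mtv_cm3 = geom$mtv_cm3,
    tlg = geom$mtv_cm3 * mean(inm),
    sphericity = sphericity(mask, params$surface_method),
    nhoc_max = nhoc(vol, mask, loc_max, geom),
    nhoc_peak = nhoc(vol, mask, loc_peak, geom),
    nhop_max = nhop(vol, mask, loc_max, geom),
    nhop_peak = nhop(vol, mask, loc_peak, geom),
    joint_entropy_log10 = gl[["joint_entropy_log10"]],
    inverse_difference_moment = gl[["inverse_difference_moment"]],
    short_run_emphasis = rl[["short_run_emphasis"]],
    long_run_emphasis = rl[["long_run_emphasis"]],
    low_gray_zone_emphasis = sz[["low_gray_zone_emphasis"]],
    high_gray_zone_emphasis = sz[["high_gray_zone_emphasis"]],
    peak_fallback_used = fallback,
    hotspot_max = loc_max, hotspot_peak = loc_peak,
    geometry = geom),
    class = "feature_vector")
}

# maximal 3D Feret diameter over boundary voxel centers
feret_diameter <- function(geom) {
  b <- geom$boundary_mm
  if (nrow(b) == 1L) return(0)
  if (nrow(b) > 3000L) b <- b[seq(1L, nrow(b), length.out = 3000L), ]
  d2 <- 0
  for (i in seq_len(nrow(b) - 1L)) {
    di <- (b[-seq_len(i), 1, drop = TRUE] - b[i, 1])^2 +
      (b[-seq_len(i), 2, drop = TRUE] - b[i, 2])^2 +
      (b[-seq_len(i), 3, drop = TRUE] - b[i, 3])^2
    d2 <- max(d2, max(di))
  }
  sqrt(d2)
}

#' Feature vector as a one-row data frame
#'
#' @param x a `feature_vector` from [extract_features()].
#' @param ... unused.
#' @return One-row `data.frame` of the 17 features, the fallback flag
#'   and the hot-spot locations.
#' @export
as.data.frame.feature_vector <- function(x, ...) {
  num <- x[c("suv_min", "suv_max", "suv_peak", "suv_mean", "mtv_cm3",
             "tlg", "sphericity", "nhoc_max", "nhoc_peak", "nhop_max",
             "nhop_peak", "joint_entropy_log10",
             "inverse_difference_moment", "short_run_emphasis",
             "long_run_emphasis", "low_gray_zone_emphasis",
             "high_gray_zone_emphasis")]
  df <- as.data.frame(num)
  df$peak_fallback_used <- x$peak_fallback_used
  df$hotspot_max_i <- x$hotspot_max$index[1]
  df$hotspot_max_j <- x$hotspot_max$index[2]
  df$hotspot_max_k <- x$hotspot_max$index[3]
  df$hotspot_peak_i <- x$hotspot_peak$index[1]
  df$hotspot_peak_j <- x$hotspot_peak$index[2]
  df$hotspot_peak_k <- x$hotspot_peak$index[3]
  df
}

#' @export
print.feature_vector <- function(x, ...) {
  cat("<feature_vector>\n")
  cat("  SUV min/mean/peak/max: ",
      paste(format(unlist(x[c("suv_min", "suv_mean", "suv_peak",
                              "suv_max")]), digits = 4), collapse = " / "),
      "\n  MTV ", format(x$mtv_cm3, digits = 4), " cm^3, TLG ",
      format(x$tlg, digits = 4), ", sphericity ",
      format(x$sphericity, digits = 4),
      "\n  NHOC max/peak: ", format(x$nhoc_max, digits = 4), " / ",
      format(x$nhoc_peak, digits = 4),
      "\n  NHOP max/peak: ", format(x$nhop_max, digits = 4), " / ",
      format(x$nhop_peak, digits = 4),
      if (x$peak_fallback_used) "\n  (peak fallback: lesion < fallback diameter)",
      "\n", sep = "")
  invisible(x)
}
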