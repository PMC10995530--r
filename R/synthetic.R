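#' Digital PET phantom specification
#'
#' Parametric phantom with known ground truth: an ellipsoidal lesion of
#' uniform plateau uptake on a low background, a gaussian hot-spot bump
#' placed at radial fraction `f` of the way from the lesion center to
#' its surface along a chosen direction, an optional cold (necrotic)
#' spherical core at the lesion center, and additive gaussian noise.
#' The bump is added only inside the lesion support, so the analytic
#' ellipsoid is the ground-truth mask of a 40%-isocontour segmentation
#' (the background stays well below the threshold).
#'
#' For necrotic phantoms the hot spot is constrained to the viable rim:
#' the effective radial fraction is at least
#' `(core_radius + hotspot_sigma) / R` so peak uptake sits in viable
#' tissue outside the cold core — the mechanism by which necrotic
#' lesions show larger hot-spot displacement.
#'
#' @param dim grid dimensions (length 3).
#' @param spacing voxel spacing in mm.
#' @param semiaxes_mm ellipsoid semi-axes in mm (length 3 or scalar).
#' @param center_mm lesion center in world mm (`NULL` = grid center).
#' @param background_suv,plateau_suv background and lesion plateau SUV.
#' @param hotspot_amplitude,hotspot_sigma_mm gaussian bump height (SUV)
#'   and SD (mm).
#' @param hotspot_fraction radial fraction `f` in `[0, 1]` of the
#'   hot-spot center (0 = lesion center, 1 = surface).
#' @param hotspot_direction direction of displacement (normalized
#'   internally).
#' @param necrotic add a cold spherical core at the lesion center.
#' @param core_radius_mm,core_suv core radius (mm) and uptake (SUV;
#'   must stay below the segmentation threshold to emulate necrosis).
#' @param noise_sd additive gaussian noise SD (SUV).
#' @param seed integer seed fixing all randomness.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(dim = c(57L, 57L, 57L), spacing = c(1, 1, 1),
                         semiaxes_mm = c(20, 20, 20), center_mm = NULL,
                         background_suv = 0.5, plateau_suv = 4,
                         hotspot_amplitude = 4, hotspot_sigma_mm = 3,
                         hotspot_fraction = 0.5,
                         hotspot_direction = c(1, 0, 0),
                         necrotic = FALSE, core_radius_mm = 8,
                         core_suv = 1.0, noise_sd = 0.2, seed = 1L) {
  spacing <- check_spacing(spacing)
  dim <- as.integer(dim)
  if (length(semiaxes_mm) == 1L) semiaxes_mm <- rep(semiaxes_mm, 3L)
  if (any(semiaxes_mm <= 0)) stop("semi-axes must be positive")
  extent <- (dim - 1L) * spacing
  if (is.null(center_mm)) center_mm <- extent / 2
  if (any(center_mm - semiaxes_mm < 0) || any(center_mm + semiaxes_mm > extent))
    stop("ellipsoid does not fit inside the grid")
  if (hotspot_fraction < 0 || hotspot_fraction > 1)
    stop("'hotspot_fraction' must be in [0, 1]")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  u <- hotspot_direction / sqrt(sum(hotspot_direction^2))
  r_dir <- 1 / sqrt(sum((u / semiaxes_mm)^2))  # center-to-surface along u
  if (necrotic) {
    if (core_radius_mm >= min(semiaxes_mm))
      stop("necrotic core larger than the lesion")
    fmin <- min(1, (core_radius_mm + hotspot_sigma_mm) / r_dir)
    hotspot_fraction <- max(hotspot_fraction, fmin)
  }
  structure(list(dim = dim, spacing = spacing, semiaxes_mm = semiaxes_mm,
                 center_mm = center_mm, background_suv = background_suv,
                 plateau_suv = plateau_suv,
                 hotspot_amplitude = hotspot_amplitude,
                 hotspot_sigma_mm = hotspot_sigma_mm,
                 hotspot_fraction = hotspot_fraction,
                 hotspot_direction = u, necrotic = necrotic,
                 core_radius_mm = if (necrotic) core_radius_mm else 0,
                 core_suv = core_suv, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a digital PET phantom
#'
#' Realizes a [phantom_spec()]: returns the SUV volume, a generous seed
#' VOI (the lesion bounding box plus margin, standing in for a manually
#' drawn box), and the analytic ground truth. Deterministic given the
#' spec's seed.
#'
#' @param spec a [phantom_spec()].
#' @param seed_margin_mm margin of the seed box around the ellipsoid.
#' @return A `pet_phantom` list: `$volume` ([suv_volume()]), `$seed`
#'   ([lesion_mask()]), `$truth` (hot-spot world position and fraction,
#'   lesion center and analytic volume, necrosis flag, the spec).
#' @export
make_phantom <- function(spec, seed_margin_mm = 6) {
  stopifnot(inherits(spec, "phantom_spec"))
  dm <- spec$dim; s <- spec$spacing
  cx <- (seq_len(dm[1]) - 1) * s[1]
  cy <- (seq_len(dm[2]) - 1) * s[2]
  cz <- (seq_len(dm[3]) - 1) * s[3]
  dx <- (cx - spec$center_mm[1]) / spec$semiaxes_mm[1]
  dy <- (cy - spec$center_mm[2]) / spec$semiaxes_mm[2]
  dz <- (cz - spec$center_mm[3]) / spec$semiaxes_mm[3]
  rho2 <- outer(outer(dx^2, dy^2, `+`), dz^2, `+`)
  inside <- rho2 <= 1
  u <- spec$hotspot_direction
  r_dir <- 1 / sqrt(sum((u / spec$semiaxes_mm)^2))
  hs <- spec$center_mm + spec$hotspot_fraction * r_dir * u
  hx <- cx - hs[1]; hy <- cy - hs[2]; hz <- cz - hs[3]
  d2 <- outer(outer(hx^2, hy^2, `+`), hz^2, `+`)
  vals <- array(spec$background_suv, dim = dm)
  bump <- spec$hotspot_amplitude * exp(-d2 / (2 * spec$hotspot_sigma_mm^2))
  vals[inside] <- spec$plateau_suv + bump[inside]
  if (spec$necrotic) {
    ex <- cx - spec$center_mm[1]; ey <- cy - spec$center_mm[2]
    ez <- cz - spec$center_mm[3]
    core <- outer(outer(ex^2, ey^2, `+`), ez^2, `+`) <= spec$core_radius_mm^2
    vals[core & inside] <- spec$core_suv
  }
  if (spec$noise_sd > 0) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()),
            add = TRUE)
    set.seed(spec$seed)
    vals <- vals + array(stats::rnorm(length(vals), sd = spec$noise_sd),
                         dim = dm)
    vals[vals < 0] <- 0
  }
  lo <- pmax(0L, floor((spec$center_mm - spec$semiaxes_mm - seed_margin_mm) / s))
  hi <- pmin(dm - 1L, ceiling((spec$center_mm + spec$semiaxes_mm +
                                 seed_margin_mm) / s))
  seedarr <- array(FALSE, dim = dm)
  seedarr[(lo[1]:hi[1]) + 1L, (lo[2]:hi[2]) + 1L, (lo[3]:hi[3]) + 1L] <- TRUE
  truth <- list(center_mm = spec$center_mm, hotspot_mm = hs,
                hotspot_fraction = spec$hotspot_fraction,
                surface_radius_mm = r_dir,
                lesion_volume_cm3 = 4 / 3 * pi * prod(spec$semiaxes_mm) / 1000,
                necrotic = spec$necrotic, spec = spec)
  structure(list(volume = suv_volume(vals, spacing = s),
                 seed = lesion_mask(seedarr, spacing = s),
                 truth = truth),
            class = "pet_phantom")
}

#' @export
print.pet_phantom <- function(x, ...) {
  cat("<pet_phantom> ", paste(dim(x$volume$values), collapse = " x "),
      " grid; hot spot at f = ", format(x$truth$hotspot_fraction, digits = 3),
      if (x$truth$necrotic) "; necrotic core", "\n", sep = "")
  invisible(x)
}

#' Survival cohort specification
#'
#' Describes a synthetic cohort with known feature-hazard links:
#' per-subject features drawn from independent gaussians, exponential
#' survival times with hazard
#' `baseline_hazard * exp(sum(beta * (x - mean)))` (log-linear
#' proportional hazards; features enter centered so the baseline hazard
#' is the hazard of an average subject), independent exponential
#' censoring plus an administrative horizon.
#'
#' Default feature distributions follow typical advanced-NSCLC cohort
#' values (NHOCmax ~ N(0.62, 0.29), NHOPmax ~ N(0.26, 0.16),
#' SUVmax ~ N(13.3, 7.2)); the default baseline hazard corresponds to a
#' median overall survival of 15 months.
#'
#' @param n number of subjects (`>= 2`).
#' @param features named list of `c(mean, sd)` pairs.
#' @param beta named numeric vector of log-hazard slopes per feature
#'   unit (missing features get 0).
#' @param baseline_hazard events per month for an average subject.
#' @param censor_rate exponential censoring rate (per month).
#' @param horizon_months administrative censoring horizon.
#' @param seed integer seed.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n = 100L,
                        features = list(nhoc_max = c(0.62, 0.29),
                                        nhop_max = c(0.26, 0.16),
                                        suv_max = c(13.3, 7.2)),
                        beta = c(),
                        baseline_hazard = log(2) / 15,
                        censor_rate = 0.01,
                        horizon_months = 60,
                        seed = 1L) {
  n <- as.integer(n)
  if (n < 2L) stop("'n' must be >= 2")
  if (baseline_hazard <= 0) stop("'baseline_hazard' must be positive")
  if (censor_rate < 0 || horizon_months < 0) stop("invalid censoring settings")
  structure(list(n = n, features = features, beta = beta,
                 baseline_hazard = baseline_hazard,
                 censor_rate = censor_rate,
                 horizon_months = horizon_months, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a survival cohort
#'
#' Draws the cohort described by a [cohort_spec()]. Deterministic given
#' the spec's seed.
#'
#' @param spec a [cohort_spec()].
#' @return data frame: `id`, `time_months`, `event`, one column per
#'   feature.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()),
          add = TRUE)
  set.seed(spec$seed)
  n <- spec$n
  feats <- lapply(spec$features, function(ms)
    stats::rnorm(n, mean = ms[1], sd = ms[2]))
  lp <- rep(0, n)
  for (f in names(spec$beta)) {
    if (!f %in% names(feats)) stop("beta names a missing feature: ", f)
    lp <- lp + spec$beta[[f]] * (feats[[f]] - spec$features[[f]][1])
  }
  haz <- spec$baseline_hazard * exp(lp)
  t_death <- stats::rexp(n, rate = haz)
  t_cens <- if (spec$censor_rate > 0) stats::rexp(n, rate = spec$censor_rate)
            else rep(Inf, n)
  t_cens <- pmin(t_cens, spec$horizon_months)
  time <- pmin(t_death, t_cens)
  event <- as.integer(t_death <= t_cens)
  if (all(event == 0L))
    warning("degenerate cohort: every record censored")
  out <- data.frame(id = seq_len(n), time_months = time, event = event)
  for (f in names(feats)) out[[f]] <- feats[[f]]
  out
}
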