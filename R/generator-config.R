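#' Configuration for the synthetic gonad generator
#'
#' Bundles every parameter of the simulated clam population: the linear
#' dependence of gonad volume (G_v, mm^3) on shell total length (TL, mm), the
#' per-stage / per-class gonad-volume occupancy targets, the class-specific
#' oocyte maximum-diameter (d_max) distributions, oocyte shape and nucleus
#' geometry, the partial-fecundity (PF) regression used by the count
#' calibration mode, and the logistic maturity ogive used for maturity
#' samples.
#'
#' Occupancy percentages, the G_v regression, the PF regression and the d_max
#' class means/bounds default to the values reported for Adriatic
#' *Chamelea gallina* in ripe (4A) and partially spawned (4B) females.
#' The `mean` entries of `diameters` are *target class means*: the generator
#' solves for the normal location parameter so that the truncated
#' distribution (mature class truncated to `(threshold, hi]`, immature to
#' `[lo, threshold]`) has exactly that mean.
#'
#' @param gv_slope,gv_intercept coefficients of G_v = slope*TL + intercept
#'   (mm^3 per mm, mm^3).
#' @param gv_noise_cv lognormal coefficient of variation of G_v about the
#'   regression line (0 = noise off). The multiplicative noise has mean 1.
#' @param occupancy named list (`"4A"`, `"4B"`) of named vectors
#'   (`mature`, `immature`) of target percent G_v occupation.
#' @param diameters named list per stage with entries `mature`/`immature`
#'   (each `list(mean, sd)` in micrometres) and `bounds = c(lo, hi)`, the
#'   stage-wide d_max range in micrometres.
#' @param maturity_threshold d_max (micrometres) above which an oocyte is
#'   vitellogenic (mature); 60 by default.
#' @param aspect_range range of the d_min/d_max aspect ratio, sampled
#'   uniformly.
#' @param nucleus_fraction nucleus diameter as a fraction of d_max; must not
#'   exceed `min(aspect_range)` so the nucleus fits inside the oocyte.
#' @param calibration_mode `"occupancy"` (add oocytes until each class meets
#'   its occupancy target) or `"count"` (draw the mature count from the PF
#'   regression; occupancy is emergent).
#' @param pf_slope,pf_intercept coefficients of PF = slope*TL + intercept
#'   (oocytes per mm, oocytes), used in count mode.
#' @param pf_noise_cv lognormal CV of counts about the PF line in count mode.
#' @param ogive_a,ogive_b logistic maturity parameters: P(mature | TL) =
#'   1 / (1 + exp(-(a + b TL))). Defaults give TL50 = -a/b = 11.2 mm and
#'   P(mature | 15 mm) > 0.99.
#' @param volume_scale multiplier applied to the G_v line, for scaled-down
#'   simulation studies (occupancy fractions and the sectioning plan are
#'   unaffected; 1 = organ at natural size).
#'
#' @return An object of class `generator_config`.
#' @examples
#' cfg <- generator_config()
#' cfg$occupancy[["4A"]]
#' @export
generator_config <- function(gv_slope = 17.2,
                             gv_intercept = -304.5,
                             gv_noise_cv = 0.10,
                             occupancy = list(
                               "4A" = c(mature = 19.1, immature = 20.5),
                               "4B" = c(mature = 7.8, immature = 14.0)
                             ),
                             diameters = list(
                               "4A" = list(mature = list(mean = 70.3, sd = 25),
                                           immature = list(mean = 41.5, sd = 15),
                                           bounds = c(5.85, 154.89)),
                               "4B" = list(mature = list(mean = 70.1, sd = 25),
                                           immature = list(mean = 38.6, sd = 15),
                                           bounds = c(9.54, 139.21))
                             ),
                             maturity_threshold = 60,
                             aspect_range = c(0.65, 0.95),
                             nucleus_fraction = 0.35,
                             calibration_mode = c("occupancy", "count"),
                             pf_slope = 3.01e4,
                             pf_intercept = -5.21e5,
                             pf_noise_cv = 0.20,
                             ogive_a = -14,
                             ogive_b = 1.25,
                             volume_scale = 1) {
  calibration_mode <- match.arg(calibration_mode)
  stopifnot(
    is.numeric(gv_slope), is.numeric(gv_intercept),
    gv_noise_cv >= 0, pf_noise_cv >= 0,
    length(aspect_range) == 2L, all(aspect_range > 0), all(aspect_range <= 1),
    aspect_range[1] <= aspect_range[2],
    nucleus_fraction > 0, volume_scale > 0,
    maturity_threshold > 0
  )
  if (nucleus_fraction > aspect_range[1]) {
    stop("nucleus_fraction (", nucleus_fraction, ") exceeds the minimum aspect ",
         "ratio (", aspect_range[1], "): the nucleus would not fit inside d_min")
  }
  if (ogive_b == 0) stop("ogive_b must be nonzero (TL50 = -a/b undefined)")
  for (st in names(occupancy)) {
    occ <- occupancy[[st]]
    if (any(occ <= 0) || sum(occ) > 100) {
      stop("occupancy targets for stage ", st,
           " must be positive and sum to at most 100%")
    }
  }
  for (st in names(diameters)) {
    dd <- diameters[[st]]
    b <- dd$bounds
    stopifnot(length(b) == 2L, b[1] > 0, b[1] < b[2])
    if (b[1] >= maturity_threshold || b[2] <= maturity_threshold) {
      stop("d_max bounds for stage ", st,
           " must straddle the maturity threshold (", maturity_threshold, " um)")
    }
  }

  cfg <- structure(
    list(
      gv_slope = gv_slope, gv_intercept = gv_intercept,
      gv_noise_cv = gv_noise_cv,
      occupancy = occupancy, diameters = diameters,
      maturity_threshold = maturity_threshold,
      aspect_range = aspect_range, nucleus_fraction = nucleus_fraction,
      calibration_mode = calibration_mode,
      pf_slope = pf_slope, pf_intercept = pf_intercept,
      pf_noise_cv = pf_noise_cv,
      ogive_a = ogive_a, ogive_b = ogive_b,
      volume_scale = volume_scale
    ),
    class = "generator_config"
  )
  # Pre-solve class-wise truncated-normal locations and store class summaries.
  cfg$classes <- lapply(setNames(nm = names(diameters)), function(st) {
    dd <- diameters[[st]]
    thr <- maturity_threshold
    lapply(setNames(nm = c("mature", "immature")), function(cl) {
      lo <- if (cl == "mature") thr else dd$bounds[1]
      hi <- if (cl == "mature") dd$bounds[2] else thr
      loc <- truncnorm_location_for_mean(dd[[cl]]$mean, dd[[cl]]$sd, lo, hi)
      list(location = loc, sd = dd[[cl]]$sd, lo = lo, hi = hi,
           mean_dmax = dd[[cl]]$mean,
           mean_nucleus = nucleus_fraction * dd[[cl]]$mean)
    })
  })
  cfg
}

#' @export
print.generator_config <- function(x, ...) {
  cat("Synthetic gonad generator configuration\n")
  cat(sprintf("  G_v = %.4g*TL %+.4g mm^3 (CV %.2g, volume scale %.3g)\n",
              x$gv_slope, x$gv_intercept, x$gv_noise_cv, x$volume_scale))
  for (st in names(x$occupancy)) {
    occ <- x$occupancy[[st]]
    cat(sprintf("  stage %s occupancy: mature %.1f%%, immature %.1f%% (total %.1f%%)\n",
                st, occ[["mature"]], occ[["immature"]], sum(occ)))
  }
  cat(sprintf("  calibration mode: %s\n", x$calibration_mode))
  cat(sprintf("  maturity ogive: a = %.4g, b = %.4g (TL50 = %.3g mm)\n",
              x$ogive_a, x$ogive_b, -x$ogive_a / x$ogive_b))
  invisible(x)
}

# Mean nucleus diameter per class (um) implied by the configuration.
config_mean_nucleus <- function(config, stage) {
  vapply(config$classes[[stage]], function(cl) cl$mean_nucleus, numeric(1))
}
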