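#' Cavalieri volume estimate from serial section areas
#'
#' The classical unbiased volume estimator for systematic sections: the sum
#' of section areas times the distance between section starts.
#'
#' @param areas gonad cross-section areas per section (mm^2).
#' @param spacing distance between section starts (um).
#' @return Volume in mm^3.
#' @examples
#' cavalieri_volume(c(2, 3, 1), 100)  # 6 mm^2 * 0.1 mm = 0.6 mm^3
#' @export
cavalieri_volume <- function(areas, spacing) {
  if (length(areas) < 1) stop("need at least one section area")
  if (any(areas < 0)) stop("negative section area")
  if (spacing <= 0) stop("spacing must be positive")
  sum(areas) * spacing / 1000  # mm^2 * mm
}

#' Spheroid oocyte volume from its two profile diameters
#'
#' `mode = "corrected"` (default) treats d_min and d_max as full diameters
#' of an oblate spheroid, V = pi/6 * d_min * d_max^2 (for d_min = d_max this
#' is the sphere volume pi d^3/6). `mode = "paper"` applies the formula
#' V = 4/3 * pi * d_min * d_max^2 verbatim, as printed in some of the
#' bivalve fecundity literature; it treats the diameters as if they were
#' semi-axes and is exactly 8 times the corrected value, so it is kept only
#' for literal reproduction of published numbers.
#'
#' @param d_min,d_max minor and major diameters (um), `0 < d_min <= d_max`.
#' @param mode `"corrected"` or `"paper"`.
#' @return Volume in um^3 (vectorized).
#' @examples
#' oocyte_volume(60, 60)                    # sphere: pi*60^3/6
#' oocyte_volume(60, 60, mode = "paper")    # 8x the sphere volume
#' @export
oocyte_volume <- function(d_min, d_max, mode = c("corrected", "paper")) {
  mode <- match.arg(mode)
  if (any(d_min <= 0) || any(d_max <= 0)) stop("diameters must be positive")
  if (any(d_min > d_max)) stop("need d_min <= d_max")
  v <- pi / 6 * d_min * d_max^2
  if (mode == "paper") 8 * v else v
}

#' Abercrombie correction for profile counts in thick sections
#'
#' A section of thickness T cuts the nucleus (diameter h) of every particle
#' whose nucleus center lies within a slab of height T + h, so raw
#' nucleus-profile counts overstate numbers by (T + h)/T. The correction
#' multiplies the raw count by T / (T + h).
#'
#' @param raw_count observed number of nucleus profiles.
#' @param thickness section thickness T (um).
#' @param mean_nucleus_diameter mean nucleus diameter h (um); 0 means point
#'   nuclei, i.e. no correction.
#' @return Corrected count (not rounded).
#' @examples
#' abercrombie_correction(100, 6, 24)  # 20
#' @export
abercrombie_correction <- function(raw_count, thickness, mean_nucleus_diameter) {
  if (thickness <= 0) stop("thickness must be positive")
  if (any(mean_nucleus_diameter < 0)) stop("nucleus diameter must be >= 0")
  raw_count * thickness / (thickness + mean_nucleus_diameter)
}

#' Total oocyte numbers from field counts
#'
#' Converts per-field nucleus-profile counts into whole-gonad numbers: the
#' class-wise number density is the (Abercrombie-corrected, under the
#' `"intersect"` rule) count divided by the sampled tissue volume
#' (total field area x section thickness), and the total is density times
#' the reconstructed gonad volume.
#'
#' @param field_rows data frame of field-restricted profile rows with columns
#'   `dev_class` and `nucleus_hit` (only nucleus-hit rows are counted).
#' @param n_fields number of fields the rows were sampled from.
#' @param field_area area of one field (um^2).
#' @param thickness section thickness (um).
#' @param mean_nucleus_diameter named vector (`mature`, `immature`) or scalar
#'   mean nucleus diameter (um), used only under the `"intersect"` rule.
#' @param G_v_hat reconstructed gonad volume (mm^3).
#' @param nucleus_rule `"intersect"` or `"center"`.
#' @return Named vector of estimated totals per class.
#' @examples
#' rows <- data.frame(dev_class = rep("mature", 3), nucleus_hit = TRUE)
#' estimate_total_count(rows, 1, 1e6, 6, 24, 100, "center")     # 50000
#' estimate_total_count(rows, 1, 1e6, 6, 24, 100, "intersect")  # 10000
#' @export
estimate_total_count <- function(field_rows, n_fields, field_area, thickness,
                                 mean_nucleus_diameter, G_v_hat,
                                 nucleus_rule = c("intersect", "center")) {
  nucleus_rule <- match.arg(nucleus_rule)
  if (n_fields < 1) stop("need at least one field")
  if (field_area <= 0) stop("field area must be positive")
  classes <- c("mature", "immature")
  nd <- rep_len(mean_nucleus_diameter, 2L)
  if (!is.null(names(mean_nucleus_diameter))) {
    nd <- mean_nucleus_diameter[classes]
  }
  names(nd) <- classes
  hits <- field_rows[field_rows$nucleus_hit, , drop = FALSE]
  raw <- vapply(classes, function(cl) sum(hits$dev_class == cl), numeric(1))
  corr <- if (nucleus_rule == "intersect") {
    abercrombie_correction(raw, thickness, nd)
  } else {
    raw
  }
  density <- corr / (n_fields * field_area * thickness)  # per um^3
  density * mm3_to_um3(G_v_hat)
}

#' Percent gonad-volume occupancy of one oocyte class
#'
#' @param N_hat estimated total number of oocytes of the class.
#' @param mean_O_v mean oocyte volume of the class (um^3).
#' @param G_v_hat gonad volume (mm^3).
#' @return Percent of gonad volume occupied.
#' @examples
#' occupancy_percent(1e5, 1e5, 50)  # 20
#' @export
occupancy_percent <- function(N_hat, mean_O_v, G_v_hat) {
  if (any(G_v_hat <= 0)) stop("gonad volume must be positive")
  if (any(N_hat < 0) || any(mean_O_v < 0)) stop("inputs must be non-negative")
  100 * N_hat * mean_O_v / mm3_to_um3(G_v_hat)
}

#' Stereological fecundity estimate for one specimen
#'
#' Composes the whole estimation chain on a field-restricted section profile
#' table: Cavalieri gonad volume from the per-section areas, class-wise
#' total counts from nucleus-hit profiles (Abercrombie-corrected under the
#' `"intersect"` rule), mean oocyte volumes from the nucleus-hit profile
#' diameters, occupancy percentages, and — for ripe (4A) females — partial
#' fecundity PF, the estimated number of mature oocytes.
#'
#' Under the `"intersect"` rule a profile's inclusion probability grows with
#' its nucleus diameter, so nucleus-hit profiles oversample large oocytes.
#' With `size_bias_correction = TRUE` (default) the mean oocyte volume is an
#' inclusion-probability-weighted (Horvitz-Thompson) mean with weights
#' 1 / (thickness + estimated nucleus diameter); with `FALSE` it is the
#' plain mean over nucleus-hit profiles.
#'
#' @param table a field-restricted `section_profile_table` (from
#'   [sample_fields()] or the pipeline).
#' @param config optional [generator_config()]; supplies the class mean
#'   nucleus diameters and the nucleus fraction when these are not given.
#' @param mode oocyte volume formula, `"corrected"` (default) or `"paper"`;
#'   see [oocyte_volume()]. A single mode is applied to every quantity in
#'   the estimate.
#' @param mean_nucleus_diameter named per-class vector or scalar (um); for
#'   observed (non-simulated) data this is a required input under the
#'   `"intersect"` rule.
#' @param nucleus_fraction nucleus diameter as a fraction of d_max, used to
#'   estimate per-profile nucleus sizes for the size-bias weights.
#' @param method `"number_volume"` (count x mean volume / gonad volume,
#'   default) or `"delesse"` (areal fraction of oocyte profiles in the
#'   fields; sensitivity check, approximate in thick sections).
#' @param size_bias_correction logical; see Details.
#' @return An object of class `fecundity_estimate` with `G_v_hat` (mm^3),
#'   `N_hat`, `mean_O_v`, `occupancy` (per class and total), `PF`
#'   (NA unless stage 4A), and provenance fields.
#' @export
estimate_fecundity <- function(table, config = NULL,
                               mode = c("corrected", "paper"),
                               mean_nucleus_diameter = NULL,
                               nucleus_fraction = NULL,
                               method = c("number_volume", "delesse"),
                               size_bias_correction = TRUE) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  stopifnot(inherits(table, "section_profile_table"))
  stage <- normalize_stage(table$stage)
  if (!stage %in% c("4A", "4B")) {
    stop("fecundity is estimated for stages 4A and 4B only (got stage ",
         stage, ")")
  }
  plan <- table$plan
  rule <- plan$nucleus_rule
  if (is.null(nucleus_fraction)) {
    nucleus_fraction <- if (!is.null(config)) config$nucleus_fraction else 0.35
  }
  if (is.null(mean_nucleus_diameter)) {
    if (!is.null(config)) {
      mean_nucleus_diameter <- config_mean_nucleus(config, stage)
    } else if (rule == "intersect") {
      stop("mean_nucleus_diameter is required under the 'intersect' rule ",
           "when no generator config is supplied")
    } else {
      mean_nucleus_diameter <- 0
    }
  }

  g_v <- cavalieri_volume(table$sections$G_a_mm2, plan$spacing)
  pr <- table$profiles
  pr <- pr[!is.na(pr$field_id), , drop = FALSE]
  n_fields <- plan$field_count

  n_hat <- estimate_total_count(pr, n_fields, plan$field_area, plan$thickness,
                                mean_nucleus_diameter, g_v, rule)

  classes <- c("mature", "immature")
  hits <- pr[pr$nucleus_hit, , drop = FALSE]
  mean_ov <- vapply(classes, function(cl) {
    d <- hits[hits$dev_class == cl, , drop = FALSE]
    if (!nrow(d)) return(0)
    ov <- oocyte_volume(d$profile_d_min, d$profile_d_max, mode)
    w <- if (rule == "intersect" && size_bias_correction) {
      1 / (plan$thickness + nucleus_fraction * d$profile_d_max)
    } else {
      rep(1, nrow(d))
    }
    sum(w * ov) / sum(w)
  }, numeric(1))

  if (method == "delesse") {
    tot_area <- vapply(classes, function(cl) {
      d <- pr[pr$dev_class == cl, , drop = FALSE]
      sum(pi / 4 * d$profile_d_max * d$profile_d_min)
    }, numeric(1))
    occ <- 100 * tot_area / (n_fields * plan$field_area)
  } else {
    occ <- ifelse(n_hat > 0 & mean_ov > 0,
                  occupancy_percent(n_hat, mean_ov, g_v), 0)
    names(occ) <- classes
  }

  structure(
    list(specimen_id = table$specimen_id, TL = table$TL, stage = stage,
         G_v_hat = g_v,
         N_hat = n_hat,
         mean_O_v = mean_ov,
         occupancy = c(occ, total = sum(occ)),
         PF = if (stage == "4A") unname(n_hat[["mature"]]) else NA_real_,
         mode = mode, nucleus_rule = rule, method = method,
         size_bias_correction = size_bias_correction),
    class = "fecundity_estimate"
  )
}

#' @export
print.fecundity_estimate <- function(x, ...) {
  cat(sprintf("Fecundity estimate for %s (TL %.1f mm, stage %s)\n",
              x$specimen_id, x$TL, x$stage))
  cat(sprintf("  G_v = %.3g mm^3; N = %.3g mature + %.3g immature\n",
              x$G_v_hat, x$N_hat[["mature"]], x$N_hat[["immature"]]))
  cat(sprintf("  occupancy: mature %.2f%%, immature %.2f%% (total %.2f%%)\n",
              x$occupancy[["mature"]], x$occupancy[["immature"]],
              x$occupancy[["total"]]))
  if (!is.na(x$PF)) cat(sprintf("  PF = %.4g oocytes\n", x$PF))
  cat(sprintf("  [%s volume mode, %s nucleus rule, %s]\n",
              x$mode, x$nucleus_rule, x$method))
  invisible(x)
}

#' @export
as.data.frame.fecundity_estimate <- function(x, ...) {
  data.frame(
    specimen_id = x$specimen_id, TL = x$TL, stage = x$stage,
    G_v_hat = x$G_v_hat,
    N_mature = x$N_hat[["mature"]], N_immature = x$N_hat[["immature"]],
    mean_O_v_mature = x$mean_O_v[["mature"]],
    mean_O_v_immature = x$mean_O_v[["immature"]],
    occ_mature = x$occupancy[["mature"]],
    occ_immature = x$occupancy[["immature"]],
    occ_total = x$occupancy[["total"]],
    PF = x$PF,
    mode = x$mode, nucleus_rule = x$nucleus_rule
  )
}

#' Run the sectioning + estimation chain over a cohort of synthetic gonads
#'
#' For each gonad, places sections and fields (per-specimen seeds derived
#' from `seed`), restricts profiles to the fields, and estimates fecundity.
#'
#' @param gonads list of `gonad_model` objects.
#' @param plan a [section_plan()].
#' @param config the [generator_config()] the gonads were built with
#'   (supplies nucleus geometry to the estimator).
#' @param seed integer seed controlling field placement.
#' @param ... passed to [estimate_fecundity()].
#' @return A data frame with one row per specimen (see
#'   [as.data.frame.fecundity_estimate()]).
#' @export
estimate_cohort <- function(gonads, plan = section_plan(),
                            config = generator_config(), seed = NULL, ...) {
  rows <- lapply(seq_along(gonads), function(i) {
    tab <- section_and_sample(gonads[[i]], plan,
                              seed = derive_seed(
                                if (is.null(seed)) 0 else seed,
                                paste0("fields-", i)))
    as.data.frame(estimate_fecundity(tab, config = config, ...))
  })
  do.call(rbind, rows)
}

#' Simulate a cohort and estimate it one specimen at a time
#'
#' Memory-light equivalent of [generate_cohort()] followed by
#' [estimate_cohort()]: each gonad is generated, observed and estimated,
#' then discarded, so natural-size cohorts (~1e6 oocytes per organ) never
#' coexist in memory. Seed derivation matches the two-step route exactly,
#' so the results are identical to it.
#'
#' @inheritParams generate_cohort
#' @param plan a [section_plan()].
#' @param sim_seed seed governing shell lengths and gonad generation.
#' @param field_seed seed governing field placement.
#' @param ... passed to [estimate_fecundity()].
#' @return A list with `estimates` (one data-frame row per specimen) and
#'   `truth` (generator ground truth: true volume, counts, occupancy).
#' @export
simulate_and_estimate <- function(n_4A, n_4B, TL_range,
                                  config = generator_config(),
                                  plan = section_plan(),
                                  sim_seed = NULL, field_seed = NULL, ...) {
  stopifnot(length(TL_range) == 2L)
  if (n_4A + n_4B < 1) stop("cohort must contain at least one specimen")
  n <- n_4A + n_4B
  stages <- rep(c("4A", "4B"), c(n_4A, n_4B))
  tls <- with_seed(sim_seed, runif(n, TL_range[1], TL_range[2]))
  est <- vector("list", n)
  tru <- vector("list", n)
  for (i in seq_len(n)) {
    g <- generate_gonad(tls[i], stages[i], config,
                        seed = derive_seed(
                          if (is.null(sim_seed)) 0 else sim_seed,
                          paste0("gonad-", i)),
                        specimen_id = sprintf("sim-%03d", i))
    tab <- section_and_sample(g, plan,
                              seed = derive_seed(
                                if (is.null(field_seed)) 0 else field_seed,
                                paste0("fields-", i)))
    est[[i]] <- as.data.frame(estimate_fecundity(tab, config = config, ...))
    tru[[i]] <- data.frame(
      specimen_id = g$specimen_id, TL = g$TL, stage = g$stage,
      true_volume = g$true_volume,
      true_N_mature = g$true_counts[["mature"]],
      true_N_immature = g$true_counts[["immature"]],
      true_occ_total = g$true_occupancy[["total"]])
  }
  list(estimates = do.call(rbind, est), truth = do.call(rbind, tru))
}
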