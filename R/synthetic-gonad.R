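#' Generate one synthetic 3-D gonad
#'
#' Builds a simulated gonad for a female of shell length `TL` in maturity
#' stage 4A (ripe) or 4B (partially spawned). The organ is a prolate
#' ellipsoid (2:1:1 axes) whose volume follows the configured G_v ~ TL line;
#' oocytes are oblate spheroids (equatorial diameter d_max, polar diameter
#' d_min) with a concentric spherical nucleus, placed uniformly at random
#' inside the organ with independent uniform orientations (a Boolean
#' germ-grain model: overlap is permitted).
#'
#' In `"occupancy"` calibration mode oocytes of each developmental class are
#' added until the class's geometric volume fraction matches the configured
#' target (within a small fraction of one oocyte volume); in `"count"` mode
#' the number of mature oocytes is drawn from the configured PF ~ TL line
#' with multiplicative lognormal noise and occupancy is emergent.
#'
#' @param TL shell total length (mm).
#' @param stage `"4A"` or `"4B"` (prefixed forms `"F4A"`/`"F4B"` accepted).
#' @param config a [generator_config()].
#' @param seed integer seed; identical `(config, seed)` give bit-identical
#'   gonads.
#' @param specimen_id identifier stored in the model.
#' @return An object of class `gonad_model`: a list with elements
#'   `specimen_id`, `TL`, `sex`, `stage`, `region` (ellipsoid semi-axes, um),
#'   `true_volume` (mm^3), `oocytes` (numeric matrix, one row per oocyte),
#'   `true_counts` and `true_occupancy` (named per class, percent).
#' @examples
#' g <- generate_gonad(25, "4A", generator_config(gv_noise_cv = 0), seed = 1)
#' g$true_volume   # 17.2*25 - 304.5 = 125.5 mm^3
#' g$true_occupancy
#' @export
generate_gonad <- function(TL, stage, config = generator_config(), seed = NULL,
                           specimen_id = "sim-1") {
  stage <- normalize_stage(stage)
  if (!stage %in% names(config$occupancy)) {
    stop("stage must be one of ", paste(names(config$occupancy), collapse = ", "),
         " (got ", stage, ")")
  }
  with_seed(seed, {
    gv_line <- config$gv_slope * TL + config$gv_intercept
    if (gv_line <= 0) {
      stop("computed gonad volume is not positive at TL = ", TL,
           " mm (slope ", config$gv_slope, ", intercept ", config$gv_intercept,
           "): increase TL or adjust the G_v coefficients")
    }
    noise <- if (config$gv_noise_cv > 0) rlnorm_cv1(1, config$gv_noise_cv) else 1
    v_mm3 <- gv_line * noise * config$volume_scale
    v_um3 <- mm3_to_um3(v_mm3)
    # Prolate ellipsoid, semi-axes (c, r, r) with c = 2r: V = (8/3) pi r^3.
    r <- (3 * v_um3 / (8 * pi))^(1 / 3)
    semi <- c(a = 2 * r, b = r, c = r)  # a along the section axis (z)

    classes <- c("mature", "immature")
    n_per_class <- integer(2L)
    names(n_per_class) <- classes
    draws <- list()
    for (cl in classes) {
      target_frac <- config$occupancy[[stage]][[cl]] / 100
      if (config$calibration_mode == "count" && cl == "mature") {
        pf_line <- config$pf_slope * TL + config$pf_intercept
        if (pf_line <= 0) {
          stop("PF regression gives a non-positive count at TL = ", TL, " mm")
        }
        n_target <- pf_line *
          (if (config$pf_noise_cv > 0) rlnorm_cv1(1, config$pf_noise_cv) else 1)
        dd <- draw_oocyte_sizes(round(n_target), stage, cl, config)
      } else if (config$calibration_mode == "count") {
        # Immature count from the occupancy target's expected count, noised.
        cs <- config$classes[[stage]][[cl]]
        mean_ov <- pi / 6 * mean(config$aspect_range) * cs$mean_dmax^3
        n_target <- target_frac * v_um3 / mean_ov *
          (if (config$pf_noise_cv > 0) rlnorm_cv1(1, config$pf_noise_cv) else 1)
        dd <- draw_oocyte_sizes(max(round(n_target), 0), stage, cl, config)
      } else {
        dd <- draw_sizes_to_occupancy(target_frac * v_um3, stage, cl, config,
                                      v_um3)
      }
      n_per_class[[cl]] <- nrow(dd)
      draws[[cl]] <- dd
    }
    sizes <- rbind(draws$mature, draws$immature)
    n <- nrow(sizes)
    cls <- rep(c(1L, 2L), n_per_class)  # 1 = mature, 2 = immature

    pos <- runif_ellipsoid(n, semi)        # centered coordinates
    pos[, 3] <- pos[, 3] + semi[["a"]]     # z in [0, 2a]
    ori <- runif_sphere(n)
    oocytes <- cbind(
      x = pos[, 1], y = pos[, 2], z = pos[, 3],
      d_max = sizes[, "d_max"], d_min = sizes[, "d_min"],
      ux = ori[, 1], uy = ori[, 2], uz = ori[, 3],
      nucleus_d = config$nucleus_fraction * sizes[, "d_max"],
      class = cls
    )
    vol <- pi / 6 * sizes[, "d_min"] * sizes[, "d_max"]^2
    occ <- c(
      mature = 100 * sum(vol[cls == 1L]) / v_um3,
      immature = 100 * sum(vol[cls == 2L]) / v_um3
    )
    structure(
      list(
        specimen_id = specimen_id, TL = TL, sex = "F", stage = stage,
        region = semi, true_volume = v_mm3,
        oocytes = oocytes,
        true_counts = n_per_class,
        true_occupancy = c(occ, total = sum(occ)),
        config_mode = config$calibration_mode
      ),
      class = "gonad_model"
    )
  })
}

# Lognormal multiplicative noise with mean exactly 1 and the given CV.
rlnorm_cv1 <- function(n, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' @importFrom stats rlnorm
NULL

normalize_stage <- function(stage) {
  s <- toupper(as.character(stage))
  sub("^[FM]", "", s)
}

# Draw n (d_max, d_min) pairs for one stage/class.
draw_oocyte_sizes <- function(n, stage, cl, config) {
  cs <- config$classes[[stage]][[cl]]
  if (n <= 0) {
    return(cbind(d_max = numeric(0), d_min = numeric(0)))
  }
  d_max <- rtruncnorm(n, cs$location, cs$sd, cs$lo, cs$hi)
  aspect <- runif(n, config$aspect_range[1], config$aspect_range[2])
  cbind(d_max = d_max, d_min = aspect * d_max)
}

# Add oocytes until the class volume crosses target_vol; stop at whichever
# side of the crossing is closer, so the realized occupancy is within one
# oocyte volume of the target.
draw_sizes_to_occupancy <- function(target_vol, stage, cl, config, v_um3) {
  cs <- config$classes[[stage]][[cl]]
  mean_ov <- pi / 6 * mean(config$aspect_range) * cs$mean_dmax^3
  if (mean_ov >= v_um3) {
    stop("occupancy target for class '", cl, "' (stage ", stage,
         ") is unreachable: a typical oocyte (~", signif(mean_ov, 3),
         " um^3) is larger than the gonad region (", signif(v_um3, 3), " um^3)")
  }
  acc <- cbind(d_max = numeric(0), d_min = numeric(0))
  cum <- 0
  repeat {
    n_need <- max(ceiling((target_vol - cum) / mean_ov * 1.02), 64L)
    dd <- draw_oocyte_sizes(n_need, stage, cl, config)
    vol <- pi / 6 * dd[, "d_min"] * dd[, "d_max"]^2
    cv <- cum + cumsum(vol)
    hit <- which(cv >= target_vol)
    if (length(hit)) {
      k <- hit[1]
      # keep k or k-1 oocytes, whichever realized volume is closer to target
      over <- cv[k] - target_vol
      under <- target_vol - (if (k > 1) cv[k - 1] else cum)
      keep <- if (over <= under) k else k - 1L
      acc <- rbind(acc, dd[seq_len(keep), , drop = FALSE])
      return(acc)
    }
    acc <- rbind(acc, dd)
    cum <- cv[length(cv)]
  }
}

# n uniform points in the ellipsoid with the given semi-axes (centered).
runif_ellipsoid <- function(n, semi) {
  if (n == 0) return(matrix(numeric(0), 0, 3))
  z <- matrix(rnorm(3 * n), n, 3)
  z <- z / sqrt(rowSums(z^2))
  rad <- runif(n)^(1 / 3)
  p <- z * rad
  cbind(p[, 2] * semi[["b"]], p[, 3] * semi[["c"]], p[, 1] * semi[["a"]])
}

#' @importFrom stats rnorm
NULL

# n uniform unit vectors (oocyte symmetry-axis orientations).
runif_sphere <- function(n) {
  if (n == 0) return(matrix(numeric(0), 0, 3))
  z <- matrix(rnorm(3 * n), n, 3)
  z / sqrt(rowSums(z^2))
}

#' @export
print.gonad_model <- function(x, ...) {
  cat(sprintf("Synthetic gonad %s: TL %.1f mm, stage %s\n",
              x$specimen_id, x$TL, x$stage))
  cat(sprintf("  true volume %.3g mm^3; %d mature + %d immature oocytes\n",
              x$true_volume, x$true_counts[["mature"]],
              x$true_counts[["immature"]]))
  cat(sprintf("  true occupancy: mature %.2f%%, immature %.2f%% (total %.2f%%)\n",
              x$true_occupancy[["mature"]], x$true_occupancy[["immature"]],
              x$true_occupancy[["total"]]))
  invisible(x)
}

#' Oocyte ground-truth table of a synthetic gonad
#'
#' @param x a `gonad_model`.
#' @param ... unused.
#' @return A data frame with one row per oocyte (positions and diameters in
#'   micrometres) and a `dev_class` factor.
#' @export
as.data.frame.gonad_model <- function(x, ...) {
  oo <- as.data.frame(x$oocytes)
  oo$dev_class <- factor(c("mature", "immature")[oo$class],
                         levels = c("mature", "immature"))
  oo$class <- NULL
  oo$oocyte_id <- seq_len(nrow(oo))
  oo$specimen_id <- x$specimen_id
  oo[, c("specimen_id", "oocyte_id", "x", "y", "z", "d_max", "d_min",
         "ux", "uy", "uz", "nucleus_d", "dev_class")]
}

#' Generate a cohort of synthetic gonads
#'
#' Shell lengths are sampled uniformly over `TL_range`; each gonad gets an
#' independent seed derived from `seed`, so cohorts are reproducible and any
#' single specimen can be regenerated in isolation.
#'
#' @param n_4A,n_4B number of ripe (4A) and partially spawned (4B) females.
#' @param TL_range length-2 range of shell length (mm).
#' @param config a [generator_config()].
#' @param seed integer seed.
#' @return A list of [generate_gonad()] models, 4A specimens first.
#' @examples
#' coh <- generate_cohort(2, 1, c(19, 33), generator_config(), seed = 1)
#' vapply(coh, function(g) g$stage, "")
#' @export
generate_cohort <- function(n_4A, n_4B, TL_range, config = generator_config(),
                            seed = NULL) {
  stopifnot(length(TL_range) == 2L)
  if (n_4A + n_4B < 1) stop("cohort must contain at least one specimen")
  if (TL_range[1] > TL_range[2]) stop("empty TL range")
  n <- n_4A + n_4B
  stages <- rep(c("4A", "4B"), c(n_4A, n_4B))
  tls <- with_seed(seed, runif(n, TL_range[1], TL_range[2]))
  lapply(seq_len(n), function(i) {
    generate_gonad(tls[i], stages[i], config,
                   seed = derive_seed(if (is.null(seed)) 0 else seed,
                                      paste0("gonad-", i)),
                   specimen_id = sprintf("sim-%03d", i))
  })
}

#' Generate a size-at-maturity sample
#'
#' Each record draws a shell length uniformly over `TL_range` and a maturity
#' flag from the logistic ogive P(mature | TL) = 1/(1 + exp(-(a + b TL))).
#'
#' @param n number of individuals.
#' @param TL_range length-2 range of shell length (mm).
#' @param a,b logistic intercept and slope; default to the package ogive
#'   (TL50 = 11.2 mm).
#' @param seed integer seed.
#' @return A data frame of maturity records: `specimen_id`, `TL`, `sex`
#'   (`"F"`/`"M"`, balanced at random), `mature` (logical).
#' @examples
#' m <- generate_maturity_sample(10, c(4, 36), seed = 3)
#' table(m$mature)
#' @export
generate_maturity_sample <- function(n, TL_range,
                                     a = generator_config()$ogive_a,
                                     b = generator_config()$ogive_b,
                                     seed = NULL) {
  if (b == 0) stop("b = 0 gives an undefined TL50 (= -a/b)")
  stopifnot(n >= 0, length(TL_range) == 2L, TL_range[1] <= TL_range[2])
  if (n == 0) {
    return(data.frame(specimen_id = character(0), TL = numeric(0),
                      sex = character(0), mature = logical(0)))
  }
  with_seed(seed, {
    tl <- runif(n, TL_range[1], TL_range[2])
    p <- 1 / (1 + exp(-(a + b * tl)))
    data.frame(
      specimen_id = sprintf("mat-%04d", seq_len(n)),
      TL = tl,
      sex = sample(c("F", "M"), n, replace = TRUE),
      mature = runif(n) < p
    )
  })
}

#' @importFrom stats runif
NULL
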