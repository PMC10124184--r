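#' Serial sectioning plan
#'
#' Describes the virtual histological observation process: section thickness
#' and spacing along the gonad's major axis, the number of microscope fields
#' per gonad, the field dimensions, and the rule deciding when a profile
#' counts as "sectioned through the nucleus".
#'
#' The defaults mirror a standard protocol for venerid clams: one 6-um-thick
#' section every 100 um, with 6 randomly positioned fields per gonad read at
#' 10x magnification.
#'
#' @param thickness section thickness (um).
#' @param spacing distance between section starts (um); must be >= thickness.
#' @param field_count number of microscope fields per gonad, allocated
#'   round-robin across sections that can contain a field.
#' @param field_dim width and height of one field (um); the default is a
#'   10x camera field of 870 x 660 um.
#' @param nucleus_rule `"intersect"` (the slab geometrically intersects the
#'   nucleus sphere — what an observer sees; counts must be de-biased with
#'   the Abercrombie correction) or `"center"` (the slab contains the nucleus
#'   center — a correction-free unbiased counting rule, used as an internal
#'   oracle).
#' @return An object of class `section_plan`.
#' @examples
#' section_plan()
#' @export
section_plan <- function(thickness = 6, spacing = 100, field_count = 6,
                         field_dim = c(870, 660),
                         nucleus_rule = c("intersect", "center")) {
  nucleus_rule <- match.arg(nucleus_rule)
  if (spacing <= 0) stop("spacing must be positive")
  if (thickness <= 0 || thickness > spacing) {
    stop("need 0 < thickness <= spacing (got thickness ", thickness,
         ", spacing ", spacing, ")")
  }
  stopifnot(length(field_dim) == 2L, all(field_dim > 0), field_count >= 1)
  structure(
    list(thickness = thickness, spacing = spacing,
         field_count = as.integer(field_count), field_dim = field_dim,
         field_area = prod(field_dim), nucleus_rule = nucleus_rule),
    class = "section_plan"
  )
}

#' @export
print.section_plan <- function(x, ...) {
  cat(sprintf(
    "Section plan: %g-um sections every %g um; %d fields of %g x %g um (%s rule)\n",
    x$thickness, x$spacing, x$field_count, x$field_dim[1], x$field_dim[2],
    x$nucleus_rule))
  invisible(x)
}

# ---- slab/spheroid geometry -------------------------------------------------
# An oocyte is an oblate spheroid: equatorial diameter d_max (two axes),
# polar diameter d_min along the unit symmetry axis u. Its covariance-form
# matrix is Sigma = A^2 I + (C^2 - A^2) u u', A = d_max/2, C = d_min/2.
# For a horizontal plane at offset delta from the center:
#   * intersection is nonempty iff delta^2 < Sigma_zz,
#   * the section ellipse has semi-axes  A*sqrt(k)  and  (A*C/sqrt(Sigma_zz))*sqrt(k)
#     with k = 1 - delta^2/Sigma_zz (every central section of a spheroid has
#     semi-major axis exactly A),
#   * its center is offset in-plane by delta * Sigma_pz / Sigma_zz.
# The profile reported for a slab is taken at the plane inside the slab
# closest to the oocyte center (thin sections approximate a single plane).

# Precomputed per-oocyte slab geometry: axial half-extent of each spheroid.
oocyte_z_geometry <- function(oo) {
  A <- oo[, "d_max"] / 2
  C <- oo[, "d_min"] / 2
  szz <- A^2 + (C^2 - A^2) * oo[, "uz"]^2
  list(A = A, C = C, szz = szz, h = sqrt(szz))
}

# Vectorized profile of many oocytes against one slab [z0, z1).
# `oo` is the gonad oocyte matrix; `geom` an oocyte_z_geometry(); `cand` an
# optional pre-filter of candidate rows. Returns a data frame (possibly 0-row).
slab_profiles_matrix <- function(oo, z0, z1, nucleus_rule,
                                 geom = oocyte_z_geometry(oo), cand = NULL) {
  zc_all <- oo[, "z"]
  if (is.null(cand)) cand <- seq_len(nrow(oo))
  h_c <- geom$h[cand]
  zc_c <- zc_all[cand]
  sel <- cand[zc_c > z0 - h_c & zc_c < z1 + h_c]
  if (!length(sel)) {
    return(empty_profiles())
  }
  A <- geom$A
  C <- geom$C
  szz <- geom$szz
  h <- geom$h
  zc <- zc_all
  zs <- pmin(pmax(zc[sel], z0), z1)
  delta <- zs - zc[sel]
  k <- 1 - delta^2 / szz[sel]
  k[k < 0] <- 0
  sqk <- sqrt(k)
  p_dmax <- oo[sel, "d_max"] * sqk
  p_dmin <- oo[sel, "d_max"] * C[sel] / h[sel] * sqk
  off <- delta * (C[sel]^2 - A[sel]^2) * oo[sel, "uz"] / szz[sel]
  rn <- oo[sel, "nucleus_d"] / 2
  hit <- if (nucleus_rule == "intersect") {
    zc[sel] - rn < z1 & zc[sel] + rn > z0
  } else {
    zc[sel] >= z0 & zc[sel] < z1
  }
  data.frame(
    oocyte_id = sel,
    dev_class = c("mature", "immature")[oo[sel, "class"]],
    profile_d_max = p_dmax,
    profile_d_min = p_dmin,
    nucleus_hit = hit,
    cx = oo[sel, "x"] + off * oo[sel, "ux"],
    cy = oo[sel, "y"] + off * oo[sel, "uy"]
  )
}

empty_profiles <- function() {
  data.frame(oocyte_id = integer(0), dev_class = character(0),
             profile_d_max = numeric(0), profile_d_min = numeric(0),
             nucleus_hit = logical(0), cx = numeric(0), cy = numeric(0))
}

#' Profile of a single oocyte in one slab
#'
#' Computes the largest in-plane cross-section of a spheroidal oocyte over
#' the planes contained in the slab `[z_start, z_end)`, and whether the slab
#' cuts the nucleus under the given rule.
#'
#' @param center oocyte center, length-3 (um).
#' @param d_max,d_min equatorial and polar diameters (um).
#' @param orientation unit symmetry axis of the spheroid.
#' @param nucleus_d nucleus diameter (um); the nucleus is concentric.
#' @param z_start,z_end slab bounds (um), `z_start < z_end`.
#' @param nucleus_rule `"intersect"` or `"center"`.
#' @return `NULL` when the spheroid misses the slab, else a list with
#'   `profile_d_max`, `profile_d_min` (um), `nucleus_hit`, and the in-plane
#'   profile center `cx`, `cy`.
#' @examples
#' # central cut through a 60-um sphere
#' slab_profile(c(0, 0, 50), 60, 60, c(0, 0, 1), 21, 47, 53)
#' @export
slab_profile <- function(center, d_max, d_min, orientation = c(0, 0, 1),
                         nucleus_d = 0, z_start, z_end,
                         nucleus_rule = c("intersect", "center")) {
  nucleus_rule <- match.arg(nucleus_rule)
  if (z_start >= z_end) stop("need z_start < z_end")
  if (d_min <= 0 || d_max <= 0 || d_min > d_max) {
    stop("need 0 < d_min <= d_max")
  }
  u <- orientation / sqrt(sum(orientation^2))
  oo <- rbind(c(x = center[1], y = center[2], z = center[3],
                d_max = d_max, d_min = d_min,
                ux = u[1], uy = u[2], uz = u[3],
                nucleus_d = nucleus_d, class = 1))
  colnames(oo) <- c("x", "y", "z", "d_max", "d_min", "ux", "uy", "uz",
                    "nucleus_d", "class")
  pr <- slab_profiles_matrix(oo, z_start, z_end, nucleus_rule)
  if (!nrow(pr)) return(NULL)
  list(profile_d_max = pr$profile_d_max, profile_d_min = pr$profile_d_min,
       nucleus_hit = pr$nucleus_hit, cx = pr$cx, cy = pr$cy)
}

# Section geometry of the gonad region: one row per slab with mid-plane
# cross-section area (the cross-sections of the prolate region are circles).
section_geometry <- function(gonad, plan) {
  a <- gonad$region[["a"]]
  L <- 2 * a
  idx <- seq.int(0L, floor((L - 1e-9) / plan$spacing))
  z_start <- idx * plan$spacing
  mid <- z_start + plan$thickness / 2
  rel <- 1 - ((mid - a) / a)^2
  rel[rel < 0] <- 0
  rz <- gonad$region[["b"]] * sqrt(rel)
  area <- pi * gonad$region[["b"]] * gonad$region[["c"]] * rel
  data.frame(section_index = idx, z_start = z_start, z_mid = mid,
             G_a_um2 = area, G_a_mm2 = area / UM2_PER_MM2, R_z = rz)
}

#' Cut a synthetic gonad into serial sections
#'
#' Applies the sectioning plan to a [generate_gonad()] model: slabs tile the
#' gonad's axial extent at the plan spacing, the gonad cross-sectional area
#' `G_a` is evaluated analytically at each slab mid-plane, and every oocyte
#' whose spheroid intersects a slab contributes one profile row per slab.
#'
#' @param gonad a `gonad_model`.
#' @param plan a [section_plan()].
#' @return An object of class `section_profile_table`: a list with
#'   `profiles` (one row per oocyte-slab intersection), `sections` (per-slab
#'   `G_a` in mm^2 and cross-section radius), the `plan`, and specimen
#'   metadata. Profiles carry `field_id = NA` until [sample_fields()].
#' @examples
#' cfg <- generator_config(gv_noise_cv = 0, volume_scale = 1e-4)
#' g <- generate_gonad(25, "4A", cfg, seed = 1)
#' tab <- section_gonad(g, section_plan())
#' head(tab$profiles)
#' @export
section_gonad <- function(gonad, plan = section_plan()) {
  stopifnot(inherits(gonad, "gonad_model"), inherits(plan, "section_plan"))
  geom <- section_geometry(gonad, plan)
  ogeom <- oocyte_z_geometry(gonad$oocytes)
  profs <- lapply(seq_len(nrow(geom)), function(i) {
    pr <- slab_profiles_matrix(gonad$oocytes, geom$z_start[i],
                               geom$z_start[i] + plan$thickness,
                               plan$nucleus_rule, geom = ogeom)
    if (nrow(pr)) {
      pr$section_index <- geom$section_index[i]
      pr$z_start <- geom$z_start[i]
    }
    pr
  })
  profs <- do.call(rbind, profs[vapply(profs, nrow, 0L) > 0])
  if (is.null(profs)) {
    profs <- cbind(empty_profiles(),
                   data.frame(section_index = integer(0), z_start = numeric(0)))
  }
  profs$field_id <- NA_integer_
  new_section_table(gonad, plan, profs, geom)
}

new_section_table <- function(gonad, plan, profiles, sections) {
  structure(
    list(specimen_id = gonad$specimen_id, TL = gonad$TL, stage = gonad$stage,
         plan = plan,
         profiles = profiles[, c("section_index", "z_start", "field_id",
                                 "oocyte_id", "dev_class", "profile_d_max",
                                 "profile_d_min", "nucleus_hit", "cx", "cy")],
         sections = sections),
    class = "section_profile_table"
  )
}

#' @export
print.section_profile_table <- function(x, ...) {
  cat(sprintf(
    "Section profiles for %s (stage %s): %d sections, %d profile rows%s\n",
    x$specimen_id, x$stage, nrow(x$sections), nrow(x$profiles),
    if (all(is.na(x$profiles$field_id))) "" else " (field-restricted)"))
  invisible(x)
}

# ---- microscope fields ------------------------------------------------------

# Deterministic field placement. Fields go to `field_count` sections spread
# evenly among those whose cross-section can contain a whole field; each
# field center is drawn uniformly inside the cross-section, rejected until
# the whole rectangle lies inside the (circular) cross-section.
place_fields <- function(sections, plan, seed) {
  half_diag <- sqrt(sum((plan$field_dim / 2)^2))
  elig <- sections[sections$R_z >= half_diag, , drop = FALSE]
  if (!nrow(elig)) {
    stop("no section cross-section can contain a ", plan$field_dim[1], " x ",
         plan$field_dim[2], " um field")
  }
  pick <- elig$section_index[
    round(seq(1, nrow(elig), length.out = plan$field_count))]
  with_seed(seed, {
    out <- lapply(seq_along(pick), function(j) {
      rz <- sections$R_z[sections$section_index == pick[j]]
      w2 <- plan$field_dim[1] / 2
      h2 <- plan$field_dim[2] / 2
      # centers for which the whole rectangle fits in the circular
      # cross-section lie inside this box; sample it and reject corners out
      bx <- sqrt(max(rz^2 - h2^2, 0)) - w2
      by <- sqrt(max(rz^2 - w2^2, 0)) - h2
      if (bx <= 0 || by <= 0) {
        return(data.frame(field_id = j, section_index = pick[j],
                          cx = 0, cy = 0))
      }
      for (i in 1:10000) {
        cx <- runif(1, -bx, bx)
        cy <- runif(1, -by, by)
        if ((abs(cx) + w2)^2 + (abs(cy) + h2)^2 <= rz^2) {
          return(data.frame(field_id = j, section_index = pick[j],
                            cx = cx, cy = cy))
        }
      }
      stop("failed to place a field inside section ", pick[j])
    })
    do.call(rbind, out)
  })
}

#' Restrict section profiles to randomly placed microscope fields
#'
#' Places `plan$field_count` rectangular fields uniformly inside the section
#' cross-sections (spread round-robin over the sections large enough to hold
#' a whole field) and keeps only the profiles whose centers fall inside a
#' field. Placements are reproducible under `seed`.
#'
#' @param table a [section_gonad()] result.
#' @param plan a [section_plan()]; defaults to the plan stored in `table`.
#' @param seed integer seed for field placement.
#' @return A `section_profile_table` whose `profiles` are field-restricted
#'   (with `field_id` filled in) and which carries the field layout in
#'   `$fields`.
#' @export
sample_fields <- function(table, plan = table$plan, seed = NULL) {
  stopifnot(inherits(table, "section_profile_table"))
  if (!any(table$sections$G_a_mm2 > 0)) {
    stop("no section with positive cross-section area")
  }
  fields <- place_fields(table$sections, plan, seed)
  pr <- table$profiles
  keep <- lapply(seq_len(nrow(fields)), function(j) {
    f <- fields[j, ]
    sel <- pr$section_index == f$section_index &
      abs(pr$cx - f$cx) <= plan$field_dim[1] / 2 &
      abs(pr$cy - f$cy) <= plan$field_dim[2] / 2
    rows <- pr[sel, , drop = FALSE]
    if (nrow(rows)) rows$field_id <- f$field_id
    rows
  })
  out <- table
  out$plan <- plan
  out$profiles <- do.call(rbind, keep)
  if (is.null(out$profiles)) out$profiles <- pr[0, , drop = FALSE]
  rownames(out$profiles) <- NULL
  out$fields <- fields
  out
}

#' Section a gonad and sample fields in one pass
#'
#' Equivalent to [section_gonad()] followed by [sample_fields()] (identical
#' field placements and retained rows under the same seed — the test suite
#' exercises the equivalence), but only the field-bearing slabs are ever
#' intersected with the oocyte list, which makes it the practical route for
#' natural-size organs with ~1e6 oocytes.
#'
#' @param gonad a `gonad_model`.
#' @param plan a [section_plan()].
#' @param seed integer seed for field placement.
#' @return A field-restricted `section_profile_table`.
#' @examples
#' cfg <- generator_config(gv_noise_cv = 0)
#' g <- generate_gonad(25, "4A", cfg, seed = 1)
#' tab <- observe_gonad(g, section_plan(), seed = 2)
#' estimate_fecundity(tab, config = cfg)
#' @export
observe_gonad <- function(gonad, plan = section_plan(), seed = NULL) {
  section_and_sample(gonad, plan, seed)
}

# Fast path used by the pipeline: identical field placements and retained
# rows as section_gonad() + sample_fields(), but only the field-bearing
# slabs are ever intersected with the oocyte list. Exercised against the
# full path in the test suite.
section_and_sample <- function(gonad, plan = section_plan(), seed = NULL) {
  geom <- section_geometry(gonad, plan)
  fields <- place_fields(geom, plan, seed)
  ogeom <- oocyte_z_geometry(gonad$oocytes)
  # presort by center z so each slab only examines nearby oocytes
  ord <- order(gonad$oocytes[, "z"])
  z_sorted <- gonad$oocytes[ord, "z"]
  h_max <- if (length(ogeom$h)) max(ogeom$h) else 0
  rows <- lapply(seq_len(nrow(fields)), function(j) {
    f <- fields[j, ]
    z0 <- geom$z_start[geom$section_index == f$section_index]
    lohi <- findInterval(c(z0 - h_max, z0 + plan$thickness + h_max), z_sorted)
    cand <- if (lohi[2] > lohi[1]) ord[(lohi[1] + 1):lohi[2]] else integer(0)
    pr <- slab_profiles_matrix(gonad$oocytes, z0, z0 + plan$thickness,
                               plan$nucleus_rule, geom = ogeom, cand = cand)
    sel <- abs(pr$cx - f$cx) <= plan$field_dim[1] / 2 &
      abs(pr$cy - f$cy) <= plan$field_dim[2] / 2
    pr <- pr[sel, , drop = FALSE]
    if (nrow(pr)) {
      pr$section_index <- f$section_index
      pr$z_start <- z0
      pr$field_id <- f$field_id
    } else {
      pr$section_index <- integer(0)
      pr$z_start <- numeric(0)
      pr$field_id <- integer(0)
    }
    pr
  })
  rows <- do.call(rbind, rows)
  tab <- new_section_table(gonad, plan, rows, geom)
  tab$fields <- fields
  tab
}

#' Write a section profile table to CSV
#'
#' Emits two plain-text files: the per-profile table (column order:
#' specimen_id, section_index, z_start, field_id, oocyte_id, dev_class,
#' profile_d_max, profile_d_min, nucleus_hit) and the per-section gonad
#' area table (specimen_id, section_index, G_a_mm2).
#'
#' @param table a `section_profile_table`.
#' @param profiles_csv,areas_csv output paths.
#' @return Invisibly, the two paths.
#' @export
write_section_csv <- function(table, profiles_csv, areas_csv) {
  pr <- table$profiles
  pr$specimen_id <- table$specimen_id
  write.csv(pr[, c("specimen_id", "section_index", "z_start", "field_id",
                   "oocyte_id", "dev_class", "profile_d_max", "profile_d_min",
                   "nucleus_hit")],
            profiles_csv, row.names = FALSE)
  ga <- table$sections
  ga$specimen_id <- table$specimen_id
  write.csv(ga[, c("specimen_id", "section_index", "G_a_mm2")],
            areas_csv, row.names = FALSE)
  invisible(c(profiles_csv, areas_csv))
}
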