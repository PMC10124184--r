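#' Assemble a pipeline run configuration
#'
#' Bundles everything one end-to-end run needs: the cohort design, the
#' generator parameters, the sectioning plan, estimator flags, the MCRS
#' scenario sizes, the master seed and an optional output directory.
#' Per-stage seeds are derived deterministically from the master seed (see
#' [derive_seed()]), so stages can be rerun in isolation.
#'
#' @param n_4A,n_4B cohort composition (ripe / partially spawned females).
#' @param TL_range shell length range (mm), sampled uniformly.
#' @param generator named list of [generator_config()] overrides.
#' @param plan named list of [section_plan()] overrides.
#' @param estimator named list: `mode`, `method`, `size_bias_correction`
#'   (see [estimate_fecundity()]).
#' @param mcrs named list with `new` and `old` sizes (mm).
#' @param seed integer master seed.
#' @param out_dir output directory, or `NULL` for no file output.
#' @return A list of class `run_config`.
#' @examples
#' cfg <- run_config(n_4A = 3, n_4B = 2, seed = 1)
#' @export
run_config <- function(n_4A = 20, n_4B = 6, TL_range = c(19, 33),
                       generator = list(), plan = list(),
                       estimator = list(), mcrs = list(),
                       seed = 1, out_dir = NULL) {
  cfg <- list(
    n_4A = n_4A, n_4B = n_4B, TL_range = TL_range,
    generator = generator, plan = plan,
    estimator = utils::modifyList(
      list(mode = "corrected", method = "number_volume",
           size_bias_correction = TRUE),
      estimator),
    mcrs = utils::modifyList(list(new = 22, old = 25), mcrs),
    seed = seed, out_dir = out_dir
  )
  class(cfg) <- "run_config"
  validate_config(cfg)
}

#' Validate a pipeline configuration
#'
#' Accepts a `run_config`, a plain named list, or a path to a YAML/JSON
#' file. Unknown keys are rejected (no silent typos), defaults are filled
#' in, and unit mistakes are caught by range checks (e.g. a section spacing
#' below 1 um was almost certainly given in mm).
#'
#' @param config configuration list or file path.
#' @return A validated `run_config` with all defaults explicit.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  stopifnot(is.list(config))
  known <- c("n_4A", "n_4B", "TL_range", "generator", "plan", "estimator",
             "mcrs", "seed", "out_dir")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         "; valid keys: ", paste(known, collapse = ", "))
  }
  if (!is.null(config$plan)) {
    pk <- setdiff(names(config$plan),
                  c("thickness", "spacing", "field_count", "field_dim",
                    "nucleus_rule"))
    if (length(pk)) stop("unknown plan key(s): ", paste(pk, collapse = ", "))
    sp <- config$plan$spacing
    if (!is.null(sp) && sp < 1) {
      stop("plan spacing ", sp, " um is implausibly small - was it given in mm?")
    }
  }
  if (!is.null(config$generator)) {
    gk <- setdiff(names(config$generator), names(formals(generator_config)))
    if (length(gk)) {
      stop("unknown generator key(s): ", paste(gk, collapse = ", "))
    }
  }
  defaults <- list(
    n_4A = 20, n_4B = 6, TL_range = c(19, 33),
    generator = list(), plan = list(),
    estimator = list(mode = "corrected", method = "number_volume",
                     size_bias_correction = TRUE),
    mcrs = list(new = 22, old = 25), seed = 1, out_dir = NULL
  )
  cfg <- utils::modifyList(defaults, config[!vapply(config, is.null, TRUE)])
  if (cfg$n_4A + cfg$n_4B < 1) {
    stop("configuration requests an empty cohort (n_4A + n_4B = 0)")
  }
  # build the component objects once, so errors surface at validation time
  do.call(generator_config, cfg$generator)
  do.call(section_plan, cfg$plan)
  class(cfg) <- "run_config"
  cfg
}

#' Write a run configuration to YAML
#'
#' @param config a `run_config`.
#' @param path output path.
#' @return The path, invisibly. `validate_config(path)` restores the
#'   configuration losslessly.
#' @export
write_config <- function(config, path) {
  cfg <- unclass(config)
  cfg <- cfg[!vapply(cfg, is.null, TRUE)]
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Run the full simulate-section-estimate-summarize pipeline
#'
#' Generates a cohort of synthetic gonads, pushes every specimen through
#' virtual sectioning and field sampling, estimates per-specimen fecundity,
#' fits the cohort regressions (G_v ~ TL; PF ~ TL over ripe females), builds
#' the MCRS egg-output scenario, and — when both stages are present with at
#' least two females each — the occupancy ANOVA and log-count ANCOVA. When
#' `out_dir` is set, writes `estimates.csv`, `fits.json`, `config.yaml` and
#' a `manifest.json` with MD5 hashes of every emitted file.
#'
#' @param config a [run_config()] (or anything [validate_config()] accepts).
#' @return A list of class `pipeline_result` with `estimates` (data frame),
#'   `gv_fit`, `pf_fit`, `mcrs`, `anova`, `ancova`, `truth` (per-specimen
#'   generator ground truth), and `manifest`.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  stage_ctx <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  gcfg <- do.call(generator_config, config$generator)
  plan <- do.call(section_plan, config$plan)

  sim <- stage_ctx("simulate+estimate", simulate_and_estimate(
    config$n_4A, config$n_4B, config$TL_range, gcfg, plan,
    sim_seed = derive_seed(config$seed, "simulate"),
    field_seed = derive_seed(config$seed, "fields"),
    mode = config$estimator$mode, method = config$estimator$method,
    size_bias_correction = config$estimator$size_bias_correction))
  est <- sim$estimates
  truth <- sim$truth

  gv_fit <- stage_ctx("stats", fit_linear(est$TL, est$G_v_hat))
  ripe <- est[est$stage == "4A", , drop = FALSE]
  pf_fit <- if (nrow(ripe) >= 3) fit_linear(ripe$TL, ripe$PF) else NULL
  mcrs <- if (!is.null(pf_fit)) {
    stage_ctx("mcrs", mcrs_scenario(pf_fit, config$mcrs$new, config$mcrs$old))
  }

  an <- anc <- NULL
  if (min(table(est$stage)) >= 2 && length(unique(est$stage)) == 2) {
    occ_rows <- data.frame(
      specimen_id = rep(est$specimen_id, 2),
      stage = rep(est$stage, 2),
      dev_class = rep(c("mature", "immature"), each = nrow(est)),
      percent = c(est$occ_mature, est$occ_immature)
    )
    an <- stage_ctx("anova", occupancy_anova(occ_rows))
    cnt <- data.frame(
      stage = rep(est$stage, 2),
      dev_class = rep(c("mature", "immature"), each = nrow(est)),
      log_count = log(pmax(c(est$N_mature, est$N_immature), 1)),
      log_TL = log(rep(est$TL, 2))
    )
    anc <- stage_ctx("ancova", count_ancova(cnt))
  }

  manifest <- list(
    package = "stereofec",
    version = as.character(utils::packageVersion("stereofec")),
    seed = config$seed,
    config = unclass(config)[c("n_4A", "n_4B", "TL_range", "generator",
                               "plan", "estimator", "mcrs", "seed")],
    n_specimens = nrow(est)
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    p_est <- file.path(config$out_dir, "estimates.csv")
    write.csv(merge(est, truth[, c("specimen_id", "true_volume",
                                   "true_N_mature", "true_N_immature",
                                   "true_occ_total")],
                    by = "specimen_id"),
              p_est, row.names = FALSE)
    p_fits <- file.path(config$out_dir, "fits.json")
    fits <- list(
      gv = list(slope = gv_fit$slope, intercept = gv_fit$intercept,
                adj_R2 = gv_fit$adj_R2),
      pf = if (!is.null(pf_fit)) {
        list(slope = pf_fit$slope, intercept = pf_fit$intercept,
             adj_R2 = pf_fit$adj_R2)
      },
      mcrs = if (!is.null(mcrs)) {
        list(new = mcrs$mcrs_new, old = mcrs$mcrs_old,
             pf_new = mcrs$pf_new$fit, pf_old = mcrs$pf_old$fit,
             percent_reduction = mcrs$percent_reduction,
             percent_reduction_rounded = mcrs$percent_reduction_rounded)
      }
    )
    jsonlite::write_json(fits, p_fits, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
    p_cfg <- file.path(config$out_dir, "config.yaml")
    cfg_science <- config
    cfg_science$out_dir <- NULL  # keep the manifest independent of the path
    write_config(cfg_science, p_cfg)
    files <- c(p_est, p_fits, p_cfg)
    manifest$files <- as.list(setNames(unname(tools::md5sum(files)),
                                       basename(files)))
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  structure(
    list(estimates = est, truth = truth, gv_fit = gv_fit, pf_fit = pf_fit,
         mcrs = mcrs, anova = an, ancova = anc, manifest = manifest,
         config = config),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("Pipeline run: %d specimens (seed %d)\n",
              nrow(x$estimates), x$config$seed))
  cat(sprintf("  G_v ~ TL: slope %.3g, intercept %.3g (adj R^2 %.2f)\n",
              x$gv_fit$slope, x$gv_fit$intercept, x$gv_fit$adj_R2))
  if (!is.null(x$pf_fit)) {
    cat(sprintf("  PF ~ TL: slope %.3g, intercept %.3g (adj R^2 %.2f)\n",
                x$pf_fit$slope, x$pf_fit$intercept, x$pf_fit$adj_R2))
  }
  if (!is.null(x$mcrs)) {
    cat(sprintf("  MCRS %g vs %g mm: %.1f%% fewer eggs (~%d%%)\n",
                x$mcrs$mcrs_new, x$mcrs$mcrs_old, x$mcrs$percent_reduction,
                x$mcrs$percent_reduction_rounded))
  }
  invisible(x)
}
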