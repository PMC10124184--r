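#' Ordinary least-squares fit of a biological quantity on shell length
#'
#' Simple linear regression (e.g. gonad volume or partial fecundity on TL)
#' with the summaries the downstream prediction and scenario tools need:
#' adjusted R^2, the F test of the slope, residual standard error, and the
#' design summaries (mean and sum of squares of x) required for confidence
#' intervals at new lengths.
#'
#' @param x predictor (shell length TL, mm).
#' @param y response.
#' @return An object of class `tl_linfit`.
#' @examples
#' f <- fit_linear(1:5, 2 * (1:5) + 1)
#' coef(f)          # intercept 1, slope 2
#' f$adj_R2         # 1
#' @export
fit_linear <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  if (var(x) == 0) stop("x is constant; slope is unidentifiable")
  fit <- lm(y ~ x)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  structure(
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         adj_R2 = sm$adj.r.squared,
         F_stat = unname(fstat[1]), df = unname(fstat[2:3]),
         p_value = unname(pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)),
         sigma = sm$sigma, n = n,
         x_mean = mean(x), ssx = sum((x - mean(x))^2),
         x_range = range(x), lm = fit),
    class = "tl_linfit"
  )
}

#' Build a linear fit object from published coefficients
#'
#' For evaluating a regression reported in the literature at new lengths.
#' Without design summaries, predictions are points only (intervals are NA).
#'
#' @param slope,intercept published coefficients.
#' @return A `tl_linfit` carrying only the coefficients.
#' @examples
#' pf_fit <- linear_fit(3.01e4, -5.21e5)   # published PF ~ TL line
#' predict(pf_fit, 22)$fit                  # ~1.4e5 oocytes/female
#' @export
linear_fit <- function(slope, intercept) {
  structure(
    list(slope = slope, intercept = intercept,
         adj_R2 = NA_real_, F_stat = NA_real_, df = c(NA_real_, NA_real_),
         p_value = NA_real_, sigma = NA_real_, n = NA_integer_,
         x_mean = NA_real_, ssx = NA_real_, x_range = c(NA_real_, NA_real_),
         lm = NULL),
    class = "tl_linfit"
  )
}

#' @export
print.tl_linfit <- function(x, ...) {
  cat(sprintf("Linear fit: y = %.4g * x %+.4g\n", x$slope, x$intercept))
  if (!is.na(x$adj_R2)) {
    cat(sprintf("  adj R^2 = %.3f; F_%d,%d = %.1f, p = %.3g; residual SE %.3g (n = %d)\n",
                x$adj_R2, x$df[1], x$df[2], x$F_stat, x$p_value, x$sigma, x$n))
  } else {
    cat("  (coefficients only; no design summaries)\n")
  }
  invisible(x)
}

#' @export
coef.tl_linfit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Predict from a linear fit with a confidence interval
#'
#' Point prediction slope*x0 + intercept with, when design summaries are
#' available, a t-based interval: `"confidence"` (default) for the mean
#' response, `"prediction"` for a new individual. Lengths outside the
#' observed range are flagged via the `extrapolated` column, not refused.
#'
#' @param object a `tl_linfit`.
#' @param newdata numeric vector of predictor values.
#' @param level confidence level.
#' @param interval `"confidence"` or `"prediction"`.
#' @param ... unused.
#' @return Data frame with columns `x`, `fit`, `lwr`, `upr`, `extrapolated`.
#' @export
predict.tl_linfit <- function(object, newdata, level = 0.95,
                              interval = c("confidence", "prediction"), ...) {
  interval <- match.arg(interval)
  x0 <- newdata
  point <- object$slope * x0 + object$intercept
  if (is.na(object$sigma) || is.na(object$ssx)) {
    lwr <- upr <- rep(NA_real_, length(x0))
  } else {
    lev <- 1 / object$n + (x0 - object$x_mean)^2 / object$ssx
    if (interval == "prediction") lev <- lev + 1
    half <- qt(1 - (1 - level) / 2, object$n - 2) * object$sigma * sqrt(lev)
    lwr <- point - half
    upr <- point + half
  }
  extrap <- if (any(is.na(object$x_range))) {
    rep(NA, length(x0))
  } else {
    x0 < object$x_range[1] | x0 > object$x_range[2]
  }
  data.frame(x = x0, fit = point, lwr = lwr, upr = upr, extrapolated = extrap)
}

#' @rdname predict.tl_linfit
#' @param fit a `tl_linfit`.
#' @param x0 predictor value(s).
#' @export
predict_with_ci <- function(fit, x0, level = 0.95,
                            interval = c("confidence", "prediction")) {
  predict(fit, newdata = x0, level = level, interval = interval)
}

#' Egg-output scenario for a change in minimum conservation reference size
#'
#' Evaluates a fecundity-on-length regression at the new and old MCRS and
#' reports the predicted eggs per female at each size, the relative
#' reduction in egg output implied by landing at the new size instead of
#' the old, and the converse relative surplus of the old size over the new.
#' The headline reduction is also rounded to the nearest multiple of 10%.
#'
#' @param fit a `tl_linfit` of PF on TL.
#' @param mcrs_new,mcrs_old new and old MCRS (mm); defaults 22 and 25.
#' @param level confidence level for the per-size prediction intervals.
#' @return An object of class `mcrs_scenario`.
#' @examples
#' sc <- mcrs_scenario(linear_fit(3.01e4, -5.21e5))
#' sc$percent_reduction          # ~39%
#' sc$percent_reduction_rounded  # 40
#' @export
mcrs_scenario <- function(fit, mcrs_new = 22, mcrs_old = 25, level = 0.95) {
  pn <- predict(fit, mcrs_new, level = level)
  po <- predict(fit, mcrs_old, level = level)
  if (pn$fit <= 0 || po$fit <= 0) {
    stop("non-positive predicted fecundity at ", mcrs_new, " or ", mcrs_old,
         " mm; the scenario is undefined")
  }
  red <- 100 * (po$fit - pn$fit) / po$fit
  structure(
    list(mcrs_new = mcrs_new, mcrs_old = mcrs_old,
         pf_new = pn, pf_old = po,
         percent_reduction = red,
         percent_reduction_rounded = round(red / 10) * 10,
         percent_increase = 100 * (po$fit - pn$fit) / pn$fit),
    class = "mcrs_scenario"
  )
}

#' @export
print.mcrs_scenario <- function(x, ...) {
  fmt_ci <- function(p) {
    if (is.na(p$lwr)) sprintf("%.3g", p$fit)
    else sprintf("%.3g (95%% CI %.3g-%.3g)", p$fit, p$lwr, p$upr)
  }
  cat(sprintf("MCRS scenario: %g mm (new) vs %g mm (old)\n",
              x$mcrs_new, x$mcrs_old))
  cat(sprintf("  eggs/female at %g mm: %s\n", x$mcrs_new, fmt_ci(x$pf_new)))
  cat(sprintf("  eggs/female at %g mm: %s\n", x$mcrs_old, fmt_ci(x$pf_old)))
  cat(sprintf("  landing at %g instead of %g mm: %.1f%% fewer eggs (~%d%%)\n",
              x$mcrs_new, x$mcrs_old, x$percent_reduction,
              x$percent_reduction_rounded))
  cat(sprintf("  equivalently, %g-mm females produce %.1f%% more eggs than %g-mm ones\n",
              x$mcrs_old, x$percent_increase, x$mcrs_new))
  invisible(x)
}

# ---- ANOVA / Tukey / ANCOVA -------------------------------------------------

# Type-II sums of squares; falls back to the sequential table when the
# residual SS is exactly zero (degenerate noise-free inputs), where the two
# decompositions coincide on the designs this package builds.
anova_type2 <- function(fit) {
  tryCatch(car::Anova(fit, type = 2), error = function(e) anova(fit))
}

#' Two-way ANOVA of percent gonad occupancy with Tukey contrasts
#'
#' Fixed-effects two-way ANOVA of per-female percent gonad-volume occupancy
#' on Maturity stage (4A/4B) x Oocyte development stage (mature/immature),
#' with type-II sums of squares (the study design is unbalanced), Tukey HSD
#' on the marginal and cell contrasts (studentized-range distribution on
#' the model residual variance with harmonic-mean cell sizes), and a
#' one-way ANOVA of per-female total occupancy on maturity stage.
#'
#' @param rows data frame with columns `specimen_id`, `stage` (4A/4B),
#'   `dev_class` (mature/immature), `percent` — one row per female per
#'   oocyte class.
#' @param conf_level confidence level for the Tukey intervals.
#' @return A list of class `occupancy_anova` with `anova` (type-II table),
#'   `tukey` (data frame: contrast, diff, lwr, upr, p_adj), `oneway`
#'   (one-way ANOVA of total occupancy), and the underlying `lm`.
#' @export
occupancy_anova <- function(rows, conf_level = 0.95) {
  need <- c("specimen_id", "stage", "dev_class", "percent")
  stopifnot(all(need %in% names(rows)))
  rows$stage <- factor(rows$stage)
  rows$dev_class <- factor(rows$dev_class, levels = c("mature", "immature"))
  tab <- table(rows$stage, rows$dev_class)
  if (any(tab < 2)) {
    bad <- which(tab < 2, arr.ind = TRUE)[1, ]
    stop("cell (", rownames(tab)[bad[1]], ", ", colnames(tab)[bad[2]],
         ") has fewer than 2 observations")
  }
  fit <- lm(percent ~ stage * dev_class, data = rows)
  a2 <- anova_type2(fit)

  df_res <- fit$df.residual
  mse <- sum(residuals(fit)^2) / df_res

  cells <- aggregate(percent ~ stage + dev_class, data = rows, FUN = mean)
  cells$n <- aggregate(percent ~ stage + dev_class, data = rows,
                       FUN = length)$percent
  cells$label <- paste(cells$stage, cells$dev_class)

  tukey_row <- function(label, m1, m2, n1, n2, nmeans) {
    nh <- 2 / (1 / n1 + 1 / n2)  # harmonic-mean cell size
    se_diff <- sqrt(2 * mse / nh)
    diff <- m1 - m2
    qcrit <- stats::qtukey(conf_level, nmeans, df_res)
    p <- ptukey(abs(diff) / (se_diff / sqrt(2)), nmeans, df_res,
                lower.tail = FALSE)
    data.frame(contrast = label, diff = diff,
               lwr = diff - qcrit * se_diff / sqrt(2),
               upr = diff + qcrit * se_diff / sqrt(2),
               p_adj = p)
  }

  out <- list()
  # marginal: maturity stage (means of females within stage, pooled classes
  # -> use marginal observation means, as in a main-effects Tukey)
  st <- levels(rows$stage)
  m_st <- tapply(rows$percent, rows$stage, mean)
  n_st <- tapply(rows$percent, rows$stage, length)
  out[[1]] <- tukey_row(paste(st[2], "-", st[1]),
                        m_st[[st[2]]], m_st[[st[1]]],
                        n_st[[st[2]]], n_st[[st[1]]], 2)
  # marginal: oocyte development stage
  m_dc <- tapply(rows$percent, rows$dev_class, mean)
  n_dc <- tapply(rows$percent, rows$dev_class, length)
  out[[2]] <- tukey_row("mature - immature",
                        m_dc[["mature"]], m_dc[["immature"]],
                        n_dc[["mature"]], n_dc[["immature"]], 2)
  # all cell pairs
  cmb <- utils::combn(nrow(cells), 2)
  for (j in seq_len(ncol(cmb))) {
    i1 <- cmb[1, j]; i2 <- cmb[2, j]
    out[[length(out) + 1]] <- tukey_row(
      paste(cells$label[i2], "-", cells$label[i1]),
      cells$percent[i2], cells$percent[i1],
      cells$n[i2], cells$n[i1], nrow(cells))
  }
  tukey <- do.call(rbind, out)
  rownames(tukey) <- NULL

  totals <- aggregate(percent ~ specimen_id + stage, data = rows, FUN = sum)
  oneway <- aov(percent ~ stage, data = totals)

  structure(
    list(anova = a2, tukey = tukey, oneway = summary(oneway),
         cells = cells, lm = fit),
    class = "occupancy_anova"
  )
}

#' @export
print.occupancy_anova <- function(x, ...) {
  cat("Two-way ANOVA of percent gonad occupancy (type-II SS)\n")
  print(x$anova)
  cat("\nTukey HSD contrasts:\n")
  print(x$tukey, row.names = FALSE, digits = 4)
  cat("\nOne-way ANOVA of total occupancy by maturity stage:\n")
  print(x$oneway)
  invisible(x)
}

#' Two-way ANCOVA of log oocyte counts with a log-length covariate
#'
#' Tests for differences in oocyte numbers between maturity stages and
#' oocyte development classes while accounting for shell length. The
#' homogeneity-of-slopes assumption (no covariate-by-factor interaction) is
#' tested first and reported; the main model is then
#' `log_count ~ log_TL + stage * dev_class` with type-II sums of squares.
#' Simple stage effects within each oocyte class are reported as
#' covariate-adjusted means and contrasts (via emmeans).
#'
#' @param rows data frame with columns `stage`, `dev_class`, `log_count`,
#'   `log_TL` — one row per female per oocyte class.
#' @return A list of class `count_ancova` with `slopes_test` (F test of the
#'   covariate-by-factor interactions), `ancova` (type-II table),
#'   `adjusted_means`, `simple_effects` (stage contrasts within class), and
#'   the underlying `lm`.
#' @export
count_ancova <- function(rows) {
  need <- c("stage", "dev_class", "log_count", "log_TL")
  stopifnot(all(need %in% names(rows)))
  rows$stage <- factor(rows$stage)
  rows$dev_class <- factor(rows$dev_class, levels = c("mature", "immature"))

  full <- lm(log_count ~ log_TL * stage * dev_class, data = rows)
  main <- lm(log_count ~ log_TL + stage * dev_class, data = rows)
  if (any(!is.finite(coef(main)))) stop("singular ANCOVA design")
  slopes_test <- anova(main, full)

  a2 <- anova_type2(main)
  emm <- emmeans::emmeans(main, ~ stage | dev_class)
  simple <- summary(emmeans::contrast(emm, method = "pairwise"))

  structure(
    list(slopes_test = slopes_test, ancova = a2,
         adjusted_means = summary(emm), simple_effects = simple, lm = main),
    class = "count_ancova"
  )
}

#' @export
print.count_ancova <- function(x, ...) {
  cat("Homogeneity of slopes (covariate x factor interactions):\n")
  print(x$slopes_test)
  cat("\nTwo-way ANCOVA of log counts (type-II SS, log TL covariate):\n")
  print(x$ancova)
  cat("\nCovariate-adjusted means:\n")
  print(x$adjusted_means)
  cat("\nSimple stage effects within oocyte class:\n")
  print(x$simple_effects)
  invisible(x)
}

#' @importFrom stats qtukey
NULL
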