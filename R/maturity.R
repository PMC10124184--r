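#' Classify a female as mature or immature from oocyte diameters
#'
#' A female is mature when at least one vitellogenic oocyte is present,
#' i.e. any observed maximum diameter exceeds the threshold (60 um by
#' default). An empty observation (no oocytes seen in the smear) satisfies
#' the "only previtellogenic oocytes" criterion vacuously and classifies as
#' immature.
#'
#' @param profile_d_max vector of observed oocyte maximum diameters (um);
#'   may be empty.
#' @param threshold vitellogenesis threshold (um).
#' @return `"mature"` or `"immature"`.
#' @examples
#' classify_female(c(59, 60))  # immature: d_max <= 60 throughout
#' classify_female(60.1)       # mature
#' @export
classify_female <- function(profile_d_max, threshold = 60) {
  if (any(profile_d_max < 0)) stop("negative oocyte diameter")
  if (length(profile_d_max) && any(profile_d_max > threshold)) {
    "mature"
  } else {
    "immature"
  }
}

#' Classify a male as mature or immature
#'
#' Males are mature when spermatozoa with well elongated tails are present.
#'
#' @param has_elongated_spermatozoa logical flag.
#' @return `"mature"` or `"immature"` (vectorized).
#' @export
classify_male <- function(has_elongated_spermatozoa) {
  stopifnot(is.logical(has_elongated_spermatozoa))
  ifelse(has_elongated_spermatozoa, "mature", "immature")
}

#' Fit a logistic size-at-maturity ogive
#'
#' Bins maturity records into size classes, and fits
#' P(mature | TL) = 1 / (1 + exp(-(a + b TL))) by maximum-likelihood
#' binomial regression of the per-class proportion mature on the class
#' midpoint, weighted by class sample size. The length at 50% maturity is
#' TL50 = -a/b, with a delta-method standard error.
#'
#' Records with indeterminate sex (or `NA` maturity) are excluded. Complete
#' separation or a non-increasing fit is reported through the `warnings`
#' field rather than failing.
#'
#' @param records data frame with columns `TL`, `mature` (logical), and
#'   optionally `sex` (`"F"`, `"M"`, `"indeterminate"`).
#' @param sex_filter `"all"`, `"F"` or `"M"`.
#' @param size_class_width width of the TL size classes (mm).
#' @return An object of class `ogive_fit` with elements `a`, `b`, `TL50`,
#'   `se` (named: `a`, `b`, `TL50`), `n_used`, `classes` (per-class
#'   proportions), `sex_filter`, `warnings`, and the underlying `glm`.
#' @examples
#' rec <- generate_maturity_sample(300, c(4, 36), seed = 1)
#' fit <- fit_ogive(rec)
#' coef(fit)
#' predict(fit, newdata = c(10, 11.2, 15))
#' @export
fit_ogive <- function(records, sex_filter = c("all", "F", "M"),
                      size_class_width = 1) {
  sex_filter <- match.arg(sex_filter)
  stopifnot(size_class_width > 0, all(records$TL > 0))
  rec <- records
  if (!is.null(rec$sex)) {
    rec <- rec[rec$sex != "indeterminate", , drop = FALSE]
    if (sex_filter != "all") rec <- rec[rec$sex == sex_filter, , drop = FALSE]
  }
  rec <- rec[!is.na(rec$mature), , drop = FALSE]
  mature <- if (is.logical(rec$mature)) rec$mature else rec$mature == "mature"

  if (length(unique(mature)) < 2L) {
    stop("all records share one maturity outcome; the ogive is unidentifiable")
  }
  mid <- (floor(rec$TL / size_class_width) + 0.5) * size_class_width
  classes <- aggregate(mature, by = list(midpoint = mid),
                       FUN = function(z) c(n = length(z), k = sum(z)))
  classes <- data.frame(midpoint = classes$midpoint,
                        n = classes$x[, "n"], k = classes$x[, "k"])
  classes$prop <- classes$k / classes$n
  if (nrow(classes) < 2L) stop("need at least two size classes")

  warnings <- character(0)
  fit <- withCallingHandlers(
    glm(cbind(k, n - k) ~ midpoint, family = binomial("logit"),
        data = classes),
    warning = function(w) {
      warnings <<- c(warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  cf <- coef(fit)
  a <- unname(cf[1])
  b <- unname(cf[2])
  if (!is.finite(b) || b <= 0) {
    warnings <- c(warnings, "fitted slope is not positive; ogive not monotone increasing in TL")
  }
  vc <- vcov(fit)
  tl50 <- -a / b
  # delta method for TL50 = -a/b
  grad <- c(-1 / b, a / b^2)
  se_tl50 <- sqrt(drop(t(grad) %*% vc %*% grad))
  structure(
    list(a = a, b = b, TL50 = tl50,
         se = c(a = sqrt(vc[1, 1]), b = sqrt(vc[2, 2]), TL50 = se_tl50),
         n_used = nrow(rec), classes = classes, sex_filter = sex_filter,
         size_class_width = size_class_width,
         warnings = warnings, glm = fit),
    class = "ogive_fit"
  )
}

#' @export
print.ogive_fit <- function(x, ...) {
  cat(sprintf("Logistic maturity ogive (%s, %d individuals, %g-mm classes)\n",
              if (x$sex_filter == "all") "both sexes" else paste("sex", x$sex_filter),
              x$n_used, x$size_class_width))
  cat(sprintf("  a = %.3f (SE %.3f), b = %.3f (SE %.3f)\n",
              x$a, x$se[["a"]], x$b, x$se[["b"]]))
  cat(sprintf("  TL50 = %.2f mm (SE %.2f)\n", x$TL50, x$se[["TL50"]]))
  if (length(x$warnings)) {
    cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  }
  invisible(x)
}

#' @export
summary.ogive_fit <- function(object, ...) {
  print(object)
  cat("\nPer-class proportions:\n")
  print(object$classes, row.names = FALSE)
  invisible(object)
}

#' @export
coef.ogive_fit <- function(object, ...) {
  c(a = object$a, b = object$b, TL50 = object$TL50)
}

#' Predicted proportion mature at given shell lengths
#'
#' @param object an `ogive_fit`.
#' @param newdata numeric vector of shell lengths (mm); defaults to the
#'   fitted class midpoints.
#' @param ... unused.
#' @return Vector of P(mature | TL).
#' @export
predict.ogive_fit <- function(object, newdata = object$classes$midpoint, ...) {
  1 / (1 + exp(-(object$a + object$b * newdata)))
}

#' @export
plot.ogive_fit <- function(x, ...) {
  tl <- seq(min(x$classes$midpoint), max(x$classes$midpoint), length.out = 200)
  plot(x$classes$midpoint, x$classes$prop, cex = sqrt(x$classes$n) / 2,
       xlab = "shell length TL (mm)", ylab = "proportion mature",
       main = sprintf("TL50 = %.2f mm", x$TL50), ...)
  lines(tl, predict(x, tl))
  abline(h = 0.5, v = x$TL50, lty = 3)
  invisible(x)
}

#' @importFrom graphics abline lines
NULL

#' Bootstrap confidence interval for TL50
#'
#' Nonparametric bootstrap over individuals; the default reports the
#' percentile interval.
#'
#' @param records as in [fit_ogive()].
#' @param n_boot number of bootstrap resamples.
#' @param level confidence level.
#' @param seed integer seed.
#' @param ... passed to [fit_ogive()].
#' @return Named vector `lower`, `upper`.
#' @export
tl50_bootstrap <- function(records, n_boot = 200, level = 0.95, seed = NULL,
                           ...) {
  with_seed(seed, {
    tl50s <- vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(nrow(records), replace = TRUE)
      f <- try(fit_ogive(records[idx, , drop = FALSE], ...), silent = TRUE)
      if (inherits(f, "try-error")) NA_real_ else f$TL50
    }, numeric(1))
    q <- quantile(tl50s, c((1 - level) / 2, 1 - (1 - level) / 2), na.rm = TRUE)
    c(lower = unname(q[1]), upper = unname(q[2]))
  })
}

#' @importFrom graphics plot
NULL
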