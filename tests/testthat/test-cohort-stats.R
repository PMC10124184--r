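test_that("OLS recovers an exact linear relationship", {
  f <- fit_linear(1:5, 2 * (1:5) + 1)
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 1)
  expect_equal(f$adj_R2, 1)
  expect_equal(unname(f$df), c(1, 3))
  expect_error(fit_linear(rep(3, 5), 1:5), "constant")
  expect_error(fit_linear(1:2, 1:2), "at least 3")
})

test_that("OLS matches the closed-form normal equations on a small dataset", {
  x <- c(1.0, 2.5, 3.1, 4.8, 6.0)
  y <- c(2.1, 4.9, 6.4, 9.2, 12.5)
  f <- fit_linear(x, y)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  expect_equal(f$slope, slope)
  expect_equal(f$intercept, intercept)
  res <- y - intercept - slope * x
  expect_equal(f$sigma, sqrt(sum(res^2) / 3))
  # residuals orthogonal to x
  expect_lt(abs(sum(res * x)), 1e-10)
})

test_that("reconstructed G_v regressed on TL returns the generator slope", {
  cfg <- cfg_fast()  # noise off, 1/10 scale
  coh <- generate_cohort(8, 0, c(20, 33), cfg, seed = 2)
  gv <- vapply(seq_along(coh), function(i) {
    tab <- stereofec:::section_and_sample(coh[[i]], section_plan(),
                                          seed = 50 + i)
    cavalieri_volume(tab$sections$G_a_mm2, 100)
  }, numeric(1))
  tls <- vapply(coh, function(g) g$TL, 0)
  f <- fit_linear(tls, gv)
  expect_equal(f$slope, 17.2 * cfg$volume_scale, tolerance = 1e-2)
})

test_that("mean-response intervals behave like the t-based formula", {
  x <- c(1.0, 2.5, 3.1, 4.8, 6.0)
  y <- c(2.1, 4.9, 6.4, 9.2, 12.5)
  f <- fit_linear(x, y)
  p <- predict_with_ci(f, 3)
  half <- qt(0.975, 3) * f$sigma * sqrt(1 / 5 + (3 - mean(x))^2 /
                                          sum((x - mean(x))^2))
  expect_equal(p$upr - p$fit, half)
  expect_equal(p$fit - p$lwr, half)
  # the interval is narrowest at the mean of x
  w <- function(x0) {
    pp <- predict_with_ci(f, x0)
    pp$upr - pp$lwr
  }
  expect_lt(w(mean(x)), w(mean(x) + 1))
  expect_lt(w(mean(x)), w(mean(x) - 1.5))
  # exact fit -> degenerate interval
  f0 <- fit_linear(1:5, 2 * (1:5) + 1)
  p0 <- predict_with_ci(f0, 3)
  expect_equal(p0$lwr, p0$fit)
  expect_equal(p0$upr, p0$fit)
  # extrapolation is flagged, not refused
  expect_true(predict_with_ci(f, 100)$extrapolated)
})

test_that("published PF coefficients predict the reported egg numbers", {
  pub <- linear_fit(3.01e4, -5.21e5)
  expect_equal(signif(predict(pub, 22)$fit, 2), 1.4e5)
  expect_equal(signif(predict(pub, 25)$fit, 2), 2.3e5)
})

test_that("the MCRS scenario reports raw and rounded reductions", {
  pub <- linear_fit(3.01e4, -5.21e5)
  sc <- mcrs_scenario(pub)
  expect_equal(sc$percent_reduction,
               100 * (231500 - 141200) / 231500)
  expect_equal(sc$percent_reduction_rounded, 40)
  expect_gt(sc$percent_increase, 60)  # the converse direction, ~64%
  # degenerate and invariance cases
  expect_equal(mcrs_scenario(pub, 25, 25)$percent_reduction, 0)
  doubled <- linear_fit(2 * 3.01e4, 2 * -5.21e5)
  expect_equal(mcrs_scenario(doubled)$percent_reduction,
               sc$percent_reduction)
  expect_error(mcrs_scenario(linear_fit(1, -1e6)), "non-positive")
})

test_that("two-way occupancy ANOVA matches the closed-form balanced oracle", {
  set.seed(42)
  n <- 8
  cells <- expand.grid(stage = c("4A", "4B"),
                       dev_class = c("mature", "immature"))
  mu <- c(19, 8, 20, 14)
  rows <- do.call(rbind, lapply(1:4, function(i) {
    data.frame(specimen_id = paste0(cells$stage[i], "-", 1:n),
               stage = cells$stage[i], dev_class = cells$dev_class[i],
               percent = mu[i] + rnorm(n, sd = 2))
  }))
  res <- occupancy_anova(rows)

  # hand-computed balanced two-way ANOVA
  y <- rows$percent
  grand <- mean(y)
  m_st <- tapply(y, rows$stage, mean)
  m_dc <- tapply(y, rows$dev_class, mean)
  m_cell <- tapply(y, interaction(rows$stage, rows$dev_class), mean)
  ss_st <- 2 * n * sum((m_st - grand)^2)
  ss_dc <- 2 * n * sum((m_dc - grand)^2)
  ss_cell <- n * sum((m_cell - grand)^2)
  ss_int <- ss_cell - ss_st - ss_dc
  ss_res <- sum((y - m_cell[interaction(rows$stage, rows$dev_class)])^2)
  df_res <- 4 * (n - 1)
  tab <- res$anova
  expect_equal(tab["stage", "Sum Sq"], ss_st)
  expect_equal(tab["dev_class", "Sum Sq"], ss_dc)
  expect_equal(tab["stage:dev_class", "Sum Sq"], ss_int)
  expect_equal(tab["stage", "F value"], (ss_st / 1) / (ss_res / df_res))

  # balanced Tukey cell contrasts agree with stats::TukeyHSD
  av <- aov(percent ~ stage * dev_class, data = rows)
  ref <- TukeyHSD(av)$`stage:dev_class`
  ours <- res$tukey[grepl("4[AB] (mature|immature)", res$tukey$contrast), ]
  expect_equal(sort(abs(ours$diff)), sort(abs(unname(ref[, "diff"]))),
               tolerance = 1e-10)
  # same adjusted p-values (compare as sorted sets; labels differ)
  expect_equal(sort(ours$p_adj), sort(unname(ref[, "p adj"])),
               tolerance = 1e-8)
})

test_that("identical occupancy values give null contrasts", {
  rows <- expand.grid(rep_id = 1:3, stage = c("4A", "4B"),
                      dev_class = c("mature", "immature"))
  rows$specimen_id <- paste0(rows$stage, rows$rep_id)
  rows$percent <- 10
  res <- occupancy_anova(rows)
  expect_true(all(res$tukey$diff == 0))
  expect_true(all(res$anova[["Sum Sq"]][1:3] < 1e-20))
})

test_that("ANOVA rejects cells with fewer than two observations", {
  rows <- data.frame(specimen_id = c("a", "b", "c", "d", "e"),
                     stage = c("4A", "4A", "4A", "4A", "4B"),
                     dev_class = rep(c("mature", "immature"), c(3, 2)),
                     percent = 1:5)
  expect_error(occupancy_anova(rows), "fewer than 2")
})

test_that("ANCOVA with a null covariate reduces to the ANOVA F", {
  set.seed(7)
  n <- 40
  rows <- expand.grid(i = 1:n, stage = c("4A", "4B"),
                      dev_class = c("mature", "immature"))
  eff <- ifelse(rows$stage == "4A", 0.8, 0) +
    ifelse(rows$dev_class == "mature", 0.4, 0)
  rows$log_count <- 10 + eff + rnorm(nrow(rows), sd = 0.3)
  rows$log_TL <- rnorm(nrow(rows), 3, 0.15)  # unrelated covariate
  anc <- count_ancova(rows)
  av <- car::Anova(lm(log_count ~ stage * dev_class, data = rows), type = 2)
  expect_equal(anc$ancova["stage", "F value"], av["stage", "F value"],
               tolerance = 0.1)
})

test_that("parallel group lines yield adjusted means at the exact offset", {
  tl <- rep(seq(2.9, 3.5, length.out = 12), 4)
  grid <- expand.grid(i = 1:12, stage = c("4A", "4B"),
                      dev_class = c("mature", "immature"))
  offset <- ifelse(grid$stage == "4A", 0.5, 0)
  rows <- data.frame(stage = grid$stage, dev_class = grid$dev_class,
                     log_TL = tl,
                     log_count = 2 * tl + offset +
                       ifelse(grid$dev_class == "mature", 0.2, 0))
  anc <- count_ancova(rows)
  am <- anc$adjusted_means
  for (dc in c("mature", "immature")) {
    m <- am[am$dev_class == dc, ]
    d <- m$emmean[m$stage == "4A"] - m$emmean[m$stage == "4B"]
    expect_equal(d, 0.5, tolerance = 1e-8)
  }
})
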