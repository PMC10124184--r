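test_that("Cavalieri sums areas times spacing", {
  expect_equal(cavalieri_volume(c(2, 3, 1), 100), 0.6)
  expect_equal(cavalieri_volume(4.2, 250), 4.2 * 0.25)
  expect_error(cavalieri_volume(numeric(0), 100), "at least one")
  expect_error(cavalieri_volume(c(1, -1), 100), "negative")
  expect_error(cavalieri_volume(1, 0), "spacing")
})

test_that("Cavalieri is exact on a constant-cross-section solid", {
  # cylinder: radius 1.2 mm, length 3 mm, sectioned every 100 um
  r_mm <- 1.2
  areas <- rep(pi * r_mm^2, 30)
  expect_equal(cavalieri_volume(areas, 100), pi * r_mm^2 * 3)
})

test_that("Cavalieri over virtual sections recovers the generated volume", {
  # ~46 sections through a 1/10-size organ: discretization error far below
  # the 0.1% asserted here
  g <- generate_gonad(25, "4A", cfg_fast(), seed = 3)
  geom <- stereofec:::section_geometry(g, section_plan())
  expect_equal(cavalieri_volume(geom$G_a_mm2, 100), g$true_volume,
               tolerance = 1e-3)
})

test_that("oocyte volume modes differ by exactly the factor 8", {
  expect_equal(oocyte_volume(60, 60), pi * 60^3 / 6)
  expect_equal(oocyte_volume(60, 60, mode = "paper"), 8 * pi * 60^3 / 6)
  # independent arithmetic for an oblate spheroid
  expect_equal(oocyte_volume(52.7, 70.3), 4 / 3 * pi * (70.3 / 2)^2 * (52.7 / 2))
  expect_error(oocyte_volume(-1, 60), "positive")
  expect_error(oocyte_volume(70, 60), "d_min <= d_max")
})

test_that("the Abercrombie correction rescales counts by T/(T+h)", {
  expect_equal(abercrombie_correction(100, 6, 24), 20)
  expect_equal(abercrombie_correction(37, 6, 0), 37)
  expect_error(abercrombie_correction(10, 0, 24), "thickness")
})

test_that("field counts scale to whole-gonad numbers", {
  rows <- data.frame(dev_class = rep("mature", 3), nucleus_hit = TRUE)
  n_center <- estimate_total_count(rows, 1, 1e6, 6, 24, 100, "center")
  expect_equal(unname(n_center[["mature"]]), 5e4)
  n_int <- estimate_total_count(rows, 1, 1e6, 6, 24, 100, "intersect")
  expect_equal(unname(n_int[["mature"]]), 1e4)
  expect_error(estimate_total_count(rows, 1, 0, 6, 24, 100, "center"), "area")
})

test_that("occupancy percent is the volume ratio", {
  expect_equal(occupancy_percent(1e5, 1e5, 50), 20)
  expect_error(occupancy_percent(1, 1, 0), "positive")
})

test_that("profile counting is unbiased under both nucleus rules", {
  # simulation oracle: compare N_hat with the generator's true counts
  plan_i <- section_plan(nucleus_rule = "intersect")
  plan_c <- section_plan(nucleus_rule = "center")
  cfg <- cfg_fast()
  rel <- t(vapply(1:50, function(i) {
    g <- generate_gonad(25, "4A", cfg, seed = i)
    ei <- estimate_one(g, plan_i, cfg, seed = 1e4 + i)
    ec <- estimate_one(g, plan_c, cfg, seed = 1e4 + i)
    c(int = ei$N_hat[["mature"]] / g$true_counts[["mature"]],
      cen = ec$N_hat[["mature"]] / g$true_counts[["mature"]])
  }, numeric(2)))
  for (col in c("int", "cen")) {
    expect_lt(abs(mean(rel[, col]) - 1),
              2 * sd(rel[, col]) / sqrt(nrow(rel)) + 0.02)
  }
})

test_that("stage-4B specimens get occupancies but no PF", {
  g <- generate_gonad(25, "4B", cfg_fast(), seed = 21)
  est <- estimate_one(g, section_plan(), cfg_fast(), seed = 22)
  expect_true(is.na(est$PF))
  expect_gt(est$occupancy[["total"]], 0)
  # PF is defined for ripe females
  g4a <- generate_gonad(25, "4A", cfg_fast(), seed = 21)
  est4a <- estimate_one(g4a, section_plan(), cfg_fast(), seed = 22)
  expect_equal(est4a$PF, unname(est4a$N_hat[["mature"]]))
})

test_that("an empty field table yields zero counts and occupancy", {
  g <- generate_gonad(25, "4A", cfg_fast(), seed = 2)
  tab <- stereofec:::section_and_sample(g, section_plan(), seed = 1)
  tab$profiles <- tab$profiles[0, , drop = FALSE]
  est <- estimate_fecundity(tab, config = cfg_fast())
  expect_equal(unname(est$N_hat), c(0, 0))
  expect_equal(unname(est$occupancy[["total"]]), 0)
})

test_that("volume-mode labelling is coherent through the estimate", {
  g <- generate_gonad(25, "4A", cfg_fast(), seed = 31)
  e_corr <- estimate_one(g, section_plan(), cfg_fast(), seed = 5)
  e_paper <- estimate_one(g, section_plan(), cfg_fast(), seed = 5,
                          mode = "paper")
  expect_equal(e_corr$mode, "corrected")
  expect_equal(e_paper$mode, "paper")
  # same profiles, so the paper formula scales volumes and occupancy by 8
  expect_equal(e_paper$mean_O_v, 8 * e_corr$mean_O_v)
  expect_equal(e_paper$occupancy[["total"]], 8 * e_corr$occupancy[["total"]])
  expect_equal(e_paper$N_hat, e_corr$N_hat)  # counts are volume-mode free
})

test_that("class occupancies always sum to the reported total", {
  for (s in 1:5) {
    g <- generate_gonad(runif(1, 20, 32), sample(c("4A", "4B"), 1),
                        cfg_fast(), seed = s)
    est <- estimate_one(g, section_plan(), cfg_fast(), seed = 100 + s)
    expect_equal(est$occupancy[["total"]],
                 est$occupancy[["mature"]] + est$occupancy[["immature"]])
  }
})

test_that("estimation error shrinks as field count grows", {
  cfg <- cfg_fast()
  plan6 <- section_plan(field_count = 6)
  plan60 <- section_plan(field_count = 60)
  err <- t(vapply(1:12, function(i) {
    g <- generate_gonad(25, "4A", cfg, seed = 300 + i)
    e6 <- estimate_one(g, plan6, cfg, seed = 400 + i)
    e60 <- estimate_one(g, plan60, cfg, seed = 400 + i)
    tr <- g$true_counts[["mature"]]
    c(f6 = (e6$N_hat[["mature"]] - tr) / tr,
      f60 = (e60$N_hat[["mature"]] - tr) / tr)
  }, numeric(2)))
  expect_lt(sqrt(mean(err[, "f60"]^2)), sqrt(mean(err[, "f6"]^2)))
})

test_that("the Delesse areal-fraction flag gives a comparable occupancy", {
  g <- generate_gonad(25, "4A", cfg_fast(), seed = 77)
  e_nv <- estimate_one(g, section_plan(), cfg_fast(), seed = 9)
  e_dl <- estimate_one(g, section_plan(), cfg_fast(), seed = 9,
                       method = "delesse")
  expect_equal(e_dl$method, "delesse")
  # same order of magnitude; the slab-projection inflates the areal fraction
  expect_gt(e_dl$occupancy[["total"]], 0.5 * e_nv$occupancy[["total"]])
  expect_lt(e_dl$occupancy[["total"]], 4 * e_nv$occupancy[["total"]])
})
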