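# Mouse lymphoma assay calculation chain.

test_that("suspension growth", {
  expect_equal(suspension_growth(6e6, 6e6, 6e6, 6e6), 1)
  expect_equal(suspension_growth(4, 1, 4, 1), 16)
  expect_error(suspension_growth(0, 1, 1, 1), "positive")
  expect_equal(relative_suspension_growth(12, 12), 1)
})

test_that("cloning efficiency: hand-computed oracles", {
  expect_equal(as.numeric(cloning_efficiency(96, 96, 1.6)), 0)
  expect_equal(as.numeric(cloning_efficiency(48, 96, 1.6)),
               0.43321698785, tolerance = 1e-10)
  expect_equal(as.numeric(cloning_efficiency(380, 384, 2000)),
               -log(380 / 384) / 2000, tolerance = 1e-12)
  expect_equal(as.numeric(cloning_efficiency(380, 384, 2000)),
               5.2356e-06, tolerance = 1e-4)
  expect_error(cloning_efficiency(97, 96), "wells_empty")
  expect_error(cloning_efficiency(10, 96, 0), "cells_per_well")
  expect_warning(lb <- cloning_efficiency(0, 96, 1.6), "lower-bound")
  expect_true(attr(lb, "lower_bound"))
  expect_equal(as.numeric(lb), -log(0.5 / 96) / 1.6)
})

test_that("cloning efficiency agrees with a Monte-Carlo plating oracle", {
  # independent route: simulate wells with Poisson(cells_per_well * ce)
  # colony founders and re-estimate CE from the empty-well fraction
  set.seed(77)
  for (ce_true in c(0.1, 0.5, 1.0)) {
    n_wells <- 96 * 50          # large plate set to shrink sampling error
    founders <- rpois(n_wells, 1.6 * ce_true)
    empty <- sum(founders == 0L)
    ce_hat <- as.numeric(cloning_efficiency(empty, n_wells, 1.6))
    se <- sqrt((1 - exp(-1.6 * ce_true)) / (n_wells * exp(-1.6 * ce_true))) /
      1.6
    expect_lt(abs(ce_hat - ce_true), 4 * se)
  }
})

test_that("relative total growth", {
  expect_equal(relative_total_growth(1, 1), 100)
  expect_equal(relative_total_growth(0.5, 0.5), 25)
  expect_equal(relative_total_growth(0.238, 0.7), 16.66)
  expect_error(relative_total_growth(-0.1, 1), ">= 0")
})

test_that("mutation frequency: ratio of cloning efficiencies", {
  # zero TFT positives -> MF exactly 0
  res0 <- mutation_frequency(
    list(wells_total = 384, wells_empty = 384, wells_small = 0,
         wells_large = 0),
    list(wells_total = 192, wells_empty = 96))
  expect_equal(res0$mf, 0)
  # generic case: mf equals ce_tft / ce_s2 exactly
  res <- mutation_frequency(
    list(wells_total = 384, wells_empty = 300, wells_small = 50,
         wells_large = 40),
    list(wells_total = 192, wells_empty = 80))
  expect_equal(res$mf, res$ce_tft / res$ce_s2, tolerance = 1e-12)
  expect_equal(res$mf_small,
               (-log((384 - 50) / 384) / 2000) / res$ce_s2, tolerance = 1e-12)
  # division identity from the formula: ce_tft = 1e-4, ce_s2 = 0.5
  expect_equal(1e-4 / 0.5, 200e-6)
  expect_error(mutation_frequency(
    list(wells_total = 384, wells_empty = 300, wells_small = 50,
         wells_large = 40),
    list(wells_total = 192, wells_empty = 192)), "zero")
})

test_that("small + large MF is first-order additive, diverging with saturation", {
  mf_parts <- function(small, large, total = 384) {
    empty <- total - small - large  # disjoint classes for this check
    res <- mutation_frequency(
      list(wells_total = total, wells_empty = empty, wells_small = small,
           wells_large = large),
      list(wells_total = 192, wells_empty = 96))
    c(gap = abs(res$mf_small + res$mf_large - res$mf) / res$mf)
  }
  low <- mf_parts(4, 4)     # ~2% positive wells
  high <- mf_parts(150, 150)  # heavily saturated plates
  expect_lt(low[["gap"]], 0.02)
  expect_gt(high[["gap"]], low[["gap"]])
})

test_that("GEF call: published decision values and boundary convention", {
  expect_true(gef_call(1229.5e-6, 201.5e-6))
  expect_false(gef_call(232.9e-6, 201.5e-6))
  expect_false(gef_call(201.5e-6 + 126e-6, 201.5e-6))  # strict inequality
  expect_error(gef_call(-1e-6, 0), ">= 0")
})

test_that("GEF call is monotone and not shift-invariant", {
  mfs <- seq(0, 2000e-6, by = 100e-6)
  calls <- vapply(mfs, gef_call, logical(1), mf_vehicle = 200e-6)
  expect_true(all(diff(as.integer(calls)) >= 0))
  # adding the same constant to both MFs never changes the call
  expect_equal(gef_call(400e-6, 200e-6), gef_call(900e-6, 700e-6))
  # but adding it to the treatment only does
  expect_false(gef_call(300e-6, 200e-6))
  expect_true(gef_call(300e-6 + 500e-6, 200e-6))
})

test_that("validity report reproduces the guideline decisions", {
  # per-condition results assembled from the published summary table of the
  # lead-compound experiment (MFs on the 1e-6 scale)
  res <- data.frame(
    condition = c("vehicle", "t0.5", "t1", "t2.5", "t5", "positive"),
    sg = c(12.8, 10.87, 9.07, 9.52, 4.65, 10.42),
    rtg = c(95.53, 72.73, 74.69, 63.67, 22.77, 58.79),
    ce_s2 = c(0.98, 0.75, 0.92, 0.75, 0.55, 0.63),
    mf = c(201.5, 232.9, 165.7, 281.5, 1229.5, 817),
    mf_small = c(32.8, 81.3, 67.7, 97.2, 633.4, 430.9),
    mf_large = c(165.6, 140.9, 92.3, 167.2, 288.6, 273.4))
  rep <- mla_validity_report(res)
  df <- as.data.frame(rep)
  fail <- df$name[!df$pass]
  expect_equal(fail, "vehicle MF [1e-6]")      # the sole failed criterion
  expect_true(df$pass[df$name == "vehicle CE survivor-2 [%]"])
  expect_false(attr(rep, "overall"))
  rep2 <- mla_validity_report(res, override_note = "high top-dose MF")
  expect_true(attr(rep2, "overall"))
  # all-inside synthetic case passes overall
  ok <- res
  ok$mf[1] <- 120
  expect_true(attr(mla_validity_report(ok), "overall"))
  expect_error(mla_validity_report(res[-1, ]), "vehicle")
})

test_that("mla_run pipeline on synthetic data recovers the truth (quick)", {
  tab <- gen_mla(seed = 11)
  res <- mla_run(tab)
  expect_equal(res$rtg[res$condition == "vehicle"], 100)
  truth <- attr(tab, "truth")
  est <- res$mf[res$condition == "treatment:1@5uM"] * 1e-6
  expect_lt(abs(est - truth$`treatment:1@5uM`$mf) /
              truth$`treatment:1@5uM`$mf, 0.35)  # single-seed Poisson noise
  expect_true(res$relevant[res$condition == "treatment:1@5uM"])
  expect_false(res$relevant[res$condition == "vehicle"])
  expect_error(mla_run(tab[tab$condition != "vehicle", ]), "vehicle")
})
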