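# Comet assay summarization.

test_that("summarize_slide basic cases", {
  s <- summarize_slide(rep(1, 100))
  expect_equal(s$mean_ti, 1)
  expect_equal(s$median_ti, 1)
  expect_equal(s$responder_fraction, 0)
  expect_equal(s$n_nuclei, 100L)
  expect_false(s$low_count)

  # the median-underestimation example: 80 intact, 20 heavily damaged nuclei
  s2 <- summarize_slide(c(rep(0, 80), rep(50, 20)))
  expect_equal(s2$mean_ti, 10)
  expect_equal(s2$median_ti, 0)

  expect_warning(s3 <- summarize_slide(c(0, 0, 0, 100)), "nominal count")
  expect_equal(s3$responder_fraction, 0.25)
})

test_that("summarize_slide validation", {
  expect_error(summarize_slide(numeric(0)), "empty slide")
  expect_error(summarize_slide(c(5, 101)), "within")
  expect_error(summarize_slide(c(5, -1)), "within")
  expect_error(summarize_slide(rep(1, 100), damage_threshold = 0), "0, 100")
  expect_error(summarize_slide(rep(1, 100), damage_threshold = 100), "0, 100")
})

test_that("mean approaches median for symmetric unimodal data", {
  set.seed(9)
  gaps <- vapply(c(100, 1000, 10000), function(n) {
    ti <- pmin(100, pmax(0, rnorm(n, 30, 5)))
    s <- summarize_slide(ti)
    abs(s$mean_ti - s$median_ti)
  }, numeric(1))
  expect_lt(gaps[3], 0.2)
  expect_lt(gaps[3], gaps[1] + 0.2)
})

test_that("two-point mixtures below 50% responders: median blind, mean not", {
  for (p in c(0.1, 0.2, 0.4)) {
    n <- 100
    ti <- c(rep(0.5, round((1 - p) * n)), rep(60, round(p * n)))
    s <- summarize_slide(ti)
    expect_equal(s$median_ti, 0.5)        # median sits on the background mode
    expect_gt(s$mean_ti, 0.5)             # mean sees the damage
    expect_equal(s$responder_fraction, p, tolerance = 1e-9)
  }
})

test_that("summarize_slide is permutation invariant", {
  set.seed(2)
  ti <- runif(100, 0, 100)
  a <- summarize_slide(ti)
  b <- summarize_slide(sample(ti))
  expect_equal(a, b)
})

test_that("summarize_condition aggregates cultures", {
  tab <- data.frame(
    slide_id = rep(c("a", "b", "c"), each = 100),
    condition = "veh", replicate = rep(1:3, each = 100),
    ti = rep(1, 300))
  res <- summarize_condition(tab)
  expect_equal(res$mean, 1)
  expect_equal(res$sd, 0)
  expect_equal(res$n, 3L)
  # mode flag switches the summarized measure
  resm <- summarize_condition(tab, mode = "median")
  expect_equal(resm$mode, "median")
})

test_that("condition means recover the generator's mixture expectation", {
  cm <- gen_comet(conditions = list(
    vehicle = list(p_responder = 0),
    trt = list(p_responder = 0.15)),
    n_replicates = 6, seed = 31)
  res <- summarize_condition(cm)
  veh <- res[res$condition == "vehicle", ]
  trt <- res[res$condition == "trt", ]
  expect_equal(veh$mean, 1.0, tolerance = 0.15)   # vehicle-like slides
  # mixture expectation 0.15*60 + 0.85*1 = 9.85
  expect_lt(abs(trt$mean - 9.85), 3)
  # median-based summary underestimates the same condition
  resm <- summarize_condition(cm, mode = "median")
  expect_lt(resm$mean[resm$condition == "trt"], trt$mean)
})
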