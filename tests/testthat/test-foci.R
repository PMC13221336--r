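# Nucleus classification.

test_that("classifier_config validation", {
  expect_error(classifier_config("gh2ax"), "intensity_threshold")
  expect_error(classifier_config("ph3", 100), "area_min")
  expect_error(classifier_config("ph3", 100, area_min = 50, area_max = 10),
               "area_min < area_max")
  cfg <- classifier_config("gh2ax", 150)
  expect_equal(cfg$min_nuclei, 2000L)
  cfg2 <- classifier_config("ph3", 150, area_min = 10, area_max = 50)
  expect_equal(cfg2$min_nuclei, 5000L)
})

test_that("gh2ax classification is a pure intensity threshold", {
  cfg <- classifier_config("gh2ax", 150, min_nuclei = 3)
  tab <- data.frame(mean_intensity = c(10, 149.9, 150, 400))
  out <- classify_nuclei(tab, cfg)
  expect_equal(out$positive, c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(out$proportion, 0.5)
  # all below threshold
  out0 <- classify_nuclei(data.frame(mean_intensity = c(1, 2, 3)), cfg)
  expect_equal(out0$proportion, 0)
})

test_that("ph3 classification is the intensity AND area conjunction", {
  cfg <- classifier_config("ph3", 150, area_min = 20, area_max = 40,
                           min_nuclei = 2)
  tab <- data.frame(mean_intensity = c(400, 400, 400, 100),
                    area = c(30, 10, 50, 30))
  out <- classify_nuclei(tab, cfg)
  expect_equal(out$positive, c(TRUE, FALSE, FALSE, FALSE))
})

test_that("low-count warning flags but does not suppress output", {
  cfg <- classifier_config("gh2ax", 150)
  tab <- data.frame(mean_intensity = rep(200, 10))
  expect_warning(out <- classify_nuclei(tab, cfg), "minimum")
  expect_true(out$low_count)
  expect_equal(out$proportion, 1)
})

test_that("classification is pure: permutation invariant and idempotent", {
  set.seed(3)
  cfg <- classifier_config("gh2ax", 150, min_nuclei = 10)
  tab <- data.frame(mean_intensity = runif(500, 0, 300))
  a <- classify_nuclei(tab, cfg)
  perm <- sample(nrow(tab))
  b <- classify_nuclei(tab[perm, , drop = FALSE], cfg)
  expect_equal(a$proportion, b$proportion)
  expect_equal(a$positive[perm], b$positive)
  expect_equal(classify_nuclei(tab, cfg)$positive, a$positive)
})

test_that("proportion is monotone non-increasing in the threshold", {
  set.seed(5)
  tab <- data.frame(mean_intensity = c(rnorm(900, 100, 25),
                                       rnorm(100, 400, 60)))
  props <- vapply(seq(50, 500, by = 25), function(thr) {
    classify_nuclei(tab, classifier_config("gh2ax", thr,
                                           min_nuclei = 10))$proportion
  }, numeric(1))
  expect_true(all(diff(props) <= 0))
})

test_that("recovered positive fraction is unbiased across p", {
  thr <- calibrate_intensity_threshold()
  for (p in c(0.01, 0.05, 0.2, 0.4)) {
    tab <- gen_foci(conditions = list(c1 = list(p_positive = p)),
                    n_replicates = 3, n_nuclei = 2000, seed = round(1e4 * p))
    cfg <- classifier_config("gh2ax", thr)
    res <- foci_condition_summary(tab, cfg)
    n <- 3 * 2000
    tol <- 3 * sqrt(p * (1 - p) / n) + 0.012  # binomial error + 1% bg rate
    expect_lt(abs(res$mean - p), tol)
  }
})

test_that("condition summary aggregates replicates", {
  tab <- data.frame(condition = "c", replicate = rep(1:3, each = 5),
                    mean_intensity = rep(c(0, 0, 200, 200, 200), 3))
  cfg <- classifier_config("gh2ax", 100, min_nuclei = 2)
  res <- foci_condition_summary(tab, cfg)
  expect_equal(res$mean, 0.6)
  expect_equal(res$sd, 0)
  expect_equal(res$n, 3L)
  expect_error(foci_condition_summary(tab[0, ], cfg), "empty")
})

test_that("pan-stained nuclei inflate intensity-only positives", {
  thr <- calibrate_intensity_threshold()
  clean <- gen_foci(conditions = list(c = list(p_positive = 0.05)), seed = 8)
  pan <- gen_foci(conditions = list(c = list(p_positive = 0.05, p_pan = 0.1)),
                  seed = 8)
  cfg <- classifier_config("gh2ax", thr)
  p_clean <- foci_condition_summary(clean, cfg)$mean
  p_pan <- foci_condition_summary(pan, cfg)$mean
  expect_gt(p_pan, p_clean + 0.05)  # saturating phenotype breaks the readout
})
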