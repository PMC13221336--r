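# Synthetic assay-data generators.
#
# The study's raw assay data are not deposited, so each analysis module is
# paired with a generator that emulates the statistical structure its input
# is assumed to have, with known ground truth for parameter-recovery tests:
#   gen_plate - absorbance wells, 3 biological x 3 technical replicates,
#               additive Gaussian noise on the corrected signal
#   gen_comet - per-slide TI values from a two-component (background /
#               damaged) mixture: the bimodal shape that motivates the
#               arithmetic-mean summary rule
#   gen_mla   - Poisson-plating outcomes for survivor and TFT microwell
#               plates plus the suspension-growth cell counts
#   gen_foci  - two-population nucleus intensity/area feature tables, with an
#               optional pan-stained (saturating) subpopulation
# All randomness is drawn under a caller-supplied seed through a local RNG
# scope; identical scenario + seed gives identical tables.

#' Simulate an absorbance plate experiment
#'
#' @param true_pct true percent cytotoxicity of each treatment condition
#'   (named numeric vector; names become condition labels).
#' @param vehicle_mean,positive_mean corrected-signal anchors of the vehicle
#'   (0%) and positive (100%) controls.
#' @param noise_sd additive Gaussian noise SD on each corrected well signal.
#' @param a_ref reference-wavelength absorbance (constant background).
#' @param n_bio,n_tech biological and technical replicate counts.
#' @param seed RNG seed.
#' @return data.frame with columns `condition`, `replicate`, `read_index`,
#'   `a_meas`, `a_ref` (the schema [aggregate_cytotox()] reads), with the
#'   ground truth attached as attribute `truth`.
#' @export
gen_plate <- function(true_pct = c(`treatment:8@5uM` = 47.2),
                      vehicle_mean = 0.20, positive_mean = 0.90,
                      noise_sd = 0.05, a_ref = 0.05,
                      n_bio = 3L, n_tech = 3L, seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (is.null(names(true_pct)) || any(!nzchar(names(true_pct)))) {
    stop("true_pct must be a named vector of condition labels", call. = FALSE)
  }
  span <- positive_mean - vehicle_mean
  means <- c(vehicle = vehicle_mean, positive = positive_mean,
             vehicle_mean + true_pct / 100 * span)
  names(means) <- c("vehicle", "positive", names(true_pct))
  nv_with_seed(seed, {
    rows <- expand.grid(read_index = seq_len(n_tech),
                        replicate = seq_len(n_bio),
                        condition = names(means),
                        stringsAsFactors = FALSE)
    rows <- rows[, c("condition", "replicate", "read_index")]
    signal <- means[rows$condition] + stats::rnorm(nrow(rows), 0, noise_sd)
    out <- data.frame(condition = rows$condition,
                      replicate = rows$replicate,
                      read_index = rows$read_index,
                      a_meas = unname(signal + a_ref),
                      a_ref = a_ref)
    attr(out, "truth") <- list(true_pct = true_pct, noise_sd = noise_sd,
                               vehicle_mean = vehicle_mean,
                               positive_mean = positive_mean)
    out
  })
}

#' Simulate comet-assay slides (bimodal tail-intensity mixtures)
#'
#' Each nucleus is a responder with probability `p_responder`; responders
#' draw TI from the damaged component, the rest from the low background
#' component. Draws are truncated to [0, 100].
#'
#' @param conditions named list; each element is a list with `p_responder`
#'   and optionally `damaged_mean`, `damaged_sd`, `bg_mean`, `bg_sd`.
#' @param n_replicates independent cultures (one slide each).
#' @param n_nuclei nuclei per slide (guideline nominal 100).
#' @param bg_mean,bg_sd,damaged_mean,damaged_sd default mixture components:
#'   background TI about 1% (vehicle slides score ~1.0), damaged nuclei
#'   around 60% tail DNA.
#' @param seed RNG seed.
#' @return data.frame with `slide_id`, `condition`, `replicate`, `ti` (the
#'   schema [summarize_condition()] reads), ground truth in `attr(.,"truth")`.
#' @export
gen_comet <- function(conditions = list(vehicle = list(p_responder = 0),
                                        treatment = list(p_responder = 0.2)),
                      n_replicates = 3L, n_nuclei = 100L,
                      bg_mean = 1, bg_sd = 0.8,
                      damaged_mean = 60, damaged_sd = 12, seed = 1L) {
  for (nm in names(conditions)) {
    p <- conditions[[nm]]$p_responder
    if (is.null(p) || p < 0 || p > 1) {
      stop("condition '", nm, "': p_responder must be in [0, 1]",
           call. = FALSE)
    }
  }
  rtrunc <- function(n, mean, sd) pmin(100, pmax(0, stats::rnorm(n, mean, sd)))
  nv_with_seed(seed, {
    out <- list()
    sid <- 0L
    for (nm in names(conditions)) {
      cf <- conditions[[nm]]
      dm <- if (is.null(cf$damaged_mean)) damaged_mean else cf$damaged_mean
      ds <- if (is.null(cf$damaged_sd)) damaged_sd else cf$damaged_sd
      bm <- if (is.null(cf$bg_mean)) bg_mean else cf$bg_mean
      bs <- if (is.null(cf$bg_sd)) bg_sd else cf$bg_sd
      for (r in seq_len(n_replicates)) {
        sid <- sid + 1L
        resp <- stats::runif(n_nuclei) < cf$p_responder
        ti <- numeric(n_nuclei)
        ti[resp] <- rtrunc(sum(resp), dm, ds)
        ti[!resp] <- rtrunc(sum(!resp), bm, bs)
        out[[length(out) + 1L]] <- data.frame(
          slide_id = sprintf("S%03d", sid), condition = nm, replicate = r,
          ti = ti)
      }
    }
    out <- do.call(rbind, out)
    attr(out, "truth") <- list(conditions = conditions, bg_mean = bg_mean,
                               damaged_mean = damaged_mean)
    out
  })
}

#' Simulate a mouse lymphoma assay experiment
#'
#' Survivor wells receive on average `cells_per_well_survivor` cells, each
#' founding a colony with probability CE, so a well stays empty with
#' probability `exp(-1.6 CE)`. TFT wells stay empty of mutant colonies with
#' probability `exp(-cells_per_well_tft * MF * CE)`; mutant founders are
#' split small/large by `small_fraction`. Suspension-growth counts are
#' log-normally perturbed around the target fold growth.
#'
#' @param conditions named list; each element a list with `ce` (cloning
#'   efficiency in (0, 1]), `mf` (mutation frequency, fraction >= 0), and
#'   optionally `sg` (target suspension growth) and `small_fraction`.
#' @param survivor_plates,tft_plates plates per role (96 wells each).
#' @param wells_per_plate default 96.
#' @param cells_per_well_survivor,cells_per_well_tft seeding densities.
#' @param setup_day0,setup_day1 seeded cell counts for the growth phase.
#' @param count_cv lognormal coefficient of variation of cell counts.
#' @param seed RNG seed.
#' @return data.frame in the schema [mla_run()] reads (one row per
#'   condition), ground truth in `attr(., "truth")`.
#' @export
gen_mla <- function(conditions = list(
                      vehicle = list(ce = 0.98, mf = 150e-6, sg = 13),
                      positive = list(ce = 0.60, mf = 800e-6, sg = 8),
                      `treatment:1@5uM` = list(ce = 0.5, mf = 1000e-6,
                                               sg = 3)),
                    survivor_plates = 2L, tft_plates = 4L,
                    wells_per_plate = 96L,
                    cells_per_well_survivor = NV_CELLS_PER_WELL_SURVIVOR,
                    cells_per_well_tft = NV_CELLS_PER_WELL_TFT,
                    setup_day0 = 6e6, setup_day1 = 6e6,
                    count_cv = 0.05, seed = 1L) {
  for (nm in names(conditions)) {
    cf <- conditions[[nm]]
    if (is.null(cf$ce) || cf$ce <= 0 || cf$ce > 1) {
      stop("condition '", nm, "': ce must be in (0, 1]", call. = FALSE)
    }
    if (is.null(cf$mf) || cf$mf < 0) {
      stop("condition '", nm, "': mf must be >= 0", call. = FALSE)
    }
  }
  nv_with_seed(seed, {
    rows <- lapply(names(conditions), function(nm) {
      cf <- conditions[[nm]]
      sg <- if (is.null(cf$sg)) 12 else cf$sg
      fs <- if (is.null(cf$small_fraction)) 0.5 else cf$small_fraction
      daily <- sqrt(sg)
      noisy <- function(x) stats::rlnorm(1, log(x), count_cv)
      count_day1 <- noisy(setup_day0 * daily)
      count_day2 <- noisy(setup_day1 * daily)

      n_s <- survivor_plates * wells_per_plate
      p_empty_s <- exp(-cells_per_well_survivor * cf$ce)
      s1_empty <- stats::rbinom(1, n_s, p_empty_s)
      s2_empty <- stats::rbinom(1, n_s, p_empty_s)

      n_t <- tft_plates * wells_per_plate
      lam <- cells_per_well_tft * cf$mf * cf$ce
      nsmall <- stats::rpois(n_t, lam * fs)
      nlarge <- stats::rpois(n_t, lam * (1 - fs))
      data.frame(condition = nm,
                 setup_day0 = setup_day0, count_day1 = count_day1,
                 setup_day1 = setup_day1, count_day2 = count_day2,
                 s1_total = n_s, s1_empty = s1_empty,
                 s2_total = n_s, s2_empty = s2_empty,
                 tft_total = n_t,
                 tft_empty = sum(nsmall + nlarge == 0L),
                 tft_small = sum(nsmall > 0L),
                 tft_large = sum(nlarge > 0L))
    })
    out <- do.call(rbind, rows)
    attr(out, "truth") <- conditions
    out
  })
}

#' Simulate a nucleus feature table for focus classification
#'
#' @param conditions named list; each element a list with `p_positive` and
#'   optionally `p_pan` (saturating pan-stained fraction, demonstrates why
#'   intensity-only classification fails for such phenotypes).
#' @param n_replicates replicate cultures.
#' @param n_nuclei nuclei per replicate.
#' @param bg_int_mean,bg_int_sd background intensity population.
#' @param pos_int_mean,pos_int_sd positive (stained) population.
#' @param bg_area_mean,bg_area_sd,pos_area_mean,pos_area_sd area populations
#'   (positives, e.g. mitotic nuclei, are smaller and condensed).
#' @param sat_intensity intensity of pan-stained nuclei.
#' @param seed RNG seed.
#' @return data.frame with `nucleus_id`, `condition`, `replicate`,
#'   `mean_intensity`, `area`, `true_positive` (ground-truth sidecar column),
#'   plus `attr(., "truth")`.
#' @export
gen_foci <- function(conditions = list(vehicle = list(p_positive = 0.05),
                                       treatment = list(p_positive = 0.40)),
                     n_replicates = 3L, n_nuclei = 2000L,
                     bg_int_mean = 100, bg_int_sd = 25,
                     pos_int_mean = 400, pos_int_sd = 60,
                     bg_area_mean = 60, bg_area_sd = 10,
                     pos_area_mean = 30, pos_area_sd = 6,
                     sat_intensity = 4095, seed = 1L) {
  for (nm in names(conditions)) {
    p <- conditions[[nm]]$p_positive
    if (is.null(p) || p < 0 || p > 1) {
      stop("condition '", nm, "': p_positive must be in [0, 1]", call. = FALSE)
    }
  }
  rpos <- function(n, mean, sd) pmax(stats::rnorm(n, mean, sd), 0.001)
  nv_with_seed(seed, {
    out <- list()
    for (nm in names(conditions)) {
      cf <- conditions[[nm]]
      p_pan <- if (is.null(cf$p_pan)) 0 else cf$p_pan
      for (r in seq_len(n_replicates)) {
        u <- stats::runif(n_nuclei)
        kind <- ifelse(u < cf$p_positive, "pos",
                       ifelse(u < cf$p_positive + p_pan, "pan", "bg"))
        int <- numeric(n_nuclei); area <- numeric(n_nuclei)
        for (kk in c("bg", "pos", "pan")) {
          idx <- which(kind == kk)
          if (!length(idx)) next
          if (kk == "bg") {
            int[idx] <- rpos(length(idx), bg_int_mean, bg_int_sd)
            area[idx] <- rpos(length(idx), bg_area_mean, bg_area_sd)
          } else if (kk == "pos") {
            int[idx] <- rpos(length(idx), pos_int_mean, pos_int_sd)
            area[idx] <- rpos(length(idx), pos_area_mean, pos_area_sd)
          } else {
            int[idx] <- sat_intensity
            area[idx] <- rpos(length(idx), bg_area_mean, bg_area_sd)
          }
        }
        out[[length(out) + 1L]] <- data.frame(
          nucleus_id = seq_len(n_nuclei), condition = nm, replicate = r,
          mean_intensity = int, area = area, true_positive = kind == "pos")
      }
    }
    out <- do.call(rbind, out)
    attr(out, "truth") <- list(conditions = conditions,
                               bg_int_mean = bg_int_mean,
                               bg_int_sd = bg_int_sd)
    out
  })
}

#' Default classifier threshold calibrated on the generator background
#'
#' The packaged default intensity threshold is the 99th percentile of the
#' synthetic background intensity population.
#'
#' @param bg_int_mean,bg_int_sd background population parameters.
#' @param q quantile (default 0.99).
#' @return intensity threshold (a.u.).
#' @export
calibrate_intensity_threshold <- function(bg_int_mean = 100, bg_int_sd = 25,
                                          q = 0.99) {
  stats::qnorm(q, bg_int_mean, bg_int_sd)
}
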