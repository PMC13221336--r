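# Mouse lymphoma assay (OECD TG 490, microwell method) calculation chain.
#
# Per treatment arm:
#   SG  = (count_day1 / setup_day0) * (count_day2 / setup_day1)
#   RSG = SG_treatment / SG_vehicle
#   CE  = -ln(empty wells / total wells) / cells_per_well   (Poisson P0)
#         cells_per_well = 1.6 on survivor plates, 2000 on TFT selection
#         plates (1e4 cells/mL x 200 uL)
#   RCE = CE_treatment / CE_vehicle        (survivor 2 plates)
#   RTG = RSG * RCE * 100                  (percent)
#   MF  = CE_TFT / CE_survivor2            (reported as x 1e6)
# Small/large colony MFs treat TFT wells lacking the respective colony class
# as empty. An MF increase is biologically relevant when it exceeds the
# vehicle MF by the Global Evaluation Factor (GEF) of 126e-6 (strict >).

NV_GEF <- 126e-6
NV_CELLS_PER_WELL_SURVIVOR <- 1.6
NV_CELLS_PER_WELL_TFT <- 2000

#' Suspension growth over the two-day expression period
#'
#' @param count_day1,setup_day0,count_day2,setup_day1 cell counts (> 0).
#' @return suspension growth SG (fold increase, product of the two daily
#'   growth ratios).
#' @export
suspension_growth <- function(count_day1, setup_day0, count_day2, setup_day1) {
  counts <- c(count_day1, setup_day0, count_day2, setup_day1)
  if (any(!is.finite(counts)) || any(counts <= 0)) {
    stop("all cell counts must be positive", call. = FALSE)
  }
  (count_day1 / setup_day0) * (count_day2 / setup_day1)
}

#' Cloning efficiency from empty-well counts (Poisson zero term)
#'
#' `CE = -ln(wells_empty / wells_total) / cells_per_well`. With every well
#' empty the CE is exactly 0. With no empty well the CE is not estimable;
#' following the documented convention a flagged lower bound
#' `-ln(0.5 / wells_total) / cells_per_well` is returned with attribute
#' `lower_bound = TRUE`.
#'
#' @param wells_empty,wells_total well counts (plates pooled per condition).
#' @param cells_per_well expected cells seeded per well (1.6 for survivor
#'   plates, 2000 for TFT selection plates).
#' @return cloning efficiency per seeded cell.
#' @examples
#' cloning_efficiency(48, 96, 1.6)      # -ln(0.5)/1.6 = 0.4332
#' cloning_efficiency(380, 384, 2000)   # 5.238e-06
#' @export
cloning_efficiency <- function(wells_empty, wells_total,
                               cells_per_well = NV_CELLS_PER_WELL_SURVIVOR) {
  if (wells_total <= 0 || wells_empty < 0 || wells_empty > wells_total) {
    stop("need 0 <= wells_empty <= wells_total with wells_total > 0",
         call. = FALSE)
  }
  if (cells_per_well <= 0) stop("cells_per_well must be > 0", call. = FALSE)
  if (wells_empty == 0) {
    warning("all wells positive: returning a lower-bound cloning efficiency",
            call. = FALSE)
    ce <- -log(0.5 / wells_total) / cells_per_well
    attr(ce, "lower_bound") <- TRUE
    return(ce)
  }
  -log(wells_empty / wells_total) / cells_per_well
}

#' Relative suspension growth
#' @param sg_treatment,sg_control suspension growths.
#' @return RSG fraction.
#' @export
relative_suspension_growth <- function(sg_treatment, sg_control) {
  if (sg_control <= 0) stop("control suspension growth must be > 0",
                            call. = FALSE)
  sg_treatment / sg_control
}

#' Relative total growth
#' @param rsg relative suspension growth (fraction, >= 0).
#' @param rce relative cloning efficiency (fraction, >= 0).
#' @return RTG in percent.
#' @export
relative_total_growth <- function(rsg, rce) {
  if (rsg < 0 || rce < 0) stop("rsg and rce must be >= 0", call. = FALSE)
  rsg * rce * 100
}

#' Mutation frequency with small/large colony split
#'
#' `MF = CE_TFT / CE_survivor2`, where the TFT cloning efficiency uses the
#' pooled TFT selection plates (2000 cells/well). For the small-colony MF,
#' wells without small colonies are treated as empty (and likewise for large
#' colonies).
#'
#' @param tft list/row with `wells_total`, `wells_empty`, `wells_small`,
#'   `wells_large` for the pooled TFT plates.
#' @param survivor2 list/row with `wells_total`, `wells_empty` for the pooled
#'   survivor 2 plates.
#' @param cells_per_well_tft,cells_per_well_survivor seeding densities.
#' @return list with `mf`, `mf_small`, `mf_large` (fractions; multiply by 1e6
#'   for the conventional reporting scale), plus the component cloning
#'   efficiencies `ce_tft` and `ce_s2`.
#' @export
mutation_frequency <- function(tft, survivor2,
                               cells_per_well_tft = NV_CELLS_PER_WELL_TFT,
                               cells_per_well_survivor =
                                 NV_CELLS_PER_WELL_SURVIVOR) {
  ce_s2 <- cloning_efficiency(survivor2$wells_empty, survivor2$wells_total,
                              cells_per_well_survivor)
  if (ce_s2 <= 0) {
    stop("survivor-2 cloning efficiency is zero: mutation frequency undefined",
         call. = FALSE)
  }
  ce_tft <- cloning_efficiency(tft$wells_empty, tft$wells_total,
                               cells_per_well_tft)
  ce_small <- cloning_efficiency(tft$wells_total - tft$wells_small,
                                 tft$wells_total, cells_per_well_tft)
  ce_large <- cloning_efficiency(tft$wells_total - tft$wells_large,
                                 tft$wells_total, cells_per_well_tft)
  list(mf = as.numeric(ce_tft) / ce_s2,
       mf_small = as.numeric(ce_small) / ce_s2,
       mf_large = as.numeric(ce_large) / ce_s2,
       ce_tft = as.numeric(ce_tft), ce_s2 = ce_s2)
}

#' Global Evaluation Factor relevance call
#'
#' An induced mutation frequency is biologically relevant iff it exceeds the
#' vehicle-control MF by more than the GEF of 126e-6 (strict inequality;
#' boundary equality is negative).
#'
#' @param mf_treatment,mf_vehicle mutation frequencies as fractions (i.e.
#'   201.5e-6, not 201.5).
#' @param gef the Global Evaluation Factor (default 126e-6).
#' @return logical.
#' @examples
#' gef_call(1229.5e-6, 201.5e-6)  # TRUE
#' gef_call(232.9e-6, 201.5e-6)   # FALSE
#' @export
gef_call <- function(mf_treatment, mf_vehicle, gef = NV_GEF) {
  if (any(c(mf_treatment, mf_vehicle) < 0)) {
    stop("mutation frequencies must be >= 0", call. = FALSE)
  }
  mf_treatment > mf_vehicle + gef
}

#' Run the full MLA calculation chain on an experiment table
#'
#' Input: one row per condition with cell counts and pooled plate counts.
#' Required columns: `condition`, `setup_day0`, `count_day1`, `setup_day1`,
#' `count_day2`, `s1_total`, `s1_empty`, `s2_total`, `s2_empty`,
#' `tft_total`, `tft_empty`, `tft_small`, `tft_large`. The vehicle condition
#' must be named `"vehicle"`.
#'
#' @param experiment data.frame (or CSV path) as described.
#' @param cells_per_well_tft TFT seeding density (config-exposed; the
#'   guideline protocol gives 1e4 cells/mL x 200 uL = 2000).
#' @return data.frame mirroring the conventional MLA report: per condition
#'   `sg`, `rsg`, `ce_s1`, `ce_s2`, `ce_tft`, `rce`, `rtg`, `mf`, `mf_small`,
#'   `mf_large` (MFs on the 1e-6 scale) and the GEF `relevant` call.
#' @export
mla_run <- function(experiment, cells_per_well_tft = NV_CELLS_PER_WELL_TFT) {
  if (is.character(experiment)) experiment <- utils::read.csv(experiment)
  req <- c("condition", "setup_day0", "count_day1", "setup_day1",
           "count_day2", "s1_total", "s1_empty", "s2_total", "s2_empty",
           "tft_total", "tft_empty", "tft_small", "tft_large")
  missing <- setdiff(req, names(experiment))
  if (length(missing)) {
    stop("experiment table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!"vehicle" %in% experiment$condition) {
    stop("experiment table must contain a 'vehicle' condition", call. = FALSE)
  }
  one <- function(row) {
    sg <- suspension_growth(row$count_day1, row$setup_day0,
                            row$count_day2, row$setup_day1)
    ce_s1 <- as.numeric(cloning_efficiency(row$s1_empty, row$s1_total,
                                           NV_CELLS_PER_WELL_SURVIVOR))
    mfres <- mutation_frequency(
      list(wells_total = row$tft_total, wells_empty = row$tft_empty,
           wells_small = row$tft_small, wells_large = row$tft_large),
      list(wells_total = row$s2_total, wells_empty = row$s2_empty),
      cells_per_well_tft = cells_per_well_tft)
    data.frame(condition = row$condition, sg = sg, ce_s1 = ce_s1,
               ce_s2 = mfres$ce_s2, ce_tft = mfres$ce_tft,
               mf = mfres$mf, mf_small = mfres$mf_small,
               mf_large = mfres$mf_large)
  }
  base <- do.call(rbind, lapply(seq_len(nrow(experiment)), function(i) {
    one(experiment[i, ])
  }))
  veh <- base[base$condition == "vehicle", ]
  base$rsg <- base$sg / veh$sg
  base$rce <- base$ce_s2 / veh$ce_s2
  base$rtg <- base$rsg * base$rce * 100
  base$relevant <- vapply(base$mf, gef_call, logical(1), mf_vehicle = veh$mf)
  out <- base[, c("condition", "sg", "rsg", "ce_s1", "ce_s2", "ce_tft",
                  "rce", "rtg", "mf", "mf_small", "mf_large", "relevant")]
  out$mf <- out$mf * 1e6
  out$mf_small <- out$mf_small * 1e6
  out$mf_large <- out$mf_large * 1e6
  rownames(out) <- NULL
  out
}

#' OECD TG 490 validity-criteria report
#'
#' Checks the guideline acceptance criteria against a set of per-condition
#' MLA results:
#' vehicle MF in 50-170e-6; vehicle CE (survivor 2) in 65-120%; vehicle SG in
#' 8-32; positive-control MF at least 300e-6 above vehicle with small-colony
#' MF >= 150e-6 or >= 40% of the induced MF from small colonies;
#' positive-control RTG > 10%; top-dose RTG in 10-30%.
#'
#' @param results data.frame as returned by [mla_run()] (MFs on the 1e-6
#'   scale; `rtg` percent; `ce_s2` per-cell fraction). Conditions `"vehicle"`
#'   and `"positive"` are required, plus at least one treatment; the top dose
#'   is taken as the last treatment row.
#' @param override_note optional free-text note explaining why an overall
#'   verdict is maintained despite a failed criterion.
#' @return an `nv_validity` object: data.frame of criteria (`name`,
#'   `observed`, `lo`, `hi`, `pass`) with attributes `overall` and `note`.
#' @export
mla_validity_report <- function(results, override_note = NULL) {
  stopifnot(is.data.frame(results))
  need <- c("vehicle", "positive")
  if (!all(need %in% results$condition)) {
    stop("results must contain 'vehicle' and 'positive' conditions",
         call. = FALSE)
  }
  treats <- results[!results$condition %in% need, , drop = FALSE]
  if (!nrow(treats)) stop("results contain no treatment condition",
                          call. = FALSE)
  veh <- results[results$condition == "vehicle", ]
  pos <- results[results$condition == "positive", ]
  top <- treats[nrow(treats), ]

  crit <- function(name, observed, lo, hi) {
    data.frame(name = name, observed = observed, lo = lo, hi = hi,
               pass = observed >= lo & observed <= hi)
  }
  pos_induced <- pos$mf - veh$mf
  small_ok <- (pos$mf_small >= 150) ||
    (pos_induced > 0 && pos$mf_small / pos$mf >= 0.40)
  rep <- rbind(
    crit("vehicle MF [1e-6]", veh$mf, 50, 170),
    crit("vehicle CE survivor-2 [%]", veh$ce_s2 * 100, 65, 120),
    crit("vehicle SG", veh$sg, 8, 32),
    crit("positive MF - vehicle MF [1e-6]", pos_induced, 300, Inf),
    data.frame(name = "positive small-colony MF >= 150e-6 or >= 40% small",
               observed = pos$mf_small, lo = NA_real_, hi = NA_real_,
               pass = small_ok),
    crit("positive RTG [%]", pos$rtg, 10, Inf),
    crit("top-dose RTG [%]", top$rtg, 10, 30)
  )
  rownames(rep) <- NULL
  overall <- all(rep$pass)
  if (!overall && !is.null(override_note)) overall <- TRUE
  structure(rep, class = c("nv_validity", "data.frame"),
            overall = overall, note = override_note)
}

#' @export
print.nv_validity <- function(x, ...) {
  cat("OECD TG 490 validity criteria:\n")
  print.data.frame(x)
  cat("overall:", if (attr(x, "overall")) "PASS" else "FAIL", "\n")
  if (!is.null(attr(x, "note"))) cat("note:", attr(x, "note"), "\n")
  invisible(x)
}
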