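# Plate cytotoxicity normalization.
#
# LDH release (membrane integrity): percent cytotoxicity anchored at the
# vehicle control (0%) and the Triton X-100 lysed positive control (100%).
# WST-1 turnover (metabolic competence): percent viability anchored at the
# vehicle control (100%) and the positive control (0%).
# Signals are background-corrected absorbances (A_measurement - A_reference);
# technical replicate reads are averaged per sample before normalization, and
# normalization is applied per biological replicate against replicate-matched
# controls. Percentages are deliberately NOT clamped to [0, 100]: treatments
# healthier than the vehicle legitimately exceed 100% viability.

#' Percent cytotoxicity (LDH endpoint)
#'
#' `(treatment - vehicle) / (positive - vehicle) * 100` on background-
#' corrected signals.
#'
#' @param treatment,vehicle,positive corrected absorbance signals.
#' @return percent cytotoxicity (unclamped).
#' @examples
#' percent_cytotoxicity(0.55, 0.20, 0.90)  # 50
#' @export
percent_cytotoxicity <- function(treatment, vehicle, positive) {
  if (isTRUE(all.equal(positive, vehicle))) {
    stop("degenerate normalization: positive control equals vehicle control",
         call. = FALSE)
  }
  (treatment - vehicle) / (positive - vehicle) * 100
}

#' Percent viability (WST-1 endpoint)
#'
#' `100 - (vehicle - treatment) / (vehicle - positive) * 100` on background-
#' corrected signals.
#'
#' @inheritParams percent_cytotoxicity
#' @return percent viability (unclamped).
#' @examples
#' percent_viability(0.60, 1.00, 0.20)  # 50
#' @export
percent_viability <- function(treatment, vehicle, positive) {
  if (isTRUE(all.equal(vehicle, positive))) {
    stop("degenerate normalization: vehicle control equals positive control",
         call. = FALSE)
  }
  100 - (vehicle - treatment) / (vehicle - positive) * 100
}

#' Aggregate an absorbance well table into per-condition cytotoxicity results
#'
#' Expects one row per well read with columns `condition`, `replicate`
#' (biological replicate id), `read_index` (technical replicate),
#' `a_meas` and `a_ref`. Conditions named `"vehicle"` and `"positive"` must
#' be present. Per biological replicate, technical reads are averaged, the
#' corrected signal (`a_meas - a_ref`) is normalized against the replicate's
#' own vehicle and positive controls, and per-condition mean and SD over
#' biological replicates are reported.
#'
#' @param wells data.frame of well reads (see above), or path to such a CSV.
#' @param endpoint `"ldh_cytotoxicity_pct"` or `"wst_viability_pct"`.
#' @return data.frame with columns `condition`, `endpoint`, `mean`, `sd`,
#'   `n`, `single_replicate` (TRUE when sd is reported as 0 because only one
#'   biological replicate was available).
#' @export
aggregate_cytotox <- function(wells,
                              endpoint = c("ldh_cytotoxicity_pct",
                                           "wst_viability_pct")) {
  endpoint <- match.arg(endpoint)
  if (is.character(wells)) wells <- utils::read.csv(wells)
  req <- c("condition", "replicate", "a_meas", "a_ref")
  missing <- setdiff(req, names(wells))
  if (length(missing)) {
    stop("well table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!all(c("vehicle", "positive") %in% wells$condition)) {
    stop("well table must contain 'vehicle' and 'positive' conditions",
         call. = FALSE)
  }
  wells$signal <- wells$a_meas - wells$a_ref
  if (any(!is.finite(wells$signal))) {
    stop("non-finite absorbance signal in well table", call. = FALSE)
  }

  # technical replicates -> one signal per (condition, biological replicate)
  agg <- stats::aggregate(signal ~ condition + replicate, data = wells,
                          FUN = mean)

  conds <- setdiff(unique(agg$condition), c("vehicle", "positive"))
  conds <- c(conds, "vehicle", "positive")
  out <- lapply(conds, function(cond) {
    reps <- sort(unique(agg$replicate[agg$condition == cond]))
    vals <- vapply(reps, function(r) {
      tr <- agg$signal[agg$condition == cond & agg$replicate == r]
      vh <- agg$signal[agg$condition == "vehicle" & agg$replicate == r]
      ps <- agg$signal[agg$condition == "positive" & agg$replicate == r]
      if (!length(vh) || !length(ps)) {
        stop("replicate ", r, " lacks matched vehicle/positive controls",
             call. = FALSE)
      }
      if (endpoint == "ldh_cytotoxicity_pct") {
        percent_cytotoxicity(tr, vh, ps)
      } else {
        percent_viability(tr, vh, ps)
      }
    }, numeric(1))
    single <- length(vals) == 1L
    if (single) {
      warning("condition '", cond, "': single biological replicate, sd = 0",
              call. = FALSE)
    }
    data.frame(condition = cond, endpoint = endpoint,
               mean = mean(vals), sd = if (single) 0 else stats::sd(vals),
               n = length(vals), single_replicate = single)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
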