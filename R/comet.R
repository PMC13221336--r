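# Alkaline comet assay summarization.
#
# Endpoint: tail intensity (TI), the percent of nuclear DNA in the comet
# tail, scored per nucleus (nominally 100 nuclei per slide). The guideline
# summary measure per slide is the median; this package defaults to the
# arithmetic mean because genotoxicants that act on cycling cells produce a
# bimodal TI distribution (a large low-damage population plus a smaller
# highly damaged one), for which the median underestimates the effect
# whenever responders are under 50% of nuclei. A responder-fraction
# diagnostic (share of nuclei above a damage threshold) is reported next to
# both location measures.

#' Summarize one comet slide
#'
#' @param ti numeric vector of per-nucleus tail intensities (percent DNA in
#'   tail, each in `[0, 100]`); or a list with a `tail_intensities` field.
#' @param damage_threshold responders are nuclei with `TI > damage_threshold`
#'   (percent, in (0, 100); default 10).
#' @return data.frame with `mean_ti`, `median_ti`, `responder_fraction`,
#'   `n_nuclei`, `low_count` (TRUE when fewer than 100 nuclei were scored).
#' @examples
#' summarize_slide(c(rep(0, 80), rep(50, 20)))  # mean 10, median 0
#' @export
summarize_slide <- function(ti, damage_threshold = 10) {
  if (is.list(ti) && !is.null(ti$tail_intensities)) ti <- ti$tail_intensities
  ti <- as.numeric(ti)
  if (!length(ti)) stop("empty slide: no nuclei scored", call. = FALSE)
  if (any(!is.finite(ti)) || any(ti < 0) || any(ti > 100)) {
    stop("tail intensities must be finite and within [0, 100]", call. = FALSE)
  }
  if (!is.numeric(damage_threshold) || damage_threshold <= 0 ||
      damage_threshold >= 100) {
    stop("damage_threshold must be in (0, 100)", call. = FALSE)
  }
  low <- length(ti) < 100L
  if (low) {
    warning("slide has ", length(ti), " nuclei (nominal count is 100)",
            call. = FALSE)
  }
  data.frame(
    mean_ti = mean(ti),
    median_ti = stats::median(ti),
    responder_fraction = mean(ti > damage_threshold),
    n_nuclei = length(ti),
    low_count = low
  )
}

#' Summarize a comet experiment per condition
#'
#' Takes a per-nucleus table (columns `slide_id`, `condition`, `replicate`,
#' `ti`), summarizes each slide with [summarize_slide()], then reports
#' mean +/- SD of the chosen per-slide measure over independent cultures
#' (replicates) for each condition.
#'
#' @param nuclei data.frame of per-nucleus rows, or path to such a CSV.
#' @param mode per-slide summary measure fed into the condition aggregate:
#'   `"mean"` (default, bimodality-robust choice) or `"median"` (guideline).
#' @param damage_threshold passed to [summarize_slide()].
#' @return data.frame with `condition`, `mode`, `mean`, `sd`, `n` (cultures),
#'   `responder_fraction` (condition-pooled mean of slide responder
#'   fractions).
#' @export
summarize_condition <- function(nuclei, mode = c("mean", "median"),
                                damage_threshold = 10) {
  mode <- match.arg(mode)
  if (is.character(nuclei)) nuclei <- utils::read.csv(nuclei)
  req <- c("slide_id", "condition", "replicate", "ti")
  missing <- setdiff(req, names(nuclei))
  if (length(missing)) {
    stop("nucleus table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  slides <- unique(nuclei[, c("slide_id", "condition", "replicate")])
  slides$key <- paste(slides$condition, slides$replicate, slides$slide_id)
  per_slide <- do.call(rbind, lapply(seq_len(nrow(slides)), function(i) {
    sel <- nuclei$slide_id == slides$slide_id[i] &
      nuclei$condition == slides$condition[i] &
      nuclei$replicate == slides$replicate[i]
    cbind(slides[i, c("slide_id", "condition", "replicate")],
          summarize_slide(nuclei$ti[sel], damage_threshold))
  }))

  out <- lapply(unique(per_slide$condition), function(cond) {
    sl <- per_slide[per_slide$condition == cond, ]
    # one slide per culture is assumed; average slides within a culture first
    per_culture <- stats::aggregate(
      cbind(mean_ti, median_ti, responder_fraction) ~ replicate,
      data = sl, FUN = mean)
    vals <- if (mode == "mean") per_culture$mean_ti else per_culture$median_ti
    data.frame(
      condition = cond, mode = mode,
      mean = mean(vals),
      sd = if (length(vals) > 1L) stats::sd(vals) else 0,
      n = length(vals),
      responder_fraction = mean(per_culture$responder_fraction)
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
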