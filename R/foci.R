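# Immunofluorescence nucleus classification.
#
# gammaH2A.X (DNA double-strand break marker): a nucleus is positive when its
# mean staining intensity reaches the intensity threshold.
# pH3(S10) (mitosis marker): positive when the intensity threshold is reached
# AND the nucleus area falls inside a window (intensity alone misclassifies
# apoptotic debris and doublets).
# Guideline minimum nucleus counts: 2000 for gammaH2A.X, 5000 for pH3(S10);
# falling short sets a low_count flag but never suppresses output.

#' Classifier configuration for nucleus scoring
#'
#' The packaged default thresholds are calibrated on the synthetic generator
#' (intensity threshold at the 99th percentile of the background population);
#' with real instrument data they must be set from the instrument classifier.
#'
#' @param marker `"gh2ax"` or `"ph3"`.
#' @param intensity_threshold minimum mean intensity (a.u.) for a positive.
#' @param area_min,area_max area window (same units as the feature table),
#'   required for `"ph3"`, ignored for `"gh2ax"`.
#' @param min_nuclei minimum analyzable nuclei (defaults: 2000 gh2ax,
#'   5000 ph3).
#' @return an `nv_classifier` list.
#' @export
classifier_config <- function(marker = c("gh2ax", "ph3"),
                              intensity_threshold,
                              area_min = NULL, area_max = NULL,
                              min_nuclei = NULL) {
  marker <- match.arg(marker)
  if (missing(intensity_threshold) || !is.numeric(intensity_threshold)) {
    stop("intensity_threshold is required", call. = FALSE)
  }
  if (marker == "ph3") {
    if (is.null(area_min) || is.null(area_max)) {
      stop("ph3 classification requires area_min and area_max", call. = FALSE)
    }
    if (area_min >= area_max) stop("need area_min < area_max", call. = FALSE)
  }
  if (is.null(min_nuclei)) {
    min_nuclei <- if (marker == "gh2ax") 2000L else 5000L
  }
  structure(list(marker = marker,
                 intensity_threshold = intensity_threshold,
                 area_min = area_min, area_max = area_max,
                 min_nuclei = as.integer(min_nuclei)),
            class = "nv_classifier")
}

#' Classify nuclei and compute the positive proportion
#'
#' @param nuclei data.frame with columns `mean_intensity` and (for ph3)
#'   `area`; one row per nucleus.
#' @param cfg an `nv_classifier` from [classifier_config()].
#' @return list with `positive` (logical per nucleus), `proportion`,
#'   `n` and `low_count` (TRUE when `n < cfg$min_nuclei`).
#' @export
classify_nuclei <- function(nuclei, cfg) {
  stopifnot(inherits(cfg, "nv_classifier"), is.data.frame(nuclei))
  if (!nrow(nuclei)) stop("empty nucleus table", call. = FALSE)
  if (!"mean_intensity" %in% names(nuclei)) {
    stop("nucleus table lacks 'mean_intensity'", call. = FALSE)
  }
  if (any(nuclei$mean_intensity < 0)) {
    stop("mean_intensity must be >= 0", call. = FALSE)
  }
  pos <- nuclei$mean_intensity >= cfg$intensity_threshold
  if (cfg$marker == "ph3") {
    if (!"area" %in% names(nuclei)) {
      stop("ph3 classification requires an 'area' column", call. = FALSE)
    }
    if (any(nuclei$area <= 0)) stop("area must be > 0", call. = FALSE)
    pos <- pos & nuclei$area >= cfg$area_min & nuclei$area <= cfg$area_max
  }
  n <- nrow(nuclei)
  low <- n < cfg$min_nuclei
  if (low) {
    warning(cfg$marker, ": only ", n, " nuclei analyzed (minimum ",
            cfg$min_nuclei, ")", call. = FALSE)
  }
  list(positive = pos, proportion = mean(pos), n = n, low_count = low)
}

#' Per-condition summary of positive-nucleus proportions
#'
#' Classifies each replicate's nucleus table and aggregates the
#' replicate-level proportions into mean +/- SD per condition.
#'
#' @param nuclei data.frame (or CSV path) with columns `condition`,
#'   `replicate`, `mean_intensity` and, for ph3, `area`.
#' @param cfg an `nv_classifier`.
#' @return data.frame with `condition`, `mean`, `sd`, `n` (replicates),
#'   `n_nuclei` (total), `low_count` (any replicate under the minimum).
#' @export
foci_condition_summary <- function(nuclei, cfg) {
  if (is.character(nuclei)) nuclei <- utils::read.csv(nuclei)
  req <- c("condition", "replicate", "mean_intensity")
  missing <- setdiff(req, names(nuclei))
  if (length(missing)) {
    stop("nucleus table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!nrow(nuclei)) stop("empty nucleus table", call. = FALSE)
  out <- lapply(unique(nuclei$condition), function(cond) {
    sub <- nuclei[nuclei$condition == cond, , drop = FALSE]
    reps <- sort(unique(sub$replicate))
    cls <- lapply(reps, function(r) {
      classify_nuclei(sub[sub$replicate == r, , drop = FALSE], cfg)
    })
    props <- vapply(cls, `[[`, numeric(1), "proportion")
    data.frame(
      condition = cond,
      mean = mean(props),
      sd = if (length(props) > 1L) stats::sd(props) else 0,
      n = length(props),
      n_nuclei = sum(vapply(cls, `[[`, numeric(1), "n")),
      low_count = any(vapply(cls, `[[`, logical(1), "low_count"))
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
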