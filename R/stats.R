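# One-way ANOVA with Dunnett many-to-one post-hoc comparisons against the
# vehicle control.
#
# The adjusted p-value of comparison i is P(max_j |T_j| >= |t_i|) under the
# joint null distribution of the k contrasts (multivariate t with the
# many-to-one correlation structure; 0.5 for balanced designs). That joint
# tail is evaluated by Monte-Carlo simulation of the exact finite-sample
# null: independent group means plus a shared pooled chi-square variance,
# which reproduces the multivariate-t dependence without numerical
# quadrature. The draw count (default 2e5) puts the MC standard error of a
# p-value near 0.05 at about 5e-4.

#' One-way ANOVA with Dunnett's many-to-one comparisons
#'
#' @param data either a data.frame with columns `condition` and `value`
#'   (optionally `replicate`, ignored) or a named list of numeric vectors.
#' @param control name of the control (vehicle) condition.
#' @param alpha significance level for the `significant` flag (default 0.05).
#' @param ndraws Monte-Carlo draws for the joint null (>= 1e5).
#' @param seed RNG seed for the Monte-Carlo evaluation (fixed default so
#'   results are reproducible; change deliberately, not per run).
#' @return an `nv_dunnett` object: data.frame of comparisons (`condition`,
#'   `mean_diff`, `t_stat`, `p_adj`, `significant`, `stars`) with attributes
#'   `df` (residual degrees of freedom), `k`, `alpha`, `f_stat`, `f_p`
#'   (omnibus ANOVA, reported but not used as a gate), `ndraws`, `seed`.
#' @export
anova_dunnett <- function(data, control = "vehicle", alpha = 0.05,
                          ndraws = 2e5, seed = 104729L) {
  groups <- if (is.data.frame(data)) {
    if (!all(c("condition", "value") %in% names(data))) {
      stop("data.frame input needs 'condition' and 'value' columns",
           call. = FALSE)
    }
    split(data$value, data$condition)
  } else if (is.list(data)) {
    data
  } else {
    stop("data must be a data.frame or a named list", call. = FALSE)
  }
  if (!control %in% names(groups)) {
    stop("control condition '", control, "' not found", call. = FALSE)
  }
  if (length(groups) < 2L) stop("need at least two groups", call. = FALSE)
  sizes <- vapply(groups, length, integer(1))
  if (any(sizes < 2L)) {
    stop("every group needs >= 2 replicates", call. = FALSE)
  }
  if (ndraws < 1e5) stop("ndraws must be >= 1e5", call. = FALSE)

  treat_names <- setdiff(names(groups), control)
  k <- length(treat_names)
  n0 <- sizes[[control]]
  ni <- sizes[treat_names]
  N <- sum(sizes)
  df <- N - length(groups)

  means <- vapply(groups, mean, numeric(1))
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2),
                          numeric(1)))
  if (ss_within <= 0) {
    stop("zero pooled variance: all groups are constant", call. = FALSE)
  }
  s2 <- ss_within / df

  # omnibus F (reported, not a gate for the comparisons)
  grand <- sum(vapply(groups, sum, numeric(1))) / N
  ss_between <- sum(sizes * (means - grand)^2)
  f_stat <- (ss_between / (length(groups) - 1)) / s2
  f_p <- stats::pf(f_stat, length(groups) - 1, df, lower.tail = FALSE)

  t_stat <- (means[treat_names] - means[[control]]) /
    sqrt(s2 * (1 / ni + 1 / n0))

  maxt <- nv_dunnett_null_maxt(ni, n0, df, ndraws, seed)
  p_adj <- vapply(abs(t_stat), function(t) mean(maxt >= t), numeric(1))
  p_adj <- pmin(1, pmax(p_adj, 1 / ndraws))

  stars <- vapply(p_adj, function(p) {
    if (p <= 0.001) "***" else if (p <= 0.01) "**"
    else if (p <= 0.05) "*" else ""
  }, character(1))

  out <- data.frame(condition = treat_names,
                    mean_diff = unname(means[treat_names] - means[[control]]),
                    t_stat = unname(t_stat),
                    p_adj = unname(p_adj),
                    significant = unname(p_adj <= alpha),
                    stars = stars)
  rownames(out) <- NULL
  structure(out, class = c("nv_dunnett", "data.frame"),
            df = df, k = k, alpha = alpha, f_stat = f_stat, f_p = f_p,
            ndraws = ndraws, seed = seed, control = control)
}

# Monte-Carlo sample of max_j |T_j| under the complete null for the
# many-to-one design: T_j = (Zbar_j - Zbar_0) / sqrt(s2 (1/n_j + 1/n_0)),
# Zbar_g ~ N(0, 1/n_g) independent, s2 ~ chi2_df / df shared.
nv_dunnett_null_maxt <- function(ni, n0, df, ndraws, seed) {
  key <- paste0("maxt:", paste(ni, collapse = ","), ":", n0, ":", df, ":",
                ndraws, ":", seed)
  cached <- .nv_env[[key]]
  if (!is.null(cached)) return(cached)
  maxt <- nv_with_seed(seed, {
    z0 <- stats::rnorm(ndraws, sd = sqrt(1 / n0))
    s <- sqrt(stats::rchisq(ndraws, df) / df)
    m <- matrix(0, nrow = ndraws, ncol = length(ni))
    for (j in seq_along(ni)) {
      zj <- stats::rnorm(ndraws, sd = sqrt(1 / ni[j]))
      m[, j] <- abs(zj - z0) / (s * sqrt(1 / ni[j] + 1 / n0))
    }
    apply(m, 1, max)
  })
  assign(key, maxt, envir = .nv_env)
  maxt
}

#' Two-sided Dunnett critical value (Monte-Carlo)
#'
#' The 1-alpha quantile of `max_j |T_j|` under the complete null; group means
#' differ from the control significantly (family-wise level alpha) exactly
#' when `|t_j|` exceeds this value.
#'
#' @param ni integer vector of treatment group sizes.
#' @param n0 control group size.
#' @param df residual degrees of freedom of the pooled variance.
#' @param alpha family-wise error level.
#' @inheritParams anova_dunnett
#' @return the critical value (numeric scalar).
#' @export
dunnett_critical_value <- function(ni, n0, df, alpha = 0.05, ndraws = 2e5,
                                   seed = 104729L) {
  maxt <- nv_dunnett_null_maxt(ni, n0, df, ndraws, seed)
  stats::quantile(maxt, 1 - alpha, names = FALSE)
}

#' @export
print.nv_dunnett <- function(x, ...) {
  cat(sprintf(
    "One-way ANOVA: F = %.3f (p = %.4g), df residual = %d\n",
    attr(x, "f_stat"), attr(x, "f_p"), attr(x, "df")))
  cat(sprintf("Dunnett many-to-one vs '%s' (k = %d, alpha = %g, MC %g draws)\n",
              attr(x, "control"), attr(x, "k"), attr(x, "alpha"),
              attr(x, "ndraws")))
  print.data.frame(x, digits = 4)
  invisible(x)
}

# evaluate expr under a temporary RNG state
nv_with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
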