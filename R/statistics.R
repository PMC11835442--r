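#' Group / ROI / segment summary of an analysis table
#'
#' Mean, standard deviation (n-1 denominator) and block count of each metric
#' per (group, roi, segment), plus pooled rows with `segment = "all"` —
#' the layout of a "Mean +/- SD by group and ROI" results table. Only
#' included blocks enter. A single-block cell reports SD 0 and is flagged.
#'
#' @param table An `analysis_table` tibble from [join_blocks()].
#' @return Tibble with columns `group`, `roi`, `segment`, `metric_name`,
#'   `mean`, `sd`, `n_blocks`, `single_block`.
#' @export
summarize_blocks <- function(table) {
  tb <- dplyr::filter(table, .data$included)
  if (nrow(tb) == 0) abort("no included blocks to summarise")
  one <- function(d) {
    dplyr::summarise(
      d,
      mean = mean(.data$metric_value),
      sd = ifelse(dplyr::n() == 1, 0, stats::sd(.data$metric_value)),
      n_blocks = dplyr::n(),
      single_block = dplyr::n() == 1,
      .groups = "drop"
    )
  }
  per_seg <- one(dplyr::group_by(
    dplyr::mutate(tb, segment = as.character(.data$segment)),
    .data$group, .data$roi, .data$segment, .data$metric_name))
  pooled <- one(dplyr::group_by(
    dplyr::mutate(tb, segment = "all"),
    .data$group, .data$roi, .data$segment, .data$metric_name))
  dplyr::arrange(dplyr::bind_rows(per_seg, pooled),
                 .data$metric_name, .data$group, .data$roi, .data$segment)
}

#' Covariate-adjusted ANOVA on block data
#'
#' General-linear-model ANOVA: the response is regressed on dummy-coded
#' factors plus numeric covariates by least squares, and each effect is
#' tested with a Type II F statistic (residual sums of squares of nested
#' models). Mirrors the analysis convention of comparing pathology metrics
#' between groups and ROIs while controlling for covariates such as age,
#' with Bonferroni correction over the tested effects.
#'
#' @param data Data frame (first argument, pipe-friendly).
#' @param response Name of the response column.
#' @param factors Character vector of factor column names (each needs >= 2
#'   levels).
#' @param covariates Character vector of numeric covariate column names.
#' @param bonferroni_m Number of tests for the Bonferroni correction; default
#'   is the number of tested effects.
#' @return Object of class `wm_anova`; use [tidy()] for the effect table and
#'   [glance()] for model-level statistics.
#' @export
anova_glm <- function(data, response, factors, covariates = character(),
                      bonferroni_m = NULL) {
  stopifnot(is.data.frame(data))
  for (f in factors) {
    lv <- unique(stats::na.omit(data[[f]]))
    if (length(lv) < 2) abort(sprintf("factor '%s' has fewer than 2 levels", f))
    data[[f]] <- factor(data[[f]])
  }
  rhs <- paste(c(factors, covariates), collapse = " + ")
  if (rhs == "") rhs <- "1"
  fml <- stats::as.formula(paste(response, "~", rhs))
  fit <- stats::lm(fml, data = data)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    abort(paste("design matrix is rank deficient; aliased terms:",
                paste(bad, collapse = ", ")))
  }
  av <- tryCatch(car::Anova(fit, type = 2), error = function(e) NULL)
  if (is.null(av)) {
    # degenerate perfect fit (zero residual SS): a constant response carries
    # no evidence against any effect -> F = 0, p = 1
    if (stats::var(data[[response]]) < 1e-24) {
      terms <- c(factors, covariates)
      dfs <- vapply(terms, function(tm) {
        if (is.factor(data[[tm]])) nlevels(data[[tm]]) - 1L else 1L
      }, integer(1))
      tab <- tibble::tibble(
        effect = terms, df = dfs,
        df_residual = nrow(data) - sum(dfs) - 1L,
        sum_sq = 0, statistic = 0, p_raw = 1,
        p_bonferroni = 1)
      m <- bonferroni_m %||% length(terms)
      return(structure(list(model = fit, table = tab,
                            formula = fml, m = m, ss_type = "II"),
                       class = "wm_anova"))
    }
    abort("ANOVA failed: zero residual variance with non-constant response")
  }
  eff <- rownames(av)
  keep <- eff != "Residuals"
  m <- bonferroni_m %||% sum(keep)
  tab <- tibble::tibble(
    effect = eff[keep],
    df = av$Df[keep],
    df_residual = av$Df[!keep],
    sum_sq = av$`Sum Sq`[keep],
    statistic = av$`F value`[keep],
    p_raw = av$`Pr(>F)`[keep],
    p_bonferroni = bonferroni(av$`Pr(>F)`[keep], m)
  )
  structure(list(model = fit, table = tab, formula = fml, m = m,
                 ss_type = "II"),
            class = "wm_anova")
}

#' @export
print.wm_anova <- function(x, ...) {
  cat("Type II ANOVA (", deparse(x$formula), "), Bonferroni m = ", x$m,
      "\n", sep = "")
  print(x$table)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the effect table of a [anova_glm()] fit
#' @param x A `wm_anova` object.
#' @param ... Unused.
#' @return Tibble with one row per tested effect.
#' @exportS3Method generics::tidy
tidy.wm_anova <- function(x, ...) x$table

#' Model-level statistics of a [anova_glm()] fit
#' @param x A `wm_anova` object.
#' @param ... Unused.
#' @return One-row tibble with fit statistics.
#' @exportS3Method generics::glance
glance.wm_anova <- function(x, ...) {
  s <- summary(x$model)
  tibble::tibble(
    r.squared = s$r.squared,
    adj.r.squared = s$adj.r.squared,
    sigma = s$sigma,
    df_residual = x$model$df.residual,
    nobs = length(stats::residuals(x$model))
  )
}

#' Bonferroni correction
#'
#' `p_adj = min(1, m * p)`; never decreases a p value.
#'
#' @param p Raw p values.
#' @param m Number of comparisons.
#' @return Adjusted p values in `[0, 1]`.
#' @export
bonferroni <- function(p, m) {
  stopifnot(m >= 1)
  pmin(1, m * p)
}

#' Pairwise segment contrasts within an ROI
#'
#' Compares the metric between every pair of intensity segments (1 vs 2,
#' 1 vs 3, 2 vs 3) inside one ROI with a two-group one-way ANOVA F test
#' (equivalently t^2) and Bonferroni correction over the three comparisons.
#' The direction of each contrast (difference of segment means) is reported
#' alongside.
#'
#' @param table An `analysis_table` tibble.
#' @param metric Metric name to test.
#' @param roi `"WMH"` or `"NAWM"`.
#' @param alpha Significance level after correction (default 0.05).
#' @return Tibble with one row per segment pair: means, mean difference
#'   (higher minus lower segment), F, dfs, raw and Bonferroni p, significance.
#' @export
pairwise_segments <- function(table, metric, roi, alpha = 0.05) {
  tb <- dplyr::filter(table, .data$included,
                      .data$metric_name == metric, .data$roi == !!roi)
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  rows <- purrr::map(pairs, function(pr) {
    d <- dplyr::filter(tb, .data$segment %in% pr)
    n1 <- sum(d$segment == pr[1]); n2 <- sum(d$segment == pr[2])
    if (n1 < 2 || n2 < 2) {
      abort(sprintf("segment %d vs %d in %s: a segment has < 2 blocks",
                    pr[1], pr[2], roi))
    }
    fit <- stats::lm(metric_value ~ factor(segment), data = d)
    av <- stats::anova(fit)
    m1 <- mean(d$metric_value[d$segment == pr[1]])
    m2 <- mean(d$metric_value[d$segment == pr[2]])
    tibble::tibble(
      comparison = sprintf("%d vs %d", pr[2], pr[1]),
      roi = roi, metric_name = metric,
      mean_low_segment = m1, mean_high_segment = m2,
      difference = m2 - m1,
      statistic = av$`F value`[1],
      df = av$Df[1], df_residual = av$Df[2],
      p_raw = av$`Pr(>F)`[1]
    )
  })
  out <- dplyr::bind_rows(rows)
  out$p_bonferroni <- bonferroni(out$p_raw, 3)
  out$significant <- out$p_bonferroni < alpha
  out
}

#' Pearson correlation with t-based p value
#'
#' Product-moment correlation between block-level MRI signal and a pathology
#' metric; two-tailed p from `t = r * sqrt((n - 2) / (1 - r^2))`. The
#' significance flag uses the correlation convention `alpha = 0.01`.
#'
#' @param x,y Numeric vectors (length >= 3, non-zero variance).
#' @param alpha Significance level (default 0.01).
#' @return One-row tibble with `r`, `n`, `df`, `statistic`, `p_value`,
#'   `significant`.
#' @export
pearson <- function(x, y, alpha = 0.01) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) abort("need at least 3 complete pairs")
  if (var(x) == 0 || var(y) == 0) abort("zero variance in x or y")
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(
    r = unname(ct$estimate), n = length(x), df = unname(ct$parameter),
    statistic = unname(ct$statistic), p_value = ct$p.value,
    significant = ct$p.value < alpha
  )
}

#' Percent difference between two means
#'
#' Reporting convention `100 * (mean_b - mean_a) / mean_a`, e.g. "the degree
#' of myelin was 53.6% lower" corresponds to a value of -53.6 with
#' `mean_a` the reference (segment 1 or control) mean.
#'
#' @param mean_a Reference mean (non-zero).
#' @param mean_b Comparison mean.
#' @return Signed percent difference.
#' @export
percent_difference <- function(mean_a, mean_b) {
  if (any(mean_a == 0)) abort("reference mean is zero")
  100 * (mean_b - mean_a) / mean_a
}
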