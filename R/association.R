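#' Spearman rank correlation with t-approximation p-value
#'
#' Pearson correlation of the average-ranked values (ties receive average
#' ranks), with the two-sided p-value from the standard t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 3, nonconstant.
#' @return List with `rho` and `p`.
#' @export
spearman_assoc <- function(x, y) {
  if (length(x) != length(y)) stop_gs("length mismatch")
  n <- length(x)
  if (n < 3) stop_gs("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop_gs("constant input")
  rho <- stats::cor(rank(x, ties.method = "average"),
                    rank(y, ties.method = "average"))
  p <- if (abs(rho) >= 1) {
    0
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p = p)
}

#' Ordinary least-squares fit with slope test
#'
#' Least-squares line `y = intercept + slope * x` and the two-sided t-test
#' of `slope = 0` (delegates to `stats::lm`).
#'
#' @param x,y Numeric vectors of equal length >= 3; `x` nonconstant.
#' @return List with `slope`, `intercept` and `slope_p`.
#' @export
ols_fit <- function(x, y) {
  if (length(x) != length(y)) stop_gs("length mismatch")
  if (length(x) < 3) stop_gs("need at least 3 observations")
  if (stats::sd(x) == 0) stop_gs("constant predictor")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)$coefficients
  list(slope = unname(sm["x", "Estimate"]),
       intercept = unname(sm["(Intercept)", "Estimate"]),
       slope_p = unname(sm["x", "Pr(>|t|)"]))
}

#' Associate divergence metrics with classification scores
#'
#' Joins a table of per-condition divergence metrics with per-condition
#' classification scores and, for each metric column, computes the
#' Spearman rank correlation and the OLS fit of score on metric -- the
#' analysis that asks whether signals (or experimental conditions) whose
#' laboratories differ more in correlation/spectral structure are also
#' easier to classify.
#'
#' @param metrics Tibble with a `condition` column and one column per
#'   divergence metric.
#' @param scores Tibble with columns `condition` and `score`.
#' @param metric_cols Metric columns to analyze (default: all numeric
#'   columns of `metrics` except `condition`).
#' @return Tibble with one row per metric: `metric`, `n`, `rho`, `rho_p`,
#'   `slope`, `intercept`, `slope_p`.
#' @export
associate <- function(metrics, scores, metric_cols = NULL) {
  if (!"condition" %in% names(metrics) || !"condition" %in% names(scores)) {
    stop_gs("both tables need a 'condition' column")
  }
  metrics_only <- metrics[, setdiff(names(metrics), "score"), drop = FALSE]
  joined <- dplyr::inner_join(metrics_only,
                              scores[, c("condition", "score")],
                              by = "condition")
  if (nrow(joined) < 3) stop_gs("fewer than 3 matched conditions")
  if (stats::sd(joined$score) == 0) {
    stop_gs("degenerate: scores have zero variance")
  }
  metric_cols <- metric_cols %||%
    setdiff(names(metrics)[vapply(metrics, is.numeric, logical(1))],
            "condition")
  dplyr::bind_rows(lapply(metric_cols, function(mc) {
    x <- joined[[mc]]
    sp <- spearman_assoc(x, joined$score)
    ol <- ols_fit(x, joined$score)
    tibble::tibble(metric = mc, n = nrow(joined), rho = sp$rho,
                   rho_p = sp$p, slope = ol$slope,
                   intercept = ol$intercept, slope_p = ol$slope_p)
  }))
}
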