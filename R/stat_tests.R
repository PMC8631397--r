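# The classical statistical layer used by the analysis: two-sample t,
# variance F-test, Kruskal-Wallis, Pearson correlation, and regression
# influence diagnostics for subject exclusion. Computation is delegated to
# the stats package behind a uniform result type with the preconditions this
# pipeline requires.

.new_test <- function(method, statistic, df, p_value, n, estimate = NULL) {
  stopifnot(p_value >= 0, p_value <= 1)
  structure(list(method = method, statistic = unname(statistic),
                 df = unname(df), p_value = unname(p_value), n = n,
                 estimate = unname(estimate)),
            class = "oculo_test")
}

#' @export
print.oculo_test <- function(x, ...) {
  dfs <- paste(signif(x$df, 4), collapse = ", ")
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g (n = %s)\n",
              x$method, x$statistic, dfs, x$p_value,
              paste(x$n, collapse = ", ")))
  if (!is.null(x$estimate)) cat(sprintf("  estimate = %.4g\n", x$estimate))
  invisible(x)
}

.check_sample <- function(x, name, min_n = 2) {
  if (!is.numeric(x) || length(x) < min_n || anyNA(x)) {
    stop(name, " must be numeric with at least ", min_n, " non-missing values")
  }
}

#' Two-sample Student's t-test
#'
#' Pooled-variance (classical Student) form by default; `pooled = FALSE`
#' gives the Welch variant. Two-sided.
#'
#' @param a,b Numeric samples (each >= 2 values; combined variance > 0).
#' @param pooled Use the pooled-variance form (default `TRUE`).
#' @return An `oculo_test` with `statistic`, `df`, `p_value`, `n`.
#' @export
students_t <- function(a, b, pooled = TRUE) {
  .check_sample(a, "a"); .check_sample(b, "b")
  if (stats::var(a) + stats::var(b) == 0) {
    stop("degenerate samples: zero combined variance")
  }
  ht <- stats::t.test(a, b, var.equal = pooled)
  .new_test(if (pooled) "Student's t (pooled)" else "Welch t",
            ht$statistic, ht$parameter, ht$p.value,
            c(length(a), length(b)),
            estimate = mean(a) - mean(b))
}

#' F-test for equality of two variances
#'
#' F is the ratio of sample variances with (n_a - 1, n_b - 1) degrees of
#' freedom; the p-value is two-sided (twice the smaller tail).
#'
#' @param a,b Numeric samples, each with positive variance.
#' @return An `oculo_test`; `estimate` is the variance ratio.
#' @export
variance_f_test <- function(a, b) {
  .check_sample(a, "a"); .check_sample(b, "b")
  if (stats::var(a) == 0 || stats::var(b) == 0) {
    stop("zero variance: F-test undefined")
  }
  ht <- stats::var.test(a, b)
  .new_test("variance F", ht$statistic, ht$parameter, ht$p.value,
            c(length(a), length(b)), estimate = ht$estimate)
}

#' Kruskal-Wallis rank test across groups
#'
#' Rank-based H statistic with tie correction; p from the chi-square
#' approximation with k - 1 degrees of freedom.
#'
#' @param groups List of >= 2 numeric samples (total n >= 3).
#' @return An `oculo_test`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    stop("need at least 2 groups")
  }
  x <- unlist(groups, use.names = FALSE)
  if (length(x) < 3) stop("need at least 3 observations in total")
  if (anyNA(x)) stop("missing values in groups")
  if (length(unique(x)) == 1) {
    stop("all values identical: H undefined under total ties")
  }
  g <- factor(rep(seq_along(groups), lengths(groups)))
  ht <- stats::kruskal.test(x, g)
  .new_test("Kruskal-Wallis H", ht$statistic, ht$parameter, ht$p.value,
            lengths(groups))
}

#' Pearson correlation with significance
#'
#' Two-sided p via the t transform `r * sqrt((n - 2) / (1 - r^2))` with
#' n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length (n >= 3), both non-constant.
#' @return An `oculo_test`; `estimate` is r.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  .check_sample(x, "x", 3); .check_sample(y, "y", 3)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("constant input: correlation undefined")
  }
  ht <- stats::cor.test(x, y, method = "pearson")
  .new_test("Pearson correlation", ht$statistic, ht$parameter, ht$p.value,
            length(x), estimate = ht$estimate)
}

#' Influence-diagnostic cutoffs
#'
#' Conventional flag thresholds for a simple linear regression with p = 2
#' parameters: leverage above `3p/n`, absolute standardized residual above
#' 2, Cook's D above the median of F(p, n - p), absolute DFITS above
#' `2 * sqrt(p/n)`.
#'
#' @param leverage_factor,resid_cut,dfits_factor,cooks_quantile Tunable
#'   multipliers of the conventions above.
#' @return A named list.
#' @export
influence_cutoffs <- function(leverage_factor = 3, resid_cut = 2,
                              dfits_factor = 2, cooks_quantile = 0.5) {
  list(leverage_factor = leverage_factor, resid_cut = resid_cut,
       dfits_factor = dfits_factor, cooks_quantile = cooks_quantile)
}

#' Regression influence diagnostics for subject exclusion
#'
#' Fits the simple linear regression `y ~ x` and reports per-observation
#' leverage, internally studentized residual, Cook's distance and DFITS,
#' with a flag per observation naming every exceeded criterion. Flagged
#' observations are the candidates for exclusion before correlation
#' analysis.
#'
#' @param x,y Numeric vectors (n >= 4, `x` non-constant).
#' @param cutoffs See [influence_cutoffs()].
#' @return An `influence_report`: data frame with columns `leverage`,
#'   `std_residual`, `cooks_d`, `dfits`, `flagged`, `criteria`, plus the
#'   fitted model in attribute `"model"`.
#' @export
regression_influence <- function(x, y, cutoffs = influence_cutoffs()) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  .check_sample(x, "x", 4); .check_sample(y, "y", 4)
  if (stats::var(x) == 0) stop("constant x: regression undefined")
  n <- length(x)
  p <- 2
  fit <- stats::lm(y ~ x)
  h <- unname(stats::hatvalues(fit))
  exact_fit <- sum(stats::residuals(fit)^2) < 1e-12 * max(1, sum(y^2))
  if (exact_fit) {
    rs <- rep(0, n); cd <- rep(0, n); df_ <- rep(0, n)
  } else {
    rs <- unname(stats::rstandard(fit))
    cd <- unname(stats::cooks.distance(fit))
    df_ <- unname(stats::dffits(fit))
  }
  lev_cut <- cutoffs$leverage_factor * p / n
  cook_cut <- stats::qf(cutoffs$cooks_quantile, p, n - p)
  dfits_cut <- cutoffs$dfits_factor * sqrt(p / n)
  crit <- vapply(seq_len(n), function(i) {
    hits <- c(if (h[i] > lev_cut) "leverage",
              if (abs(rs[i]) > cutoffs$resid_cut) "residual",
              if (cd[i] > cook_cut) "cooks_d",
              if (abs(df_[i]) > dfits_cut) "dfits")
    paste(hits, collapse = "+")
  }, character(1))
  out <- data.frame(leverage = h, std_residual = rs, cooks_d = cd,
                    dfits = df_, flagged = nzchar(crit), criteria = crit,
                    stringsAsFactors = FALSE)
  attr(out, "cutoffs") <- c(leverage = lev_cut, residual = cutoffs$resid_cut,
                            cooks_d = cook_cut, dfits = dfits_cut)
  attr(out, "model") <- fit
  class(out) <- c("influence_report", "data.frame")
  out
}

#' @export
print.influence_report <- function(x, ...) {
  cat(sprintf("Influence report over %d observations; %d flagged\n",
              nrow(x), sum(x$flagged)))
  cuts <- attr(x, "cutoffs")
  cat(sprintf("  cutoffs: leverage > %.3g, |std resid| > %.3g, Cook's D > %.3g, |DFITS| > %.3g\n",
              cuts["leverage"], cuts["residual"], cuts["cooks_d"], cuts["dfits"]))
  if (any(x$flagged)) {
    print.data.frame(x[x$flagged, c("leverage", "std_residual", "cooks_d",
                                    "dfits", "criteria")])
  }
  invisible(x)
}
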