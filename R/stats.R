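#' Nonparametric comparisons across resistance levels
#'
#' Metrics are compared between conditions with the two-sided Mann-Whitney
#' U test (exact null when both samples are small and tie-free, otherwise a
#' tie-corrected normal approximation with continuity correction), without
#' multiple-comparison correction by default.
#'
#' @name group_stats
NULL

#' Two-sided Mann-Whitney U test
#'
#' @param x,y numeric samples with at least 2 observations each.
#' @param exact_max_n exact null enumeration is used when both sample sizes
#'   are at most this and there are no ties; default 20.
#' @return one-row data.frame: `U`, `p_value`, `n_a`, `n_b`, `exact`,
#'   `significant_at_0_05`.
#' @export
mann_whitney_u <- function(x, y, exact_max_n = 20L) {
  if (length(x) < 2L || length(y) < 2L) {
    stop("both samples need >= 2 observations")
  }
  if (!all(is.finite(c(x, y)))) stop("samples must be finite")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && length(x) <= exact_max_n && length(y) <= exact_max_n
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = TRUE)
  )
  data.frame(U = unname(wt$statistic), p_value = wt$p.value,
             n_a = length(x), n_b = length(y), exact = exact,
             significant_at_0_05 = wt$p.value < 0.05)
}

#' Wilcoxon signed-rank test (paired alternative)
#'
#' @param x,y paired numeric samples of equal length.
#' @return one-row data.frame as in [mann_whitney_u()] (`U` holds the
#'   signed-rank statistic V).
#' @export
signed_rank_test <- function(x, y) {
  if (length(x) != length(y)) stop("paired samples must have equal length")
  wt <- suppressWarnings(wilcox.test(x, y, paired = TRUE))
  data.frame(U = unname(wt$statistic), p_value = wt$p.value,
             n_a = length(x), n_b = length(y), exact = NA,
             significant_at_0_05 = wt$p.value < 0.05)
}

#' Pairwise condition comparisons of a metric
#'
#' Tests every unordered pair of condition levels on a long-format metric
#' table. No multiplicity correction is applied by default (raw p < 0.05
#' convention); Holm adjustment is available via `p_adjust = "holm"`.
#'
#' @param metric_table data.frame with at least a condition column and a
#'   value column.
#' @param metric_name label copied into the results.
#' @param condition_col,value_col column names, defaults `"condition"` and
#'   `"value"`.
#' @param method `"mann_whitney"` (default) or `"signed_rank"`.
#' @param alpha significance level for flagging, default 0.05.
#' @param p_adjust `"none"` (default) or any [stats::p.adjust()] method.
#' @param exact_max_n passed to [mann_whitney_u()].
#' @return data.frame: one row per condition pair with `metric_name`,
#'   `condition_a`, `condition_b`, `U`, `p_value`, `n_a`, `n_b`,
#'   `significant_at_0_05`.
#' @export
pairwise_tests <- function(metric_table, metric_name = "metric",
                           condition_col = "condition", value_col = "value",
                           method = c("mann_whitney", "signed_rank"),
                           alpha = 0.05, p_adjust = "none",
                           exact_max_n = 20L) {
  method <- match.arg(method)
  cond <- metric_table[[condition_col]]
  vals <- metric_table[[value_col]]
  if (is.null(cond) || is.null(vals)) stop("condition/value column missing")
  levels_all <- sort(unique(cond))
  usable <- levels_all[vapply(levels_all,
                              function(l) sum(cond == l) >= 2L, logical(1))]
  dropped <- setdiff(levels_all, usable)
  if (length(dropped)) {
    warning(sprintf("conditions with < 2 values skipped: %s",
                    paste(dropped, collapse = ", ")))
  }
  if (length(usable) < 2L) stop("need >= 2 usable condition levels")
  pairs <- utils::combn(usable, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    x <- vals[cond == a]; y <- vals[cond == b]
    res <- if (method == "mann_whitney") {
      mann_whitney_u(x, y, exact_max_n)
    } else {
      signed_rank_test(x, y)
    }
    cbind(data.frame(metric_name = metric_name, condition_a = a,
                     condition_b = b), res)
  })
  out <- do.call(rbind, rows)
  out$p_value_adj <- stats::p.adjust(out$p_value, method = p_adjust)
  out$significant_at_0_05 <- out$p_value_adj < alpha
  out
}
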