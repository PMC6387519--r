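# Thin tidy wrappers around the standard statistical tests used in the
# comparative analyses. All delegate to stats:: and return broom-tidied
# one-row tibbles; degenerate inputs surface as missing statistics rather
# than errors.

tidy_or_na <- function(expr) {
  out <- tryCatch(suppressMessages(broom::tidy(expr)),
                  error = function(e) NULL)
  if (is.null(out)) {
    tibble::tibble(statistic = NA_real_, p.value = NA_real_)
  } else out
}

#' Two-sample or paired t-test, tidied
#'
#' Welch (unequal-variance) by default, matching the cohort signature test.
#'
#' @param x,y Numeric vectors.
#' @param paired Paired test (default `FALSE`).
#' @param ... Passed to [stats::t.test()].
#' @return One-row tibble (broom layout); `NA` statistics on degenerate
#'   input (e.g. zero variance).
#' @export
ssr_t_test <- function(x, y, paired = FALSE, ...) {
  tidy_or_na(stats::t.test(x, y, paired = paired, var.equal = FALSE, ...))
}

#' F-test of equal variances, tidied
#' @inheritParams ssr_t_test
#' @param ... Passed to [stats::var.test()].
#' @return One-row tibble.
#' @export
ssr_var_test <- function(x, y, ...) {
  tidy_or_na(stats::var.test(x, y, ...))
}

#' Fisher's exact test on a 2x2 table, tidied
#' @param tbl 2x2 matrix of counts.
#' @param ... Passed to [stats::fisher.test()].
#' @return One-row tibble.
#' @export
ssr_fisher_test <- function(tbl, ...) {
  tidy_or_na(stats::fisher.test(tbl, ...))
}

#' Pearson or Spearman correlation test, tidied
#' @inheritParams ssr_t_test
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param ... Passed to [stats::cor.test()].
#' @return One-row tibble.
#' @export
ssr_cor_test <- function(x, y, method = "pearson", ...) {
  tidy_or_na(stats::cor.test(x, y, method = method, ...))
}
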