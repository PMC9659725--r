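#' Tidy a test report
#'
#' @param x An `ecsig_test_report` (e.g. from [logrank_test()]).
#' @param ... Unused.
#' @return One-row tibble: `test`, `statistic`, `df`, `p_value`, `n`.
#' @method tidy ecsig_test_report
#' @export
tidy.ecsig_test_report <- function(x, ...) {
  tibble(test = x$test, statistic = x$statistic, df = x$df,
         p_value = x$p_value, n = x$n)
}

#' @method glance ecsig_test_report
#' @export
glance.ecsig_test_report <- function(x, ...) tidy(x)

#' @export
print.ecsig_test_report <- function(x, ...) {
  cat(sprintf("%s: chisq = %.4g, df = %d, p = %.4g (n = %d)\n",
              x$test, x$statistic, x$df, x$p_value, x$n))
  invisible(x)
}

#' Tidy a gated location test (post-hoc comparisons)
#'
#' @param x An `ecsig_gated_test`.
#' @param ... Unused.
#' @return The post-hoc comparison tibble, or the omnibus row when no
#'   post-hoc was run (two groups).
#' @method tidy ecsig_gated_test
#' @export
tidy.ecsig_gated_test <- function(x, ...) {
  if (!is.null(x$posthoc)) x$posthoc else glance(x)
}

#' @method glance ecsig_gated_test
#' @export
glance.ecsig_gated_test <- function(x, ...) {
  tibble(test = x$test, path = x$path, statistic = x$statistic,
         df = x$df, p_value = x$p_value,
         min_shapiro_p = min(x$normality$shapiro_p))
}

#' @export
print.ecsig_gated_test <- function(x, ...) {
  cat(sprintf("%s (%s path): statistic = %.4g, p = %.4g\n",
              x$test, x$path, x$statistic, x$p_value))
  cat(sprintf("  normality gate (Shapiro-Wilk, alpha = %g): min p = %.3g\n",
              x$gate_alpha, min(x$normality$shapiro_p)))
  if (!is.null(x$posthoc)) {
    cat(sprintf("  %d pairwise post-hoc comparison(s)\n", nrow(x$posthoc)))
  }
  invisible(x)
}
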