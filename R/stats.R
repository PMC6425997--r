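#' Paired t-test between two matched conditions
#'
#' Two-sided paired t-test on per-donor differences, the comparison used for
#' the cohort percentages.  When the differences have zero variance the t
#' statistic is undefined and reported as such (`degenerate = TRUE`) rather
#' than forced to a number.
#'
#' @param values_a,values_b matched numeric vectors (percent per donor),
#'   equal length >= 2.
#' @param condition_a,condition_b labels for the two conditions.
#' @return object of class `paired_t`: `condition_a`, `condition_b`,
#'   `differences`, `n_pairs`, `mean_diff`, `t_statistic`, `p_value`,
#'   `degenerate`.
#' @examples
#' paired_t(c(10, 20, 30), c(12, 25, 28))
#' @export
paired_t <- function(values_a, values_b, condition_a = "a", condition_b = "b") {
  if (length(values_a) != length(values_b)) {
    abort("paired test needs equal-length vectors.")
  }
  if (length(values_a) < 2) abort("paired test needs >= 2 pairs.")
  diffs <- values_a - values_b
  degenerate <- sd(diffs) < .Machine$double.eps^0.5
  if (degenerate) {
    t_stat <- NA_real_; p <- NA_real_
  } else {
    tt <- stats::t.test(values_a, values_b, paired = TRUE)
    t_stat <- unname(tt$statistic); p <- tt$p.value
  }
  structure(
    list(condition_a = condition_a, condition_b = condition_b,
         differences = diffs, n_pairs = length(diffs),
         mean_diff = mean(diffs), t_statistic = t_stat, p_value = p,
         degenerate = degenerate),
    class = "paired_t"
  )
}

#' @export
print.paired_t <- function(x, ...) {
  cat(sprintf("<paired_t> %s vs %s: n = %d, mean diff = %.3g",
              x$condition_a, x$condition_b, x$n_pairs, x$mean_diff))
  if (x$degenerate) {
    cat(", t undefined (zero-variance differences)\n")
  } else {
    cat(sprintf(", t = %.4g, p = %.4g\n", x$t_statistic, x$p_value))
  }
  invisible(x)
}

#' @rdname paired_t
#' @param x a `paired_t` object.
#' @param ... unused.
#' @export
tidy.paired_t <- function(x, ...) {
  tibble(condition_a = x$condition_a, condition_b = x$condition_b,
         n_pairs = x$n_pairs, estimate = x$mean_diff,
         statistic = x$t_statistic, p.value = x$p_value,
         degenerate = x$degenerate)
}

#' @rdname paired_t
#' @export
glance.paired_t <- function(x, ...) tidy(x)
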