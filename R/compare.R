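# Cohort comparisons: unpaired t-tests of per-track motility metrics and
# paired t-tests of before/after cluster intensities. Two-sided throughout,
# no multiple-testing correction (comparisons are listed so users can
# adjust externally).

#' Significance stars
#'
#' The figure-legend convention: `*` < 0.05, `**` < 0.01, `***` < 0.001,
#' `****` < 0.0001, `ns` otherwise.
#'
#' @param p p-value(s) in \[0, 1\].
#' @return Character vector of star labels.
#' @export
significance_stars <- function(p) {
  vapply(p, function(pp) {
    if (pp < 1e-4) "****"
    else if (pp < 1e-3) "***"
    else if (pp < 0.01) "**"
    else if (pp < 0.05) "*"
    else "ns"
  }, character(1))
}

new_comparison <- function(group_names, n, means, sds, test_name, statistic,
                           df, p, extra = list()) {
  structure(c(list(group_names = group_names, n_per_group = n, means = means,
                   sds = sds, test_name = test_name, statistic = statistic,
                   degrees_of_freedom = df, p_value = p,
                   stars = significance_stars(p)), extra),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s: %s (n=%d, mean=%.4g) vs %s (n=%d, mean=%.4g)\n",
              x$test_name, x$group_names[1], x$n_per_group[1], x$means[1],
              x$group_names[2], x$n_per_group[2], x$means[2]))
  cat(sprintf("  t = %.4f, df = %.2f, p = %.4g %s\n",
              x$statistic, x$degrees_of_freedom, x$p_value, x$stars))
  invisible(x)
}

#' Unpaired two-group comparison
#'
#' Two-sided unpaired t-test of two groups of per-track values. The
#' default variant is Student's equal-variance test (as in classical
#' mean-speed comparisons); Welch's unequal-variance test is available for
#' robustness checks.
#'
#' @param values_a,values_b numeric vectors (>= 2 values each, non-zero
#'   pooled variance).
#' @param variant `"student"` or `"welch"`.
#' @param group_names length-2 labels for the report.
#' @return A `comparison_result`: group summaries, `test_name`
#'   (`"unpaired-t"` or `"welch-t"`), `statistic`, `degrees_of_freedom`,
#'   `p_value` and significance `stars`.
#' @export
compare_unpaired <- function(values_a, values_b, variant = c("student", "welch"),
                             group_names = c("A", "B")) {
  variant <- match.arg(variant)
  values_a <- as.numeric(values_a); values_b <- as.numeric(values_b)
  if (length(values_a) < 2 || length(values_b) < 2) {
    ivm_stop("ivm_insufficient_n", "each group needs at least 2 values")
  }
  if (stats::var(values_a) + stats::var(values_b) == 0) {
    ivm_stop("ivm_degenerate_variance", "pooled variance is zero")
  }
  ht <- stats::t.test(values_a, values_b, var.equal = (variant == "student"))
  new_comparison(group_names,
                 n = c(length(values_a), length(values_b)),
                 means = c(mean(values_a), mean(values_b)),
                 sds = c(stats::sd(values_a), stats::sd(values_b)),
                 test_name = if (variant == "student") "unpaired-t" else "welch-t",
                 statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p = ht$p.value)
}

#' Paired before/after comparison
#'
#' Two-sided paired t-test on after - before differences, as used for the
#' mean-fluorescence-intensity of the same regions before and after drug
#' injection. Reports the mean difference with its 95% confidence
#' interval. Depends only on the differences (adding a constant to both
#' members of every pair changes nothing). If every difference is exactly
#' zero the comparison is the identity pairing and is reported as
#' statistic 0, p = 1; constant non-zero differences leave the statistic
#' undefined and raise `ivm_degenerate_variance`.
#'
#' @param records either a cluster-intensity data.frame with columns
#'   `mfi_before`/`mfi_after` (see [read_cluster_intensity()]) or a numeric
#'   vector of "before" values.
#' @param after "after" values when `records` is a numeric vector.
#' @param group_names length-2 labels.
#' @return A `comparison_result` with extra fields `mean_difference` and
#'   `conf_int`.
#' @export
compare_paired <- function(records, after = NULL,
                           group_names = c("before", "after")) {
  if (is.data.frame(records)) {
    before <- records$mfi_before; after <- records$mfi_after
    if (is.null(before) || is.null(after)) {
      ivm_stop("ivm_missing_column", "records needs mfi_before and mfi_after columns")
    }
  } else {
    before <- as.numeric(records)
  }
  if (length(before) != length(after)) {
    ivm_stop("ivm_insufficient_n", "before/after lengths differ")
  }
  if (length(before) < 2) {
    ivm_stop("ivm_insufficient_n", "paired comparison needs at least 2 pairs")
  }
  d <- after - before
  if (stats::sd(d) == 0) {
    if (all(d == 0)) {
      return(new_comparison(group_names, n = rep(length(before), 2),
                            means = c(mean(before), mean(after)),
                            sds = c(stats::sd(before), stats::sd(after)),
                            test_name = "paired-t", statistic = 0,
                            df = length(d) - 1, p = 1,
                            extra = list(mean_difference = 0, conf_int = c(0, 0))))
    }
    ivm_stop("ivm_degenerate_variance",
             "all differences identical and non-zero: paired t undefined")
  }
  ht <- stats::t.test(after, before, paired = TRUE)
  new_comparison(group_names, n = rep(length(before), 2),
                 means = c(mean(before), mean(after)),
                 sds = c(stats::sd(before), stats::sd(after)),
                 test_name = "paired-t",
                 statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p = ht$p.value,
                 extra = list(mean_difference = mean(d),
                              conf_int = unname(ht$conf.int)))
}

#' Compare a motility metric between epochs
#'
#' Unpaired comparison of a per-track metric (e.g. `mean_speed`) between
#' pre- and post-drug epochs. The comparison is unpaired because the two
#' epochs are distinct samplings of the cell population, not repeated
#' measurements of matched tracks.
#'
#' @param stats_pre,stats_post [cohort_stats_table()] outputs for the two
#'   epochs.
#' @param metric column name to compare (default `"mean_speed"`).
#' @param variant `"student"` or `"welch"`.
#' @return A `comparison_result`.
#' @export
compare_epochs <- function(stats_pre, stats_post, metric = "mean_speed",
                           variant = "student") {
  for (tab in list(stats_pre, stats_post)) {
    if (!metric %in% names(tab)) {
      ivm_stop("ivm_unknown_metric", paste0("metric '", metric, "' not in stats table"))
    }
  }
  compare_unpaired(stats_pre[[metric]], stats_post[[metric]], variant = variant,
                   group_names = c("pre", "post"))
}
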