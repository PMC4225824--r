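#' Differential-expression filter
#'
#' Selects components whose expression change passes a fold-change
#' criterion, optionally combined with an adjusted p-value threshold.
#' Values are log2-scale stimulated-minus-control differences, so a
#' `fc_threshold` of 2 requires `max_t |log2 difference| >= 1`; the
#' comparison is inclusive at the boundary. When a p-value threshold is
#' requested, per-component p-values come from an ordinary F-test of the
#' null hypothesis that the mean difference is zero at every time point
#' (fitted on the replicate values), with Benjamini-Hochberg adjustment
#' across components; alternatively, pre-computed adjusted p-values can be
#' supplied. The typical configuration mirrors common microarray practice:
#' 2-fold plus adjusted p <= 1e-10 for mRNAs, 2-fold only for miRNAs whose
#' replicate number is too low for a useful test.
#'
#' @param raw a [grn_raw()] replicate set (log2 differences).
#' @param fc_threshold linear fold-change threshold (>= 1).
#' @param p_threshold adjusted p-value threshold, or `NULL` to filter on
#'   fold change alone.
#' @param p_values optional named vector of pre-adjusted p-values per
#'   component, used instead of the built-in F-test.
#' @return data frame of passing components with columns `component`,
#'   `max_abs_log2` (max absolute log2 difference over time),
#'   `fold_change` (linear scale), and `p_adj` when a p-value threshold is
#'   active. The full table over all components is attached as attribute
#'   `"all"`.
#' @export
de_filter <- function(raw, fc_threshold = 2, p_threshold = NULL,
                      p_values = NULL) {
  raw <- grn_raw(raw)
  if (!is_scalar_num(fc_threshold) || fc_threshold < 1) {
    stop_("fc_threshold must be >= 1")
  }
  comps <- unique(raw$component)
  avg <- average_replicates(raw)
  max_abs <- apply(abs(unclass_ts(avg)), 1L, max)[comps]
  res <- data.frame(component = comps,
                    max_abs_log2 = unname(max_abs),
                    fold_change = unname(2^max_abs),
                    stringsAsFactors = FALSE)
  pass <- res$max_abs_log2 >= log2(fc_threshold)
  if (!is.null(p_threshold)) {
    if (is.null(p_values)) {
      p_raw <- vapply(comps, function(cp) zero_mean_f_test(raw[raw$component == cp, ]), 0)
      res$p_adj <- stats::p.adjust(p_raw, method = "BH")
    } else {
      res$p_adj <- unname(p_values[comps])
      if (anyNA(res$p_adj)) stop_("p_values must cover every component")
    }
    pass <- pass & res$p_adj <= p_threshold
  }
  out <- res[pass, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "all") <- res
  out
}

# F-test of H0: the mean difference is 0 at every time point,
# using the replicate scatter within time points as the error term.
zero_mean_f_test <- function(d) {
  grp <- factor(d$time)
  t_levels <- nlevels(grp)
  n <- nrow(d)
  if (n - t_levels < 1L) {
    stop_("no residual degrees of freedom for the F-test; ",
          "supply p_values or drop the p-value threshold")
  }
  means <- tapply(d$value, grp, mean)
  counts <- tapply(d$value, grp, length)
  ss_model <- sum(counts * means^2)
  ss_err <- sum((d$value - means[grp])^2)
  f <- (ss_model / t_levels) / (ss_err / (n - t_levels))
  stats::pf(f, t_levels, n - t_levels, lower.tail = FALSE)
}

#' qPCR relative expression
#'
#' Relative expression of a marker gene against a housekeeping gene from
#' qPCR cycle-threshold (Ct) values:
#' `(2^-Ct_marker * 1e6) / (2^-Ct_housekeeping * 1e6) = 2^(Ct_housekeeping - Ct_marker)`.
#' One extra cycle needed for the marker halves its relative expression.
#'
#' @param ct_marker,ct_housekeeping finite Ct values (vectorised).
#' @return relative expression ratio(s).
#' @export
relative_expression <- function(ct_marker, ct_housekeeping) {
  if (!all(is.finite(ct_marker)) || !all(is.finite(ct_housekeeping))) {
    stop_("Ct values must be finite")
  }
  2^(ct_housekeeping - ct_marker)
}
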