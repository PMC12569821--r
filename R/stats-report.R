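# Summary statistics and group comparisons: per-isolate event rates,
# rank-based two-sample tests, DNA-fragmentation arithmetic, and box-plot
# statistics.

#' Mean rearrangement events per isolate
#'
#' Averages, over non-excluded isolates, the number of events whose class is
#' in `classes`.
#'
#' @param reports list of `isolate_report` objects.
#' @param classes event classes counted.
#' @return mean events per isolate.
#' @export
events_per_isolate <- function(reports,
                               classes = c("SGC", "BIR", "NMTL", "NAHR",
                                           "aneuploidy")) {
  kept <- Filter(function(r) !isTRUE(r$excluded), reports)
  if (!length(kept)) stop("no isolates remain after exclusion")
  mean(vapply(kept, count_events, numeric(1), classes = classes))
}

#' Two-sided Mann-Whitney-Wilcoxon rank-sum test
#'
#' U is computed from rank sums with midranks for ties. The p-value is
#' exact (by enumeration) when the smaller sample has at most 8
#' observations and there are no ties; otherwise the normal approximation
#' with tie and continuity corrections is used.
#'
#' @param x,y numeric samples.
#' @return list of class `rank_test`: `u_statistic` (U for `x`),
#'   `p_two_sided`, `n_x`, `n_y`, `method`.
#' @export
mann_whitney_two_sided <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !ties && min(length(x), length(y)) <= 8
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = TRUE))
  structure(list(u_statistic = unname(wt$statistic),
                 p_two_sided = wt$p.value,
                 n_x = length(x), n_y = length(y),
                 method = if (exact) "exact" else "normal_approx"),
            class = "rank_test")
}

#' @export
print.rank_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %.1f (n = %d, %d), two-sided p = %.4g [%s]\n",
              x$u_statistic, x$n_x, x$n_y, x$p_two_sided, x$method))
  invisible(x)
}

#' Relative double-strand-break level from fragment tables
#'
#' Sums fragment mass inside the closed size window (default 200-48,500 bp,
#' the fragmented-DNA definition for genomic screen tapes) for the dark and
#' light conditions; the relative DSB level is the light/dark mass ratio.
#'
#' @param fragment_table_dark,fragment_table_light data.frames with columns
#'   `size_bp`, `mass` (or TSV paths with that header).
#' @param size_range closed \[min, max\] fragment-size window in bp.
#' @return list of class `dsb_quant`: `fragmented_mass_dark`,
#'   `fragmented_mass_light`, `size_range`, `relative_dsb`.
#' @export
relative_dsb <- function(fragment_table_dark, fragment_table_light,
                         size_range = c(200, 48500)) {
  load_tab <- function(x) {
    if (is.character(x) && length(x) == 1L) x <- read.delim(x)
    if (!all(c("size_bp", "mass") %in% names(x))) {
      stop("fragment table needs columns size_bp, mass")
    }
    x
  }
  dk <- load_tab(fragment_table_dark)
  lt <- load_tab(fragment_table_light)
  in_range <- function(tab) {
    sum(tab$mass[tab$size_bp >= size_range[1] & tab$size_bp <= size_range[2]])
  }
  dark <- in_range(dk); light <- in_range(lt)
  if (dark <= 0) stop("dark-condition fragmented mass is zero")
  structure(list(fragmented_mass_dark = dark,
                 fragmented_mass_light = light,
                 size_range = size_range,
                 relative_dsb = light / dark),
            class = "dsb_quant")
}

#' Percent increase between two values
#'
#' @param a reference value (> 0).
#' @param b new value.
#' @return `100 * (b - a) / a`, rounded to one decimal.
#' @export
percent_increase <- function(a, b) {
  if (a <= 0) stop("reference value must be positive")
  round(100 * (b - a) / a, 1)
}

#' Box-plot statistics
#'
#' Quartiles use the linear-interpolation convention
#' (`stats::quantile type 7`); whiskers extend to the most extreme data
#' points within 1.5 x IQR of the quartiles.
#'
#' @param values numeric vector with at least one value.
#' @return list of class `box_stats`: `median`, `q1`, `q3`, `whisker_low`,
#'   `whisker_high`.
#' @export
box_stats <- function(values) {
  if (!length(values)) stop("need at least one value")
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  structure(list(median = q[2], q1 = q[1], q3 = q[3],
                 whisker_low = min(values[values >= lo_fence]),
                 whisker_high = max(values[values <= hi_fence])),
            class = "box_stats")
}

#' Compare two isolate groups
#'
#' Computes per-group mean event counts (non-excluded isolates), their fold
#' change, the two-sided Mann-Whitney test on per-isolate counts, and per
#' group box statistics for counts, total LOH length and total CNV length.
#'
#' @param reports_a,reports_b lists of `isolate_report` objects.
#' @param classes event classes counted.
#' @return list of class `group_comparison`.
#' @export
compare_isolate_groups <- function(reports_a, reports_b,
                                   classes = c("SGC", "BIR", "NMTL", "NAHR",
                                               "aneuploidy")) {
  keep <- function(rs) Filter(function(r) !isTRUE(r$excluded), rs)
  ra <- keep(reports_a); rb <- keep(reports_b)
  if (!length(ra) || !length(rb)) stop("a group is empty after exclusion")
  counts_a <- vapply(ra, count_events, numeric(1), classes = classes)
  counts_b <- vapply(rb, count_events, numeric(1), classes = classes)
  loh_a <- vapply(ra, function(r) r$total_loh_length, numeric(1))
  loh_b <- vapply(rb, function(r) r$total_loh_length, numeric(1))
  cnv_a <- vapply(ra, function(r) r$total_cnv_length, numeric(1))
  cnv_b <- vapply(rb, function(r) r$total_cnv_length, numeric(1))
  structure(list(
    mean_events_a = mean(counts_a), mean_events_b = mean(counts_b),
    fold_change = mean(counts_b) / mean(counts_a),
    events_test = mann_whitney_two_sided(counts_a, counts_b),
    loh_test = mann_whitney_two_sided(loh_a, loh_b),
    cnv_test = mann_whitney_two_sided(cnv_a, cnv_b),
    box = list(events_a = box_stats(counts_a), events_b = box_stats(counts_b),
               loh_a = box_stats(loh_a), loh_b = box_stats(loh_b),
               cnv_a = box_stats(cnv_a), cnv_b = box_stats(cnv_b)),
    n_a = length(ra), n_b = length(rb)),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(paste0("group comparison: %.2f vs %.2f events/isolate ",
                     "(%.2f-fold), events p = %.4g, LOH p = %.4g, ",
                     "CNV p = %.4g (n = %d, %d)\n"),
              x$mean_events_a, x$mean_events_b, x$fold_change,
              x$events_test$p_two_sided, x$loh_test$p_two_sided,
              x$cnv_test$p_two_sided, x$n_a, x$n_b))
  invisible(x)
}
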