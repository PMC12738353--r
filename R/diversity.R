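#' Filter low-abundance isomiRs
#'
#' Retains isomiRs with strictly more than `min_reads` raw reads in at least
#' `min_samples` samples; all other rows are dropped. The sample set is
#' unchanged. With the default thresholds (>100 reads in >=1 sample) and a
#' typical small RNA-seq depth of ~8.9 million reads this corresponds to
#' roughly 12 reads per million.
#'
#' @param x an [isomir_counts()] object.
#' @param min_reads keep rows exceeding this raw count (strict inequality).
#' @param min_samples in at least this many samples.
#' @return A filtered [isomir_counts()] object.
#' @export
filter_low_abundance <- function(x, min_reads = 100, min_samples = 1) {
  stopifnot(inherits(x, "isomir_counts"), min_reads >= 0, min_samples >= 1)
  keep <- rowSums(x$counts > min_reads) >= min_samples
  x[keep, ]
}

#' Reads per million
#'
#' @param count raw read count(s), non-negative.
#' @param depth library depth (total reads) of the sample, positive.
#' @return `count / depth * 1e6`.
#' @examples
#' rpm(100, 8.9e6)  # ~11.24 RPM
#' @export
rpm <- function(count, depth) {
  if (any(depth <= 0)) stop("'depth' must be positive")
  if (any(count < 0)) stop("'count' must be non-negative")
  count / depth * 1e6
}

#' Per-miRNA, per-sample isoform diversity
#'
#' Counts, for each miRNA and sample, the number of distinct isomiRs present
#' at or above `presence_min` reads. Intended to run on an
#' abundance-filtered table, so a retained isomiR counts as present in a
#' sample whenever it has at least one read there (the default).
#'
#' @param x an [isomir_counts()] object (typically already filtered with
#'   [filter_low_abundance()]).
#' @param presence_min minimum per-sample read count for an isomiR to count
#'   as present.
#' @return An integer matrix, miRNAs x samples.
#' @export
diversity_matrix <- function(x, presence_min = 1) {
  stopifnot(inherits(x, "isomir_counts"), presence_min >= 1)
  present <- (x$counts >= presence_min) + 0L
  m <- rowsum(present, group = x$ids$mirna, reorder = TRUE)
  storage.mode(m) <- "integer"
  m
}

#' Pooled isoform-count categories per tissue
#'
#' Pools all samples of one tissue and assigns each miRNA to a category by
#' the number of distinct isomiRs observed anywhere in that tissue:
#' exactly 1, 2-9, or >=10. Only miRNAs with at least one observed isomiR in
#' the tissue are counted, so the three categories partition the tissue's
#' miRNA total.
#'
#' @param x an [isomir_counts()] object.
#' @param tissue `"tumor"` or `"normal"`.
#' @param presence_min minimum read count for an isomiR to count as observed.
#' @return A list with `counts` (named integer vector over categories
#'   `"1"`, `"2-9"`, `">=10"`), `total` and `shares` (percentages, rounded
#'   to two decimals).
#' @export
pooled_category_counts <- function(x, tissue, presence_min = 1) {
  stopifnot(inherits(x, "isomir_counts"))
  sel <- x$samples$tissue == tissue
  if (!any(sel)) stop(sprintf("no samples with tissue %s", dQuote(tissue)))
  seen <- rowSums(x$counts[, sel, drop = FALSE] >= presence_min) > 0
  per_mirna <- rowsum(seen + 0L, group = x$ids$mirna)[, 1]
  per_mirna <- per_mirna[per_mirna > 0]
  counts <- c(
    "1"    = sum(per_mirna == 1),
    "2-9"  = sum(per_mirna >= 2 & per_mirna <= 9),
    ">=10" = sum(per_mirna >= 10)
  )
  list(counts = counts, total = sum(counts),
       shares = category_shares(counts))
}

#' Category percentages from category counts
#'
#' @param counts named non-negative vector of category counts.
#' @param digits decimals to round the percentages to.
#' @return Named vector of percentages summing to ~100.
#' @export
category_shares <- function(counts, digits = 2) {
  round(100 * counts / sum(counts), digits)
}

#' Chi-square test on two category-count vectors
#'
#' Pearson chi-square (no continuity correction) on the 2 x k contingency
#' table formed by the two count vectors, with k - 1 degrees of freedom.
#'
#' @param counts_a,counts_b category counts of the two groups, same length
#'   >= 2.
#' @return A list with `statistic`, `df` and `p_value`.
#' @export
category_chisq <- function(counts_a, counts_b) {
  if (length(counts_a) != length(counts_b) || length(counts_a) < 2)
    stop("need two count vectors of equal length >= 2")
  tab <- rbind(counts_a, counts_b)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0))
    stop("zero expected cell count; merge sparse categories before testing")
  ct <- stats::chisq.test(tab, correct = FALSE)
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value))
}

#' miRNAs eligible for diversity analysis
#'
#' Diversity statistics are restricted to miRNAs whose median isoform count
#' across all samples is at least `min_median` (default 3), so that
#' "diversity" is a meaningful per-sample quantity.
#'
#' @param div a diversity matrix from [diversity_matrix()].
#' @param min_median minimum across-sample median isoform count.
#' @return Character vector of eligible miRNA names.
#' @export
eligible_mirnas <- function(div, min_median = 3) {
  med <- apply(div, 1, stats::median)
  rownames(div)[med >= min_median]
}

#' Split samples into "more"/"less" diversity groups for one miRNA
#'
#' Samples strictly above the across-sample median isoform count are labelled
#' `"more"`, samples strictly below `"less"`. Ties at the median go to
#' `"less"` by default (configurable); this is the conservative choice when
#' higher diversity is the putatively protective state.
#'
#' @param counts per-sample isoform counts for one miRNA (named vector).
#' @param tie `"less"` (default) or `"more"`: which group samples equal to
#'   the median join.
#' @return Character vector of labels, named like `counts`.
#' @export
diversity_grouping <- function(counts, tie = c("less", "more")) {
  tie <- match.arg(tie)
  if (length(counts) < 2) stop("need at least 2 samples")
  med <- stats::median(counts)
  labels <- ifelse(counts > med, "more",
                   ifelse(counts < med, "less", tie))
  if (length(unique(labels)) == 1L)
    warning("degenerate split: all samples fall in one group")
  names(labels) <- names(counts)
  labels
}

#' Differential isoform diversity between two sample groups
#'
#' Per-miRNA two-sample t-test (Welch by default) on isoform counts between
#' two groups, with group means and fold change. The fold change is
#' `mean(numerator group) / mean(denominator group)`; pass `numerator` to fix
#' the orientation (e.g. tumor/normal).
#'
#' @param div a diversity matrix from [diversity_matrix()], usually restricted
#'   to [eligible_mirnas()].
#' @param groups factor or character vector of group labels, one per column
#'   of `div`, with exactly two distinct non-NA values. Columns with `NA`
#'   labels are dropped.
#' @param alpha significance threshold on the raw p-value.
#' @param numerator the group placed in the fold-change numerator; default
#'   the first of `sort(unique(groups))`.
#' @param var_equal use the pooled-variance (classical Student) test instead
#'   of Welch.
#' @param p_adjust `"none"` (raw p-values, the default) or any method of
#'   [stats::p.adjust()] such as `"BH"`; when not `"none"`, significance is
#'   called on the adjusted values.
#' @return A data.frame with one row per miRNA: `mirna`, `mean_num`,
#'   `mean_den`, `fold_change`, `p_value`, `significant`; groups used are in
#'   attributes `numerator`/`denominator`.
#' @export
differential_diversity <- function(div, groups, alpha = 0.05,
                                   numerator = NULL, var_equal = FALSE,
                                   p_adjust = "none") {
  groups <- as.character(groups)
  keep <- !is.na(groups)
  div <- div[, keep, drop = FALSE]
  groups <- groups[keep]
  lev <- sort(unique(groups))
  if (length(lev) != 2) stop("need exactly two groups, got: ", paste(lev, collapse = ", "))
  if (is.null(numerator)) numerator <- lev[1]
  if (!numerator %in% lev) stop("'numerator' must be one of the group labels")
  denominator <- setdiff(lev, numerator)
  a <- div[, groups == numerator, drop = FALSE]
  b <- div[, groups == denominator, drop = FALSE]
  if (ncol(a) < 2 || ncol(b) < 2) stop("each group needs >= 2 samples")
  n <- nrow(div)
  p <- numeric(n)
  for (i in seq_len(n)) {
    xi <- a[i, ]; yi <- b[i, ]
    if (stats::var(xi) == 0 && stats::var(yi) == 0) {
      # no within-group variability: identical means carry no evidence
      p[i] <- if (mean(xi) == mean(yi)) 1 else 0
    } else {
      p[i] <- stats::t.test(xi, yi, var.equal = var_equal)$p.value
    }
  }
  mean_num <- rowMeans(a); mean_den <- rowMeans(b)
  p_eff <- if (identical(p_adjust, "none")) p else stats::p.adjust(p, method = p_adjust)
  out <- data.frame(
    mirna = rownames(div),
    mean_num = mean_num,
    mean_den = mean_den,
    fold_change = mean_num / mean_den,
    p_value = p,
    significant = p_eff < alpha,
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "numerator") <- numerator
  attr(out, "denominator") <- denominator
  attr(out, "alpha") <- alpha
  out
}

#' Select candidate miRNAs by significance and fold change
#'
#' Keeps miRNAs that are significant and whose diversity fold change exceeds
#' `fc_threshold` in either direction (strictly `> fc_threshold` or
#' `< 1/fc_threshold`); the two-sided band matters because biologically
#' interesting hits may have fewer isoforms in the numerator group.
#'
#' @param comparisons output of [differential_diversity()].
#' @param fc_threshold fold-change threshold (> 1).
#' @param two_sided also accept fold changes below `1/fc_threshold`.
#' @return Character vector of candidate miRNA names, sorted.
#' @export
select_candidates <- function(comparisons, fc_threshold = 2, two_sided = TRUE) {
  stopifnot(fc_threshold > 1)
  fc <- comparisons$fold_change
  hit <- comparisons$significant &
    (fc > fc_threshold | (two_sided & fc < 1 / fc_threshold))
  sort(comparisons$mirna[hit])
}

#' Intersect two candidate lists
#'
#' @param set_a,set_b character vectors of miRNA names.
#' @return Their intersection, sorted by name.
#' @export
intersect_candidates <- function(set_a, set_b) {
  sort(intersect(set_a, set_b))
}
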