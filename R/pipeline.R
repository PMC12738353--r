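#' Per-isoform expression comparison for one miRNA
#'
#' Compares the expression (reads per million) of each retained isomiR of one
#' miRNA between two sample groups: Welch t-test on log2(RPM + 1) with group
#' mean RPM and fold change per isomiR.
#'
#' @param x a filtered [isomir_counts()] object.
#' @param mirna miRNA name.
#' @param groups two-level label per sample (`NA` columns dropped).
#' @param depths per-sample library depths (reads); default the column sums
#'   of `x`.
#' @param numerator group placed in the fold-change numerator.
#' @return data.frame: `isomir`, `mean_num`, `mean_den` (RPM),
#'   `fold_change`, `p_value`.
#' @export
isoform_expression_comparison <- function(x, mirna, groups, depths = NULL,
                                          numerator = NULL) {
  stopifnot(inherits(x, "isomir_counts"))
  rows <- which(x$ids$mirna == mirna)
  if (!length(rows)) stop(sprintf("miRNA %s not in the table", dQuote(mirna)))
  if (is.null(depths)) depths <- colSums(x$counts)
  groups <- as.character(groups)
  keep <- !is.na(groups)
  lev <- sort(unique(groups[keep]))
  if (length(lev) != 2) stop("need exactly two groups")
  if (is.null(numerator)) numerator <- lev[1]
  denominator <- setdiff(lev, numerator)
  r <- rpm(x$counts[rows, keep, drop = FALSE],
           matrix(depths[keep], nrow = length(rows), ncol = sum(keep), byrow = TRUE))
  ga <- groups[keep] == numerator
  lg <- log2(r + 1)
  p <- vapply(seq_len(nrow(r)), function(i) {
    a <- lg[i, ga]; b <- lg[i, !ga]
    if (stats::var(a) == 0 && stats::var(b) == 0)
      return(if (mean(a) == mean(b)) 1 else 0)
    stats::t.test(a, b)$p.value
  }, numeric(1))
  data.frame(
    isomir = rownames(x$counts)[rows],
    mean_num = rowMeans(r[, ga, drop = FALSE]),
    mean_den = rowMeans(r[, !ga, drop = FALSE]),
    fold_change = rowMeans(r[, ga, drop = FALSE]) / rowMeans(r[, !ga, drop = FALSE]),
    p_value = p,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Run the full isomiR diversity pipeline
#'
#' Orchestrates the stages in their natural order: (simulate ->) filter ->
#' pooled category table + chi-square -> differential diversity for
#' tumor/normal and unfavorable/favorable -> candidate selection and
#' intersection -> per-candidate isoform expression comparison -> survival
#' stratification (Kaplan-Meier/log-rank and Cox with histology adjustment)
#' -> optional target scan on simulated sequences. Every threshold is echoed
#' into the returned `thresholds` element and the run log.
#'
#' @param counts an [isomir_counts()] object, or `NULL` to simulate.
#' @param clinical clinical data.frame, or `NULL` to simulate (requires
#'   `sim`).
#' @param sim a [sim_config()] used when `counts`/`clinical` are `NULL`.
#' @param min_reads,min_samples abundance filter (see
#'   [filter_low_abundance()]).
#' @param min_median eligibility threshold on the median isoform count.
#' @param alpha_tn significance level for the tumor/normal diversity test.
#' @param alpha_uf significance level for the unfavorable/favorable test.
#' @param fc fold-change selection threshold.
#' @param tie median tie rule for diversity grouping.
#' @param scan run the target-scan stage on simulated sequences (only
#'   meaningful with `sim`).
#' @param out_dir if given, stage outputs are written there as TSV plus a
#'   `run_log.txt` with all thresholds.
#' @return An object of class `isomir_pipeline`: a list with the filtered
#'   table, category tables and chi-square, the two comparison tables,
#'   candidate sets and their intersection, per-candidate isoform expression
#'   and survival results, optional scan results, and `thresholds`.
#' @export
run_pipeline <- function(counts = NULL, clinical = NULL, sim = NULL,
                         min_reads = 100, min_samples = 1, min_median = 3,
                         alpha_tn = 0.01, alpha_uf = 0.05, fc = 2,
                         tie = "less", scan = FALSE, out_dir = NULL) {
  thresholds <- list(min_reads = min_reads, min_samples = min_samples,
                     min_median = min_median, alpha_tn = alpha_tn,
                     alpha_uf = alpha_uf, fc = fc, tie = tie)
  if (is.null(counts)) {
    if (is.null(sim)) stop("stage 'input': provide 'counts' or a sim_config in 'sim'")
    counts <- simulate_isomir_counts(sim)
  }
  stopifnot(inherits(counts, "isomir_counts"))
  depths <- colSums(counts$counts)

  filtered <- filter_low_abundance(counts, min_reads, min_samples)
  if (nrow(filtered$counts) == 0) stop("stage 'filter': no isomiRs pass the abundance filter")

  categories <- list(tumor = pooled_category_counts(filtered, "tumor"),
                     normal = pooled_category_counts(filtered, "normal"))
  cat_test <- tryCatch(
    category_chisq(categories$tumor$counts, categories$normal$counts),
    error = function(e) list(statistic = NA_real_, df = NA_real_,
                             p_value = NA_real_, note = conditionMessage(e)))

  div <- diversity_matrix(filtered)
  eligible <- eligible_mirnas(div, min_median)
  if (!length(eligible)) stop("stage 'diversity': no miRNA passes the median >= ",
                              min_median, " eligibility rule")
  div_e <- div[eligible, , drop = FALSE]

  tissue <- filtered$samples$tissue
  comp_tn <- differential_diversity(div_e, tissue, alpha = alpha_tn,
                                    numerator = "tumor")
  cand_tn <- select_candidates(comp_tn, fc)

  hist_lab <- ifelse(filtered$samples$tissue == "tumor",
                     filtered$samples$histology, NA_character_)
  comp_uf <- cand_uf <- NULL
  if (sum(!is.na(hist_lab)) >= 4 && length(unique(stats::na.omit(hist_lab))) == 2) {
    comp_uf <- differential_diversity(div_e, hist_lab, alpha = alpha_uf,
                                      numerator = "unfavorable")
    cand_uf <- select_candidates(comp_uf, fc)
  }
  candidates <- if (is.null(cand_uf)) cand_tn else intersect_candidates(cand_tn, cand_uf)

  isoform_expression <- lapply(stats::setNames(candidates, candidates), function(m)
    isoform_expression_comparison(filtered, m, tissue, depths,
                                  numerator = "tumor"))

  # survival: clinical table keyed to the leading marker miRNA's grouping
  marker <- if (length(candidates)) candidates[1]
            else if (!is.null(attr(counts, "signal_mirnas")) &&
                     length(attr(counts, "signal_mirnas"))) attr(counts, "signal_mirnas")[1]
            else eligible[1]
  tumor_cols <- filtered$samples$tissue == "tumor"
  marker_groups <- if (marker %in% rownames(div)) {
    diversity_grouping(div[marker, tumor_cols], tie = tie)
  } else NULL
  if (is.null(clinical)) {
    if (!is.null(sim) && !is.null(marker_groups))
      clinical <- simulate_clinical(sim, marker_groups, filtered$samples)
  }
  surv <- NULL
  if (!is.null(clinical) && !is.null(marker_groups)) {
    cl <- clinical[clinical$tissue == "tumor", ]
    cl$group <- unname(marker_groups[cl$sample_id])
    cl <- cl[!is.na(cl$group) & !is.na(cl$time_days), ]
    surv_dat <- data.frame(time = cl$time_days, event = cl$event,
                           less_diversity = as.integer(cl$group == "less"),
                           unfavorable = as.integer(cl$histology == "unfavorable"))
    surv <- list(
      marker = marker,
      km = lapply(split(seq_len(nrow(cl)), cl$group), function(i)
        km_curve(cl$time_days[i], cl$event[i])),
      logrank = logrank_test(cl$time_days, cl$event, cl$group),
      # an inestimable Cox (separation at small n) is reported, not fatal
      cox_univariate = tryCatch(cox_fit(surv_dat, "less_diversity"),
                                error = function(e) conditionMessage(e)),
      cox_adjusted = if (length(unique(surv_dat$unfavorable)) == 2)
        tryCatch(cox_fit(surv_dat, c("less_diversity", "unfavorable")),
                 error = function(e) conditionMessage(e)) else NULL
    )
  }

  scan_res <- NULL
  if (isTRUE(scan) && !is.null(sim)) {
    seqs <- simulate_sequences(sim)
    if (nrow(seqs$manifest)) {
      m <- seqs$manifest$mirna[1]
      u <- seqs$manifest$utr_id[1]
      hits <- seed_sites(seqs$matures[m], seqs$utrs[u], utr_id = u)
      scan_res <- list(mirna = m, utr_id = u, hits = hits,
                       manifest = seqs$manifest)
    }
  }

  out <- structure(list(
    counts = counts, filtered = filtered, depths = depths,
    categories = categories, category_test = cat_test,
    diversity = div, eligible = eligible,
    comparison_tn = comp_tn, comparison_uf = comp_uf,
    candidates_tn = cand_tn, candidates_uf = cand_uf,
    candidates = candidates,
    isoform_expression = isoform_expression,
    survival = surv, scan = scan_res,
    thresholds = thresholds
  ), class = "isomir_pipeline")
  if (!is.null(out_dir)) .write_pipeline(out, out_dir)
  out
}

.write_pipeline <- function(x, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_isomir_counts(x$filtered, p("filtered_counts.tsv"))
  utils::write.table(data.frame(mirna = rownames(x$diversity), x$diversity,
                                check.names = FALSE),
                     p("diversity_matrix.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cat_tab <- data.frame(
    category = names(x$categories$tumor$counts),
    tumor = as.integer(x$categories$tumor$counts),
    normal = as.integer(x$categories$normal$counts))
  utils::write.table(cat_tab, p("category_counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(x$comparison_tn, p("comparison_tumor_normal.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(x$comparison_uf))
    utils::write.table(x$comparison_uf, p("comparison_unfav_fav.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(x$candidates, p("candidates.txt"))
  th <- x$thresholds
  writeLines(c(
    "isomirdiv run log",
    sprintf("%s=%s", names(th), unlist(th)),
    sprintf("n_isomirs_input=%d", nrow(x$counts$counts)),
    sprintf("n_isomirs_filtered=%d", nrow(x$filtered$counts)),
    sprintf("n_eligible_mirnas=%d", length(x$eligible)),
    sprintf("n_candidates=%d", length(x$candidates)),
    sprintf("category_chisq_p=%g", x$category_test$p_value)
  ), p("run_log.txt"))
  invisible(out_dir)
}

#' @export
print.isomir_pipeline <- function(x, ...) {
  cat("isomiR diversity pipeline run\n")
  cat(sprintf("  input: %d isomiRs, %d after abundance filter (> %d reads in >= %d sample(s))\n",
              nrow(x$counts$counts), nrow(x$filtered$counts),
              x$thresholds$min_reads, x$thresholds$min_samples))
  cat(sprintf("  pooled categories (tumor):  %s of %d miRNAs\n",
              paste(sprintf("%s: %d", names(x$categories$tumor$counts),
                            x$categories$tumor$counts), collapse = ", "),
              x$categories$tumor$total))
  cat(sprintf("  pooled categories (normal): %s of %d miRNAs\n",
              paste(sprintf("%s: %d", names(x$categories$normal$counts),
                            x$categories$normal$counts), collapse = ", "),
              x$categories$normal$total))
  cat(sprintf("  category chi-square p = %.3g\n", x$category_test$p_value))
  cat(sprintf("  eligible miRNAs (median >= %g): %d\n",
              x$thresholds$min_median, length(x$eligible)))
  cat(sprintf("  candidates tumor/normal: %d; unfavorable/favorable: %s; shared: %s\n",
              length(x$candidates_tn),
              if (is.null(x$candidates_uf)) "not tested" else length(x$candidates_uf),
              if (length(x$candidates)) paste(x$candidates, collapse = ", ") else "none"))
  if (!is.null(x$survival)) {
    hr <- if (is.data.frame(x$survival$cox_univariate))
      sprintf("%.2f", x$survival$cox_univariate$hazard_ratio[1]) else "inestimable"
    cat(sprintf("  survival (marker %s): log-rank p = %.3g; univariate HR(less) = %s\n",
                x$survival$marker, x$survival$logrank$p_value, hr))
  }
  invisible(x)
}
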