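test_that("abundance filter keeps exactly the rows exceeding the threshold", {
  x <- hand_table()
  f <- filter_low_abundance(x)
  # mB peaks at exactly 100 (strict >) and mE at 99: both dropped
  expect_equal(nrow(f$counts), 9)
  expect_false("mB 0|0" %in% rownames(f$counts))
  expect_false("mE 0|0" %in% rownames(f$counts))
  expect_true("mA 1|-1" %in% rownames(f$counts))  # single sample at 101
  expect_equal(colnames(f$counts), colnames(x$counts))

  # brute-force recount on random tables, and monotonicity in min_reads
  set.seed(31)
  for (i in 1:10) {
    n <- 40
    counts <- matrix(rnbinom(n * 6, mu = 120, size = 1), n, 6)
    ids <- data.frame(mirna = paste0("m", seq_len(n)), offset5 = 0, offset3 = 0)
    smp <- data.frame(sample_id = paste0("s", 1:6),
                      tissue = rep(c("tumor", "normal"), 3))
    xt <- isomir_counts(counts, ids, smp)
    thr <- sample(50:200, 1)
    f1 <- filter_low_abundance(xt, thr)
    expect_equal(nrow(f1$counts), sum(apply(counts, 1, max) > thr))
    f2 <- filter_low_abundance(xt, thr + 50)
    expect_true(all(rownames(f2$counts) %in% rownames(f1$counts)))
  }
})

test_that("reads-per-million matches its definition and the ~12 RPM threshold", {
  expect_equal(rpm(0, 5e6), 0)
  expect_equal(rpm(1e6, 1e6), 1e6)
  v <- rpm(100, 8.9e6)
  expect_equal(v, 100 / 8.9e6 * 1e6)
  expect_lt(v, 12)          # "approximately 12 RPM" rounds up from here
  expect_equal(round(v), 11)
  expect_error(rpm(10, 0), "positive")
  expect_error(rpm(-1, 10), "non-negative")
})

test_that("diversity matrix counts distinct present isomiRs per miRNA and sample", {
  x <- hand_table()
  f <- filter_low_abundance(x)
  d <- diversity_matrix(f)
  expect_equal(d["mA", ], c(T1 = 3L, T2 = 2L, T3 = 2L, N1 = 1L, N2 = 2L, N3 = 1L))
  expect_equal(d["mD", ], c(T1 = 3L, T2 = 3L, T3 = 3L, N1 = 3L, N2 = 3L, N3 = 3L))

  # counts {120, 0, 5} across three retained isoforms -> 2 present
  expect_equal(unname(d["mA", "N2"]), 2L)

  # exhaustive per-cell recount on random small tables
  set.seed(37)
  for (i in 1:10) {
    counts <- matrix(rpois(60, 3), 20, 3)
    ids <- data.frame(mirna = rep(paste0("m", 1:5), each = 4),
                      offset5 = rep(0:3, 5), offset3 = 0)
    smp <- data.frame(sample_id = paste0("s", 1:3), tissue = "tumor",
                      histology = "favorable")
    xt <- isomir_counts(counts, ids, smp)
    dt <- diversity_matrix(xt)
    for (m in unique(ids$mirna)) for (j in 1:3)
      expect_equal(dt[m, j], sum(counts[ids$mirna == m, j] >= 1))
  }

  # all-zero sample column gives an all-zero diversity column
  counts <- cbind(c(5L, 3L), c(0L, 0L))
  xt <- isomir_counts(counts, data.frame(mirna = c("m1", "m1"),
                                         offset5 = 0:1, offset3 = 0),
                      data.frame(sample_id = c("a", "b"), tissue = "tumor"))
  expect_equal(unname(diversity_matrix(xt)[, "b"]), 0L)
})

test_that("pooled categories partition the per-tissue miRNA total", {
  x <- hand_table()
  f <- filter_low_abundance(x)
  tum <- pooled_category_counts(f, "tumor")
  expect_equal(unname(tum$counts), c(0L, 3L, 0L))  # mA, mC, mD all in 2-9
  expect_equal(tum$total, 3L)
  expect_error(pooled_category_counts(f, "adjacent"), "no samples")

  # planted category structure: one miRNA with a single isoform, one with 10
  ids <- data.frame(mirna = c("solo", rep("rich", 10), rep("mid", 3)),
                    offset5 = 0, offset3 = c(0, 0:9, 0:2))
  counts <- matrix(200L, nrow(ids), 2)
  xt <- isomir_counts(counts, ids,
                      data.frame(sample_id = c("t1", "t2"), tissue = "tumor"))
  pc <- pooled_category_counts(xt, "tumor")
  expect_equal(pc$counts, c("1" = 1L, "2-9" = 1L, ">=10" = 1L))
  expect_equal(sum(pc$counts), pc$total)
  expect_lt(abs(sum(pc$shares) - 100), 0.05)  # two-decimal rounding
})

test_that("category chi-square equals the closed form and behaves symmetrically", {
  # closed-form oracle on a 2x2 table
  a <- c(30, 70); b <- c(50, 50)
  tab <- rbind(a, b)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat_hand <- sum((tab - expected)^2 / expected)
  res <- category_chisq(a, b)
  expect_equal(res$statistic, stat_hand, tolerance = 1e-10)
  expect_equal(res$df, 1)
  expect_equal(res$p_value, pchisq(stat_hand, 1, lower.tail = FALSE),
               tolerance = 1e-12)

  # identical rows: statistic 0, p = 1
  same <- category_chisq(c(10, 20, 30), c(10, 20, 30))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  # symmetric under row swap
  r1 <- category_chisq(c(195, 1742, 53), c(287, 842, 2))
  r2 <- category_chisq(c(287, 842, 2), c(195, 1742, 53))
  expect_equal(r1$statistic, r2$statistic)

  expect_error(category_chisq(c(0, 5), c(0, 7)), "expected cell")
  expect_error(category_chisq(c(1, 2, 3), c(1, 2)), "equal length")
})

test_that("median-based eligibility and grouping follow their boundary rules", {
  d <- rbind(const3 = rep(3, 6), const2 = rep(2, 6), mixed = c(1, 2, 3, 4, 5, 6))
  expect_equal(eligible_mirnas(d), c("const3", "mixed"))

  set.seed(41)
  for (i in 1:20) {
    row <- matrix(rpois(30, 4), 1, dimnames = list("m", NULL))
    expect_equal(length(eligible_mirnas(row)) == 1, median(row) >= 3)
  }

  expect_equal(unname(diversity_grouping(c(1, 2, 3, 4, 5))),
               c("less", "less", "less", "more", "more"))
  expect_equal(unname(diversity_grouping(c(1, 5))), c("less", "more"))
  expect_equal(unname(diversity_grouping(c(1, 3, 3, 5), tie = "more")),
               c("less", "more", "more", "more"))
  expect_warning(diversity_grouping(c(4, 4, 4)), "degenerate")

  set.seed(43)
  for (i in 1:20) {
    v <- rpois(15, 5)
    g <- suppressWarnings(diversity_grouping(v))
    expect_equal(unname(g), ifelse(v > median(v), "more", "less"))
  }
})

test_that("differential diversity matches a hand-computed Welch test", {
  set.seed(47)
  d <- matrix(rpois(40, 5), 2, 20,
              dimnames = list(c("m1", "m2"), paste0("s", 1:20)))
  g <- rep(c("tumor", "normal"), each = 10)
  res <- differential_diversity(d, g, alpha = 0.05, numerator = "tumor")
  for (i in 1:2) {
    x <- d[i, g == "tumor"]; y <- d[i, g == "normal"]
    expect_equal(res$p_value[i], oracle_welch_p(x, y), tolerance = 1e-12)
    expect_equal(res$fold_change[i], mean(x) / mean(y))
  }
  expect_equal(attr(res, "numerator"), "tumor")

  # identical groups: no significance; zero-variance identical means -> p = 1
  d2 <- rbind(m1 = rep(3, 10), m2 = c(rep(2, 5), rep(6, 5)))
  g2 <- rep(c("a", "b"), 5)
  r2 <- differential_diversity(d2, g2, alpha = 0.05)
  expect_equal(r2$p_value[1], 1)
  expect_false(r2$significant[1])

  # pooled-variance option reproduces the classical test
  rs <- differential_diversity(d, g, var_equal = TRUE, numerator = "tumor")
  expect_equal(rs$p_value[1],
               t.test(d[1, g == "tumor"], d[1, g == "normal"],
                      var.equal = TRUE)$p.value)

  # optional BH adjustment flags on the adjusted scale
  rbh <- differential_diversity(d, g, alpha = 0.05, numerator = "tumor",
                                p_adjust = "BH")
  expect_equal(rbh$significant, p.adjust(rbh$p_value, "BH") < 0.05)
})

test_that("candidate selection applies a strict two-sided fold-change band", {
  comp <- data.frame(
    mirna = c("a", "b", "c", "d", "e"),
    mean_num = 1, mean_den = 1,
    fold_change = c(2.0, 2.5, 0.4, 0.5, 3.0),
    p_value = c(0.001, 0.001, 0.001, 0.001, 0.5),
    significant = c(TRUE, TRUE, TRUE, TRUE, FALSE)
  )
  expect_equal(select_candidates(comp, 2), c("b", "c"))  # 2.0 and 0.5 excluded, e not significant
  expect_equal(select_candidates(comp, 2, two_sided = FALSE), "b")
  expect_equal(intersect_candidates(c("a", "b", "c"), c("b", "c", "d")), c("b", "c"))
  expect_equal(intersect_candidates(c("a"), c("b")), character(0))
})

test_that("every stage of the hand-built 5-miRNA table matches hand computation", {
  x <- hand_table()
  f <- filter_low_abundance(x)
  d <- diversity_matrix(f)
  # eligibility by hand: mA medians (3,2,2,1,2,1) -> 2; mC -> 2; mD -> 3
  expect_equal(eligible_mirnas(d), "mD")
  # mD diversity is constant 3 everywhere: degenerate grouping, null test
  expect_warning(g <- diversity_grouping(d["mD", ]), "degenerate")
  expect_true(all(g == "less"))
  comp <- differential_diversity(d["mD", , drop = FALSE], f$samples$tissue,
                                 alpha = 0.01, numerator = "tumor")
  expect_equal(comp$p_value, 1)
  expect_equal(comp$fold_change, 1)
  expect_equal(select_candidates(comp, 2), character(0))
})
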