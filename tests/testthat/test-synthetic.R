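test_that("configuration validation names the offending field", {
  expect_error(sim_config(n_tumor = 0), "n_tumor")
  expect_error(sim_config(diversity_fc = 0.5), "diversity_fc")
  expect_error(sim_config(censor_rate = 1), "censor_rate")
  expect_error(sim_config(nb_dispersion = 0), "nb_dispersion")
  expect_error(sim_config(n_signal = 10, n_mirnas = 5), "n_signal")
  expect_error(sim_config(hr_diversity = -1), "hr_diversity")
})

test_that("identical seed and config give identical outputs, and the caller's RNG is untouched", {
  cfg <- sim_config(n_tumor = 15, n_normal = 8, n_mirnas = 25, seed = 5)
  set.seed(999)
  before <- .Random.seed
  x1 <- simulate_isomir_counts(cfg)
  expect_identical(.Random.seed, before)
  x2 <- simulate_isomir_counts(cfg)
  expect_identical(x1$counts, x2$counts)
  expect_identical(x1$ids, x2$ids)
  expect_identical(x1$samples, x2$samples)

  g <- setNames(rep(c("more", "less"), length.out = 15),
                x1$samples$sample_id[x1$samples$tissue == "tumor"])
  c1 <- simulate_clinical(cfg, g, x1$samples)
  c2 <- simulate_clinical(cfg, g, x1$samples)
  expect_identical(c1, c2)

  s1 <- simulate_sequences(cfg, n_utrs = 3, utr_length = 300)
  s2 <- simulate_sequences(cfg, n_utrs = 3, utr_length = 300)
  expect_identical(s1, s2)

  # a different seed changes the data
  x3 <- simulate_isomir_counts(sim_config(n_tumor = 15, n_normal = 8,
                                          n_mirnas = 25, seed = 6))
  expect_false(identical(x1$counts, x3$counts))
})

test_that("per-sample read totals concentrate around the configured depth", {
  cfg <- sim_config(n_tumor = 80, n_normal = 40, n_mirnas = 60,
                    depth_mean = 2e6, depth_cv = 0.1, seed = 9)
  x <- simulate_isomir_counts(cfg)
  totals <- colSums(x$counts)
  expect_gte(length(totals), 100)
  expect_lt(abs(mean(totals) - cfg$depth_mean) / cfg$depth_mean, 0.1)
  expect_true(all(abs(totals - mean(totals)) <= 3 * sd(totals) + 1e-9) ||
                mean(abs(totals - mean(totals)) <= 3 * sd(totals)) >= 0.99)
})

test_that("the planted diversity fold change is recovered from group means", {
  cfg <- sim_config(n_tumor = 50, n_normal = 50, n_mirnas = 40, n_signal = 4,
                    diversity_fc = 2, seed = 13)
  x <- filter_low_abundance(simulate_isomir_counts(cfg))
  d <- diversity_matrix(x)
  sig <- attr(x, "signal_mirnas")
  tumor <- x$samples$tissue == "tumor"
  for (m in sig) {
    ratio <- mean(d[m, !tumor]) / mean(d[m, tumor])
    expect_lt(abs(ratio - cfg$diversity_fc) / cfg$diversity_fc, 0.2)
  }
  # 5' offsets concentrate at 0, 3' offsets are dispersed
  expect_gt(mean(x$ids$offset5 == 0), mean(x$ids$offset3 == 0))
})

test_that("a null configuration yields hits at about the false-positive rate", {
  cfg <- sim_config(n_tumor = 50, n_normal = 50, n_mirnas = 400, n_signal = 0,
                    diversity_fc = 1, seed = 17)
  x <- filter_low_abundance(simulate_isomir_counts(cfg))
  d <- diversity_matrix(x)
  e <- eligible_mirnas(d)
  comp <- differential_diversity(d[e, , drop = FALSE], x$samples$tissue,
                                 alpha = 0.01, numerator = "tumor")
  expect_lt(mean(comp$significant), 0.05)
  expect_lte(length(select_candidates(comp, 2)), 2)
})

test_that("planted signal miRNAs are recovered by the significance-and-fold-change filter", {
  # diversity_fc = 2.5 clears the strict two-fold selection band; at the
  # boundary value 2 the sampled fold change straddles the threshold
  recovered <- vapply(1:5, function(s) {
    cfg <- sim_config(n_tumor = 60, n_normal = 60, n_mirnas = 60, n_signal = 5,
                      diversity_fc = 2.5, seed = s)
    x <- filter_low_abundance(simulate_isomir_counts(cfg))
    d <- diversity_matrix(x)
    e <- eligible_mirnas(d)
    comp <- differential_diversity(d[e, , drop = FALSE], x$samples$tissue,
                                   alpha = 0.01, numerator = "tumor")
    length(intersect(select_candidates(comp, 2), attr(x, "signal_mirnas")))
  }, numeric(1))
  expect_true(all(recovered >= 4))
})

test_that("clinical simulation honours censoring and covariate structure", {
  cfg0 <- sim_config(n_tumor = 40, censor_rate = 0, seed = 19)
  smp <- data.frame(sample_id = sprintf("T%02d", 1:40), tissue = "tumor",
                    histology = rep(c("favorable", "unfavorable"), 20),
                    gender = "female")
  g <- setNames(rep(c("more", "less"), 20), smp$sample_id)
  cl <- simulate_clinical(cfg0, g, smp)
  expect_true(all(cl$event == 1))
  expect_true(all(cl$time_days > 0))

  expect_error(simulate_clinical(cfg0, g[1:10], smp), "T11")

  # null hazard ratios: Cox estimate centres on HR 1 at large n
  cfgn <- sim_config(n_tumor = 500, hr_diversity = 1, hr_histology = 1,
                     censor_rate = 0.3, seed = 23)
  smp2 <- data.frame(sample_id = sprintf("T%03d", 1:500), tissue = "tumor",
                     histology = rep(c("favorable", "unfavorable"), 250),
                     gender = "female")
  g2 <- setNames(rep(c("more", "less"), 250), smp2$sample_id)
  cl2 <- simulate_clinical(cfgn, g2, smp2)
  fit <- cox_fit(data.frame(time = cl2$time_days, event = cl2$event,
                            less = as.integer(cl2$diversity_group == "less")),
                 "less")
  expect_true(fit$ci_low < 1 && 1 < fit$ci_high)
})

test_that("univariate Cox recovers a planted hazard ratio within its CI", {
  covered <- vapply(1:50, function(s) {
    cfg <- sim_config(n_tumor = 500, hr_diversity = 2, censor_rate = 0.5,
                      seed = s)
    smp <- data.frame(sample_id = sprintf("T%03d", 1:500), tissue = "tumor",
                      histology = "favorable", gender = "female")
    g <- setNames(rep(c("more", "less"), 250), smp$sample_id)
    cl <- simulate_clinical(cfg, g, smp)
    fit <- cox_fit(data.frame(time = cl$time_days, event = cl$event,
                              less = as.integer(cl$diversity_group == "less")),
                   "less")
    fit$ci_low <= 2 && 2 <= fit$ci_high
  }, logical(1))
  expect_gte(mean(covered), 0.9)
})

test_that("generated UTRs contain exactly the manifest's planted sites", {
  cfg <- sim_config(n_mirnas = 10, n_signal = 2, seed = 29)
  sq <- simulate_sequences(cfg, n_utrs = 4, utr_length = 400)

  # precursor carries its mature arm at the annotated coordinates
  ann <- sq$annotations
  for (i in seq_len(nrow(ann))) {
    expect_equal(unname(substr(sq$precursors[ann$precursor_id[i]],
                               ann$start[i], ann$end[i])),
                 unname(sq$matures[ann$mirna[i]]))
  }

  man <- sq$manifest
  m1 <- man$mirna[1]
  u1 <- unique(man$utr_id[man$mirna == m1])[1]
  exact <- man[man$mirna == m1 & man$utr_id == u1 & man$mismatches == 0, ]
  mm1 <- man[man$mirna == m1 & man$utr_id == u1 & man$mismatches == 1, ]

  h0 <- seed_sites(sq$matures[m1], sq$utrs[u1], max_mismatch = 0)
  expect_equal(nrow(h0), nrow(exact))
  expect_setequal(h0$start, exact$position)

  h1 <- seed_sites(sq$matures[m1], sq$utrs[u1], max_mismatch = 1)
  expect_equal(nrow(h1), nrow(exact) + nrow(mm1))
  # one-mismatch sites appear only when a mismatch is allowed
  if (nrow(mm1) > 0) {
    expect_true(all(mm1$position %in% h1$start))
    expect_false(any(mm1$position %in% h0$start))
  }

  # a UTR with no planted sites for this miRNA has no hits at all
  free_utrs <- setdiff(names(sq$utrs), man$utr_id[man$mirna == m1])
  if (length(free_utrs)) {
    hf <- seed_sites(sq$matures[m1], sq$utrs[free_utrs[1]], max_mismatch = 1)
    expect_equal(nrow(hf), 0)
  }
})

test_that("fixture and simulation round-trip through the text formats", {
  cfg <- sim_config(n_tumor = 6, n_normal = 4, n_mirnas = 8, seed = 31)
  x <- simulate_isomir_counts(cfg)
  tmp <- tempfile(fileext = ".tsv")
  write_isomir_counts(x, tmp)
  x2 <- read_isomir_counts(tmp, x$samples)
  expect_identical(unname(x2$counts), unname(x$counts))
  expect_identical(x2$ids$mirna, x$ids$mirna)

  g <- setNames(rep(c("more", "less"), 3), x$samples$sample_id[1:6])
  cl <- simulate_clinical(cfg, g, x$samples)
  tcl <- tempfile(fileext = ".tsv")
  write_clinical(cl, tcl)
  cl2 <- read_clinical(tcl)
  expect_equal(cl2$sample_id, cl$sample_id)
  expect_equal(cl2$time_days, cl$time_days, tolerance = 1e-8)

  sq <- simulate_sequences(cfg, n_utrs = 2, utr_length = 200)
  tfa <- tempfile(fileext = ".fa")
  write_fasta(sq$utrs, tfa)
  expect_equal(read_fasta(tfa), sq$utrs)
  tmn <- tempfile(fileext = ".txt")
  write_manifest(sq$manifest, tmn)
  man2 <- read_manifest(tmn)
  expect_equal(man2, sq$manifest)
})
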