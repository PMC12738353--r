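# Hand-built 5-miRNA x 6-sample count table. Every downstream stage has been
# worked out by hand for this table; the expected values are frozen in the
# tests that use it.
hand_table <- function() {
  ids <- data.frame(
    mirna = c("mA", "mA", "mA", "mB", "mC", "mC", "mD", "mD", "mD", "mD", "mE"),
    offset5 = c(0, 0, 1, 0, 0, 0, 0, 0, -1, 0, 0),
    offset3 = c(0, 1, -1, 0, 0, 1, 0, 1, 0, 2, 0),
    stringsAsFactors = FALSE
  )
  counts <- rbind(
    c(200, 150, 300, 500, 400, 450),  # mA 0|0
    c(120,  90,  80,   0,   5,   0),  # mA 0|1   (max 120 -> kept)
    c(101,   0,   0,   0,   0,   0),  # mA 1|-1  (boundary: 101 kept)
    c(100, 100, 100, 100, 100, 100),  # mB 0|0   (max 100 -> dropped, strict >)
    c(5000, 4000, 3000, 2000, 1000, 1500),  # mC 0|0
    c(0,  300, 200, 600, 700, 800),   # mC 0|1
    c(150, 160, 170, 180, 190, 200),  # mD 0|0
    c(110, 120, 130, 140, 150, 160),  # mD 0|1
    c(105,   0, 115,   0, 125,   0),  # mD -1|0
    c(0,  102,   0, 104,   0, 106),   # mD 0|2
    c(99,  98,   0,   0,   0,   0)    # mE 0|0   (max 99 -> dropped)
  )
  samples <- data.frame(
    sample_id = c("T1", "T2", "T3", "N1", "N2", "N3"),
    tissue = rep(c("tumor", "normal"), each = 3),
    histology = c("favorable", "favorable", "unfavorable", NA, NA, NA),
    stringsAsFactors = FALSE
  )
  isomir_counts(counts, ids, samples)
}

# independent brute-force seed scan used as the oracle for seed_sites():
# plain character comparison at every window
oracle_seed_scan <- function(mirna, utr, seed_start = 2, seed_end = 8,
                             max_mismatch = 1) {
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  m <- strsplit(chartr("T", "U", toupper(mirna)), "")[[1]]
  u <- strsplit(chartr("T", "U", toupper(utr)), "")[[1]]
  seed <- m[seed_start:seed_end]
  target <- rev(unname(comp[seed]))   # reverse complement of the seed
  k <- length(target)
  hits <- integer(0)
  mism <- integer(0)
  for (s in seq_len(length(u) - k + 1)) {
    d <- sum(u[s:(s + k - 1)] != target)
    if (d <= max_mismatch) { hits <- c(hits, s); mism <- c(mism, d) }
  }
  data.frame(start = hits, mismatches = mism)
}

# hand product-limit estimator (no library calls)
oracle_km <- function(time, event) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  ut <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(length(ut))
  for (i in seq_along(ut)) {
    at_risk <- sum(time >= ut[i])
    d <- sum(time == ut[i] & event == 1)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  data.frame(time = ut, survival = surv)
}

# Welch two-sample t-test p-value straight from the textbook formulas
oracle_welch_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- var(x); vy <- var(y)
  se2 <- vx / nx + vy / ny
  tstat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  2 * pt(-abs(tstat), df)
}

# antiparallel duplex scorer built independently of the package internals
oracle_pair_score <- function(mirna, window) {
  m <- strsplit(chartr("T", "U", toupper(mirna)), "")[[1]]
  w <- rev(strsplit(chartr("T", "U", toupper(window)), "")[[1]])
  sc <- 0
  for (i in seq_along(m)) {
    pair <- paste0(m[i], w[i])
    sc <- sc + if (pair %in% c("AU", "UA", "GC", "CG")) 1
      else if (pair %in% c("GU", "UG")) 0.5 else 0
  }
  sc
}

random_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, replace = TRUE),
                                collapse = "")

# planted effective-site UTR: 4 sites fully complementary to the archetype
# (score 22 for both forms; a C before each blocks the isoform's extension)
# plus one partial site pairing the seed, miRNA 9-14, and the isoform's
# templated 3' +U (archetype score 13, isoform 14)
planted_site_bundle <- function() {
  arch <- "UAUGUGCCUUUGGACUACAUCG"
  iso <- paste0(arch, "U")
  rc <- function(s) as.character(Biostrings::reverseComplement(Biostrings::RNAString(s)))
  nonpair <- function(b) c(A = "C", C = "A", G = "G", U = "C")[b]
  m <- strsplit(arch, "")[[1]]
  np <- paste(rev(unname(nonpair(m[15:22]))), collapse = "")
  partial <- paste0("A", np, rc(substr(arch, 9, 14)), rc(substr(arch, 2, 8)))
  spacer <- strrep("C", 10)
  full <- rc(arch)
  utr <- paste0(spacer, paste(rep(paste0("C", full, spacer), 4), collapse = ""),
                partial, spacer)
  list(arch = arch, iso = iso, utr = utr,
       n_full = 4L, partial_scores = c(arch = 13, iso = 14))
}
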