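# All randomness in the generator flows from the config seed through
# .with_seed(); the caller's RNG state is left untouched.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulation configuration
#'
#' Parameters of the synthetic cohort. The defaults emulate the study
#' conditions the pipeline is designed for: 127 tumor and 5 adjacent
#' non-tumorous samples, a mean small RNA-seq depth of 8.9 million reads, and
#' two planted signal miRNAs whose isoform diversity differs about
#' three-fold between groups (candidate miRNAs are selected at a two-fold
#' threshold, and real hits clear it with margin). Event-free survival is
#' mostly censored, as in pediatric cohorts where most patients stay
#' event-free.
#'
#' @param n_tumor,n_normal sample counts per tissue.
#' @param n_mirnas number of simulated miRNA families.
#' @param n_signal number of planted diversity-signal miRNAs (<= n_mirnas).
#'   Signal miRNAs have reduced isoform diversity in tumors versus normal
#'   tissue and further reduced diversity in unfavorable-histology tumors,
#'   each by `diversity_fc`.
#' @param depth_mean mean library depth in reads.
#' @param depth_cv coefficient of variation of per-sample depth.
#' @param nb_dispersion negative-binomial dispersion of read counts (> 0;
#'   variance = mu + dispersion * mu^2).
#' @param diversity_fc planted fold change (>= 1) of mean isoform count
#'   between groups.
#' @param hr_diversity hazard ratio of the "less"-diversity group versus
#'   "more" (> 0).
#' @param hr_histology hazard ratio of unfavorable versus favorable
#'   histology (> 0).
#' @param censor_rate expected censored fraction in \[0, 1).
#' @param p_unfavorable probability a tumor is unfavorable histology.
#' @param surv_model `"exponential"` (default) or `"weibull"`.
#' @param weibull_shape Weibull shape when `surv_model = "weibull"`.
#' @param seed integer random seed; identical seed and config give
#'   byte-identical outputs.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_tumor = 127, n_normal = 5, n_mirnas = 150,
                       n_signal = 2, depth_mean = 8.9e6, depth_cv = 0.1,
                       nb_dispersion = 0.2, diversity_fc = 3,
                       hr_diversity = 2, hr_histology = 3,
                       censor_rate = 0.75, p_unfavorable = 0.3,
                       surv_model = c("exponential", "weibull"),
                       weibull_shape = 1, seed = 1) {
  cfg <- list(n_tumor = n_tumor, n_normal = n_normal, n_mirnas = n_mirnas,
              n_signal = n_signal, depth_mean = depth_mean, depth_cv = depth_cv,
              nb_dispersion = nb_dispersion, diversity_fc = diversity_fc,
              hr_diversity = hr_diversity, hr_histology = hr_histology,
              censor_rate = censor_rate, p_unfavorable = p_unfavorable,
              surv_model = match.arg(surv_model),
              weibull_shape = weibull_shape, seed = seed)
  check <- function(ok, field, msg) {
    if (!isTRUE(ok)) stop(sprintf("invalid sim_config field '%s': %s", field, msg))
  }
  for (f in c("n_tumor", "n_normal", "n_mirnas"))
    check(is.numeric(cfg[[f]]) && length(cfg[[f]]) == 1 && cfg[[f]] >= 1 &&
            cfg[[f]] == round(cfg[[f]]), f, "must be a positive integer")
  check(cfg$n_signal >= 0 && cfg$n_signal <= cfg$n_mirnas && cfg$n_signal == round(cfg$n_signal),
        "n_signal", "must be an integer in [0, n_mirnas]")
  check(cfg$depth_mean > 0, "depth_mean", "must be positive")
  check(cfg$depth_cv >= 0, "depth_cv", "must be non-negative")
  check(cfg$nb_dispersion > 0, "nb_dispersion", "must be > 0")
  check(cfg$diversity_fc >= 1, "diversity_fc", "must be >= 1")
  check(cfg$hr_diversity > 0, "hr_diversity", "must be > 0")
  check(cfg$hr_histology > 0, "hr_histology", "must be > 0")
  check(cfg$censor_rate >= 0 && cfg$censor_rate < 1, "censor_rate",
        "must be in [0, 1)")
  check(cfg$p_unfavorable > 0 && cfg$p_unfavorable < 1, "p_unfavorable",
        "must be in (0, 1)")
  check(cfg$weibull_shape > 0, "weibull_shape", "must be > 0")
  check(is.numeric(cfg$seed) && length(cfg$seed) == 1 && cfg$seed == round(cfg$seed),
        "seed", "must be an integer")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: %d tumor + %d normal samples, %d miRNAs (%d signal, fc=%g), depth %.3g\n",
              x$n_tumor, x$n_normal, x$n_mirnas, x$n_signal, x$diversity_fc,
              x$depth_mean))
  invisible(x)
}

# zero-truncated Poisson with a given *mean* (the mean of a ZTP exceeds its
# rate lambda, so the rate is solved for numerically)
.ztpois_lambda <- function(target_mean) {
  target_mean <- max(target_mean, 1 + 1e-6)
  f <- function(l) l / (1 - exp(-l)) - target_mean
  stats::uniroot(f, c(1e-9, target_mean + 10), tol = 1e-10)$root
}

.rztpois <- function(n, lambda) {
  u <- stats::runif(n, stats::dpois(0, lambda), 1)
  stats::qpois(u, lambda)
}

# Offset pool: isoform identities ranked by biological plausibility. 5'
# offsets concentrate at 0 (Drosha/Dicer 5' cleavage is precise), 3' offsets
# are dispersed. The rank order is fixed; per-miRNA abundance decays
# geometrically along it.
.offset_pool <- function() {
  o5 <- c(-2, -1, 0, 1, 2)
  w5 <- c(0.02, 0.1, 0.72, 0.12, 0.04)
  o3 <- -4:5
  w3 <- c(0.015, 0.04, 0.1, 0.17, 0.22, 0.23, 0.12, 0.06, 0.03, 0.015)
  grid <- expand.grid(offset5 = o5, offset3 = o3)
  grid$w <- w5[match(grid$offset5, o5)] * w3[match(grid$offset3, o3)]
  grid <- grid[order(-grid$w, abs(grid$offset5), abs(grid$offset3),
                     grid$offset5, grid$offset3), ]
  rownames(grid) <- NULL
  grid
}

#' Simulate an isomiR read-count table
#'
#' For each miRNA, the number of distinct isoforms in a sample is drawn from
#' a zero-truncated Poisson whose mean depends on the sample's group:
#' non-signal miRNAs share one mean everywhere, while planted signal miRNAs
#' have group means ordered unfavorable < favorable < normal such that both
#' the tumor/normal and the unfavorable/favorable expected-mean ratios equal
#' `diversity_fc`. Isoform identities come from a fixed plausibility-ranked
#' pool (5' offsets concentrated at 0, 3' offsets dispersed); within a
#' miRNA, abundance decays geometrically along the ranks, with the `0|1`
#' isoform dominant for signal miRNAs. Read counts are negative binomial
#' with per-sample library-size scaling. Histology labels for tumor samples
#' are assigned here (they shape the planted signal) and carried in the
#' sample annotation.
#'
#' @param config a [sim_config()].
#' @return An [isomir_counts()] object, with attributes `signal_mirnas`
#'   (planted miRNA names) and `depths` (simulated library sizes).
#' @export
simulate_isomir_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(config$seed, {
    n_t <- config$n_tumor; n_n <- config$n_normal
    n_samp <- n_t + n_n
    fc <- config$diversity_fc
    samples <- data.frame(
      sample_id = c(sprintf("T%03d", seq_len(n_t)), sprintf("N%03d", seq_len(n_n))),
      tissue = rep(c("tumor", "normal"), c(n_t, n_n)),
      stringsAsFactors = FALSE
    )
    histology <- rep(NA_character_, n_samp)
    histology[seq_len(n_t)] <- ifelse(
      stats::runif(n_t) < config$p_unfavorable, "unfavorable", "favorable")
    samples$histology <- histology
    samples$gender <- sample(c("female", "male"), n_samp, replace = TRUE)

    pool <- .offset_pool()
    K <- nrow(pool)
    mirnas <- sprintf("miR-sim-%03d-5p", seq_len(config$n_mirnas))
    signal <- if (config$n_signal > 0) mirnas[seq_len(config$n_signal)] else character(0)

    # per-miRNA baseline mean isoform count; signal miRNAs get a narrow base
    # so that base * fc^2 stays well inside the offset pool
    base_mean <- pmin(pmax(exp(stats::rnorm(config$n_mirnas, log(2.2), 0.45)), 1.05), 8)
    base_mean[seq_len(config$n_signal)] <- stats::runif(config$n_signal, 1.6, 2.2)

    # group-specific target means: columns unfavorable / favorable / normal
    p_u <- config$p_unfavorable
    mean_by_group <- cbind(unfav = base_mean, fav = base_mean, normal = base_mean)
    if (config$n_signal > 0) {
      i <- seq_len(config$n_signal)
      mean_by_group[i, "fav"] <- base_mean[i] * fc
      # normal mean set so that the *tumor-average* (histology mixture) to
      # normal ratio is exactly fc
      tumor_avg <- (1 - p_u) * base_mean[i] * fc + p_u * base_mean[i]
      mean_by_group[i, "normal"] <- fc * tumor_avg
    }
    grp_of_sample <- ifelse(samples$tissue == "normal", "normal",
                            ifelse(samples$histology == "unfavorable", "unfav", "fav"))

    # overall miRNA expression (relative weights) and isoform decay
    expr <- exp(stats::rnorm(config$n_mirnas, 0, 1))
    tumor_expr_factor <- rep(1, config$n_mirnas)
    tumor_expr_factor[seq_len(config$n_signal)] <- 2  # planted abundance shift
    decay <- 0.65
    rank_w <- decay^(seq_len(K) - 1)

    depth <- pmax(round(stats::rnorm(n_samp, config$depth_mean,
                                     config$depth_cv * config$depth_mean)), 1e5)

    # presence: for each miRNA x sample, how many top-ranked isoforms exist
    lam <- matrix(0, config$n_mirnas, 3, dimnames = list(NULL, colnames(mean_by_group)))
    for (g in colnames(mean_by_group))
      lam[, g] <- vapply(mean_by_group[, g], .ztpois_lambda, numeric(1))
    n_iso <- matrix(0L, config$n_mirnas, n_samp)
    for (j in seq_len(n_samp))
      n_iso[, j] <- pmin(.rztpois(config$n_mirnas, lam[, grp_of_sample[j]]), K)

    # expected reads per isomiR x sample, scaled to the sample depth
    n_rows <- config$n_mirnas * K
    rank_of_row <- rep(seq_len(K), times = config$n_mirnas)
    mirna_of_row <- rep(seq_len(config$n_mirnas), each = K)
    w_row <- expr[mirna_of_row] * rank_w[rank_of_row]
    counts <- matrix(0L, n_rows, n_samp)
    for (j in seq_len(n_samp)) {
      present <- rank_of_row <= n_iso[mirna_of_row, j]
      w <- w_row * present
      if (samples$tissue[j] == "tumor") w <- w * tumor_expr_factor[mirna_of_row]
      mu <- depth[j] * w / sum(w)
      cj <- integer(n_rows)
      nz <- which(mu > 0)
      cj[nz] <- stats::rnbinom(length(nz), mu = mu[nz], size = 1 / config$nb_dispersion)
      counts[, j] <- cj
    }

    # isoform identity per row: ranked pool, with 0|0 and 0|1 swapped for
    # signal miRNAs so the templated 3' +1 isoform dominates
    ids <- data.frame(
      mirna = mirnas[mirna_of_row],
      offset5 = pool$offset5[rank_of_row],
      offset3 = pool$offset3[rank_of_row],
      stringsAsFactors = FALSE
    )
    i00 <- which(pool$offset5 == 0 & pool$offset3 == 0)
    i01 <- which(pool$offset5 == 0 & pool$offset3 == 1)
    for (s in seq_len(config$n_signal)) {
      r <- (s - 1) * K
      ids[r + i00, c("offset5", "offset3")] <- pool[i01, c("offset5", "offset3")]
      ids[r + i01, c("offset5", "offset3")] <- pool[i00, c("offset5", "offset3")]
    }

    observed <- rowSums(counts) > 0
    out <- isomir_counts(counts[observed, , drop = FALSE],
                         ids[observed, , drop = FALSE], samples)
    attr(out, "signal_mirnas") <- signal
    attr(out, "depths") <- stats::setNames(depth, samples$sample_id)
    out
  })
}

#' Simulate a clinical table with diversity-dependent survival
#'
#' Event-free survival times for tumor samples are drawn from a proportional
#' hazards model (exponential baseline by default, Weibull optional) with
#' log-hazard `log(hr_diversity) * [less] + log(hr_histology) *
#' [unfavorable]`. Censoring is independent exponential, with its rate
#' calibrated against the cohort-average hazard so the expected censored
#' fraction is `censor_rate`; `censor_rate = 0` gives fully observed events.
#' Normal-tissue samples carry `NA` survival fields.
#'
#' @param config a [sim_config()].
#' @param diversity_groups named character vector of `"more"`/`"less"`
#'   labels covering every tumor sample (names are sample ids).
#' @param samples the sample annotation of the simulated count table
#'   (provides tissue, histology, gender).
#' @return A clinical data.frame: `sample_id`, `time_days`, `event`,
#'   `histology`, `gender`, `tissue`, `diversity_group`.
#' @export
simulate_clinical <- function(config, diversity_groups, samples) {
  stopifnot(inherits(config, "sim_config"), is.data.frame(samples))
  tumor_ids <- samples$sample_id[samples$tissue == "tumor"]
  missing <- setdiff(tumor_ids, names(diversity_groups))
  if (length(missing))
    stop("diversity_groups missing for tumor sample(s): ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) sprintf(" (and %d more)", length(missing) - 5))
  bad <- setdiff(unique(diversity_groups), c("more", "less"))
  if (length(bad)) stop("diversity labels must be 'more'/'less', got: ",
                        paste(bad, collapse = ", "))
  .with_seed(config$seed + 1L, {
    out <- data.frame(
      sample_id = samples$sample_id,
      time_days = NA_real_,
      event = NA_integer_,
      histology = samples$histology,
      gender = samples$gender,
      tissue = samples$tissue,
      diversity_group = NA_character_,
      stringsAsFactors = FALSE
    )
    it <- match(tumor_ids, out$sample_id)
    grp <- unname(diversity_groups[tumor_ids])
    out$diversity_group[it] <- grp
    # baseline daily hazard: ~30% cumulative event probability at 5 years
    h0 <- -log(0.7) / (5 * 365)
    h <- h0 * exp(log(config$hr_diversity) * (grp == "less") +
                  log(config$hr_histology) * (out$histology[it] == "unfavorable"))
    shape <- if (config$surv_model == "weibull") config$weibull_shape else 1
    t_event <- (stats::rexp(length(it), rate = 1) / h)^(1 / shape)
    if (config$censor_rate > 0) {
      hc <- config$censor_rate / (1 - config$censor_rate) * mean(h)
      t_cens <- (stats::rexp(length(it), rate = 1) / hc)^(1 / shape)
    } else {
      t_cens <- rep(Inf, length(it))
    }
    out$time_days[it] <- pmin(t_event, t_cens)
    out$event[it] <- as.integer(t_event <= t_cens)
    out
  })
}

# naive seed-hit counter used only inside the generator (the scanner proper
# lives in seed_sites(); keeping this separate avoids testing the scanner
# against itself)
.naive_seed_hits <- function(seed_rc_chars, utr_chars, max_mismatch) {
  k <- length(seed_rc_chars)
  n <- length(utr_chars)
  if (n < k) return(integer(0))
  hits <- integer(0)
  for (s in seq_len(n - k + 1)) {
    mm <- sum(utr_chars[s:(s + k - 1)] != seed_rc_chars)
    if (mm <= max_mismatch) hits <- c(hits, s)
  }
  hits
}

.random_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, replace = TRUE),
                                 collapse = "")

#' Simulate precursor, mature-annotation and UTR sequences with planted sites
#'
#' Generates one precursor hairpin per miRNA with the mature 5p arm at
#' annotated coordinates, plus a set of 3'UTR sequences in which
#' seed-complementary sites for the planted miRNAs are inserted at recorded
#' positions: `exact` sites are perfect reverse complements of the seed
#' (miRNA positions `seed_start..seed_end`), `mismatch1` sites carry exactly
#' one mismatch. Background sequence is rejection-sampled so planted
#' miRNAs have no accidental sites within one mismatch; the manifest
#' therefore is the exact ground truth for a scanner.
#'
#' @param config a [sim_config()].
#' @param n_utrs number of UTR sequences.
#' @param utr_length UTR length in nt.
#' @param plant data.frame with columns `mirna` (index into the simulated
#'   miRNAs), `utr` (index into the UTRs), `exact`, `mismatch1` (site
#'   counts). Default: the first signal miRNA gets 3 exact + 1 one-mismatch
#'   sites in UTR 1 and 1 exact site in UTR 2.
#' @param seed_start,seed_end seed definition used for planting.
#' @return A list with `precursors` (named character vector of RNA
#'   sequences), `annotations` (data.frame `precursor_id`, `mirna`, `start`,
#'   `end`), `matures` (named mature sequences), `utrs` (named character
#'   vector), and `manifest` (data.frame `mirna`, `utr_id`, `position`,
#'   `mismatches`, one row per planted site).
#' @export
simulate_sequences <- function(config, n_utrs = 6, utr_length = 500,
                               plant = NULL, seed_start = 2, seed_end = 8) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(config$seed + 2L, {
    n_mir <- config$n_mirnas
    mirnas <- sprintf("miR-sim-%03d-5p", seq_len(n_mir))
    prec_ids <- sprintf("mir-sim-%03d", seq_len(n_mir))
    mat_start <- 10L; mat_len <- 22L
    prec_len <- 72L
    precursors <- vapply(seq_len(n_mir), function(i) .random_rna(prec_len), character(1))
    names(precursors) <- prec_ids
    matures <- substr(precursors, mat_start, mat_start + mat_len - 1L)
    names(matures) <- mirnas
    annotations <- data.frame(
      precursor_id = prec_ids, mirna = mirnas,
      start = mat_start, end = mat_start + mat_len - 1L,
      stringsAsFactors = FALSE
    )

    if (is.null(plant)) {
      first_sig <- if (config$n_signal > 0) 1L else NA_integer_
      plant <- if (is.na(first_sig)) {
        data.frame(mirna = integer(0), utr = integer(0),
                   exact = integer(0), mismatch1 = integer(0))
      } else {
        data.frame(mirna = c(first_sig, first_sig), utr = c(1L, 2L),
                   exact = c(3L, 1L), mismatch1 = c(1L, 0L))
      }
    }
    stopifnot(all(plant$utr <= n_utrs), all(plant$mirna <= n_mir))

    k <- seed_end - seed_start + 1L
    planted_mirs <- unique(plant$mirna)
    seed_rc <- lapply(planted_mirs, function(i)
      strsplit(.rc_rna(substr(matures[i], seed_start, seed_end)), "")[[1]])
    names(seed_rc) <- as.character(planted_mirs)

    utr_ids <- sprintf("utr%02d", seq_len(n_utrs))
    utrs <- character(n_utrs)
    manifest <- list()
    for (u in seq_len(n_utrs)) {
      rows <- plant[plant$utr == u, , drop = FALSE]
      placed <- NULL
      for (attempt in seq_len(500)) {
        bg <- strsplit(.random_rna(utr_length), "")[[1]]
        # background must be free of accidental sites for all planted miRNAs
        clean <- all(vapply(planted_mirs, function(i)
          length(.naive_seed_hits(seed_rc[[as.character(i)]], bg, 1L)) == 0,
          logical(1)))
        if (!clean) next
        n_sites <- sum(rows$exact) + sum(rows$mismatch1)
        if (n_sites == 0) { placed <- list(seq = bg, sites = NULL); break }
        # non-overlapping slots, spaced by > seed length
        slots <- sort(sample(seq(5, utr_length - k - 5, by = k + 4), n_sites))
        site_tab <- NULL
        si <- 1L
        for (r in seq_len(nrow(rows))) {
          rc <- seed_rc[[as.character(rows$mirna[r])]]
          for (e in seq_len(rows$exact[r])) {
            bg[slots[si]:(slots[si] + k - 1)] <- rc
            site_tab <- rbind(site_tab, data.frame(
              mirna = mirnas[rows$mirna[r]], utr_id = utr_ids[u],
              position = slots[si], mismatches = 0L))
            si <- si + 1L
          }
          if (rows$mismatch1[r] > 0) for (e in seq_len(rows$mismatch1[r])) {
            w <- rc
            pos <- sample.int(k, 1)
            w[pos] <- sample(setdiff(c("A", "C", "G", "U"), w[pos]), 1)
            bg[slots[si]:(slots[si] + k - 1)] <- w
            site_tab <- rbind(site_tab, data.frame(
              mirna = mirnas[rows$mirna[r]], utr_id = utr_ids[u],
              position = slots[si], mismatches = 1L))
            si <- si + 1L
          }
        }
        # verify: observed hit counts must equal the planted truth exactly
        # (insertions can create junction artifacts; retry if so)
        ok <- all(vapply(planted_mirs, function(i) {
          rc <- seed_rc[[as.character(i)]]
          h0 <- .naive_seed_hits(rc, bg, 0L)
          h1 <- .naive_seed_hits(rc, bg, 1L)
          want0 <- sum(site_tab$mirna == mirnas[i] & site_tab$mismatches == 0)
          want1 <- want0 + sum(site_tab$mirna == mirnas[i] & site_tab$mismatches == 1)
          length(h0) == want0 && length(h1) == want1 &&
            all(site_tab$position[site_tab$mirna == mirnas[i]] %in% h1)
        }, logical(1)))
        if (ok) { placed <- list(seq = bg, sites = site_tab); break }
      }
      if (is.null(placed))
        stop(sprintf("could not place planted sites in UTR %d; lower the site count or lengthen the UTR", u))
      utrs[u] <- paste(placed$seq, collapse = "")
      if (!is.null(placed$sites)) manifest[[length(manifest) + 1L]] <- placed$sites
    }
    names(utrs) <- utr_ids
    manifest <- if (length(manifest)) do.call(rbind, manifest)
      else data.frame(mirna = character(0), utr_id = character(0),
                      position = integer(0), mismatches = integer(0))
    list(precursors = precursors, annotations = annotations,
         matures = matures, utrs = utrs, manifest = manifest)
  })
}
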