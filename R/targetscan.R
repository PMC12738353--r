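# Pairing model: Watson-Crick pair scores 1, G:U wobble 0.5, anything else 0.
# Within the seed, only Watson-Crick counts as a match (wobble = mismatch).
.BASES <- c(A = 1L, C = 2L, G = 3L, U = 4L)

.PAIR_SCORE <- local({
  m <- matrix(0, 4, 4, dimnames = list(names(.BASES), names(.BASES)))
  m["A", "U"] <- m["U", "A"] <- m["G", "C"] <- m["C", "G"] <- 1
  m["G", "U"] <- m["U", "G"] <- 0.5
  m
})

.encode <- function(s) .BASES[strsplit(s, "", fixed = TRUE)[[1]]]

.rc_rna <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::RNAString(s)))
}

#' Complementarity score of an antiparallel miRNA:target duplex
#'
#' Scores a miRNA against a target window of the same length, paired
#' antiparallel (miRNA position 1 against the window's last base): each
#' Watson-Crick pair contributes +1, each G:U wobble +0.5, anything else 0.
#' The maximum is therefore the miRNA length, attained by the window that is
#' the exact reverse complement.
#'
#' @param mirna_seq miRNA sequence (RNA letters; T accepted as U).
#' @param utr_window target subsequence of the same length.
#' @return The score, with attribute `"pairing"`: one character per miRNA
#'   position 5'->3' (`|` Watson-Crick, `:` wobble, `.` unpaired).
#' @export
pairing_score <- function(mirna_seq, utr_window) {
  m <- .encode(.normalize_rna(mirna_seq, "mirna_seq"))
  w <- .encode(.normalize_rna(utr_window, "utr_window"))
  if (length(m) != length(w))
    stop(sprintf("window length %d != miRNA length %d", length(w), length(m)))
  per <- .PAIR_SCORE[cbind(m, rev(w))]
  structure(sum(per),
            pairing = paste(c("." , ":", "|")[1L + 2L * (per == 1) + (per == 0.5)],
                            collapse = ""))
}

# Extended-duplex scores of a full-length miRNA against every alignment
# window of a UTR (integer-coded), antiparallel. Returns a vector over window
# start positions 1..(nchar(utr) - L + 1).
.score_profile <- function(m_code, u_code) {
  L <- length(m_code)
  n <- length(u_code)
  if (n < L) return(numeric(0))
  nw <- n - L + 1L
  total <- numeric(nw)
  a <- seq_len(nw)
  for (p in seq_len(L)) {
    # miRNA position p pairs UTR position a + (L - p) under antiparallel pairing
    total <- total + .PAIR_SCORE[cbind(rep.int(m_code[p], nw), u_code[a + (L - p)])]
  }
  total
}

#' Scan a 3'UTR for miRNA seed-complementary sites
#'
#' Finds every UTR window (sense strand, 5'->3') whose sequence is the
#' reverse complement of the miRNA seed (positions `seed_start..seed_end`,
#' default 2-8) up to `max_mismatch` mismatches. A G:U wobble counts as a
#' mismatch within the seed. Overlapping sites are all reported. Each hit
#' also carries an extended-duplex `pairing_score` obtained by pairing the
#' full miRNA antiparallel around the seed match (clipped at the UTR ends),
#' so that isoforms sharing a seed can still be ranked by 3'-supplementary
#' pairing.
#'
#' @param mirna_seq miRNA sequence, 5'->3' (RNA letters; T read as U).
#' @param utr_seq UTR sequence (DNA or RNA letters; normalised to RNA).
#' @param seed_start,seed_end miRNA positions delimiting the seed (1-based,
#'   inclusive).
#' @param max_mismatch maximum mismatches tolerated in the seed (0 or 1
#'   typically).
#' @param utr_id identifier copied into the result.
#' @return A data.frame of hits: `utr_id`, `start` (1-based position of the
#'   site's first paired UTR base), `end`, `mismatches`, `pairing_score`.
#' @export
seed_sites <- function(mirna_seq, utr_seq, seed_start = 2, seed_end = 8,
                       max_mismatch = 1, utr_id = "utr") {
  mirna <- .normalize_rna(mirna_seq, "mirna_seq")
  utr <- .normalize_rna(utr_seq, "utr_seq")
  L <- nchar(mirna)
  if (seed_start < 1 || seed_end > L || seed_start >= seed_end)
    stop("invalid seed positions for a miRNA of length ", L)
  k <- seed_end - seed_start + 1L
  if (nchar(utr) < k) stop("UTR shorter than the seed")
  if (max_mismatch < 0 || max_mismatch >= k) stop("'max_mismatch' out of range")
  seed <- substr(mirna, seed_start, seed_end)
  target <- .rc_rna(seed)
  m <- Biostrings::matchPattern(target, Biostrings::RNAString(utr),
                                max.mismatch = max_mismatch, with.indels = FALSE)
  starts <- BiocGenerics::start(m)
  if (length(starts) == 0L) {
    return(data.frame(utr_id = character(0), start = integer(0),
                      end = integer(0), mismatches = integer(0),
                      pairing_score = numeric(0)))
  }
  tgt <- .encode(target)
  u_code <- .encode(utr)
  m_code <- .encode(mirna)
  mism <- vapply(starts, function(s) {
    sum(u_code[s:(s + k - 1L)] != tgt)
  }, integer(1))
  score <- vapply(starts, function(s) {
    # miRNA position p pairs UTR position s + (seed_end - p); clip to the UTR
    pos <- s + seed_end - seq_len(L)
    ok <- pos >= 1L & pos <= length(u_code)
    sum(.PAIR_SCORE[cbind(m_code[ok], u_code[pos[ok]])])
  }, numeric(1))
  out <- data.frame(utr_id = utr_id, start = as.integer(starts),
                    end = as.integer(starts + k - 1L),
                    mismatches = mism, pairing_score = score,
                    stringsAsFactors = FALSE)
  out[order(out$start), , drop = FALSE]
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Altschul-Erickson shuffle: returns a random sequence with exactly the same
#' dinucleotide (and hence mononucleotide) composition as the input, via a
#' random Eulerian path on the dinucleotide multigraph. First and last
#' residues are preserved. Used to build the empirical null for pairing
#' scores.
#'
#' @param seq sequence to shuffle (RNA/DNA letters).
#' @return A shuffled sequence of the same length (RNA letters).
#' @export
dinucleotide_shuffle <- function(seq) {
  s <- strsplit(.normalize_rna(seq, "seq"), "", fixed = TRUE)[[1]]
  n <- length(s)
  if (n <= 3L) return(paste(s, collapse = ""))
  verts <- unique(s)
  if (length(verts) == 1L) return(paste(s, collapse = ""))
  from <- s[-n]; to <- s[-1]
  adj <- split(to, factor(from, levels = verts))
  z <- s[n]
  # choose a random last-exit edge for every vertex except z such that the
  # chosen edges form an arborescence toward z (Altschul-Erickson condition)
  nonz <- setdiff(names(adj)[lengths(adj) > 0], z)
  repeat {
    last_edge <- vapply(nonz, function(v) sample(adj[[v]], 1L)[1], character(1))
    ok <- all(vapply(nonz, function(v) {
      seen <- character(0)
      while (v != z) {
        if (v %in% seen || !v %in% nonz) return(FALSE)
        seen <- c(seen, v)
        v <- last_edge[[v]]
      }
      TRUE
    }, logical(1)))
    if (ok) break
  }
  ordered <- adj
  for (v in names(adj)) {
    e <- adj[[v]]
    if (!length(e)) next
    if (v %in% nonz) {
      i <- match(last_edge[[v]], e)
      rest <- e[-i]
      ordered[[v]] <- c(if (length(rest)) sample(rest, length(rest)) else character(0),
                        e[i])
    } else {
      ordered[[v]] <- if (length(e) > 1) sample(e, length(e)) else e
    }
  }
  ptr <- stats::setNames(rep(1L, length(ordered)), names(ordered))
  out <- character(n)
  out[1] <- s[1]
  cur <- s[1]
  for (i in 2:n) {
    nxt <- ordered[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    out[i] <- nxt
    cur <- nxt
  }
  paste(out, collapse = "")
}

#' Empirical p-values for site pairing scores
#'
#' Builds a null distribution of extended-duplex pairing scores by scoring
#' the miRNA against every alignment window of dinucleotide-shuffled copies
#' of the UTR, then assigns each observed score an upper-tail empirical
#' p-value (rank-based, with the +1 correction). Sites with p below `alpha`
#' are flagged effective.
#'
#' @param hits a hit table from [seed_sites()] (needs a `pairing_score`
#'   column).
#' @param mirna_seq,utr_seq the scanned sequences.
#' @param shuffles number of dinucleotide shuffles (default 1000).
#' @param alpha significance level for the effective flag.
#' @return `hits` with extra columns `p_empirical` and `effective`.
#' @export
effective_sites <- function(hits, mirna_seq, utr_seq, shuffles = 1000,
                            alpha = 0.05) {
  mirna <- .normalize_rna(mirna_seq, "mirna_seq")
  utr <- .normalize_rna(utr_seq, "utr_seq")
  m_code <- .encode(mirna)
  null_scores <- unlist(lapply(seq_len(shuffles), function(i) {
    .score_profile(m_code, .encode(dinucleotide_shuffle(utr)))
  }), use.names = FALSE)
  hits$p_empirical <- vapply(hits$pairing_score, function(sc) {
    (1 + sum(null_scores >= sc)) / (1 + length(null_scores))
  }, numeric(1))
  hits$effective <- hits$p_empirical < alpha
  hits
}

#' Compare target-site counts of an archetype and one of its isoforms
#'
#' Scans the same UTR with both sequences and reports site counts and their
#' difference. Two countings are reported: plain seed-site counts, and
#' "effective" counts restricted to sites whose extended-duplex
#' `pairing_score` reaches `min_score` (when given). For a pure 3'-extension
#' isoform (e.g. `0|1`) the seed is identical to the archetype's, so the
#' seed-site counts are necessarily equal and any difference can only come
#' from 3'-supplementary pairing picked up by the score filter — the result
#' flags this case explicitly.
#'
#' @param archetype_seq,isoform_seq the two miRNA sequences.
#' @param utr_seq UTR to scan.
#' @param seed_start,seed_end,max_mismatch as in [seed_sites()].
#' @param min_score optional extended-duplex score threshold defining
#'   effective sites.
#' @param utr_id identifier for reporting.
#' @return An object of class `site_comparison`: a list with `sites_archetype`,
#'   `sites_isoform`, `delta` (isoform - archetype; effective counts when
#'   `min_score` is given, otherwise seed counts), `seed_identical`, and the
#'   two hit tables.
#' @export
compare_site_counts <- function(archetype_seq, isoform_seq, utr_seq,
                                seed_start = 2, seed_end = 8, max_mismatch = 1,
                                min_score = NULL, utr_id = "utr") {
  ha <- seed_sites(archetype_seq, utr_seq, seed_start, seed_end, max_mismatch, utr_id)
  hi <- seed_sites(isoform_seq, utr_seq, seed_start, seed_end, max_mismatch, utr_id)
  seed_a <- substr(.normalize_rna(archetype_seq), seed_start, seed_end)
  seed_i <- substr(.normalize_rna(isoform_seq), seed_start, seed_end)
  if (is.null(min_score)) {
    na <- nrow(ha); ni <- nrow(hi)
  } else {
    na <- sum(ha$pairing_score >= min_score)
    ni <- sum(hi$pairing_score >= min_score)
  }
  structure(
    list(sites_archetype = na, sites_isoform = ni, delta = ni - na,
         seed_identical = identical(seed_a, seed_i),
         min_score = min_score,
         hits_archetype = ha, hits_isoform = hi),
    class = "site_comparison"
  )
}

#' @export
print.site_comparison <- function(x, ...) {
  kind <- if (is.null(x$min_score)) "seed sites"
          else sprintf("effective sites (score >= %g)", x$min_score)
  cat(sprintf("%s: archetype %d, isoform %d (delta %+d)\n",
              kind, x$sites_archetype, x$sites_isoform, x$delta))
  if (x$seed_identical)
    cat("seeds identical: any difference originates in 3'-supplementary pairing\n")
  invisible(x)
}

#' Pearson correlation between miRNA and gene expression
#'
#' @param mirna_expr,gene_expr per-sample expression values over the same
#'   samples, n >= 3.
#' @return A list with `r`, `p_value`, `n`.
#' @export
expression_correlation <- function(mirna_expr, gene_expr) {
  if (length(mirna_expr) != length(gene_expr))
    stop("expression vectors differ in length")
  if (length(mirna_expr) < 3) stop("need n >= 3 samples")
  if (stats::var(mirna_expr) == 0 || stats::var(gene_expr) == 0)
    stop("zero variance in one of the expression vectors")
  ct <- stats::cor.test(mirna_expr, gene_expr, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(mirna_expr))
}
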