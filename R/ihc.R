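#' Positive-cell proportion category
#'
#' Bins the percentage of positively stained tumor cells into the ordinal
#' scale 0 (0%), 1 (1-25%), 2 (26-50%), 3 (51-75%), 4 (76-100%). Fractional
#' percentages are rounded half-up to integer percent before binning, since
#' the bins are integer-valued.
#'
#' @param percent percentage(s) of positive cells in \[0, 100\].
#' @return Integer category 0-4.
#' @export
proportion_category <- function(percent) {
  if (any(is.na(percent)) || any(percent < 0) || any(percent > 100))
    stop("'percent' must be within [0, 100]")
  p <- floor(percent + 0.5)  # round half-up
  as.integer(findInterval(p, c(0, 1, 26, 51, 76)) - 1L)
}

#' Immunoreactivity score (IRS)
#'
#' Product of the staining-intensity ordinal (0 negative, 1 weak,
#' 2 moderate, 3 strong) and the positive-proportion category (0-4), giving
#' a score in 0-12.
#'
#' @param intensity intensity ordinal(s) in 0-3.
#' @param proportion_cat proportion categor(ies) in 0-4, from
#'   [proportion_category()].
#' @return Integer IRS in 0-12.
#' @export
irs_score <- function(intensity, proportion_cat) {
  if (any(!intensity %in% 0:3)) stop("'intensity' must be in 0..3")
  if (any(!proportion_cat %in% 0:4)) stop("'proportion_cat' must be in 0..4")
  as.integer(intensity) * as.integer(proportion_cat)
}

#' H-score
#'
#' Weighted sum of the percentages of cells at each positive intensity:
#' `1*p1 + 2*p2 + 3*p3`, range 0-300. The remaining cells (up to 100%) are
#' negative.
#'
#' @param p1,p2,p3 percent of cells staining at intensity 1, 2 and 3.
#' @return H-score(s) in \[0, 300\].
#' @export
h_score <- function(p1, p2, p3) {
  if (any(c(p1, p2, p3) < 0)) stop("per-intensity percentages must be >= 0")
  if (any(p1 + p2 + p3 > 100 + 1e-8))
    stop("per-intensity percentages exceed 100% in total")
  1 * p1 + 2 * p2 + 3 * p3
}

#' Compare IHC scores between tissue groups
#'
#' One-way ANOVA across three or more groups (e.g. normal vs favorable vs
#' unfavorable histology); with exactly two groups a two-sample t-test is
#' used instead (Welch by default).
#'
#' @param scores per-sample scores (IRS or H-score).
#' @param labels group label per sample.
#' @param var_equal for the two-group case, use the pooled-variance test.
#' @return A list with `method`, `statistic`, `p_value` and `group_means`.
#' @export
ihc_group_compare <- function(scores, labels, var_equal = FALSE) {
  labels <- as.factor(labels)
  k <- nlevels(droplevels(labels))
  if (k < 2) stop("need at least two groups")
  sizes <- table(droplevels(labels))
  if (any(sizes < 2)) stop("each group needs n >= 2")
  gm <- tapply(scores, labels, mean)
  if (k == 2) {
    lv <- levels(droplevels(labels))
    tt <- stats::t.test(scores[labels == lv[1]], scores[labels == lv[2]],
                        var.equal = var_equal)
    list(method = "t-test", statistic = unname(tt$statistic),
         p_value = tt$p.value, group_means = gm)
  } else {
    fit <- stats::aov(scores ~ labels)
    s <- summary(fit)[[1]]
    list(method = "one-way ANOVA", statistic = s[1, "F value"],
         p_value = s[1, "Pr(>F)"], group_means = gm)
  }
}

#' Merge two raters' IHC observations with an agreement report
#'
#' Observations scored independently by two raters are merged case by case;
#' ordinals are never averaged. Concordant cases take the shared score;
#' discordant cases are flagged and resolved by the chosen rule:
#' `"consensus"` (the default) leaves the score `NA` so the case must be
#' re-read, `"max"`/`"min"` take the higher/lower score.
#'
#' @param obs data.frame with columns `sample_id`, `rater`, `intensity`,
#'   `percent_positive`; exactly two raters, each scoring every sample once.
#' @param rule discordance resolution rule.
#' @return A list with `merged` (data.frame: `sample_id`, `intensity`,
#'   `proportion_cat`, `irs`, `discordant`) and `agreement` (exact-match
#'   rate over intensity and proportion category).
#' @export
merge_rater_scores <- function(obs, rule = c("consensus", "max", "min")) {
  rule <- match.arg(rule)
  stopifnot(is.data.frame(obs),
            all(c("sample_id", "rater", "intensity", "percent_positive") %in% names(obs)))
  raters <- sort(unique(obs$rater))
  if (length(raters) != 2) stop("need exactly two raters, got ", length(raters))
  a <- obs[obs$rater == raters[1], ]
  b <- obs[obs$rater == raters[2], ]
  ids <- sort(unique(obs$sample_id))
  if (!setequal(a$sample_id, ids) || !setequal(b$sample_id, ids))
    stop("each rater must score every sample exactly once")
  a <- a[match(ids, a$sample_id), ]
  b <- b[match(ids, b$sample_id), ]
  pa <- proportion_category(a$percent_positive)
  pb <- proportion_category(b$percent_positive)
  agree <- a$intensity == b$intensity & pa == pb
  pick <- function(xa, xb) switch(rule,
    consensus = ifelse(agree, xa, NA_integer_),
    max = pmax(xa, xb),
    min = pmin(xa, xb))
  intensity <- pick(a$intensity, b$intensity)
  prop <- pick(pa, pb)
  merged <- data.frame(
    sample_id = ids,
    intensity = intensity,
    proportion_cat = prop,
    irs = ifelse(is.na(intensity) | is.na(prop), NA_integer_,
                 as.integer(intensity) * as.integer(prop)),
    discordant = !agree,
    stringsAsFactors = FALSE
  )
  list(merged = merged, agreement = mean(agree))
}
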