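#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survival function, computed with
#' [survival::survfit()]. The curve starts at S(0) = 1, is non-increasing and
#' right-continuous, and is constant between event times.
#'
#' @param time positive times to event or censoring.
#' @param event 1 = event, 0 = censored.
#' @return An object of class `km_curve`: a data.frame with columns `time`,
#'   `n_risk`, `n_event`, `n_censor`, `survival`, plus the underlying
#'   `survfit` object as an attribute.
#' @export
km_curve <- function(time, event) {
  if (length(time) < 1) stop("need at least one record")
  if (any(time <= 0)) stop("survival times must be positive")
  if (!all(event %in% c(0, 1))) stop("'event' must be 0/1")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    survival = fit$surv)
  attr(out, "survfit") <- fit
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' @param km a [km_curve()].
#' @param t times to evaluate at.
#' @return Survival probabilities S(t) (right-continuous step function,
#'   S(t) = 1 before the first event).
#' @export
km_survival_at <- function(km, t) {
  ev <- km[km$n_event > 0, ]
  vapply(t, function(ti) {
    s <- ev$survival[ev$time <= ti]
    if (length(s)) s[length(s)] else 1
  }, numeric(1))
}

#' @export
plot.km_curve <- function(x, ...) {
  plot(attr(x, "survfit"), xlab = "time", ylab = "survival probability", ...)
  invisible(x)
}

#' Log-rank test between survival curves
#'
#' Standard log-rank chi-square with k - 1 degrees of freedom across k
#' groups, via [survival::survdiff()].
#'
#' @param time,event as in [km_curve()].
#' @param group group label per record, >= 2 distinct values.
#' @return A list with `statistic`, `df`, `p_value`.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2)
    stop("log-rank needs at least two groups")
  if (any(time <= 0)) stop("survival times must be positive")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(sd$n) - 1
  list(statistic = unname(sd$chisq), df = df,
       p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards regression
#'
#' Partial-likelihood estimation via [survival::coxph()] with Efron handling
#' of tied event times. With a single term this is a univariate model; with
#' several it adjusts each hazard ratio for the others (e.g. a diversity
#' group adjusted for tumor histology).
#'
#' @param clinical data.frame with columns `time`, `event` and the covariates
#'   named in `terms`.
#' @param terms character vector of covariate column names.
#' @param horizon optional administrative-censoring horizon (same units as
#'   `time`): records beyond it are censored at the horizon, e.g. 5 * 365
#'   for 5-year event-free survival.
#' @return A data.frame with one row per coefficient: `term`,
#'   `hazard_ratio`, `ci_low`, `ci_high` (95%), `p_value`. The fitted
#'   `coxph` object is attached as attribute `"fit"`.
#' @export
cox_fit <- function(clinical, terms, horizon = NULL) {
  stopifnot(is.data.frame(clinical), all(c("time", "event") %in% names(clinical)))
  missing_terms <- setdiff(terms, names(clinical))
  if (length(missing_terms))
    stop("covariate(s) not in the clinical table: ", paste(missing_terms, collapse = ", "))
  dat <- clinical[, c("time", "event", terms)]
  if (anyNA(dat))
    stop("missing values in time/event/selected covariates")
  if (!is.null(horizon)) {
    over <- dat$time > horizon
    dat$event[over] <- 0
    dat$time[over] <- horizon
  }
  for (tm in terms) {
    v <- dat[[tm]]
    if (length(unique(v)) < 2)
      stop(sprintf("covariate %s is constant", dQuote(tm)))
  }
  f <- stats::as.formula(paste("survival::Surv(time, event) ~",
                               paste(terms, collapse = " + ")))
  fit <- tryCatch(
    survival::coxph(f, data = dat, ties = "efron"),
    warning = function(w) {
      if (grepl("converge|infinite|beta may be", conditionMessage(w)))
        stop("Cox model failed to converge (possible separation) for terms: ",
             paste(terms, collapse = ", "))
      suppressWarnings(survival::coxph(f, data = dat, ties = "efron"))
    }
  )
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("inestimable (collinear?) covariate(s): ", paste(bad, collapse = ", "))
  }
  s <- summary(fit)
  out <- data.frame(
    term = rownames(s$coefficients),
    hazard_ratio = unname(s$coefficients[, "exp(coef)"]),
    ci_low = unname(s$conf.int[, "lower .95"]),
    ci_high = unname(s$conf.int[, "upper .95"]),
    p_value = unname(s$coefficients[, "Pr(>|z|)"]),
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "fit") <- fit
  out
}

#' Median split of a continuous marker into high/low groups
#'
#' Samples strictly above the median are `"high"`, the rest `"low"` — the
#' same tie rule as [diversity_grouping()], so diversity-based and
#' expression-based stratifications are comparable.
#'
#' @param values per-sample marker values (named vector).
#' @return Character labels `"high"`/`"low"`, named like `values`.
#' @export
median_split <- function(values) {
  if (length(values) < 2) stop("need at least 2 samples")
  med <- stats::median(values)
  labels <- ifelse(values > med, "high", "low")
  if (length(unique(labels)) == 1L)
    warning("degenerate split: all samples fall in one group")
  names(labels) <- names(values)
  labels
}
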