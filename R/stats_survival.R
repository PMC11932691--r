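#' Pearson correlation with t-distribution test
#'
#' Product-moment correlation with significance from the exact null
#' t distribution: `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2`
#' degrees of freedom, two-sided. Incomplete pairs (NA in either
#' variable) are dropped (pairwise-complete).
#'
#' @param x,y paired numeric vectors.
#' @return List: `r`, `t`, `p` (two-sided), `n` (complete pairs).
#' @examples
#' d <- generate_correlated_pair(36, 0.57, seed = 7)
#' pearson(d$x, d$y)
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y", call. = FALSE)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  if (abs(r) >= 1) {
    t <- sign(r) * Inf
    p <- 0
  } else {
    t <- r * sqrt(n - 2) / sqrt(1 - r^2)
    p <- 2 * stats::pt(-abs(t), df = n - 2)
  }
  list(r = r, t = t, p = p, n = n)
}

#' Two-sample t-test
#'
#' Unpaired two-tailed Student's t-test (pooled variance), or the
#' Welch unequal-variance form.
#'
#' @param group_a,group_b numeric samples.
#' @param welch use the Welch correction (default FALSE: Student).
#' @return List: `t`, `df`, `p` (two-sided), `difference`
#'   (mean of a minus mean of b).
#' @export
ttest <- function(group_a, group_b, welch = FALSE) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs at least 2 observations", call. = FALSE)
  ht <- stats::t.test(group_a, group_b, var.equal = !welch,
                      alternative = "two.sided")
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, difference = mean(group_a) - mean(group_b))
}

#' One-way ANOVA with Tukey HSD pairwise comparisons
#'
#' @param groups named list of numeric samples (>= 2 groups).
#' @return List: `F`, `p` and `tukey`, a data.frame of pairwise
#'   contrasts (`contrast`, `difference`, `lower`, `upper`,
#'   `p_adjusted`) adjusted by the studentized-range (Tukey) method.
#' @export
anova_tukey <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("g", seq_along(groups))
  d <- data.frame(y = unlist(groups, use.names = FALSE),
                  g = factor(rep(names(groups), lengths(groups))))
  fit <- stats::aov(y ~ g, data = d)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$g
  tukey <- data.frame(contrast = rownames(tk), difference = tk[, "diff"],
                      lower = tk[, "lwr"], upper = tk[, "upr"],
                      p_adjusted = tk[, "p adj"], stringsAsFactors = FALSE)
  rownames(tukey) <- NULL
  list(F = an[["F value"]][1], p = an[["Pr(>F)"]][1], tukey = tukey)
}

#' Mann-Whitney area under the ROC curve
#'
#' `AUC = P(pos > neg) + 0.5 * P(pos = neg)`, computed exactly from
#' midranks of the pooled sample.
#'
#' @param group_pos values of the positive class.
#' @param group_neg values of the negative class.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(group_pos, group_neg) {
  if (!length(group_pos) || !length(group_neg))
    stop("both groups must be non-empty", call. = FALSE)
  n1 <- length(group_pos); n2 <- length(group_neg)
  r <- rank(c(group_pos, group_neg), ties.method = "average")
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Flag outliers by a robust MAD rule
#'
#' Flags observations more than `k` median-absolute-deviations (scaled
#' to the normal, constant 1.4826) from the median. Flagged points are
#' reported, never removed. A zero MAD (e.g. a constant vector) flags
#' nothing.
#'
#' @param x numeric vector.
#' @param k flagging multiple (default 5).
#' @return Integer indices of flagged observations.
#' @export
flag_outliers <- function(x, k = 5) {
  m <- stats::median(x, na.rm = TRUE)
  s <- stats::mad(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) return(integer(0))
  which(abs(x - m) > k * s)
}

#' Kaplan-Meier product-limit estimate
#'
#' @param times follow-up times (> 0).
#' @param events event indicators (1 = event, 0 = censored).
#' @return Data.frame of the stepwise survival function: `time`,
#'   `n_risk`, `n_event`, `survival`; S(0) = 1 is implicit and the
#'   curve is nonincreasing.
#' @export
km_estimate <- function(times, events) {
  if (any(times <= 0)) stop("times must be positive", call. = FALSE)
  stopifnot(all(events %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk,
             n_event = fit$n.event, survival = fit$surv)
}

#' Two-group log-rank test
#'
#' @param times,events follow-up times and event indicators.
#' @param group two-level group labels.
#' @return List: `chisq` (1 df), `p`.
#' @export
logrank <- function(times, events, group) {
  if (length(unique(group)) < 2)
    stop("need at least 2 groups", call. = FALSE)
  fit <- survival::survdiff(survival::Surv(times, events) ~ group)
  df <- length(fit$n) - 1
  list(chisq = fit$chisq, p = stats::pchisq(fit$chisq, df,
                                            lower.tail = FALSE))
}

#' Dichotomize values at an empirical percentile
#'
#' Threshold at the empirical quantile (linear interpolation between
#' order statistics, R type 7); values strictly above the threshold
#' are `"high"`, all others `"low"`.
#'
#' @param values numeric vector.
#' @param q quantile in \[0, 1\] (default 0.75).
#' @return List: `labels` (character vector high/low), `threshold`,
#'   `n_high`, `n_low`.
#' @export
dichotomize_percentile <- function(values, q = 0.75) {
  stopifnot(q >= 0, q <= 1)
  if (length(unique(values)) < 2)
    stop("all values equal: no split possible", call. = FALSE)
  thr <- unname(stats::quantile(values, q, type = 7))
  labels <- ifelse(values > thr, "high", "low")
  list(labels = labels, threshold = thr,
       n_high = sum(labels == "high"), n_low = sum(labels == "low"))
}

#' Cox proportional hazards fit
#'
#' Partial-likelihood fit (Efron ties handling) of follow-up time on
#' the given covariates, in multivariable mode (one joint model) or
#' univariable mode (one model per covariate). Donors without
#' follow-up (NA time or event, e.g. healthy controls) are excluded.
#'
#' @param cohort data.frame with `time`, `event` and covariate
#'   columns.
#' @param covariates covariate column names.
#' @param mode `"multivariable"` (default) or `"univariable"`.
#' @return Data.frame, one row per covariate (and per model in
#'   univariable mode): `covariate`, `beta`, `hr`, `lower`, `upper`
#'   (Wald 95% CI), `se`, `p`, `mode`; attribute `loglik` (final
#'   model log partial likelihood; multivariable mode) and `ties`.
#' @export
cox_fit <- function(cohort, covariates,
                    mode = c("multivariable", "univariable")) {
  mode <- match.arg(mode)
  stopifnot(all(c("time", "event") %in% names(cohort)),
            all(covariates %in% names(cohort)))
  d <- cohort[stats::complete.cases(cohort[, c("time", "event", covariates)]), ]
  if (sum(d$event) < 1) stop("no events in the cohort", call. = FALSE)
  const <- covariates[vapply(covariates,
                             function(v) stats::sd(d[[v]]) == 0, logical(1))]
  if (length(const))
    stop("constant covariate(s): ", paste(const, collapse = ", "),
         call. = FALSE)
  fit_one <- function(vars) {
    f <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(vars, collapse = " + ")))
    fit <- survival::coxph(f, data = d, ties = "efron",
                           control = survival::coxph.control(iter.max = 100))
    if (!is.null(fit$info) && grepl("did not converge", fit$info %||% ""))
      stop("Cox fit did not converge", call. = FALSE)
    s <- summary(fit)
    data.frame(covariate = vars,
               beta = unname(stats::coef(fit)),
               hr = unname(exp(stats::coef(fit))),
               lower = unname(s$conf.int[, "lower .95"]),
               upper = unname(s$conf.int[, "upper .95"]),
               se = unname(s$coefficients[, "se(coef)"]),
               p = unname(s$coefficients[, "Pr(>|z|)"]),
               loglik = fit$loglik[2],
               stringsAsFactors = FALSE)
  }
  out <- if (mode == "multivariable") fit_one(covariates)
         else do.call(rbind, lapply(covariates, fit_one))
  out$mode <- mode
  loglik <- out$loglik
  out$loglik <- NULL
  rownames(out) <- NULL
  attr(out, "loglik") <- loglik
  attr(out, "ties") <- "efron"
  out
}

#' Replicated Cox hazard-ratio recovery simulation
#'
#' Simulates repeated survival cohorts from one configuration, fits
#' the Cox model to the CRC donors of each replicate, and returns the
#' per-replicate coefficients. The central hazard-ratio estimate over
#' replicates is summarized by the geometric mean (exp of the mean log
#' hazard ratio), the standard scale-appropriate summary for ratios.
#'
#' @param cfg a [survival_sim_config()].
#' @param covariates covariate names passed to [cox_fit()].
#' @param mode `"multivariable"` or `"univariable"`.
#' @param reps number of replicate cohorts.
#' @param seed integer base seed; replicate r uses `seed + r`.
#' @return Data.frame: `replicate`, `covariate`, `beta`, `hr`;
#'   attribute `hr_geomean`, the named vector of exp(mean beta) per
#'   covariate.
#' @export
simulate_cox_recovery <- function(cfg, covariates = c("activity", "age"),
                                  mode = "multivariable", reps = 500,
                                  seed = 1) {
  rows <- vector("list", reps)
  for (r in seq_len(reps)) {
    coh <- generate_survival_cohort(cfg, seed + r)
    fit <- cox_fit(coh[coh$group == "crc", ], covariates, mode = mode)
    rows[[r]] <- data.frame(replicate = r, covariate = fit$covariate,
                            beta = fit$beta, hr = fit$hr)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  gm <- tapply(out$beta, out$covariate, mean)
  attr(out, "hr_geomean") <- exp(gm[covariates])
  out
}
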