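# Survival evaluation battery: product-limit estimator, two-group log-rank,
# Harrell concordance, restricted mean survival, rank AUC, and the classical
# group-difference / correlation tests used across the figures.

check_surv <- function(time, event) {
  assert_finite(time, "time")
  if (any(time <= 0)) stopf("survival times must be positive")
  event <- assert_binary_event(event)
  if (length(time) != length(event)) stopf("time and event lengths differ")
  list(time = as.numeric(time), event = event)
}

#' Kaplan-Meier product-limit estimate
#'
#' @param time Positive follow-up times (months).
#' @param event 0/1 event indicator (1 = death observed).
#' @return A `km_curve`: distinct event times with numbers at risk, event
#'   counts and the survival probability after each event time. The curve is
#'   taken as constant beyond the last observed time.
#' @export
km_estimate <- function(time, event) {
  s <- check_surv(time, event)
  et <- sort(unique(s$time[s$event == 1L]))
  st <- sort(s$time)
  n_risk <- length(st) - findInterval(et, st, left.open = TRUE)
  n_event <- tabulate(match(s$time[s$event == 1L], et), length(et))
  structure(list(time = et, n_risk = n_risk, n_event = n_event,
                 survival = cumprod(1 - n_event / n_risk),
                 n = length(st), max_time = if (length(st)) max(st) else 0),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve: n=%d, %d event times, S(last)=%.3f>\n",
              x$n, length(x$time), if (length(x$survival)) min(x$survival) else 1))
  invisible(x)
}

#' Evaluate a Kaplan-Meier curve at given times
#' @param km A `km_curve`.
#' @param t Numeric times.
#' @return Survival probabilities S(t).
#' @export
km_survival_at <- function(km, t) {
  stopifnot(inherits(km, "km_curve"))
  idx <- findInterval(t, km$time)
  c(1, km$survival)[idx + 1L]
}

# Fast scalar S(t) without building the curve object (used by the
# time-dependent ROC sweep).
km_at <- function(time, event, t) {
  keep <- event == 1L & time <= t
  if (!any(keep)) return(1)
  et <- sort(unique(time[keep]))
  st <- sort(time)
  n_risk <- length(st) - findInterval(et, st, left.open = TRUE)
  d <- tabulate(match(time[keep], et), length(et))
  prod(1 - d / n_risk)
}

#' Two-group log-rank test
#'
#' Standard one-degree-of-freedom log-rank chi-square: at each distinct event
#' time the observed group-A deaths are compared with their hypergeometric
#' expectation given the risk sets, and the standardized squared sum is
#' referred to chi-square(1).
#'
#' @param time_a,event_a Follow-up and 0/1 event indicator, group A.
#' @param time_b,event_b Same for group B.
#' @return List with `statistic`, `p_value`, `observed`, `expected` (group A).
#' @export
logrank_test <- function(time_a, event_a, time_b, event_b) {
  a <- check_surv(time_a, event_a)
  b <- check_surv(time_b, event_b)
  if (!length(a$time) || !length(b$time)) stopf("both groups must be non-empty")
  time <- c(a$time, b$time)
  event <- c(a$event, b$event)
  if (sum(event) == 0L) stopf("log-rank test undefined: no events in either group")
  dt <- sort(unique(time[event == 1L]))
  st <- sort(time)
  sta <- sort(a$time)
  nj <- length(st) - findInterval(dt, st, left.open = TRUE)
  n1j <- length(sta) - findInterval(dt, sta, left.open = TRUE)
  dj <- tabulate(match(time[event == 1L], dt), length(dt))
  d1j <- tabulate(match(a$time[a$event == 1L], dt), length(dt))
  O <- sum(d1j)
  E <- sum(dj * n1j / nj)
  vterm <- ifelse(nj > 1, dj * (n1j / nj) * (1 - n1j / nj) * (nj - dj) / (nj - 1), 0)
  V <- sum(vterm)
  stat <- if (V > 0) (O - E)^2 / V else 0
  list(statistic = stat, p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       observed = O, expected = E)
}

#' Harrell's concordance index
#'
#' Fraction of comparable pairs in which the subject with the higher score
#' fails earlier. A pair is comparable when the shorter follow-up ends in an
#' observed event (tied event times are not comparable; a censored subject
#' tied with an event is). Score ties count 1/2.
#'
#' @param scores Risk scores (higher = worse prognosis).
#' @param time,event Survival data.
#' @return Concordance in \[0, 1\].
#' @export
harrell_cindex <- function(scores, time, event) {
  s <- check_surv(time, event)
  assert_finite(scores, "scores")
  if (length(scores) != length(s$time)) stopf("scores and survival lengths differ")
  conc <- ties <- npairs <- 0
  for (i in which(s$event == 1L)) {
    comp <- s$time > s$time[i] | (s$time == s$time[i] & s$event == 0L)
    if (!any(comp)) next
    npairs <- npairs + sum(comp)
    conc <- conc + sum(scores[i] > scores[comp])
    ties <- ties + sum(scores[i] == scores[comp])
  }
  if (npairs == 0) stopf("concordance undefined: no comparable pairs")
  (conc + 0.5 * ties) / npairs
}

#' Restricted mean survival time
#'
#' Area under the Kaplan-Meier curve from 0 to `tau` (exact step-function
#' integration); the life expectancy over the first `tau` months. When
#' follow-up ends before `tau` the curve is carried forward flat.
#'
#' @param time,event Survival data.
#' @param tau Truncation horizon in months (default 120 = 10 years).
#' @return RMS time in months.
#' @export
rms_time <- function(time, event, tau = 120) {
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0) stopf("tau must be positive")
  km <- km_estimate(time, event)
  et <- km$time[km$time < tau]
  surv <- km$survival[km$time < tau]
  knots <- c(0, et, tau)
  heights <- c(1, surv)
  sum(diff(knots) * heights)
}

#' Ratio of restricted mean survival, low- over high-risk group
#'
#' @param group Vector with values `"high"` / `"low"` per sample.
#' @param time,event Survival data.
#' @param tau Truncation horizon in months.
#' @return `rms_time(low) / rms_time(high)`; above 1 when the low-risk group
#'   lives longer over the horizon.
#' @export
rms_ratio_by_group <- function(group, time, event, tau = 120) {
  group <- as.character(group)
  if (!all(group %in% c("high", "low"))) stopf("group must be 'high'/'low'")
  if (!any(group == "high") || !any(group == "low"))
    stopf("both risk groups must be non-empty")
  lo <- group == "low"
  rms_time(time[lo], event[lo], tau) / rms_time(time[!lo], event[!lo], tau)
}

#' Binary ROC area under the curve
#'
#' Rank-based AUC, identical to the Mann-Whitney U statistic divided by
#' `n1 * n0`; ties contribute 1/2. Invariant to any strictly increasing
#' transform of the scores.
#'
#' @param scores Numeric scores (higher = more likely positive).
#' @param labels Logical or 0/1 class labels.
#' @return AUC in \[0, 1\].
#' @export
binary_roc_auc <- function(scores, labels) {
  assert_finite(scores, "scores")
  labels <- as.logical(labels)
  if (anyNA(labels)) stopf("labels must be binary without NA")
  if (length(scores) != length(labels)) stopf("scores and labels lengths differ")
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stopf("both label classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classical group-difference and correlation tests
#'
#' Thin dispatcher over the standard tests used throughout the analysis:
#' Wilcoxon rank-sum (2 groups), Kruskal-Wallis (>= 2 groups), Fisher's exact
#' test on a contingency table, and Spearman correlation.
#'
#' @param x For `wilcoxon`/`kruskal`: numeric values. For `fisher`: a factor
#'   or a contingency matrix. For `spearman`: numeric vector.
#' @param g For `wilcoxon`/`kruskal`: group labels. For `fisher`: second
#'   factor (ignored when `x` is already a table). For `spearman`: paired
#'   numeric vector.
#' @param test One of `"wilcoxon"`, `"kruskal"`, `"fisher"`, `"spearman"`.
#' @return List with `statistic` (Fisher: the 2x2 odds-ratio estimate or NA),
#'   `p_value` and `method`.
#' @export
group_stats <- function(x, g = NULL, test = c("wilcoxon", "kruskal", "fisher", "spearman")) {
  test <- match.arg(test)
  res <- switch(test,
    wilcoxon = {
      g <- factor(g)
      if (nlevels(g) != 2L) stopf("wilcoxon needs exactly two groups")
      ht <- stats::wilcox.test(x[g == levels(g)[1L]], x[g == levels(g)[2L]], exact = FALSE)
      list(statistic = unname(ht$statistic), p_value = ht$p.value)
    },
    kruskal = {
      g <- factor(g)
      if (nlevels(g) < 2L) stopf("kruskal needs at least two groups")
      ht <- stats::kruskal.test(x, g)
      list(statistic = unname(ht$statistic), p_value = ht$p.value)
    },
    fisher = {
      tab <- if (is.matrix(x)) x else table(x, g)
      ht <- stats::fisher.test(tab)
      list(statistic = if (!is.null(ht$estimate)) unname(ht$estimate) else NA_real_,
           p_value = ht$p.value)
    },
    spearman = {
      ht <- stats::cor.test(x, g, method = "spearman", exact = FALSE)
      list(statistic = unname(ht$estimate), p_value = ht$p.value)
    })
  c(res, list(method = test))
}

#' Cytolytic activity (CYT) score
#'
#' Mean expression of PRF1 and GZMA per sample.
#'
#' @param expr Gene x sample matrix containing rows `PRF1` and `GZMA`.
#' @return Named numeric vector of per-sample CYT scores.
#' @export
cyt_score <- function(expr) {
  m <- as_expr_matrix(expr)
  need <- c("PRF1", "GZMA")
  miss <- setdiff(need, rownames(m))
  if (length(miss)) stopf("expression matrix lacks gene(s): %s", paste(miss, collapse = ", "))
  colMeans(m[need, , drop = FALSE])
}

#' Paired bootstrap test for a difference of concordance indices
#'
#' Resamples subjects with replacement and recomputes both C-indices on each
#' replicate, giving a two-sided p-value for the observed difference against
#' the bootstrap null of zero difference, plus a percentile interval.
#'
#' @param scores_a,scores_b Two risk scores on the same samples.
#' @param time,event Survival data.
#' @param reps Bootstrap replicates.
#' @param seed Integer seed.
#' @return List with `diff` (C_a - C_b), `ci` (2.5/97.5 percentiles),
#'   `p_value`.
#' @export
cindex_diff_bootstrap <- function(scores_a, scores_b, time, event,
                                  reps = 1000L, seed = 1L) {
  s <- check_surv(time, event)
  n <- length(s$time)
  obs <- harrell_cindex(scores_a, s$time, s$event) -
    harrell_cindex(scores_b, s$time, s$event)
  set.seed(stage_seed(seed, "bootstrap"))
  d <- vapply(seq_len(reps), function(i) {
    idx <- sample.int(n, n, replace = TRUE)
    tryCatch(
      harrell_cindex(scores_a[idx], s$time[idx], s$event[idx]) -
        harrell_cindex(scores_b[idx], s$time[idx], s$event[idx]),
      error = function(e) NA_real_)
  }, numeric(1))
  d <- d[!is.na(d)]
  p <- 2 * min(mean(c(d - obs, 0) >= obs), mean(c(d - obs, 0) <= obs))
  list(diff = obs, ci = stats::quantile(d, c(0.025, 0.975), names = FALSE),
       p_value = min(1, p))
}
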