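# TCRPI construction: random 1:1:1:1 split, log-rank screening of pairs,
# LASSO-penalized Cox selection, multivariate Cox coefficients, the linear
# risk index TCRPI = sum_i Coef_i * TCP_i, a 5-year time-dependent ROC
# cutoff, and the composite clinical index (CTCPI).

#' Randomly partition samples into equal parts
#'
#' Emulates the meta-cohort design: one training part and three testing
#' parts in a 1:1:1:1 ratio. Simple random (unstratified) assignment; part
#' sizes differ by at most one, earlier parts taking the remainder.
#'
#' @param sample_ids Character vector of unique sample ids.
#' @param n_parts Number of parts (default 4).
#' @param seed Integer seed.
#' @return Named list `part1`..`partk` of disjoint, exhaustive id vectors.
#' @export
split_cohort <- function(sample_ids, n_parts = 4L, seed = 1L) {
  if (anyDuplicated(sample_ids)) stopf("sample ids must be unique")
  n <- length(sample_ids)
  if (n < n_parts) stopf("need at least %d samples to make %d parts", n_parts, n_parts)
  set.seed(stage_seed(seed, "split"))
  perm <- sample(sample_ids)
  sizes <- rep(n %/% n_parts, n_parts) + (seq_len(n_parts) <= n %% n_parts)
  parts <- split(perm, rep(seq_len(n_parts), times = sizes))
  stats::setNames(parts, paste0("part", seq_len(n_parts)))
}

#' Screen pairs for prognostic value by the log-rank test
#'
#' Each pair splits the training samples into its 0- and 1-scoring groups;
#' pairs whose two-group log-rank p-value falls below `alpha` are retained.
#' Pairs constant on the training subset are skipped with a warning.
#'
#' @param pm Binary pair x sample matrix (training samples).
#' @param time,event Survival data aligned with `colnames(pm)`.
#' @param alpha Retention level (default 0.05).
#' @return Data frame of retained pairs (`pair`, `p_value`); the full screen
#'   is attached as attribute `"screen"`.
#' @export
select_prognostic_pairs <- function(pm, time, event, alpha = 0.05) {
  s <- check_surv(time, event)
  if (ncol(pm) != length(s$time)) stopf("pm columns and survival length differ")
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1) stopf("alpha must be in [0, 1]")
  pv <- rep(NA_real_, nrow(pm))
  for (i in seq_len(nrow(pm))) {
    g1 <- pm[i, ] == 1L
    if (!any(g1) || all(g1)) next
    pv[i] <- logrank_test(s$time[g1], s$event[g1], s$time[!g1], s$event[!g1])$p_value
  }
  skipped <- sum(is.na(pv))
  if (skipped > 0L)
    warnf("%d pair(s) constant on the training subset; skipped", skipped)
  screen <- data.frame(pair = rownames(pm), p_value = pv, stringsAsFactors = FALSE)
  out <- screen[!is.na(pv) & pv < alpha, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "screen") <- screen
  out
}

#' LASSO-penalized Cox selection of pairs
#'
#' Maximizes the Cox partial log-likelihood with an L1 penalty; the penalty
#' weight is chosen by k-fold cross-validated partial-likelihood deviance
#' (`"min"` rule by default, `"1se"` available). Fold assignment is seeded,
#' so the fit is deterministic.
#'
#' @param x Sample x feature matrix (binary pair scores; rownames sample ids).
#' @param time,event Survival data aligned with `rownames(x)`.
#' @param nfolds Cross-validation folds (default 10).
#' @param seed Integer seed for fold assignment.
#' @param lambda_rule `"min"` (deviance minimizer) or `"1se"`.
#' @param lambda Optional fixed penalty; bypasses cross-validation (0 gives
#'   the unpenalized Cox fit).
#' @return List of class `lasso_cox` with `coefficients` (full named vector),
#'   `support` (names of nonzero coefficients), `lambda`, `lambda_rule`,
#'   `nfolds`, `seed`.
#' @export
fit_lasso_cox <- function(x, time, event, nfolds = 10L, seed = 1L,
                          lambda_rule = c("min", "1se"), lambda = NULL) {
  lambda_rule <- match.arg(lambda_rule)
  s <- check_surv(time, event)
  if (!is.matrix(x)) stopf("x must be a matrix")
  if (nrow(x) != length(s$time)) stopf("x rows and survival length differ")
  if (sum(s$event) == 0L) stopf("cannot fit a Cox model with no events")
  if (sum(s$event) < nfolds && is.null(lambda))
    stopf("fewer events (%d) than folds (%d)", sum(s$event), nfolds)
  if (ncol(x) < 2L) stopf("LASSO selection needs at least two candidate features")
  y <- survival::Surv(s$time, s$event)
  if (!is.null(lambda)) {
    fit <- glmnet::glmnet(x, y, family = "cox", thresh = 1e-14, maxit = 1e6)
    cf <- as.vector(stats::coef(fit, s = lambda, exact = TRUE, x = x, y = y,
                                thresh = 1e-14, maxit = 1e6))
    lam <- lambda
  } else {
    set.seed(stage_seed(seed, "lasso"))
    foldid <- sample(rep_len(seq_len(nfolds), nrow(x)))
    cv <- glmnet::cv.glmnet(x, y, family = "cox", foldid = foldid)
    lam <- if (lambda_rule == "min") cv$lambda.min else cv$lambda.1se
    cf <- as.vector(stats::coef(cv, s = lam))
  }
  names(cf) <- colnames(x)
  support <- names(cf)[cf != 0]
  if (!length(support)) warnf("LASSO retained no features at the chosen penalty")
  structure(list(coefficients = cf, support = support, lambda = lam,
                 lambda_rule = if (is.null(lambda)) lambda_rule else "fixed",
                 nfolds = nfolds, seed = seed),
            class = "lasso_cox")
}

# coxph on a feature matrix with arbitrary (non-syntactic) column names.
coxph_matrix <- function(x, time, event) {
  safe <- paste0("f", seq_len(ncol(x)))
  dd <- as.data.frame(x)
  names(dd) <- safe
  dd$.time <- time
  dd$.event <- event
  fit <- survival::coxph(survival::Surv(.time, .event) ~ ., data = dd)
  if (anyNA(stats::coef(fit)))
    stopf("multivariate Cox fit did not converge (NA coefficient); features: %s",
          paste(colnames(x)[is.na(stats::coef(fit))], collapse = ", "))
  sm <- summary(fit)
  list(fit = fit,
       coefficients = stats::setNames(as.vector(stats::coef(fit)), colnames(x)),
       p_values = stats::setNames(sm$coefficients[, "Pr(>|z|)"], colnames(x)))
}

#' Final multivariate Cox coefficients for the selected pairs
#'
#' Fits an unpenalized multivariate Cox model on the LASSO support and keeps
#' the features that remain individually significant (Wald p below
#' `p_threshold`), refitting on the kept set; these coefficients define the
#' TCRPI. Set `retain = "all"` to keep the whole support.
#'
#' @param x Sample x feature matrix restricted to the LASSO support.
#' @param time,event Survival data.
#' @param retain `"wald"` (default) or `"all"`.
#' @param p_threshold Wald retention level (default 0.05).
#' @return List of class `cox_refit` with `coefficients`, `p_values`
#'   (initial fit), `dropped`.
#' @export
fit_final_cox <- function(x, time, event, retain = c("wald", "all"),
                          p_threshold = 0.05) {
  retain <- match.arg(retain)
  s <- check_surv(time, event)
  if (!is.matrix(x) || ncol(x) == 0L) stopf("x must be a matrix with features")
  if (nrow(x) != length(s$time)) stopf("x rows and survival length differ")
  full <- coxph_matrix(x, s$time, s$event)
  if (retain == "all") {
    return(structure(list(coefficients = full$coefficients,
                          p_values = full$p_values, dropped = character(0)),
                     class = "cox_refit"))
  }
  keep <- names(full$p_values)[full$p_values < p_threshold]
  dropped <- setdiff(colnames(x), keep)
  if (!length(keep)) {
    warnf("no feature met Wald p < %g; returning an empty model", p_threshold)
    return(structure(list(coefficients = stats::setNames(numeric(0), character(0)),
                          p_values = full$p_values, dropped = dropped),
                     class = "cox_refit"))
  }
  refit <- if (length(dropped)) coxph_matrix(x[, keep, drop = FALSE], s$time, s$event)
           else full
  structure(list(coefficients = refit$coefficients, p_values = full$p_values,
                 dropped = dropped),
            class = "cox_refit")
}

#' Construct a pair index model
#'
#' Bundle of the fitted TCRPI: selected pairs with their multivariate Cox
#' coefficients, the risk cutoff, and the ROC horizon it was derived at.
#'
#' @param coefficients Named numeric vector (names are pair ids `"A|B"`).
#' @param cutoff Risk-group cutoff on the TCRPI scale.
#' @param roc_time ROC horizon in months (default 60 = 5 years).
#' @param training_meta Free-form list (seed, lambda rule, n_train, ...).
#' @return Object of class `pair_index_model`.
#' @export
pair_index_model <- function(coefficients, cutoff, roc_time = 60,
                             training_meta = list()) {
  if (is.null(names(coefficients)) || anyDuplicated(names(coefficients)))
    stopf("coefficients must be uniquely named by pair id")
  assert_finite(cutoff, "cutoff")
  structure(list(coefficients = coefficients, cutoff = cutoff,
                 roc_time = roc_time, training_meta = training_meta),
            class = "pair_index_model")
}

#' @export
print.pair_index_model <- function(x, ...) {
  cat(sprintf("<pair_index_model: %d pairs, cutoff %.4f at %g months>\n",
              length(x$coefficients), x$cutoff, x$roc_time))
  invisible(x)
}

#' Compute the TCRPI risk score
#'
#' `TCRPI(s) = sum_i Coef_i * TCP_i(s)` over the model's selected pairs.
#'
#' @param pm Binary pair x sample matrix containing all model pairs.
#' @param model A `pair_index_model`, or a named coefficient vector.
#' @return Named numeric vector of per-sample scores.
#' @export
compute_tcrpi <- function(pm, model) {
  cf <- if (inherits(model, "pair_index_model")) model$coefficients else model
  if (is.null(names(cf))) stopf("coefficients must be named by pair id")
  miss <- setdiff(names(cf), rownames(pm))
  if (length(miss)) stopf("pair matrix lacks model pair(s): %s", paste(miss, collapse = ", "))
  if (!length(cf)) return(stats::setNames(rep(0, ncol(pm)), colnames(pm)))
  drop(crossprod(pm[names(cf), , drop = FALSE], cf))
}

#' Time-dependent ROC curve at a fixed horizon
#'
#' Cumulative-case / dynamic-control ROC of Heagerty, Lumley and Pepe with
#' Kaplan-Meier-estimated conditional survival: cases are subjects with
#' `T <= t_star`, controls those with `T > t_star`, and for each threshold c
#' \deqn{sens(c) = (1 - S(t* | X > c)) P(X > c) / (1 - S(t*)),}
#' \deqn{spec(c) = S(t* | X <= c) P(X <= c) / S(t*),}
#' with the subgroup survival curves estimated by KM. Thresholds sweep the
#' observed score values; the AUC is the trapezoidal area with (0,0)/(1,1)
#' anchors. With no censoring before `t_star` this reduces exactly to the
#' plain binary ROC for the label `T <= t_star`.
#'
#' @param scores Risk scores.
#' @param time,event Survival data.
#' @param t_star Horizon in months (default 60 = 5 years).
#' @return List of class `td_roc`: `curve` (threshold, sensitivity,
#'   specificity), `auc`, `t_star`.
#' @export
time_dependent_roc <- function(scores, time, event, t_star = 60) {
  s <- check_surv(time, event)
  assert_finite(scores, "scores")
  if (length(scores) != length(s$time)) stopf("scores and survival lengths differ")
  S_all <- km_at(s$time, s$event, t_star)
  if (S_all >= 1) stopf("no events observed before t_star = %g", t_star)
  if (S_all <= 0 || !any(s$time > t_star))
    stopf("no subjects at risk beyond t_star = %g", t_star)
  th <- sort(unique(scores))
  sens <- spec <- numeric(length(th))
  for (i in seq_along(th)) {
    hi <- scores > th[i]
    sens[i] <- if (!any(hi)) 0 else
      (1 - km_at(s$time[hi], s$event[hi], t_star)) * mean(hi) / (1 - S_all)
    spec[i] <- if (all(hi)) 0 else
      km_at(s$time[!hi], s$event[!hi], t_star) * mean(!hi) / S_all
  }
  # KM reweighting can step slightly outside [0,1] in small samples
  sens <- pmin(pmax(sens, 0), 1)
  spec <- pmin(pmax(spec, 0), 1)
  curve <- data.frame(threshold = th, sensitivity = sens, specificity = spec)
  # integrate in sweep order (decreasing threshold traces (0,0) -> (1,1))
  ord <- order(th, decreasing = TRUE)
  xs <- c(0, (1 - spec)[ord], 1)
  ys <- c(0, sens[ord], 1)
  auc <- sum(diff(xs) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2)
  structure(list(curve = curve, auc = auc, t_star = t_star), class = "td_roc")
}

#' @export
print.td_roc <- function(x, ...) {
  cat(sprintf("<td_roc: AUC %.3f at %g months, %d thresholds>\n",
              x$auc, x$t_star, nrow(x$curve)))
  invisible(x)
}

#' Choose the risk cutoff closest to the ideal ROC corner
#'
#' Returns the threshold minimizing the Euclidean distance
#' `sqrt((1 - sens)^2 + (1 - spec)^2)` to the perfect-classification corner
#' (0, 1) in (1 - specificity, sensitivity) space; ties break toward the
#' smaller threshold.
#'
#' @param roc A `td_roc` or any data frame with columns `threshold`,
#'   `sensitivity`, `specificity`.
#' @return The cutoff value.
#' @export
select_cutoff <- function(roc) {
  curve <- if (inherits(roc, "td_roc")) roc$curve else roc
  if (!all(c("threshold", "sensitivity", "specificity") %in% names(curve)))
    stopf("roc must provide threshold, sensitivity and specificity")
  if (!nrow(curve)) stopf("empty ROC curve")
  d2 <- (1 - curve$sensitivity)^2 + (1 - curve$specificity)^2
  min(curve$threshold[d2 == min(d2)])
}

#' Assign high/low risk groups
#'
#' High risk iff the score strictly exceeds the cutoff (a score exactly at
#' the cutoff goes to the low-risk group, mirroring the strict inequality of
#' the pair score).
#'
#' @param scores Named numeric TCRPI scores.
#' @param cutoff Risk cutoff.
#' @return Data frame `sample_id`, `tcrpi`, `group` (factor low/high).
#' @export
assign_risk <- function(scores, cutoff) {
  assert_finite(scores, "scores")
  assert_finite(cutoff, "cutoff")
  data.frame(sample_id = names(scores) %||% seq_along(scores),
             tcrpi = as.numeric(scores),
             group = factor(ifelse(scores > cutoff, "high", "low"),
                            levels = c("low", "high")),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Default encodings for the composite clinical index
#'
#' Age is dichotomized at the cut (default above 65 years), stage collapsed
#' to early (I-II) vs advanced (III-IV), grade to low vs high, gender to
#' female = 0 / male = 1, and the TCRPI enters either as the high-risk-group
#'
#' indicator or — the default — as the continuous score, which preserves the
#' index's resolution inside the composite.
#'
#' @param age One of `"gt_cut"`, `"continuous"`.
#' @param age_cut Age cut in years.
#' @param tcrpi One of `"continuous"`, `"group"`.
#' @return Encoding specification list.
#' @export
ctcpi_encodings <- function(age = c("gt_cut", "continuous"), age_cut = 65,
                            tcrpi = c("continuous", "group")) {
  list(age = match.arg(age), age_cut = age_cut, tcrpi = match.arg(tcrpi))
}

encode_ctcpi_features <- function(clinical, risk, encodings) {
  need <- c("sample_id", "age_years", "gender", "stage", "grade")
  miss <- setdiff(need, names(clinical))
  if (length(miss)) stopf("clinical table missing column(s): %s", paste(miss, collapse = ", "))
  idx <- match(clinical$sample_id, risk$sample_id)
  if (anyNA(idx)) stopf("risk scores missing for %d clinical sample(s)", sum(is.na(idx)))
  age <- if (encodings$age == "continuous") clinical$age_years
         else as.numeric(clinical$age_years > encodings$age_cut)
  tc <- if (encodings$tcrpi == "continuous") risk$tcrpi[idx]
        else as.numeric(risk$group[idx] == "high")
  cbind(age = age,
        gender = as.numeric(clinical$gender == "male"),
        stage = as.numeric(clinical$stage %in% c("III", "IV")),
        grade = as.numeric(clinical$grade == "high"),
        tcrpi = tc)
}

#' Fit the composite TCRPI and clinical prognostic index (CTCPI)
#'
#' Multivariable Cox regression of survival on the encoded TCRPI, age,
#' gender, stage and grade; features with Wald p below `p_threshold` are
#' retained and refit, and the composite score is their coefficient-weighted
#' sum (the published form `Age * c1 + Stage * c2 + TCRPI * c3` arises when
#' exactly those three survive). Samples with missing candidate features are
#' excluded from the fit. When nothing is retained, a TCRPI-only model is
#' returned with a warning.
#'
#' @param risk Data frame from [assign_risk()] (`sample_id`, `tcrpi`, `group`).
#' @param clinical Clinical table with `sample_id`, `os_months`, `os_event`,
#'   `age_years`, `gender`, `stage`, `grade`.
#' @param encodings From [ctcpi_encodings()].
#' @param p_threshold Wald retention level.
#' @return List of class `ctcpi_model`: `terms` (named coefficients),
#'   `p_values` (initial fit), `encodings`, `n`.
#' @export
fit_ctcpi <- function(risk, clinical, encodings = ctcpi_encodings(),
                      p_threshold = 0.05) {
  X <- encode_ctcpi_features(clinical, risk, encodings)
  ok <- stats::complete.cases(X) & !is.na(clinical$os_months) & !is.na(clinical$os_event)
  if (sum(ok) < nrow(clinical))
    warnf("%d sample(s) with missing features excluded from CTCPI fitting",
          nrow(clinical) - sum(ok))
  X <- X[ok, , drop = FALSE]
  time <- clinical$os_months[ok]
  event <- clinical$os_event[ok]
  # drop degenerate (constant) candidates before fitting
  varying <- apply(X, 2L, function(v) length(unique(v)) > 1L)
  fit <- fit_final_cox(X[, varying, drop = FALSE], time, event,
                       retain = "wald", p_threshold = p_threshold)
  terms <- fit$coefficients
  if (!length(terms)) {
    warnf("no feature met the retention rule; falling back to a TCRPI-only model")
    uni <- coxph_matrix(X[, "tcrpi", drop = FALSE], time, event)
    terms <- uni$coefficients
  }
  structure(list(terms = terms, p_values = fit$p_values,
                 encodings = encodings, n = sum(ok)),
            class = "ctcpi_model")
}

#' @export
print.ctcpi_model <- function(x, ...) {
  cat(sprintf("<ctcpi_model: %s (n=%d)>\n",
              paste(sprintf("%s*%.3f", names(x$terms), x$terms), collapse = " + "),
              x$n))
  invisible(x)
}

#' Compute the composite clinical index for samples
#'
#' @param model A `ctcpi_model`.
#' @param risk Data frame from [assign_risk()].
#' @param clinical Clinical table (same columns as in [fit_ctcpi()]).
#' @return Named numeric composite scores (NA where a needed feature is
#'   missing).
#' @export
compute_ctcpi <- function(model, risk, clinical) {
  X <- encode_ctcpi_features(clinical, risk, model$encodings)
  sc <- drop(X[, names(model$terms), drop = FALSE] %*% model$terms)
  stats::setNames(sc, clinical$sample_id)
}
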