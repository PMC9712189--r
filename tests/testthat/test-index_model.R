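test_that("cohort split is a deterministic balanced partition", {
  ids <- sprintf("s%04d", 1:3134)
  parts <- split_cohort(ids, 4L, seed = 5L)
  expect_equal(sort(unname(lengths(parts)), decreasing = TRUE),
               c(784, 784, 783, 783))
  expect_setequal(unlist(parts), ids)
  expect_equal(anyDuplicated(unlist(parts)), 0L)
  expect_identical(parts, split_cohort(ids, 4L, seed = 5L))
  expect_false(identical(parts, split_cohort(ids, 4L, seed = 6L)))
  expect_error(split_cohort(c("a", "b"), 4L, 1L), "at least 4")
})

test_that("log-rank screening keeps small-p pairs and skips degenerate ones", {
  set.seed(20)
  n <- 120
  time <- rexp(n, 0.05)
  # pair 1 strongly prognostic, pair 2 noise, pair 3 constant
  p1 <- as.integer(time < median(time))
  p1[sample(n, 10)] <- 1L - p1[sample(n, 10)]
  pm <- rbind(a = p1, b = rbinom(n, 1, 0.5), c = rep(1L, n))
  colnames(pm) <- sprintf("s%03d", 1:n)
  expect_warning(sel <- select_prognostic_pairs(pm, time, rep(1L, n), alpha = 0.05),
                 "constant")
  expect_true("a" %in% sel$pair)
  expect_false("c" %in% sel$pair)
  expect_equal(nrow(suppressWarnings(
    select_prognostic_pairs(pm, time, rep(1L, n), alpha = 0))), 0L)
})

test_that("LASSO Cox: extreme penalty zeroes everything; zero penalty matches Newton", {
  set.seed(21)
  n <- 40
  X <- cbind(f1 = rbinom(n, 1, 0.5), f2 = rbinom(n, 1, 0.5), f3 = rbinom(n, 1, 0.5))
  rownames(X) <- sprintf("s%02d", 1:n)
  risk <- 1.2 * X[, 1] - 0.6 * X[, 2]
  time <- rexp(n, 0.05 * exp(risk)) + runif(n, 0, 1e-4)  # break ties
  event <- rep(1L, n)
  expect_warning(big <- fit_lasso_cox(X, time, event, lambda = 1e4),
                 "no features")
  expect_true(all(big$coefficients == 0))
  free <- fit_lasso_cox(X, time, event, lambda = 0)
  ref <- oracle_cox_newton(X, time, event)
  expect_equal(unname(free$coefficients), unname(ref), tolerance = 1e-6)
  cph <- survival::coxph(survival::Surv(time, event) ~ X)
  expect_equal(unname(free$coefficients), unname(coef(cph)), tolerance = 1e-6)
  expect_error(fit_lasso_cox(X, time, rep(0L, n), lambda = 0), "no events")
})

test_that("cross-validated LASSO is deterministic given the seed", {
  set.seed(22)
  n <- 120
  X <- matrix(rbinom(n * 8, 1, 0.5), n, 8,
              dimnames = list(sprintf("s%03d", 1:n), paste0("f", 1:8)))
  time <- rexp(n, 0.05 * exp(X[, 1]))
  event <- rbinom(n, 1, 0.8)
  f1 <- fit_lasso_cox(X, time, event, seed = 3L)
  f2 <- fit_lasso_cox(X, time, event, seed = 3L)
  expect_identical(f1$coefficients, f2$coefficients)
  expect_identical(f1$lambda, f2$lambda)
})

test_that("final Cox matches the univariate score-equation oracle and drops null features", {
  set.seed(23)
  n <- 60
  x <- rbinom(n, 1, 0.5)
  time <- rexp(n, 0.05 * exp(0.9 * x)) + runif(n, 0, 1e-4)
  event <- rep(1L, n)
  X <- cbind(risk_pair = x)
  rownames(X) <- sprintf("s%02d", 1:n)
  fit <- fit_final_cox(X, time, event, retain = "all")
  expect_equal(unname(fit$coefficients),
               oracle_cox_univariate(x, time, event), tolerance = 1e-6)
  # a large-n null feature gets a near-zero coefficient and is dropped
  set.seed(24)
  n <- 600
  Xn <- cbind(signal = rbinom(n, 1, 0.5), noise = rbinom(n, 1, 0.5))
  rownames(Xn) <- sprintf("s%03d", 1:n)
  tt <- rexp(n, 0.05 * exp(Xn[, "signal"]))
  fitn <- fit_final_cox(Xn, tt, rep(1L, n))
  expect_true("noise" %in% fitn$dropped)
  expect_lt(abs(coef(survival::coxph(
    survival::Surv(tt, rep(1, n)) ~ Xn[, "noise"]))), 0.2)
  expect_true("signal" %in% names(fitn$coefficients))
})

test_that("TCRPI is the coefficient-weighted sum of pair scores", {
  pm <- rbind("A|B" = c(1L, 0L), "C|D" = c(1L, 1L), "E|F" = c(0L, 1L))
  colnames(pm) <- c("s1", "s2")
  cf <- c("A|B" = 0.5, "C|D" = -0.25)
  expect_equal(compute_tcrpi(pm, cf), c(s1 = 0.25, s2 = -0.25))
  expect_equal(unname(compute_tcrpi(pm, c("A|B" = 0, "C|D" = 0))), c(0, 0))
  expect_error(compute_tcrpi(pm, c("X|Y" = 1)), "X\\|Y")
})

test_that("time-dependent ROC reduces to the binary ROC without censoring", {
  set.seed(25)
  n <- 60
  sc <- rnorm(n)
  time <- rexp(n, 0.04 * exp(sc))
  event <- rep(1L, n)
  t_star <- median(time)
  roc <- time_dependent_roc(sc, time, event, t_star)
  ref <- oracle_binary_roc(sc, time <= t_star, roc$curve$threshold)
  expect_equal(roc$curve$sensitivity, ref$sensitivity, tolerance = 1e-10)
  expect_equal(roc$curve$specificity, ref$specificity, tolerance = 1e-10)
  expect_equal(roc$auc, binary_roc_auc(sc, time <= t_star), tolerance = 1e-10)
})

test_that("a perfect marker attains AUC 1 and the corner cutoff", {
  time <- c(1, 2, 3, 4, 50, 60, 70, 80)
  event <- rep(1L, 8)
  sc <- c(10, 9, 8, 7, 1, 2, 3, 4)
  roc <- time_dependent_roc(sc, time, event, t_star = 10)
  expect_equal(roc$auc, 1)
  cut <- select_cutoff(roc)
  d <- roc$curve[roc$curve$threshold == cut, ]
  expect_equal((1 - d$sensitivity)^2 + (1 - d$specificity)^2, 0)
  expect_true(cut >= 4 && cut < 7)
})

test_that("permuted scores give a null time-dependent AUC near one half", {
  set.seed(26)
  n <- 80
  time <- rexp(n, 0.05)
  event <- rbinom(n, 1, 0.7)
  sc <- rnorm(n)
  t_star <- median(time)
  aucs <- replicate(500, time_dependent_roc(sample(sc), time, event, t_star)$auc)
  expect_equal(mean(aucs), 0.5, tolerance = 0.02)
})

test_that("ROC preconditions are enforced", {
  expect_error(time_dependent_roc(1:4, c(10, 20, 30, 40), rep(1L, 4), 5),
               "no events")
  expect_error(time_dependent_roc(1:4, c(1, 2, 3, 4), rep(1L, 4), 10),
               "at risk")
})

test_that("cutoff selection equals exhaustive distance minimization", {
  toy <- data.frame(threshold = c(1, 2, 3, 4),
                    sensitivity = c(0.9, 0.8, 0.5, 0.2),
                    specificity = c(0.3, 0.7, 0.8, 0.95))
  d <- sqrt((1 - toy$sensitivity)^2 + (1 - toy$specificity)^2)
  expect_equal(select_cutoff(toy), toy$threshold[which.min(d)])
  for (i in 1:20) {
    set.seed(500 + i)
    cv <- data.frame(threshold = sort(runif(15)),
                     sensitivity = runif(15), specificity = runif(15))
    dd <- sqrt((1 - cv$sensitivity)^2 + (1 - cv$specificity)^2)
    best <- min(cv$threshold[dd == min(dd)])  # smaller-threshold tie-break
    expect_equal(select_cutoff(cv), best)
  }
  expect_error(select_cutoff(data.frame(threshold = numeric(0),
                                        sensitivity = numeric(0),
                                        specificity = numeric(0))), "empty")
})

test_that("risk assignment uses a strict cutoff with ties going low", {
  sc <- c(a = 0.5, b = 1.0, c = 1.5)
  r <- assign_risk(sc, cutoff = 1.0)
  expect_equal(as.character(r$group), c("low", "low", "high"))
  expect_true(all(assign_risk(sc, 2)$group == "low"))
})

test_that("composite index arithmetic reproduces the published coefficient form", {
  model <- structure(list(terms = c(age = 0.627, stage = 0.538, tcrpi = 0.334),
                          p_values = NULL,
                          encodings = ctcpi_encodings(tcrpi = "group"), n = 1L),
                     class = "ctcpi_model")
  clin <- data.frame(sample_id = "s1", age_years = 70, gender = "male",
                     stage = "III", grade = "high", os_months = 10, os_event = 1)
  risk <- data.frame(sample_id = "s1", tcrpi = 2,
                     group = factor("high", levels = c("low", "high")))
  expect_equal(unname(compute_ctcpi(model, risk, clin)), 1.499)
})

test_that("CTCPI fitting retains only significant features", {
  set.seed(27)
  n <- 500
  clin <- data.frame(sample_id = sprintf("s%03d", 1:n),
                     age_years = round(rnorm(n, 65, 10)),
                     gender = sample(c("male", "female"), n, TRUE),
                     stage = sample(c("I", "II", "III", "IV"), n, TRUE),
                     grade = sample(c("low", "high"), n, TRUE))
  tcrpi <- rnorm(n)
  lp <- 0.8 * (clin$age_years > 65) + 0.8 * tcrpi
  clin$os_months <- rexp(n, 0.02 * exp(lp - mean(lp)))
  clin$os_event <- rbinom(n, 1, 0.8)
  risk <- assign_risk(stats::setNames(tcrpi, clin$sample_id), 0)
  fit <- fit_ctcpi(risk, clin, ctcpi_encodings(tcrpi = "continuous"))
  expect_true(all(c("age", "tcrpi") %in% names(fit$terms)))
  expect_false(any(c("gender", "grade") %in% names(fit$terms)))
})
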