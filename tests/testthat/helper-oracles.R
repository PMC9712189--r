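# Independent brute-force oracles. Each materializes the defining
# computation step by step (loops, full enumeration) and is kept free of any
# package internals beyond plain arithmetic.

# ssGSEA running sum: build both cumulative distributions position by
# position and accumulate their difference.
oracle_ssgsea <- function(expr, set, alpha = 0.25) {
  genes <- names(expr)
  r <- rank(expr, ties.method = "average")
  ord <- order(-r, genes, method = "radix")
  g <- genes[ord]
  w <- r[ord]^alpha
  inset <- g %in% set
  n <- length(g)
  m <- sum(inset)
  w_in_total <- sum(w[inset])
  score <- 0
  cum_in <- 0
  cum_out <- 0
  for (i in seq_len(n)) {
    if (inset[i]) cum_in <- cum_in + w[i] else cum_out <- cum_out + 1
    score <- score + cum_in / w_in_total - cum_out / (n - m)
  }
  unname(score)
}

# Log-rank by explicit risk-set enumeration at each event time.
oracle_logrank <- function(t1, e1, t2, e2) {
  time <- c(t1, t2)
  ev <- c(e1, e2)
  grp <- rep(1:2, c(length(t1), length(t2)))
  O <- E <- V <- 0
  for (t in sort(unique(time[ev == 1]))) {
    n <- sum(time >= t)
    n1 <- sum(time >= t & grp == 1)
    d <- sum(time == t & ev == 1)
    d1 <- sum(time == t & ev == 1 & grp == 1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  stat <- if (V > 0) (O - E)^2 / V else 0
  list(statistic = stat, p_value = pchisq(stat, 1, lower.tail = FALSE))
}

# Harrell C by enumerating every pair of subjects.
oracle_cindex <- function(scores, time, event) {
  n <- length(scores)
  conc <- ties <- npairs <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    # comparable iff the earlier time is an observed event (ties only with
    # a censored partner)
    if (time[i] == time[j]) {
      if (event[i] + event[j] != 1L) next
      ev <- if (event[i] == 1L) i else j
      cs <- if (event[i] == 1L) j else i
    } else {
      ev <- if (time[i] < time[j]) i else j
      cs <- if (time[i] < time[j]) j else i
      if (event[ev] != 1L) next
    }
    npairs <- npairs + 1
    if (scores[ev] > scores[cs]) conc <- conc + 1
    else if (scores[ev] == scores[cs]) ties <- ties + 1
  }
  (conc + 0.5 * ties) / npairs
}

# Product-limit estimator by a literal loop over sorted event times.
oracle_km <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  surv <- numeric(length(ts))
  s <- 1
  for (i in seq_along(ts)) {
    at_risk <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  list(time = ts, survival = surv)
}

# Area under the product-limit step function on [0, tau].
oracle_rms <- function(time, event, tau) {
  km <- oracle_km(time, event)
  area <- 0
  prev_t <- 0
  prev_s <- 1
  for (i in seq_along(km$time)) {
    if (km$time[i] >= tau) break
    area <- area + (km$time[i] - prev_t) * prev_s
    prev_t <- km$time[i]
    prev_s <- km$survival[i]
  }
  area + (tau - prev_t) * prev_s
}

# AUC by exhaustive positive/negative pair counting (Mann-Whitney U).
oracle_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Fisher's exact p for a 2x2 table by hypergeometric enumeration of all
# tables with the observed margins.
oracle_fisher_2x2 <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  probs <- vapply(max(0, r1 + c1 - n):min(r1, c1), function(a)
    choose(c1, a) * choose(n - c1, r1 - a) / choose(n, r1), numeric(1))
  obs <- choose(c1, tab[1, 1]) * choose(n - c1, tab[1, 2]) / choose(n, r1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Unpenalized Cox fit by straight Newton iteration on the partial
# log-likelihood (Breslow risk sets; valid for untied times).
oracle_cox_newton <- function(X, time, event, iter = 50) {
  ord <- order(time)
  X <- X[ord, , drop = FALSE]
  time <- time[ord]
  event <- event[ord]
  beta <- rep(0, ncol(X))
  for (it in seq_len(iter)) {
    w <- exp(drop(X %*% beta))
    U <- rep(0, ncol(X))
    Info <- matrix(0, ncol(X), ncol(X))
    for (i in which(event == 1)) {
      R <- which(time >= time[i])
      sw <- sum(w[R])
      xbar <- colSums(X[R, , drop = FALSE] * w[R]) / sw
      U <- U + X[i, ] - xbar
      xc <- sweep(X[R, , drop = FALSE], 2, xbar)
      Info <- Info + t(xc * w[R]) %*% xc / sw
    }
    step <- solve(Info, U)
    beta <- beta + step
    if (max(abs(step)) < 1e-12) break
  }
  beta
}

# Univariate Cox score equation for one binary covariate, solved by uniroot.
oracle_cox_univariate <- function(x, time, event) {
  score <- function(beta) {
    w <- exp(beta * x)
    s <- 0
    for (i in which(event == 1)) {
      R <- time >= time[i]
      s <- s + x[i] - sum(x[R] * w[R]) / sum(w[R])
    }
    s
  }
  uniroot(score, c(-20, 20), tol = 1e-12)$root
}

# Plain binary ROC points at the same thresholds the package sweeps.
oracle_binary_roc <- function(scores, labels, thresholds) {
  labels <- as.logical(labels)
  data.frame(threshold = thresholds,
             sensitivity = vapply(thresholds, function(c)
               sum(scores > c & labels) / sum(labels), numeric(1)),
             specificity = vapply(thresholds, function(c)
               sum(scores <= c & !labels) / sum(!labels), numeric(1)))
}
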