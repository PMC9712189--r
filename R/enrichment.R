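# Single-sample gene set enrichment (ssGSEA, Barbie-style running sum).
# For one sample, genes are ranked decreasingly by expression (average ranks
# for ties); the enrichment score of a set S is the sum, over positions i of
# the ranked list, of the difference between the weighted in-set empirical
# CDF (weights |rank|^alpha) and the unweighted out-of-set CDF:
#
#   ES = sum_i [ sum_{j<=i, j in S} w_j / sum_{j in S} w_j
#               - #{j<=i, j notin S} / (N - |S|) ]
#
# Because only within-sample ranks enter, the score is invariant to any
# strictly increasing transform of the sample's expression vector.

#' Construct an expression cohort
#'
#' @param values Gene x sample numeric matrix (log-scale expression) with
#'   unique rownames (gene ids) and colnames (sample ids).
#' @param cohort_id Cohort label.
#' @param min_samples Minimum sample count (the meta-analysis inclusion rule
#'   keeps cohorts with more than 20 samples; relax for toy data).
#' @return An object of class `expression_cohort`.
#' @export
expression_cohort <- function(values, cohort_id, min_samples = 20L) {
  if (!is.matrix(values) || !is.numeric(values))
    stopf("values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stopf("values must carry gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stopf("duplicate gene id: %s",
          paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stopf("duplicate sample id: %s",
          paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (anyNA(values) || any(!is.finite(values)))
    stopf("expression values must be finite")
  if (ncol(values) < min_samples)
    stopf("cohort '%s' has %d samples; at least %d required",
          cohort_id, ncol(values), min_samples)
  structure(list(values = values, cohort_id = as.character(cohort_id)),
            class = "expression_cohort")
}

#' @export
print.expression_cohort <- function(x, ...) {
  cat(sprintf("<expression_cohort '%s': %d genes x %d samples>\n",
              x$cohort_id, nrow(x$values), ncol(x$values)))
  invisible(x)
}

as_expr_matrix <- function(x) {
  if (inherits(x, "expression_cohort")) x$values
  else if (is.matrix(x)) x
  else stopf("expected an expression_cohort or matrix")
}

# Restrict a gene set to the cohort universe; warn on unknown ids, error when
# nothing remains or the set swallows the whole universe.
restrict_set <- function(set, universe, name) {
  set <- unique(set)
  if (!length(set)) stopf("gene set '%s' is empty", name)
  unknown <- setdiff(set, universe)
  if (length(unknown)) {
    warnf("gene set '%s': %d gene id(s) absent from the expression universe; dropped",
          name, length(unknown))
    set <- intersect(set, universe)
  }
  if (!length(set))
    stopf("gene set '%s' has no genes in the expression universe", name)
  if (length(set) >= length(universe))
    stopf("gene set '%s' covers the whole gene universe", name)
  set
}

#' ssGSEA score for a single sample and a single gene set
#'
#' Reference implementation of the running-sum statistic (see the package
#' vignette for the formula). [ssgsea_matrix()] computes the same quantity
#' for all sets and samples through a closed-form rearrangement.
#'
#' @param expr Named numeric vector: one sample's expression over the gene
#'   universe.
#' @param gene_set Character vector of gene ids; must be a non-empty strict
#'   subset of `names(expr)` (unknown ids are dropped with a warning).
#' @param alpha Non-negative rank-weighting exponent (ssGSEA default 0.25).
#' @return The enrichment score (a single number).
#' @export
ssgsea_sample_score <- function(expr, gene_set, alpha = 0.25) {
  assert_finite(expr, "expr")
  if (is.null(names(expr)) || anyDuplicated(names(expr)))
    stopf("expr must be named with unique gene ids")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0)
    stopf("alpha must be a single non-negative number")
  genes <- names(expr)
  set <- restrict_set(gene_set, genes, "gene_set")
  n <- length(genes)
  r <- rank(expr, ties.method = "average")
  ord <- order(-r, genes, method = "radix")  # gene-id tie-break: deterministic
  w <- r[ord]^alpha
  inset <- genes[ord] %in% set
  p_in <- cumsum(w * inset) / sum(w * inset)
  p_out <- cumsum(!inset) / (n - length(set))
  sum(p_in - p_out)
}

#' ssGSEA scores for all gene sets and samples of a cohort
#'
#' Each column is scored independently, so results do not depend on which
#' samples are co-loaded. Uses the identity
#' `sum_i cumsum(v)_i = sum_j (N - j + 1) v_j` to reduce each score to two
#' dot products; agrees with [ssgsea_sample_score()] exactly.
#'
#' @param x An `expression_cohort` or gene x sample matrix.
#' @param sets Named list of gene-id character vectors (one per cell type).
#' @param alpha Rank-weighting exponent.
#' @return Raw (unnormalized) cell-type x sample score matrix.
#' @export
ssgsea_matrix <- function(x, sets, alpha = 0.25) {
  X <- as_expr_matrix(x)
  if (!length(sets) || is.null(names(sets)) || anyDuplicated(names(sets)))
    stopf("sets must be a non-empty uniquely named list")
  genes <- rownames(X)
  n <- length(genes)
  sets_r <- lapply(seq_along(sets), function(i)
    restrict_set(sets[[i]], genes, names(sets)[i]))
  M <- vapply(sets_r, function(s) genes %in% s, logical(n))  # n x k
  m <- colSums(M)
  out <- matrix(NA_real_, length(sets), ncol(X),
                dimnames = list(names(sets), colnames(X)))
  for (s in seq_len(ncol(X))) {
    r <- rank(X[, s], ties.method = "average")
    ord <- order(-r, genes, method = "radix")
    w <- r[ord]^alpha
    u <- as.numeric(n:1)               # times each position enters the sum
    Mo <- M[ord, , drop = FALSE]
    out[, s] <- drop(crossprod(Mo, u * w)) / drop(crossprod(Mo, w)) -
      (sum(u) - drop(crossprod(Mo, u))) / (n - m)
  }
  out
}

#' Normalize enrichment scores by the global score range
#'
#' Divides every score by the global (all cell types x all samples) range,
#' the documented ssGSEA normalization, giving the normalized enrichment
#' score (NES). The map is a positive rescaling, so within-sample cell-type
#' ordering — all that the downstream pair transform consumes — is unchanged.
#'
#' @param raw Raw score matrix from [ssgsea_matrix()].
#' @return NES matrix whose global range equals 1.
#' @export
normalize_enrichment <- function(raw) {
  if (!is.matrix(raw)) stopf("raw must be a matrix")
  assert_finite(as.vector(raw), "raw scores")
  rng <- max(raw) - min(raw)
  if (rng <= 0) stopf("degenerate enrichment matrix: all scores identical")
  raw / rng
}
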