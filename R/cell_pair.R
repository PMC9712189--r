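# Binary cell-pair (TCP) features: within each sample, a pair (a, b) scores 1
# exactly when cell type a's enrichment exceeds cell type b's. Because the
# comparison is within-sample, the features are invariant to any strictly
# increasing per-sample transform of the expression values, which is what
# makes models built on them portable across platforms and cohorts.

#' Enumerate the canonical cell-pair universe
#'
#' All unordered pairs of distinct cell types, each listed once with its
#' members in lexicographic order (C locale). For `k` cell types this yields
#' `k * (k - 1) / 2` pairs; the 19 curated T-cell types give 171 pairs.
#'
#' @param cell_types Character vector of at least two distinct names.
#' @return A data frame with columns `first`, `second` and `id`
#'   (`"first|second"`), one row per pair.
#' @examples
#' nrow(enumerate_pairs(paste0("CT", 1:19)))  # 171
#' @export
enumerate_pairs <- function(cell_types) {
  if (!is.character(cell_types) || length(cell_types) < 2L)
    stopf("need at least two cell type names")
  dup <- unique(cell_types[duplicated(cell_types)])
  if (length(dup))
    stopf("duplicate cell type name: %s", paste(dup, collapse = ", "))
  ct <- sort(cell_types, method = "radix")
  idx <- utils::combn(length(ct), 2L)
  first <- ct[idx[1L, ]]
  second <- ct[idx[2L, ]]
  data.frame(first = first, second = second,
             id = paste(first, second, sep = "|"),
             stringsAsFactors = FALSE)
}

#' Score one cell pair in one or more samples
#'
#' Returns 1 when the first cell type's normalized enrichment score strictly
#' exceeds the second's and 0 otherwise; exact ties score 0 (the strict
#' reading of "greater than"; ties have measure zero for continuous scores).
#'
#' @param nes_a,nes_b Finite numeric vectors of equal length.
#' @return Integer vector of 0/1 scores.
#' @examples
#' pair_score(0.5, 0.3)  # 1
#' pair_score(0.3, 0.5)  # 0
#' @export
pair_score <- function(nes_a, nes_b) {
  assert_finite(nes_a, "nes_a")
  assert_finite(nes_b, "nes_b")
  if (length(nes_a) != length(nes_b))
    stopf("nes_a and nes_b must have equal length")
  as.integer(nes_a > nes_b)
}

#' Build the binary pair matrix from an enrichment matrix
#'
#' @param nes Cell-type x sample numeric matrix with unique rownames
#'   (cell types) and colnames (samples).
#' @param pairs Optional pair universe as returned by [enumerate_pairs()];
#'   defaults to all pairs of `rownames(nes)`.
#' @return Integer pair x sample matrix with rownames `"first|second"`.
#' @export
build_pair_matrix <- function(nes, pairs = NULL) {
  if (!is.matrix(nes) || is.null(rownames(nes)))
    stopf("nes must be a matrix with cell-type rownames")
  assert_finite(as.vector(nes), "nes")
  pairs <- pairs %||% enumerate_pairs(rownames(nes))
  missing <- setdiff(unique(c(pairs$first, pairs$second)), rownames(nes))
  if (length(missing))
    stopf("cell types absent from nes: %s", paste(missing, collapse = ", "))
  pm <- (nes[pairs$first, , drop = FALSE] > nes[pairs$second, , drop = FALSE]) + 0L
  dimnames(pm) <- list(pairs$id, colnames(nes))
  pm
}

#' Drop pairs that are constant across all samples
#'
#' Pairs scoring all 0 or all 1 over the merged analysis set carry no
#' information and mostly reflect platform-dependent preferential measurement;
#' they are removed before any survival screening. "Constant" is read strictly
#' (zero variance); an optional frequency band is available for users who
#' prefer to drop near-constant pairs as well.
#'
#' @param pm Binary pair x sample matrix.
#' @param min_freq,max_freq Optional frequency band: keep pairs whose mean
#'   score lies in `(min_freq, max_freq)`. Defaults (0, 1) reproduce the
#'   strict zero-variance rule.
#' @return The filtered matrix (possibly with zero rows, with a warning).
#' @export
filter_constant_pairs <- function(pm, min_freq = 0, max_freq = 1) {
  if (!is.matrix(pm)) stopf("pm must be a matrix")
  if (!all(pm %in% c(0L, 1L))) stopf("pm must be binary")
  f <- rowMeans(pm)
  keep <- f > min_freq & f < max_freq
  if (!any(keep)) warnf("all pairs are constant; returning an empty pair matrix")
  pm[keep, , drop = FALSE]
}
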