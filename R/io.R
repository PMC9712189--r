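# Plain-text interchange: gene x sample TSV, GMT gene sets, clinical CSV,
# JSON model serializations.

#' Read a gene x sample expression table
#'
#' First column holds gene ids, header row holds sample ids; tab-separated by
#' default.
#'
#' @param path File path.
#' @param cohort_id Cohort label (defaults to the file name).
#' @param sep Field separator.
#' @param min_samples Passed to [expression_cohort()].
#' @return An `expression_cohort`.
#' @export
read_expression <- function(path, cohort_id = NULL, sep = "\t", min_samples = 20L) {
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "")
  if (ncol(df) < 2L) stopf("expression table '%s' needs gene id + sample columns", path)
  gid <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- gid
  expression_cohort(m, cohort_id %||% sub("\\.[^.]*$", "", basename(path)),
                    min_samples = min_samples)
}

#' Write a gene x sample expression table
#' @param cohort An `expression_cohort` or matrix.
#' @param path Output path.
#' @param sep Field separator.
#' @export
write_expression <- function(cohort, path, sep = "\t") {
  m <- as_expr_matrix(cohort)
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then gene ids.
#'
#' @param path File path.
#' @return Named list of gene-id character vectors, with a `"description"`
#'   attribute carrying the per-set description column.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stopf("GMT file '%s' is empty", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad)) stopf("GMT line(s) without genes: %s", paste(which(bad), collapse = ", "))
  nm <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(nm)) stopf("duplicate gene set name in '%s'", path)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- nm
  attr(sets, "description") <- stats::setNames(vapply(parts, `[[`, character(1), 2L), nm)
  sets
}

#' Write gene sets to a GMT file
#' @param sets Named list of gene-id vectors.
#' @param path Output path.
#' @param description Per-set description (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  if (is.null(names(sets))) stopf("sets must be named")
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a clinical table
#'
#' CSV with columns `sample_id`, `os_months`, `os_event`, and optionally
#' `age_years`, `gender`, `stage`, `grade`, `response`. Missing values stay
#' `NA` and are never imputed; samples lacking survival are dropped (with a
#' message) only at model-fitting time.
#'
#' @param path File path.
#' @return A data frame.
#' @export
read_clinical <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "os_months", "os_event")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("clinical table missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stopf("duplicate sample_id in clinical table")
  df
}

#' Write a clinical table
#' @param clinical Data frame as from [read_clinical()].
#' @param path Output path.
#' @export
write_clinical <- function(clinical, path) {
  utils::write.csv(clinical, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a fitted pair index model to JSON
#' @param model A `pair_index_model`.
#' @param path Output path.
#' @export
write_pair_index_model <- function(model, path) {
  stopifnot(inherits(model, "pair_index_model"))
  obj <- list(selected_pairs = names(model$coefficients),
              coefficients = as.list(model$coefficients),
              cutoff = model$cutoff,
              roc_time = model$roc_time,
              training_meta = model$training_meta)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a pair index model from JSON
#' @param path File path.
#' @return A `pair_index_model`.
#' @export
read_pair_index_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pair_index_model(coefficients = unlist(obj$coefficients),
                   cutoff = obj$cutoff, roc_time = obj$roc_time,
                   training_meta = obj$training_meta)
}
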