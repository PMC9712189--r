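`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_finite <- function(x, what) {
  if (!is.numeric(x) || length(x) == 0L || anyNA(x) || any(!is.finite(x)))
    stopf("%s must be non-empty finite numeric", what)
  invisible(x)
}

assert_binary_event <- function(event) {
  if (!all(event %in% c(0, 1)))
    stopf("event indicator must be 0/1")
  invisible(as.integer(event))
}

#' Derive a per-stage random seed from one master seed
#'
#' One master seed fans out to independent stage seeds through a fixed affine
#' map modulo the largest 32-bit prime, so that any stage (split, fold
#' assignment, simulation, ...) can be rerun in isolation and still match a
#' full pipeline run with the same master seed.
#'
#' @param seed Integer master seed.
#' @param stage Stage name, one of `"simulate"`, `"split"`, `"lasso"`,
#'   `"distort"`, `"censor"`, `"response"`, `"bootstrap"`.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
stage_seed <- function(seed, stage) {
  stages <- c(simulate = 1, split = 2, lasso = 3, distort = 4,
              censor = 5, response = 6, bootstrap = 7)
  if (!stage %in% names(stages)) stopf("unknown stage '%s'", stage)
  as.integer((abs(as.numeric(seed)) + 104729 * stages[[stage]]) %% 2147483647)
}
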