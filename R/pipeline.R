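# End-to-end orchestration in the fixed stage order: enrichment (per
# cohort) -> NES normalization -> pair matrix -> constant-pair filter on the
# merged set -> 1:1:1:1 split -> log-rank screen (training) -> LASSO Cox
# (training) -> final multivariate Cox (training) -> ROC cutoff (training)
# -> risk assignment and evaluation on every part. Test-part survival is
# never touched before the model is frozen.

#' Build and validate a pipeline run configuration
#'
#' @param mode `"simulate"` (generate a synthetic study) or `"load"` (read
#'   expression/GMT/clinical from `paths`).
#' @param simulation A [simulation_config()] (simulate mode).
#' @param paths Load mode: list with `expression` (character vector of
#'   per-cohort TSVs), `gmt`, `clinical`.
#' @param alpha_ssgsea ssGSEA rank-weighting exponent.
#' @param logrank_alpha Log-rank screening level.
#' @param lasso List: `nfolds`, `rule` (`"min"`/`"1se"`).
#' @param roc_time_months ROC horizon for the cutoff (default 60).
#' @param rms_tau_months Restricted-mean horizon (default 120).
#' @param encodings CTCPI encodings ([ctcpi_encodings()]).
#' @param seed Master seed (fans out per stage via [stage_seed()]).
#' @param output_dir Optional directory for tabular outputs.
#' @return Validated list of class `run_config`.
#' @export
run_config <- function(mode = c("simulate", "load"), simulation = NULL,
                       paths = NULL, alpha_ssgsea = 0.25, logrank_alpha = 0.05,
                       lasso = list(nfolds = 10L, rule = "min"),
                       roc_time_months = 60, rms_tau_months = 120,
                       encodings = ctcpi_encodings(), seed = 1L,
                       output_dir = NULL) {
  mode <- match.arg(mode)
  if (mode == "simulate" && !is.null(paths))
    stopf("config invalid: input paths given in simulate mode (choose one mode)")
  if (mode == "load" && !is.null(simulation))
    stopf("config invalid: simulation settings given in load mode (choose one mode)")
  if (mode == "load") {
    if (is.null(paths) || !all(c("expression", "gmt", "clinical") %in% names(paths)))
      stopf("config invalid: load mode needs paths$expression, paths$gmt, paths$clinical")
  } else {
    simulation <- simulation %||% simulation_config(seed = seed)
  }
  if (logrank_alpha <= 0 || logrank_alpha >= 1)
    stopf("config invalid: logrank_alpha must lie in (0, 1)")
  if (roc_time_months <= 0 || rms_tau_months <= 0)
    stopf("config invalid: time horizons must be positive")
  structure(list(mode = mode, simulation = simulation, paths = paths,
                 alpha_ssgsea = alpha_ssgsea, logrank_alpha = logrank_alpha,
                 lasso = utils::modifyList(list(nfolds = 10L, rule = "min"), lasso),
                 roc_time_months = roc_time_months,
                 rms_tau_months = rms_tau_months, encodings = encodings,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "run_config")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
}

#' Cross-validate expression, gene sets and clinical inputs
#'
#' Intersects expression and clinical sample ids (mismatches are dropped and
#' counted), checks gene-id uniqueness per cohort, and verifies each gene
#' set against each cohort's universe.
#'
#' @param cohorts List of `expression_cohort`.
#' @param sets Named list of gene sets.
#' @param clinical Clinical data frame.
#' @return List: validated `cohorts` (columns restricted to clinical-matched
#'   samples), `sets`, `clinical` (rows restricted and ordered to match),
#'   and `dropped` counts.
#' @export
validate_inputs <- function(cohorts, sets, clinical) {
  if (!length(cohorts)) stopf("no expression cohorts supplied")
  for (co in cohorts) {
    m <- as_expr_matrix(co)
    if (anyDuplicated(rownames(m)))
      stopf("duplicate gene id: %s",
            paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  }
  expr_ids <- unlist(lapply(cohorts, function(co) colnames(as_expr_matrix(co))))
  if (anyDuplicated(expr_ids)) stopf("sample ids duplicated across cohorts")
  common <- intersect(expr_ids, clinical$sample_id)
  if (!length(common))
    stopf("no sample ids shared between expression and clinical inputs")
  dropped_expr <- length(expr_ids) - length(common)
  dropped_clin <- nrow(clinical) - length(common)
  if (dropped_expr) message(dropped_expr, " expression sample(s) lack clinical rows; dropped")
  if (dropped_clin) message(dropped_clin, " clinical row(s) lack expression; dropped")
  cohorts <- lapply(cohorts, function(co) {
    keep <- colnames(co$values) %in% common
    co$values <- co$values[, keep, drop = FALSE]
    co
  })
  cohorts <- Filter(function(co) ncol(co$values) > 0L, cohorts)
  missing_genes <- 0L
  for (co in cohorts) {
    for (nm in names(sets)) {
      absent <- setdiff(sets[[nm]], rownames(co$values))
      if (length(absent)) {
        missing_genes <- missing_genes + length(absent)
        message(sprintf("cohort '%s': %d gene(s) of set '%s' absent; set restricted",
                        co$cohort_id, length(absent), nm))
      }
    }
  }
  order_ids <- unlist(lapply(cohorts, function(co) colnames(co$values)))
  clinical <- clinical[match(order_ids, clinical$sample_id), , drop = FALSE]
  rownames(clinical) <- NULL
  list(cohorts = cohorts, sets = sets, clinical = clinical,
       dropped = list(expression_samples = dropped_expr,
                      clinical_samples = dropped_clin,
                      set_genes_missing = missing_genes))
}

#' Run the full TCRPI analysis
#'
#' @param config A [run_config()].
#' @param data Optional pre-built study (a `tcrpi_simulation`, or a list with
#'   `cohorts`, `gene_sets`, `clinical`); overrides the config's input mode.
#'   Intended for programmatic use, e.g. robustness experiments that perturb
#'   a generated study before running.
#' @return List of class `tcrpi_report`: the fitted `model`
#'   (`pair_index_model`), `ctcpi` model, per-sample `risk` table with part
#'   labels and composite scores, `metrics` per part, `response` metrics
#'   (when labels exist), `selection` stage counts, and a `provenance` block
#'   (config, seeds, versions) sufficient to reproduce every number.
#' @export
run_pipeline <- function(config, data = NULL) {
  stopifnot(inherits(config, "run_config"))
  study <- with_stage("input", {
    if (!is.null(data)) data
    else if (config$mode == "simulate") generate_study(config$simulation)
    else list(cohorts = lapply(config$paths$expression, read_expression),
              gene_sets = read_gmt(config$paths$gmt),
              clinical = read_clinical(config$paths$clinical))
  })
  val <- with_stage("validate", validate_inputs(study$cohorts, study$gene_sets,
                                                study$clinical))
  nes <- with_stage("enrichment", {
    raw <- do.call(cbind, lapply(val$cohorts, ssgsea_matrix, sets = val$sets,
                                 alpha = config$alpha_ssgsea))
    normalize_enrichment(raw)
  })
  pm <- with_stage("pair_matrix",
                   filter_constant_pairs(build_pair_matrix(nes)))

  clin <- val$clinical
  has_surv <- !is.na(clin$os_months) & !is.na(clin$os_event) & clin$os_months > 0
  if (any(!has_surv))
    message(sum(!has_surv), " sample(s) without usable survival excluded from modeling")
  surv_ids <- clin$sample_id[has_surv]
  stime <- stats::setNames(clin$os_months[has_surv], surv_ids)
  sevent <- stats::setNames(as.integer(clin$os_event[has_surv]), surv_ids)

  parts <- with_stage("split", split_cohort(surv_ids, 4L, config$seed))
  train <- parts$part1

  model <- with_stage("fit", {
    pm_tr <- pm[, train, drop = FALSE]
    prog <- select_prognostic_pairs(pm_tr, stime[train], sevent[train],
                                    alpha = config$logrank_alpha)
    if (nrow(prog) < 2L)
      stopf("fewer than two prognostic pairs at alpha = %g", config$logrank_alpha)
    x_tr <- t(pm_tr[prog$pair, , drop = FALSE])
    lasso <- fit_lasso_cox(x_tr, stime[train], sevent[train],
                           nfolds = config$lasso$nfolds, seed = config$seed,
                           lambda_rule = config$lasso$rule)
    if (!length(lasso$support)) stopf("empty LASSO support")
    final <- fit_final_cox(x_tr[, lasso$support, drop = FALSE],
                           stime[train], sevent[train])
    if (!length(final$coefficients)) stopf("no pair retained by the final Cox model")
    scores_tr <- compute_tcrpi(pm_tr, final$coefficients)
    roc <- time_dependent_roc(scores_tr, stime[train], sevent[train],
                              t_star = config$roc_time_months)
    m <- pair_index_model(final$coefficients, select_cutoff(roc),
                          roc_time = config$roc_time_months,
                          training_meta = list(seed = config$seed,
                                               lasso_support = lasso$support,
                                               lambda = lasso$lambda,
                                               lambda_rule = lasso$lambda_rule,
                                               nfolds = lasso$nfolds,
                                               n_train = length(train),
                                               train_auc = roc$auc))
    attr(m, "selection") <- list(n_pairs_universe = nrow(enumerate_pairs(rownames(nes))),
                                 n_nonconstant = nrow(pm),
                                 n_prognostic = nrow(prog),
                                 n_lasso = length(lasso$support),
                                 n_final = length(final$coefficients))
    m
  })

  scores <- compute_tcrpi(pm, model)
  risk <- assign_risk(scores[surv_ids], model$cutoff)
  risk$part <- rep(names(parts), times = lengths(parts))[
    match(risk$sample_id, unlist(parts))]

  ctcpi <- with_stage("ctcpi", {
    tr_clin <- clin[match(train, clin$sample_id), , drop = FALSE]
    tryCatch(fit_ctcpi(risk[match(train, risk$sample_id), , drop = FALSE],
                       tr_clin, encodings = config$encodings),
             error = function(e) NULL)
  })
  ctcpi_scores <- if (!is.null(ctcpi))
    compute_ctcpi(ctcpi, risk, clin[match(risk$sample_id, clin$sample_id), ]) else NULL

  metrics <- with_stage("evaluate", {
    part_of <- c(stats::setNames(risk$part, risk$sample_id))
    eval_part <- function(ids, label) {
      g <- risk$group[match(ids, risk$sample_id)]
      ti <- stime[ids]; ev <- sevent[ids]
      lr <- if (any(g == "high") && any(g == "low"))
        logrank_test(ti[g == "high"], ev[g == "high"],
                     ti[g == "low"], ev[g == "low"])$p_value else NA_real_
      rr <- if (any(g == "high") && any(g == "low"))
        rms_ratio_by_group(as.character(g), ti, ev, tau = config$rms_tau_months)
        else NA_real_
      ci_c <- if (!is.null(ctcpi_scores)) {
        cs <- ctcpi_scores[ids]
        ok <- !is.na(cs)
        if (sum(ok) > 2) harrell_cindex(cs[ok], ti[ok], ev[ok]) else NA_real_
      } else NA_real_
      data.frame(part = label, n = length(ids),
                 n_high = sum(g == "high"), n_low = sum(g == "low"),
                 logrank_p = lr,
                 cindex_tcrpi = harrell_cindex(risk$tcrpi[match(ids, risk$sample_id)],
                                               ti, ev),
                 cindex_ctcpi = ci_c, rms_ratio = rr,
                 stringsAsFactors = FALSE)
    }
    do.call(rbind, c(lapply(names(parts), function(p) eval_part(parts[[p]], p)),
                     list(eval_part(surv_ids, "meta_entire"))))
  })

  response <- with_stage("response", {
    has_resp <- !is.na(clin$response) & clin$sample_id %in% risk$sample_id
    if (sum(has_resp) < 4L) NULL else {
      ids <- clin$sample_id[has_resp]
      r4 <- clin$response[has_resp]
      responder <- r4 %in% c("CR", "PR")
      sc <- risk$tcrpi[match(ids, risk$sample_id)]
      if (length(unique(responder)) < 2L) NULL else
        list(n = length(ids),
             auc = binary_roc_auc(-sc, responder),
             wilcoxon_p = group_stats(sc, responder, "wilcoxon")$p_value,
             kruskal_p = if (length(unique(r4)) > 1L)
               group_stats(sc, r4, "kruskal")$p_value else NA_real_)
    }
  })

  report <- structure(list(
    model = model, ctcpi = ctcpi, risk = risk, metrics = metrics,
    response = response, nes = nes, pair_matrix = pm, parts = parts,
    selection = attr(model, "selection"),
    provenance = list(config = unclass(config),
                      seeds = list(master = config$seed,
                                   split = stage_seed(config$seed, "split"),
                                   lasso = stage_seed(config$seed, "lasso")),
                      dropped = val$dropped,
                      package_version = as.character(utils::packageVersion("tcrpi")),
                      r_version = R.version.string)),
    class = "tcrpi_report")
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

#' @export
print.tcrpi_report <- function(x, ...) {
  cat("TCRPI pipeline report\n")
  cat(sprintf("  pairs: %d universe -> %d non-constant -> %d prognostic -> %d LASSO -> %d final\n",
              x$selection$n_pairs_universe, x$selection$n_nonconstant,
              x$selection$n_prognostic, x$selection$n_lasso, x$selection$n_final))
  cat(sprintf("  cutoff %.4f (training AUC %.3f at %g months)\n",
              x$model$cutoff, x$model$training_meta$train_auc, x$model$roc_time))
  print(x$metrics, row.names = FALSE)
  if (!is.null(x$response))
    cat(sprintf("  response: AUC %.3f (n=%d)\n", x$response$auc, x$response$n))
  invisible(x)
}

#' Write the tabular outputs of a pipeline run
#'
#' @param report A `tcrpi_report`.
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(data.frame(cell_type = rownames(report$nes), report$nes,
                                check.names = FALSE),
                     file.path(dir, "nes.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(pair = rownames(report$pair_matrix),
                                report$pair_matrix, check.names = FALSE),
                     file.path(dir, "pair_matrix.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_pair_index_model(report$model, file.path(dir, "pair_index_model.json"))
  utils::write.csv(report$risk, file.path(dir, "risk_assignment.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.table(report$metrics, file.path(dir, "metrics.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(metrics = report$metrics,
                            selection = report$selection,
                            response = report$response,
                            ctcpi = if (!is.null(report$ctcpi))
                              as.list(report$ctcpi$terms) else NULL,
                            provenance = report$provenance),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(dir)
}

#' Apply a fitted pair index model to a new cohort
#'
#' Scores a cohort with a frozen model: ssGSEA on the cohort's own gene
#' universe, NES normalization, pair matrix, TCRPI, risk groups at the
#' stored cutoff.
#'
#' @param model A `pair_index_model`.
#' @param cohort An `expression_cohort` or gene x sample matrix.
#' @param sets Named list of cell-type gene sets.
#' @param alpha ssGSEA exponent (must match the training run).
#' @return Data frame from [assign_risk()].
#' @export
apply_index <- function(model, cohort, sets, alpha = 0.25) {
  nes <- normalize_enrichment(ssgsea_matrix(cohort, sets, alpha = alpha))
  pm <- build_pair_matrix(nes)
  assign_risk(compute_tcrpi(pm, model), model$cutoff)
}
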