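# Multi-cohort synthetic study with a planted cell-pair signature.
#
# Latent per-sample cell-type abundances are embedded additively into the
# expression of each cell type's gene set; cohorts receive gene-level batch
# offsets and every sample an independent strictly increasing (affine)
# platform distortion. Survival follows an exponential proportional-hazards
# model whose linear predictor counts the active planted pairs plus clinical
# contributions; censoring is independent uniform, numerically tuned to the
# requested rate; a designated cohort carries immunotherapy response labels
# linked to low risk.

#' Configuration for the synthetic study generator
#'
#' Defaults describe the study conditions used throughout the package's
#' validation: 4 cohorts of 800 samples (so a quarter split yields 800
#' training samples), 19 cell types (171 pairs), disjoint 10-gene sets within
#' a 500-gene universe, 8 planted pairs each contributing `pair_log_hazard`
#' to the log hazard, age/stage clinical effects, 30% censoring, and
#' response labels in the last cohort only.
#'
#' @param n_cohorts Number of cohorts.
#' @param samples_per_cohort Samples per cohort (>= 20).
#' @param n_genes Size of the gene universe.
#' @param n_cell_types Number of cell types (default 19).
#' @param genes_per_set Genes per cell-type set (disjoint by construction).
#' @param set_overlap Fraction of each set additionally drawn from other
#'   sets' genes (default 0 = disjoint).
#' @param n_true_pairs Number of planted prognostic pairs.
#' @param pair_log_hazard Log-hazard contribution per active planted pair.
#' @param clinical_log_hazards Named vector `c(age = ..., stage = ...)`:
#'   log-hazard of age > 65 and of stage III-IV.
#' @param censoring_rate Target fraction censored, in \[0, 1).
#' @param baseline_hazard Baseline exponential hazard per month.
#' @param response_link_slope Logistic slope linking low risk to response.
#' @param abundance_effect Expression shift per unit latent abundance on the
#'   set's genes.
#' @param noise_sd Gene-level residual noise SD.
#' @param batch_sd SD of per-cohort gene-level batch offsets.
#' @param platform_distortion Apply a random per-sample affine distortion.
#' @param seed Master seed.
#' @return Validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_cohorts = 4L, samples_per_cohort = 800L,
                              n_genes = 500L, n_cell_types = 19L,
                              genes_per_set = 10L, set_overlap = 0,
                              n_true_pairs = 8L, pair_log_hazard = 1.0,
                              clinical_log_hazards = c(age = 0.6, stage = 0.5),
                              censoring_rate = 0.3, baseline_hazard = 0.01,
                              response_link_slope = 1.0,
                              abundance_effect = 1.5, noise_sd = 0.5,
                              batch_sd = 0.5, platform_distortion = TRUE,
                              seed = 1L) {
  cfg <- list(n_cohorts = as.integer(n_cohorts),
              samples_per_cohort = as.integer(samples_per_cohort),
              n_genes = as.integer(n_genes),
              n_cell_types = as.integer(n_cell_types),
              genes_per_set = as.integer(genes_per_set),
              set_overlap = set_overlap,
              n_true_pairs = as.integer(n_true_pairs),
              pair_log_hazard = pair_log_hazard,
              clinical_log_hazards = clinical_log_hazards,
              censoring_rate = censoring_rate,
              baseline_hazard = baseline_hazard,
              response_link_slope = response_link_slope,
              abundance_effect = abundance_effect, noise_sd = noise_sd,
              batch_sd = batch_sd,
              platform_distortion = isTRUE(platform_distortion),
              seed = as.integer(seed))
  with(cfg, {
    if (n_cohorts < 1L) stopf("config invalid: n_cohorts must be positive")
    if (samples_per_cohort < 20L)
      stopf("config invalid: samples_per_cohort must be >= 20")
    if (n_cell_types < 2L) stopf("config invalid: n_cell_types must be >= 2")
    if (genes_per_set < 1L) stopf("config invalid: genes_per_set must be positive")
    if (n_true_pairs < 1L ||
        n_true_pairs > n_cell_types * (n_cell_types - 1L) / 2L)
      stopf("config invalid: n_true_pairs must lie in [1, n_cell_types*(n_cell_types-1)/2]")
    if (genes_per_set * n_cell_types > n_genes)
      stopf("config invalid: genes_per_set * n_cell_types must not exceed n_genes")
    if (censoring_rate < 0 || censoring_rate >= 1)
      stopf("config invalid: censoring_rate must lie in [0, 1)")
    if (baseline_hazard <= 0) stopf("config invalid: baseline_hazard must be positive")
    if (!all(c("age", "stage") %in% names(clinical_log_hazards)))
      stopf("config invalid: clinical_log_hazards needs 'age' and 'stage'")
  })
  structure(cfg, class = "simulation_config")
}

#' Specify a strictly increasing per-sample distortion
#'
#' Families: `affine` (`y = slope * x + intercept`, slope > 0; slope and
#' intercept may be per-sample vectors), `exponential` (`y = exp(rate * x)`,
#' rate > 0), and `random_affine` (per-sample slopes log-uniform in
#' \[0.5, 2\] and intercepts N(0, 1.5), drawn from the seed given to
#' [apply_monotone_distortion()]).
#'
#' @param family Distortion family.
#' @param slope,intercept Affine parameters.
#' @param rate Exponential rate.
#' @return Validated list of class `distortion_spec`.
#' @export
distortion_spec <- function(family = c("affine", "exponential", "random_affine"),
                            slope = 1, intercept = 0, rate = 1) {
  family <- match.arg(family)
  if (family == "affine" && any(slope <= 0))
    stopf("config invalid: affine distortion requires strictly positive slope")
  if (family == "exponential" && (length(rate) != 1L || rate <= 0))
    stopf("config invalid: exponential distortion requires a positive rate")
  structure(list(family = family, slope = slope, intercept = intercept,
                 rate = rate), class = "distortion_spec")
}

#' Apply a strictly monotone per-sample distortion to a cohort
#'
#' Values change; within-sample gene rankings do not, so every downstream
#' rank-based quantity (ssGSEA scores up to normalization, the pair matrix,
#' the fitted index) is unchanged.
#'
#' @param cohort An `expression_cohort` or gene x sample matrix.
#' @param spec A [distortion_spec()].
#' @param seed Seed for the `random_affine` family.
#' @return Object of the same type with distorted values.
#' @export
apply_monotone_distortion <- function(cohort, spec, seed = 1L) {
  if (!inherits(spec, "distortion_spec")) stopf("spec must be a distortion_spec")
  m <- as_expr_matrix(cohort)
  out <- switch(spec$family,
    affine = {
      sl <- rep_len(spec$slope, ncol(m))
      ic <- rep_len(spec$intercept, ncol(m))
      sweep(sweep(m, 2L, sl, `*`), 2L, ic, `+`)
    },
    exponential = exp(spec$rate * m),
    random_affine = {
      set.seed(stage_seed(seed, "distort"))
      sl <- exp(stats::runif(ncol(m), log(0.5), log(2)))
      ic <- stats::rnorm(ncol(m), 0, 1.5)
      sweep(sweep(m, 2L, sl, `*`), 2L, ic, `+`)
    })
  if (inherits(cohort, "expression_cohort")) {
    cohort$values <- out
    cohort
  } else out
}

# u such that C ~ U(0, u) censors the target fraction of the drawn times.
tune_uniform_censoring <- function(times, rate) {
  f <- function(u) mean(pmin(times / u, 1)) - rate
  upper <- max(times) / rate
  while (f(upper) > 0) upper <- upper * 10
  stats::uniroot(f, c(1e-9, upper))$root
}

#' Generate a complete synthetic multi-cohort study
#'
#' @param config A [simulation_config()].
#' @return List of class `tcrpi_simulation` with elements `cohorts` (list of
#'   `expression_cohort`), `gene_sets` (named list), `clinical` (data frame
#'   with survival, covariates and response), and `ground_truth` (latent
#'   abundances, planted pairs, per-sample true risk) — the latter is never
#'   consumed by the pipeline.
#' @export
generate_study <- function(config) {
  if (!inherits(config, "simulation_config"))
    stopf("config must be a simulation_config")
  cfg <- config
  k <- cfg$n_cell_types
  n <- cfg$n_cohorts * cfg$samples_per_cohort
  set.seed(stage_seed(cfg$seed, "simulate"))

  cell_types <- sprintf("CT%02d", seq_len(k))
  genes <- sprintf("g%05d", seq_len(cfg$n_genes))
  cohort_ids <- sprintf("cohort%02d", seq_len(cfg$n_cohorts))
  cohort_of <- rep(cohort_ids, each = cfg$samples_per_cohort)
  sample_ids <- sprintf("%s_s%04d", cohort_of,
                        rep(seq_len(cfg$samples_per_cohort), cfg$n_cohorts))

  set_idx <- split(seq_len(k * cfg$genes_per_set),
                   rep(seq_len(k), each = cfg$genes_per_set))
  gene_sets <- lapply(set_idx, function(i) genes[i])
  names(gene_sets) <- cell_types
  if (cfg$set_overlap > 0) {
    n_extra <- round(cfg$set_overlap * cfg$genes_per_set)
    for (c in seq_len(k)) {
      pool <- setdiff(unlist(gene_sets[-c]), gene_sets[[c]])
      gene_sets[[c]] <- c(gene_sets[[c]], sample(pool, min(n_extra, length(pool))))
    }
  }

  abundance <- matrix(stats::rnorm(k * n), k, n,
                      dimnames = list(cell_types, sample_ids))
  universe <- enumerate_pairs(cell_types)
  true_pairs <- universe[sort(sample.int(nrow(universe), cfg$n_true_pairs)), ]
  rownames(true_pairs) <- NULL
  z <- (abundance[true_pairs$first, , drop = FALSE] >
          abundance[true_pairs$second, , drop = FALSE]) + 0

  age <- round(stats::rnorm(n, 65, 10))
  gender <- sample(c("male", "female"), n, replace = TRUE)
  stage <- sample(c("I", "II", "III", "IV"), n, replace = TRUE,
                  prob = c(0.15, 0.25, 0.35, 0.25))
  grade <- sample(c("low", "high"), n, replace = TRUE, prob = c(0.35, 0.65))
  lh <- cfg$clinical_log_hazards
  true_risk <- cfg$pair_log_hazard * colSums(z) +
    lh[["age"]] * (age > 65) + lh[["stage"]] * (stage %in% c("III", "IV"))
  names(true_risk) <- sample_ids

  # centered linear predictor so baseline_hazard describes the median subject
  lat <- stats::rexp(n, cfg$baseline_hazard * exp(true_risk - mean(true_risk)))
  set.seed(stage_seed(cfg$seed, "censor"))
  if (cfg$censoring_rate > 0) {
    u <- tune_uniform_censoring(lat, cfg$censoring_rate)
    cens <- stats::runif(n, 0, u)
    os_months <- pmin(lat, cens)
    os_event <- as.integer(lat <= cens)
  } else {
    os_months <- lat
    os_event <- rep(1L, n)
  }

  set.seed(stage_seed(cfg$seed, "response"))
  response <- rep(NA_character_, n)
  resp_cohort <- cohort_of == cohort_ids[cfg$n_cohorts]
  p_resp <- stats::plogis(cfg$response_link_slope *
                            (stats::median(true_risk) - true_risk[resp_cohort]))
  responder <- stats::rbinom(sum(resp_cohort), 1L, p_resp) == 1L
  lab <- ifelse(responder,
                ifelse(stats::runif(sum(resp_cohort)) < 0.3, "CR", "PR"),
                ifelse(stats::runif(sum(resp_cohort)) < 0.5, "SD", "PD"))
  response[resp_cohort] <- lab

  clinical <- data.frame(sample_id = sample_ids, cohort = cohort_of,
                         os_months = os_months, os_event = os_event,
                         age_years = age, gender = gender, stage = stage,
                         grade = grade, response = response,
                         stringsAsFactors = FALSE)

  set.seed(stage_seed(cfg$seed, "distort"))
  mu <- stats::rnorm(cfg$n_genes, 6, 1)
  cohorts <- vector("list", cfg$n_cohorts)
  names(cohorts) <- cohort_ids
  for (ci in seq_len(cfg$n_cohorts)) {
    cols <- which(cohort_of == cohort_ids[ci])
    nc <- length(cols)
    E <- matrix(stats::rnorm(cfg$n_genes * nc, 0, cfg$noise_sd), cfg$n_genes, nc)
    E <- E + mu + stats::rnorm(cfg$n_genes, 0, cfg$batch_sd)
    for (c in seq_len(k)) {
      gi <- match(gene_sets[[c]], genes)
      E[gi, ] <- E[gi, ] + cfg$abundance_effect *
        matrix(abundance[c, cols], length(gi), nc, byrow = TRUE)
    }
    dimnames(E) <- list(genes, sample_ids[cols])
    if (cfg$platform_distortion) {
      sl <- exp(stats::runif(nc, log(0.5), log(2)))
      ic <- stats::rnorm(nc, 0, 1.5)
      E <- apply_monotone_distortion(E, distortion_spec("affine", slope = sl,
                                                        intercept = ic))
    }
    cohorts[[ci]] <- expression_cohort(E, cohort_ids[ci])
  }

  structure(list(cohorts = cohorts, gene_sets = gene_sets, clinical = clinical,
                 ground_truth = list(cell_abundance = abundance,
                                     true_pairs = true_pairs,
                                     true_risk = true_risk),
                 config = cfg),
            class = "tcrpi_simulation")
}

#' @export
print.tcrpi_simulation <- function(x, ...) {
  cat(sprintf(
    "<tcrpi_simulation: %d cohorts x %d samples, %d genes, %d cell types, %d planted pairs>\n",
    x$config$n_cohorts, x$config$samples_per_cohort, x$config$n_genes,
    x$config$n_cell_types, nrow(x$ground_truth$true_pairs)))
  invisible(x)
}

#' Write a synthetic study to disk
#'
#' Expression as per-cohort gene x sample TSV, gene sets as GMT, clinical as
#' CSV, and ground truth (planted pairs and true risk) as a separate CSV that
#' the pipeline never reads.
#'
#' @param sim A `tcrpi_simulation`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the list of written paths.
#' @export
write_study <- function(sim, dir) {
  stopifnot(inherits(sim, "tcrpi_simulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  for (co in sim$cohorts) {
    p <- file.path(dir, paste0("expression_", co$cohort_id, ".tsv"))
    write_expression(co, p)
    paths$expression <- c(paths$expression, p)
  }
  paths$gmt <- write_gmt(sim$gene_sets, file.path(dir, "gene_sets.gmt"),
                         description = "synthetic cell-type set")
  paths$clinical <- write_clinical(sim$clinical, file.path(dir, "clinical.csv"))
  gt <- data.frame(sample_id = names(sim$ground_truth$true_risk),
                   true_risk = as.numeric(sim$ground_truth$true_risk))
  paths$ground_truth <- file.path(dir, "ground_truth.csv")
  utils::write.csv(gt, paths$ground_truth, row.names = FALSE, quote = FALSE)
  utils::write.csv(sim$ground_truth$true_pairs,
                   file.path(dir, "true_pairs.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(paths)
}
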