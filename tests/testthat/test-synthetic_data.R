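test_that("configuration invariants are enforced with named violations", {
  expect_s3_class(small_sim_config(), "simulation_config")
  expect_error(simulation_config(n_true_pairs = 200, n_cell_types = 6),
               "n_true_pairs")
  expect_error(simulation_config(genes_per_set = 100, n_cell_types = 19,
                                 n_genes = 500), "genes_per_set")
  expect_error(simulation_config(samples_per_cohort = 10), "samples_per_cohort")
  expect_error(simulation_config(censoring_rate = 1.2), "censoring_rate")
  expect_error(simulation_config(baseline_hazard = -1), "baseline_hazard")
})

test_that("generation is bit-identical under a fixed seed", {
  s1 <- generate_study(small_sim_config(seed = 7L))
  s2 <- generate_study(small_sim_config(seed = 7L))
  expect_identical(s1$cohorts[[1]]$values, s2$cohorts[[1]]$values)
  expect_identical(s1$clinical, s2$clinical)
  expect_identical(s1$ground_truth, s2$ground_truth)
  s3 <- generate_study(small_sim_config(seed = 8L))
  expect_false(identical(s1$cohorts[[1]]$values, s3$cohorts[[1]]$values))
})

test_that("study geometry matches the configuration", {
  sim <- generate_study(small_sim_config())
  cfg <- sim$config
  expect_length(sim$cohorts, cfg$n_cohorts)
  expect_equal(ncol(sim$cohorts[[1]]$values), cfg$samples_per_cohort)
  expect_length(sim$gene_sets, cfg$n_cell_types)
  expect_equal(anyDuplicated(unlist(sim$gene_sets)), 0L)  # disjoint sets
  expect_equal(nrow(sim$clinical), cfg$n_cohorts * cfg$samples_per_cohort)
  expect_true(all(sim$clinical$os_months > 0))
  # 19 cell types yield the full 171-pair universe downstream
  sim19 <- generate_study(simulation_config(n_cohorts = 1L,
                                            samples_per_cohort = 20L,
                                            n_genes = 200L, seed = 2L))
  expect_equal(nrow(enumerate_pairs(rownames(sim19$ground_truth$cell_abundance))),
               171L)
})

test_that("true risk decomposes into pair counts plus clinical contributions", {
  sim <- generate_study(small_sim_config())
  gt <- sim$ground_truth
  cfg <- sim$config
  z <- (gt$cell_abundance[gt$true_pairs$first, ] >
          gt$cell_abundance[gt$true_pairs$second, ]) + 0
  lh <- cfg$clinical_log_hazards
  expected <- cfg$pair_log_hazard * colSums(z) +
    lh[["age"]] * (sim$clinical$age_years > 65) +
    lh[["stage"]] * (sim$clinical$stage %in% c("III", "IV"))
  expect_equal(unname(gt$true_risk), unname(expected), tolerance = 1e-12)
  expect_true(all(gt$true_pairs$id %in%
                    enumerate_pairs(rownames(gt$cell_abundance))$id))
})

test_that("censoring lands near the configured rate", {
  sim <- generate_study(simulation_config(n_cohorts = 2L,
                                          samples_per_cohort = 500L,
                                          n_genes = 200L, censoring_rate = 0.3,
                                          seed = 3L))
  expect_equal(mean(sim$clinical$os_event == 0), 0.3, tolerance = 0.06)
  sim0 <- generate_study(small_sim_config(censoring_rate = 0))
  expect_true(all(sim0$clinical$os_event == 1))
})

test_that("response labels exist only in the designated cohort and track low risk", {
  sim <- generate_study(simulation_config(n_cohorts = 3L,
                                          samples_per_cohort = 300L,
                                          n_genes = 200L, seed = 4L))
  resp_cohort <- sim$clinical$cohort == "cohort03"
  expect_true(all(is.na(sim$clinical$response[!resp_cohort])))
  expect_true(all(sim$clinical$response[resp_cohort] %in%
                    c("CR", "PR", "SD", "PD")))
  responder <- sim$clinical$response[resp_cohort] %in% c("CR", "PR")
  risk <- sim$ground_truth$true_risk[resp_cohort]
  expect_lt(mean(risk[responder]), mean(risk[!responder]))
})

test_that("monotone distortions preserve within-sample ranks and reject bad families", {
  sim <- generate_study(small_sim_config())
  co <- sim$cohorts[[1]]
  aff <- apply_monotone_distortion(co, distortion_spec("affine", slope = 2,
                                                       intercept = 1))
  expect_equal(apply(aff$values, 2, rank), apply(co$values, 2, rank))
  expect_false(identical(aff$values, co$values))
  expect_equal(aff$values, 2 * co$values + 1)
  expect_error(distortion_spec("affine", slope = -1), "positive slope")
  expect_error(distortion_spec("exponential", rate = 0), "positive rate")
})

test_that("the pair matrix is unchanged by any strictly increasing distortion", {
  sim <- generate_study(small_sim_config())
  pm_of <- function(cohorts) {
    raw <- do.call(cbind, lapply(cohorts, ssgsea_matrix, sets = sim$gene_sets))
    build_pair_matrix(normalize_enrichment(raw))
  }
  base <- pm_of(sim$cohorts)
  distorted <- list(
    apply_monotone_distortion(sim$cohorts[[1]], distortion_spec("exponential",
                                                                rate = 0.5)),
    apply_monotone_distortion(sim$cohorts[[2]], distortion_spec("random_affine"),
                              seed = 99L))
  expect_identical(pm_of(distorted), base)
})

test_that("a strong planted signature yields an estimable hazard ratio above 1", {
  sim <- generate_study(simulation_config(n_cohorts = 2L,
                                          samples_per_cohort = 400L,
                                          n_genes = 200L,
                                          pair_log_hazard = 0.8,
                                          clinical_log_hazards = c(age = 0,
                                                                   stage = 0),
                                          seed = 5L))
  gt <- sim$ground_truth
  z <- colSums((gt$cell_abundance[gt$true_pairs$first, ] >
                  gt$cell_abundance[gt$true_pairs$second, ]) + 0)
  cph <- survival::coxph(survival::Surv(sim$clinical$os_months,
                                        sim$clinical$os_event) ~ z)
  expect_gt(exp(coef(cph)), 1)
  expect_equal(unname(coef(cph)), 0.8, tolerance = 0.15)
})

test_that("a null generator yields about the nominal log-rank retention", {
  sim <- generate_study(simulation_config(
    n_cohorts = 2L, samples_per_cohort = 250L, n_genes = 300L,
    n_cell_types = 19L, genes_per_set = 10L, pair_log_hazard = 0,
    clinical_log_hazards = c(age = 0, stage = 0), seed = 6L))
  raw <- do.call(cbind, lapply(sim$cohorts, ssgsea_matrix,
                               sets = sim$gene_sets))
  pm <- filter_constant_pairs(build_pair_matrix(normalize_enrichment(raw)))
  sel <- suppressWarnings(select_prognostic_pairs(
    pm, sim$clinical$os_months, sim$clinical$os_event, alpha = 0.05))
  # pairs sharing cell types are correlated, so the band is generous
  expect_lt(nrow(sel) / nrow(pm), 0.15)
})

test_that("a study written to disk reads back equivalently", {
  sim <- generate_study(small_sim_config())
  dir <- withr::local_tempdir()
  write_study(sim, dir)
  co <- read_expression(file.path(dir, "expression_cohort01.tsv"),
                        cohort_id = "cohort01")
  expect_equal(co$values, sim$cohorts[[1]]$values, tolerance = 1e-12)
  sets <- read_gmt(file.path(dir, "gene_sets.gmt"))
  expect_identical(lapply(sets, identity)[names(sim$gene_sets)],
                   sim$gene_sets)
  clin <- read_clinical(file.path(dir, "clinical.csv"))
  expect_equal(clin$os_months, sim$clinical$os_months, tolerance = 1e-12)
  expect_identical(clin$sample_id, sim$clinical$sample_id)
})
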