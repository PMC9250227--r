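test_that("generators are pure functions of (config, seed)", {
  cfg <- small_sim_config()
  a <- generate_reference(cfg, seed = 51)
  b <- generate_reference(cfg, seed = 51)
  expect_identical(as.matrix(a$counts), as.matrix(b$counts))
  expect_identical(a$markers, b$markers)
  c <- generate_reference(cfg, seed = 52)
  expect_false(identical(as.matrix(a$counts), as.matrix(c$counts)))

  coh1 <- generate_cohort(a, cfg, seed = 53)
  coh2 <- generate_cohort(a, cfg, seed = 53)
  expect_identical(as.matrix(coh1$bulk), as.matrix(coh2$bulk))
  expect_identical(coh1$truth, coh2$truth)
})

test_that("library-size calibration hits the detection target within 20%", {
  cfg <- small_sim_config()
  ref <- generate_reference(cfg, seed = 54)
  det <- stats::median(Matrix::colSums(ref$counts$values > 0))
  expect_lt(abs(det - cfg$mean_genes_per_nucleus),
            0.2 * cfg$mean_genes_per_nucleus)
  ## reference shape
  expect_equal(dim(ref$counts), c(cfg$n_genes, sum(cfg$nuclei_per_cluster)))
  expect_length(cluster_ids(ref$labels), 5L)
  expect_equal(nrow(ref$markers), 5L * cfg$n_markers_per_cluster)
})

test_that("planted markers are recovered; a null simulation yields none", {
  cfg <- small_sim_config()
  ref <- generate_reference(cfg, seed = 55)
  mk <- find_markers(log_normalize(ref$counts), ref$labels,
                     top_n = cfg$n_markers_per_cluster)
  rec <- dplyr::inner_join(tibble::as_tibble(mk), ref$markers,
                           by = c("gene", "cluster"))
  expect_gte(nrow(rec) / nrow(ref$markers), 0.9)

  null_cfg <- small_sim_config(marker_fold_change = 1)
  null_ref <- generate_reference(null_cfg, seed = 56)
  null_mk <- find_markers(log_normalize(null_ref$counts), null_ref$labels)
  null_rec <- dplyr::inner_join(tibble::as_tibble(null_mk), null_ref$markers,
                                by = c("gene", "cluster"))
  ## at most FDR-level leakage of "planted" genes that carry no signal
  expect_lte(nrow(null_rec), ceiling(0.05 * nrow(null_ref$markers)))
})

test_that("cohort truth is recovered at high depth", {
  cfg <- small_sim_config(depth = 1e7, cohort_size = 25)
  ref <- generate_reference(cfg, seed = 57)
  S <- build_signature(ref$counts, ref$labels, ref$markers)
  sim <- generate_cohort(ref, cfg, seed = 58)
  est <- suppressMessages(deconvolve_cohort(S, sim$bulk))
  j <- dplyr::inner_join(tibble::as_tibble(est), sim$truth, by = "sample_id")
  expect_gte(spearman_with_ci(j$type1_fraction.x, j$type1_fraction.y)$r, 0.99)
})

test_that("an all-type-I cohort is estimated as pure within 0.01", {
  cfg <- small_sim_config(cohort_size = 8,
                          fraction_distribution = tibble::tibble(
                            group = "pure", mode = 0.999, concentration = 5000,
                            n = NA_integer_))
  ref <- generate_reference(cfg, seed = 59)
  sim <- generate_cohort(ref, cfg, seed = 60)
  est <- suppressMessages(deconvolve_cohort(ref$profiles, sim$bulk))
  expect_true(all(abs(est$type1_fraction - 1) < 0.01))
})

test_that("the sex preset draws groups at the published medians and sizes", {
  fd <- sex_fraction_groups()
  cfg <- small_sim_config(fraction_distribution = fd)
  ref <- generate_reference(cfg, seed = 61)
  sim <- generate_cohort(ref, cfg, seed = 62)
  expect_equal(as.integer(table(sim$truth$group)[c("women", "men")]),
               c(171L, 398L))
  med <- tapply(sim$truth$type1_fraction, sim$truth$group, stats::median)
  expect_lt(abs(med[["women"]] - 0.68), 0.03)
  expect_lt(abs(med[["men"]] - 0.56), 0.04)
})

test_that("contamination requires a non-fiber column and perturbs the fit", {
  cfg <- small_sim_config(contamination = 0.2, cohort_size = 6)
  ref <- generate_reference(cfg, seed = 63)
  fiber_only_sig <- signature_matrix(ref$profiles$values[, c("type_I", "type_II")])
  expect_error(generate_cohort(fiber_only_sig, cfg, seed = 64), "non-fiber")
  sim <- generate_cohort(ref, cfg, seed = 64)
  expect_equal(dim(sim$bulk)[2], 6L)
})

test_that("simulation_config validates its fields", {
  expect_error(simulation_config(marker_fold_change = 0.5))
  expect_error(simulation_config(n_clusters = 1))
  expect_error(simulation_config(contamination = 1))
  expect_error(simulation_config(
    fraction_distribution = tibble::tibble(group = "g", mode = 1.2,
                                           concentration = 10, n = 5)),
    "modes")
})
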