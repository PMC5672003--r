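test_that("the same seed reproduces the dataset byte for byte", {
  d1 <- simulate_dataset(simulation_config(seed = 5, n_proteins = 20))
  d2 <- simulate_dataset(simulation_config(seed = 5, n_proteins = 20))
  expect_identical(d1$sec_table, d2$sec_table)
  expect_identical(d1$sucrose_table, d2$sucrose_table)
  expect_identical(d1$truth$proteins, d2$truth$proteins)

  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  p1 <- write_dataset(d1, dir1); p2 <- write_dataset(d2, dir2)
  for (k in seq_along(p1))
    expect_identical(readLines(p1[k]), readLines(p2[k]))

  d3 <- simulate_dataset(simulation_config(seed = 6, n_proteins = 20))
  expect_false(identical(d1$sec_table, d3$sec_table))
})

test_that("emitted tables are readable by the parser without modification", {
  d <- simulate_dataset(simulation_config(seed = 7, n_proteins = 15))
  dir <- withr::local_tempdir()
  paths <- write_dataset(d, dir)
  parsed <- read_quant_table(paths["sec"], d$schemes$sec)
  expect_equal(nrow(parsed$profiles$intensities$bio1), 15)
  expect_equal(sort(names(parsed$profiles$intensities)), c("bio1", "bio2"))
  expect_true(all(c("peptide_count", "id_score") %in% names(parsed$records)))
})

test_that("a noise-free simulation is recovered nearly exactly", {
  cfg <- simulation_config(seed = 8, n_proteins = 40, noise_cv = 0,
                           jitter_sd = 0, additive_floor = 0,
                           dropout_prob = 0, void_trapped_rate = 0,
                           single_peptide_rate = 0,
                           peak_count_probs = c(1, 0, 0, 0))
  d <- simulate_dataset(cfg)
  run <- run_pipeline(d)
  ev <- evaluate_against_truth(run, d$truth)
  expect_equal(ev$peak_recall, 1)
  expect_lt(ev$center_rmse, 0.05)
  # noiseless standards: truth R_app of the dominant peak round-trips
  dom <- d$truth$sec_peaks[d$truth$sec_peaks$dominant, ]
  st <- d$truth$proteins$state[match(dom$protein_id,
                                     d$truth$proteins$protein_id)]
  targets <- cfg$rapp_targets[st]
  expect_equal(unname(dom$r_app_true), unname(targets))
})

test_that("generated profiles satisfy the eligibility rule", {
  d <- simulate_dataset(simulation_config(seed = 9, n_proteins = 50,
                                          dropout_prob = 0))
  for (r in c("bio1", "bio2")) {
    m <- d$sec_table[, grep(paste0("Intensity.", r), names(d$sec_table),
                            fixed = TRUE)]
    elig <- apply(as.matrix(m), 1, eligible_for_fitting)
    expect_true(all(elig))
  }
})

test_that("infeasible peak layouts are rejected before generation", {
  expect_error(simulation_config(sec_fractions = 12,
                                 peak_count_probs = c(0.25, 0.25, 0.25, 0.25)),
               "infeasible")
  expect_error(simulation_config(contaminant_rate = 1.2), "probabilities")
})

test_that("evaluation scores a scripted systematic shift correctly", {
  cfg <- simulation_config(seed = 10, n_proteins = 25, noise_cv = 0,
                           jitter_sd = 0, additive_floor = 0,
                           dropout_prob = 0, void_trapped_rate = 0,
                           single_peptide_rate = 0,
                           peak_count_probs = c(1, 0, 0, 0))
  d <- simulate_dataset(cfg)
  run <- run_pipeline(d)
  # push every reported center one fraction late: RMSE becomes exactly 1
  shifted <- run
  shifted$labeled_peaks$center_rep1 <- run$labeled_peaks$center_rep1 + 1
  shifted$labeled_peaks$center_rep2 <- run$labeled_peaks$center_rep2 + 1
  ev <- evaluate_against_truth(shifted, d$truth)
  expect_equal(ev$center_rmse, 1, tolerance = 0.05)
  # results naming proteins absent from the truth are rejected
  bad <- run
  bad$labeled_peaks$protein_id <- rep("NOPE", nrow(bad$labeled_peaks))
  expect_error(evaluate_against_truth(bad, d$truth), "unknown")
})
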