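test_that("preset truths are reproduced by fresh computation, never stale", {
  chain <- get_preset("chain")
  expect_equal(chain$truth$optimum, 5, tolerance = 1e-9)
  expect_identical(chain$truth$essential_genes, "g1")

  diamond <- get_preset("diamond")
  expect_equal(diamond$truth$optimum, 10, tolerance = 1e-9)
  expect_length(diamond$truth$essential_genes, 0)   # every gene rerouted
  expect_setequal(diamond$truth$core_reactions, c("U", "Z"))
})

test_that("mini_fix wires lethality, isozyme rescue and partial loss", {
  preset <- get_preset("mini_fix")
  ph <- tibble::deframe(preset$truth$phenotypes[, c("gene", "phenotype")])

  for (g in c("nifH", "nifD", "nifK")) {
    expect_identical(ph[[g]], "-")
    expect_true(g %in% preset$truth$essential_genes)  # nitrogenase complex
  }
  for (g in c("dme", "tme", "alaA", "alaB")) {
    expect_identical(ph[[g]], "=")                    # isozyme pairs
  }
  expect_identical(ph[["iolD"]], "-")                 # inositol feeds carbon
  expect_false("iolD" %in% preset$truth$essential_genes)
  for (g in c("glcP", "glk", "aceA")) {
    expect_identical(ph[[g]], "=")                    # inactive routes
  }
  expect_gte(length(preset$truth$essential_genes), 2)
})

test_that("unknown preset names fail loudly", {
  expect_error(make_toy_network("mega_fix"))
})

test_that("omics simulation is seed-deterministic", {
  preset <- get_preset("mini_fix")
  a <- simulate_omics(preset, 0.7, 2, seed = 42)
  b <- simulate_omics(preset, 0.7, 2, seed = 42)
  expect_identical(a$log_ratios, b$log_ratios)
  expect_identical(a$proteome$genes, b$proteome$genes)
  expect_identical(a$proteome$enzymes, b$proteome$enzymes)

  c_ <- simulate_omics(preset, 0.7, 2, seed = 43)
  expect_false(identical(a$log_ratios, c_$log_ratios))
})

test_that("detection probability extremes bracket the proteome channel", {
  preset <- get_preset("mini_fix")
  all_in <- simulate_omics(preset, detection_prob = 1, shift = 0, seed = 1)
  expect_setequal(all_in$proteome$genes, preset$truth$active_genes)
  expect_setequal(all_in$proteome$enzymes, preset$truth$active_enzymes)

  none <- simulate_omics(preset, detection_prob = 0, shift = 0, seed = 1)
  expect_length(none$proteome$genes, 0)
})

test_that("inactive genes carry centred noise", {
  preset <- get_preset("mini_fix")
  sim <- simulate_omics(preset, 0.5, shift = 3, n_background = 400,
                        seed = 99)
  lr <- sim$log_ratios
  inactive <- !(lr$gene_id %in% sim$truth$active_genes)
  vals <- as.matrix(lr[inactive, -1])
  expect_lt(abs(mean(vals)), 3 / sqrt(length(vals)))
})

test_that("a compact recovery run reports calibrated curves and exact confusion", {
  preset <- get_preset("mini_fix")
  rec <- end_to_end_recovery(preset, detection_probs = c(0.6, 1),
                             shift = 4, n_seeds = 40, seed = 3)
  expect_equal(nrow(rec$eta_curve), 2)
  expect_equal(rec$eta_curve$mean_eta_genes[2], 1)     # p = 1 is exact
  expect_lt(abs(rec$eta_curve$mean_eta_genes[1] - 0.6), 0.06)
  expect_gt(rec$transcriptome$mean_sensitivity, 0.9)
  expect_lt(rec$transcriptome$mean_false_positive_rate, 0.2)

  # knockout calls equal the generated truth, category by category
  off_diag <- rec$knockout_confusion$truth != rec$knockout_confusion$called
  expect_false(any(off_diag))
})

test_that("perfect detection with a strong shift recovers the active set exactly", {
  preset <- get_preset("mini_fix")
  for (s in 1:5) {
    sim <- simulate_omics(preset, detection_prob = 1, shift = 4, seed = s)
    sel <- selected_genes(zscore_select(average_log_ratio(sim$log_ratios)))
    bench <- merge_benchmark(sel, sim$proteome, quiet = TRUE)
    expect_setequal(intersect(bench$genes, preset$model$genes),
                    sim$truth$active_genes)
  }
})
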