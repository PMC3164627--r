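test_that("the consistency coefficient is overlap over predictions, on sets", {
  expect_equal(consistency_coefficient(letters[1:4], letters[10:12])$eta, 0)
  expect_equal(consistency_coefficient(letters[1:4], letters[1:8])$eta, 1)

  cc <- consistency_coefficient(c("a", "b", "c", "a", "a"),
                                c("b", "b", "z"))
  expect_equal(cc$eta, 1 / 3)           # duplicates never count
  expect_equal(cc$overlap, 1)
  expect_equal(cc$n_predicted, 3)

  expect_error(consistency_coefficient(character(0), "a"), "undefined")
})

test_that("eta never decreases as experimental evidence accumulates", {
  set.seed(11)
  predicted <- sample(letters, 10)
  exp_sets <- Reduce(union, lapply(1:8, function(i) sample(letters, 3)),
                     accumulate = TRUE)
  etas <- vapply(exp_sets, function(e) {
    consistency_coefficient(predicted, e)$eta
  }, numeric(1))
  expect_true(all(diff(etas) >= 0))
})

test_that("hypergeometric enrichment matches closed forms and the spot example", {
  # everything overlaps: the only possible draw
  expect_equal(hypergeometric_enrichment(5, 5, 5, 5), 1)
  # zero draws can only give zero overlap
  expect_equal(hypergeometric_enrichment(0, 0, 3, 10), 1)
  # universe 10, 5 detected, 4 drawn, >= 3 shared: 55/210 = 11/42
  expect_equal(hypergeometric_enrichment(3, 4, 5, 10), 11 / 42,
               tolerance = 1e-12)
  expect_equal(hypergeometric_enrichment(3, 4, 5, 10),
               oracle_hyper(3, 4, 5, 10), tolerance = 1e-12)

  expect_error(hypergeometric_enrichment(5, 4, 5, 10), "exceed")
  expect_error(hypergeometric_enrichment(0, 8, 8, 10), "feasible minimum")
  expect_error(hypergeometric_enrichment(1, 4, 20, 10), "universe")
})

test_that("pathway breakdowns partition the union inside each pathway", {
  map <- as_pathway_map(tibble::tibble(
    pathway_id = "pw1", member_type = "gene",
    member_id = c("a", "b", "c")
  ))
  bd <- pathway_breakdown(map, predicted = c("a", "b"),
                          experimental = c("b", "c"))
  expect_equal(unlist(bd[, c("in_silico_only", "both", "experimental_only")],
                      use.names = FALSE), c(1, 1, 1))

  bd2 <- pathway_breakdown(map, predicted = c("a", "b", "c"),
                           experimental = c("a", "b", "c"))
  expect_equal(bd2$both, 3)
  expect_equal(bd2$in_silico_only + bd2$experimental_only, 0)

  # set-algebra identity on random sets
  set.seed(23)
  ids <- sprintf("m%02d", 1:40)
  map2 <- as_pathway_map(tibble::tibble(
    pathway_id = rep(c("p1", "p2", "p3"), times = c(15, 15, 10)),
    member_type = "gene",
    member_id = ids
  ))
  for (i in 1:20) {
    pred <- sample(ids, sample(40, 1))
    expr <- sample(ids, sample(40, 1))
    bd3 <- pathway_breakdown(map2, pred, expr)
    members <- pathway_members(map2, "gene")
    for (k in seq_len(nrow(bd3))) {
      pw <- members[[bd3$pathway_id[k]]]
      expect_equal(
        bd3$in_silico_only[k] + bd3$both[k] + bd3$experimental_only[k],
        length(intersect(union(pred, expr), pw))
      )
    }
  }
})

test_that("perfect detection scores eta = 1 on every preset network", {
  for (name in c("chain", "diamond", "mini_fix")) {
    preset <- get_preset(name)
    fit <- solve_fba(preset$model, mode = "parsimonious")
    omics <- omics_gene_set("perfect",
                            genes = preset$truth$active_genes,
                            enzymes = preset$truth$active_enzymes)
    rep <- score_model_vs_omics(preset$model, fit, omics,
                                preset$pathway_map)
    g <- glance(rep)
    expect_equal(g$eta_genes, 1, info = name)
    expect_equal(g$eta_enzymes, 1, info = name)
  }
})

test_that("an empty omics set gives eta 0 with p-value 1", {
  preset <- get_preset("mini_fix")
  fit <- solve_fba(preset$model)
  rep <- score_model_vs_omics(preset$model, fit,
                              omics_gene_set("empty"),
                              preset$pathway_map)
  g <- glance(rep)
  expect_equal(g$eta_genes, 0)
  expect_equal(g$p_genes, 1)
  expect_true(is.na(g$eta_enzymes))   # no enzyme channel supplied
})

test_that("the per-pathway breakdown in the report covers both set types", {
  preset <- get_preset("mini_fix")
  fit <- solve_fba(preset$model)
  omics <- omics_gene_set("half",
                          genes = preset$truth$active_genes[1:10],
                          enzymes = preset$truth$active_enzymes[1:5])
  rep <- score_model_vs_omics(preset$model, fit, omics, preset$pathway_map)
  expect_setequal(unique(tidy(rep)$set_type), c("gene", "enzyme"))
  expect_setequal(unique(tidy(rep)$pathway_id),
                  unique(preset$pathway_map$pathway_id))
})
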