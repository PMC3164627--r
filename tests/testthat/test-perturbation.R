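two_route_model <- function() {
  # two routes of unequal capacity: deleting the big one leaves 4 of 10
  m <- build_model(tibble::tibble(
    reaction_id = c("U", "R1", "R2"),
    formula = c("-> a[c]", "a[c] -> p[c]", "a[c] -> p[c]"),
    gpr = c(NA, "gA", "gB"),
    lower_bound = c(0, NA, NA),
    upper_bound = c(10, NA, 4)
  ))
  attach_objective(m, c("p[c]" = 1))
}

test_that("gene deletion honours isozyme rescue and complex loss", {
  m <- build_model(tibble::tibble(
    reaction_id = c("ISO", "CPX"),
    formula = c("a[c] -> b[c]", "b[c] -> c[c]"),
    gpr = c("g1 or g2", "g3 and g4")
  ))
  iso <- delete_gene(m, "g1")
  expect_length(iso$disabled_reactions, 0)           # isozyme rescues
  cpx <- delete_gene(m, "g3")
  expect_identical(cpx$disabled_reactions, "CPX")    # complex collapses
  expect_equal(cpx$model$reactions$upper_bound[2], 0)

  both <- delete_gene(m, c("g1", "g2"))              # double isozyme knockout
  expect_identical(both$disabled_reactions, "ISO")
})

test_that("double knockouts close a reaction exactly when the rule says so", {
  rules <- c("g1 or g2", "g1 and g2", "(g1 and g2) or g3", "g3")
  m <- build_model(tibble::tibble(
    reaction_id = paste0("R", seq_along(rules)),
    formula = rep("a[c] -> b[c]", length(rules)),
    gpr = rules
  ))
  del <- delete_gene(m, c("g1", "g2"))
  expected_closed <- vapply(rules, function(r) {
    !oracle_gpr_eval(r, present = "g3")
  }, logical(1))
  expect_setequal(del$disabled_reactions,
                  paste0("R", which(expected_closed)))
})

test_that("deletion is idempotent and unknown genes are warned no-ops", {
  model <- get_preset("mini_fix")$model
  once <- delete_gene(model, "nifH")
  twice <- delete_gene(once$model, "nifH")
  expect_identical(once$model$reactions$upper_bound,
                   twice$model$reactions$upper_bound)

  expect_warning(res <- delete_gene(model, "not_a_gene"), "not in model")
  expect_length(res$disabled_reactions, 0)
  expect_identical(res$model$reactions$upper_bound,
                   model$reactions$upper_bound)
})

test_that("knockout phenotypes quantify the percentage reduction", {
  m <- two_route_model()
  ko <- knockout_phenotype(m, "gA")
  expect_equal(ko$wildtype_objective, 10, tolerance = 1e-9)
  expect_equal(ko$mutant_objective, 4, tolerance = 1e-9)
  expect_equal(ko$percent_reduction, 60, tolerance = 1e-7)
  expect_identical(ko$phenotype, "-")
  expect_false(ko$lethal)

  # a gene appearing in no GPR of the wired routes changes nothing
  ko2 <- knockout_phenotype(m, "gB")
  expect_equal(ko2$mutant_objective, 10, tolerance = 1e-9)
  expect_identical(ko2$phenotype, "=")
})

test_that("the sole gluconeogenic entry to the objective is essential", {
  preset <- get_preset("mini_fix")
  ko <- knockout_phenotype(preset$model, "pckA")
  expect_true(ko$lethal)
  expect_equal(ko$percent_reduction, 100, tolerance = 1e-6)
})

test_that("phenotype classes split on the tolerance band", {
  expect_identical(classify_phenotype(c(60, 0, -12)), c("-", "=", "+"))
  expect_identical(classify_phenotype(4.9), "=")
  expect_identical(classify_phenotype(30, tol_percent = 40), "=")
})

test_that("no single knockout ever increases the LP objective", {
  for (name in c("chain", "diamond", "mini_fix")) {
    preset <- get_preset(name)
    wt <- solve_fba(preset$model, mode = "plain")$objective_value
    kos <- preset$truth$phenotypes  # generated from knockout_all
    full <- knockout_all(preset$model)
    expect_true(all(full$mutant_objective <= wt + 1e-9), info = name)
    expect_true(all(full$mutant_objective >= -1e-9), info = name)
  }
})

test_that("robustness scans recover coupling, redundancy and concavity", {
  chain <- get_preset("chain")$model
  rc <- robustness_scan(chain, "T", lo = 0, hi = 5, n_points = 6)
  expect_equal(rc$objective_value[1], 0, tolerance = 1e-9)  # clamped to zero
  expect_equal(rc$objective_value[6], 5, tolerance = 1e-9)

  diamond <- get_preset("diamond")$model
  flat <- robustness_scan(diamond, "B1", lo = 0, hi = 10, n_points = 6)
  expect_true(all(abs(flat$objective_value - 10) < 1e-7))   # redundant branch

  mf <- get_preset("mini_fix")$model
  sink <- robustness_scan(mf, "SINK_inost", lo = 0, hi = 2, n_points = 9)
  expect_true(all(diff(sink$objective_value) > -1e-9))      # less inositol, less fixation
  expect_lt(sink$objective_value[1], sink$objective_value[9])

  for (curve in list(rc, flat, sink)) {
    obj <- curve$objective_value
    inner <- 2:(length(obj) - 1)
    expect_true(all(obj[inner] >= (obj[inner - 1] + obj[inner + 1]) / 2 - 1e-6))
  }
})
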