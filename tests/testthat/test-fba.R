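test_that("a bound-limited chain attains its uptake capacity", {
  preset <- get_preset("chain")
  fit <- solve_fba(preset$model)
  expect_identical(fit$status, "optimal")
  expect_equal(fit$objective_value, 5, tolerance = 1e-9)
  expect_true(all(abs(tidy(fit)$flux - 5) < 1e-9))
  expect_lt(fit$steady_state_error, 1e-6)
})

test_that("the diamond optimum is route-split invariant and matches the vertex oracle", {
  preset <- get_preset("diamond")
  for (mode in c("plain", "parsimonious")) {
    fit <- solve_fba(preset$model, mode = mode)
    expect_equal(fit$objective_value, 10, tolerance = 1e-9)
  }
  expect_equal(solve_fba(preset$model)$objective_value,
               oracle_fba_vertex(preset$model), tolerance = 1e-8)
  expect_equal(solve_fba(get_preset("chain")$model)$objective_value,
               oracle_fba_vertex(get_preset("chain")$model),
               tolerance = 1e-8)
})

test_that("an unproducible objective metabolite gives a zero optimum, not an error", {
  m <- build_model(tibble::tibble(
    reaction_id = c("R1", "DM_d"),
    formula = c("c[c] -> d[c]", "d[c] ->")
  ))
  m <- attach_objective(m, c("c[c]" = 1))
  fit <- solve_fba(m)
  expect_identical(fit$status, "optimal")
  expect_equal(fit$objective_value, 0, tolerance = 1e-9)
  act <- active_sets(m, fit)
  expect_length(act$enzymes, 0)
  expect_length(act$genes, 0)
})

test_that("FVA spans the alternate-optima structure of the diamond", {
  preset <- get_preset("diamond")
  fva <- flux_variability(preset$model)
  rng <- function(id) unlist(fva[fva$reaction_id == id, c("min_flux", "max_flux")],
                             use.names = FALSE)
  expect_equal(rng("B1"), c(0, 10), tolerance = 1e-7)
  expect_equal(rng("C1"), c(0, 10), tolerance = 1e-7)
  expect_equal(rng("C2"), c(0, 10), tolerance = 1e-7)
  expect_equal(rng("U"), c(10, 10), tolerance = 1e-7)
  expect_equal(rng("Z"), c(10, 10), tolerance = 1e-7)
})

test_that("chain FVA is a point and blocked reactions pin to zero", {
  fva <- flux_variability(get_preset("chain")$model)
  expect_true(all(abs(fva$min_flux - 5) < 1e-7))
  expect_true(all(abs(fva$max_flux - 5) < 1e-7))

  fva_mf <- flux_variability(get_preset("mini_fix")$model)
  for (id in c("GLCT", "GLK")) {   # downstream of a closed uptake
    row <- fva_mf[fva_mf$reaction_id == id, ]
    expect_equal(c(row$min_flux, row$max_flux), c(0, 0), tolerance = 1e-7)
  }
})

test_that("every FVA interval contains the FBA flux and stays inside the bounds", {
  for (name in c("chain", "diamond", "mini_fix")) {
    preset <- get_preset(name)
    fit <- solve_fba(preset$model, mode = "plain")
    fva <- flux_variability(preset$model)
    v <- tidy(fit)$flux[match(fva$reaction_id, tidy(fit)$reaction_id)]
    expect_true(all(fva$min_flux <= v + 1e-6), info = name)
    expect_true(all(fva$max_flux >= v - 1e-6), info = name)
    rx <- preset$model$reactions
    expect_true(all(fva$min_flux >= rx$lower_bound - 1e-7), info = name)
    expect_true(all(fva$max_flux <= rx$upper_bound + 1e-7), info = name)
    expect_true(all(fva$min_flux <= fva$max_flux), info = name)
  }
})

test_that("the null-variability core excludes alternate routes and is tol-monotone", {
  fva <- flux_variability(get_preset("diamond")$model)
  core <- null_variability_core(fva)
  expect_setequal(core, c("U", "Z"))
  expect_false(any(c("B1", "C1", "C2") %in% core))
  expect_setequal(null_variability_core(fva, tol = Inf), fva$reaction_id)

  chain_fva <- flux_variability(get_preset("chain")$model)
  expect_setequal(null_variability_core(chain_fva),
                  chain_fva$reaction_id)
})

test_that("active sets collect flux-carrying enzymatic reactions and their genes", {
  preset <- get_preset("chain")
  fit <- solve_fba(preset$model)
  act <- active_sets(preset$model, fit)
  expect_identical(act$enzymes, "T")   # boundary uptake and drain excluded
  expect_identical(act$genes, "g1")
})

test_that("parsimonious FBA activates exactly one diamond branch, deterministically", {
  preset <- get_preset("diamond")
  fit1 <- solve_fba(preset$model, mode = "parsimonious")
  fit2 <- solve_fba(preset$model, mode = "parsimonious")
  expect_identical(tidy(fit1), tidy(fit2))   # bit-for-bit

  v <- tibble::deframe(tidy(fit1))
  branches_active <- c(v[["B1"]], v[["C1"]]) > 1e-6
  expect_identical(sum(branches_active), 1L)
  expect_gt(v[["B1"]], 9)   # the shorter route wins the total-flux tie-break
})

test_that("the optimum is invariant to reaction column permutation", {
  spec_rows <- symbioflux:::mini_fix_spec()
  set.seed(7)
  shuffled <- spec_rows$reactions[sample(nrow(spec_rows$reactions)), ]
  m <- attach_objective(build_model(shuffled), spec_rows$objective)
  expect_equal(solve_fba(m)$objective_value,
               get_preset("mini_fix")$truth$optimum, tolerance = 1e-9)
})

test_that("all preset optima satisfy mass balance to 1e-6", {
  for (name in c("chain", "diamond", "mini_fix")) {
    for (mode in c("plain", "parsimonious")) {
      fit <- solve_fba(get_preset(name)$model, mode = mode)
      expect_lt(fit$steady_state_error, 1e-6)
    }
  }
})

test_that("infeasible models are reported as a status, never a silent zero", {
  m <- build_model(tibble::tibble(
    reaction_id = c("IN", "OUT"),
    formula = c("-> a[c]", "a[c] ->"),
    lower_bound = c(5, 0), upper_bound = c(10, 2)  # forced in > allowed out
  ))
  m <- attach_objective(m, c("a[c]" = 1), upper_bound = 0.5)
  fit <- solve_fba(m)
  expect_identical(fit$status, "infeasible")
  expect_true(is.na(fit$objective_value))
})
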