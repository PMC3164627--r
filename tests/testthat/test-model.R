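toy_reactions <- function() {
  tibble::tibble(
    reaction_id = c("R1", "R2"),
    formula = c("a[c] -> b[c]", "2 a[c] -> b[c]"),
    gpr = c("g1", NA)
  )
}

test_that("the stoichiometric matrix is assembled column by column", {
  m <- build_model(tibble::tibble(reaction_id = "R1",
                                  formula = "a[c] -> b[c]"))
  expect_equal(unname(as.matrix(m$S)), matrix(c(-1, 1), ncol = 1))

  m2 <- build_model(toy_reactions())
  expect_equal(as.numeric(m2$S[, "R2"]), c(-2, 1))
  expect_identical(rownames(m2$S), c("a[c]", "b[c]"))
  expect_identical(colnames(m2$S), c("R1", "R2"))
  expect_identical(m2$genes, "g1")
})

test_that("declared metabolites constrain the formulas", {
  expect_error(
    build_model(toy_reactions(), metabolites = c("a[c]")),
    "undeclared metabolites.*b\\[c\\]"
  )
})

test_that("compartment suffixes must be registered", {
  bad <- tibble::tibble(reaction_id = "R1", formula = "a[c] -> b[m]")
  expect_error(build_model(bad), "unregistered compartment")
  expect_silent(build_model(bad, compartments = c("c", "m")))
  nosuffix <- tibble::tibble(reaction_id = "R1", formula = "a -> b[c]")
  expect_error(build_model(nosuffix), "compartment")
})

test_that("absent bounds default by reversibility", {
  m <- build_model(tibble::tibble(
    reaction_id = c("F", "R"),
    formula = c("a[c] -> b[c]", "a[c] <=> b[c]")
  ))
  expect_equal(m$reactions$lower_bound, c(0, -1000))
  expect_equal(m$reactions$upper_bound, c(1000, 1000))
  expect_error(
    build_model(tibble::tibble(reaction_id = "F", formula = "a[c] -> b[c]",
                               lower_bound = -1, upper_bound = 1)),
    "negative lower bound"
  )
})

test_that("duplicate reaction ids are rejected", {
  dup <- tibble::tibble(reaction_id = c("R1", "R1"),
                        formula = c("a[c] -> b[c]", "b[c] -> a[c]"))
  expect_error(build_model(dup), "duplicate reaction_id: R1")
})

test_that("the objective drain consumes each target with its coefficient", {
  base <- zfix_objective(extended = FALSE)
  ext <- zfix_objective(extended = TRUE)
  expect_equal(nrow(base), 6)
  expect_equal(nrow(ext), 8)
  expect_true(all(c("val[c]", "his[c]") %in% ext$metabolite))
  expect_true(all(ext$coefficient == 1))

  preset <- get_preset("mini_fix")
  z <- preset$model$reactions$stoichiometry[[
    match("Z", preset$model$reactions$reaction_id)]]
  expect_equal(length(z), 8)
  expect_true(all(z == -1))
})

test_that("attach_objective validates inputs and never touches old columns", {
  m <- build_model(toy_reactions())
  before <- as.matrix(m$S)
  m2 <- attach_objective(m, c("b[c]" = 1))
  expect_equal(as.matrix(m2$S)[, colnames(before)], before)
  expect_identical(m2$objective_id, "Z")

  expect_error(attach_objective(m, numeric(0)), "no coefficients")
  expect_error(attach_objective(m, c("ghost[c]" = 1)), "absent from model")
  expect_error(attach_objective(m, c("b[c]" = -1)), "strictly positive")
  expect_error(attach_objective(m2, c("b[c]" = 1)), "already exists")
})

test_that("internal reaction columns both consume and produce mass", {
  for (name in c("chain", "diamond", "mini_fix")) {
    model <- get_preset(name)$model
    internal <- !model$reactions$boundary
    for (j in which(internal)) {
      col <- model$reactions$stoichiometry[[j]]
      expect_true(any(col < 0) && any(col > 0),
                  info = paste(name, model$reactions$reaction_id[j]))
    }
  }
})
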