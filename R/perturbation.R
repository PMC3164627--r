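#' Delete genes in silico
#'
#' Evaluates every reaction's GPR rule with the given genes absent (all
#' other model genes present); reactions losing enzymatic support —
#' complexes missing a subunit, isozyme pairs with both members gone —
#' have both flux bounds set to zero.  Reactions whose rule still
#' evaluates `TRUE`, and GPR-less reactions, are untouched.  The
#' operation is idempotent.
#'
#' @param model a `"metabolic_model"`.
#' @param genes character vector of genes to remove (a vector of length
#'   two performs a double knockout, etc.).  Genes absent from the model
#'   trigger a warning and contribute nothing.
#' @return list with `model` (bounds-modified copy) and
#'   `disabled_reactions` (character vector).
#' @export
delete_gene <- function(model, genes) {
  stopifnot(inherits(model, "metabolic_model"))
  unknown <- setdiff(genes, model$genes)
  if (length(unknown)) {
    warn(paste0("genes not in model (no-op): ", comma(unknown)))
  }
  present <- setdiff(model$genes, genes)
  has_gpr <- !vapply(model$reactions$gpr, is.null, logical(1))
  off <- has_gpr & !vapply(model$reactions$gpr, eval_gpr, logical(1),
                           present = present)
  model$reactions$lower_bound[off] <- 0
  model$reactions$upper_bound[off] <- 0
  list(model = model,
       disabled_reactions = model$reactions$reaction_id[off])
}

#' Classify a knockout phenotype from its percent reduction
#'
#' Signs follow the convention: `"-"` a decrement in the nitrogen-fixation
#' objective (reduction above `tol_percent`), `"+"` an increment
#' (reduction below `-tol_percent`; unreachable by pure LP knockout,
#' where tightening bounds can never raise the optimum, but reachable in
#' bound-widening experiments), `"="` invariance.
#'
#' @param percent_reduction numeric vector, `100 * (1 - mutant/wildtype)`;
#'   negative values denote an increase.
#' @param tol_percent half-width of the invariance band, in percent.
#' @return character vector over `{"+", "=", "-"}`.
#' @export
classify_phenotype <- function(percent_reduction, tol_percent = 5) {
  ifelse(percent_reduction > tol_percent, "-",
         ifelse(percent_reduction < -tol_percent, "+", "="))
}

#' Knockout phenotype of a single gene
#'
#' Deletes the gene ([delete_gene()]), re-solves FBA, and quantifies the
#' mutant as the percentage of reduced objective activity relative to
#' the wild type.
#'
#' @inheritParams delete_gene
#' @param gene a single gene id.
#' @param wildtype optional precomputed wild-type `"fba_fit"` (saves one
#'   LP when scanning many genes).
#' @param tol_percent passed to [classify_phenotype()].
#' @param lethal_tol mutant objective at or below this counts as lethal.
#' @return one-row tibble: `gene`, `n_disabled`, `disabled_reactions`
#'   (list-column), `wildtype_objective`, `mutant_objective`,
#'   `percent_reduction`, `phenotype`, `lethal`.
#' @export
knockout_phenotype <- function(model, gene, wildtype = NULL,
                               tol_percent = 5, lethal_tol = 1e-6) {
  stopifnot(length(gene) == 1)
  if (is.null(wildtype)) wildtype <- solve_fba(model, mode = "plain")
  if (wildtype$status != "optimal") {
    abort("wild-type FBA is not optimal; cannot normalize knockout effects")
  }
  wt <- wildtype$objective_value
  if (wt <= lethal_tol) {
    abort("wild-type objective is numerically zero; cannot normalize")
  }
  del <- delete_gene(model, gene)
  mut_fit <- solve_fba(del$model, mode = "plain")
  mut <- if (mut_fit$status == "optimal") mut_fit$objective_value else 0
  pct <- 100 * (1 - mut / wt)
  tibble(
    gene = gene,
    n_disabled = length(del$disabled_reactions),
    disabled_reactions = list(del$disabled_reactions),
    wildtype_objective = wt,
    mutant_objective = mut,
    percent_reduction = pct,
    phenotype = classify_phenotype(pct, tol_percent),
    lethal = mut <= lethal_tol
  )
}

#' Knockout scan over many genes
#'
#' @inheritParams knockout_phenotype
#' @param genes genes to scan; default all model genes.
#' @return a `"knockout_result"` tibble, one row per gene (columns as in
#'   [knockout_phenotype()]).
#' @export
knockout_all <- function(model, genes = NULL, tol_percent = 5,
                         lethal_tol = 1e-6) {
  genes <- genes %||% model$genes
  wildtype <- solve_fba(model, mode = "plain")
  out <- purrr::map_dfr(genes, function(g) {
    knockout_phenotype(model, g, wildtype = wildtype,
                       tol_percent = tol_percent, lethal_tol = lethal_tol)
  })
  class(out) <- c("knockout_result", class(out))
  out
}

#' Robustness analysis of a single reaction
#'
#' Fixes the reaction flux to each grid value in turn (lower = upper =
#' value), re-solves FBA, and records the resulting objective; grid
#' points rendering the model infeasible are recorded as `NA`.  As the
#' optimum of an LP over a shrinking parametric constraint, the curve is
#' concave piecewise-linear in the fixed flux.
#'
#' @inheritParams delete_gene
#' @param reaction reaction id to clamp.
#' @param lo,hi grid end points (flux units).
#' @param n_points number of grid points (>= 2).
#' @return a `"robustness_curve"` tibble: `fixed_flux`,
#'   `objective_value`; attribute `reaction`.
#' @export
robustness_scan <- function(model, reaction, lo, hi, n_points = 21) {
  stopifnot(inherits(model, "metabolic_model"))
  if (!(reaction %in% model$reactions$reaction_id)) {
    abort(paste0("unknown reaction: '", reaction, "'"))
  }
  check_number(lo, "lo"); check_number(hi, "hi")
  if (lo > hi) abort("`lo` must be <= `hi`")
  if (n_points < 2) abort("`n_points` must be >= 2")
  grid <- seq(lo, hi, length.out = n_points)
  j <- match(reaction, model$reactions$reaction_id)
  vals <- vapply(grid, function(f) {
    m2 <- model
    m2$reactions$lower_bound[j] <- f
    m2$reactions$upper_bound[j] <- f
    fit <- solve_fba(m2, mode = "plain")
    if (fit$status == "optimal") fit$objective_value else NA_real_
  }, numeric(1))
  out <- tibble(fixed_flux = grid, objective_value = vals)
  attr(out, "reaction") <- reaction
  class(out) <- c("robustness_curve", class(out))
  out
}
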