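#' Consistency coefficient between predicted and experimental sets
#'
#' The consistency coefficient is the fraction of in-silico
#' predicted-active identifiers that were also detected experimentally:
#' `eta = |predicted intersect experimental| / |predicted|`, ranging
#' from 0 (no support) to 1 (every prediction supported).  Inputs are
#' treated as sets: duplicates never change the value.
#'
#' @param predicted character vector of predicted-active ids (genes or
#'   enzymes); must be non-empty after de-duplication.
#' @param experimental character vector of experimentally detected ids.
#' @return one-row tibble: `eta`, `overlap`, `n_predicted`.
#' @examples
#' consistency_coefficient(letters[1:4], letters[3:6])  # eta = 0.5
#' @export
consistency_coefficient <- function(predicted, experimental) {
  predicted <- unique(as.character(predicted))
  experimental <- unique(as.character(experimental))
  if (length(predicted) == 0) {
    abort("consistency coefficient is undefined for an empty predicted set")
  }
  overlap <- length(intersect(predicted, experimental))
  tibble(eta = overlap / length(predicted),
         overlap = overlap,
         n_predicted = length(predicted))
}

#' Hypergeometric enrichment of a set overlap
#'
#' Upper-tail probability `P(X >= overlap)` of drawing at least the
#' observed overlap when `n_predicted` ids are sampled without
#' replacement from a universe of `n_universe` ids of which
#' `n_experimental` are experimentally detected.
#'
#' @param overlap observed intersection size.
#' @param n_predicted size of the predicted (drawn) set.
#' @param n_experimental number of detected ids in the universe.
#' @param n_universe universe size.
#' @return the p-value (a bare number).
#' @export
hypergeometric_enrichment <- function(overlap, n_predicted,
                                      n_experimental, n_universe) {
  counts <- c(overlap, n_predicted, n_experimental, n_universe)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("all counts must be non-negative integers")
  }
  if (n_predicted > n_universe || n_experimental > n_universe) {
    abort("set sizes cannot exceed the universe")
  }
  if (overlap > min(n_predicted, n_experimental)) {
    abort("overlap cannot exceed either set size")
  }
  if (overlap < max(0, n_predicted + n_experimental - n_universe)) {
    abort("overlap below the feasible minimum for these counts")
  }
  phyper(overlap - 1, n_experimental, n_universe - n_experimental,
         n_predicted, lower.tail = FALSE)
}

#' Per-pathway three-way breakdown of predicted vs experimental
#'
#' For every pathway, counts the members that were (1) predicted in
#' silico but not detected experimentally, (2) consistently observed in
#' both schemes, and (3) experimentally detected but not predicted —
#' each intersected with the pathway's membership.
#'
#' @param map a `"pathway_map"` ([read_pathway_map()] /
#'   [as_pathway_map()]).
#' @param predicted,experimental character vectors of ids.
#' @param type `"gene"` or `"enzyme"` membership to break down.
#' @return tibble: `pathway_id`, `in_silico_only`, `both`,
#'   `experimental_only`.
#' @export
pathway_breakdown <- function(map, predicted, experimental,
                              type = c("gene", "enzyme")) {
  type <- match.arg(type)
  members <- pathway_members(map, type)
  predicted <- unique(as.character(predicted))
  experimental <- unique(as.character(experimental))
  purrr::map_dfr(names(members), function(pw) {
    pws <- members[[pw]]
    p <- intersect(predicted, pws)
    e <- intersect(experimental, pws)
    tibble(
      pathway_id = pw,
      in_silico_only = length(setdiff(p, e)),
      both = length(intersect(p, e)),
      experimental_only = length(setdiff(e, p))
    )
  })
}

#' Score a model's FBA-active sets against omics data
#'
#' Composes the concordance pipeline: extract the FBA-active enzyme and
#' gene sets ([active_sets()]), restrict them and the omics sets to the
#' scoring universe (by default the union of the pathway map's members,
#' the central core on which in-silico and experimental interpretations
#' are comparable), compute the gene and enzyme consistency coefficients,
#' attach hypergeometric enrichment p-values, and break the comparison
#' down per pathway.
#'
#' @param model the model.
#' @param fit an optimal `"fba_fit"` for `model`.
#' @param omics an [omics_gene_set()] (genes required; enzymes optional —
#'   when empty the enzyme-level scores are `NA`).
#' @param map a `"pathway_map"`.
#' @param universe `"pathways"` (default) restricts scoring to the
#'   pathway map's members; `"model"` uses all model genes/non-boundary
#'   reactions.
#' @param tol active-flux threshold passed to [active_sets()].
#' @return an object of class `"concordance_report"`; see
#'   [glance.concordance_report()] and [tidy.concordance_report()].
#' @export
score_model_vs_omics <- function(model, fit, omics, map,
                                 universe = c("pathways", "model"),
                                 tol = 1e-6) {
  stopifnot(inherits(omics, "omics_gene_set"))
  universe <- match.arg(universe)
  act <- active_sets(model, fit, tol = tol)

  if (universe == "pathways") {
    ug <- pathway_universe(map, "gene")
    ue <- pathway_universe(map, "enzyme")
  } else {
    ug <- model$genes
    ue <- model$reactions$reaction_id[!model$reactions$boundary &
      model$reactions$reaction_id != model$objective_id]
  }

  score_one <- function(pred, exp, uni, type) {
    pred <- intersect(pred, uni)
    exp <- intersect(exp, uni)
    if (length(pred) == 0) {
      abort(paste0("no predicted ", type, "s fall in the scoring universe"))
    }
    cc <- consistency_coefficient(pred, exp)
    p <- hypergeometric_enrichment(cc$overlap, cc$n_predicted,
                                   length(exp), length(uni))
    list(eta = cc$eta, overlap = cc$overlap, n_predicted = cc$n_predicted,
         n_experimental = length(exp), n_universe = length(uni), p = p,
         predicted = pred, experimental = exp)
  }

  genes <- score_one(act$genes, omics$genes, ug, "gene")
  enzymes <- if (length(omics$enzymes) > 0) {
    score_one(act$enzymes, omics$enzymes, ue, "enzyme")
  } else {
    NULL
  }

  per_pathway <- bind_rows(
    mutate(pathway_breakdown(map, genes$predicted, genes$experimental,
                             "gene"), set_type = "gene"),
    if (!is.null(enzymes)) {
      mutate(pathway_breakdown(map, enzymes$predicted,
                               enzymes$experimental, "enzyme"),
             set_type = "enzyme")
    }
  )

  structure(
    list(genes = genes, enzymes = enzymes, per_pathway = per_pathway,
         omics_label = omics$label, universe = universe, tol = tol),
    class = "concordance_report"
  )
}

#' @describeIn score_model_vs_omics one-row summary: `eta_genes`,
#'   `eta_enzymes`, overlap and set-size counts, and hypergeometric
#'   p-values (`NA` where no enzyme-level omics were supplied).
#' @method glance concordance_report
#' @param x a `"concordance_report"`.
#' @param ... unused.
#' @export
glance.concordance_report <- function(x, ...) {
  g <- x$genes; e <- x$enzymes
  tibble(
    eta_genes = g$eta,
    eta_enzymes = if (is.null(e)) NA_real_ else e$eta,
    overlap_genes = g$overlap,
    predicted_genes = g$n_predicted,
    overlap_enzymes = if (is.null(e)) NA_integer_ else e$overlap,
    predicted_enzymes = if (is.null(e)) NA_integer_ else e$n_predicted,
    p_genes = g$p,
    p_enzymes = if (is.null(e)) NA_real_ else e$p
  )
}

#' @describeIn score_model_vs_omics the per-pathway three-way breakdown
#'   in long form (`pathway_id`, `set_type`, `in_silico_only`, `both`,
#'   `experimental_only`).
#' @method tidy concordance_report
#' @export
tidy.concordance_report <- function(x, ...) x$per_pathway

#' @export
print.concordance_report <- function(x, ...) {
  g <- glance(x)
  cat("<concordance_report> vs '", x$omics_label, "' (universe: ",
      x$universe, ")\n", sep = "")
  cat(sprintf("  eta_genes   = %s (%d / %d), p = %.3g\n",
              format(round_half_up(g$eta_genes, 4), nsmall = 4),
              g$overlap_genes, g$predicted_genes, g$p_genes))
  if (!is.null(x$enzymes)) {
    cat(sprintf("  eta_enzymes = %s (%d / %d), p = %.3g\n",
                format(round_half_up(g$eta_enzymes, 4), nsmall = 4),
                g$overlap_enzymes, g$predicted_enzymes, g$p_enzymes))
  }
  invisible(x)
}
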