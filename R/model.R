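#' Build a metabolic model from a reaction table
#'
#' Assembles the stoichiometric matrix `S` (rows = metabolites, columns =
#' reactions) from a tidy reaction table.  Each row must carry a unique
#' `reaction_id` and a `formula` in the dialect of
#' [parse_reaction_formula()]; optional columns are `reaction_name`,
#' `gpr` (boolean rule string, see [parse_gpr()]), `lower_bound`,
#' `upper_bound` and `subsystem`.  Missing bounds default to
#' `[0, default_bound]` for irreversible and `[-default_bound,
#' default_bound]` for reversible reactions, the usual surrogate for an
#' unconstrained flux.
#'
#' Metabolite identifiers carry a compartment suffix, `[c]` for cytoplasm
#' and `[e]` for the external (plant/nodule) space by default; additional
#' compartments can be registered through `compartments`.
#'
#' @param reactions data frame of reactions (one per row).
#' @param metabolites optional character vector (or data frame with an
#'   `id` column) declaring the admissible metabolites; formulas that
#'   mention undeclared metabolites then raise an error listing them.
#'   When `NULL` the metabolite list is derived from the formulas in
#'   order of first appearance.
#' @param compartments registered compartment suffixes.
#' @param default_bound magnitude used for absent bounds.
#' @return an object of class `"metabolic_model"` with elements
#'   `metabolites` (tibble), `reactions` (tibble with parsed
#'   stoichiometry and GPR list-columns), `genes`, `S` (sparse matrix)
#'   and `objective_id` (`NA` until [attach_objective()]).
#' @examples
#' rxns <- tibble::tibble(
#'   reaction_id = c("EX_a", "T"),
#'   formula = c("-> a[e]", "a[e] -> b[c]"),
#'   gpr = c("", "g1"),
#'   lower_bound = c(0, NA), upper_bound = c(5, NA)
#' )
#' m <- build_model(rxns)
#' m$S
#' @export
build_model <- function(reactions, metabolites = NULL,
                        compartments = c("c", "e"), default_bound = 1000) {
  reactions <- as_tibble(reactions)
  if (!all(c("reaction_id", "formula") %in% names(reactions))) {
    abort("`reactions` needs at least columns `reaction_id` and `formula`")
  }
  dup <- unique(reactions$reaction_id[duplicated(reactions$reaction_id)])
  if (length(dup)) {
    abort(paste0("duplicate reaction_id: ", comma(dup)))
  }

  n <- nrow(reactions)
  opt_col <- function(col, default) {
    if (col %in% names(reactions)) reactions[[col]] else rep(default, n)
  }
  name <- opt_col("reaction_name", NA_character_)
  gpr_rule <- opt_col("gpr", NA_character_)
  lb <- as.numeric(opt_col("lower_bound", NA_real_))
  ub <- as.numeric(opt_col("upper_bound", NA_real_))
  subsystem <- opt_col("subsystem", NA_character_)

  parsed <- vector("list", n)
  reversible <- logical(n)
  for (i in seq_len(n)) {
    p <- tryCatch(
      parse_reaction_formula(reactions$formula[i]),
      error = function(e) {
        abort(paste0("reaction '", reactions$reaction_id[i], "' (row ", i,
                     "): ", conditionMessage(e)))
      }
    )
    parsed[[i]] <- p$stoichiometry
    reversible[i] <- p$reversible
  }

  gprs <- lapply(seq_len(n), function(i) {
    tryCatch(parse_gpr(gpr_rule[i]), error = function(e) {
      abort(paste0("reaction '", reactions$reaction_id[i], "': ",
                   conditionMessage(e)))
    })
  })

  lb <- ifelse(is.na(lb), ifelse(reversible, -default_bound, 0), lb)
  ub <- ifelse(is.na(ub), default_bound, ub)
  bad <- which(lb > ub)
  if (length(bad)) {
    abort(paste0("lower_bound > upper_bound for: ",
                 comma(reactions$reaction_id[bad])))
  }
  bad <- which(!reversible & lb < 0)
  if (length(bad)) {
    abort(paste0("irreversible reactions with negative lower bound: ",
                 comma(reactions$reaction_id[bad])))
  }

  used <- unique(unlist(lapply(parsed, names)))
  if (is.null(metabolites)) {
    met_ids <- used
  } else {
    met_ids <- if (is.data.frame(metabolites)) metabolites$id else metabolites
    unknown <- setdiff(used, met_ids)
    if (length(unknown)) {
      abort(paste0("formulas reference undeclared metabolites: ",
                   comma(unknown)))
    }
  }

  comp <- sub("^.*\\[([^][]+)\\]$", "\\1", met_ids)
  no_suffix <- !grepl("\\[[^][]+\\]$", met_ids)
  if (any(no_suffix)) {
    abort(paste0("metabolite ids must end in a [compartment] suffix: ",
                 comma(met_ids[no_suffix])))
  }
  bad_comp <- !(comp %in% compartments)
  if (any(bad_comp)) {
    abort(paste0("unregistered compartment in: ", comma(met_ids[bad_comp]),
                 " (registered: ", comma(compartments), ")"))
  }

  met_tbl <- tibble(
    id = met_ids,
    name = sub("\\[[^][]+\\]$", "", met_ids),
    compartment = comp
  )

  i_idx <- integer(0); j_idx <- integer(0); x_val <- numeric(0)
  row_of <- setNames(seq_along(met_ids), met_ids)
  for (j in seq_len(n)) {
    st <- parsed[[j]]
    i_idx <- c(i_idx, row_of[names(st)])
    j_idx <- c(j_idx, rep(j, length(st)))
    x_val <- c(x_val, unname(st))
  }
  S <- Matrix::sparseMatrix(
    i = i_idx, j = j_idx, x = x_val,
    dims = c(length(met_ids), n),
    dimnames = list(met_ids, reactions$reaction_id)
  )

  boundary <- vapply(parsed, function(st) {
    all(st < 0) || all(st > 0)
  }, logical(1))

  rxn_tbl <- tibble(
    reaction_id = reactions$reaction_id,
    reaction_name = name,
    stoichiometry = parsed,
    gpr = gprs,
    gpr_rule = vapply(gprs, render_gpr, character(1)),
    lower_bound = lb,
    upper_bound = ub,
    reversible = reversible,
    boundary = boundary,
    subsystem = subsystem
  )

  structure(
    list(
      metabolites = met_tbl,
      reactions = rxn_tbl,
      genes = sort(unique(unlist(lapply(gprs, gpr_genes)))),
      S = S,
      compartments = compartments,
      objective_id = NA_character_
    ),
    class = "metabolic_model"
  )
}

#' Nitrogen-fixation objective coefficients
#'
#' The symbiotic nitrogen-fixation objective is a linear combination of
#' metabolite drains, all with unit coefficients: glycogen, lysine and
#' poly-hydroxybutyrate in the cytoplasm plus exported alanine, aspartate
#' and ammonium.  The extended form adds L-valine and L-histidine
#' (cytoplasmic by default; the compartment is configurable because it is
#' a modeling choice).
#'
#' @param extended include the valine and histidine terms.
#' @param extra_compartment compartment suffix for the two added terms.
#' @return tibble with columns `metabolite`, `coefficient`.
#' @export
zfix_objective <- function(extended = TRUE, extra_compartment = "c") {
  base <- c("glycogen[c]", "lys[c]", "phb[c]", "ala[e]", "asp[e]", "nh4[e]")
  mets <- if (extended) {
    c(base, paste0(c("val[", "his["), extra_compartment, "]"))
  } else {
    base
  }
  tibble(metabolite = mets, coefficient = 1)
}

#' Attach a metabolite-production objective as a drain reaction
#'
#' The objective "maximize weighted production of target metabolites" is
#' realized as a single irreversible drain reaction consuming each target
#' metabolite `i` with coefficient `-c_i`; under the steady-state
#' constraint the drain flux then equals the net synthesis the network
#' can sustain, and FBA maximizes it.
#'
#' @param model a `"metabolic_model"`.
#' @param objective coefficients `c_i > 0` per metabolite: a named numeric
#'   vector, or a data frame with columns `metabolite` and `coefficient`
#'   (e.g. [zfix_objective()]).
#' @param id reaction id for the drain (default `"Z"`).
#' @param upper_bound upper flux bound of the drain.
#' @return the model with one extra column in `S`, the drain appended to
#'   `reactions`, and `objective_id` set.  Existing columns of `S` are
#'   unchanged.
#' @export
attach_objective <- function(model, objective, id = "Z", upper_bound = 1000) {
  stopifnot(inherits(model, "metabolic_model"))
  if (is.data.frame(objective)) {
    coef <- setNames(objective$coefficient, objective$metabolite)
  } else {
    coef <- objective
  }
  if (length(coef) == 0) abort("objective has no coefficients")
  if (is.null(names(coef)) || any(!nzchar(names(coef)))) {
    abort("objective coefficients must be named by metabolite id")
  }
  if (any(!is.finite(coef)) || any(coef <= 0)) {
    abort("objective coefficients must be strictly positive")
  }
  missing <- setdiff(names(coef), model$metabolites$id)
  if (length(missing)) {
    abort(paste0("objective metabolites absent from model: ", comma(missing)))
  }
  if (id %in% model$reactions$reaction_id) {
    abort(paste0("reaction id '", id, "' already exists"))
  }

  st <- -coef
  new_row <- tibble(
    reaction_id = id,
    reaction_name = "metabolite-production objective drain",
    stoichiometry = list(st),
    gpr = list(NULL),
    gpr_rule = "",
    lower_bound = 0,
    upper_bound = upper_bound,
    reversible = FALSE,
    boundary = TRUE,
    subsystem = "objective"
  )
  col <- Matrix::sparseMatrix(
    i = match(names(st), model$metabolites$id),
    j = rep(1L, length(st)),
    x = unname(st),
    dims = c(nrow(model$metabolites), 1),
    dimnames = list(model$metabolites$id, id)
  )
  model$S <- cbind(model$S, col)
  model$reactions <- bind_rows(model$reactions, new_row)
  model$objective_id <- id
  model
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ",
      nrow(x$metabolites), " metabolites, ",
      nrow(x$reactions), " reactions, ",
      length(x$genes), " genes\n", sep = "")
  if (!is.na(x$objective_id)) {
    st <- x$reactions$stoichiometry[[match(x$objective_id, x$reactions$reaction_id)]]
    cat("objective drain '", x$objective_id, "' over: ",
        comma(names(st)), "\n", sep = "")
  }
  invisible(x)
}
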