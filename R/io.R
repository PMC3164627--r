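#' Parse a reaction formula string
#'
#' Formula dialect: terms `coef met[comp]` joined by `+` (spaces around
#' `+` required, missing coefficient = 1), sides separated by `->`
#' (irreversible) or `<=>` (reversible).  An empty side denotes a
#' boundary reaction (exchange, sink or demand), e.g. `"a[e] ->"` or
#' `"-> mal[e]"`.  Left-side coefficients come out negative (consumed),
#' right-side positive (produced); a metabolite appearing on both sides
#' is netted, and a formula whose net stoichiometry is empty (a null
#' transformation such as `"a[c] -> a[c]"`) is rejected.
#'
#' @param formula a single string.
#' @return list with `stoichiometry` (named numeric vector) and
#'   `reversible` (logical).
#' @examples
#' parse_reaction_formula("2 a[c] + b[c] <=> c[e]")
#' @export
parse_reaction_formula <- function(formula) {
  if (!is.character(formula) || length(formula) != 1 || is.na(formula)) {
    abort("`formula` must be a single string")
  }
  reversible <- grepl("<=>", formula, fixed = TRUE)
  arrow <- if (reversible) "<=>" else "->"
  parts <- strsplit(formula, arrow, fixed = TRUE)[[1]]
  if (!grepl(arrow, formula, fixed = TRUE) || length(parts) > 2) {
    abort(paste0("formula must contain exactly one '->' or '<=>': '",
                 formula, "'"))
  }
  lhs <- if (length(parts) >= 1) parts[1] else ""
  rhs <- if (length(parts) == 2) parts[2] else ""

  st <- c(parse_formula_side(lhs, -1, formula),
          parse_formula_side(rhs, +1, formula))
  if (length(st) == 0) {
    abort(paste0("formula has no metabolites: '", formula, "'"))
  }
  st <- tapply(st, names(st), sum)
  st <- st[st != 0]
  if (length(st) == 0) {
    abort(paste0("null transformation (all coefficients cancel): '",
                 formula, "'"))
  }
  # tapply sorts by name; restore nothing — order is irrelevant downstream
  list(stoichiometry = setNames(as.numeric(st), names(st)),
       reversible = reversible)
}

parse_formula_side <- function(side, sign, formula) {
  side <- trimws(side)
  if (!nzchar(side)) return(numeric(0))
  terms <- trimws(strsplit(side, "\\s+\\+\\s+")[[1]])
  out <- numeric(0)
  for (term in terms) {
    if (!nzchar(term)) {
      abort(paste0("empty term in formula '", formula, "'"))
    }
    m <- regmatches(term, regexec(
      "^(?:([0-9]*\\.?[0-9]+(?:[eE][+-]?[0-9]+)?)\\s+)?(\\S+)$", term))[[1]]
    if (length(m) == 0) {
      abort(paste0("malformed term '", term, "' in formula '", formula, "'"))
    }
    coef <- if (nzchar(m[2])) as.numeric(m[2]) else 1
    out <- c(out, setNames(sign * coef, m[3]))
  }
  out
}

#' Read a metabolic reconstruction table
#'
#' Reads the tab-separated reconstruction dialect (header:
#' `reaction_id`, `reaction_name`, `formula`, `gpr`, `lb`, `ub`,
#' `subsystem`; UTF-8; blank bounds take the defaults described in
#' [build_model()]) and assembles the model.  Reaction, gene and
#' metabolite counts are reported via a message so that inventory checks
#' against a published reconstruction are immediate.
#'
#' @param path file path.
#' @inheritParams build_model
#' @param quiet suppress the count message.
#' @return a `"metabolic_model"`.
#' @export
read_reconstruction <- function(path, compartments = c("c", "e"),
                                default_bound = 1000, quiet = FALSE) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    reaction_id = readr::col_character(),
    reaction_name = readr::col_character(),
    formula = readr::col_character(),
    gpr = readr::col_character(),
    lb = readr::col_double(),
    ub = readr::col_double(),
    subsystem = readr::col_character()
  ), progress = FALSE)
  need <- c("reaction_id", "formula")
  if (!all(need %in% names(tbl))) {
    abort(paste0("reconstruction table must have columns: ",
                 comma(need), " (got: ", comma(names(tbl)), ")"))
  }
  model <- build_model(
    tibble(
      reaction_id = tbl$reaction_id,
      reaction_name = tbl$reaction_name %||% NA_character_,
      formula = tbl$formula,
      gpr = tbl$gpr %||% NA_character_,
      lower_bound = tbl$lb %||% NA_real_,
      upper_bound = tbl$ub %||% NA_real_,
      subsystem = tbl$subsystem %||% NA_character_
    ),
    compartments = compartments, default_bound = default_bound
  )
  if (!quiet) {
    inform(paste0("read_reconstruction: ", nrow(model$reactions),
                  " reactions, ", length(model$genes), " genes, ",
                  nrow(model$metabolites), " metabolites"))
  }
  model
}

#' Write a model back to the reconstruction dialect
#'
#' Inverse of [read_reconstruction()] on canonical tables: one reaction
#' per row, formulas re-rendered from the parsed stoichiometry (sorted
#' metabolite order within each side), GPRs in canonical form.
#'
#' @param model a `"metabolic_model"`.
#' @param path output file path.
#' @param include_objective keep the attached objective drain row.
#' @return `path`, invisibly.
#' @export
write_reconstruction <- function(model, path, include_objective = FALSE) {
  stopifnot(inherits(model, "metabolic_model"))
  rx <- model$reactions
  if (!include_objective && !is.na(model$objective_id)) {
    rx <- rx[rx$reaction_id != model$objective_id, ]
  }
  tbl <- tibble(
    reaction_id = rx$reaction_id,
    reaction_name = rx$reaction_name,
    formula = vapply(seq_len(nrow(rx)), function(i) {
      render_formula(rx$stoichiometry[[i]], rx$reversible[i])
    }, character(1)),
    gpr = rx$gpr_rule,
    lb = rx$lower_bound,
    ub = rx$upper_bound,
    subsystem = rx$subsystem
  )
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(path)
}

render_formula <- function(stoichiometry, reversible) {
  side <- function(st) {
    st <- st[order(names(st))]
    paste(vapply(seq_along(st), function(k) {
      coef <- abs(st[k])
      if (coef == 1) names(st)[k] else paste(format(coef), names(st)[k])
    }, character(1)), collapse = " + ")
  }
  lhs <- side(stoichiometry[stoichiometry < 0])
  rhs <- side(stoichiometry[stoichiometry > 0])
  arrow <- if (reversible) "<=>" else "->"
  trimws(paste(lhs, arrow, rhs))
}

#' Read a gene or enzyme set from a plain-text list
#'
#' One identifier per line; blank lines and `#` comments ignored;
#' whitespace trimmed; duplicates dropped (sets, not multisets).
#'
#' @param path file path.
#' @param label set label, e.g. `"transcriptome"` or `"proteome"`.
#' @return an [omics_gene_set()].
#' @export
read_gene_set <- function(path, label) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  ids <- unique(lines[nzchar(lines)])
  if (length(ids) == 0) {
    warn(paste0("gene-set file '", path, "' is empty"))
  }
  omics_gene_set(label, genes = ids)
}

#' Construct an omics-derived gene/enzyme set
#'
#' @param label non-empty label.
#' @param genes character vector of gene ids (de-duplicated).
#' @param enzymes optional character vector of enzyme (reaction) ids.
#' @return an object of class `"omics_gene_set"`.
#' @export
omics_gene_set <- function(label, genes = character(0), enzymes = character(0)) {
  if (!is.character(label) || length(label) != 1 || !nzchar(label)) {
    abort("`label` must be a non-empty string")
  }
  structure(
    list(label = label, genes = unique(as.character(genes)),
         enzymes = unique(as.character(enzymes))),
    class = "omics_gene_set"
  )
}

#' @export
print.omics_gene_set <- function(x, ...) {
  cat("<omics_gene_set> '", x$label, "': ", length(x$genes), " genes, ",
      length(x$enzymes), " enzymes\n", sep = "")
  invisible(x)
}

#' Read a pathway membership map
#'
#' TSV with header `pathway_id`, `member_type`, `member_id`;
#' `member_type` is `gene` or `enzyme`.  The map drives the
#' consistency-coefficient scoring universe and the per-pathway
#' breakdowns (by default 22 pathways for the rhizobial analysis, but any
#' number is accepted).
#'
#' @param path file path.
#' @return a `"pathway_map"` tibble (`pathway_id`, `member_type`,
#'   `member_id`), de-duplicated.
#' @export
read_pathway_map <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    pathway_id = readr::col_character(),
    member_type = readr::col_character(),
    member_id = readr::col_character()
  ), progress = FALSE)
  as_pathway_map(tbl)
}

#' Coerce a data frame to a pathway map
#'
#' @param x data frame with columns `pathway_id`, `member_type`
#'   (`"gene"`/`"enzyme"`), `member_id`.
#' @return a `"pathway_map"` tibble.
#' @export
as_pathway_map <- function(x) {
  x <- as_tibble(x)
  need <- c("pathway_id", "member_type", "member_id")
  if (!all(need %in% names(x))) {
    abort(paste0("pathway map needs columns: ", comma(need)))
  }
  bad <- setdiff(unique(x$member_type), c("gene", "enzyme"))
  if (length(bad)) {
    abort(paste0("unknown member_type: ", comma(bad)))
  }
  if (nrow(x) == 0) abort("pathway map is empty")
  empty <- setdiff(unique(x$pathway_id), x$pathway_id[nzchar(x$member_id)])
  if (length(empty)) abort(paste0("pathways with no members: ", comma(empty)))
  out <- distinct(x[, need])
  class(out) <- c("pathway_map", class(out))
  out
}

#' Pathway-map accessors
#'
#' `pathway_members()` returns a named list (one character vector per
#' pathway) for the chosen member type; `pathway_universe()` the union of
#' all members of that type, i.e. the default scoring universe for the
#' consistency coefficient.
#'
#' @param map a `"pathway_map"`.
#' @param type `"gene"` or `"enzyme"`.
#' @return a named list, or a character vector.
#' @export
pathway_members <- function(map, type = c("gene", "enzyme")) {
  type <- match.arg(type)
  sub <- map[map$member_type == type, ]
  split(sub$member_id, sub$pathway_id)
}

#' @rdname pathway_members
#' @export
pathway_universe <- function(map, type = c("gene", "enzyme")) {
  type <- match.arg(type)
  unique(map$member_id[map$member_type == type])
}
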