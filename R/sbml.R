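# SBML Level 3 export/import (core + fbc version 2: flux bounds as
# constant parameters, GPRs as gene-product associations).  Identifiers
# follow the COBRA convention: metabolite "x[c]" <-> species "M_x_c",
# reaction "R_<id>", gene "G_<id>".

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

sbml_sid <- function(x) gsub("[^A-Za-z0-9_]", "_", x)

species_sid <- function(met_id) {
  paste0("M_", sbml_sid(sub("\\[([^][]+)\\]$", "_\\1", met_id)))
}

#' Export a model to SBML
#'
#' Writes an SBML Level 3 Version 1 document with the fbc-v2 extension:
#' flux bounds become constant parameters referenced per reaction, GPR
#' rules become `geneProductAssociation` trees, and the attached
#' objective (if any) becomes an fbc maximization objective.  The file
#' is readable by standard constraint-based tools and by [read_sbml()].
#'
#' @param model a `"metabolic_model"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_sbml <- function(model, path) {
  stopifnot(inherits(model, "metabolic_model"))
  doc <- xml2::xml_new_root(
    "sbml",
    xmlns = SBML_NS, "xmlns:fbc" = FBC_NS,
    level = "3", version = "1", "fbc:required" = "false"
  )
  mdl <- xml2::xml_add_child(doc, "model", id = "model",
                             "fbc:strict" = "true")

  comps <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cmp in model$compartments) {
    xml2::xml_add_child(comps, "compartment", id = cmp, constant = "true")
  }

  sps <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    xml2::xml_add_child(
      sps, "species",
      id = species_sid(m$id), name = m$id, compartment = m$compartment,
      hasOnlySubstanceUnits = "false", boundaryCondition = "false",
      constant = "false"
    )
  }

  pars <- xml2::xml_add_child(mdl, "listOfParameters")
  rx <- model$reactions
  for (i in seq_len(nrow(rx))) {
    rid <- sbml_sid(rx$reaction_id[i])
    xml2::xml_add_child(pars, "parameter", id = paste0("lb_", rid),
                        value = format(rx$lower_bound[i]), constant = "true")
    xml2::xml_add_child(pars, "parameter", id = paste0("ub_", rid),
                        value = format(rx$upper_bound[i]), constant = "true")
  }

  rxs <- xml2::xml_add_child(mdl, "listOfReactions")
  for (i in seq_len(nrow(rx))) {
    rid <- sbml_sid(rx$reaction_id[i])
    rnode <- xml2::xml_add_child(
      rxs, "reaction",
      id = paste0("R_", rid), name = rx$reaction_id[i],
      reversible = tolower(as.character(rx$reversible[i])), fast = "false",
      "fbc:lowerFluxBound" = paste0("lb_", rid),
      "fbc:upperFluxBound" = paste0("ub_", rid)
    )
    st <- rx$stoichiometry[[i]]
    subs <- st[st < 0]; prods <- st[st > 0]
    if (length(subs)) {
      ln <- xml2::xml_add_child(rnode, "listOfReactants")
      for (k in seq_along(subs)) {
        xml2::xml_add_child(ln, "speciesReference",
                            species = species_sid(names(subs)[k]),
                            stoichiometry = format(abs(subs[k])),
                            constant = "true")
      }
    }
    if (length(prods)) {
      ln <- xml2::xml_add_child(rnode, "listOfProducts")
      for (k in seq_along(prods)) {
        xml2::xml_add_child(ln, "speciesReference",
                            species = species_sid(names(prods)[k]),
                            stoichiometry = format(prods[k]),
                            constant = "true")
      }
    }
    if (!is.null(rx$gpr[[i]])) {
      ga <- xml2::xml_add_child(rnode, "fbc:geneProductAssociation")
      add_gpr_xml(ga, rx$gpr[[i]])
    }
  }

  gps <- xml2::xml_add_child(mdl, "fbc:listOfGeneProducts")
  for (g in model$genes) {
    xml2::xml_add_child(gps, "fbc:geneProduct",
                        "fbc:id" = paste0("G_", sbml_sid(g)),
                        "fbc:label" = g)
  }

  if (!is.na(model$objective_id)) {
    objs <- xml2::xml_add_child(mdl, "fbc:listOfObjectives",
                                "fbc:activeObjective" = "obj")
    obj <- xml2::xml_add_child(objs, "fbc:objective", "fbc:id" = "obj",
                               "fbc:type" = "maximize")
    lof <- xml2::xml_add_child(obj, "fbc:listOfFluxObjectives")
    xml2::xml_add_child(lof, "fbc:fluxObjective",
                        "fbc:reaction" = paste0("R_", sbml_sid(model$objective_id)),
                        "fbc:coefficient" = "1")
  }

  xml2::write_xml(doc, path)
  invisible(path)
}

add_gpr_xml <- function(parent, gpr) {
  if (gpr$type == "gene") {
    xml2::xml_add_child(parent, "fbc:geneProductRef",
                        "fbc:geneProduct" = paste0("G_", sbml_sid(gpr$gene)))
  } else {
    node <- xml2::xml_add_child(parent, paste0("fbc:", gpr$type))
    for (a in gpr$args) add_gpr_xml(node, a)
  }
}

#' Read an SBML model written by [export_sbml()]
#'
#' Parses SBML L3 + fbc-v2 back into a `"metabolic_model"`; species map
#' to `name[compartment]` metabolite ids, fbc flux-bound parameters to
#' bounds, and gene-product associations to GPR rules.
#'
#' @param path SBML file path.
#' @return a `"metabolic_model"`.
#' @export
read_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(s = SBML_NS, fbc = FBC_NS)

  sp_nodes <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  sp_id <- xml2::xml_attr(sp_nodes, "id")
  sp_name <- xml2::xml_attr(sp_nodes, "name")
  sp_comp <- xml2::xml_attr(sp_nodes, "compartment")
  met_of_species <- setNames(
    ifelse(is.na(sp_name),
           paste0(sub("^M_", "", sp_id), "[", sp_comp, "]"),
           sp_name),
    sp_id
  )

  par_nodes <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  par_val <- setNames(as.numeric(xml2::xml_attr(par_nodes, "value")),
                      xml2::xml_attr(par_nodes, "id"))

  gp_nodes <- xml2::xml_find_all(doc, ".//fbc:listOfGeneProducts/fbc:geneProduct", ns)
  gene_of_gp <- setNames(xml2::xml_attr(gp_nodes, "label"),
                         xml2::xml_attr(gp_nodes, "id"))

  obj_rxn <- xml2::xml_attr(
    xml2::xml_find_first(doc, ".//fbc:fluxObjective", ns), "reaction")

  rx_nodes <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  rows <- purrr::map_dfr(rx_nodes, function(node) {
    rid_raw <- xml2::xml_attr(node, "id")
    rid <- xml2::xml_attr(node, "name")
    if (is.na(rid)) rid <- sub("^R_", "", rid_raw)
    reversible <- identical(xml2::xml_attr(node, "reversible"), "true")

    side <- function(xpath) {
      refs <- xml2::xml_find_all(node, xpath, ns)
      st <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      setNames(st, met_of_species[xml2::xml_attr(refs, "species")])
    }
    subs <- side("./s:listOfReactants/s:speciesReference")
    prods <- side("./s:listOfProducts/s:speciesReference")
    fml <- render_formula(c(-subs, prods), reversible)

    ga <- xml2::xml_find_first(node, "./fbc:geneProductAssociation/*", ns)
    rule <- if (inherits(ga, "xml_missing")) "" else {
      render_gpr(gpr_from_xml(ga, gene_of_gp, ns))
    }

    tibble(
      reaction_id = rid,
      formula = fml,
      gpr = rule,
      lower_bound = unname(par_val[xml2::xml_attr(node, "lowerFluxBound")]),
      upper_bound = unname(par_val[xml2::xml_attr(node, "upperFluxBound")]),
      is_objective = identical(rid_raw, obj_rxn)
    )
  })

  comp_nodes <- xml2::xml_find_all(doc, ".//s:listOfCompartments/s:compartment", ns)
  comps <- xml2::xml_attr(comp_nodes, "id")

  obj_row <- which(rows$is_objective)
  model <- build_model(rows[setdiff(seq_len(nrow(rows)), obj_row),
                            c("reaction_id", "formula", "gpr",
                              "lower_bound", "upper_bound")],
                       compartments = comps)
  if (length(obj_row)) {
    st <- parse_reaction_formula(rows$formula[obj_row])$stoichiometry
    model <- attach_objective(model, -st[st < 0],
                              id = rows$reaction_id[obj_row],
                              upper_bound = rows$upper_bound[obj_row])
  }
  model
}

gpr_from_xml <- function(node, gene_of_gp, ns) {
  tag <- xml2::xml_name(node)
  if (tag == "geneProductRef") {
    gp <- xml2::xml_attr(node, "geneProduct")
    gpr_leaf(unname(gene_of_gp[gp]))
  } else {
    kids <- xml2::xml_children(node)
    gpr_node(tag, lapply(kids, gpr_from_xml, gene_of_gp = gene_of_gp, ns = ns))
  }
}
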