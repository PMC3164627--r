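#' Assemble a pipeline run configuration
#'
#' Collects the paths, objective specification, tolerances and mode
#' flags that [full_run()] needs.  Defaults reproduce the analysis
#' settings: the extended eight-metabolite nitrogen-fixation objective,
#' z-score threshold 1.65, FVA at the full optimum, parsimonious flux
#' representative.
#'
#' @param model path to a reconstruction TSV ([read_reconstruction()]),
#'   or the name of a toy preset (`"chain"`, `"diamond"`, `"mini_fix"`).
#' @param outdir output directory (created if absent).
#' @param omics optional path to a gene-list file, or an
#'   [omics_gene_set()]; when `NULL` the concordance stage is skipped.
#' @param pathway_map optional path to a pathway-map TSV or a
#'   `"pathway_map"`; presets supply their own when `NULL`.
#' @param objective `"extended"`, `"base"`, or a named coefficient
#'   vector.
#' @param active_tol,fva_tol,phenotype_tol tolerances: active-flux
#'   threshold, null-variability range width, phenotype percent band.
#' @param parsimonious use the parsimonious flux representative.
#' @param optimum_fraction FVA optimum fraction.
#' @param zscore_threshold transcriptome selection threshold.
#' @param seed integer seed recorded in the manifest.
#' @return a `"run_config"` list.
#' @export
run_config <- function(model, outdir, omics = NULL, pathway_map = NULL,
                       objective = "extended",
                       active_tol = 1e-6, fva_tol = 1e-6,
                       phenotype_tol = 5, parsimonious = TRUE,
                       optimum_fraction = 1.0, zscore_threshold = 1.65,
                       seed = 1L) {
  for (tl in c(active_tol, fva_tol, phenotype_tol)) {
    if (!is.numeric(tl) || tl <= 0) abort("all tolerances must be > 0")
  }
  structure(
    list(model = model, outdir = outdir, omics = omics,
         pathway_map = pathway_map, objective = objective,
         active_tol = active_tol, fva_tol = fva_tol,
         phenotype_tol = phenotype_tol, parsimonious = parsimonious,
         optimum_fraction = optimum_fraction,
         zscore_threshold = zscore_threshold, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Load a run configuration from YAML
#'
#' Field names mirror the arguments of [run_config()]; unknown fields
#' raise an error naming them.
#'
#' @param path YAML file path.
#' @return a `"run_config"`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    abort(paste0("unknown config fields: ", comma(unknown)))
  }
  missing <- setdiff(c("model", "outdir"), names(raw))
  if (length(missing)) {
    abort(paste0("config is missing required fields: ", comma(missing)))
  }
  do.call(run_config, raw)
}

#' Run the full pipeline
#'
#' Chains model loading, FBA, FVA, null-variability core extraction,
#' a whole-genome knockout scan and (when omics and a pathway map are
#' supplied) concordance scoring, writing each stage's table to
#' `outdir`: `fluxes.tsv`, `fva.tsv`, `core_reactions.txt`,
#' `knockouts.tsv`, `concordance.json`, and `manifest.json` (package
#' version, configuration hash and seed, so that deterministic runs can
#' be reproduced byte for byte).  A stage failure aborts with the stage
#' name; earlier outputs are left in place.
#'
#' @param config a `"run_config"` ([run_config()]) or the path to a YAML
#'   file for [read_run_config()].
#' @return (invisibly) a list of output paths plus the in-memory stage
#'   results.
#' @export
full_run <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }

  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()

  preset <- NULL
  model <- stage("load_model", {
    if (config$model %in% c("chain", "diamond", "mini_fix")) {
      preset <- make_toy_network(config$model)
      preset$model
    } else {
      m <- read_reconstruction(config$model, quiet = TRUE)
      obj <- if (is.character(config$objective)) {
        zfix_objective(extended = identical(config$objective, "extended"))
      } else {
        unlist(config$objective)
      }
      attach_objective(m, obj)
    }
  })

  fit <- stage("fba", {
    solve_fba(model, mode = if (config$parsimonious) "parsimonious" else "plain")
  })
  if (fit$status != "optimal") {
    abort(paste0("pipeline stage 'fba' failed: solver status ", fit$status))
  }
  paths$fluxes <- file.path(config$outdir, "fluxes.tsv")
  readr::write_tsv(tidy(fit), paths$fluxes, progress = FALSE)

  fva <- stage("fva", flux_variability(model, config$optimum_fraction))
  paths$fva <- file.path(config$outdir, "fva.tsv")
  readr::write_tsv(as_tibble(fva), paths$fva, progress = FALSE)

  core <- stage("core", null_variability_core(fva, tol = config$fva_tol))
  paths$core <- file.path(config$outdir, "core_reactions.txt")
  writeLines(core, paths$core)

  kos <- stage("knockouts", {
    knockout_all(model, tol_percent = config$phenotype_tol)
  })
  paths$knockouts <- file.path(config$outdir, "knockouts.tsv")
  readr::write_tsv(
    kos %>% select(-"disabled_reactions") %>% as_tibble(),
    paths$knockouts, progress = FALSE
  )

  report <- NULL
  if (!is.null(config$omics)) {
    report <- stage("concordance", {
      omics <- if (inherits(config$omics, "omics_gene_set")) {
        config$omics
      } else {
        read_gene_set(config$omics, label = "omics")
      }
      map <- if (!is.null(config$pathway_map)) {
        if (inherits(config$pathway_map, "pathway_map")) config$pathway_map
        else read_pathway_map(config$pathway_map)
      } else if (!is.null(preset)) {
        preset$pathway_map
      } else {
        abort("a pathway map is required for the concordance stage")
      }
      score_model_vs_omics(model, fit, omics, map, tol = config$active_tol)
    })
    paths$concordance <- file.path(config$outdir, "concordance.json")
    jsonlite::write_json(
      list(summary = glance(report), per_pathway = tidy(report)),
      paths$concordance, digits = NA, auto_unbox = TRUE
    )
  }

  manifest <- list(
    package = "symbioflux",
    version = as.character(utils::packageVersion("symbioflux")),
    config_hash = rlang::hash(unclass(config)),
    seed = config$seed,
    stages = names(paths)
  )
  paths$manifest <- file.path(config$outdir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE)

  invisible(list(paths = paths, model = model, fit = fit, fva = fva,
                 core = core, knockouts = kos, concordance = report))
}
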