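#' Toy metabolic network presets with known ground truth
#'
#' Three programmatically generated networks exercise every pipeline
#' stage without external data:
#'
#' * `"chain"` — a three-step linear pathway (uptake capped at 5,
#'   a single GPR-bearing conversion, objective drain) with a unique
#'   optimum of 5 and no alternate optima.
#' * `"diamond"` — an uptake of 10 feeding two parallel routes to the
#'   product, one direct and one two-step: the classic alternate-optima
#'   polytope.  Every branch has FVA range `[0, 10]`; only uptake and
#'   drain are flux-invariant; parsimonious FBA deterministically picks
#'   the shorter route.
#' * `"mini_fix"` — a ~30-reaction bacteroid-like network: dicarboxylate
#'   (malate) uptake, a nitrogenase-like complex (`nifH and nifD and
#'   nifK`) reducing N2 to ammonium at ATP cost, glycogen/PHB storage
#'   drains, amino-acid export, isozyme pairs (`dme or tme`, `alaA or
#'   alaB`), a myo-inositol sink feeding catabolism, and a permanently
#'   closed glucose route providing truly inactive genes.  The
#'   symbiotic nitrogen-fixation objective ([zfix_objective()]) is
#'   attached in its extended eight-metabolite form.
#'
#' The returned `truth` element is recomputed at generation time (never
#' cached on disk): the FBA optimum, parsimoniously active gene and
#' enzyme sets, the null-variability core, every gene's knockout
#' phenotype, and the lethal (essential) genes.
#'
#' @param name `"chain"`, `"diamond"` or `"mini_fix"`.
#' @return an object of class `"network_preset"`: `name`, `model` (with
#'   objective attached), `pathway_map`, and `truth` (list).
#' @export
make_toy_network <- function(name = c("chain", "diamond", "mini_fix")) {
  name <- match.arg(name)
  spec <- switch(name,
    chain = chain_spec(),
    diamond = diamond_spec(),
    mini_fix = mini_fix_spec()
  )
  model <- build_model(spec$reactions)
  model <- attach_objective(model, spec$objective)

  fit <- solve_fba(model, mode = "parsimonious")
  act <- active_sets(model, fit)
  fva <- flux_variability(model)
  ko <- knockout_all(model)
  truth <- list(
    optimum = fit$objective_value,
    active_genes = act$genes,
    active_enzymes = act$enzymes,
    core_reactions = null_variability_core(fva),
    phenotypes = ko[, c("gene", "phenotype", "lethal")],
    essential_genes = ko$gene[ko$lethal]
  )

  structure(
    list(name = name, model = model,
         pathway_map = as_pathway_map(spec$pathway_map), truth = truth),
    class = "network_preset"
  )
}

#' @export
print.network_preset <- function(x, ...) {
  cat("<network_preset> '", x$name, "': ", nrow(x$model$reactions),
      " reactions, ", length(x$model$genes), " genes; optimum ",
      format(x$truth$optimum, digits = 6), ", ",
      length(x$truth$essential_genes), " essential genes\n", sep = "")
  invisible(x)
}

chain_spec <- function() {
  rxn <- function(id, formula, gpr = NA, lb = NA, ub = NA, subsystem = NA) {
    tibble(reaction_id = id, formula = formula, gpr = gpr,
           lower_bound = lb, upper_bound = ub, subsystem = subsystem)
  }
  list(
    reactions = bind_rows(
      rxn("EX_a", "-> a[e]", lb = 0, ub = 5, subsystem = "exchange"),
      rxn("T", "a[e] -> b[c]", gpr = "g1", subsystem = "transport")
    ),
    objective = c("b[c]" = 1),
    pathway_map = tibble(
      pathway_id = "transport",
      member_type = c("gene", "enzyme"),
      member_id = c("g1", "T")
    )
  )
}

diamond_spec <- function() {
  rxn <- function(id, formula, gpr = NA, lb = NA, ub = NA, subsystem = NA) {
    tibble(reaction_id = id, formula = formula, gpr = gpr,
           lower_bound = lb, upper_bound = ub, subsystem = subsystem)
  }
  list(
    reactions = bind_rows(
      rxn("U", "-> a[c]", lb = 0, ub = 10, subsystem = "exchange"),
      rxn("B1", "a[c] -> p[c]", gpr = "gB1", subsystem = "route_short"),
      rxn("C1", "a[c] -> c[c]", gpr = "gC1", subsystem = "route_long"),
      rxn("C2", "c[c] -> p[c]", gpr = "gC2", subsystem = "route_long")
    ),
    objective = c("p[c]" = 1),
    pathway_map = tibble(
      pathway_id = "routes",
      member_type = c(rep("gene", 3), rep("enzyme", 3)),
      member_id = c("gB1", "gC1", "gC2", "B1", "C1", "C2")
    )
  )
}

mini_fix_spec <- function() {
  reactions <- tibble::tribble(
    ~reaction_id, ~formula,                                   ~gpr,                      ~lower_bound, ~upper_bound, ~subsystem,
    "EX_mal",     "-> mal[e]",                                NA,                        0,  10,   "exchange",
    "DCT",        "mal[e] -> mal[c]",                         "dctA",                    NA, NA,   "transport",
    "EX_n2",      "-> n2[c]",                                 NA,                        0,  1000, "exchange",
    "EX_o2",      "-> o2[c]",                                 NA,                        0,  1000, "exchange",
    "EX_co2",     "co2[c] ->",                                NA,                        0,  1000, "exchange",
    "ME",         "mal[c] -> pyr[c] + co2[c]",                "dme or tme",              NA, NA,   "central_carbon",
    "MDH",        "mal[c] -> oaa[c]",                         "mdh",                     NA, NA,   "central_carbon",
    "PCK",        "oaa[c] -> pep[c] + co2[c]",                "pckA",                    NA, NA,   "gluconeogenesis",
    "GLYS",       "2 pep[c] -> glycogen[c]",                  "glgA and glgC",           NA, NA,   "storage",
    "PDH",        "pyr[c] -> accoa[c] + co2[c]",              "pdhA and pdhB",           NA, NA,   "central_carbon",
    "PHBS",       "2 accoa[c] -> phb[c]",                     "phbB and phbC",           NA, NA,   "storage",
    "RESP",       "accoa[c] + 2 o2[c] -> 2 co2[c] + 2 atp[c]", "cyoA",                   NA, NA,   "respiration",
    "NIF",        "n2[c] + atp[c] -> 2 nh4[c]",               "nifH and nifD and nifK",  NA, NA,   "nitrogen_fixation",
    "NH4T",       "nh4[c] -> nh4[e]",                         NA,                        NA, NA,   "transport",
    "EX_nh4",     "nh4[e] ->",                                NA,                        0,  1000, "exchange",
    "ALAD",       "pyr[c] + nh4[c] -> ala[c]",                "alaA or alaB",            NA, NA,   "amino_acids",
    "ALAT",       "ala[c] -> ala[e]",                         NA,                        NA, NA,   "transport",
    "EX_ala",     "ala[e] ->",                                NA,                        0,  1000, "exchange",
    "AAT",        "oaa[c] + nh4[c] -> asp[c]",                "aspC",                    NA, NA,   "amino_acids",
    "ASPT",       "asp[c] -> asp[e]",                         NA,                        NA, NA,   "transport",
    "EX_asp",     "asp[e] ->",                                NA,                        0,  1000, "exchange",
    "DAPS",       "asp[c] + pyr[c] -> lys[c]",                "dapA and dapB",           NA, NA,   "amino_acids",
    "VALS",       "2 pyr[c] + nh4[c] -> val[c]",              "ilvC",                    NA, NA,   "amino_acids",
    "HISS",       "pep[c] + nh4[c] -> his[c]",                "hisB",                    NA, NA,   "amino_acids",
    "SINK_inost", "-> inost[c]",                              NA,                        0,  2,    "sink",
    "INSCT",      "inost[c] -> pyr[c] + co2[c]",              "iolD",                    NA, NA,   "inositol",
    "GLX",        "accoa[c] + o2[c] -> co2[c] + atp[c]",      "aceA",                    NA, NA,   "respiration",
    "EX_glc",     "-> glc[e]",                                NA,                        0,  0,    "exchange",
    "GLCT",       "glc[e] -> glc[c]",                         "glcP",                    NA, NA,   "transport",
    "GLK",        "glc[c] -> 2 pyr[c]",                       "glk",                     NA, NA,   "glycolysis"
  )
  pathway_map <- tibble::tribble(
    ~pathway_id,         ~member_type, ~member_id,
    "central_carbon",    "gene",       "dctA",
    "central_carbon",    "gene",       "dme",
    "central_carbon",    "gene",       "tme",
    "central_carbon",    "gene",       "mdh",
    "central_carbon",    "gene",       "pckA",
    "central_carbon",    "gene",       "glcP",
    "central_carbon",    "gene",       "glk",
    "central_carbon",    "gene",       "aceA",
    "central_carbon",    "enzyme",     "DCT",
    "central_carbon",    "enzyme",     "ME",
    "central_carbon",    "enzyme",     "MDH",
    "central_carbon",    "enzyme",     "PCK",
    "central_carbon",    "enzyme",     "GLX",
    "central_carbon",    "enzyme",     "GLCT",
    "central_carbon",    "enzyme",     "GLK",
    "nitrogen_fixation", "gene",       "nifH",
    "nitrogen_fixation", "gene",       "nifD",
    "nitrogen_fixation", "gene",       "nifK",
    "nitrogen_fixation", "gene",       "cyoA",
    "nitrogen_fixation", "enzyme",     "NIF",
    "nitrogen_fixation", "enzyme",     "RESP",
    "nitrogen_fixation", "enzyme",     "NH4T",
    "storage",           "gene",       "glgA",
    "storage",           "gene",       "glgC",
    "storage",           "gene",       "phbB",
    "storage",           "gene",       "phbC",
    "storage",           "gene",       "pdhA",
    "storage",           "gene",       "pdhB",
    "storage",           "enzyme",     "GLYS",
    "storage",           "enzyme",     "PHBS",
    "storage",           "enzyme",     "PDH",
    "amino_acids",       "gene",       "alaA",
    "amino_acids",       "gene",       "alaB",
    "amino_acids",       "gene",       "aspC",
    "amino_acids",       "gene",       "dapA",
    "amino_acids",       "gene",       "dapB",
    "amino_acids",       "gene",       "ilvC",
    "amino_acids",       "gene",       "hisB",
    "amino_acids",       "enzyme",     "ALAD",
    "amino_acids",       "enzyme",     "AAT",
    "amino_acids",       "enzyme",     "DAPS",
    "amino_acids",       "enzyme",     "VALS",
    "amino_acids",       "enzyme",     "HISS",
    "amino_acids",       "enzyme",     "ALAT",
    "amino_acids",       "enzyme",     "ASPT",
    "inositol",          "gene",       "iolD",
    "inositol",          "enzyme",     "INSCT"
  )
  list(reactions = reactions,
       objective = zfix_objective(extended = TRUE),
       pathway_map = pathway_map)
}

#' Simulate omics data over a network preset
#'
#' Emulates the statistical structure of the experimental channels with
#' known ground truth.  Genes truly active under the preset's
#' parsimonious optimum receive replicate log-ratios from
#' `Normal(shift, 1)`; inactive genes from `Normal(0, 1)`.  The
#' proteome channel detects each truly-active gene (and, independently,
#' each truly-active enzyme) with probability `detection_prob`.  All
#' randomness flows from `seed`; identical seeds give identical output.
#'
#' @param preset a `"network_preset"` from [make_toy_network()].
#' @param detection_prob proteome detection probability in `[0, 1]`.
#' @param shift planted log-ratio effect for active genes, in units of
#'   the unit noise SD.
#' @param n_replicates number of replicate columns (>= 1).
#' @param n_background number of non-model background genes added to the
#'   log-ratio matrix with null (`Normal(0, 1)`) log-ratios.  Microarrays
#'   measure the whole transcriptome, so the z-score standardization
#'   must see a majority of unregulated genes — exactly as in real data,
#'   where most array genes lie outside the reconstruction.
#' @param seed integer seed.
#' @return an object of class `"omics_simulation"`: `log_ratios`
#'   (tibble, `gene_id` + `rep1..repN`), `proteome`
#'   (an [omics_gene_set()]), `truth` (active genes/enzymes), `params`.
#' @export
simulate_omics <- function(preset, detection_prob = 0.7, shift = 2,
                           n_replicates = 3, n_background = 200, seed = 1) {
  stopifnot(inherits(preset, "network_preset"))
  if (detection_prob < 0 || detection_prob > 1) {
    abort("`detection_prob` must be in [0, 1]")
  }
  if (n_replicates < 1) abort("`n_replicates` must be >= 1")

  background <- if (n_background > 0) {
    sprintf("bg%04d", seq_len(n_background))
  } else {
    character(0)
  }
  genes <- c(preset$model$genes, background)
  active_g <- preset$truth$active_genes
  active_e <- preset$truth$active_enzymes

  withr::with_seed(seed, {
    mu <- ifelse(genes %in% active_g, shift, 0)
    mat <- matrix(rnorm(length(genes) * n_replicates, mean = mu),
                  nrow = length(genes))
    detected_g <- active_g[rbinom(length(active_g), 1, detection_prob) == 1]
    detected_e <- active_e[rbinom(length(active_e), 1, detection_prob) == 1]
  })

  lr <- as_tibble(mat, .name_repair = ~ paste0("rep", seq_len(n_replicates)))
  lr <- bind_cols(tibble(gene_id = genes), lr)

  structure(
    list(
      log_ratios = lr,
      proteome = omics_gene_set("proteome", genes = detected_g,
                                enzymes = detected_e),
      truth = list(active_genes = active_g, active_enzymes = active_e),
      params = list(detection_prob = detection_prob, shift = shift,
                    n_replicates = n_replicates,
                    n_background = n_background, seed = seed)
    ),
    class = "omics_simulation"
  )
}

#' End-to-end recovery experiment
#'
#' Runs the whole pipeline on simulated data and reports how well it
#' recovers the generating truth:
#'
#' 1. a detection-calibration curve — for each detection probability
#'    `p`, the proteome channel is simulated over `n_seeds` independent
#'    seeds and the gene consistency coefficient of the model's
#'    FBA-active set against the detected set is averaged (its
#'    expectation is exactly `p`, since each truly-active gene is
#'    detected independently with probability `p`);
#' 2. the transcriptome branch — mean sensitivity and false-positive
#'    rate of the z-score selection against the planted active set at
#'    the given `shift`;
#' 3. the knockout confusion table — phenotype calls of a fresh
#'    knockout scan against the preset's generated truth.
#'
#' @param preset a `"network_preset"`.
#' @param detection_probs detection probabilities to scan.
#' @param shift planted log-ratio shift (SD units) for the
#'   transcriptome branch.
#' @param n_replicates replicates per simulated matrix.
#' @param n_seeds Monte-Carlo draws per grid point.
#' @param seed base seed; draw `i` of grid point `k` uses
#'   `seed + 1000 * k + i`.
#' @param threshold z-score selection threshold.
#' @return a `"recovery_report"`: `eta_curve` (tibble `detection_prob`,
#'   `mean_eta_genes`, `se`, `n_seeds`, `n_active`), `transcriptome`
#'   (tibble with mean sensitivity/FPR), `knockout_confusion`
#'   (tibble `truth`, `called`, `n`), `params`.
#' @export
end_to_end_recovery <- function(preset,
                                detection_probs = c(0.5, 0.7, 1.0),
                                shift = 4, n_replicates = 3,
                                n_seeds = 200, seed = 1,
                                threshold = 1.65) {
  stopifnot(inherits(preset, "network_preset"))
  model <- preset$model
  fit <- solve_fba(model, mode = "parsimonious")
  act <- active_sets(model, fit)
  n_active <- length(act$genes)

  eta_rows <- list()
  sens <- numeric(0); fpr <- numeric(0)
  for (k in seq_along(detection_probs)) {
    p <- detection_probs[k]
    etas <- numeric(n_seeds)
    for (i in seq_len(n_seeds)) {
      sim <- simulate_omics(preset, detection_prob = p, shift = shift,
                            n_replicates = n_replicates,
                            seed = seed + 1000L * k + i)
      conc <- score_model_vs_omics(model, fit, sim$proteome,
                                   preset$pathway_map)
      etas[i] <- conc$genes$eta

      if (k == 1L) {  # transcriptome branch: shift recovery, once per seed
        selection <- zscore_select(average_log_ratio(sim$log_ratios),
                                   threshold = threshold)
        sel <- selected_genes(selection)
        truly <- sim$truth$active_genes
        inactive <- setdiff(sim$log_ratios$gene_id, truly)
        sens[i] <- length(intersect(sel, truly)) / max(1, length(truly))
        fpr[i] <- length(intersect(sel, inactive)) / max(1, length(inactive))
      }
    }
    eta_rows[[k]] <- tibble(
      detection_prob = p,
      mean_eta_genes = mean(etas),
      se = sd(etas) / sqrt(n_seeds),
      n_seeds = n_seeds,
      n_active = n_active
    )
  }

  ko <- knockout_all(model)
  truth_ph <- preset$truth$phenotypes
  conf <- ko %>%
    left_join(truth_ph, by = "gene", suffix = c("_called", "_truth")) %>%
    count(truth = .data$phenotype_truth, called = .data$phenotype_called,
          name = "n")

  structure(
    list(
      eta_curve = bind_rows(eta_rows),
      transcriptome = tibble(shift = shift, threshold = threshold,
                             mean_sensitivity = mean(sens),
                             mean_false_positive_rate = mean(fpr)),
      knockout_confusion = conf,
      params = list(detection_probs = detection_probs, shift = shift,
                    n_replicates = n_replicates, n_seeds = n_seeds,
                    seed = seed, threshold = threshold)
    ),
    class = "recovery_report"
  )
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report>\n")
  print(x$eta_curve)
  cat("transcriptome branch (shift ", x$transcriptome$shift, "): ",
      "sensitivity ", format(x$transcriptome$mean_sensitivity, digits = 3),
      ", FPR ", format(x$transcriptome$mean_false_positive_rate, digits = 3),
      "\n", sep = "")
  invisible(x)
}
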