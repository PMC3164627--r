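#' Flux balance analysis
#'
#' Maximizes the flux through the attached objective drain subject to the
#' steady-state constraint `S v = 0` and the flux bounds
#' `lb_j <= v_j <= ub_j` that encode thermodynamic (directionality) and
#' enzymatic (capacity) limits.  In `"parsimonious"` mode (the default) a
#' second LP then minimizes the total absolute flux `sum(|v_j|)` at the
#' fixed optimum, picking a canonical, reproducible representative among
#' the alternate optima that plain FBA leaves to solver whim.
#'
#' @param model a `"metabolic_model"` with an attached objective
#'   ([attach_objective()]).
#' @param mode `"parsimonious"` or `"plain"`.
#' @param tol numeric slack used when pinning the optimum in the
#'   parsimonious stage.
#' @return an object of class `"fba_fit"`: `fluxes` (tibble
#'   `reaction_id`, `flux`), `objective_value`, `status` (`"optimal"`,
#'   `"infeasible"`), `mode`, and `steady_state_error`
#'   (`max |S v|`, reported so mass-balance violations cannot pass
#'   silently).  Infeasibility is returned as a status, never as a
#'   silent zero.
#' @examples
#' preset <- make_toy_network("chain")
#' fit <- solve_fba(preset$model)
#' glance(fit)
#' @export
solve_fba <- function(model, mode = c("parsimonious", "plain"), tol = 1e-9) {
  stopifnot(inherits(model, "metabolic_model"))
  mode <- match.arg(mode)
  if (is.na(model$objective_id)) {
    abort("model has no objective; call attach_objective() first")
  }
  b <- model_bounds(model)
  m <- nrow(model$reactions)
  z_col <- match(model$objective_id, model$reactions$reaction_id)
  cvec <- numeric(m); cvec[z_col] <- 1
  S <- as.matrix(model$S)

  sol <- lp_solve(cvec, b$lb, b$ub,
                  A_eq = S, b_eq = rep(0, nrow(S)), maximize = TRUE)
  if (sol$status != "optimal") {
    return(new_fba_fit(model, rep(NA_real_, m), NA_real_, sol$status, mode))
  }
  z_star <- unname(sol$v[z_col])
  v <- sol$v

  if (mode == "parsimonious") {
    v <- pfba_refine(model, S, b, z_col, z_star, tol)
  }
  new_fba_fit(model, v, z_star, "optimal", mode)
}

# minimize sum |v| subject to steady state, bounds, and v_Z = z*,
# via the split v = p - n, p, n >= 0.
pfba_refine <- function(model, S, b, z_col, z_star, tol) {
  m <- ncol(S)
  obj <- rep(1, 2 * m)                 # min sum(p) + sum(n)
  lb2 <- rep(0, 2 * m)
  ub2 <- c(pmax(b$ub, 0), pmax(-b$lb, 0))
  # v = p - n expressed on the split variables
  V <- cbind(diag(m), -diag(m))
  fix <- matrix(V[z_col, ], nrow = 1)  # v_Z pinned at the solved optimum
  A_eq <- rbind(as.matrix(S %*% V), fix)
  b_eq <- c(rep(0, nrow(S)), z_star)
  A_geq <- rbind(V, -V)                # lb <= v <= ub on the split variables
  b_geq <- c(b$lb, -b$ub)

  sol <- lp_solve(obj, lb2, ub2,
                  A_eq = A_eq, b_eq = b_eq,
                  A_geq = A_geq, b_geq = b_geq, maximize = FALSE)
  if (sol$status != "optimal") {
    abort("parsimonious stage infeasible; this should not happen at a solved optimum")
  }
  as.numeric(V %*% sol$v)
}

new_fba_fit <- function(model, v, objective_value, status, mode) {
  err <- if (status == "optimal") max(abs(as.numeric(model$S %*% v))) else NA_real_
  structure(
    list(
      fluxes = tibble(reaction_id = model$reactions$reaction_id,
                      flux = unname(v)),
      objective_value = objective_value,
      status = status,
      mode = mode,
      objective_id = model$objective_id,
      steady_state_error = err
    ),
    class = "fba_fit"
  )
}

#' @export
print.fba_fit <- function(x, ...) {
  cat("<fba_fit> status: ", x$status, ", mode: ", x$mode, "\n", sep = "")
  if (x$status == "optimal") {
    cat("objective (", x$objective_id, ") = ",
        format(x$objective_value, digits = 6),
        "; max |S v| = ", format(x$steady_state_error, digits = 3),
        "\n", sep = "")
  }
  invisible(x)
}

#' @describeIn solve_fba flux vector as a tibble (`reaction_id`, `flux`).
#' @method tidy fba_fit
#' @param x,object an `"fba_fit"`.
#' @param ... unused.
#' @export
tidy.fba_fit <- function(x, ...) x$fluxes

#' @describeIn solve_fba one-row summary (`objective_value`, `status`,
#'   `mode`, `n_active`, `steady_state_error`).
#' @param active_tol threshold on `|v|` for counting a flux as active.
#' @method glance fba_fit
#' @export
glance.fba_fit <- function(x, active_tol = 1e-6, ...) {
  tibble(
    objective_value = x$objective_value,
    status = x$status,
    mode = x$mode,
    n_active = if (x$status == "optimal")
      sum(abs(x$fluxes$flux) > active_tol) else NA_integer_,
    steady_state_error = x$steady_state_error
  )
}

#' Flux variability analysis
#'
#' For each reaction, minimizes and maximizes its flux over the optimal
#' face of the flux polytope: steady state, bounds, and objective flux
#' held at (at least) `optimum_fraction` times the FBA optimum.  The
#' width `max_flux - min_flux` characterizes the alternate-optima
#' structure; see [null_variability_core()].
#'
#' @inheritParams solve_fba
#' @param optimum_fraction in `(0, 1]`; 1 examines the optimal face
#'   itself.
#' @return an `"fva_result"`: tibble with columns `reaction_id`,
#'   `min_flux`, `max_flux`, plus attributes `optimum` and
#'   `optimum_fraction`.
#' @export
flux_variability <- function(model, optimum_fraction = 1.0) {
  stopifnot(inherits(model, "metabolic_model"))
  if (!is.numeric(optimum_fraction) || optimum_fraction <= 0 ||
      optimum_fraction > 1) {
    abort("`optimum_fraction` must be in (0, 1]")
  }
  fit <- solve_fba(model, mode = "plain")
  if (fit$status != "optimal") {
    abort(paste0("FBA did not solve (status: ", fit$status, ")"))
  }
  b <- model_bounds(model)
  m <- nrow(model$reactions)
  S <- as.matrix(model$S)
  z_col <- match(model$objective_id, model$reactions$reaction_id)
  z_row <- numeric(m); z_row[z_col] <- 1
  z_min <- optimum_fraction * fit$objective_value - 1e-9

  mins <- numeric(m); maxs <- numeric(m)
  for (j in seq_len(m)) {
    cvec <- numeric(m); cvec[j] <- 1
    for (sense in c("min", "max")) {
      sol <- lp_solve(cvec, b$lb, b$ub,
                      A_eq = S, b_eq = rep(0, nrow(S)),
                      A_geq = matrix(z_row, nrow = 1), b_geq = z_min,
                      maximize = (sense == "max"))
      if (sol$status != "optimal") {
        abort(paste0("FVA sub-problem failed for reaction '",
                     model$reactions$reaction_id[j], "' (", sense, ")"))
      }
      if (sense == "min") mins[j] <- unname(sol$v[j]) else maxs[j] <- unname(sol$v[j])
    }
  }
  # solver noise can invert a degenerate pair by ~1e-12
  swap <- mins > maxs
  if (any(swap)) {
    tmp <- mins[swap]; mins[swap] <- maxs[swap]; maxs[swap] <- tmp
  }
  out <- tibble(reaction_id = model$reactions$reaction_id,
                min_flux = mins, max_flux = maxs)
  attr(out, "optimum") <- fit$objective_value
  attr(out, "optimum_fraction") <- optimum_fraction
  class(out) <- c("fva_result", class(out))
  out
}

#' Invariant metabolic core across alternate optima
#'
#' Reactions whose FVA range is numerically zero carry the same flux in
#' every optimal solution; they form the invariant core of the optimal
#' face, robust to the solver's arbitrary choice among alternate optima.
#'
#' @param fva an `"fva_result"` from [flux_variability()].
#' @param tol range width at or below which a reaction counts as
#'   invariant.
#' @return character vector of reaction ids.
#' @export
null_variability_core <- function(fva, tol = 1e-6) {
  stopifnot(inherits(fva, "fva_result"))
  fva$reaction_id[abs(fva$max_flux - fva$min_flux) <= tol]
}

#' Active enzyme and gene sets of a flux distribution
#'
#' The in-silico active enzyme set contains every non-boundary,
#' non-objective reaction carrying flux `|v_j| > tol`; the active gene
#' set is the union of genes appearing in the GPR rules of those
#' reactions.  These are the model-predicted sets that the consistency
#' coefficient compares with omics-derived sets.
#'
#' @param model the model the fit was solved on.
#' @param fit an optimal `"fba_fit"`.
#' @param tol activity threshold on `|v_j|`; must exceed the solver
#'   feasibility tolerance.
#' @return an object of class `"active_sets"`: list with character
#'   vectors `enzymes` and `genes`.
#' @export
active_sets <- function(model, fit, tol = 1e-6) {
  stopifnot(inherits(model, "metabolic_model"), inherits(fit, "fba_fit"))
  if (fit$status != "optimal") abort("`fit` is not an optimal solution")
  v <- fit$fluxes$flux[match(model$reactions$reaction_id,
                             fit$fluxes$reaction_id)]
  keep <- abs(v) > tol & !model$reactions$boundary &
    model$reactions$reaction_id != model$objective_id
  enzymes <- model$reactions$reaction_id[keep]
  genes <- sort(unique(unlist(lapply(model$reactions$gpr[keep], gpr_genes))))
  structure(list(enzymes = enzymes, genes = genes %||% character(0)),
            class = "active_sets")
}

#' @export
print.active_sets <- function(x, ...) {
  cat("<active_sets> ", length(x$enzymes), " enzymes (reactions), ",
      length(x$genes), " genes\n", sep = "")
  invisible(x)
}
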