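# Independent oracles used across the suite.  None of them share code
# with the package's own solver or parser.

# --- polytope-vertex enumeration ------------------------------------------
# Vertices of {v : S v = 0, lb <= v <= ub}: with r = rank(S), fix every
# subset of (m - r) coordinates at one of its bounds, solve the square-ish
# system for the rest, keep solutions that are feasible.  Exponential, so
# only used on networks of <= 6 reactions.
enumerate_vertices <- function(S, lb, ub, tol = 1e-8) {
  S <- as.matrix(S)
  m <- ncol(S)
  r <- qr(S)$rank
  n_fix <- m - r
  verts <- list()
  add_vertex <- function(v) {
    for (w in verts) if (max(abs(w - v)) < 1e-6) return()
    verts[[length(verts) + 1L]] <<- v
  }
  if (n_fix == 0) {
    sol <- qr.solve(S, rep(0, nrow(S)))
    if (all(sol >= lb - tol & sol <= ub + tol)) add_vertex(sol)
  } else {
    subsets <- utils::combn(m, n_fix, simplify = FALSE)
    for (fix_idx in subsets) {
      free_idx <- setdiff(seq_len(m), fix_idx)
      choices <- expand.grid(rep(list(c("lb", "ub")), n_fix),
                             stringsAsFactors = FALSE)
      for (ci in seq_len(nrow(choices))) {
        v_fix <- ifelse(unlist(choices[ci, ]) == "lb",
                        lb[fix_idx], ub[fix_idx])
        rhs <- -S[, fix_idx, drop = FALSE] %*% v_fix
        fit <- tryCatch(
          qr.solve(S[, free_idx, drop = FALSE], rhs),
          error = function(e) NULL
        )
        if (is.null(fit)) next
        resid <- S[, free_idx, drop = FALSE] %*% fit - rhs
        if (max(abs(resid)) > tol) next
        v <- numeric(m)
        v[fix_idx] <- v_fix
        v[free_idx] <- fit
        if (all(v >= lb - tol & v <= ub + tol)) add_vertex(v)
      }
    }
  }
  verts
}

# brute-force FBA optimum: best objective-drain flux over all vertices
oracle_fba_vertex <- function(model) {
  z <- match(model$objective_id, model$reactions$reaction_id)
  verts <- enumerate_vertices(model$S,
                              model$reactions$lower_bound,
                              model$reactions$upper_bound)
  stopifnot(length(verts) > 0)
  max(vapply(verts, function(v) v[z], numeric(1)))
}

# --- boolean GPR evaluation via R's own parser ----------------------------
oracle_gpr_eval <- function(rule, present) {
  tokens <- strsplit(gsub("([()])", " \\1 ", rule), "\\s+")[[1]]
  tokens <- tokens[nzchar(tokens)]
  mapped <- vapply(tokens, function(tk) {
    lw <- tolower(tk)
    if (lw == "and") "&" else if (lw == "or") "|"
    else if (tk %in% c("(", ")")) tk
    else as.character(tk %in% present)
  }, character(1))
  eval(parse(text = paste(mapped, collapse = " ")))
}

# --- exhaustive hypergeometric upper tail ---------------------------------
# enumerate all draws of size n from a universe of size N containing K
# marked elements; count draws with overlap >= k
oracle_hyper <- function(k, n, K, N) {
  draws <- utils::combn(N, n, simplify = FALSE)
  marked <- seq_len(K)
  hits <- vapply(draws, function(d) sum(d %in% marked) >= k, logical(1))
  mean(hits)
}

# --- scipy linprog (HiGHS) batch oracle -----------------------------------
# problems: list of list(c, Aeq, beq, lb, ub, maximize); returns a list of
# list(status, value) solved in a single python process.
oracle_lp_batch <- function(problems) {
  stopifnot(length(problems) > 0)
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  jsonlite::write_json(problems, fin, digits = NA, auto_unbox = FALSE)
  script <- test_path("lp_oracle.py")
  status <- system2("python", c(script, fin, fout),
                    stdout = FALSE, stderr = FALSE)
  stopifnot(status == 0)
  jsonlite::read_json(fout, simplifyVector = TRUE)
}

# package model -> one oracle problem maximizing the objective drain
lp_problem_from_model <- function(model) {
  zc <- match(model$objective_id, model$reactions$reaction_id)
  cc <- numeric(nrow(model$reactions)); cc[zc] <- 1
  list(
    c = cc,
    Aeq = unname(as.matrix(model$S)),
    beq = rep(0, nrow(model$S)),
    lb = model$reactions$lower_bound,
    ub = model$reactions$upper_bound,
    maximize = TRUE
  )
}

# --- preset cache (presets are deterministic; build each once) ------------
.preset_cache <- new.env(parent = emptyenv())
get_preset <- function(name) {
  if (is.null(.preset_cache[[name]])) {
    .preset_cache[[name]] <- make_toy_network(name)
  }
  .preset_cache[[name]]
}
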