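# Internal linear-programming layer.
#
# All FBA-family problems reduce to
#     optimize  c'v   s.t.  A_eq v = b_eq,  A_geq v >= b_geq,  lb <= v <= ub
# with finite bounds (infinite capacities are encoded as +/-1000 upstream).
# The solver is a dense two-phase tableau simplex written for this
# package: Dantzig pricing for speed, switching to Bland's rule after a
# pivot budget so termination is guaranteed on the degenerate LPs that
# knockouts and FVA produce.  Problems here are small (tens of
# variables), so dense arithmetic is ample.

lp_solve <- function(objective, lb, ub,
                     A_eq = NULL, b_eq = NULL,
                     A_geq = NULL, b_geq = NULL,
                     maximize = TRUE, eps = 1e-9) {
  m <- length(objective)
  stopifnot(length(lb) == m, length(ub) == m)
  if (any(!is.finite(lb)) || any(!is.finite(ub))) {
    abort("lp_solve requires finite bounds; encode infinity as a surrogate")
  }
  if (any(lb > ub)) {
    return(list(status = "infeasible", value = NA_real_,
                v = rep(NA_real_, m)))
  }

  # Variables pinned by equal bounds (e.g. knocked-out reactions) are
  # eliminated up front; this shrinks the tableau and removes pointless
  # degenerate rows.
  fixed <- which(ub - lb <= 0)
  if (length(fixed) > 0) {
    free <- setdiff(seq_len(m), fixed)
    vfix <- lb[fixed]
    shrink <- function(A, b) {
      if (is.null(A)) return(list(A = NULL, b = NULL))
      A <- as.matrix(A)
      list(A = A[, free, drop = FALSE],
           b = b - as.numeric(A[, fixed, drop = FALSE] %*% vfix))
    }
    eqr <- shrink(A_eq, b_eq); ger <- shrink(A_geq, b_geq)
    if (length(free) == 0) {
      feas <- (is.null(eqr$b) || all(abs(eqr$b) <= 1e-7)) &&
        (is.null(ger$b) || all(ger$b <= 1e-7))
      return(if (feas) {
        list(status = "optimal", value = sum(objective * lb), v = lb)
      } else {
        list(status = "infeasible", value = NA_real_,
             v = rep(NA_real_, m))
      })
    }
    sub <- lp_solve(objective[free], lb[free], ub[free],
                    A_eq = eqr$A, b_eq = eqr$b,
                    A_geq = ger$A, b_geq = ger$b,
                    maximize = maximize, eps = eps)
    v <- rep(NA_real_, m)
    if (sub$status == "optimal") {
      v[fixed] <- vfix
      v[free] <- sub$v
    }
    return(list(status = sub$status,
                value = if (sub$status == "optimal") sum(objective * v)
                        else NA_real_,
                v = v))
  }

  # shift to w = v - lb >= 0
  n <- m
  rows_A <- list(); rows_b <- numeric(0); rows_dir <- character(0)
  push <- function(A, b, dir) {
    if (is.null(A)) return()
    A <- as.matrix(A)
    if (nrow(A) == 0) return()
    b2 <- b - as.numeric(A %*% lb)
    for (k in seq_len(nrow(A))) {
      a <- A[k, ]; rhs <- b2[k]; d <- dir
      if (rhs < 0) {
        a <- -a; rhs <- -rhs
        d <- switch(dir, "<=" = ">=", ">=" = "<=", "=" = "=")
      }
      rows_A[[length(rows_A) + 1L]] <<- a
      rows_b[length(rows_b) + 1L] <<- rhs
      rows_dir[length(rows_dir) + 1L] <<- d
    }
  }
  push(diag(n), ub, "<=")
  push(A_eq, b_eq, "=")
  push(A_geq, b_geq, ">=")

  res <- simplex_two_phase(
    cost = if (maximize) -objective else objective,
    A = do.call(rbind, rows_A), b = rows_b, dir = rows_dir, tol = eps
  )
  if (res$status != "optimal") {
    return(list(status = res$status, value = NA_real_,
                v = rep(NA_real_, m)))
  }
  v <- pmin(pmax(res$x + lb, lb), ub)   # clamp solver noise into the box
  list(status = "optimal", value = sum(objective * v), v = v)
}

# Minimize cost'x subject to A x (dir) b, x >= 0, all b >= 0.
simplex_two_phase <- function(cost, A, b, dir, tol = 1e-9) {
  n <- length(cost)
  n_con <- nrow(A)
  n_slack <- sum(dir == "<=")
  n_surp <- sum(dir == ">=")
  n_art <- sum(dir != "<=")

  ncol_T <- n + n_slack + n_surp + n_art
  Tm <- matrix(0, n_con, ncol_T + 1L)
  Tm[, seq_len(n)] <- A
  Tm[, ncol_T + 1L] <- b

  basis <- integer(n_con)
  s_i <- n; u_i <- n + n_slack; a_i <- n + n_slack + n_surp
  for (k in seq_len(n_con)) {
    if (dir[k] == "<=") {
      s_i <- s_i + 1L
      Tm[k, s_i] <- 1
      basis[k] <- s_i
    } else {
      if (dir[k] == ">=") {
        u_i <- u_i + 1L
        Tm[k, u_i] <- -1
      }
      a_i <- a_i + 1L
      Tm[k, a_i] <- 1
      basis[k] <- a_i
    }
  }
  art_cols <- seq.int(n + n_slack + n_surp + 1L, length.out = n_art)

  # phase 1: minimize the sum of artificials
  if (n_art > 0) {
    c1 <- numeric(ncol_T); c1[art_cols] <- 1
    ph1 <- simplex_iterate(Tm, basis, c1, tol)
    Tm <- ph1$T; basis <- ph1$basis
    if (ph1$status != "optimal" || ph1$objective > 1e-7) {
      return(list(status = "infeasible", x = NULL))
    }
    # pivot lingering zero-level artificials out of the basis
    for (k in which(basis %in% art_cols)) {
      piv <- which(abs(Tm[k, seq_len(n + n_slack + n_surp)]) > tol)[1]
      if (!is.na(piv)) {
        Tm <- simplex_pivot(Tm, k, piv)
        basis[k] <- piv
      }
    }
    keep_rows <- !(basis %in% art_cols)
    Tm <- Tm[keep_rows, , drop = FALSE]
    basis <- basis[keep_rows]
    Tm <- Tm[, -art_cols, drop = FALSE]
  }

  c2 <- numeric(ncol(Tm) - 1L)
  c2[seq_len(n)] <- cost
  ph2 <- simplex_iterate(Tm, basis, c2, tol)
  if (ph2$status == "unbounded") {
    return(list(status = "unbounded", x = NULL))
  }
  x <- numeric(ncol(Tm) - 1L)
  x[ph2$basis] <- ph2$T[, ncol(Tm)]
  list(status = "optimal", x = x[seq_len(n)], objective = ph2$objective)
}

simplex_iterate <- function(Tm, basis, cost, tol) {
  n_con <- nrow(Tm)
  ncol_T <- ncol(Tm) - 1L
  rhs_col <- ncol_T + 1L
  # reduced costs z = cost - cost_B' B^-1 A, maintained by pivoting
  z <- cost - as.numeric(crossprod(cost[basis], Tm[, seq_len(ncol_T), drop = FALSE]))
  obj <- -sum(cost[basis] * Tm[, rhs_col])

  bland_after <- 50L * (n_con + ncol_T)
  it <- 0L
  repeat {
    it <- it + 1L
    cand <- which(z < -tol)
    if (length(cand) == 0) {
      return(list(T = Tm, basis = basis, status = "optimal",
                  objective = sum(cost[basis] * Tm[, rhs_col])))
    }
    j <- if (it > bland_after) cand[1] else cand[which.min(z[cand])]

    col <- Tm[, j]
    pos <- which(col > tol)
    if (length(pos) == 0) {
      return(list(T = Tm, basis = basis, status = "unbounded",
                  objective = NA_real_))
    }
    ratios <- Tm[pos, rhs_col] / col[pos]
    best <- min(ratios)
    ties <- pos[ratios <= best + tol]
    i <- if (length(ties) > 1) ties[which.min(basis[ties])] else ties[1]

    Tm <- simplex_pivot(Tm, i, j)
    z <- z - z[j] * Tm[i, seq_len(ncol_T)]
    z[j] <- 0
    basis[i] <- j
  }
}

simplex_pivot <- function(Tm, i, j) {
  Tm[i, ] <- Tm[i, ] / Tm[i, j]
  other <- setdiff(seq_len(nrow(Tm)), i)
  Tm[other, ] <- Tm[other, ] - outer(Tm[other, j], Tm[i, ])
  Tm
}

# convenience: bounds vectors of a model (named)
model_bounds <- function(model) {
  list(lb = setNames(model$reactions$lower_bound, model$reactions$reaction_id),
       ub = setNames(model$reactions$upper_bound, model$reactions$reaction_id))
}
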