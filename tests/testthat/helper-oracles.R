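# Test helpers: brute-force LP oracle (vertex enumeration) and tiny toy
# network builders, independent of the package's simplex implementation.

# Enumerate vertices of {A x = b, lb <= x <= ub}: fix n - rank(A) variables
# at a bound, solve for the rest, keep feasible points, scan the objective.
brute_force_lp <- function(cc, A, b, lb, ub, maximize = FALSE) {
  n <- ncol(A)
  m <- qr(A)$rank
  best <- NULL; best_x <- NULL
  for (fs in utils::combn(n, m, simplify = FALSE)) {
    fixed <- setdiff(seq_len(n), fs)
    grids <- if (length(fixed) == 0) list(integer(0)) else {
      g <- expand.grid(rep(list(c(0L, 1L)), length(fixed)))
      lapply(seq_len(nrow(g)), function(i) as.integer(g[i, ]))
    }
    Bm <- A[, fs, drop = FALSE]
    if (qr(Bm)$rank < m) next
    for (g in grids) {
      xf <- ifelse(g == 0L, lb[fixed], ub[fixed])
      rhs <- b - if (length(fixed)) as.vector(A[, fixed, drop = FALSE] %*% xf) else 0
      xb <- tryCatch(qr.solve(Bm, rhs), error = function(e) NULL)
      if (is.null(xb)) next
      x <- numeric(n); x[fs] <- xb
      if (length(fixed)) x[fixed] <- xf
      if (any(x < lb - 1e-8) || any(x > ub + 1e-8)) next
      if (max(abs(as.vector(A %*% x) - b)) > 1e-8) next
      v <- sum(cc * x)
      if (is.null(best) || (maximize && v > best + 1e-12) ||
          (!maximize && v < best - 1e-12)) { best <- v; best_x <- x }
    }
  }
  list(obj = best, x = best_x)
}

# Assemble a toy stoichiometric model from a list of reactions
# (every metabolite gets formula C1; compartment read from the id suffix).
toy_model <- function(rxns, objective_id) {
  mets <- list()
  for (r in rxns) for (mid in names(r$stoichiometry)) {
    if (is.null(mets[[mid]])) {
      comp <- sub("^.*_(e|c|m|p)$", "\\1", mid)
      mets[[mid]] <- metabolite(mid, mid, comp, c(C = 1))
    }
  }
  rl <- stats::setNames(rxns, vapply(rxns, `[[`, "", "id"))
  structure(list(metabolites = mets, reactions = rl,
                 objective_id = objective_id,
                 biomass_composition = c(C = 1, H = 1.8, O = 0.5, N = 0.2)),
            class = "stoichiometric_model")
}

# linear chain: uptake (<= 10) -> transport -> growth sink
toy_chain <- function(transport_ub = 1000) {
  toy_model(list(
    reaction("EX_A", "A exchange", c(A_e = -1), -10, 0),
    reaction("T_A", "A transport", c(A_e = -1, A_c = 1), 0, transport_ub),
    reaction("GROW", "growth sink", c(A_c = -1), 0, 1000)
  ), "GROW")
}

# diamond: direct A -> B versus two-step A -> C -> B, equal capacity
toy_diamond <- function() {
  toy_model(list(
    reaction("EX_A", "A exchange", c(A_e = -1), -10, -10),
    reaction("DIRECT", "A to B direct", c(A_e = -1, B_c = 1), 0, 1000),
    reaction("VIA1", "A to C", c(A_e = -1, C_c = 1), 0, 1000),
    reaction("VIA2", "C to B", c(C_c = -1, B_c = 1), 0, 1000),
    reaction("GROW", "B sink", c(B_c = -1), 0, 1000)
  ), "GROW")
}

# two parallel equal routes carrying a shared demand
toy_parallel <- function() {
  toy_model(list(
    reaction("EX_A", "A exchange", c(A_e = -1), -10, 0),
    reaction("R1", "route 1", c(A_e = -1, B_c = 1), 0, 1000),
    reaction("R2", "route 2", c(A_e = -1, B_c = 1), 0, 1000),
    reaction("GROW", "B sink", c(B_c = -1), 0, 1000)
  ), "GROW")
}

lp_inputs <- function(model, constraints = NULL) {
  bd <- if (is.null(constraints)) model_bounds(model) else constraints
  S <- stoichiometric_matrix(model)
  list(S = S, lb = bd$lower, ub = bd$upper,
       obj = as.numeric(colnames(S) == model$objective_id))
}
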