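# Flux analysis engine: FBA, parsimonious FBA, flux variability analysis,
# seeded hit-and-run sampling of the near-optimal flux polytope, and
# uptake-normalized reporting.

#' Build a flux constraint set from measured specific rates
#'
#' Every listed reaction gets a fixed (two-sided) flux constraint equal to
#' the measured value, per the convention that uptake is negative on
#' exchange reactions; all other reactions inherit the model's default
#' bounds.
#'
#' @param model A `stoichiometric_model`.
#' @param rates Named numeric vector, reaction id -> measured flux
#'   (mmol/gCDW/h).
#' @return Data frame with columns `id`, `lower`, `upper`, `provenance`
#'   (`"measured"` or `"default"`).
#' @export
apply_measured_rates <- function(model, rates = numeric()) {
  cs <- model_bounds(model)
  cs$provenance <- "default"
  if (length(rates)) {
    if (is.null(names(rates)) || any(names(rates) == ""))
      stop("rates must be a named vector of reaction ids")
    unknown <- setdiff(names(rates), cs$id)
    if (length(unknown))
      stop("unknown reaction id(s) in measured rates: ",
           paste(unknown, collapse = ", "))
    idx <- match(names(rates), cs$id)
    cs$lower[idx] <- cs$upper[idx] <- as.numeric(rates)
    cs$provenance[idx] <- "measured"
  }
  cs
}

resolve_constraints <- function(model, constraints) {
  if (is.null(constraints)) constraints <- model_bounds(model)
  stopifnot(all(c("id", "lower", "upper") %in% names(constraints)))
  unknown <- setdiff(constraints$id, names(model$reactions))
  if (length(unknown))
    stop("constraint set references unknown reaction(s): ",
         paste(unknown, collapse = ", "))
  bd <- model_bounds(model)
  idx <- match(constraints$id, bd$id)
  bd$lower[idx] <- constraints$lower
  bd$upper[idx] <- constraints$upper
  if (any(bd$lower > bd$upper))
    stop("inconsistent constraint set: lower > upper for ",
         paste(bd$id[bd$lower > bd$upper], collapse = ", "))
  bd
}

flux_solution <- function(status, objective_value = NA_real_,
                          fluxes = NULL) {
  structure(list(status = status, objective_value = objective_value,
                 fluxes = fluxes), class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("flux_solution:", x$status, "objective =",
      format(x$objective_value, digits = 6), "\n")
  invisible(x)
}

#' Flux balance analysis
#'
#' Solves max (or min) of the objective flux subject to steady state
#' (S v = 0) and the flux bounds.
#'
#' @param model A `stoichiometric_model`.
#' @param constraints Optional constraint set (see
#'   [apply_measured_rates()]); `NULL` uses the model bounds.
#' @param objective_id Reaction to optimize; defaults to the model's
#'   biomass reaction.
#' @param direction `"max"` or `"min"`.
#' @return A `flux_solution` with `status` in
#'   `{"optimal","infeasible","unbounded"}`, `objective_value`, and the
#'   named flux vector.
#' @export
solve_fba <- function(model, constraints = NULL,
                      objective_id = model$objective_id,
                      direction = c("max", "min")) {
  direction <- match.arg(direction)
  bd <- resolve_constraints(model, constraints)
  S <- stoichiometric_matrix(model)
  if (!objective_id %in% colnames(S))
    stop("unknown objective reaction ", objective_id)
  cc <- as.numeric(colnames(S) == objective_id)
  r <- lp_solve_core(cc, S, rep(0, nrow(S)), bd$lower, bd$upper,
                     maximize = direction == "max")
  if (r$status != "optimal") return(flux_solution(r$status))
  v <- stats::setNames(r$x, colnames(S))
  flux_solution("optimal", r$obj, v)
}

#' Parsimonious FBA
#'
#' Two-stage LP: (1) maximize growth; (2) with growth fixed at the stage-1
#' optimum (relative tolerance 1e-9), minimize the total absolute flux
#' sum(|v|), linearized by splitting every reaction into irreversible
#' forward/backward halves. The split is internal; the returned vector is
#' in the model's reaction space.
#'
#' @inheritParams solve_fba
#' @return A `flux_solution`; `objective_value` is the (stage-1) growth.
#' @export
solve_pfba <- function(model, constraints = NULL) {
  stage1 <- solve_fba(model, constraints)
  if (stage1$status != "optimal") return(stage1)
  mu <- stage1$objective_value
  bd <- resolve_constraints(model, constraints)
  i_obj <- match(model$objective_id, bd$id)
  slack <- 1e-9 * max(1, abs(mu))
  bd$lower[i_obj] <- max(bd$lower[i_obj], mu - slack)
  bd$upper[i_obj] <- min(bd$upper[i_obj], mu + slack)

  S <- stoichiometric_matrix(model)
  n <- ncol(S)
  # v = vf - vb, vf in [0, max(0,ub)], vb in [0, max(0,-lb)]
  S2 <- cbind(S, -S)
  lb2 <- c(pmax(0, bd$lower), pmax(0, -bd$upper))
  ub2 <- c(pmax(0, bd$upper), pmax(0, -bd$lower))
  cc <- rep(1, 2 * n)
  r <- lp_solve_core(cc, S2, rep(0, nrow(S)), lb2, ub2, maximize = FALSE)
  if (r$status != "optimal") return(flux_solution(r$status))
  v <- stats::setNames(r$x[seq_len(n)] - r$x[n + seq_len(n)], colnames(S))
  out <- flux_solution("optimal", v[[model$objective_id]], v)
  attr(out, "total_flux") <- sum(abs(v))
  out
}

#' Flux variability analysis
#'
#' For each reaction, the minimum and maximum attainable flux subject to
#' growth at or above `growth_fraction` times the FBA optimum.
#'
#' @inheritParams solve_fba
#' @param growth_fraction Fraction of the optimal growth that must be
#'   retained (default 0.9, i.e. 10% variability from the predicted
#'   specific growth rate).
#' @param reactions Optional subset of reaction ids to scan.
#' @param keep_solutions Internal: also return the optimal vertex flux
#'   vectors (used to warm-start the sampler).
#' @return Data frame with columns `id`, `min`, `max`.
#' @export
flux_variability <- function(model, constraints = NULL,
                             growth_fraction = 0.9, reactions = NULL,
                             keep_solutions = FALSE) {
  fba <- solve_fba(model, constraints)
  if (fba$status != "optimal")
    stop("FBA ", fba$status, "; cannot run flux variability analysis")
  bd <- resolve_constraints(model, constraints)
  i_obj <- match(model$objective_id, bd$id)
  floor_mu <- growth_fraction * fba$objective_value
  bd$lower[i_obj] <- max(bd$lower[i_obj], floor_mu)
  S <- stoichiometric_matrix(model)
  ids <- reactions %||% colnames(S)
  unknown <- setdiff(ids, colnames(S))
  if (length(unknown)) stop("unknown reaction(s): ", paste(unknown, collapse = ", "))
  res <- data.frame(id = ids, min = NA_real_, max = NA_real_)
  sols <- list()
  zero <- rep(0, nrow(S))
  for (k in seq_along(ids)) {
    j <- match(ids[k], colnames(S))
    if (bd$upper[j] - bd$lower[j] < 1e-12) {     # fixed flux: no LPs needed
      res$min[k] <- res$max[k] <- bd$lower[j]
      next
    }
    cc <- as.numeric(seq_len(ncol(S)) == j)
    lo <- lp_solve_core(cc, S, zero, bd$lower, bd$upper, maximize = FALSE)
    hi <- lp_solve_core(cc, S, zero, bd$lower, bd$upper, maximize = TRUE)
    if (lo$status != "optimal" || hi$status != "optimal")
      stop("FVA subproblem for ", ids[k], " returned ", lo$status, "/", hi$status)
    res$min[k] <- lo$obj; res$max[k] <- hi$obj
    if (keep_solutions) { sols[[length(sols) + 1L]] <- lo$x
                          sols[[length(sols) + 1L]] <- hi$x }
  }
  if (keep_solutions) attr(res, "solutions") <- sols
  res
}

# orthonormal null-space basis of S
null_space_basis <- function(S, tol = 1e-10) {
  sv <- svd(S, nu = 0, nv = ncol(S))
  rank <- sum(sv$d > tol * max(sv$d))
  if (rank == ncol(S)) return(matrix(0, ncol(S), 0))
  sv$v[, (rank + 1):ncol(S), drop = FALSE]
}

#' Random sampling of the near-optimal flux space
#'
#' Seeded hit-and-run walk over the polytope {S v = 0, bounds, growth >=
#' `growth_fraction` x optimum}. Directions are random combinations of an
#' orthonormal null-space basis of S; the walk is warm-started from the
#' mean of the FVA-extreme vertex solutions, bounds are tightened to the
#' FVA box first, and every 10th accepted point is recorded (thinning).
#'
#' @inheritParams flux_variability
#' @param n Number of sampled points (>= 2).
#' @param seed Integer seed; the same seed reproduces the summary exactly.
#' @param thin Thinning interval between recorded points.
#' @return A `sampling_summary`: `n_samples`, `seed`, `growth_fraction`,
#'   and a `summary` data frame (per reaction `median`, `sd`, `min`,
#'   `max`). The raw sample matrix (reactions x samples) is attached as
#'   attribute `"samples"`.
#' @export
sample_solution_space <- function(model, constraints = NULL, n = 2000,
                                  growth_fraction = 0.9, seed,
                                  thin = 10) {
  if (missing(seed) || is.null(seed)) stop("a seed is required for sampling")
  if (n < 2) stop("n must be at least 2")
  fba <- solve_fba(model, constraints)
  if (fba$status != "optimal")
    stop("FBA ", fba$status, "; solution space is empty")
  bd <- resolve_constraints(model, constraints)
  i_obj <- match(model$objective_id, bd$id)
  bd$lower[i_obj] <- max(bd$lower[i_obj], growth_fraction * fba$objective_value)
  fva <- flux_variability(model, constraints, growth_fraction,
                          keep_solutions = TRUE)
  sols <- attr(fva, "solutions")
  # FVA box tightening
  bd$lower <- pmax(bd$lower, fva$min - 1e-9)
  bd$upper <- pmin(bd$upper, fva$max + 1e-9)

  S <- stoichiometric_matrix(model)
  N <- null_space_basis(S)
  k <- ncol(N)
  x <- Reduce(`+`, sols) / length(sols)   # interior-ish feasible start
  nr <- ncol(S)

  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)

  samples <- matrix(NA_real_, nr, n, dimnames = list(colnames(S), NULL))
  taken <- 0L; step <- 0L
  lb <- bd$lower; ub <- bd$upper
  while (taken < n) {
    step <- step + 1L
    if (k > 0) {
      d <- as.vector(N %*% stats::rnorm(k))
      nd <- sqrt(sum(d^2))
      if (nd > 1e-12) {
        d <- d / nd
        # admissible step interval from the box bounds
        amin <- -Inf; amax <- Inf
        pos <- d > 1e-12; neg <- d < -1e-12
        if (any(pos)) {
          amax <- min(amax, min((ub[pos] - x[pos]) / d[pos]))
          amin <- max(amin, max((lb[pos] - x[pos]) / d[pos]))
        }
        if (any(neg)) {
          amax <- min(amax, min((lb[neg] - x[neg]) / d[neg]))
          amin <- max(amin, max((ub[neg] - x[neg]) / d[neg]))
        }
        if (is.finite(amin) && is.finite(amax) && amax > amin) {
          x <- x + stats::runif(1, amin, amax) * d
        }
      }
      if (step %% 200L == 0L) {        # curb drift off the null space
        x <- as.vector(N %*% crossprod(N, x))
        x <- pmin(pmax(x, lb), ub)
      }
    }
    if (step %% thin == 0L) {
      taken <- taken + 1L
      samples[, taken] <- x
    }
  }
  med <- apply(samples, 1, stats::median)
  sdv <- apply(samples, 1, stats::sd)
  mn <- apply(samples, 1, min)
  mx <- apply(samples, 1, max)
  out <- structure(list(
    n_samples = n, seed = seed, growth_fraction = growth_fraction,
    summary = data.frame(id = colnames(S), median = med, sd = sdv,
                         min = mn, max = mx, row.names = NULL)),
    class = "sampling_summary")
  attr(out, "samples") <- samples
  attr(out, "fva") <- fva
  out
}

#' @export
print.sampling_summary <- function(x, ...) {
  cat("sampling_summary:", x$n_samples, "samples, seed", x$seed,
      ", growth fraction", x$growth_fraction, "\n")
  invisible(x)
}

#' Normalize fluxes by the substrate uptake rate
#'
#' Divides fluxes by the absolute flux of the uptake reaction, the scale in
#' which network flux maps are labeled (flux per unit substrate consumed).
#'
#' @param x A `flux_solution` or `sampling_summary`.
#' @param uptake_id Exchange reaction id of the substrate.
#' @return For a solution, a named vector of normalized fluxes; for a
#'   sampling summary, its `summary` data frame with the statistics scaled
#'   by the median uptake magnitude.
#' @export
normalize_by_uptake <- function(x, uptake_id) {
  if (inherits(x, "flux_solution")) {
    if (x$status != "optimal") stop("cannot normalize a non-optimal solution")
    up <- abs(x$fluxes[[uptake_id]])
    if (up <= 1e-9) stop("uptake flux of ", uptake_id, " is zero")
    return(x$fluxes / up)
  }
  if (inherits(x, "sampling_summary")) {
    sm <- x$summary
    up <- abs(sm$median[match(uptake_id, sm$id)])
    if (is.na(up)) stop("unknown uptake reaction ", uptake_id)
    if (up <= 1e-9) stop("uptake flux of ", uptake_id, " is zero")
    sm[c("median", "sd", "min", "max")] <-
      sm[c("median", "sd", "min", "max")] / up
    return(sm)
  }
  stop("x must be a flux_solution or sampling_summary")
}

#' Fraction of flux carried by a subset of routes
#'
#' Sum of flux magnitudes over `numerator_ids` divided by the sum over
#' `denominator_ids`; e.g. the share of EG oxidation carried by the
#' NADP-dependent dehydrogenase.
#'
#' @param fluxes Named numeric vector (e.g. `solution$fluxes`).
#' @param numerator_ids,denominator_ids Reaction ids.
#' @return Fraction in `[0, 1]` when the numerator routes are a subset of
#'   the denominator routes.
#' @export
route_fraction <- function(fluxes, numerator_ids, denominator_ids) {
  missing_ids <- setdiff(c(numerator_ids, denominator_ids), names(fluxes))
  if (length(missing_ids))
    stop("unknown reaction id(s): ", paste(missing_ids, collapse = ", "))
  den <- sum(abs(fluxes[denominator_ids]))
  if (den <= 0) stop("zero denominator flux")
  sum(abs(fluxes[numerator_ids])) / den
}
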