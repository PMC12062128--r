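# Dense bounded-variable two-phase simplex for the flux LPs.
#
# Solves   min  c'x   s.t.  A x = b,  lb <= x <= ub
# with finite bounds on every structural variable (flux bounds are always
# finite in this package; the default open bound is +/-1000 mmol/gCDW/h).
# Phase 1 uses signed artificial columns; phase 2 keeps them pinned at zero.
# Dantzig pricing with a switch to Bland's rule for anti-cycling.

lp_solve_core <- function(cc, A, b, lb, ub, maximize = FALSE,
                          tol = 1e-9, max_iter = NULL) {
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(cc) == n, length(b) == m, length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stop("lp_solve_core requires finite variable bounds")
  if (any(lb > ub + 1e-12))
    return(list(status = "infeasible", x = NULL, obj = NA_real_))
  if (maximize) cc <- -cc
  if (is.null(max_iter)) max_iter <- 50L * (n + m) + 2000L

  # extended problem: n structural + m artificial columns
  ntot <- n + m
  x <- numeric(ntot)
  status <- integer(ntot)            # 0 = at lb, 1 = at ub (nonbasic state)
  x[seq_len(n)] <- ifelse(abs(lb) <= abs(ub), lb, ub)
  status[seq_len(n)] <- ifelse(abs(lb) <= abs(ub), 0L, 1L)

  r <- b - as.vector(A %*% x[seq_len(n)])
  sgn <- ifelse(r >= 0, 1, -1)
  Aext <- cbind(A, diag(sgn, nrow = m))
  lbe <- c(lb, rep(0, m))
  ube <- c(ub, rep(Inf, m))
  basis <- n + seq_len(m)
  x[basis] <- abs(r)

  run_phase <- function(cost, x, basis, status, lbe, ube, bland_after) {
    iter <- 0L
    in_basis <- logical(ntot); in_basis[basis] <- TRUE
    repeat {
      iter <- iter + 1L
      if (iter > max_iter)
        return(list(ok = FALSE, reason = "iteration limit", x = x,
                    basis = basis, status = status))
      B <- Aext[, basis, drop = FALSE]
      luB <- tryCatch(solve(B), error = function(e) NULL)
      if (is.null(luB))
        return(list(ok = FALSE, reason = "singular basis", x = x,
                    basis = basis, status = status))
      nb <- which(!in_basis)
      xN <- x[nb]
      x[basis] <- as.vector(luB %*% (b - Aext[, nb, drop = FALSE] %*% xN))
      y <- as.vector(crossprod(luB, cost[basis]))
      dN <- cost[nb] - as.vector(crossprod(Aext[, nb, drop = FALSE], y))
      # candidate entering: improves objective moving off its bound
      can_inc <- status[nb] == 0L & dN < -tol & lbe[nb] < ube[nb]
      can_dec <- status[nb] == 1L & dN > tol & lbe[nb] < ube[nb]
      cand <- which(can_inc | can_dec)
      if (length(cand) == 0L)
        return(list(ok = TRUE, x = x, basis = basis, status = status,
                    obj = sum(cost * x)))
      if (iter > bland_after) {
        j <- cand[which.min(nb[cand])]           # Bland: smallest index
      } else {
        j <- cand[which.max(abs(dN[cand]))]
      }
      q <- nb[j]
      dirq <- if (status[q] == 0L) 1 else -1     # move up from lb / down from ub
      w <- as.vector(luB %*% Aext[, q])
      dxB <- -dirq * w
      # ratio test over basic vars and the entering var's own opposite bound
      tmax <- ube[q] - lbe[q]
      leave <- 0L; leave_to <- NA_integer_
      xB <- x[basis]
      for (i in seq_len(m)) {
        if (dxB[i] > 1e-11) {
          ti <- (ube[basis[i]] - xB[i]) / dxB[i]
          if (ti < tmax - 1e-12) { tmax <- ti; leave <- i; leave_to <- 1L }
        } else if (dxB[i] < -1e-11) {
          ti <- (lbe[basis[i]] - xB[i]) / dxB[i]
          if (ti < tmax - 1e-12) { tmax <- ti; leave <- i; leave_to <- 0L }
        }
      }
      if (!is.finite(tmax))
        return(list(ok = FALSE, reason = "unbounded", x = x,
                    basis = basis, status = status))
      tmax <- max(tmax, 0)
      x[basis] <- xB + tmax * dxB
      x[q] <- x[q] + dirq * tmax
      if (leave == 0L) {
        status[q] <- 1L - status[q]              # bound flip, basis unchanged
      } else {
        out <- basis[leave]
        x[out] <- if (leave_to == 1L) ube[out] else lbe[out]
        status[out] <- leave_to
        in_basis[out] <- FALSE
        in_basis[q] <- TRUE
        basis[leave] <- q
      }
    }
  }

  # phase 1: drive artificial infeasibility to zero
  cost1 <- c(rep(0, n), rep(1, m))
  ph1 <- run_phase(cost1, x, basis, status, lbe, ube,
                   bland_after = 10L * (n + m))
  if (!ph1$ok) return(list(status = "infeasible", x = NULL, obj = NA_real_))
  if (ph1$obj > 1e-7) return(list(status = "infeasible", x = NULL, obj = NA_real_))
  x <- ph1$x; basis <- ph1$basis; status <- ph1$status
  # pin artificials at zero for phase 2 (basic ones may remain, at value 0)
  ube[(n + 1):ntot] <- 0
  x[(n + 1):ntot][x[(n + 1):ntot] < 1e-9] <- 0

  cost2 <- c(cc, rep(0, m))
  ph2 <- run_phase(cost2, x, basis, status, lbe, ube,
                   bland_after = 10L * (n + m))
  if (!ph2$ok) {
    if (identical(ph2$reason, "unbounded"))
      return(list(status = "unbounded", x = NULL, obj = NA_real_))
    return(list(status = "infeasible", x = NULL, obj = NA_real_))
  }
  xs <- ph2$x[seq_len(n)]
  obj <- sum(cc * xs)
  if (maximize) obj <- -obj
  list(status = "optimal", x = xs, obj = obj)
}
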