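# Internal dense linear-programming core shared by the feasibility tests
# and the MILP branch-and-bound.  Solves
#
#   min / max  c'x   s.t.   A x <= b,   Aeq x = beq,   lb <= x <= ub
#
# with finite bounds on every variable, by a two-phase tableau simplex
# with Bland's anti-cycling rule.  Instances here are tiny (tens of
# variables and rows), so the dense tableau and Bland's conservative
# pivoting are the right trade-off: guaranteed finite termination and no
# degeneracy stalls, at negligible cost.

# Phase engine: minimize cvec' z over the tableau rows Tz = rhs (rhs >= 0
# maintained by pivoting), starting from the given basis.  `allowed`
# masks columns that may enter the basis.  Returns the updated state.
simplex_phase <- function(Tab, rhs, basis, cvec, allowed, tol = 1e-9,
                          max_iter = 100000L) {
  m <- nrow(Tab)
  for (it in seq_len(max_iter)) {
    cb <- cvec[basis]
    red <- cvec - as.numeric(crossprod(Tab, cb))   # reduced costs
    red[basis] <- 0
    cand <- which(allowed & red < -tol)
    if (length(cand) == 0L) {
      return(list(Tab = Tab, rhs = rhs, basis = basis, status = "optimal"))
    }
    j <- cand[[1L]]                                # Bland: smallest index
    col <- Tab[, j]
    rows <- which(col > tol)
    if (length(rows) == 0L) {
      return(list(Tab = Tab, rhs = rhs, basis = basis, status = "unbounded"))
    }
    ratio <- rhs[rows] / col[rows]
    rmin <- min(ratio)
    ties <- rows[ratio <= rmin + tol * (1 + abs(rmin))]
    i <- ties[which.min(basis[ties])]              # Bland tie-break
    # pivot on (i, j)
    piv <- Tab[i, j]
    Tab[i, ] <- Tab[i, ] / piv
    rhs[i] <- rhs[i] / piv
    other <- setdiff(seq_len(m), i)
    f <- Tab[other, j]
    Tab[other, ] <- Tab[other, , drop = FALSE] - outer(f, Tab[i, ])
    rhs[other] <- rhs[other] - f * rhs[i]
    rhs[rhs < 0 & rhs > -1e-11] <- 0
    basis[i] <- j
  }
  stop("simplex iteration limit reached")
}

lp_solve <- function(obj, A = NULL, b = NULL, Aeq = NULL, beq = NULL,
                     lb, ub, maximize = FALSE, tol = 1e-9) {
  n <- length(obj)
  stopifnot(length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb)) || any(!is.finite(ub))) {
    stop("lp_solve() requires finite variable bounds")
  }
  if (any(lb > ub + 1e-12)) {
    return(list(status = "infeasible", x = NULL, objval = NA_real_))
  }
  cc <- if (maximize) -obj else obj

  # shift x = y + lb (y >= 0); upper bounds become rows y_i <= ub_i - lb_i
  if (is.null(A)) { A <- matrix(0, 0L, n); b <- numeric(0L) }
  b <- as.numeric(b) - as.numeric(A %*% lb)
  span <- ub - lb
  fix <- span <= 1e-12           # variables pinned by equal bounds
  bndr <- which(!fix)
  Aub <- diag(1, n)[bndr, , drop = FALSE]
  bub <- span[bndr]
  if (is.null(Aeq)) { Aeq <- matrix(0, 0L, n); beq <- numeric(0L) }
  beq <- as.numeric(beq) - as.numeric(Aeq %*% lb)
  # pinned variables contribute nothing once shifted; force y_i = 0 via ub row
  if (any(fix)) {
    Aub <- rbind(Aub, diag(1, n)[fix, , drop = FALSE])
    bub <- c(bub, rep(0, sum(fix)))
  }

  nle <- nrow(A) + nrow(Aub)
  M <- rbind(A, Aub, Aeq)
  rhs <- c(b, bub, beq)
  m <- nrow(M)
  # No row equilibration: the feasibility margin epsilon (1e-6 kJ/mol in
  # the thermodynamic constraints) must stay well above the phase-1
  # infeasibility threshold below, which is absolute.

  # standard form: add one slack per inequality row, then normalise rhs >= 0
  S <- rbind(diag(1, nle), matrix(0, m - nle, nle))
  Tab <- cbind(M, S)
  negr <- rhs < 0
  Tab[negr, ] <- -Tab[negr, , drop = FALSE]
  rhs[negr] <- -rhs[negr]

  # phase 1: artificial basis
  Na <- ncol(Tab)
  Tab <- cbind(Tab, diag(1, m))
  basis <- Na + seq_len(m)
  c1 <- c(rep(0, Na), rep(1, m))
  allowed1 <- c(rep(TRUE, Na), rep(FALSE, m))
  ph1 <- simplex_phase(Tab, rhs, basis, c1, allowed = rep(TRUE, Na + m),
                       tol = tol)
  if (ph1$status != "optimal") stop("phase-1 simplex failure")
  if (sum(ph1$rhs[ph1$basis > Na]) > 1e-8) {
    return(list(status = "infeasible", x = NULL, objval = NA_real_))
  }
  Tab <- ph1$Tab; rhs <- ph1$rhs; basis <- ph1$basis
  # drive residual artificials out of the basis (degenerate rows)
  for (i in which(basis > Na)) {
    jalt <- which(abs(Tab[i, seq_len(Na)]) > tol)
    if (length(jalt)) {
      j <- jalt[[1L]]
      piv <- Tab[i, j]
      Tab[i, ] <- Tab[i, ] / piv; rhs[i] <- rhs[i] / piv
      other <- setdiff(seq_len(m), i)
      f <- Tab[other, j]
      Tab[other, ] <- Tab[other, , drop = FALSE] - outer(f, Tab[i, ])
      rhs[other] <- rhs[other] - f * rhs[i]
      basis[i] <- j
    }
    # else: redundant constraint row; the artificial stays basic at zero
  }

  c2 <- c(cc, rep(0, Na - n), rep(0, m))
  allowed2 <- c(rep(TRUE, Na), rep(FALSE, m))
  ph2 <- simplex_phase(Tab, rhs, basis, c2, allowed = allowed2, tol = tol)
  if (ph2$status == "unbounded") stop("LP is unbounded")
  if (ph2$status != "optimal") stop("phase-2 simplex failure")

  y <- numeric(Na + m)
  y[ph2$basis] <- ph2$rhs
  x <- y[seq_len(n)] + lb
  x <- pmin(pmax(x, lb), ub)
  list(status = "optimal", x = x, objval = sum(obj * x))
}

# Pure feasibility probe: is {A x <= b, lb <= x <= ub} nonempty?
lp_feasible <- function(A, b, lb, ub) {
  r <- lp_solve(numeric(length(lb)), A = A, b = b, lb = lb, ub = ub)
  identical(r$status, "optimal")
}
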