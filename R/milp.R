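# Internal mixed-integer linear programming by depth-first branch-and-bound
# on the LP relaxation.  Designed for the small indicator-constrained
# instances built by build_milp(): tens of binaries, dense rows.
#
# When `objective_integral = TRUE` every feasible integer solution is known
# to have an integer objective value, which permits the strong pruning rule
# floor(relaxation bound) <= incumbent.

milp_solve <- function(obj, A = NULL, b = NULL, lb, ub, int_vars,
                       maximize = TRUE, int_tol = 1e-6,
                       objective_integral = FALSE, node_cap = 200000L) {
  n <- length(obj)
  sgn <- if (maximize) 1 else -1

  best_x <- NULL
  best_val <- -Inf   # in maximization orientation (sgn * objective)

  # node = list(lb, ub); depth-first, explore the "fix to upper" child first
  # so maximal-cardinality candidates are met early.
  stack <- list(list(lb = lb, ub = ub))
  nodes <- 0L

  while (length(stack) > 0L) {
    node <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    nodes <- nodes + 1L
    if (nodes > node_cap) {
      stop("MILP node cap exceeded (", node_cap, " nodes)")
    }

    rel <- lp_solve(obj, A = A, b = b, lb = node$lb, ub = node$ub,
                    maximize = maximize)
    if (rel$status != "optimal") next
    bound <- sgn * rel$objval
    if (objective_integral) {
      if (floor(bound + 1e-6) <= best_val + 1e-9) next
    } else {
      if (bound <= best_val + 1e-9) next
    }

    xi <- rel$x[int_vars]
    frac <- abs(xi - round(xi))
    jb <- NA_integer_
    if (all(frac <= int_tol)) {
      # Candidate: re-solve with the integers pinned at their rounded
      # values; rounding is not always harmless (a big-M indicator can sit
      # at 1 - eps/M, within int_tol of 1 yet structurally fractional).
      plb <- node$lb; pub <- node$ub
      plb[int_vars] <- round(xi); pub[int_vars] <- round(xi)
      chk <- lp_solve(obj, A = A, b = b, lb = plb, ub = pub,
                      maximize = maximize)
      if (chk$status == "optimal") {
        val <- sgn * chk$objval
        if (val > best_val + 1e-9) {
          best_val <- val
          best_x <- chk$x
        }
        next
      }
      # pinned problem infeasible: branch on a not-yet-pinned near-integral
      # variable (all integers here are binaries)
      loose <- int_vars[frac > 1e-12 & node$lb[int_vars] < node$ub[int_vars]]
      if (length(loose) == 0L) {
        stop("internal error: integral MILP candidate infeasible when pinned")
      }
      jb <- loose[[1L]]
    } else {
      jb <- int_vars[which(frac > int_tol)[1L]] # first fractional, fixed order
    }
    lo <- node; hi <- node
    if (frac[match(jb, int_vars)] > int_tol) {
      lo$ub[jb] <- floor(rel$x[jb])
      hi$lb[jb] <- ceiling(rel$x[jb])
    } else {
      # near-integral but unroundable binary: pin the children to the two
      # ends of its current range (guarantees progress either way)
      lo$ub[jb] <- node$lb[jb]
      hi$lb[jb] <- node$ub[jb]
    }
    # push "floor" child first so the "ceiling" child is explored first
    stack[[length(stack) + 1L]] <- lo
    stack[[length(stack) + 1L]] <- hi
  }

  if (is.null(best_x)) {
    return(list(status = "infeasible", x = NULL, objval = NA_real_,
                nodes = nodes))
  }
  list(status = "optimal", x = best_x, objval = sgn * best_val, nodes = nodes)
}
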