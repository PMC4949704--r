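# Largest thermodynamically consistent sets (LTCSs).
#
# A set of TF EFMs is thermodynamically consistent when one concentration
# vector within the bounds simultaneously drives every reaction used by
# any member in its direction of use; a single witness then certifies
# every nonnegative linear combination of the members (conformality: no
# reversible reaction is used in opposite directions inside the set).  An
# LTCS is a consistent set to which no further TF EFM can be added.  The
# maximum-cardinality set is the optimum of a MILP with one binary per
# EFM, one indicator binary per used reaction-direction, and big-M
# linearized conditional energy constraints; further sets are found by
# successively adding exclusion constraints.

# (reaction, sign) directions used by any column of an EFM matrix,
# restricted to non-exempt reactions; members: which EFMs use each.
used_directions <- function(network, thermo, efms) {
  out <- list()
  for (j in seq_along(network$reaction_ids)) {
    rid <- network$reaction_ids[[j]]
    if (rid %in% thermo$exempt_reactions) next
    sg <- sign(efms[j, ])
    for (s in c(1, -1)) {
      mem <- which(sg == s)
      if (length(mem)) {
        out[[length(out) + 1L]] <- list(reaction = rid, sign = s,
                                        members = mem)
      }
    }
  }
  out
}

#' Build the LTCS mixed-integer linear program
#'
#' Variables: one binary \eqn{\lambda_i} per TF EFM (membership), one
#' indicator binary per reaction-direction used by any EFM, and one
#' continuous log concentration per metabolite.  If any selected EFM uses
#' a direction, its indicator is forced on (counting constraint), which
#' activates the big-M linearized requirement that the reaction energy be
#' at most \eqn{-\epsilon} in that direction.  The objective maximizes the
#' number of selected EFMs; an optional integer-weighted secondary term
#' prefers low EFM indices among equal-cardinality optima, making the
#' enumeration order deterministic.
#'
#' Exclusion of previously found sets supports two schemes:
#' `"cover"` adds, per previous solution, the constraint that at least one
#' EFM never selected so far must be selected (guarantees every TF EFM
#' appears in some returned set); `"exhaustive"` adds, per previous
#' solution, the constraint that at least one EFM outside that solution
#' must be selected, which excludes exactly the subsets of known solutions
#' and therefore enumerates every maximal consistent set.
#'
#' @param network a [metabolic_network()].
#' @param thermo a [thermo_data()].
#' @param tf_efms `efm_set` matrix of individually feasible EFMs.
#' @param exclusions list of previously found member index vectors.
#' @param yield_spec optional list with elements `substrate` (uptake
#'   reaction id) and `thresholds` (named vector, product reaction id ->
#'   minimum yield); for every thresholded product at least one selected
#'   EFM must reach the threshold.
#' @param epsilon feasibility margin (kJ/mol).
#' @param exclusion_mode `"cover"` or `"exhaustive"` (see above).
#' @param tie_break add the secondary lexicographic objective term.
#' @return a `milp_instance` object.
#' @export
build_milp <- function(network, thermo, tf_efms, exclusions = list(),
                       yield_spec = NULL, epsilon = 1e-6,
                       exclusion_mode = c("cover", "exhaustive"),
                       tie_break = TRUE) {
  exclusion_mode <- match.arg(exclusion_mode)
  n <- ncol(tf_efms)
  if (is.null(n) || n == 0L) stop("empty TF EFM set")
  m <- length(network$metabolite_ids)
  dirs <- used_directions(network, thermo, tf_efms)
  D <- length(dirs)
  lnb <- ln_bounds(thermo)
  if (any(!is.finite(lnb$lb)) || any(!is.finite(lnb$ub))) {
    stop("concentration bounds must be finite for the big-M constants")
  }
  eb <- energy_bounds(network, thermo)
  RT <- thermo$gas_constant * thermo$temperature
  g0 <- thermo$dfG0

  nv <- n + D + m
  lam <- seq_len(n); yv <- n + seq_len(D); cv <- n + D + seq_len(m)
  A <- NULL; b <- numeric(0)
  add_row <- function(row, rhs) {
    A <<- rbind(A, row); b <<- c(b, rhs)
  }
  for (d in seq_along(dirs)) {
    dd <- dirs[[d]]
    # counting: sum of member lambdas <= n * y_d
    row <- numeric(nv)
    row[lam[dd$members]] <- 1
    row[yv[d]] <- -n
    add_row(row, 0)
    # big-M energy: s*dG(ln_c) <= -eps + M*(1 - y_d)
    col <- network$S[, dd$reaction]
    act <- col != 0
    base <- sum(col[act] * g0[act])
    M <- if (dd$sign > 0) eb[dd$reaction, "max"] + epsilon else
      -eb[dd$reaction, "min"] + epsilon
    if (!is.finite(M)) stop("non-finite big-M constant for reaction ", dd$reaction)
    row <- numeric(nv)
    row[cv] <- dd$sign * RT * col
    row[yv[d]] <- M
    add_row(row, -epsilon + M - dd$sign * base)
  }
  if (length(exclusions)) {
    if (exclusion_mode == "cover") {
      seen <- integer(0)
      for (P in exclusions) {
        seen <- union(seen, P)
        Z <- setdiff(seq_len(n), seen)
        row <- numeric(nv)
        row[lam[Z]] <- -1
        add_row(row, -1)   # sum_{i in Z} lambda_i >= 1 (infeasible when Z empty)
      }
    } else {
      for (P in exclusions) {
        out <- setdiff(seq_len(n), P)
        row <- numeric(nv)
        row[lam[out]] <- -1
        add_row(row, -1)   # at least one EFM outside P
      }
    }
  }
  if (!is.null(yield_spec)) {
    yt <- efm_yields(network, tf_efms, yield_spec$substrate,
                     names(yield_spec$thresholds))
    for (u in names(yield_spec$thresholds)) {
      ok <- which(!is.na(yt[, u]) & yt[, u] >= yield_spec$thresholds[[u]])
      row <- numeric(nv)
      row[lam[ok]] <- -1
      add_row(row, -1)     # sigma_u >= 1
    }
  }

  W <- n * (n + 1) / 2 + 1
  obj <- numeric(nv)
  obj[lam] <- if (tie_break) W - seq_len(n) else W
  lb <- c(rep(0, n + D), lnb$lb)
  ub <- c(rep(1, n + D), lnb$ub)
  structure(list(obj = obj, A = A, b = b, lb = lb, ub = ub,
                 int_vars = c(lam, yv), n = n, dirs = dirs,
                 lambda_weight = W, tie_break = tie_break,
                 epsilon = epsilon,
                 network = network, thermo = thermo, tf_efms = tf_efms),
            class = "milp_instance")
}

#' @export
print.milp_instance <- function(x, ...) {
  cat("milp_instance: ", x$n, " EFM binaries, ", length(x$dirs),
      " direction indicators, ", length(x$lb) - x$n - length(x$dirs),
      " log concentrations, ", if (is.null(x$A)) 0L else nrow(x$A),
      " constraint rows\n", sep = "")
  invisible(x)
}

ltcs_object <- function(members, member_ids, witness, index = NA_integer_) {
  structure(list(members = members, member_ids = member_ids,
                 witness = witness, cardinality = length(members),
                 index = index),
            class = "ltcs")
}

#' @export
print.ltcs <- function(x, ...) {
  cat("LTCS", if (!is.na(x$index)) paste0(" #", x$index) else "", ": ",
      x$cardinality, " EFM(s): ",
      paste(x$member_ids, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Solve a built LTCS MILP once
#'
#' Branch-and-bound over the LP relaxation.  Returns the
#' maximum-cardinality consistent set together with a joint witness
#' concentration vector (re-derived with maximal slack), or `NULL` when
#' the instance is infeasible, which terminates the enumeration loop.
#'
#' @param instance a `milp_instance` from [build_milp()].
#' @return an `ltcs` object or `NULL`.
#' @export
solve_max_ltcs <- function(instance) {
  sol <- milp_solve(instance$obj, A = instance$A, b = instance$b,
                    lb = instance$lb, ub = instance$ub,
                    int_vars = instance$int_vars, maximize = TRUE,
                    objective_integral = TRUE)
  if (sol$status != "optimal") return(NULL)
  members <- which(sol$x[seq_len(instance$n)] > 0.5)
  if (length(members) == 0L) return(NULL)
  vc <- verify_consistency(instance$network, instance$thermo,
                           instance$tf_efms[, members, drop = FALSE],
                           epsilon = instance$epsilon)
  if (!vc$feasible) {
    stop("internal error: MILP solution failed the joint feasibility check")
  }
  ltcs_object(members, colnames(instance$tf_efms)[members], vc$witness)
}

#' Enumerate largest thermodynamically consistent sets
#'
#' Repeatedly solves the LTCS MILP, after each solution adding an
#' exclusion constraint, until the program becomes infeasible.  The
#' default `"cover"` scheme requires each new solution to contain at
#' least one EFM never selected before; it returns a family of maximal
#' consistent sets whose union is the whole TF set, with the first set of
#' globally maximal cardinality.  `exhaustive = TRUE` instead excludes all
#' subsets of every found solution and provably enumerates *every*
#' maximal consistent set (intended for small instances).
#'
#' @inheritParams build_milp
#' @param exhaustive enumerate all maximal consistent sets.
#' @param max_sets safety cap on the number of solutions.
#' @return list of `ltcs` objects in discovery order.
#' @export
enumerate_ltcs <- function(network, thermo, tf_efms, yield_spec = NULL,
                           epsilon = 1e-6, exhaustive = FALSE,
                           max_sets = 10000L, tie_break = TRUE) {
  mode <- if (exhaustive) "exhaustive" else "cover"
  found <- list()
  prev <- list()
  repeat {
    if (length(found) >= max_sets) {
      warning("stopping after ", max_sets, " sets (max_sets cap)")
      break
    }
    if (mode == "cover" && length(prev) &&
        length(setdiff(seq_len(ncol(tf_efms)), Reduce(union, prev))) == 0L) {
      break   # every TF EFM covered: the next exclusion set is empty
    }
    inst <- build_milp(network, thermo, tf_efms, exclusions = prev,
                       yield_spec = yield_spec, epsilon = epsilon,
                       exclusion_mode = mode, tie_break = tie_break)
    sol <- solve_max_ltcs(inst)
    if (is.null(sol)) break
    sol$index <- length(found) + 1L
    found[[length(found) + 1L]] <- sol
    prev[[length(prev) + 1L]] <- sol$members
  }
  found
}

#' Joint feasibility of a set of EFMs
#'
#' Tests whether one concentration vector within the bounds certifies
#' every member simultaneously: the union of the members' directional
#' constraints must be satisfiable.  A single witness then proves every
#' nonnegative linear combination of the members thermodynamically
#' feasible.  Two members using a non-exempt reversible reaction in
#' opposite directions make the union trivially infeasible (the energy
#' cannot be negative in both directions).
#'
#' @param network a [metabolic_network()].
#' @param thermo a [thermo_data()].
#' @param member_efms matrix whose columns are the member EFMs.
#' @param epsilon feasibility margin (kJ/mol).
#' @return a `feasibility_result`.
#' @export
verify_consistency <- function(network, thermo, member_efms, epsilon = 1e-6) {
  member_efms <- as.matrix(member_efms)
  if (ncol(member_efms) == 0L) stop("empty member set")
  dirs <- used_directions(network, thermo, member_efms)
  rxn <- vapply(dirs, `[[`, character(1L), "reaction")
  both <- unique(rxn[duplicated(rxn)])
  if (length(both)) {
    return(feasibility_result(FALSE, violated_reactions = both))
  }
  cons <- direction_constraints(network, thermo, rxn,
                                vapply(dirs, `[[`, numeric(1L), "sign"),
                                epsilon = epsilon)
  res <- solve_direction_lp(network, thermo, cons)
  if (res$feasible) {
    feasibility_result(TRUE, witness = res$witness)
  } else {
    feasibility_result(FALSE,
                       violated_reactions =
                         irreducible_conflict(network, thermo, cons))
  }
}

#' Maximality of a consistent set
#'
#' A consistent set is maximal when no excluded TF EFM can be added
#' without losing joint feasibility.  Every non-member is tried in turn.
#'
#' @inheritParams verify_consistency
#' @param ltcs an `ltcs` object or an integer vector of member column
#'   indices into `all_tf_efms`.
#' @param all_tf_efms the full TF `efm_set`.
#' @return list with `maximal` (logical) and `addable` (ids of EFMs whose
#'   addition preserves consistency).
#' @export
verify_maximality <- function(network, thermo, ltcs, all_tf_efms,
                              epsilon = 1e-6) {
  members <- if (inherits(ltcs, "ltcs")) ltcs$members else as.integer(ltcs)
  others <- setdiff(seq_len(ncol(all_tf_efms)), members)
  addable <- character(0)
  for (i in others) {
    vc <- verify_consistency(network, thermo,
                             all_tf_efms[, c(members, i), drop = FALSE],
                             epsilon = epsilon)
    if (vc$feasible) addable <- c(addable, colnames(all_tf_efms)[i])
  }
  list(maximal = length(addable) == 0L, addable = addable)
}

#' All maximal consistent sets by exhaustive search
#'
#' Independent brute-force oracle: enumerates subsets of the TF EFMs in
#' decreasing cardinality, tests joint feasibility (with a cheap pairwise
#' direction-compatibility pre-check and a cache keyed by the union of
#' used reaction-directions), and keeps the inclusion-maximal feasible
#' subsets.
#'
#' @inheritParams verify_consistency
#' @param tf_efms the TF `efm_set`.
#' @param max_efms guard: refuse more than this many EFMs.
#' @return list of sorted integer member vectors, ordered by decreasing
#'   cardinality then lexicographically.
#' @export
brute_force_maximal_sets <- function(network, thermo, tf_efms,
                                     epsilon = 1e-6, max_efms = 15L) {
  n <- ncol(tf_efms)
  if (n > max_efms) {
    stop("brute force limited to ", max_efms, " EFMs (got ", n, ")")
  }
  # per-EFM sign over non-exempt reactions, for the quick compatibility check
  chk <- !(network$reaction_ids %in% thermo$exempt_reactions)
  sg <- sign(unclass(tf_efms)[chk, , drop = FALSE])
  cache <- new.env(parent = emptyenv())
  consistent <- function(idx) {
    if (length(idx) >= 2L) {
      smin <- apply(sg[, idx, drop = FALSE], 1L, min)
      smax <- apply(sg[, idx, drop = FALSE], 1L, max)
      if (any(smin < 0 & smax > 0)) return(FALSE)
    }
    pat <- if (length(idx) >= 2L) {
      paste(pmin(pmax(apply(sg[, idx, drop = FALSE], 1L, sum), -1), 1),
            collapse = "")
    } else paste(sg[, idx], collapse = "")
    hit <- cache[[pat]]
    if (!is.null(hit)) return(hit)
    ans <- verify_consistency(network, thermo,
                              tf_efms[, idx, drop = FALSE],
                              epsilon = epsilon)$feasible
    cache[[pat]] <- ans
    ans
  }
  maximal <- list()
  for (k in rev(seq_len(n))) {
    for (idx in utils::combn(n, k, simplify = FALSE)) {
      covered <- any(vapply(maximal, function(M) all(idx %in% M), logical(1L)))
      if (covered) next
      if (consistent(idx)) maximal[[length(maximal) + 1L]] <- idx
    }
  }
  maximal
}
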