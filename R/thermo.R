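# Gibbs energy arithmetic and the per-EFM thermodynamic feasibility test.
#
# All concentrations enter as natural logs of c/c0 (dimensionless,
# c0 = 1 M).  A flux is thermodynamically feasible (TF) when some
# concentration vector within the bounds gives every non-exempt used
# reaction a Gibbs energy of reaction that is negative in its direction
# of use.  The strict inequality dG < 0 is realized as dG <= -epsilon
# with a small configurable epsilon (epsilon = 0 would admit equilibrium
# fluxes, which is physically marginal).

ln_bounds <- function(thermo) {
  list(lb = log(thermo$c_min / thermo$c0),
       ub = log(thermo$c_max / thermo$c0))
}

#' Transformed Gibbs energies of formation at given concentrations
#'
#' \eqn{\Delta_f G'_k = \Delta_f G'^0_k + RT \ln(c_k/c_0)}.
#'
#' @param thermo a [thermo_data()].
#' @param ln_c named numeric vector of log concentrations
#'   (\eqn{\ln(c_k/c_0)}).
#' @return named numeric vector of formation energies (kJ/mol).
#' @export
formation_energy <- function(thermo, ln_c) {
  mets <- names(ln_c)
  if (is.null(mets)) stop("'ln_c' must be a named vector")
  g0 <- thermo$dfG0[mets]
  if (anyNA(g0)) {
    stop("missing formation energy for metabolite(s): ",
         paste(mets[is.na(g0)], collapse = ", "))
  }
  g0 + thermo$gas_constant * thermo$temperature * ln_c
}

#' Gibbs energies of reaction at given concentrations
#'
#' \eqn{\Delta_r G_j = \sum_k S_{kj}\,\Delta_f G'_k} over the internal
#' metabolites.  Reactions in the exempt set (including exchange reactions,
#' whose internal stoichiometry is empty) are reported as `NA`.
#'
#' @param network a [metabolic_network()].
#' @param thermo a [thermo_data()].
#' @param ln_c named log-concentration vector covering all metabolites of
#'   the network.
#' @return named numeric vector, one entry per reaction (kJ/mol; `NA` for
#'   exempt reactions).
#' @export
reaction_energy <- function(network, thermo, ln_c) {
  ln_c <- ln_c[network$metabolite_ids]
  if (anyNA(ln_c)) stop("'ln_c' must cover every network metabolite")
  exempt <- network$reaction_ids %in% thermo$exempt_reactions
  out <- stats::setNames(rep(NA_real_, length(network$reaction_ids)),
                         network$reaction_ids)
  if (any(!exempt)) {
    g0 <- thermo$dfG0
    g0[is.na(g0)] <- 0   # only touches exempt reactions
    gf <- g0 + thermo$gas_constant * thermo$temperature * ln_c
    out[!exempt] <- as.numeric(crossprod(network$S[, !exempt, drop = FALSE], gf))
  }
  out
}

#' Reaction-energy ranges over the concentration box
#'
#' For every non-exempt reaction the attainable interval of
#' \eqn{\Delta_r G_j} as the concentrations range over their bounds,
#' by interval arithmetic: the maximum puts every product at its upper
#' bound and every substrate at its lower bound, and conversely for the
#' minimum.  These intervals provide the big-M constants of the LTCS MILP.
#'
#' @inheritParams reaction_energy
#' @return a matrix with columns `min` and `max`, one row per reaction
#'   (`NA` rows for exempt reactions).
#' @export
energy_bounds <- function(network, thermo) {
  lnb <- ln_bounds(thermo)
  RT <- thermo$gas_constant * thermo$temperature
  rids <- network$reaction_ids
  out <- matrix(NA_real_, length(rids), 2L, dimnames = list(rids, c("min", "max")))
  for (j in seq_along(rids)) {
    if (rids[[j]] %in% thermo$exempt_reactions) next
    col <- network$S[, j]
    act <- which(col != 0)
    g0 <- thermo$dfG0[act]
    if (anyNA(g0)) {
      stop("missing formation energy on non-exempt reaction ", rids[[j]])
    }
    base <- sum(col[act] * g0)
    pos <- col[act] > 0
    hi <- base + RT * (sum(col[act][pos] * lnb$ub[act][pos]) +
                         sum(col[act][!pos] * lnb$lb[act][!pos]))
    lo <- base + RT * (sum(col[act][pos] * lnb$lb[act][pos]) +
                         sum(col[act][!pos] * lnb$ub[act][!pos]))
    out[j, ] <- c(lo, hi)
  }
  out
}

# Directional constraint rows over ln_c for a set of (reaction, sign)
# pairs: sign * dG_j(ln_c) <= -epsilon, written as  a' ln_c <= b.
# Returns list(A, b, reaction, sign); exempt reactions are dropped.
direction_constraints <- function(network, thermo, reactions, signs,
                                  epsilon = 1e-6) {
  RT <- thermo$gas_constant * thermo$temperature
  keep <- !(reactions %in% thermo$exempt_reactions)
  reactions <- reactions[keep]; signs <- signs[keep]
  m <- length(network$metabolite_ids)
  A <- matrix(0, length(reactions), m,
              dimnames = list(NULL, network$metabolite_ids))
  b <- numeric(length(reactions))
  for (i in seq_along(reactions)) {
    col <- network$S[, reactions[[i]]]
    g0 <- thermo$dfG0
    act <- col != 0
    if (anyNA(g0[act])) {
      stop("missing formation energy on non-exempt reaction ", reactions[[i]])
    }
    A[i, ] <- signs[[i]] * RT * col
    b[i] <- -epsilon - signs[[i]] * sum(col[act] * g0[act])
  }
  list(A = A, b = b, reaction = reactions, sign = signs)
}

# Max-margin feasibility over directional constraints: find ln_c in the
# box with every constraint satisfied by at least `epsilon`, maximizing
# the extra slack (capped at 1 kJ/mol to keep the LP bounded).
solve_direction_lp <- function(network, thermo, cons) {
  lnb <- ln_bounds(thermo)
  m <- length(network$metabolite_ids)
  if (nrow(cons$A) == 0L) {
    return(list(feasible = TRUE,
                witness = stats::setNames((lnb$lb + lnb$ub) / 2,
                                          network$metabolite_ids),
                margin = Inf))
  }
  # variables: ln_c (m), slack t
  A <- cbind(cons$A, 1)
  obj <- c(numeric(m), 1)
  r <- lp_solve(obj, A = A, b = cons$b,
                lb = c(lnb$lb, 0), ub = c(lnb$ub, 1), maximize = TRUE)
  if (r$status != "optimal") {
    return(list(feasible = FALSE, witness = NULL, margin = NA_real_))
  }
  list(feasible = TRUE,
       witness = stats::setNames(r$x[seq_len(m)], network$metabolite_ids),
       margin = r$x[m + 1L])
}

feasibility_result <- function(feasible, witness = NULL,
                               violated_reactions = character()) {
  structure(list(feasible = feasible, witness = witness,
                 violated_reactions = violated_reactions),
            class = "feasibility_result")
}

#' @export
print.feasibility_result <- function(x, ...) {
  if (x$feasible) {
    cat("feasible (witness concentration vector attached)\n")
  } else {
    cat("infeasible; conflicting reaction(s): ",
        paste(x$violated_reactions, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

# Deletion filter: shrink an infeasible constraint system to an
# irreducible infeasible subset (each LP is tiny, so O(k) probes are fine).
irreducible_conflict <- function(network, thermo, cons) {
  keep <- seq_len(nrow(cons$A))
  for (i in seq_len(nrow(cons$A))) {
    trial <- setdiff(keep, i)
    sub <- list(A = cons$A[trial, , drop = FALSE], b = cons$b[trial],
                reaction = cons$reaction[trial], sign = cons$sign[trial])
    if (!solve_direction_lp(network, thermo, sub)$feasible) keep <- trial
  }
  unique(cons$reaction[keep])
}

#' Thermodynamic feasibility of a single EFM
#'
#' Tests whether some concentration vector within the bounds drives every
#' non-exempt reaction in the EFM's support in its direction of use
#' (negative reaction energy forward, positive when a reversible reaction
#' is used backward).  When feasible, a witness log-concentration vector
#' with maximal slack is returned; when infeasible, an irreducible
#' conflicting subset of the supported reactions is reported.
#'
#' @param network a [metabolic_network()].
#' @param thermo a [thermo_data()].
#' @param efm signed flux vector (a column of an `efm_set`).
#' @param epsilon feasibility margin in kJ/mol; reaction energies must be
#'   at most `-epsilon` in the direction of use.
#' @return a `feasibility_result` with fields `feasible`, `witness`,
#'   `violated_reactions`.
#' @export
efm_is_tf <- function(network, thermo, efm, epsilon = 1e-6) {
  efm <- as.numeric(efm)
  if (length(efm) != length(network$reaction_ids)) {
    stop("EFM length does not match the network")
  }
  sup <- which(abs(efm) > 0)
  if (length(sup) == 0L) stop("zero vector is not an EFM")
  cons <- direction_constraints(network, thermo,
                                network$reaction_ids[sup], sign(efm[sup]),
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

#' Partition an EFM set by thermodynamic feasibility
#'
#' Applies [efm_is_tf()] to every column and splits the set into the
#' thermodynamically feasible (TF) modes and the infeasible ones,
#' preserving column order.
#'
#' @inheritParams efm_is_tf
#' @param efms an `efm_set` matrix.
#' @return a list with elements `tf` and `infeasible` (both `efm_set`
#'   matrices) and `results` (per-EFM `feasibility_result`s).
#' @export
filter_tf <- function(network, thermo, efms, epsilon = 1e-6) {
  res <- lapply(seq_len(ncol(efms)), function(i) {
    efm_is_tf(network, thermo, efms[, i], epsilon = epsilon)
  })
  names(res) <- colnames(efms)
  ok <- vapply(res, `[[`, logical(1L), "feasible")
  sel <- function(idx) {
    M <- unclass(efms)[, idx, drop = FALSE]
    class(M) <- c("efm_set", class(M))
    M
  }
  list(tf = sel(ok), infeasible = sel(!ok), results = res)
}
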