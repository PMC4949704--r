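# Phenotype screening of LTCSs: yields, reaction-direction signatures,
# Venn segmentation with signed support frequencies, and conformal flux
# decomposition within one set.

#' Molar yields of EFMs
#'
#' Yield of product `u` in EFM `i` is the molar ratio of the product's
#' exchange flux magnitude to the substrate uptake magnitude,
#' \eqn{Y_u^i = |e^i_u| / |e^i_{substrate}|}.  EFMs that do not use the
#' substrate reaction have undefined yields (`NA`).  Yields are invariant
#' under rescaling of an EFM.
#'
#' @param network a [metabolic_network()].
#' @param efms an `efm_set` matrix.
#' @param substrate_rxn reaction id of the substrate uptake flux.
#' @param product_rxns reaction ids of the product fluxes (for ATP-type
#'   yields this may be an internal maintenance reaction).
#' @return numeric matrix, EFMs (rows, named as in `efms`) by products.
#' @export
efm_yields <- function(network, efms, substrate_rxn, product_rxns) {
  bad <- setdiff(c(substrate_rxn, product_rxns), network$reaction_ids)
  if (length(bad)) stop("unknown reaction id(s): ", paste(bad, collapse = ", "))
  up <- abs(efms[substrate_rxn, ])
  Y <- matrix(NA_real_, ncol(efms), length(product_rxns),
              dimnames = list(colnames(efms), product_rxns))
  use <- up > 0
  for (u in product_rxns) {
    Y[use, u] <- abs(efms[u, use]) / up[use]
  }
  Y
}

#' Maximum yields over the members of an LTCS
#'
#' The yield an LTCS can reach for a product is the maximum over the
#' defined yields of its members (any value between zero and this maximum
#' is attainable by combining a maximum-yield member with a zero-yield
#' member).  `NA` when no member uses the substrate.
#'
#' @param ltcs an `ltcs` object or integer vector of member row indices
#'   into `yield_table`.
#' @param yield_table matrix from [efm_yields()].
#' @param products product columns to report (default: all).
#' @return named numeric vector of per-product maxima.
#' @export
max_yields <- function(ltcs, yield_table, products = colnames(yield_table)) {
  members <- if (inherits(ltcs, "ltcs")) ltcs$members else as.integer(ltcs)
  vapply(products, function(u) {
    v <- yield_table[members, u]
    if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
  }, numeric(1L))
}

#' Screen LTCSs by measured yields
#'
#' Keeps the LTCSs whose reachable maximum yield meets or exceeds the
#' measured value for every thresholded product: when the maximum is
#' below a measured yield, no combination of members can reproduce the
#' measurement and the set is excluded.  Undefined maxima count as zero.
#'
#' @param ltcss list of `ltcs` objects.
#' @param yield_table matrix from [efm_yields()].
#' @param thresholds named numeric vector, product reaction id -> minimum
#'   required maximum yield.
#' @return the surviving subset of `ltcss`.
#' @export
screen_by_yields <- function(ltcss, yield_table, thresholds) {
  if (length(thresholds) == 0L) return(ltcss)
  keep <- vapply(ltcss, function(L) {
    mx <- max_yields(L, yield_table, names(thresholds))
    mx[is.na(mx)] <- 0
    all(mx >= thresholds)
  }, logical(1L))
  ltcss[keep]
}

#' Direction signature of a reaction within an LTCS
#'
#' Aggregates the signs with which the members use a reaction:
#' `"zero"` (unused by all members), `"forward"` / `"backward"` (all
#' members use it, one direction), or `"forward-with-zeros"` /
#' `"backward-with-zeros"` (some members idle).  Opposite signs cannot
#' occur inside a consistent set; encountering them raises an error.
#'
#' @param ltcs an `ltcs` object or integer member index vector.
#' @param efms the `efm_set` the members index into.
#' @param reaction a reaction id (row of `efms`).
#' @return a character signature.
#' @export
direction_signature <- function(ltcs, efms, reaction) {
  if (!reaction %in% rownames(efms)) stop("unknown reaction: ", reaction)
  members <- if (inherits(ltcs, "ltcs")) ltcs$members else as.integer(ltcs)
  s <- sign(efms[reaction, members])
  if (any(s > 0) && any(s < 0)) {
    stop("corrupt LTCS: reaction ", reaction,
         " used in opposite directions by members")
  }
  if (all(s == 0)) return("zero")
  dir <- if (any(s > 0)) "forward" else "backward"
  if (any(s == 0)) paste0(dir, "-with-zeros") else dir
}

#' Screen LTCSs by required reaction directions
#'
#' Rules per reaction: `"forward-or-zero"` / `"backward-or-zero"` (no
#' member may use the opposite direction; idle members are fine),
#' `"inactive"` (no member uses the reaction), `"active"` (at least one
#' member uses it, either direction).
#'
#' @param ltcss list of `ltcs` objects.
#' @param efms the `efm_set` the members index into.
#' @param rules named character vector, reaction id -> rule.
#' @return the surviving subset of `ltcss`.
#' @export
screen_by_directions <- function(ltcss, efms, rules) {
  if (length(rules) == 0L) return(ltcss)
  bad <- setdiff(names(rules), rownames(efms))
  if (length(bad)) stop("unknown reaction id(s): ", paste(bad, collapse = ", "))
  ok_rule <- function(sig, rule) {
    switch(rule,
           "forward-or-zero" = sig %in% c("zero", "forward", "forward-with-zeros"),
           "backward-or-zero" = sig %in% c("zero", "backward", "backward-with-zeros"),
           "inactive" = sig == "zero",
           "active" = sig != "zero",
           stop("unknown direction rule: ", rule))
  }
  keep <- vapply(ltcss, function(L) {
    all(vapply(names(rules), function(rxn) {
      ok_rule(direction_signature(L, efms, rxn), rules[[rxn]])
    }, logical(1L)))
  }, logical(1L))
  ltcss[keep]
}

#' Venn segmentation of a selection of LTCSs
#'
#' Partitions the union of the selected LTCSs' members by membership
#' bit-pattern (which of the sets each EFM belongs to).  Per segment it
#' reports the EFM count, the signed support frequency of every reaction
#' (percentage of segment EFMs using the reaction, negative when the
#' common direction is backward), and the distribution of EFM support
#' cardinalities.
#'
#' @param ltcss list of `ltcs` objects (at least one).
#' @param efms the `efm_set` the members index into.
#' @return an object of class `segment_report`: list with `segments`
#'   (per-segment pattern, member ids, count), `frequencies` (reactions
#'   by segments matrix of signed percentages), and
#'   `support_cardinality` (per-segment integer vectors).
#' @export
venn_segments <- function(ltcss, efms) {
  if (length(ltcss) == 0L) stop("need at least one LTCS")
  members <- lapply(ltcss, function(L) {
    if (inherits(L, "ltcs")) L$members else as.integer(L)
  })
  universe <- sort(unique(unlist(members)))
  pat <- vapply(universe, function(i) {
    paste(vapply(members, function(M) as.integer(i %in% M), integer(1L)),
          collapse = "")
  }, character(1L))
  keys <- sort(unique(pat), decreasing = TRUE)
  segments <- list()
  freqs <- matrix(0, nrow(efms), length(keys),
                  dimnames = list(rownames(efms), keys))
  supp_card <- list()
  for (k in keys) {
    idx <- universe[pat == k]
    E <- unclass(efms)[, idx, drop = FALSE]
    sg <- sign(E)
    n_fwd <- rowSums(sg > 0); n_bwd <- rowSums(sg < 0)
    freqs[, k] <- 100 * (n_fwd - n_bwd) / length(idx)
    segments[[k]] <- list(pattern = k,
                          in_sets = which(strsplit(k, "")[[1L]] == "1"),
                          efm_ids = colnames(efms)[idx],
                          members = idx,
                          count = length(idx))
    supp_card[[k]] <- unname(colSums(sg != 0))
  }
  structure(list(segments = segments, frequencies = freqs,
                 support_cardinality = supp_card),
            class = "segment_report")
}

#' @export
print.segment_report <- function(x, ...) {
  cat("segment_report: ", length(x$segments), " nonempty segment(s)\n", sep = "")
  for (s in x$segments) {
    cat("  [", s$pattern, "] sets {",
        paste(s$in_sets, collapse = ","), "}: ", s$count, " EFM(s)\n", sep = "")
  }
  invisible(x)
}

#' Conformal decomposition of a flux within an LTCS
#'
#' Expresses a steady-state flux `v` as a nonnegative combination of the
#' members of one LTCS, \eqn{v = \sum_i \alpha_i e^i} with
#' \eqn{\alpha \ge 0}, by linear programming (minimizing
#' \eqn{\sum_i \alpha_i} as a tie-break among alternative decompositions).
#' Within a consistent set members never oppose each other on a reaction,
#' so any such representation is conformal and inherits the set's
#' witness.  When `v` uses a reaction against the set's direction (or no
#' nonnegative solution exists) the flux is not representable in this
#' set, which is reported rather than raised.
#'
#' @param network a [metabolic_network()].
#' @param v signed steady-state flux vector.
#' @param ltcs an `ltcs` object or integer member index vector.
#' @param efms the `efm_set` the members index into.
#' @param tol numeric tolerance for the steady-state check.
#' @param require_conformal reject fluxes that oppose a member's direction
#'   on some reaction (the default; within an LTCS any nonnegative
#'   representation is automatically conformal).  With `FALSE` the plain
#'   nonnegative least-coefficient LP is solved even when members cancel
#'   each other, which exposes thermodynamically inconsistent
#'   decompositions such as superposing both directions of a reversible
#'   reaction.
#' @return list with `representable` (logical), `coefficients` (named by
#'   member EFM ids, when representable), and `reason` (when not).
#' @export
decompose_flux <- function(network, v, ltcs, efms, tol = 1e-8,
                           require_conformal = TRUE) {
  v <- as.numeric(v)
  if (length(v) != nrow(efms)) stop("flux length does not match the EFM matrix")
  scale <- max(abs(v), 1)
  if (max(abs(network$S %*% v)) > tol * scale * 10) {
    stop("flux is not at steady state (S v != 0)")
  }
  members <- if (inherits(ltcs, "ltcs")) ltcs$members else as.integer(ltcs)
  E <- unclass(efms)[, members, drop = FALSE]
  # sign conflict: v must not oppose the direction any member uses
  conflict <- require_conformal & rowSums(sign(E) * sign(v) < 0) > 0
  if (any(conflict)) {
    return(list(representable = FALSE, coefficients = NULL,
                reason = paste0("flux opposes the set's direction on: ",
                                paste(rownames(efms)[conflict], collapse = ", "))))
  }
  k <- ncol(E)
  amax <- sum(abs(v)) / min(apply(abs(E), 2L, function(x) max(x))) + 1
  r <- lp_solve(rep(1, k), Aeq = E, beq = v,
                lb = rep(0, k), ub = rep(amax, k), maximize = FALSE)
  if (r$status != "optimal") {
    return(list(representable = FALSE, coefficients = NULL,
                reason = "no nonnegative combination of the members equals v"))
  }
  alpha <- stats::setNames(r$x, colnames(efms)[members])
  resid <- max(abs(E %*% r$x - v))
  if (resid > tol * scale * 100) {
    return(list(representable = FALSE, coefficients = NULL,
                reason = "LP residual above tolerance"))
  }
  list(representable = TRUE, coefficients = alpha, residual = resid)
}
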