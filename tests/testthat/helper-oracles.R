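# Independent brute-force oracles used to cross-check the double
# description enumeration and the MILP-based LTCS enumeration.

# Subset-rank EFM oracle: for every support subset T of reactions, accept
# T iff the nullspace of S restricted to T is one-dimensional, nowhere
# zero on T, and sign-feasible for the irreversible reactions; then keep
# the support-minimal accepted vectors.
oracle_efms <- function(net, tol = 1e-9) {
  r <- ncol(net$S)
  found <- list()
  for (sz in seq_len(r)) {
    for (T in utils::combn(r, sz, simplify = FALSE)) {
      sub <- net$S[, T, drop = FALSE]
      qr_ <- qr(sub, tol = 1e-9)
      if (sz - qr_$rank != 1L) next
      ns <- qr.Q(qr(t(sub)), complete = TRUE)[, sz, drop = TRUE]
      if (any(abs(ns) < tol)) next          # support must be exactly T
      irr <- !net$reversible[T]
      if (any(irr)) {
        sgs <- unique(sign(ns[irr]))
        if (length(sgs) > 1L) next
        if (sgs[[1L]] < 0) ns <- -ns
      } else if (ns[[1L]] < 0) ns <- -ns
      full <- numeric(r)
      full[T] <- ns
      found[[length(found) + 1L]] <- ltcsr:::canonicalize_flux(full)
    }
  }
  sups <- lapply(found, function(v) which(abs(v) > 0))
  keep <- vapply(seq_along(found), function(i) {
    !any(vapply(seq_along(found), function(j) {
      j != i && length(sups[[j]]) < length(sups[[i]]) &&
        all(sups[[j]] %in% sups[[i]])
    }, logical(1L)))
  }, logical(1L))
  found <- found[keep]
  if (length(found) == 0L) {
    return(matrix(numeric(0), nrow = r, ncol = 0L))
  }
  M <- do.call(cbind, found)
  rownames(M) <- colnames(net$S)
  M[, ltcsr:::order_efms(M), drop = FALSE]
}

same_efm_sets <- function(E1, E2, tol = 1e-8) {
  ncol(E1) == ncol(E2) &&
    (ncol(E1) == 0L || max(abs(unclass(E1) - unclass(E2))) < tol)
}

member_key <- function(members) paste(sort(members), collapse = ",")

# support of an EFM column as a string like "R1+,R3-,R5+"
signed_support <- function(v, ids = names(v)) {
  s <- which(abs(v) > 0)
  paste0(ids[s], ifelse(v[s] > 0, "+", "-"), collapse = ",")
}
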