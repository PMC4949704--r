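#' @keywords internal
# Canonical scaling: divide by the smallest absolute nonzero entry and
# clean entries below tol to exact zero.
canonicalize_flux <- function(v, tol = 1e-9) {
  v[abs(v) < tol] <- 0
  nz <- abs(v) > 0
  if (!any(nz)) return(v)
  v / min(abs(v[nz]))
}

support_key <- function(v) {
  paste(sprintf("%04d", which(abs(v) > 0)), collapse = ",")
}

# Order EFM columns lexicographically by support index set, then by values.
order_efms <- function(E) {
  keys1 <- apply(E, 2L, support_key)
  keys2 <- apply(E, 2L, function(v) paste(sprintf("%+.6e", v), collapse = ","))
  order(keys1, keys2)
}

#' Enumerate elementary flux modes
#'
#' Computes the complete set of elementary flux modes (EFMs) of a
#' stoichiometric network: the support-minimal steady-state flux vectors
#' that respect all irreversibility constraints.  Each reversible reaction
#' is split into a forward and a backward column, the extreme rays of the
#' resulting pointed polyhedral cone \eqn{\{x \ge 0 : Sx = 0\}} are
#' enumerated by the double-description (Motzkin) iteration with the
#' combinatorial adjacency test, spurious two-cycle rays are dropped, and
#' the two half-reactions are merged back into a signed representation
#' (negative entries mean a reversible reaction runs backward).
#'
#' EFMs are scaled canonically (smallest absolute nonzero entry equal to
#' 1; see [uptake_normalize()] for the alternative convention) and sorted
#' lexicographically by support so the output order is deterministic.  An
#' EFM whose support consists solely of reversible reactions is valid in
#' both orientations; it is reported once, oriented so that its first
#' nonzero entry is positive.
#'
#' @param network a [metabolic_network()].
#' @param max_reactions refuse networks with more reactions than this
#'   (double description is intended for desk-scale models; precomputed
#'   EFM matrices for larger models can be supplied via [read_efms()]).
#' @param tol numeric tolerance for zero tests.
#' @return a numeric matrix of class `efm_set`, reactions (rows) by EFMs
#'   (columns, named `EFM1`, `EFM2`, ...).
#' @export
enumerate_efms <- function(network, max_reactions = 40L, tol = 1e-9) {
  r <- length(network$reaction_ids)
  if (r > max_reactions) {
    stop("network has ", r, " reactions, above the enumeration guard of ",
         max_reactions, "; supply a precomputed EFM file via read_efms()")
  }
  rev <- network$reversible
  # split reversible reactions: columns [irrev & fwd | bwd copies]
  Ssplit <- cbind(network$S, -network$S[, rev, drop = FALSE])
  split_of <- c(seq_len(r), which(rev))          # original reaction index
  split_sign <- c(rep(1, r), rep(-1, sum(rev)))  # orientation of the copy
  rp <- ncol(Ssplit)

  rays <- diag(1, rp)
  zeros <- rays == 0   # logical: which coordinates of each ray are zero
  for (k in seq_len(nrow(Ssplit))) {
    row <- Ssplit[k, ]
    if (all(row == 0)) next
    s <- as.numeric(row %*% rays)
    scale <- pmax(1, apply(abs(rays), 2L, max))
    s[abs(s) <= tol * scale] <- 0
    zi <- which(s == 0); pi <- which(s > 0); ni <- which(s < 0)
    keep <- rays[, zi, drop = FALSE]
    keep_z <- zeros[, zi, drop = FALSE]
    new <- list(); new_z <- list()
    if (length(pi) && length(ni)) {
      for (p in pi) {
        zp <- zeros[, p]
        for (q in ni) {
          zpq <- zp & zeros[, q]
          # adjacency: no third ray's zero set contains zero(p) & zero(q)
          others <- setdiff(c(zi, pi, ni), c(p, q))
          adjacent <- TRUE
          if (length(others)) {
            contained <- colSums(zpq & !zeros[, others, drop = FALSE]) == 0
            if (any(contained)) adjacent <- FALSE
          }
          if (!adjacent) next
          comb <- s[p] * rays[, q] - s[q] * rays[, p]
          comb <- canonicalize_flux(comb, tol)
          new[[length(new) + 1L]] <- comb
          new_z[[length(new_z) + 1L]] <- comb == 0
        }
      }
    }
    if (length(new)) {
      rays <- cbind(keep, do.call(cbind, new))
      zeros <- cbind(keep_z, do.call(cbind, new_z))
    } else {
      rays <- keep
      zeros <- keep_z
    }
    if (ncol(rays) == 0L) break
  }

  if (ncol(rays) == 0L) {
    E <- matrix(numeric(0), nrow = r, ncol = 0L,
                dimnames = list(network$reaction_ids, NULL))
    class(E) <- c("efm_set", class(E))
    return(E)
  }

  # merge the split columns back to a signed representation
  merge_one <- function(x) {
    v <- numeric(r)
    for (jj in seq_len(rp)) {
      v[split_of[jj]] <- v[split_of[jj]] + split_sign[jj] * x[jj]
    }
    v
  }
  V <- apply(rays, 2L, merge_one)
  if (is.null(dim(V))) V <- matrix(V, nrow = r)
  V <- apply(V, 2L, canonicalize_flux, tol = tol)
  if (is.null(dim(V))) V <- matrix(V, nrow = r)
  # drop two-cycles (forward+backward of one reversible reaction cancel out)
  nz <- colSums(abs(V)) > 0
  V <- V[, nz, drop = FALSE]
  # a fully-reversible EFM appears in both orientations: keep the one whose
  # first nonzero entry is positive, then deduplicate
  orient <- function(v) {
    sup <- which(abs(v) > 0)
    if (length(sup) && all(network$reversible[sup]) && v[sup[1L]] < 0) -v else v
  }
  V <- apply(V, 2L, orient)
  if (is.null(dim(V))) V <- matrix(V, nrow = r)
  keys <- apply(V, 2L, function(v) paste(sprintf("%+.9e", v), collapse = ","))
  V <- V[, !duplicated(keys), drop = FALSE]

  V <- V[, order_efms(V), drop = FALSE]
  dimnames(V) <- list(network$reaction_ids,
                      if (ncol(V)) paste0("EFM", seq_len(ncol(V))) else NULL)
  class(V) <- c("efm_set", class(V))
  V
}

#' Rescale EFMs to unit substrate uptake
#'
#' Rescales every column so that the flux through a designated uptake
#' reaction equals 1.  Columns that do not use the uptake reaction are
#' left in canonical scaling.
#'
#' @param efms an `efm_set` matrix.
#' @param uptake_reaction reaction id whose flux is normalized to 1.
#' @return the rescaled `efm_set`.
#' @export
uptake_normalize <- function(efms, uptake_reaction) {
  if (!uptake_reaction %in% rownames(efms)) {
    stop("unknown uptake reaction: ", uptake_reaction)
  }
  up <- efms[uptake_reaction, ]
  sc <- ifelse(abs(up) > 0, abs(up), 1)
  out <- sweep(unclass(efms), 2L, sc, "/")
  class(out) <- c("efm_set", class(out))
  out
}

#' Test elementarity of a steady-state flux
#'
#' A steady-state flux vector is elementary when no reaction can be
#' removed from its support without losing the ability to carry a nonzero
#' steady-state flux, i.e. when the nullspace of the stoichiometric matrix
#' restricted to the support has dimension one.
#'
#' @param network a [metabolic_network()].
#' @param flux signed flux vector of length equal to the number of
#'   reactions (negative entries only on reversible reactions).
#' @param tol numeric tolerance.
#' @return `TRUE` or `FALSE`.
#' @export
is_elementary <- function(network, flux, tol = 1e-9) {
  flux <- as.numeric(flux)
  r <- length(network$reaction_ids)
  if (length(flux) != r) stop("flux length does not match the network")
  scale <- max(abs(flux), 1)
  if (max(abs(network$S %*% flux)) > tol * scale * 100) {
    stop("flux is not at steady state (S v != 0)")
  }
  sup <- which(abs(flux) > tol * scale)
  if (length(sup) == 0L) stop("zero flux vector has no support")
  if (any(flux[sup] < 0 & !network$reversible[sup])) {
    stop("flux uses an irreversible reaction backward")
  }
  sub <- network$S[, sup, drop = FALSE]
  rk <- qr(sub, tol = 1e-9)$rank
  (length(sup) - rk) == 1L
}

#' Write an EFM matrix to TSV
#'
#' One row per reaction, one column per EFM, signed values; the first
#' column holds the reaction ids.  [read_efms()] is the exact inverse.
#'
#' @param efms an `efm_set` matrix.
#' @param path output file path.
#' @export
write_efms <- function(efms, path) {
  df <- data.frame(reaction = rownames(efms),
                   unclass(efms), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an EFM matrix from TSV
#'
#' @param path file path as written by [write_efms()] (or produced by an
#'   external enumerator with the same layout).
#' @param network the [metabolic_network()] the EFMs refer to; the row ids
#'   must match the network's reaction ids exactly (any order).
#' @return an `efm_set` matrix with rows in network reaction order.
#' @export
read_efms <- function(path, network) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!"reaction" %in% names(df)) stop("EFM TSV lacks a 'reaction' column")
  ids <- as.character(df$reaction)
  if (!setequal(ids, network$reaction_ids) || anyDuplicated(ids)) {
    stop("EFM row ids do not match the network's reaction ids")
  }
  M <- as.matrix(df[, setdiff(names(df), "reaction"), drop = FALSE])
  storage.mode(M) <- "double"
  rownames(M) <- ids
  M <- M[network$reaction_ids, , drop = FALSE]
  if (any(colSums(abs(M)) == 0)) {
    stop("EFM file contains an all-zero column (the zero vector is not an EFM)")
  }
  bad <- which(apply(M, 2L, function(v) any(v < 0 & !network$reversible)))
  if (length(bad)) {
    stop("EFM column(s) use an irreversible reaction backward: ",
         paste(colnames(M)[bad], collapse = ", "))
  }
  if (is.null(colnames(M))) colnames(M) <- paste0("EFM", seq_len(ncol(M)))
  class(M) <- c("efm_set", class(M))
  M
}
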