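#' Construct a metabolic network
#'
#' A `metabolic_network` holds the stoichiometric matrix over *internal*
#' metabolites only (external/boundary species are dropped at load time),
#' reaction reversibilities, and an exchange flag marking reactions whose
#' internal stoichiometry is empty (pure uptake/secretion of externals).
#'
#' Sign convention: products positive, substrates negative, reactions read
#' left to right as written in the source file.
#'
#' @param S numeric matrix, metabolites (rows) by reactions (columns).
#' @param reversible logical vector, one entry per reaction.
#' @param exchange logical vector flagging exchange reactions; by default
#'   no reaction is an exchange reaction.  All-zero columns of `S` are only
#'   accepted when flagged here.
#' @param metabolite_ids,reaction_ids identifiers; default to the dimnames
#'   of `S`.
#' @return an object of class `metabolic_network`.
#' @export
metabolic_network <- function(S, reversible, exchange = NULL,
                              metabolite_ids = rownames(S),
                              reaction_ids = colnames(S)) {
  S <- as.matrix(S)
  storage.mode(S) <- "double"
  m <- nrow(S); r <- ncol(S)
  if (m < 1L || r < 1L) stop("network needs at least one metabolite and one reaction")
  if (is.null(metabolite_ids)) metabolite_ids <- paste0("M", seq_len(m))
  if (is.null(reaction_ids)) reaction_ids <- paste0("R", seq_len(r))
  metabolite_ids <- as.character(metabolite_ids)
  reaction_ids <- as.character(reaction_ids)
  if (anyDuplicated(metabolite_ids)) stop("duplicate metabolite ids")
  if (anyDuplicated(reaction_ids)) stop("duplicate reaction ids")
  if (length(metabolite_ids) != m || length(reaction_ids) != r) {
    stop("id lengths do not match the stoichiometric matrix")
  }
  reversible <- as.logical(reversible)
  if (length(reversible) != r || anyNA(reversible)) {
    stop("'reversible' must be a logical vector with one entry per reaction")
  }
  if (is.null(exchange)) exchange <- rep(FALSE, r)
  exchange <- as.logical(exchange)
  if (length(exchange) != r || anyNA(exchange)) {
    stop("'exchange' must be a logical vector with one entry per reaction")
  }
  zero_col <- colSums(abs(S)) == 0
  if (any(zero_col & !exchange)) {
    stop("all-zero stoichiometric column(s) not flagged as exchange: ",
         paste(reaction_ids[zero_col & !exchange], collapse = ", "))
  }
  dimnames(S) <- list(metabolite_ids, reaction_ids)
  structure(list(S = S,
                 reversible = stats::setNames(reversible, reaction_ids),
                 exchange = stats::setNames(exchange, reaction_ids),
                 metabolite_ids = metabolite_ids,
                 reaction_ids = reaction_ids),
            class = "metabolic_network")
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat("metabolic_network: ", length(x$metabolite_ids), " internal metabolites, ",
      length(x$reaction_ids), " reactions (",
      sum(x$reversible), " reversible, ", sum(x$exchange), " exchange)\n",
      sep = "")
  invisible(x)
}

#' Construct thermodynamic data for a network
#'
#' Holds standard transformed Gibbs energies of formation (kJ/mol, `NA`
#' when unavailable), concentration bounds (M), temperature, and the set of
#' reactions exempt from the thermodynamic feasibility check.  Any reaction
#' touching a metabolite with missing formation energy is exempted
#' automatically, as are exchange reactions (their internal stoichiometry
#' is empty so their reaction energy over internal metabolites is
#' identically zero).
#'
#' @param network a [metabolic_network()].
#' @param dfG0 named numeric vector of formation energies (kJ/mol); missing
#'   metabolites get `NA`.
#' @param c_min,c_max named numeric vectors of concentration bounds (M);
#'   defaults 1e-7 and 1 apply to unnamed metabolites.
#' @param temperature temperature in K (default 310.15).
#' @param exempt_reactions additional reaction ids to exempt.
#' @return an object of class `thermo_data`.
#' @export
thermo_data <- function(network, dfG0 = NULL, c_min = NULL, c_max = NULL,
                        temperature = 310.15, exempt_reactions = character()) {
  mets <- network$metabolite_ids
  unknown <- setdiff(c(names(dfG0), names(c_min), names(c_max)), mets)
  if (length(unknown)) {
    warning("ignoring thermodynamic data for unknown metabolite(s): ",
            paste(unique(unknown), collapse = ", "))
  }
  fill <- function(x, default) {
    out <- stats::setNames(rep(default, length(mets)), mets)
    if (!is.null(x)) {
      known <- intersect(names(x), mets)
      out[known] <- x[known]
    }
    out
  }
  g <- fill(dfG0, NA_real_)
  lo <- fill(c_min, 1e-7)
  hi <- fill(c_max, 1)
  if (any(!is.finite(lo)) || any(!is.finite(hi)) || any(lo <= 0)) {
    stop("concentration bounds must be finite and positive")
  }
  if (any(lo > hi)) {
    stop("c_min > c_max for metabolite(s): ",
         paste(mets[lo > hi], collapse = ", "))
  }
  if (!is.numeric(temperature) || temperature <= 0) stop("temperature must be positive")
  bad <- setdiff(exempt_reactions, network$reaction_ids)
  if (length(bad)) stop("unknown exempt reaction(s): ", paste(bad, collapse = ", "))
  # reactions touching a metabolite without formation energy cannot be checked
  miss <- mets[is.na(g)]
  auto <- network$reaction_ids[colSums(abs(network$S[miss, , drop = FALSE])) > 0]
  exempt <- sort(unique(c(as.character(exempt_reactions), auto,
                          network$reaction_ids[network$exchange])))
  structure(list(dfG0 = g, c_min = lo, c_max = hi,
                 temperature = temperature,
                 gas_constant = 8.3145e-3,   # kJ mol^-1 K^-1
                 c0 = 1,
                 exempt_reactions = exempt),
            class = "thermo_data")
}

#' @export
print.thermo_data <- function(x, ...) {
  cat("thermo_data: ", length(x$dfG0), " metabolites (",
      sum(is.na(x$dfG0)), " without formation energy), T = ",
      x$temperature, " K, ", length(x$exempt_reactions),
      " exempt reaction(s)\n", sep = "")
  invisible(x)
}

strip_comments <- function(lines) {
  lines <- sub("#.*$", "", lines)
  trimws(lines)
}

parse_side <- function(txt, rxn) {
  txt <- trimws(txt)
  if (txt == "") return(list(ids = character(), coef = numeric()))
  terms <- strsplit(txt, "\\s*\\+\\s*")[[1L]]
  ids <- character(0); coef <- numeric(0)
  for (tm in terms) {
    tm <- trimws(tm)
    if (tm == "") next
    m <- regmatches(tm, regexec("^([0-9]*\\.?[0-9]+)?\\s*(\\S+)$", tm))[[1L]]
    if (length(m) == 0L) stop("cannot parse term '", tm, "' in reaction ", rxn)
    cf <- if (m[2L] == "") 1 else as.numeric(m[2L])
    ids <- c(ids, m[3L]); coef <- c(coef, cf)
  }
  list(ids = ids, coef = coef)
}

load_network_tsv <- function(path) {
  lines <- strip_comments(readLines(path, warn = FALSE))
  externals <- character(0)
  met_order <- character(0)
  section <- ""
  rxn_ids <- character(0); rev <- logical(0)
  eqs <- list()
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (ln == "") next
    if (grepl("^\\[externals\\]$", ln)) { section <- "ext"; next }
    if (grepl("^\\[metabolites\\]$", ln)) { section <- "met"; next }
    if (grepl("^\\[", ln)) { section <- ""; next }
    if (!grepl("\t", ln, fixed = TRUE) && section != "") {
      # still inside a header block (reaction lines always carry tabs)
      ids <- strsplit(ln, "\\s+")[[1L]]
      if (section == "ext") externals <- c(externals, ids)
      if (section == "met") met_order <- c(met_order, ids)
      next
    }
    section <- ""
    fields <- strsplit(ln, "\t")[[1L]]
    if (length(fields) < 2L) {
      stop("model TSV parse error at line ", i, ": expected id<TAB>equation")
    }
    id <- trimws(fields[[1L]])
    eq <- fields[[2L]]
    is_rev <- grepl("<=>", eq, fixed = TRUE)
    if (!is_rev && !grepl("=>", eq, fixed = TRUE)) {
      stop("model TSV parse error at line ", i, ": no '=>' or '<=>' arrow")
    }
    if (length(fields) >= 3L && trimws(fields[[3L]]) != "") {
      declared <- trimws(fields[[3L]]) %in% c("1", "true", "TRUE", "rev")
      if (declared != is_rev) {
        stop("reversibility flag contradicts arrow for reaction ", id,
             " at line ", i)
      }
    }
    sides <- strsplit(eq, if (is_rev) "<=>" else "=>", fixed = TRUE)[[1L]]
    if (length(sides) == 1L) sides <- c(sides, "")
    rxn_ids <- c(rxn_ids, id)
    rev <- c(rev, is_rev)
    eqs[[length(eqs) + 1L]] <- list(lhs = parse_side(sides[[1L]], id),
                                    rhs = parse_side(sides[[2L]], id))
  }
  if (length(rxn_ids) == 0L) stop("model TSV contains no reactions")
  if (anyDuplicated(rxn_ids)) {
    stop("duplicate reaction id(s): ",
         paste(unique(rxn_ids[duplicated(rxn_ids)]), collapse = ", "))
  }
  all_mets <- unique(unlist(lapply(eqs, function(e) c(e$lhs$ids, e$rhs$ids))))
  is_ext <- (grepl("_e$", all_mets) | all_mets %in% externals) &
    !(all_mets %in% met_order)
  internal <- all_mets[!is_ext]
  if (length(met_order)) {
    # an explicit [metabolites] block fixes the internal ids and their order
    missing_ <- setdiff(internal, met_order)
    if (length(missing_)) {
      stop("metabolite(s) not listed in [metabolites] block: ",
           paste(missing_, collapse = ", "))
    }
    internal <- intersect(met_order, internal)
  }
  if (length(internal) == 0L) stop("model has no internal metabolites")
  S <- matrix(0, length(internal), length(rxn_ids),
              dimnames = list(internal, rxn_ids))
  exch <- logical(length(rxn_ids))
  for (j in seq_along(eqs)) {
    e <- eqs[[j]]
    touched_internal <- FALSE
    for (k in seq_along(e$lhs$ids)) {
      id <- e$lhs$ids[[k]]
      if (id %in% internal) {
        S[id, j] <- S[id, j] - e$lhs$coef[[k]]
        touched_internal <- TRUE
      }
    }
    for (k in seq_along(e$rhs$ids)) {
      id <- e$rhs$ids[[k]]
      if (id %in% internal) {
        S[id, j] <- S[id, j] + e$rhs$coef[[k]]
        touched_internal <- TRUE
      }
    }
    exch[j] <- !touched_internal
  }
  metabolic_network(S, reversible = rev, exchange = exch)
}

load_network_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  sp <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  if (length(sp) == 0L) stop("SBML parse error: no species found")
  sp_id <- xml2::xml_attr(sp, "id")
  if (anyNA(sp_id)) stop("SBML parse error: species without id")
  bc <- xml2::xml_attr(sp, "boundaryCondition")
  external <- !is.na(bc) & bc %in% c("true", "1")
  internal <- sp_id[!external]
  if (anyDuplicated(sp_id)) stop("duplicate species id(s) in SBML file")
  rx <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  if (length(rx) == 0L) stop("SBML parse error: no reactions found")
  rxn_ids <- xml2::xml_attr(rx, "id")
  if (anyNA(rxn_ids)) stop("SBML parse error: reaction without id")
  rev_attr <- xml2::xml_attr(rx, "reversible")
  # SBML L3 has no default for 'reversible'; L2 defaults to true
  rev <- is.na(rev_attr) | rev_attr %in% c("true", "1")
  S <- matrix(0, length(internal), length(rx),
              dimnames = list(internal, rxn_ids))
  exch <- logical(length(rx))
  for (j in seq_along(rx)) {
    touched <- FALSE
    for (side in c(-1, 1)) {
      tag <- if (side < 0) "listOfReactants" else "listOfProducts"
      refs <- xml2::xml_find_all(rx[[j]], paste0("./", tag, "/speciesReference"))
      for (ref in refs) {
        sid <- xml2::xml_attr(ref, "species")
        st <- xml2::xml_attr(ref, "stoichiometry")
        cf <- if (is.na(st)) 1 else as.numeric(st)
        if (!sid %in% sp_id) {
          stop("SBML parse error: reaction ", rxn_ids[[j]],
               " references unknown species ", sid)
        }
        if (sid %in% internal) {
          S[sid, j] <- S[sid, j] + side * cf
          touched <- TRUE
        }
      }
    }
    exch[j] <- !touched
  }
  metabolic_network(S, reversible = rev, exchange = exch)
}

#' Read a stoichiometric model
#'
#' Supports a human-writable TSV dialect (one reaction per line,
#' `id<TAB>equation` with `"1 A + 2 B => C"` for irreversible and `"<=>"`
#' for reversible reactions; metabolites suffixed `_e` or listed under an
#' `[externals]` header are external) and a read-only subset of SBML Level
#' 2/3 core (species with `boundaryCondition="true"` are external).
#' External species are dropped from the stoichiometric matrix; reactions
#' left with an empty internal column are flagged as exchange reactions.
#'
#' @param path file path.
#' @param dialect `"tsv"` or `"sbml"`; guessed from the file extension by
#'   default.
#' @return a [metabolic_network()].
#' @export
load_network <- function(path, dialect = c("auto", "tsv", "sbml")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "tsv"
  }
  switch(dialect, tsv = load_network_tsv(path), sbml = load_network_sbml(path))
}

#' Write a model in the TSV dialect
#'
#' Inverse of [load_network()] for the internal stoichiometry: reloading
#' the written file reproduces `S`, the reversibility vector and the id
#' lists exactly.  Exchange reactions are written with empty equations.
#'
#' @param network a [metabolic_network()].
#' @param path output file path.
#' @export
write_network <- function(network, path) {
  fmt_side <- function(ids, coef) {
    if (length(ids) == 0L) return("")
    paste(ifelse(coef == 1, ids, paste(format(coef, trim = TRUE), ids)),
          collapse = " + ")
  }
  lines <- c("[metabolites]", network$metabolite_ids, "")
  for (j in seq_along(network$reaction_ids)) {
    col <- network$S[, j]
    sub <- which(col < 0); prod <- which(col > 0)
    arrow <- if (network$reversible[[j]]) "<=>" else "=>"
    eq <- paste(fmt_side(network$metabolite_ids[sub], -col[sub]), arrow,
                fmt_side(network$metabolite_ids[prod], col[prod]))
    lines <- c(lines, paste(network$reaction_ids[[j]], eq,
                            as.integer(network$reversible[[j]]), sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a thermodynamics table
#'
#' TSV with columns `metabolite_id`, `dfG0_kJ_per_mol` (or `NA`),
#' `c_min_M`, `c_max_M`; `#` comments allowed; an optional `[exempt]`
#' block lists reaction ids excluded from the feasibility check.  Rows for
#' metabolites not in the network are ignored with a warning; network
#' metabolites absent from the table get the default concentration bounds
#' (1e-7 to 1 M) and a missing formation energy.  Reactions touching a
#' metabolite with missing formation energy are exempted automatically.
#'
#' @param path file path.
#' @param network a [metabolic_network()].
#' @param temperature temperature in K.
#' @return a [thermo_data()].
#' @export
load_thermo <- function(path, network, temperature = 310.15) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- strip_comments(readLines(path, warn = FALSE))
  exempt <- character(0)
  in_ex <- FALSE
  ids <- character(0); g <- numeric(0); lo <- numeric(0); hi <- numeric(0)
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (ln == "") next
    if (grepl("^\\[exempt\\]$", ln)) { in_ex <- TRUE; next }
    if (grepl("^\\[", ln)) { in_ex <- FALSE; next }
    if (in_ex) { exempt <- c(exempt, strsplit(ln, "\\s+")[[1L]]); next }
    fields <- strsplit(ln, "\t")[[1L]]
    if (length(fields) < 4L) {
      stop("thermo TSV parse error at line ", i, ": expected 4 columns")
    }
    if (trimws(fields[[1L]]) == "metabolite_id") next   # header
    ids <- c(ids, trimws(fields[[1L]]))
    gv <- trimws(fields[[2L]])
    g <- c(g, if (toupper(gv) %in% c("NA", "")) NA_real_ else as.numeric(gv))
    lo <- c(lo, as.numeric(fields[[3L]]))
    hi <- c(hi, as.numeric(fields[[4L]]))
  }
  names(g) <- ids; names(lo) <- ids; names(hi) <- ids
  thermo_data(network, dfG0 = g, c_min = lo, c_max = hi,
              temperature = temperature, exempt_reactions = exempt)
}

#' Write a thermodynamics table
#'
#' Inverse of [load_thermo()]; explicitly exempted reactions are written
#' into an `[exempt]` block.
#'
#' @param thermo a [thermo_data()].
#' @param path output file path.
#' @export
write_thermo <- function(thermo, path) {
  lines <- c("metabolite_id\tdfG0_kJ_per_mol\tc_min_M\tc_max_M",
             vapply(names(thermo$dfG0), function(k) {
               paste(k,
                     if (is.na(thermo$dfG0[[k]])) "NA" else
                       format(thermo$dfG0[[k]], digits = 15),
                     format(thermo$c_min[[k]], digits = 15),
                     format(thermo$c_max[[k]], digits = 15), sep = "\t")
             }, character(1L)))
  if (length(thermo$exempt_reactions)) {
    lines <- c(lines, "[exempt]", thermo$exempt_reactions)
  }
  writeLines(lines, path)
  invisible(path)
}

#' The two-metabolite example network
#'
#' A network of two internal metabolites A and B and five reactions —
#' uptake of A (`R1`) and B (`R2`), reversible interconversion `R3`
#' (A to B counted forward), and secretion of A (`R4`) and B (`R5`) —
#' together with symmetric thermodynamic data: A and B share the same
#' formation energy, so within the default concentration bounds either
#' direction of `R3` is individually feasible but never both at once.
#' The boundary reactions `R1`, `R2`, `R4`, `R5` carry metabolites across
#' the system boundary and are exempt from the feasibility check, which
#' therefore hinges on `R3` alone.
#'
#' The network has exactly four elementary flux modes and two largest
#' thermodynamically consistent sets of three modes each, distinguished by
#' the direction of `R3`.
#'
#' @return a list with elements `network` and `thermo`.
#' @export
toy_fixture <- function() {
  S <- matrix(c(1, 0,    # R1: -> A
                0, 1,    # R2: -> B
                -1, 1,   # R3: A <=> B
                -1, 0,   # R4: A ->
                0, -1),  # R5: B ->
              nrow = 2L,
              dimnames = list(c("A", "B"), paste0("R", 1:5)))
  net <- metabolic_network(S, reversible = c(FALSE, FALSE, TRUE, FALSE, FALSE))
  th <- thermo_data(net,
                    dfG0 = c(A = -10, B = -10),
                    exempt_reactions = c("R1", "R2", "R4", "R5"))
  list(network = net, thermo = th)
}
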