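# Random desk-scale networks with thermodynamic data, for testing every
# stage of the pipeline without external model downloads.

#' Configuration for the random network generator
#'
#' Defaults mimic the sparsity of core carbon models at desk scale: sparse
#' internal columns touching 2-4 metabolites with coefficients in {1, 2},
#' a handful of boundary (uptake/secretion) reactions so nontrivial steady
#' states exist, formation energies drawn from a normal distribution, and
#' the conservative default concentration bounds of 1e-7 to 1 M.  Only
#' formation-energy *differences* matter thermodynamically; the default
#' zero-mean spread of 10 kJ/mol, against the roughly 41 kJ/mol of
#' adjustment each metabolite's concentration range affords, produces a
#' realistic mixture in which most modes are individually feasible, some
#' are not, and opposite-direction conflicts on reversible reactions are
#' common.
#'
#' @param n_metabolites number of internal metabolites.
#' @param n_reactions total reactions, including `n_exchange` boundary
#'   reactions.
#' @param n_reversible number of reversible internal reactions.
#' @param n_exchange number of boundary reactions (at least 2: one uptake,
#'   one secretion).
#' @param stoich_values pool of stoichiometric coefficients.
#' @param dfG0_mean,dfG0_sd normal distribution of formation energies
#'   (kJ/mol).
#' @param c_min,c_max concentration bounds (M) applied to all metabolites.
#' @param max_efms reject draws with more EFMs than this (keeps
#'   enumeration-based testing fast).
#' @param seed integer seed fixing all randomness.
#' @return a list of class `generator_config`.
#' @export
generator_config <- function(n_metabolites = 6L, n_reactions = 10L,
                             n_reversible = 3L, n_exchange = 4L,
                             stoich_values = c(1, 2),
                             dfG0_mean = 0, dfG0_sd = 10,
                             c_min = 1e-7, c_max = 1,
                             max_efms = 80L, seed = 1L) {
  if (n_exchange < 2L) stop("need at least one uptake and one secretion reaction")
  if (n_reactions <= n_exchange) stop("no internal reactions left")
  if (n_reversible > n_reactions - n_exchange) {
    stop("more reversible reactions than internal reactions")
  }
  structure(list(n_metabolites = as.integer(n_metabolites),
                 n_reactions = as.integer(n_reactions),
                 n_reversible = as.integer(n_reversible),
                 n_exchange = as.integer(n_exchange),
                 stoich_values = stoich_values,
                 dfG0_mean = dfG0_mean, dfG0_sd = dfG0_sd,
                 c_min = c_min, c_max = c_max,
                 max_efms = as.integer(max_efms),
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Generate a random network with thermodynamic data
#'
#' Draws sparse internal reactions and boundary uptake/secretion
#' reactions, rejecting draws until every metabolite has both a producer
#' and a consumer and the network admits between 1 and `max_efms`
#' elementary flux modes.  Boundary reactions carry metabolites across the
#' system boundary and are exempted from the thermodynamic feasibility
#' check; every internal reaction is thermodynamically constrained.
#' All randomness is fixed by `config$seed`.
#'
#' @param config a [generator_config()].
#' @return list with elements `network` ([metabolic_network()]) and
#'   `thermo` ([thermo_data()]).
#' @export
random_network <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  m <- config$n_metabolites
  mets <- paste0("M", seq_len(m))
  n_int <- config$n_reactions - config$n_exchange

  for (attempt in seq_len(200L)) {
    S <- matrix(0, m, config$n_reactions,
                dimnames = list(mets, paste0("R", seq_len(config$n_reactions))))
    # internal conversions: 2-4 metabolites, >=1 substrate and >=1 product
    for (j in seq_len(n_int)) {
      k <- sample(2:min(4L, m), 1L)
      who <- sample(m, k)
      nsub <- sample(seq_len(k - 1L), 1L)
      cf <- sample(config$stoich_values, k, replace = TRUE)
      S[who[seq_len(nsub)], j] <- -cf[seq_len(nsub)]
      S[who[(nsub + 1L):k], j] <- cf[(nsub + 1L):k]
    }
    # boundary reactions: half uptake, half secretion, distinct metabolites
    # where possible
    n_up <- ceiling(config$n_exchange / 2)
    bnd <- sample(m, config$n_exchange, replace = config$n_exchange > m)
    for (e in seq_len(config$n_exchange)) {
      j <- n_int + e
      S[bnd[[e]], j] <- if (e <= n_up) 1 else -1
    }
    reversible <- rep(FALSE, config$n_reactions)
    reversible[sample(n_int, config$n_reversible)] <- TRUE

    # every metabolite needs a potential producer and consumer
    has_prod <- rowSums(S > 0 | (S != 0 & rep(reversible, each = m))) > 0
    has_cons <- rowSums(S < 0 | (S != 0 & rep(reversible, each = m))) > 0
    if (!all(has_prod & has_cons)) next

    net <- metabolic_network(S, reversible = reversible)
    efms <- tryCatch(enumerate_efms(net), error = function(e) NULL)
    if (is.null(efms)) next
    if (ncol(efms) < 1L || ncol(efms) > config$max_efms) next

    boundary <- paste0("R", n_int + seq_len(config$n_exchange))
    th <- thermo_data(net,
                      dfG0 = stats::setNames(
                        stats::rnorm(m, config$dfG0_mean, config$dfG0_sd), mets),
                      c_min = stats::setNames(rep(config$c_min, m), mets),
                      c_max = stats::setNames(rep(config$c_max, m), mets),
                      exempt_reactions = boundary)
    return(list(network = net, thermo = th))
  }
  stop("rejection cap exceeded; loosen the generator configuration")
}

#' A fixture with guaranteed direction conflict
#'
#' Returns a network containing at least two individually feasible EFMs
#' that use a shared reversible reaction in opposite directions, so that
#' more than one LTCS exists downstream and each LTCS is strictly smaller
#' than the full EFM set.  The two-metabolite example network has exactly
#' this structure.
#'
#' @return list with elements `network` and `thermo`.
#' @export
conflict_pair_fixture <- function() {
  toy_fixture()
}
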