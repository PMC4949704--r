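toy_setup <- function() {
  toy <- toy_fixture()
  E <- enumerate_efms(toy$network)
  sups <- apply(E, 2L, signed_support, ids = rownames(E))
  list(net = toy$network, th = toy$thermo, E = E,
       fwd = unname(which(sups == "R1+,R3+,R5+")),   # uses R3 forward
       bwd = unname(which(sups == "R2+,R3-,R4+")),   # uses R3 backward
       thru_a = unname(which(sups == "R1+,R4+")),
       thru_b = unname(which(sups == "R2+,R5+")))
}

test_that("the toy MILP instance has the expected shape", {
  s <- toy_setup()
  inst <- build_milp(s$net, s$th, s$E)
  expect_equal(inst$n, 4L)                 # one binary per EFM
  expect_equal(length(inst$dirs), 2L)      # R3 forward and backward
  expect_equal(length(inst$lb), 4L + 2L + 2L)
  expect_error(build_milp(s$net, s$th, s$E[, 0]), "empty")
})

test_that("the maximum LTCS on the toy network has cardinality 3", {
  s <- toy_setup()
  sol <- solve_max_ltcs(build_milp(s$net, s$th, s$E))
  expect_s3_class(sol, "ltcs")
  expect_equal(sol$cardinality, 3L)
  expect_setequal(sol$members, c(s$thru_a, s$fwd, s$thru_b))
})

test_that("excluding the first solution yields the opposite-direction set", {
  s <- toy_setup()
  first <- c(s$thru_a, s$fwd, s$thru_b)
  sol <- solve_max_ltcs(build_milp(s$net, s$th, s$E, exclusions = list(first)))
  expect_setequal(sol$members, c(s$thru_a, s$bwd, s$thru_b))
})

test_that("a single-EFM instance returns that EFM", {
  s <- toy_setup()
  sol <- solve_max_ltcs(build_milp(s$net, s$th, s$E[, s$fwd, drop = FALSE]))
  expect_equal(sol$cardinality, 1L)
})

test_that("toy enumeration returns exactly the two documented LTCSs", {
  s <- toy_setup()
  L <- enumerate_ltcs(s$net, s$th, s$E)
  expect_length(L, 2L)
  expect_equal(vapply(L, `[[`, integer(1L), "cardinality"), c(3L, 3L))
  expect_setequal(L[[1L]]$members, c(s$thru_a, s$fwd, s$thru_b))
  expect_setequal(L[[2L]]$members, c(s$thru_a, s$bwd, s$thru_b))
  # every TF EFM appears in at least one set
  expect_setequal(unlist(lapply(L, `[[`, "members")), 1:4)
})

test_that("a network without reversible reactions has a single LTCS", {
  g <- random_network(generator_config(seed = 21, n_reversible = 0L))
  E <- enumerate_efms(g$network)
  ft <- filter_tf(g$network, g$thermo, E)
  L <- enumerate_ltcs(g$network, g$thermo, ft$tf)
  expect_length(L, 1L)
  expect_equal(L[[1L]]$cardinality, ncol(ft$tf))
})

test_that("an unreachable yield threshold makes the program infeasible", {
  s <- toy_setup()
  spec <- list(substrate = "R1", thresholds = c(R5 = 2))  # max yield is 1
  L <- enumerate_ltcs(s$net, s$th, s$E, yield_spec = spec)
  expect_length(L, 0L)
  # reachable threshold keeps only the forward set
  spec2 <- list(substrate = "R1", thresholds = c(R5 = 1))
  L2 <- enumerate_ltcs(s$net, s$th, s$E, yield_spec = spec2)
  expect_true(all(vapply(L2, function(l) s$fwd %in% l$members, logical(1L))))
})

test_that("joint feasibility detects the opposed reversible reaction", {
  s <- toy_setup()
  bad <- verify_consistency(s$net, s$th, s$E[, c(s$fwd, s$bwd)])
  expect_false(bad$feasible)
  expect_equal(bad$violated_reactions, "R3")
  good <- verify_consistency(s$net, s$th, s$E[, c(s$thru_a, s$bwd, s$thru_b)])
  expect_true(good$feasible)
  single <- verify_consistency(s$net, s$th, s$E[, s$fwd, drop = FALSE])
  expect_true(single$feasible)
})

test_that("maximality verification finds addable EFMs", {
  s <- toy_setup()
  full <- verify_maximality(s$net, s$th, c(s$thru_a, s$fwd, s$thru_b), s$E)
  expect_true(full$maximal)
  part <- verify_maximality(s$net, s$th, c(s$thru_a, s$thru_b), s$E)
  expect_false(part$maximal)
  expect_setequal(part$addable, colnames(s$E)[c(s$fwd, s$bwd)])
})

test_that("brute force agrees with the documented toy sets", {
  s <- toy_setup()
  B <- brute_force_maximal_sets(s$net, s$th, s$E)
  expect_length(B, 2L)
  expect_setequal(vapply(B, member_key, character(1L)),
                  c(member_key(c(s$thru_a, s$fwd, s$thru_b)),
                    member_key(c(s$thru_a, s$bwd, s$thru_b))))
  B1 <- brute_force_maximal_sets(s$net, s$th, s$E[, s$fwd, drop = FALSE])
  expect_equal(B1, list(1L))
  big <- matrix(1, nrow(s$E), 16L, dimnames = list(rownames(s$E), NULL))
  expect_error(brute_force_maximal_sets(s$net, s$th, big), "limited")
})

test_that("enumerated LTCSs are sound, covering, and conflict-free", {
  eps <- 1e-6
  for (seed in c(1, 2, 4, 6)) {
    g <- random_network(generator_config(seed = seed))
    E <- enumerate_efms(g$network)
    ft <- filter_tf(g$network, g$thermo, E, epsilon = eps)
    n_tf <- ncol(ft$tf)
    if (n_tf == 0L || n_tf > 14L) next
    L <- enumerate_ltcs(g$network, g$thermo, ft$tf, epsilon = eps)
    expect_gt(length(L), 0L)
    cards <- vapply(L, `[[`, integer(1L), "cardinality")
    expect_true(all(cards[1L] >= cards))   # first solve is the global max
    chk <- !(g$network$reaction_ids %in% g$thermo$exempt_reactions)
    for (l in L) {
      expect_true(verify_consistency(g$network, g$thermo,
                                     ft$tf[, l$members, drop = FALSE],
                                     epsilon = eps)$feasible)
      expect_true(verify_maximality(g$network, g$thermo, l, ft$tf,
                                    epsilon = eps)$maximal)
      # no-cancelation within the set on thermodynamically checked reactions
      sg <- sign(unclass(ft$tf)[chk, l$members, drop = FALSE])
      expect_true(all(apply(sg, 1L, function(x) {
        !(any(x > 0) && any(x < 0))
      })))
      # witness replay with margin
      dg <- reaction_energy(g$network, g$thermo, l$witness)
      for (i in l$members) {
        v <- ft$tf[, i]
        sup <- which(abs(v) > 0 & !is.na(dg))
        if (length(sup)) {
          expect_true(all(sign(v[sup]) * dg[sup] <= -eps * (1 - 1e-6)))
        }
      }
    }
    expect_setequal(unlist(lapply(L, `[[`, "members")), seq_len(n_tf))
  }
})

test_that("exhaustive enumeration matches the brute-force oracle", {
  for (seed in c(1, 2, 4, 6, 9, 13)) {
    g <- random_network(generator_config(seed = seed))
    E <- enumerate_efms(g$network)
    ft <- filter_tf(g$network, g$thermo, E)
    n_tf <- ncol(ft$tf)
    if (n_tf == 0L || n_tf > 12L) next
    Lx <- enumerate_ltcs(g$network, g$thermo, ft$tf, exhaustive = TRUE)
    B <- brute_force_maximal_sets(g$network, g$thermo, ft$tf)
    expect_setequal(vapply(Lx, function(l) member_key(l$members), character(1L)),
                    vapply(B, member_key, character(1L)))
    # the covering scheme never returns more sets than exist
    L <- enumerate_ltcs(g$network, g$thermo, ft$tf)
    expect_lte(length(L), length(Lx))
  }
})
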