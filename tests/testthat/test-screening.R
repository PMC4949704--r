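scr_setup <- function() {
  toy <- toy_fixture()
  E <- enumerate_efms(toy$network)
  sups <- apply(E, 2L, signed_support, ids = rownames(E))
  L <- enumerate_ltcs(toy$network, toy$thermo, E)
  list(net = toy$network, th = toy$thermo, E = E, L = L,
       fwd = unname(which(sups == "R1+,R3+,R5+")),
       bwd = unname(which(sups == "R2+,R3-,R4+")),
       thru_a = unname(which(sups == "R1+,R4+")),
       thru_b = unname(which(sups == "R2+,R5+")))
}

test_that("EFM yields are ratios of exchange fluxes", {
  s <- scr_setup()
  yt <- efm_yields(s$net, s$E, "R1", "R5")
  expect_equal(unname(yt[s$fwd, "R5"]), 1)
  expect_equal(unname(yt[s$thru_a, "R5"]), 0)
  expect_true(is.na(yt[s$thru_b, "R5"]))   # no R1 uptake
  expect_true(is.na(yt[s$bwd, "R5"]))
  # scaling invariance
  E7 <- unclass(s$E); E7[, s$fwd] <- 7 * E7[, s$fwd]
  expect_equal(efm_yields(s$net, E7, "R1", "R5")[s$fwd, "R5"],
               yt[s$fwd, "R5"])
  expect_error(efm_yields(s$net, s$E, "R99", "R5"), "unknown reaction")
})

test_that("LTCS maximum yields and yield screening behave as documented", {
  s <- scr_setup()
  yt <- efm_yields(s$net, s$E, "R1", "R5")
  fwd_set <- s$L[[which(vapply(s$L, function(l) s$fwd %in% l$members,
                               logical(1L)))]]
  bwd_set <- s$L[[which(vapply(s$L, function(l) s$bwd %in% l$members,
                               logical(1L)))]]
  expect_equal(unname(max_yields(fwd_set, yt)), 1)
  expect_equal(unname(max_yields(bwd_set, yt)), 0)  # only the zero-yield mode defined
  expect_length(max_yields(fwd_set, yt, products = character(0)), 0L)

  expect_length(screen_by_yields(s$L, yt, c(R5 = 0)), 2L)      # identity
  expect_length(screen_by_yields(s$L, yt, c(R5 = 1)), 1L)      # equality survives
  expect_length(screen_by_yields(s$L, yt, c(R5 = 1.01)), 0L)   # above global max
  expect_identical(screen_by_yields(s$L, yt, numeric(0)), s$L)
})

test_that("direction signatures aggregate member signs", {
  s <- scr_setup()
  fwd_set <- s$L[[which(vapply(s$L, function(l) s$fwd %in% l$members,
                               logical(1L)))]]
  bwd_set <- s$L[[which(vapply(s$L, function(l) s$bwd %in% l$members,
                               logical(1L)))]]
  expect_equal(direction_signature(fwd_set, s$E, "R3"), "forward-with-zeros")
  expect_equal(direction_signature(bwd_set, s$E, "R3"), "backward-with-zeros")
  expect_equal(direction_signature(c(s$thru_a, s$thru_b), s$E, "R3"), "zero")
  expect_equal(direction_signature(c(s$fwd), s$E, "R3"), "forward")
  expect_error(direction_signature(c(s$fwd, s$bwd), s$E, "R3"), "corrupt")
  expect_error(direction_signature(fwd_set, s$E, "R99"), "unknown reaction")
})

test_that("direction screening applies the documented rules", {
  s <- scr_setup()
  kept <- screen_by_directions(s$L, s$E, c(R3 = "backward-or-zero"))
  expect_length(kept, 1L)
  expect_true(s$bwd %in% kept[[1L]]$members)
  expect_length(screen_by_directions(s$L, s$E, c(R3 = "inactive")), 0L)
  expect_length(screen_by_directions(s$L, s$E, c(R3 = "active")), 2L)
  expect_identical(screen_by_directions(s$L, s$E, character(0)), s$L)
  expect_error(screen_by_directions(s$L, s$E, c(R99 = "active")), "unknown")
  expect_error(screen_by_directions(s$L, s$E, c(R3 = "sideways")),
               "unknown direction rule")
})

test_that("Venn segmentation partitions the union with signed frequencies", {
  s <- scr_setup()
  rep2 <- venn_segments(s$L, s$E)
  expect_length(rep2$segments, 3L)
  counts <- vapply(rep2$segments, `[[`, integer(1L), "count")
  expect_equal(sum(counts), 4L)   # equals |union of the two sets|
  shared <- rep2$segments[["11"]]
  expect_setequal(shared$members, c(s$thru_a, s$thru_b))
  expect_equal(rep2$frequencies["R3", "11"], 0)
  expect_equal(abs(rep2$frequencies["R3", "10"]) +
                 abs(rep2$frequencies["R3", "01"]), 200)  # one +100, one -100
  expect_true(all(abs(rep2$frequencies) <= 100))
  # support cardinalities: the two one-set segments hold the 3-reaction modes
  expect_setequal(unlist(rep2$support_cardinality[c("10", "01")]), c(3L, 3L))
  single <- venn_segments(s$L[1L], s$E)
  expect_length(single$segments, 1L)
  expect_equal(single$segments[[1L]]$count, 3L)
})

test_that("conformal decomposition reproduces the worked example", {
  s <- scr_setup()
  v <- c(1, 2, -1, 2, 1)
  bwd_members <- c(s$thru_a, s$bwd, s$thru_b)
  d <- decompose_flux(s$net, v, bwd_members, s$E)
  expect_true(d$representable)
  expect_equal(unname(d$coefficients), c(1, 1, 1))
  # the R3-forward set cannot represent a flux using R3 backward
  fwd_members <- c(s$thru_a, s$fwd, s$thru_b)
  d2 <- decompose_flux(s$net, v, fwd_members, s$E)
  expect_false(d2$representable)
  expect_match(d2$reason, "R3")
  # scaling: v = 2 x single EFM
  d3 <- decompose_flux(s$net, 2 * s$E[, s$thru_a], s$thru_a, s$E)
  expect_equal(unname(d3$coefficients), 2)
  expect_error(decompose_flux(s$net, c(1, 0, 0, 0, 0), s$thru_a, s$E),
               "steady state")
})

test_that("reconstruction holds for random conformal combinations", {
  s <- scr_setup()
  set.seed(7)
  bwd_members <- c(s$thru_a, s$bwd, s$thru_b)
  for (i in 1:20) {
    a <- stats::runif(3L, 0, 5)
    v <- as.numeric(unclass(s$E)[, bwd_members] %*% a)
    d <- decompose_flux(s$net, v, bwd_members, s$E)
    expect_true(d$representable)
    expect_lt(max(abs(unclass(s$E)[, bwd_members] %*% d$coefficients - v)), 1e-8)
  }
})

test_that("nonnegative combinations within an LTCS replay as feasible", {
  # direct check of the defining property: any nonnegative combination of
  # members satisfies every directional constraint at the shared witness
  set.seed(11)
  for (seed in c(1, 6)) {
    g <- random_network(generator_config(seed = seed))
    E <- enumerate_efms(g$network)
    ft <- filter_tf(g$network, g$thermo, E)
    if (ncol(ft$tf) == 0L || ncol(ft$tf) > 14L) next
    L <- enumerate_ltcs(g$network, g$thermo, ft$tf)
    for (l in L) {
      dg <- reaction_energy(g$network, g$thermo, l$witness)
      for (rep_i in 1:5) {
        a <- stats::runif(l$cardinality, 0, 3)
        v <- as.numeric(unclass(ft$tf)[, l$members, drop = FALSE] %*% a)
        sup <- which(abs(v) > 1e-9 & !is.na(dg))
        if (length(sup)) {
          expect_true(all(sign(v[sup]) * dg[sup] < 0))
        }
      }
    }
  }
})
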