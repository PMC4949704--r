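test_that("formation energies follow dfG'0 + RT ln(c/c0)", {
  toy <- toy_fixture()
  th <- toy$thermo
  # at the reference concentration the standard value is returned exactly
  expect_equal(formation_energy(th, c(A = 0, B = 0)),
               c(A = -10, B = -10))
  # RT ln(1e-7) at 310.15 K, frozen from an independent calculation
  shift <- formation_energy(th, c(A = log(1e-7)))[["A"]] - th$dfG0[["A"]]
  expect_equal(shift, -41.5644130358, tolerance = 1e-9)
  # symmetry: equal dfG'0 and equal ln_c give equal energies
  fe <- formation_energy(th, c(A = -3, B = -3))
  expect_equal(fe[["A"]], fe[["B"]])
  expect_error(formation_energy(thermo_data(toy$network), c(A = 0)),
               "missing formation energy")
})

test_that("reaction energies sum formation energies over the column", {
  toy <- toy_fixture()
  RT <- toy$thermo$gas_constant * toy$thermo$temperature
  dg <- reaction_energy(toy$network, toy$thermo, c(A = -2, B = -2))
  expect_equal(dg[["R3"]], 0)                  # symmetric configuration
  dg2 <- reaction_energy(toy$network, toy$thermo, c(A = -1, B = -2))
  expect_equal(dg2[["R3"]], -RT)
  expect_true(all(is.na(dg[c("R1", "R2", "R4", "R5")])))  # exempt
})

test_that("energy_bounds gives the closed-form interval for R3", {
  toy <- toy_fixture()
  eb <- energy_bounds(toy$network, toy$thermo)
  expect_equal(unname(eb["R3", ]), c(-41.5644130358, 41.5644130358),
               tolerance = 1e-9)
  # point concentration box collapses the interval
  net <- toy$network
  th <- thermo_data(net, dfG0 = c(A = -10, B = -20),
                    c_min = c(A = 1e-3, B = 1e-4),
                    c_max = c(A = 1e-3, B = 1e-4),
                    exempt_reactions = c("R1", "R2", "R4", "R5"))
  eb2 <- energy_bounds(net, th)
  expect_equal(eb2["R3", "min"], eb2["R3", "max"])
})

test_that("energy_bounds brackets random in-box evaluations", {
  g <- random_network(generator_config(seed = 4))
  eb <- energy_bounds(g$network, g$thermo)
  lnb <- ltcsr:::ln_bounds(g$thermo)
  set.seed(99)
  for (i in 1:200) {
    ln_c <- stats::setNames(stats::runif(length(lnb$lb), lnb$lb, lnb$ub),
                            g$network$metabolite_ids)
    dg <- reaction_energy(g$network, g$thermo, ln_c)
    chk <- !is.na(dg)
    expect_true(all(dg[chk] >= eb[chk, "min"] - 1e-8))
    expect_true(all(dg[chk] <= eb[chk, "max"] + 1e-8))
  }
})

test_that("all four toy EFMs are individually feasible", {
  toy <- toy_fixture()
  E <- enumerate_efms(toy$network)
  ft <- filter_tf(toy$network, toy$thermo, E)
  expect_equal(ncol(ft$tf), 4L)
  expect_equal(ncol(ft$infeasible), 0L)
})

test_that("an always-uphill reaction is infeasible and reported", {
  # dfG0 gap larger than the concentration range can compensate
  fx <- gap_fixture(gap = 100)
  E <- enumerate_efms(fx$network)
  expect_equal(ncol(E), 1L)
  res <- efm_is_tf(fx$network, fx$thermo, E[, 1L])
  expect_false(res$feasible)
  expect_equal(res$violated_reactions, "Rconv")
  # a modest gap is rescued by concentrations (bound: RT ln(1e7) ~ 41.6)
  fx2 <- gap_fixture(gap = 30)
  expect_true(efm_is_tf(fx2$network, fx2$thermo, E[, 1L])$feasible)
})

test_that("an EFM supported only by exempt reactions is vacuously feasible", {
  toy <- toy_fixture()
  E <- enumerate_efms(toy$network)
  k <- which(apply(E, 2L, function(v) {
    setequal(rownames(E)[abs(v) > 0], c("R1", "R4"))
  }))
  res <- efm_is_tf(toy$network, toy$thermo, E[, k])
  expect_true(res$feasible)
})

test_that("all-exempt thermodynamics keeps every EFM", {
  g <- random_network(generator_config(seed = 2))
  E <- enumerate_efms(g$network)
  th <- thermo_data(g$network)   # no formation energies: everything exempt
  ft <- filter_tf(g$network, th, E)
  expect_equal(ncol(ft$tf), ncol(E))
})

test_that("witnesses replay with at least the required margin", {
  eps <- 1e-6
  for (seed in c(1, 4, 6)) {
    g <- random_network(generator_config(seed = seed))
    E <- enumerate_efms(g$network)
    ft <- filter_tf(g$network, g$thermo, E, epsilon = eps)
    for (nm in colnames(ft$tf)) {
      res <- ft$results[[nm]]
      dg <- reaction_energy(g$network, g$thermo, res$witness)
      v <- ft$tf[, nm]
      sup <- which(abs(v) > 0 & !is.na(dg))
      if (length(sup)) {
        expect_true(all(sign(v[sup]) * dg[sup] <= -eps * (1 - 1e-6)),
                    info = paste("seed", seed, nm))
      }
    }
  }
})

test_that("widening concentration bounds never loses feasibility", {
  for (seed in c(1, 4, 8)) {
    g <- random_network(generator_config(seed = seed))
    E <- enumerate_efms(g$network)
    ok1 <- vapply(seq_len(ncol(E)), function(i) {
      efm_is_tf(g$network, g$thermo, E[, i])$feasible
    }, logical(1L))
    wide <- g$thermo
    wide$c_min <- wide$c_min / 100
    wide$c_max <- pmin(wide$c_max * 100, 10)
    ok2 <- vapply(seq_len(ncol(E)), function(i) {
      efm_is_tf(g$network, wide, E[, i])$feasible
    }, logical(1L))
    expect_true(all(ok2[ok1]), info = paste("seed", seed))
  }
})

test_that("adding constraints preserves infeasibility (sub-EFM coherence)", {
  fx <- gap_fixture(gap = 100)
  # the uphill conversion alone is infeasible; adding any further
  # directional constraint cannot rescue it
  base <- verify_consistency(fx$network, fx$thermo,
                             matrix(c(1, 1, 1), 3L,
                                    dimnames = list(c("Rin", "Rconv", "Rout"))))
  expect_false(base$feasible)
  th2 <- fx$thermo
  th2$exempt_reactions <- character(0)   # now Rin/Rout constrained too
  more <- verify_consistency(fx$network, th2,
                             matrix(c(1, 1, 1), 3L,
                                    dimnames = list(c("Rin", "Rconv", "Rout"))))
  expect_false(more$feasible)
})
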