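test_that("the fully dephosphorylated, unstimulated system is a fixed point", {
  p <- che_parameters(k1 = 0, k2 = 0)
  d <- che_rhs(network_state(), p)
  expect_equal(unname(d), rep(0, 7))
})

test_that("kinase input rates from the unphosphorylated state are k*XT", {
  p <- che_parameters()
  d <- che_rhs(network_state(), p)
  expect_equal(unname(d["A2P"]), 0.12 * 89.9)   # 10.788 uM/s
  expect_equal(unname(d["A3P"]), 0.98 * 89.9)   # 88.102 uM/s
  expect_equal(unname(d[c("Y3P", "Y4P", "Y6P", "B1P", "B2P")]), rep(0, 5))
})

test_that("closed-form RHS agrees with the per-reaction accumulation oracle", {
  p <- che_parameters()
  set.seed(421)
  for (i in 1:300) {
    s <- rand_state(p)
    got <- che_rhs(s, p)
    want <- oracle_rhs(as.list(s), p)
    expect_equal(got, want, tolerance = 1e-12)
  }
  # and on a perturbed parameterization
  p2 <- che_parameters(k5r = 2e3, Y6T = 22.5, k15b = 0)
  for (i in 1:100) {
    s <- rand_state(p2)
    expect_equal(che_rhs(s, p2), oracle_rhs(as.list(s), p2),
                 tolerance = 1e-12)
  }
})

test_that("with inputs and reverse transfer off, phosphoforms decay monotonically", {
  # no kinase input, no reverse transfer, and no kinase-P reservoir:
  # every RR-P then only loses phosphoryl groups
  p <- che_parameters(k1 = 0, k2 = 0, k3r = 0, k4r = 0, k5r = 0, k6r = 0,
                      k7r = 0, k8r = 0, k9r = 0)
  set.seed(99)
  s0 <- rand_state(p)
  s0[c("A2P", "A3P")] <- 0
  q <- phosrelay:::.p_internal(p)
  out <- deSolve::ode(s0, seq(0, 200, by = 0.5), phosrelay:::.ode_func, q,
                      method = "vode", rtol = 1e-10, atol = 1e-12)
  for (sp in c("Y3P", "Y4P", "Y6P", "B1P", "B2P"))
    expect_true(all(diff(out[, sp]) <= 1e-9))
})

test_that("integration never drives phosphoforms below -atol", {
  p <- che_parameters()
  q <- phosrelay:::.p_internal(p)
  set.seed(7)
  for (i in 1:5) {
    s0 <- rand_state(p)
    out <- deSolve::ode(s0, c(0, 10^seq(-2, 4, length.out = 300)),
                        phosrelay:::.ode_func, q, method = "vode",
                        rtol = 1e-8, atol = 1e-12)
    expect_true(all(out[, phosrelay:::.species] > -1e-12))
  }
})

test_that("scenarios modify exactly what they name and compose", {
  p <- che_parameters()
  ko <- apply_scenario(p, scenario(knockouts = "CheY3"))
  expect_equal(ko$Y3T, 0)
  same <- names(which(unlist(p) == unlist(ko)))
  expect_setequal(setdiff(names(unlist(p)), same), "Y3T")

  np <- apply_scenario(p, scenario(phosphatase_off = TRUE))
  expect_equal(np$k15a, 0)
  expect_equal(np$k15b, 0)

  both <- apply_scenario(p, scenario(knockouts = "CheY6",
                                     rates_zeroed = "k6r"))
  expect_equal(both$Y6T, 0)
  expect_equal(both$k6r, 0)

  expect_identical(unclass(apply_scenario(p, scenario())), unclass(p))
  expect_identical(unclass(apply_scenario(p, NULL)), unclass(p))
  expect_error(scenario(knockouts = "CheZ"), "unknown protein")
  expect_error(scenario(rates_zeroed = "k77"), "unknown rate")
})

test_that("stoichiometry times fluxes reproduces the derivative vector", {
  p <- che_parameters()
  S <- stoichiometry()
  set.seed(11)
  for (i in 1:100) {
    s <- rand_state(p)
    fl <- reaction_fluxes(s, p)
    expect_equal(as.numeric(S %*% fl), unname(che_rhs(s, p)),
                 tolerance = 1e-12)
  }
})
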