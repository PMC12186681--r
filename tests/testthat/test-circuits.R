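# Circuit augmentation, pathway attachment, perturbation knobs.

test_that("adding a circuit is pure augmentation", {
  base <- cellModel()
  m <- addCircuit(base, twoReporterCircuit(u1 = 0.4, u2 = 1))
  expect_equal(nrow(modelGenes(m)), nrow(modelGenes(base)) + 2)
  # removal restores a model whose RHS equals the original everywhere
  back <- removeCircuit(m)
  for (x in random_states(base, 5, seed = 21))
    expect_identical(cellRHS(back, x), cellRHS(base, x))
  expect_error(addCircuit(m, circuitGene("c1")), "duplicate")
  expect_error(addCircuit(base, defaultGenes()), "class 'circuit'")
})

test_that("an uninduced gene is fully off at steady state", {
  m <- two_reporter_model(u1 = 0, u2 = 1)
  ss <- solveSteadyState(m)
  expect_true(ss@converged)
  expect_equal(unname(ss@state[["m_c1"]]), 0)
  expect_equal(unname(ss@state[["p_c1"]]), 0)
  expect_gt(ss@state[["p_c2"]], 0)
})

test_that("expressing a circuit burdens growth", {
  base <- cellModel()
  ss0 <- solveSteadyState(base)
  ss1 <- solveSteadyState(addCircuit(base, twoReporterCircuit(u1 = 1, u2 = 1)))
  expect_true(ss0@converged && ss1@converged)
  expect_lt(ss1@lambda, ss0@lambda)
})

test_that("burden is monotone in induction", {
  m <- two_reporter_model(u1 = 0, u2 = 1)
  lam <- sweep_values(m, "u1", seq(0, 1, length.out = 5), "lambda")$lambda
  expect_true(all(diff(lam) < 0))
})

test_that("the pathway drains M into X with term-level mass balance", {
  m <- pathway_model(mode = "single_cell")
  # flux out of M equals flux into X at every evaluation
  m_off <- removePathway(m)
  for (x in random_states(m, 10, seed = 22)) {
    d <- derivedQuantities(m, x)
    dx <- cellRHS(m, x)
    expect_equal(unname(dx[["X"]]),
                 unname(d$drain - d$lambda * x[["X"]]), tolerance = 1e-9)
    # dM loses exactly the drain relative to the pathway-free model
    dx0 <- cellRHS(m_off, x[setdiff(names(x), "X")])
    scale <- 1 + abs(dx[["M"]]) + abs(d$drain)
    expect_lt(abs(dx0[["M"]] - dx[["M"]] - d$drain), 1e-8 * scale)
  }
  # no enzyme, no production
  x <- random_states(m, 1, seed = 23)[[1]]
  x[["p_enz"]] <- 0
  d <- derivedQuantities(m, x)
  expect_equal(d$drain, 0)
  expect_equal(unname(cellRHS(m, x)[["X"]]),
               unname(-d$lambda * x[["X"]]))
  # half-saturation of the drain
  x[["p_enz"]] <- 50; x[["M"]] <- 300   # kappa_ME of the fixture
  expect_equal(derivedQuantities(m, x)$drain, 30 * 50 / 2)
  expect_error(addPathway(cellModel(), "nope", 1, 1), "not a circuit gene")
})

test_that("steady-state X matches its analytic balance", {
  m <- pathway_model(mode = "chemostat", delta = 0.3)
  ss <- solveSteadyState(m)
  expect_true(ss@converged)
  st <- ss@state
  xan <- 30 * st[["M"]] * st[["p_enz"]] /
    ((300 + st[["M"]]) * ss@lambda)
  expect_equal(unname(st[["X"]]), unname(xan), tolerance = 1e-6)
})

test_that("perturbations are identity at defaults and compose", {
  m <- two_reporter_model()
  same <- applyPerturbations(m)
  for (x in random_states(m, 5, seed = 24))
    expect_identical(cellRHS(same, x), cellRHS(m, x))
  twice <- applyPerturbations(applyPerturbations(m, D_r = 0.5, k_rf = 0.02),
                              D_r = 0.5, k_rf = 0.02)
  expect_equal(modelParams(twice)[["D_r"]], 0.25)
  expect_equal(modelParams(twice)[["k_rf"]], 0.04)
  expect_error(applyPerturbations(m, D_gamma = 0), "> 0")
  expect_error(applyPerturbations(m, k_cm = -1), ">= 0")
})
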