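# The assembled right-hand side: culture modes, flux conservation,
# state-vector contract.

test_that("state vector layout is fixed and round-trips", {
  m <- two_reporter_model()
  nm <- stateNames(m)
  expect_identical(nm[1:5], c("S", "N", "M", "tu", "tc"))
  expect_true(all(c("m_E", "p_E", "p_P", "p_R", "r", "Rt", "Pab", "Rab")
                  %in% nm))
  expect_false("X" %in% nm)           # no pathway attached
  expect_true("X" %in% stateNames(pathway_model()))
  x <- defaultInitialState(m)
  expect_identical(names(x), nm)
  # vector <-> named state is lossless
  expect_identical(unname(x)[match("p_c2", nm)], x[["p_c2"]])
  dx <- cellRHS(m, x)
  expect_identical(names(dx), nm)
  expect_error(cellRHS(m, x[-1]), "length")
  expect_error(cellRHS(m, replace(x, 3, NaN)), "non-finite")
})

test_that("culture modes gate the population equations", {
  x <- defaultInitialState(cellModel(mode = "single_cell"))
  for (st in c(list(x), random_states(cellModel(), 5, seed = 2))) {
    dx <- cellRHS(cellModel(mode = "single_cell"), st)
    expect_identical(unname(dx[["S"]]), 0)
    expect_identical(unname(dx[["N"]]), 0)
  }
  # batch: substrate falls while the population grows
  mb <- cellModel(mode = "batch", S0 = 1e6, N0 = 10)
  xb <- random_states(mb, 3, seed = 4)
  for (st in xb) {
    dx <- cellRHS(mb, st)
    expect_lte(dx[["S"]], 0)
    expect_gte(dx[["N"]], 0)
  }
  # chemostat: dN = (lambda - delta) N, dS carries influx and efflux
  mc <- cellModel(mode = "chemostat", delta = 0.4, k_in = 1e8)
  st <- random_states(mc, 1, seed = 6)[[1]]
  dx <- cellRHS(mc, st)
  lam <- growthRate(mc, st)
  expect_equal(unname(dx[["N"]]), unname((lam - 0.4) * st[["N"]]))
})

test_that("the charging flux is conserved across tu, tc and M", {
  # toggling the charging machinery off must change dtc by -flux and both
  # dtu and dM by +flux: the same molecules move, none are created
  m <- two_reporter_model()
  m0 <- cellModel(params = c(v_T = 0))
  m0 <- addCircuit(m0, twoReporterCircuit(u1 = 0, u2 = 1))
  for (x in random_states(m, 20, seed = 9)) {
    dx1 <- cellRHS(m, x)
    dx0 <- cellRHS(m0, x)
    flux <- dx1[["tc"]] - dx0[["tc"]]
    expect_gte(flux, 0)
    # term magnitudes reach 1e6; allow only float cancellation error
    scale <- 1 + abs(dx0[["tu"]]) + abs(dx1[["tu"]]) + abs(flux)
    expect_lt(abs(dx0[["tu"]] - dx1[["tu"]] - flux), 1e-8 * scale)
    expect_lt(abs(dx0[["M"]] - dx1[["M"]] - flux), 1e-8 * scale)
  }
})

test_that("the tRNA pool balance closes at quasi-steady state", {
  # d(tu + tc)/dt = psi_max * R_r * D_psi - lambda * (tu + tc): charging and
  # the translation cycle cancel between the two pools
  m <- two_reporter_model()
  p <- modelParams(m)
  for (x in random_states(m, 10, seed = 10)) {
    dx <- cellRHS(m, x)
    d <- derivedQuantities(m, x)
    lhs <- dx[["tu"]] + dx[["tc"]]
    rhs <- p[["psi_max"]] * p[["D_psi"]] * d$regulation[["rrn"]] -
      d$lambda * (x[["tu"]] + x[["tc"]])
    scale <- 1 + abs(dx[["tu"]]) + abs(dx[["tc"]])
    expect_lt(abs(lhs - rhs), 1e-8 * scale)
  }
})

test_that("sequestration moves polymerase without destroying it", {
  m <- applyPerturbations(two_reporter_model(), k_rf = 0.07)
  for (x in random_states(m, 10, seed = 12)) {
    dx <- cellRHS(m, x)
    lam <- growthRate(m, x)
    # d(P_tot + P_ab) has no k_rf term: only translation in, dilution out
    total <- dx[["p_P"]] + dx[["Pab"]]
    d <- derivedQuantities(m, x)
    expect_equal(unname(total),
                 unname(d$gamma_j[["P"]] * d$ctilde[["P"]] -
                          lam * (x[["p_P"]] + x[["Pab"]])),
                 tolerance = 1e-9)
    expect_equal(unname(dx[["Pab"]]),
                 unname(0.07 * x[["p_P"]] - lam * x[["Pab"]]))
  }
  # ribosome sequestration engages whenever functional ribosomes exist
  mc <- applyPerturbations(two_reporter_model(), k_cm = 0.05)
  x <- defaultInitialState(mc)
  expect_gt(cellRHS(mc, x)[["Rab"]], 0)
})

test_that("nonnegativity holds along integration from default start", {
  m <- two_reporter_model()
  tr <- integrateModel(m, times = seq(0, 50, by = 0.5), derived = FALSE)
  expect_true(all(as.matrix(tr[, -1]) > -1e-6))
})
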