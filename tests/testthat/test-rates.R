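# Rate laws: elongation, alarmone proxy, regulation, copy numbers, growth.

test_that("transcription elongation saturates in the metabolite pool", {
  m <- cellModel(params = c(tau_max = 6e4, K_tau = 1e3))
  expect_equal(transcriptionElongation(m, 1e3)$tau_X, 3e4)   # half-saturation
  expect_equal(transcriptionElongation(m, 0)$tau_X, 0)
  # hand evaluation: tau_X = 6e4 * 9e3/(1e3+9e3) = 54000; gene of 300 codons
  # completes 54000 / 900 = 60 transcripts per hour
  te <- transcriptionElongation(m, 9e3)
  expect_equal(te$tau_X, 54000)
  expect_equal(unname(te$tau_j[["E"]]), 60)
  # rRNA elongation is metabolite-independent by default
  expect_equal(transcriptionElongation(m, 10)$tau_j[["rrn"]],
               transcriptionElongation(m, 1e8)$tau_j[["rrn"]])
  # and shares the saturation when the documented switch is on
  m2 <- cellModel(params = c(tau_max = 6e4, K_tau = 1e3),
                  options = list(rrn_M_dependent = TRUE))
  r1 <- transcriptionElongation(m2, 1e3)$tau_j[["rrn"]]
  r2 <- transcriptionElongation(m2, 1e9)$tau_j[["rrn"]]
  expect_equal(r1, r2 / 2, tolerance = 1e-2)
  expect_error(transcriptionElongation(m, -1), "M must be")
})

test_that("translation elongation saturates and scales with D_gamma", {
  m <- cellModel()
  p <- modelParams(m)
  expect_equal(translationElongation(m, p[["K_gamma"]])$gamma_X,
               p[["gamma_max"]] / 2)
  big <- translationElongation(m, 1e6 * p[["K_gamma"]])$gamma_X
  expect_equal(big, p[["gamma_max"]], tolerance = 1e-4)
  m2 <- applyPerturbations(m, D_gamma = 0.5)
  expect_equal(translationElongation(m2, 777)$gamma_X,
               translationElongation(m, 777)$gamma_X / 2)
  # protein completion scales inversely with length
  ge <- translationElongation(m, 5e4)$gamma_j
  expect_equal(unname(ge[["P"]] / ge[["E"]]), 300 / 4000)
  expect_error(translationElongation(m, -5), "tc must be")
})

test_that("alarmone proxy is the scaled charged/uncharged ratio", {
  expect_equal(ppgppProxy(100, 100), 1)
  expect_equal(ppgppProxy(0, 50), 0)
  expect_equal(ppgppProxy(200, 100, D_g = 2), 4)
  # floor keeps boundary states finite instead of raising
  expect_true(is.finite(ppgppProxy(10, 0)))
  expect_equal(ppgppProxy(10, 0, theta_floor = 1e-9), 1e10)
  expect_error(ppgppProxy(-1, 1), ">= 0")
  expect_error(ppgppProxy(1, 1, D_g = 0), "D_g")
})

test_that("regulation functions hit their half-points and partition", {
  m <- two_reporter_model(u1 = 0.25, u2 = 1)
  nm <- stateNames(m)
  x <- setNames(rep(100, length(nm)), nm)
  # theta = tc/tu = 1 = kappa_theta: resource and enzyme classes at 1/2
  x["tu"] <- x["tc"] <- 500
  x["p_Q"] <- modelParams(m)[["kappa_q"]]
  r <- regulationValues(m, x)
  expect_equal(unname(r[["P"]]), 0.5)
  expect_equal(unname(r[["R"]]), 0.5)
  expect_equal(unname(r[["rrn"]]), 0.5)
  expect_equal(unname(r[["E"]]), 0.5)
  expect_equal(unname(r[["Q"]]), 0.5)
  # R_E + R_P = 1 at any theta
  x["tc"] <- 1234
  r2 <- regulationValues(m, x)
  expect_equal(unname(r2[["E"]] + r2[["P"]]), 1)
  # circuit gene scales the enzyme-type factor by its induction
  expect_equal(unname(r2[["c1"]]), unname(0.25 * r2[["E"]]))
  m0 <- setInduction(m, "c1", 0)
  expect_equal(unname(regulationValues(m0, x)[["c1"]]), 0)
  expect_error(setInduction(m, "c1", 1.5), "\\[0, 1\\]")
  expect_true(all(r >= 0 & r <= 1))
})

test_that("effective copy number expands with growth rate", {
  m <- cellModel()
  g0 <- modelGenes(m)$g0
  expect_equal(unname(effectiveCopyNumber(m, 0)), g0)
  mq <- cellModel(params = c(q_x = 0))
  expect_equal(unname(effectiveCopyNumber(mq, 2)), g0)
  # g0 = 7, q_x = 1, lambda = ln 2 doubles the copy number
  m1 <- cellModel(params = c(q_x = 1))
  expect_equal(unname(effectiveCopyNumber(m1, log(2))[["rrn"]]), 14)
  # rRNA dosage perturbation multiplies on top
  m2 <- applyPerturbations(m1, D_r = 3 / 7)
  expect_equal(unname(effectiveCopyNumber(m2, 0)[["rrn"]]), 3)
  expect_error(effectiveCopyNumber(m, -1), "lambda")
})

test_that("growth rate is translational capacity over cell mass", {
  m <- two_reporter_model()
  st <- random_states(m, 5, seed = 7)
  for (x in st) {
    d <- derivedQuantities(m, x)
    expect_equal(d$lambda,
                 d$gamma_X * sum(d$ctilde) / modelParams(m)[["M0"]])
  }
  # no ribosomes, no growth
  x <- st[[1]]
  x["Rt"] <- 0
  expect_equal(growthRate(m, x), 0)
  x["Rt"] <- 50; x["tc"] <- 0
  expect_equal(growthRate(m, x), 0)
  # doubling M0 halves lambda at fixed state
  m2 <- cellModel(params = c(M0 = 2 * defaultParams()[["M0"]]))
  x2 <- random_states(m2, 1, seed = 8)[[1]]
  expect_equal(growthRate(m2, x2),
               growthRate(cellModel(), x2) / 2)
})

test_that("mass fractions weight copies by length and sum to one", {
  m <- cellModel()
  nm <- stateNames(m)
  x <- setNames(numeric(length(nm)), nm)
  # two populated proteins with equal counts and n_E = n_Q: equal shares
  x["p_E"] <- 100; x["p_Q"] <- 100
  phi <- massFractions(m, x)
  expect_equal(unname(phi[["E"]]), 0.5)
  # P is 4000 aa vs E 300 aa: same counts, mass ratio 4000/4300
  x["p_Q"] <- 0; x["p_P"] <- 100
  phi <- massFractions(m, x)
  expect_equal(unname(phi[["P"]]), 4000 / 4300)
  expect_equal(sum(phi), 1)
  # assembled and sequestered ribosomes count as r-protein mass
  x["Rt"] <- 10; x["Rab"] <- 5; x["p_R"] <- 5
  phi <- massFractions(m, x)
  expect_equal(unname(phi[["R"]]),
               7500 * 20 / (7500 * 20 + 300 * 100 + 4000 * 100))
  expect_error(massFractions(m, setNames(numeric(length(nm)), nm)),
               "zero total")
})
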