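# Growth-law calibration: curves, the normalized error, the weighted cost,
# the synthetic-data generator and the swarm optimizer.

test_that("normalized SSE behaves as a scale-free error", {
  expect_equal(normalizedSSE(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(normalizedSSE(c(0, 0), c(3, 4)), 1)   # sim = 0 gives exactly 1
  expect_equal(normalizedSSE(c(2, 2), c(1, 1)), 1)
  # invariant under a common rescaling of both vectors
  s <- runif(5); e <- runif(5) + 0.5
  expect_equal(normalizedSSE(10 * s, 10 * e), normalizedSSE(s, e))
  expect_error(normalizedSSE(c(1, 2), c(0, 0)), "all zero")
  expect_error(normalizedSSE(1:3, 1:4), "equal length")
})

test_that("the weighted cost carries the six terms with their weights", {
  w <- cellecon:::.cost_weights
  expect_equal(unname(w), c(10, 5, 5, 1, 1, 1))
  expect_equal(sum(w), 23)   # all-sigma-one total
  m <- cellModel()
  dat <- synthGrowthLawData(m, phi_grid = c(0.1, 1), kcm_grid = 0)
  cache <- new.env()
  expect_equal(as.numeric(fitCost(m, dat, warm_cache = cache)), 0)
  # doubling one observable series makes its sigma exactly 1/4
  # (sum((x - 2x)^2) / sum((2x)^2)), so the weight is read off the cost
  d2 <- dat
  d2$lambda[d2$source == "DB"] <- 2 * d2$lambda[d2$source == "DB"]
  expect_equal(as.numeric(fitCost(m, d2, warm_cache = cache)), 10 / 4)
  d3 <- dat
  d3$phi_R[d3$source == "Scott"] <- 2 * d3$phi_R[d3$source == "Scott"]
  expect_equal(as.numeric(fitCost(m, d3, warm_cache = cache)), 5 / 4)
  # all six series doubled: cost = 23/4
  d4 <- dat
  for (col in c("lambda", "phi_R", "gamma", "theta"))
    d4[[col]] <- 2 * d4[[col]]
  expect_equal(as.numeric(fitCost(m, d4, warm_cache = cache)), 23 / 4)
  # missing series contribute zero, each with its own warning
  d5 <- dat[dat$source == "DB", ]
  ws <- capture_warnings(c5 <- fitCost(m, d5, warm_cache = cache))
  expect_match(ws, "lambda_Scott", all = FALSE)
  expect_match(ws, "R_Scott", all = FALSE)
  expect_equal(as.numeric(c5), 0)
})

test_that("growth-law curves reproduce the nutrient and inhibitor laws", {
  m <- cellModel()
  cv <- growthLawCurves(m, phi_grid = c(0.05, 0.2, 1), kcm_grid = c(0, 2))
  expect_true(all(cv$converged))
  # lambda increases with nutrient quality at k_cm = 0
  noab <- cv[cv$k_cm == 0, ]
  expect_true(all(diff(noab$lambda) > 0))
  # translation inhibition lowers growth and raises ribosome content
  for (phi in unique(cv$phi)) {
    sub <- cv[cv$phi == phi, ]
    expect_lt(sub$lambda[sub$k_cm == 2], sub$lambda[sub$k_cm == 0])
    expect_gt(sub$phi_R[sub$k_cm == 2], sub$phi_R[sub$k_cm == 0])
  }
  # explicit conditions give exactly one row each
  one <- growthLawCurves(m, conditions = data.frame(phi = 1, k_cm = 0))
  expect_equal(nrow(one), 1)
})

test_that("the synthetic dataset is exact at zero noise and seeded", {
  m <- cellModel()
  grid <- list(phi = c(0.1, 1), kcm = c(0, 1))
  d0 <- synthGrowthLawData(m, grid$phi, grid$kcm, noise_sd = 0)
  cv <- growthLawCurves(m, grid$phi, grid$kcm)
  db <- d0[d0$source == "DB", ]
  expect_equal(db$lambda, cv$lambda)
  expect_equal(db$theta, cv$theta)
  expect_true(all(is.na(d0$gamma[d0$source == "Scott"])))
  d1 <- synthGrowthLawData(m, grid$phi, grid$kcm, noise_sd = 0.05, seed = 99)
  d2 <- synthGrowthLawData(m, grid$phi, grid$kcm, noise_sd = 0.05, seed = 99)
  expect_identical(d1, d2)
  d3 <- synthGrowthLawData(m, grid$phi, grid$kcm, noise_sd = 0.05, seed = 100)
  expect_false(identical(d1, d3))
})

test_that("multiplicative noise has the stated spread", {
  m <- cellModel()
  phi_grid <- seq(0.05, 1, length.out = 9)
  kcm_grid <- c(0, 0.5, 1, 2, 4)
  clean <- synthGrowthLawData(m, phi_grid, kcm_grid, noise_sd = 0)
  noisy <- synthGrowthLawData(m, phi_grid, kcm_grid, noise_sd = 0.05,
                              seed = 7)
  rel <- unlist(lapply(c("lambda", "phi_R", "gamma", "theta"), function(col)
    (noisy[[col]] - clean[[col]]) / clean[[col]]))
  rel <- rel[is.finite(rel)]
  expect_gte(length(rel), 200)
  expect_gt(sd(rel), 0.03)
  expect_lt(sd(rel), 0.07)
})

test_that("the swarm is deterministic and its trace never worsens", {
  m <- cellModel()
  dat <- synthGrowthLawData(m, phi_grid = c(0.1, 1), kcm_grid = 0)
  free <- list(gamma_max = defaultParams()[["gamma_max"]] * c(0.7, 1.4))
  f1 <- fitParameters(m, dat, free, swarm = 6, generations = 4, seed = 5)
  f2 <- fitParameters(m, dat, free, swarm = 6, generations = 4, seed = 5)
  expect_identical(f1$par, f2$par)
  expect_identical(f1$trace, f2$trace)
  expect_true(all(diff(f1$trace) <= 0))
  expect_equal(f1$evaluations, 6 * 5)
  expect_error(fitParameters(m, dat, list(nonsense = c(0, 1))),
               "named list")
  expect_error(fitParameters(m, dat, list(gamma_max = c(2, 1))),
               "lower < upper")
})

test_that("the cost surface identifies the generating parameters", {
  m <- cellModel()
  dat <- synthGrowthLawData(m, phi_grid = c(0.1, 0.3, 1), kcm_grid = c(0, 2))
  cache <- new.env()
  c0 <- as.numeric(fitCost(m, dat, warm_cache = cache))
  expect_equal(c0, 0)
  for (pn in c("gamma_max", "K_gamma", "kappa_theta")) {
    for (fac in c(0.8, 1.2)) {
      mp <- m
      mp@params[[pn]] <- mp@params[[pn]] * fac
      cp <- as.numeric(fitCost(mp, dat, warm_cache = cache))
      expect_gt(cp, c0)
    }
  }
})
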