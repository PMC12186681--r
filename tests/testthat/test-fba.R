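# Flux balance capacity module: fixture network, SBML round trip, protein
# demand, LP optima, FVA classification, subsystem aggregation.

toy_protein <- "MGKVLAADE"   # 9 residues over 7 amino-acid species

test_that("the fixture network is deterministic and well formed", {
  net <- toyNetworkFixture()
  expect_s4_class(net, "FluxNetwork")
  r <- reactions(net)
  expect_equal(nrow(r), 30)
  expect_equal(nrow(metabolites(net)), 27)
  expect_gte(length(unique(r$subsystem)), 2)
  expect_true(all(!is.na(r$subsystem)))
  f1 <- tempfile(fileext = ".xml"); f2 <- tempfile(fileext = ".xml")
  toyNetworkFixture(f1); toyNetworkFixture(f2)
  expect_identical(readLines(f1), readLines(f2))   # byte-identical output
})

test_that("SBML serialization round-trips the network", {
  net <- toyNetworkFixture()
  f <- tempfile(fileext = ".xml")
  writeSBMLNetwork(net, f)
  back <- readSBMLNetwork(f)
  expect_equal(reactions(back)$id, reactions(net)$id)
  expect_equal(reactions(back)$lb, reactions(net)$lb)
  expect_equal(reactions(back)$ub, reactions(net)$ub)
  expect_equal(reactions(back)$subsystem, reactions(net)$subsystem)
  expect_equal(metabolites(back)$id, metabolites(net)$id)
  expect_equal(unname(stoichiometry(back)), unname(stoichiometry(net)))
  # and the re-serialization is identical to the first
  f2 <- tempfile(fileext = ".xml")
  writeSBMLNetwork(back, f2)
  expect_identical(readLines(f), readLines(f2))
  expect_error(readSBMLNetwork(tempfile()), "no such file")
})

test_that("the demand reaction mirrors the sequence composition", {
  net <- toyNetworkFixture()
  aug <- addProteinDemand(net, "MG", gtp_per_bond = 2)
  S <- stoichiometry(aug)
  expect_equal(S["aa_M_c", "PROT_DEMAND"], -1)
  expect_equal(S["aa_G_c", "PROT_DEMAND"], -1)
  expect_equal(S["gtp_c", "PROT_DEMAND"], -2)       # one bond, two GTP
  expect_equal(S["gdp_c", "PROT_DEMAND"], 2)
  expect_equal(S["protein_c", "PROT_DEMAND"], 1)
  expect_equal(S["protein_c", "SK_protein_c"], -1)
  # total amino-acid consumption equals the sequence length
  seq239 <- paste(rep(c(toy_protein, "WYHQRNDCTSPIF"), 20), collapse = "")
  seq239 <- substr(seq239, 1, 239)
  aug2 <- addProteinDemand(net, seq239)
  aa <- grep("^aa_", metabolites(aug2)$id, value = TRUE)
  expect_equal(-sum(stoichiometry(aug2)[aa, "PROT_DEMAND"]), 239)
  expect_error(addProteinDemand(net, ""), "empty")
  expect_error(addProteinDemand(net, "MGX"), "unknown residue")
  # a network lacking an amino-acid metabolite is reported by name
  slim <- toyNetworkFixture()
  keep <- slim@metabolites$id != "aa_W_c"
  slim@metabolites <- slim@metabolites[keep, ]
  slim@S <- slim@S[keep, ]
  expect_error(addProteinDemand(slim, "MW"), "aa_W_c")
})

test_that("maximal protein flux matches the hand-computed optimum", {
  net <- addProteinDemand(toyNetworkFixture(), toy_protein, gtp_per_bond = 2)
  L <- nchar(toy_protein)
  hand <- function(U, b, yield) (yield * U - b) / (L + 2 * (L - 1) / 2)
  sol <- maxProteinFlux(net, c(EX_glc_e = 10), biomass = 2)
  expect_equal(sol$objval, hand(10, 2, 2), tolerance = 1e-9)
  expect_equal(sol$status, "optimal")
  # rich carbon strictly outperforms poor carbon at equal uptake
  poor <- maxProteinFlux(net, c(EX_gly_e = 10), biomass = 2)
  expect_equal(poor$objval, hand(10, 2, 1), tolerance = 1e-9)
  expect_gt(sol$objval, poor$objval)
  # LP homogeneity: doubling uptake at zero biomass doubles the optimum
  s1 <- maxProteinFlux(net, c(EX_glc_e = 5), biomass = 0)
  s2 <- maxProteinFlux(net, c(EX_glc_e = 10), biomass = 0)
  expect_equal(s2$objval, 2 * s1$objval, tolerance = 1e-9)
  # nothing in, nothing out; and infeasible is reported, not zeroed
  s0 <- maxProteinFlux(net, c(EX_glc_e = 0), biomass = 0)
  expect_equal(s0$objval, 0, tolerance = 1e-12)
  sinf <- maxProteinFlux(net, c(EX_glc_e = 0), biomass = 1)
  expect_true(is.na(sinf$objval))
  expect_equal(sinf$status, "infeasible")
  # returned solutions satisfy steady-state mass balance
  expect_lt(max(abs(stoichiometry(net) %*% sol$flux)), 1e-8)
})

test_that("the capacity grid tabulates optima and infeasibility", {
  net <- addProteinDemand(toyNetworkFixture(), toy_protein)
  cg <- capacityGrid(net, "EX_glc_e", c(0, 5, 10), c(0, 4))
  expect_equal(nrow(cg), 6)
  expect_true(is.na(cg$protein_flux[cg$uptake == 0 & cg$biomass == 4]))
  # more uptake never hurts; more biomass never helps
  ok <- !is.na(cg$protein_flux)
  expect_true(all(diff(cg$protein_flux[cg$biomass == 0]) > 0))
})

test_that("FVA separates the parallel paths from the pinned backbone", {
  net <- addProteinDemand(toyNetworkFixture(), toy_protein, gtp_per_bond = 2)
  fva <- runFVA(net, c(EX_glc_e = 10), biomass = 2)
  expect_equal(attr(fva, "threshold"), 0.001)
  flex <- fva$id[fva$flexible]
  # exactly the two redundant central reactions are slack: each ranges from
  # zero to the full backbone flux (brute-force expectation: total 20)
  expect_setequal(flex, c("PATH_A", "PATH_B"))
  expect_equal(fva$min[fva$id == "PATH_A"], 0, tolerance = 1e-6)
  expect_equal(fva$max[fva$id == "PATH_A"], 20, tolerance = 1e-6)
  # a reaction pinned by equal bounds cannot flex
  expect_false(fva$flexible[fva$id == "BIOMASS"])
  expect_equal(fva$min[fva$id == "BIOMASS"], fva$max[fva$id == "BIOMASS"],
               tolerance = 1e-9)
  # FVA ranges bracket the FBA solution everywhere
  sol <- maxProteinFlux(net, c(EX_glc_e = 10), biomass = 2)
  v <- sol$flux[fva$id]
  expect_true(all(v >= fva$min - 1e-6 & v <= fva$max + 1e-6))
})

test_that("subsystem and metabolite aggregation sum signed rates", {
  net <- addProteinDemand(toyNetworkFixture(), toy_protein)
  sol <- maxProteinFlux(net, c(EX_glc_e = 10), biomass = 2)
  fva <- runFVA(net, c(EX_glc_e = 10), biomass = 2)
  tab <- subsystemNetFlux(net, sol$flux, fva)
  # hand check: exchange runs at -10 (uptake), transport at +10
  expect_equal(tab$net_flux[tab$subsystem == "Exchange"], -10,
               tolerance = 1e-9)
  expect_equal(tab$net_flux[tab$subsystem == "Transport"], 10,
               tolerance = 1e-9)
  # the all-flexible subsystem contributes nothing through pinned reactions
  cm <- tab[tab$subsystem == "Central Metabolism", ]
  expect_equal(cm$n_flexible, 2)
  expect_equal(cm$inflexible_net_flux, 0)
  expect_equal(cm$net_flux, 20, tolerance = 1e-6)
  # per-metabolite committed turnover balances for an interior metabolite
  mf <- metaboliteNetFlux(net, sol$flux, fva, c("gtp_c", "pyr_c"))
  expect_equal(mf$net[mf$metabolite == "gtp_c"], 0, tolerance = 1e-9)
  expect_equal(mf$produced[mf$metabolite == "gtp_c"],
               -mf$consumed[mf$metabolite == "gtp_c"], tolerance = 1e-9)
  # signed-sum arithmetic on a constructed two-reaction subsystem
  toy <- fluxNetwork(
    reactions = data.frame(id = c("u", "w"), lb = -10, ub = 10,
                           subsystem = "s", objective = 0),
    metabolites = data.frame(id = "x"),
    stoich = list(u = c(x = 1), w = c(x = -1)))
  expect_equal(subsystemNetFlux(toy, c(u = 3, w = -1))$net_flux, 2)
})
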