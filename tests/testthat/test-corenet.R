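# Synthetic core phototrophic network.

test_that("every non-exchange, non-pseudo reaction is elementally balanced", {
  full <- coreCache("full", function()
    generateCoreNetwork(extensions = c("fermentative", "isoprenoid_mep",
                                       "fatty_acid", "arginine_tca",
                                       "photorespiration")))
  bal <- checkElementalBalance(full)
  expect_equal(nrow(bal), 0L)
  # product pathways are balanced too (library criterion)
  for (pid in listProducts()) {
    aug <- augmentWithProduct(full, pid)
    expect_equal(nrow(checkElementalBalance(aug)), 0L, label = pid)
  }
})

test_that("network generation is deterministic (byte-identical serialization)", {
  f1 <- tempfile(fileext = ".xml"); f2 <- tempfile(fileext = ".xml")
  writeSBMLModel(generateCoreNetwork(extensions = "fermentative",
                                     include_toy_biomass = TRUE), f1)
  writeSBMLModel(generateCoreNetwork(extensions = "fermentative",
                                     include_toy_biomass = TRUE), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("unknown extension names are rejected", {
  expect_error(generateCoreNetwork(extensions = "mevalonate"),
               "unknown extension")
})

test_that("the base network supports photon-driven NADPH formation", {
  core <- coreCache("base", function() generateCoreNetwork())
  m <- addReaction(core, "SINK_NADPH",
                   c(nadph_c = -1, h_c = -1, nadp_c = 1), 0, 1000,
                   unbalanced = TRUE)
  ap <- applyScenario(m, yieldScenario())
  sol <- solveFBA(ap$model, c(SINK_NADPH = 1), "max", ap$constraints)
  expect_equal(sol@status, "optimal")
  # 1 photon per electron and photosystem: 4 photons per NADPH
  expect_equal(sol@objective_value, 15.57 / 4, tolerance = 1e-9)
})

test_that("linear electron chain yields ATP/NADPH = 9/7 by LP", {
  core <- coreCache("base", function() generateCoreNetwork())
  expect_equal(etcAtpNadphRatio(core), 9 / 7, tolerance = 1e-9)
  # halving the ATP synthase proton demand doubles the ratio
  half <- generateCoreNetwork(atp_synthase_h_per_atp = 14 / 6)
  expect_equal(etcAtpNadphRatio(half), 18 / 7, tolerance = 1e-9)
})

test_that("cyclic electron flow pushes ATP per NADPH beyond the linear ratio", {
  core <- coreCache("base", function() generateCoreNetwork())
  ex <- core@reactions$id[core@reactions$is_exchange]
  keep <- c("EX_photon", "EX_o2", "EX_h2o", "EX_h", "EX_na")
  m <- setBounds(core, setdiff(ex, keep), 0, 0)
  m <- setBounds(m, c("NDH1", "MEHLER", "ROS_PSI", "ROS_PSII", "CYOX", "ATPM"),
                 0, 0)   # CEF stays available
  m <- addReaction(m, "SINK_NADPH", c(nadph_c = -1, h_c = -1, nadp_c = 1),
                   1, 1, unbalanced = TRUE)
  m <- addReaction(m, "SINK_ATP",
                   c(atp_c = -1, h2o_c = -1, adp_c = 1, pi_c = 1, h_c = 1),
                   0, 1000)
  sol <- solveFBA(m, c(SINK_ATP = 1), "max")
  expect_gt(sol@objective_value, 9 / 7 + 1)
})

test_that("each extension pack suffices for its products", {
  packProducts <- list(
    fermentative = c("ethanol", "lactate", "butane-2,3-diol",
                     "isobutyraldehyde", "isobutanol", "1-butanol", "propane"),
    isoprenoid_mep = "isoprene",
    fatty_acid = c("pentadecane", "heptadecane", "1-octadecanol"),
    arginine_tca = "ethylene")
  for (pack in names(packProducts)) {
    host <- generateCoreNetwork(extensions = pack)
    for (pid in packProducts[[pack]]) {
      aug <- augmentWithProduct(host, pid)
      ap <- applyScenario(aug, yieldScenario())
      sol <- solveFBA(ap$model, setNames(1, aug@annotations$product_exports[[pid]]),
                      "max", ap$constraints)
      expect_equal(sol@status, "optimal", label = pid)
      expect_gt(sol@objective_value, 1e-6)
    }
  }
})

test_that("photon influx 15.57 corresponds to about 2.7 J/gDW/h at 680 nm", {
  core <- coreCache("base", function() generateCoreNetwork())
  e <- core@annotations$photon_energy_kj            # kJ per mol photons
  uptake <- 15.57                                    # umol photons /gDW/h
  expect_equal(uptake * 1e-6 * e * 1e3, 2.7, tolerance = 0.02)
})

test_that("the toy biomass objective grows and demands ATP/NADPH above 9/7", {
  bm <- coreCache("biomass", function()
    generateCoreNetwork(extensions = "fermentative", include_toy_biomass = TRUE))
  ap <- applyScenario(bm, yieldScenario())
  sol <- solveFBA(ap$model, extra_constraints = ap$constraints)
  expect_equal(sol@status, "optimal")
  expect_gt(sol@objective_value, 0.001)
  # demand accounting at the growth optimum, via the accounting conventions
  mu <- sol@objective_value
  fixed <- setBounds(ap$model, "BIOMASS", mu - 1e-9, 1000)
  atp <- solveFBA(fixed, c(ATPS = 1), "min", ap$constraints)@objective_value
  nad <- solveFBA(fixed, c(FNR = 1, NDH1 = -1), "min",
                  ap$constraints)@objective_value
  expect_gt(atp / nad, 9 / 7)
  expect_error(toyBiomassObjective(bm), "already")
})

test_that("maximal-yield optima leave the oxygenase unused", {
  aug <- augmentWithProduct(generateCoreNetwork(), "ethanol")
  ap <- applyScenario(aug, yieldScenario())
  sol <- solveFBA(ap$model, c(EXP_ethanol = 1), "max", ap$constraints)
  mas <- minimalActiveSet(ap$model, c(EXP_ethanol = 1), sol@objective_value,
                          extra_constraints = ap$constraints)
  expect_lt(abs(mas$fluxes[["RBO"]]), 1e-9)
})
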