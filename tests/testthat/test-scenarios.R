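# Constraint presets and coupling constraints.

test_that("presets carry the documented parameters", {
  y <- yieldScenario()
  expect_equal(y@photon_influx, 15.57)
  expect_equal(y@maintenance_atp, 0)
  expect_false(y@rubisco_coupled)

  t <- transitionScenario()
  expect_equal(t@photon_influx, 18.0)
  expect_equal(t@maintenance_atp, 0.6312)
  expect_true(t@rubisco_coupled)
  expect_equal(t@oxygenase_fraction, 0.03)
  expect_equal(t@respiration_fraction, 0.10)
  expect_equal(t@mehler_fraction, 0.10)
  expect_equal(t@ros_fraction, 0.005)
})

test_that("the oxygenase coupling encodes 3% of total Rubisco flux", {
  core <- generateCoreNetwork()
  ap <- applyScenario(core, transitionScenario())
  oxy <- Filter(function(cc) "RBO" %in% names(cc$coef), ap$constraints)
  expect_equal(length(oxy), 1L)
  coef <- oxy[[1]]$coef
  # v_RBO = (3/97) v_RBC, i.e. one matrix row with coefficients (1, -3/97)
  expect_equal(unname(coef["RBO"]), 1)
  expect_equal(unname(coef["RBC"]), -3 / 97)
  expect_equal(oxy[[1]]$rhs, 0)
})

test_that("transition solutions respect the wild-type couplings", {
  bm <- coreCache("biomass", function()
    generateCoreNetwork(extensions = "fermentative", include_toy_biomass = TRUE))
  ap <- applyScenario(bm, transitionScenario())
  sol <- solveFBA(ap$model, extra_constraints = ap$constraints)
  expect_equal(sol@status, "optimal")
  v <- sol@fluxes
  expect_gte(v[["ATPM"]], 0.6312 - 1e-9)            # basal floor
  expect_equal(v[["CYOX"]], 0.10 * v[["PSII"]], tolerance = 1e-8)
  expect_equal(v[["MEHLER"]], 0.10 * v[["PSII"]], tolerance = 1e-8)
  expect_equal(2 * v[["ROS_PSII"]], 0.005 * 4 * v[["PSII"]], tolerance = 1e-8)
  expect_equal(2 * v[["ROS_PSI"]], 0.005 * v[["PSI"]], tolerance = 1e-8)
  expect_equal(v[["RBO"]], 0.03 * (v[["RBO"]] + v[["RBC"]]), tolerance = 1e-8)
})

test_that("transition optimum never exceeds the yield optimum at equal light", {
  bm <- coreCache("biomass", function()
    generateCoreNetwork(extensions = "fermentative", include_toy_biomass = TRUE))
  y <- yieldScenario(); y@photon_influx <- 18.0
  apy <- applyScenario(bm, y)
  apt <- applyScenario(bm, transitionScenario())
  gy <- solveFBA(apy$model, extra_constraints = apy$constraints)@objective_value
  gt <- solveFBA(apt$model, extra_constraints = apt$constraints)@objective_value
  expect_lte(gt, gy + 1e-9)

  # with all couplings and maintenance zeroed the optima coincide
  t0 <- transitionScenario(maintenance_atp = 0, oxygenase_fraction = 0,
                           respiration_fraction = 0, mehler_fraction = 0,
                           ros_fraction = 0)
  t0@rubisco_coupled <- FALSE
  ap0 <- applyScenario(bm, t0)
  g0 <- solveFBA(ap0$model, extra_constraints = ap0$constraints)@objective_value
  expect_equal(g0, gy, tolerance = 1e-8)

  # respiration coupling alone strictly lowers the optimum
  tr <- transitionScenario(maintenance_atp = 0, oxygenase_fraction = 0,
                           mehler_fraction = 0, ros_fraction = 0)
  tr@rubisco_coupled <- FALSE
  apr <- applyScenario(bm, tr)
  gr <- solveFBA(apr$model, extra_constraints = apr$constraints)@objective_value
  expect_lt(gr, gy - 1e-6)
})

test_that("fixing maintenance with zero light is infeasible", {
  bm <- coreCache("biomass", function()
    generateCoreNetwork(extensions = "fermentative", include_toy_biomass = TRUE))
  t <- transitionScenario(photon_influx = 1e-9)
  ap <- applyScenario(bm, t)
  sol <- solveFBA(ap$model, extra_constraints = ap$constraints)
  expect_equal(sol@status, "infeasible")
})

test_that("the fixed-value coupling variant freezes side fluxes", {
  bm <- coreCache("biomass", function()
    generateCoreNetwork(extensions = "fermentative", include_toy_biomass = TRUE))
  st <- transitionScenario(dynamic_coupling = FALSE)
  ap <- applyScenario(bm, st)
  b <- reactionBounds(ap$model)
  cy <- b[b$id == "CYOX", ]
  expect_equal(cy$lower_bound, cy$upper_bound)
  expect_gt(cy$lower_bound, 0)
})

test_that("missing role reactions are reported by name", {
  m <- chainModel(3)
  expect_error(applyScenario(m, yieldScenario()), "role")
})
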