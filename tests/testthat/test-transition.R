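# Trade-off scans, transition experiments, trajectory classification.

test_that("trajectory classification follows the endpoint rules", {
  tr <- function(a, b, amin = a, amax = a, bmin = b, bmax = b)
    data.frame(growth_fraction = c(1, 0), min = c(amin, bmin),
               max = c(amax, bmax), midpoint = c(a, b))
  expect_equal(classifyTrajectory(tr(0.5, 0.5)), "no_change")
  expect_equal(classifyTrajectory(tr(0, 0.3)), "increase_from_zero")
  expect_equal(classifyTrajectory(tr(0.3, 0.9)), "increase_from_flux")
  expect_equal(classifyTrajectory(tr(0.9, 0.3)), "decrease_to_flux")
  expect_equal(classifyTrajectory(tr(0.9, 0)), "decrease_to_zero")
  expect_equal(classifyTrajectory(tr(0, 0)), "below_focus")
  expect_equal(classifyTrajectory(tr(1e-7, 5e-5)), "below_focus")
  # growth range [-2,-1] against production range [1,2]: both endpoint
  # products of minima and maxima are negative
  expect_equal(classifyTrajectory(tr(-1.5, 1.5, -2, -1, 1, 2)), "sign_change")
  # 4% change is "no change", 6% is a decrease
  expect_equal(classifyTrajectory(tr(1, 0.96)), "no_change")
  expect_equal(classifyTrajectory(tr(1, 0.94)), "decrease_to_flux")
  # classification is invariant to flipping the reaction's sign convention
  expect_equal(classifyTrajectory(tr(-0.3, -0.9)), "increase_from_flux")
  expect_equal(classifyTrajectory(tr(-0.9, -0.3)), "decrease_to_flux")
})

test_that("category counts tally focus reactions in published column order", {
  cats <- c(A = "sign_change", B = "increase_from_zero", C = "below_focus",
            D = "no_change", E = "no_change", F = "decrease_to_zero")
  cnt <- categoryCounts(cats)
  expect_equal(names(cnt), c("sign_change", "increase_from_flux",
                             "increase_from_zero", "decrease_to_flux",
                             "decrease_to_zero", "no_change"))
  expect_equal(unname(cnt), c(1L, 0L, 1L, 0L, 1L, 2L))
  expect_equal(sum(cnt), sum(cats != "below_focus"))
})

test_that("the six-reaction toy transition matches hand enumeration", {
  # growth-only: GROW = 10; CONV, ALT in [4,6]; SHUT in [-6,-4]
  # production-only: PROD = 10; SHUT in [4,6] -> sign change
  toy <- transitionToy()
  ex <- transitionExperiment(toy, getProduct("ethanol"), scenario = NULL,
                             n_steps = 3,
                             roles = list(biomass = "GROW"),
                             product_export = "PROD")
  expect_equal(ex$mu_max, 10)
  g <- ex$trajectories[ex$trajectories$growth_fraction == 1, ]
  p <- ex$trajectories[ex$trajectories$growth_fraction == 0, ]
  expect_equal(g$min[g$reaction_id == "SHUT"], -6, tolerance = 1e-8)
  expect_equal(g$max[g$reaction_id == "SHUT"], -4, tolerance = 1e-8)
  expect_equal(p$min[p$reaction_id == "SHUT"], 4, tolerance = 1e-8)
  expect_equal(p$max[p$reaction_id == "SHUT"], 6, tolerance = 1e-8)
  expect_equal(unname(ex$categories),
               c("no_change", "no_change", "no_change", "sign_change",
                 "decrease_to_zero", "increase_from_zero"))
  expect_equal(unname(ex$counts),
               c(1L, 0L, 1L, 0L, 1L, 3L))
})

test_that("every focus reaction receives exactly one category label", {
  toy <- transitionToy()
  ex <- transitionExperiment(toy, getProduct("ethanol"), scenario = NULL,
                             n_steps = 3, roles = list(biomass = "GROW"),
                             product_export = "PROD")
  expect_equal(length(ex$categories), length(reactionIds(toy)))
  expect_true(all(ex$categories %in%
                    c("sign_change", "increase_from_flux", "increase_from_zero",
                      "decrease_to_flux", "decrease_to_zero", "no_change",
                      "below_focus")))
})

test_that("classification is endpoint-determined: grid density is irrelevant", {
  toy <- transitionToy()
  e2 <- transitionExperiment(toy, getProduct("ethanol"), scenario = NULL,
                             n_steps = 2, roles = list(biomass = "GROW"),
                             product_export = "PROD")
  e5 <- transitionExperiment(toy, getProduct("ethanol"), scenario = NULL,
                             n_steps = 5, roles = list(biomass = "GROW"),
                             product_export = "PROD")
  expect_identical(e2$categories, e5$categories)
})

test_that("the ethanol frontier on the core network is monotone and concave", {
  bm <- coreCache("biomass", function()
    generateCoreNetwork(extensions = "fermentative", include_toy_biomass = TRUE))
  aug <- augmentWithProduct(bm, "ethanol")
  tr <- tradeoffScan(aug, "ethanol", transitionScenario(), n_steps = 9)
  p <- tr$max_product_flux
  f <- tr$growth_fraction
  expect_equal(p[1], 0, tolerance = 1e-6)            # all resources in growth
  expect_gt(p[length(p)], 0.1)                       # production-only endpoint
  expect_true(all(diff(p) >= -1e-8))                 # monotone as f decreases
  # concavity: the frontier lies on or above every endpoint chord
  chord <- p[1] + (p[length(p)] - p[1]) * (f[1] - f) / (f[1] - f[length(f)])
  expect_true(all(p >= chord - 1e-6))
  expect_error(tradeoffScan(aug, "ethanol", n_steps = 1), "endpoints")
})

test_that("an ethanol transition shows the published qualitative signatures", {
  bm <- coreCache("biomass", function()
    generateCoreNetwork(extensions = "fermentative", include_toy_biomass = TRUE))
  aug <- collapseIsoenzymes(augmentWithProduct(bm, "ethanol"))
  ex <- transitionExperiment(aug, "ethanol", n_steps = 3)
  # heterologous pathway reactions switch on from zero
  expect_equal(ex$categories[["Bi0001"]], "increase_from_zero")
  expect_equal(ex$categories[["EXP_ethanol"]], "increase_from_zero")
  # excess ATP must be hydrolyzed in the production-only phenotype
  expect_true(ex$categories[["ATPM"]] %in%
                c("increase_from_flux", "increase_from_zero"))
  # every focus reaction gets exactly one label; counts add up
  expect_equal(sum(ex$counts), sum(ex$categories != "below_focus"))
  # an infeasible regime (maintenance demand with vanishing light) aborts
  starving <- transitionScenario(photon_influx = 1e-9)
  expect_error(transitionExperiment(aug, "ethanol", scenario = starving,
                                    n_steps = 2), "failed|infeasible")
})
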