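# Tabular dialect, scenario configs, SBML round trips.

test_that("equation parsing handles coefficients, arrows and compartments", {
  pe <- parseEquation("2 A <=> B")
  expect_true(pe$reversible)
  expect_equal(pe$stoichiometry, c(A = -2, B = 1))

  pe <- parseEquation("Pyruvate => Acetaldehyde + CO2")
  expect_false(pe$reversible)
  expect_equal(pe$stoichiometry,
               c(Pyruvate = -1, Acetaldehyde = 1, CO2 = 1))

  pe <- parseEquation("glc[e] => glc[c]")
  expect_equal(names(pe$stoichiometry), c("glc[e]", "glc[c]"))
  expect_error(parseEquation("A -> B"), "arrow")
})

test_that("tabular round trip preserves the stoichiometric matrix and bounds", {
  m <- generateCoreNetwork(extensions = "fermentative")
  rx <- tempfile(fileext = ".tsv"); mt <- tempfile(fileext = ".tsv")
  writeTabularModel(m, rx, mt)
  m2 <- readTabularModel(rx, mt)
  S1 <- as.matrix(stoichMatrix(m))
  S2 <- as.matrix(stoichMatrix(m2))[rownames(S1), colnames(S1)]
  expect_lt(max(abs(S1 - S2)), 1e-12)
  expect_equal(m2@reactions$lower_bound, m@reactions$lower_bound)
  expect_equal(m2@reactions$upper_bound, m@reactions$upper_bound)
})

test_that("tabular reader builds reactions from equation text", {
  rx <- tempfile(fileext = ".tsv"); mt <- tempfile(fileext = ".tsv")
  writeLines(c("id\tequation\tlower_bound\tupper_bound",
               "Bi0001\tPyruvate => Acetaldehyde + CO2\t0\t1000"), rx)
  writeLines(c("id", "Pyruvate", "Acetaldehyde", "CO2"), mt)
  m <- readTabularModel(rx, mt)
  expect_equal(length(m@stoichiometry$Bi0001), 3L)
  expect_equal(reactionBounds(m)$lower_bound, 0)

  # empty reactions table -> empty model
  writeLines("id\tequation", rx)
  writeLines("id", mt)
  m0 <- readTabularModel(rx, mt)
  expect_equal(length(reactionIds(m0)), 0L)

  # unknown metabolite named with the offending row
  writeLines(c("id\tequation", "R1\tA => B"), rx)
  writeLines(c("id", "A"), mt)
  expect_error(readTabularModel(rx, mt), "R1.*B")
})

test_that("SBML write-read is a fixed point on stoichiometry, bounds, objective", {
  m <- generateCoreNetwork(extensions = c("fermentative", "isoprenoid_mep"),
                           include_toy_biomass = TRUE)
  f1 <- tempfile(fileext = ".xml"); f2 <- tempfile(fileext = ".xml")
  writeSBMLModel(m, f1)
  m2 <- readSBMLModel(f1)
  S1 <- as.matrix(stoichMatrix(m))
  S2 <- as.matrix(stoichMatrix(m2))[rownames(S1), colnames(S1)]
  expect_equal(max(abs(S1 - S2)), 0)
  expect_equal(m2@reactions$lower_bound, m@reactions$lower_bound)
  expect_equal(m2@reactions$upper_bound, m@reactions$upper_bound)
  expect_equal(m2@objective, m@objective)
  # write-read-write reaches a byte-stable fixed point
  writeSBMLModel(m2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("a minimal one-reaction SBML fixture reads correctly", {
  f <- tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2" level="2" version="4">',
    '<model id="mini"><listOfCompartments><compartment id="c"/></listOfCompartments>',
    '<listOfSpecies><species id="A" compartment="c"/><species id="B" compartment="c"/></listOfSpecies>',
    '<listOfReactions><reaction id="R1" reversible="false">',
    '<listOfReactants><speciesReference species="A" stoichiometry="1"/></listOfReactants>',
    '<listOfProducts><speciesReference species="B" stoichiometry="1"/></listOfProducts>',
    '<kineticLaw><listOfParameters>',
    '<parameter id="LOWER_BOUND" value="0"/><parameter id="UPPER_BOUND" value="800"/>',
    '</listOfParameters></kineticLaw>',
    '</reaction></listOfReactions></model></sbml>'), f)
  m <- readSBMLModel(f)
  expect_equal(reactionIds(m), "R1")
  expect_equal(m@stoichiometry$R1, c(A = -1, B = 1))
  expect_equal(reactionBounds(m)$upper_bound, 800)
  expect_error(readSBMLModel(textConnectionValue <- {
    f2 <- tempfile(); writeLines("<sbml><broken", f2); f2
  }), "parse error")
})

test_that("cobrapy independently reproduces the FBA optimum from our SBML", {
  # external oracle: the packaged core network with the ethanol pathway,
  # serialized to SBML, optimized by an independent constraint-based toolbox
  py <- Sys.which("python")
  m <- augmentWithProduct(generateCoreNetwork(), "ethanol")
  ap <- applyScenario(m, yieldScenario())
  mod <- setObjective(ap$model, c(EXP_ethanol = 1))
  f <- tempfile(fileext = ".xml")
  writeSBMLModel(mod, f)
  script <- paste(
    "import cobra, sys",
    "m = cobra.io.read_sbml_model(sys.argv[1])",
    "print(round(m.optimize().objective_value, 9))", sep = "\n")
  out <- suppressWarnings(system2(py, c("-c", shQuote(script), shQuote(f)),
                                  stdout = TRUE, stderr = FALSE))
  ours <- solveFBA(mod, c(EXP_ethanol = 1))@objective_value
  expect_equal(as.numeric(tail(out, 1)), ours, tolerance = 1e-6)
  expect_equal(ours, 15.57 / 24, tolerance = 1e-9)
})

test_that("scenario files parse with defaults, overrides and validation", {
  f <- tempfile()
  writeLines(c("# wild-type-state constraints",
               "maintenance_atp 0.6312", "photon_influx 18.0"), f)
  s <- readScenarioConfig(f)
  expect_equal(s@name, "transition_mode")
  expect_equal(s@maintenance_atp, 0.6312)
  expect_equal(s@photon_influx, 18.0)
  expect_equal(s@oxygenase_fraction, 0.03)

  writeLines(character(0), f)
  s0 <- readScenarioConfig(f)
  expect_equal(s0@name, "yield_mode")
  expect_equal(s0@photon_influx, 15.57)
  expect_equal(s0@maintenance_atp, 0)

  writeLines("oxygenase_fraction 0.03", f)
  expect_equal(readScenarioConfig(f)@oxygenase_fraction, 0.03)

  writeLines("unknown_key 1", f)
  expect_error(readScenarioConfig(f), "unknown scenario key")
  writeLines("photon_influx -3", f)
  expect_error(readScenarioConfig(f), "photon_influx")
  writeLines("maintenance_atp -1", f)
  expect_error(readScenarioConfig(f), "maintenance_atp")

  # round trip
  writeScenarioConfig(transitionScenario(), f)
  s2 <- readScenarioConfig(f)
  expect_equal(s2@photon_influx, 18.0)
  expect_equal(s2@name, "transition_mode")
})
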