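# Stoichiometric matrix, elemental balance, isoenzyme handling.

test_that("stoichiometric matrix matches the reaction definitions", {
  empty <- makeModel(data.frame(id = character(0)),
                     data.frame(id = character(0)), list())
  expect_equal(dim(stoichMatrix(empty)), c(0L, 0L))

  mets <- data.frame(id = c("A", "B", "C"))
  rxn <- data.frame(id = c("R1", "R2"))
  st <- list(R1 = c(A = -1, B = 1), R2 = c(B = -1, C = 1))
  m <- makeModel(mets, rxn, st)
  S <- as.matrix(stoichMatrix(m))
  expect_equal(unname(S), rbind(c(-1, 0), c(1, -1), c(0, 1)))
  expect_equal(dimnames(S), list(c("A", "B", "C"), c("R1", "R2")))
})

test_that("model validity rejects dangling metabolite references", {
  mets <- data.frame(id = "A")
  rxn <- data.frame(id = "R1")
  expect_error(makeModel(mets, rxn, list(R1 = c(A = -1, Ghost = 1))),
               "Ghost")
})

test_that("elemental balance checking counts atoms correctly", {
  # the ethylene-forming reaction: 21 C and 4 N on each side
  mets <- data.frame(
    id = c("akg", "o2", "arg", "h", "eth", "co2", "succ", "gua", "p5c", "h2o"),
    formula = c("C5H4O5", "O2", "C6H15N4O2", "H", "C2H4", "CO2", "C4H4O4",
                "CH5N3", "C5H6NO2", "H2O"))
  st <- list(EFE = c(akg = -3, o2 = -3, arg = -1, h = -2, eth = 2, co2 = 7,
                     succ = 1, gua = 1, p5c = 1, h2o = 3))
  m <- makeModel(mets, data.frame(id = "EFE"), st)
  expect_equal(nrow(checkElementalBalance(m)), 0L)

  # transport of the same species is trivially balanced
  mets2 <- data.frame(id = c("a_e", "a_c"), formula = c("C6H12O6", "C6H12O6"))
  m2 <- makeModel(mets2, data.frame(id = "T"),
                  list(T = c(a_e = -1, a_c = 1)))
  expect_equal(nrow(checkElementalBalance(m2)), 0L)

  # corrupted pyruvate decarboxylase missing its CO2: carbon imbalance 1
  mets3 <- data.frame(id = c("pyr", "h", "acald"),
                      formula = c("C3H3O3", "H", "C2H4O"))
  m3 <- makeModel(mets3, data.frame(id = "PDC_bad"),
                  list(PDC_bad = c(pyr = -1, h = -1, acald = 1)))
  bal <- checkElementalBalance(m3)
  crow <- bal[bal$element == "C", ]
  expect_equal(nrow(crow), 1L)
  expect_equal(abs(crow$imbalance), 1)
})

test_that("missing formulas are reported as uncheckable, not imbalanced", {
  mets <- data.frame(id = c("A", "B"), formula = c("C2H4", ""))
  m <- makeModel(mets, data.frame(id = "R"), list(R = c(A = -1, B = 1)))
  bal <- checkElementalBalance(m)
  expect_equal(bal$element, "uncheckable")
  expect_true(is.na(bal$imbalance))
})

test_that("isoenzyme collapse merges bounds, is idempotent, rejects conflicts", {
  mets <- data.frame(id = c("A", "B"))
  rxn <- data.frame(id = c("E1", "E2"),
                    isoenzyme_group = c("g1", "g1"),
                    lower_bound = c(0, 0), upper_bound = c(10, 10))
  st <- list(E1 = c(A = -1, B = 1), E2 = c(A = -1, B = 1))
  m <- makeModel(mets, rxn, st)
  col <- collapseIsoenzymes(m)
  expect_equal(length(reactionIds(col)), 1L)
  expect_equal(reactionBounds(col)$upper_bound, 20)
  expect_equal(reactionBounds(col)$lower_bound, 0)
  # idempotent
  expect_equal(collapseIsoenzymes(col)@reactions, col@reactions)
  # ungrouped model unchanged
  m0 <- makeModel(mets, data.frame(id = "E1"), st["E1"])
  expect_identical(collapseIsoenzymes(m0)@reactions$id, "E1")
  # conflicting stoichiometry may not merge
  st2 <- list(E1 = c(A = -1, B = 1), E2 = c(A = -2, B = 1))
  m2 <- makeModel(mets, rxn, st2)
  expect_error(collapseIsoenzymes(m2), "conflicting stoichiometry")
})

test_that("structurally identical reactions are auto-grouped when asked", {
  mets <- data.frame(id = c("A", "B"))
  rxn <- data.frame(id = c("E1", "E2", "E3"),
                    lower_bound = 0, upper_bound = c(5, 7, 9))
  st <- list(E1 = c(A = -1, B = 1), E2 = c(A = -1, B = 1),
             E3 = c(A = -1, B = 2))
  m <- makeModel(mets, rxn, st)
  col <- collapseIsoenzymes(m, auto_group = TRUE)
  expect_setequal(reactionIds(col), c("E1", "E3"))
  expect_equal(reactionBounds(col)$upper_bound[1], 12)
})
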