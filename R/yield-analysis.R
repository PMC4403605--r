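# Maximal-yield accounting: per-product stoichiometric properties.
#
# Conventions (matching the published accounting): ATP demand is read from
# the flux through the ATP-synthase reaction; NADPH demand is the FNR flux
# minus the NDH-1 flux; Rubisco is the carboxylase flux; net CO2 is the net
# inorganic-carbon uptake; O2 is the net O2 export. All per unit of product
# flux at the fixed photon influx. Electrons entering pathways directly from
# reduced ferredoxin (ADO, MEP-pathway reductases) bypass FNR, so the total
# two-electron-equivalent demand is reported alongside the FNR-based count.

#' Degree of reduction of a product
#'
#' Available-electron count per molecule, \code{4C + H - 2O} (N, P, S absent
#' from the twelve products). Twice this number lower-bounds the photon
#' demand at one photon per electron and photosystem.
#'
#' @param formula Hill formula string or a [ProductDefinition-class].
#' @return electrons per molecule.
#' @export
degreeOfReduction <- function(formula) {
  if (is(formula, "ProductDefinition")) formula <- formula@formula
  f <- parseFormula(formula)
  cnt <- function(el) if (el %in% names(f)) f[[el]] else 0
  4 * cnt("C") + cnt("H") - 2 * cnt("O")
}

#' Per-product stoichiometric summary at maximal yield
#'
#' Maximizes product export at the scenario's fixed photon influx, resolves
#' degenerate optima by total-flux minimization, and normalizes the
#' characteristic fluxes per unit product.
#'
#' @param model a model already augmented with the product (see
#'   [augmentWithProduct()]).
#' @param product a [ProductDefinition-class] or product id.
#' @param scenario a yield-mode [Scenario-class] (default [yieldScenario()]).
#' @param roles optional role map (see [applyScenario()]).
#' @return one-row data.frame: product_id, n_active_reactions,
#'   photons_per_product, nadph_per_product, e2_equivalents_per_product,
#'   atp_per_product, atp_nadph_ratio, o2_per_product, rubisco_per_product,
#'   net_co2_per_product, max_flux, energetic_yield.
#' @export
stoichiometricSummary <- function(model, product, scenario = yieldScenario(),
                                  roles = NULL) {
  if (is.character(product)) product <- getProduct(product)
  expid <- product@export_reaction$id
  if (!expid %in% model@reactions$id)
    stop("model is not augmented with product '", product@product_id,
         "'; call augmentWithProduct() first")
  roles <- .modelRoles(model, roles)
  ap <- applyScenario(model, scenario, roles)
  obj <- setNames(1, expid)
  sol <- solveFBA(ap$model, obj, "max", ap$constraints)
  if (sol@status != "optimal")
    stop("yield optimization failed: ", sol@status)
  if (sol@objective_value <= 1e-9) {
    fva <- runFVA(ap$model, targets = vapply(product@pathway, `[[`, "", "id"),
                  extra_constraints = ap$constraints)
    blocked <- fva$id[fva$max < 1e-9]
    stop("product unreachable: maximal ", product@product_id,
         " flux is zero; blocked pathway step(s): ",
         paste(blocked, collapse = ", "))
  }
  mas <- minimalActiveSet(ap$model, obj, sol@objective_value,
                          extra_constraints = ap$constraints)
  p <- sol@objective_value
  # fix the product at its optimum; report every demand as the minimal flux
  # over the optimal polytope (the unavoidable stoichiometric requirement),
  # which is invariant to the degeneracy of the optimum
  fixed <- setBounds(ap$model, expid, p - 1e-9, p)
  minOf <- function(coef) {
    coef <- coef[names(coef) %in% fixed@reactions$id]
    if (length(coef) == 0L) return(0)
    s <- solveFBA(fixed, coef, "min", ap$constraints)
    if (s@status != "optimal") stop("demand minimization failed: ", s@status)
    s@objective_value
  }
  rid <- function(role) roles[[role]] %||% ".absent"
  photons <- abs(minOf(setNames(1, rid("photon_exchange")))) / p
  nadph <- minOf(setNames(c(1, -1), c(rid("fnr"), rid("ndh")))) / p
  atp <- minOf(setNames(1, rid("atpase"))) / p
  # electrons delivered by water splitting, as 2e- equivalents
  e2 <- 4 * minOf(setNames(1, rid("psii"))) / (2 * p)
  o2 <- minOf(setNames(1, rid("o2_exchange"))) / p
  rub <- minOf(setNames(1, rid("rubisco_carboxylase"))) / p
  netco2 <- minOf(setNames(c(-1, -1),
                           c(rid("co2_exchange"), rid("hco3_exchange")))) / p
  data.frame(
    product_id = product@product_id,
    n_active_reactions = mas$count,
    photons_per_product = photons,
    nadph_per_product = nadph,
    e2_equivalents_per_product = e2,
    atp_per_product = atp,
    atp_nadph_ratio = if (nadph > 0) atp / nadph else NA_real_,
    o2_per_product = o2,
    rubisco_per_product = rub,
    net_co2_per_product = netco2,
    max_flux = p,
    energetic_yield = energeticYield(p, product),
    stringsAsFactors = FALSE)
}

#' ATP/NADPH ratio of the linear photosynthetic electron chain
#'
#' Computed by LP, not from the closed form: all exchanges except photons,
#' O2, water, protons and sodium are closed, cyclic electron flow, NDH-1 and
#' all alternative electron sinks (Mehler-like, ROS, respiration, maintenance)
#' are disabled, NADPH output is fixed at 1 and ATP output is maximized. With
#' 6 lumen protons per NADPH (2 from the oxygen-evolving complex, 4 from the
#' Q-cycle) and 14/3 protons per ATP this is 9/7, approximately 1.29.
#'
#' @param model a core-network [MetabolicModel-class].
#' @param roles optional role map.
#' @return ATP produced per NADPH (numeric scalar).
#' @export
etcAtpNadphRatio <- function(model, roles = NULL) {
  roles <- .modelRoles(model, roles)
  ex <- model@reactions$id[model@reactions$is_exchange]
  keep <- c(roles$photon_exchange, roles$o2_exchange, "EX_h2o", "EX_h", "EX_na")
  m <- setBounds(model, setdiff(ex, keep), 0, 0)
  off <- c(roles$cef, roles$ndh, roles$mehler, roles$ros_psii, roles$ros_psi,
           roles$respiration, roles$maintenance)
  off <- off[!vapply(off, is.null, logical(1))]
  m <- setBounds(m, unlist(off), 0, 0)
  m <- addReaction(m, ".SINK_NADPH", c(nadph_c = -1, h_c = -1, nadp_c = 1),
                   1, 1, name = "NADPH output (fixed at 1)", unbalanced = TRUE)
  m <- addReaction(m, ".SINK_ATP",
                   c(atp_c = -1, h2o_c = -1, adp_c = 1, pi_c = 1, h_c = 1),
                   0, 1000, name = "ATP output")
  sol <- solveFBA(m, c(.SINK_ATP = 1), "max")
  if (sol@status != "optimal")
    stop("linear-electron-chain LP failed: ", sol@status)
  sol@objective_value
}

#' Yield table across products
#'
#' Builds the per-product stoichiometric summary for a set of products. When
#' no model is given, a core network with the required extension packs is
#' generated per product.
#'
#' @param products character vector of product ids (default: all twelve).
#' @param model optional pre-built host model used for every product.
#' @param scenario a [Scenario-class] (default [yieldScenario()]).
#' @param variant export variant passed to [augmentWithProduct()].
#' @return data.frame, one row per product, plus attribute
#'   \code{"deviations"} with [knownDeviations()] rows for flagged products.
#' @export
yieldTable <- function(products = listProducts(), model = NULL,
                       scenario = yieldScenario(), variant = "default") {
  rows <- lapply(products, function(pid) {
    prod <- getProduct(pid)
    host <- model %||% generateCoreNetwork(extensions = prod@requires)
    aug <- augmentWithProduct(host, prod, variant = variant)
    stoichiometricSummary(aug, prod, scenario)
  })
  out <- do.call(rbind, rows)
  flagged <- knownDeviations()
  attr(out, "deviations") <- flagged
  out
}
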