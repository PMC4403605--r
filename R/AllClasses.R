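#' MetabolicModel: an in-memory stoichiometric network
#'
#' Central data container of the package. Holds a metabolite table, a reaction
#' table, the signed stoichiometry of every reaction, and a linear objective.
#' The stoichiometric matrix S (metabolites x reactions) is derived with
#' [stoichMatrix()]; a steady-state flux vector v satisfies S v = 0.
#'
#' @slot metabolites data.frame with columns \code{id}, \code{name},
#'   \code{compartment}, \code{formula} (Hill string, empty for formula-less
#'   pseudo-species), \code{charge} (integer, may be NA).
#' @slot reactions data.frame with columns \code{id}, \code{name},
#'   \code{lower_bound}, \code{upper_bound} (mmol gDW^-1 h^-1),
#'   \code{subsystem}, \code{isoenzyme_group} (NA when ungrouped),
#'   \code{is_exchange}, \code{unbalanced} (pseudo-reactions exempt from
#'   elemental checking, e.g. photon uptake and biomass).
#' @slot stoichiometry named list, one named numeric vector per reaction
#'   (metabolite id -> signed coefficient, negative = substrate).
#' @slot objective named numeric vector, reaction id -> weight.
#' @slot annotations free-form named list.
#' @exportClass MetabolicModel
setClass("MetabolicModel", representation(
  metabolites = "data.frame",
  reactions = "data.frame",
  stoichiometry = "list",
  objective = "numeric",
  annotations = "list"
))

setValidity("MetabolicModel", function(object) {
  msgs <- character(0)
  met <- object@metabolites; rxn <- object@reactions
  needM <- c("id", "name", "compartment", "formula", "charge")
  needR <- c("id", "name", "lower_bound", "upper_bound", "subsystem",
             "isoenzyme_group", "is_exchange", "unbalanced")
  if (!all(needM %in% names(met))) msgs <- c(msgs, "metabolite table lacks required columns")
  if (!all(needR %in% names(rxn))) msgs <- c(msgs, "reaction table lacks required columns")
  if (length(msgs)) return(msgs)
  if (anyNA(met$id) || any(!nzchar(met$id))) msgs <- c(msgs, "metabolite ids must be non-empty")
  if (anyDuplicated(met$id)) msgs <- c(msgs, "duplicate metabolite ids")
  if (anyNA(rxn$id) || any(!nzchar(rxn$id))) msgs <- c(msgs, "reaction ids must be non-empty")
  if (anyDuplicated(rxn$id)) msgs <- c(msgs, "duplicate reaction ids")
  if (!identical(sort(names(object@stoichiometry)), sort(rxn$id)) && nrow(rxn) > 0)
    msgs <- c(msgs, "stoichiometry list must have one entry per reaction")
  if (any(rxn$lower_bound > rxn$upper_bound))
    msgs <- c(msgs, "lower_bound > upper_bound for some reaction")
  for (rid in names(object@stoichiometry)) {
    st <- object@stoichiometry[[rid]]
    if (length(st) == 0L) { msgs <- c(msgs, paste0("empty stoichiometry in ", rid)); next }
    if (any(st == 0)) msgs <- c(msgs, paste0("zero coefficient in ", rid))
    bad <- setdiff(names(st), met$id)
    if (length(bad))
      msgs <- c(msgs, paste0("reaction ", rid, " references unknown metabolite(s): ",
                             paste(bad, collapse = ", ")))
  }
  if (length(object@objective) && length(setdiff(names(object@objective), rxn$id)))
    msgs <- c(msgs, "objective references unknown reaction(s)")
  if (length(msgs)) msgs else TRUE
})

#' Scenario: a named constraint preset
#'
#' Encodes one of the two simulation regimes: \emph{yield mode} (maximal
#' stoichiometric yield: no maintenance, no energy-consuming side reactions,
#' Rubisco carboxylase/oxygenase decoupled, cost-free Na+-dependent bicarbonate
#' uptake, photon influx 15.57) and \emph{transition mode} (wild-type-like
#' state: oxygenase, respiration, Mehler-like and ROS couplings plus a fixed
#' maintenance ATP demand, photon influx 18.0).
#'
#' @slot name one of "yield_mode", "transition_mode", "custom".
#' @slot photon_influx fixed photon uptake (flux units).
#' @slot maintenance_atp basal ATP hydrolysis flux (mmol gDW^-1 h^-1).
#' @slot rubisco_coupled logical; TRUE installs the oxygenase coupling.
#' @slot oxygenase_fraction fraction of total Rubisco flux forced through the
#'   oxygenase (default 0.03).
#' @slot respiration_fraction cytochrome-c-oxidase flux as a fraction of PSII
#'   oxygen evolution (default 0.10).
#' @slot mehler_fraction Mehler-like flux as a fraction of PSII oxygen
#'   evolution (default 0.10).
#' @slot ros_fraction ROS electron fraction per photosystem (default 0.005).
#' @slot couplings list of extra linear constraints (see [solveFBA()]).
#' @slot nitrogen_source "nitrate" or "ammonium".
#' @slot dynamic_coupling logical; TRUE ties respiration/Mehler fluxes to the
#'   PSII flux variable itself, FALSE fixes them to the initial wild-type value.
#' @exportClass Scenario
setClass("Scenario", representation(
  name = "character",
  photon_influx = "numeric",
  maintenance_atp = "numeric",
  rubisco_coupled = "logical",
  oxygenase_fraction = "numeric",
  respiration_fraction = "numeric",
  mehler_fraction = "numeric",
  ros_fraction = "numeric",
  couplings = "list",
  nitrogen_source = "character",
  dynamic_coupling = "logical"
))

setValidity("Scenario", function(object) {
  msgs <- character(0)
  if (!object@name %in% c("yield_mode", "transition_mode", "custom"))
    msgs <- c(msgs, "name must be yield_mode, transition_mode or custom")
  if (object@photon_influx <= 0) msgs <- c(msgs, "photon_influx must be > 0")
  if (object@maintenance_atp < 0) msgs <- c(msgs, "maintenance_atp must be >= 0")
  fr <- c(object@oxygenase_fraction, object@respiration_fraction,
          object@mehler_fraction, object@ros_fraction)
  if (any(fr < 0 | fr >= 1)) msgs <- c(msgs, "all fractions must lie in [0, 1)")
  if (!object@nitrogen_source %in% c("nitrate", "ammonium"))
    msgs <- c(msgs, "nitrogen_source must be nitrate or ammonium")
  if (length(msgs)) msgs else TRUE
})

#' ProductDefinition: a heterologous product pathway
#'
#' Bundles one product's molecular formula, lower heating value, synthesis
#' pathway reactions, export reaction, and any route constraints (reactions
#' that must be disabled so that synthesis proceeds via the published route).
#'
#' @slot product_id registry key, e.g. "ethanol".
#' @slot name display name.
#' @slot formula Hill formula of the product, e.g. "C2H6O".
#' @slot lhv lower heating value, kJ mol^-1.
#' @slot pathway list of reaction descriptors (id, name, stoichiometry,
#'   lower_bound, upper_bound), the Bi-numbered synthesis steps.
#' @slot export_reaction a single reaction descriptor moving the product out
#'   of the system.
#' @slot route_constraints named list: reaction id -> c(lb, ub) to impose on
#'   the host model (e.g. disabling the acetate route for ethanol).
#' @slot requires character: core-network extension packs this pathway needs.
#' @exportClass ProductDefinition
setClass("ProductDefinition", representation(
  product_id = "character",
  name = "character",
  formula = "character",
  lhv = "numeric",
  pathway = "list",
  export_reaction = "list",
  route_constraints = "list",
  requires = "character"
))

setValidity("ProductDefinition", function(object) {
  msgs <- character(0)
  if (object@lhv <= 0) msgs <- c(msgs, "lhv must be positive")
  if (length(object@export_reaction) == 0L) msgs <- c(msgs, "export reaction missing")
  if (length(msgs)) msgs else TRUE
})

#' FluxSolution: result of one flux-balance optimization
#'
#' @slot fluxes named numeric vector, reaction id -> flux (mmol gDW^-1 h^-1).
#' @slot objective_value optimal objective, same units.
#' @slot status "optimal", "infeasible" or "unbounded".
#' @slot dual_objective dual objective value at the reported basis (equals the
#'   primal objective at a verified optimum).
#' @exportClass FluxSolution
setClass("FluxSolution", representation(
  fluxes = "numeric",
  objective_value = "numeric",
  status = "character",
  dual_objective = "numeric"
))

setMethod("show", "MetabolicModel", function(object) {
  cat("MetabolicModel with", nrow(object@reactions), "reactions and",
      nrow(object@metabolites), "metabolites\n")
  nex <- sum(object@reactions$is_exchange)
  cat("  exchange reactions:", nex, "\n")
  if (length(object@objective))
    cat("  objective:", paste(names(object@objective), collapse = ", "), "\n")
  invisible(object)
})

setMethod("show", "Scenario", function(object) {
  cat("Scenario <", object@name, ">\n", sep = "")
  cat("  photon influx:   ", object@photon_influx, "\n")
  cat("  maintenance ATP: ", object@maintenance_atp, "\n")
  cat("  rubisco coupled: ", object@rubisco_coupled,
      if (object@rubisco_coupled) paste0(" (oxygenase fraction ",
                                         object@oxygenase_fraction, ")") else "", "\n", sep = "")
  cat("  nitrogen source: ", object@nitrogen_source, "\n")
  invisible(object)
})

setMethod("show", "ProductDefinition", function(object) {
  cat("ProductDefinition <", object@product_id, "> ", object@formula,
      ", LHV ", object@lhv, " kJ/mol\n", sep = "")
  cat("  pathway steps: ", paste(vapply(object@pathway, `[[`, "", "id"),
                                 collapse = ", "), "\n", sep = "")
  invisible(object)
})

setMethod("show", "FluxSolution", function(object) {
  cat("FluxSolution:", object@status,
      if (object@status == "optimal") paste0("(objective ",
        format(object@objective_value, digits = 8), ")") else "", "\n")
  invisible(object)
})
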