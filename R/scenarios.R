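# Constraint presets: the two simulation regimes.
#
# Yield mode estimates maximal stoichiometric yield: no maintenance and no
# energy-consuming side reactions (respiration, Mehler-like, ROS), Rubisco
# carboxylase/oxygenase decoupled, bicarbonate importable by the cost-free
# Na+-dependent route, photon influx fixed at 15.57.
#
# Transition mode reflects the initial wild-type state: oxygenase carries 3%
# of total Rubisco flux, basal respiration and the Mehler-like reaction each
# run at 10% of PSII oxygen evolution, ROS evolution at 0.5% of the electrons
# converted in each photosystem, maintenance ATP hydrolysis fixed at 0.6312
# mmol gDW^-1 h^-1, photon influx fixed at 18.0.

.newScenario <- function(name, photon_influx, maintenance_atp, rubisco_coupled,
                         oxygenase_fraction = 0.03, respiration_fraction = 0,
                         mehler_fraction = 0, ros_fraction = 0,
                         couplings = list(), nitrogen_source = "nitrate",
                         dynamic_coupling = TRUE) {
  s <- new("Scenario", name = name, photon_influx = photon_influx,
           maintenance_atp = maintenance_atp, rubisco_coupled = rubisco_coupled,
           oxygenase_fraction = oxygenase_fraction,
           respiration_fraction = respiration_fraction,
           mehler_fraction = mehler_fraction, ros_fraction = ros_fraction,
           couplings = couplings, nitrogen_source = nitrogen_source,
           dynamic_coupling = dynamic_coupling)
  validObject(s)
  s
}

#' Yield-mode constraint preset
#'
#' @param photon_influx fixed light input (default 15.57).
#' @param nitrogen_source "nitrate" (default) or "ammonium".
#' @return a [Scenario-class].
#' @export
yieldScenario <- function(photon_influx = 15.57, nitrogen_source = "nitrate")
  .newScenario("yield_mode", photon_influx, maintenance_atp = 0,
               rubisco_coupled = FALSE, nitrogen_source = nitrogen_source)

#' Transition-mode constraint preset
#'
#' @param photon_influx fixed light input (default 18.0).
#' @param maintenance_atp basal ATP demand (default 0.6312 mmol gDW^-1 h^-1).
#' @param oxygenase_fraction fraction of total Rubisco flux through the
#'   oxygenase (default 0.03).
#' @param respiration_fraction,mehler_fraction fractions of PSII oxygen
#'   evolution (default 0.10 each).
#' @param ros_fraction electron fraction per photosystem (default 0.005).
#' @param nitrogen_source "nitrate" (default) or "ammonium".
#' @param dynamic_coupling TRUE (default) ties respiration/Mehler to the PSII
#'   flux variable; FALSE fixes them to the initial wild-type value.
#' @return a [Scenario-class].
#' @export
transitionScenario <- function(photon_influx = 18.0, maintenance_atp = 0.6312,
                               oxygenase_fraction = 0.03,
                               respiration_fraction = 0.10,
                               mehler_fraction = 0.10, ros_fraction = 0.005,
                               nitrogen_source = "nitrate",
                               dynamic_coupling = TRUE)
  .newScenario("transition_mode", photon_influx, maintenance_atp,
               rubisco_coupled = TRUE,
               oxygenase_fraction = oxygenase_fraction,
               respiration_fraction = respiration_fraction,
               mehler_fraction = mehler_fraction, ros_fraction = ros_fraction,
               nitrogen_source = nitrogen_source,
               dynamic_coupling = dynamic_coupling)

.modelRoles <- function(model, roles = NULL) {
  r <- roles %||% model@annotations$roles
  if (is.null(r)) stop("model carries no reaction-role annotations; supply 'roles'")
  r
}

#' Apply a scenario to a model
#'
#' Installs the scenario's bounds (photon influx, maintenance, disabled side
#' reactions, nitrogen source) on a copy of the model and returns the coupling
#' rows as extra linear constraints for the LP. The original model is not
#' modified.
#'
#' @param model a [MetabolicModel-class] with reaction-role annotations (the
#'   core network carries them; supply \code{roles} for external models).
#' @param scenario a [Scenario-class].
#' @param roles optional named list mapping roles (psii, atpase, maintenance,
#'   rubisco_carboxylase, ...) to reaction ids.
#' @return list with \code{model} (bounded copy) and \code{constraints}
#'   (coupling rows for [solveFBA()]).
#' @export
applyScenario <- function(model, scenario, roles = NULL) {
  roles <- .modelRoles(model, roles)
  need <- function(role) {
    id <- roles[[role]]
    if (is.null(id) || !id %in% model@reactions$id)
      stop("scenario requires reaction with role '", role,
           "' which is missing from the model")
    id
  }
  # light input: fixed influx (uptake is a negative exchange flux)
  m <- setBounds(model, need("photon_exchange"),
                 -scenario@photon_influx, -scenario@photon_influx)
  # maintenance: a basal floor; the optimizer may hydrolyze more (excess ATP
  # must be dissipated in production-dominated phenotypes)
  m <- setBounds(m, need("maintenance"), lower = scenario@maintenance_atp)
  # nitrogen source
  if (scenario@nitrogen_source == "nitrate") {
    m <- setBounds(m, need("no3_exchange"), -1000, 0)
    m <- setBounds(m, need("nh4_exchange"), 0, 0)
  } else {
    m <- setBounds(m, need("no3_exchange"), 0, 0)
    m <- setBounds(m, need("nh4_exchange"), -1000, 0)
  }
  cons <- scenario@couplings
  side <- c("respiration", "mehler", "ros_psii", "ros_psi", "maintenance")
  if (scenario@name == "yield_mode" ||
      (scenario@respiration_fraction == 0 && scenario@mehler_fraction == 0 &&
       scenario@ros_fraction == 0 && scenario@maintenance_atp == 0 &&
       !scenario@rubisco_coupled)) {
    # maximal-yield accounting: energy-consuming side reactions off
    for (role in side)
      if (!is.null(roles[[role]]) && roles[[role]] %in% m@reactions$id)
        m <- setBounds(m, roles[[role]], 0, 0)
    return(list(model = m, constraints = cons))
  }
  # transition-style couplings
  f <- scenario@oxygenase_fraction
  if (scenario@rubisco_coupled && f > 0) {
    cons <- c(cons, list(list(
      coef = setNames(c(1, -f / (1 - f)),
                      c(need("rubisco_oxygenase"), need("rubisco_carboxylase"))),
      dir = "=", rhs = 0)))
  }
  psii <- need("psii")
  ePSII <- roles$psii_electrons_per_unit %||% 4
  ePSI <- roles$psi_electrons_per_unit %||% 1
  eROS <- roles$ros_electrons_per_unit %||% 2
  dynOr <- function(role, frac, base = psii) {
    # coupling target flux = frac * v_base (per O2-evolution unit)
    if (scenario@dynamic_coupling) {
      list(coef = setNames(c(1, -frac), c(need(role), base)), dir = "=", rhs = 0)
    } else {
      NULL  # handled below via fixed bounds
    }
  }
  if (scenario@respiration_fraction > 0) {
    cc <- dynOr("respiration", scenario@respiration_fraction)
    if (!is.null(cc)) cons <- c(cons, list(cc))
  }
  if (scenario@mehler_fraction > 0) {
    cc <- dynOr("mehler", scenario@mehler_fraction)
    if (!is.null(cc)) cons <- c(cons, list(cc))
  }
  if (scenario@ros_fraction > 0 && scenario@dynamic_coupling) {
    cons <- c(cons, list(
      list(coef = setNames(c(eROS, -scenario@ros_fraction * ePSII),
                           c(need("ros_psii"), psii)), dir = "=", rhs = 0),
      list(coef = setNames(c(eROS, -scenario@ros_fraction * ePSI),
                           c(need("ros_psi"), need("psi"))), dir = "=", rhs = 0)))
  }
  if (!scenario@dynamic_coupling) {
    # fixed-value variant: compute the initial wild-type PSII oxygen evolution
    # (growth maximization under dynamic couplings), then freeze side fluxes
    dynScen <- scenario
    dynScen@dynamic_coupling <- TRUE
    ap <- applyScenario(model, dynScen, roles)
    if (length(model@objective) == 0L)
      stop("fixed-value coupling needs a growth objective on the model")
    sol <- solveFBA(ap$model, extra_constraints = ap$constraints)
    if (sol@status != "optimal")
      stop("initial wild-type solve failed: ", sol@status)
    v0 <- sol@fluxes[[psii]]
    m <- setBounds(m, need("respiration"),
                   scenario@respiration_fraction * v0,
                   scenario@respiration_fraction * v0)
    m <- setBounds(m, need("mehler"), scenario@mehler_fraction * v0,
                   scenario@mehler_fraction * v0)
    rosII <- scenario@ros_fraction * ePSII * v0 / eROS
    rosI <- scenario@ros_fraction * ePSI * sol@fluxes[[need("psi")]] / eROS
    m <- setBounds(m, need("ros_psii"), rosII, rosII)
    m <- setBounds(m, need("ros_psi"), rosI, rosI)
  }
  list(model = m, constraints = cons)
}
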