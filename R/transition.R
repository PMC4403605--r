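# Trade-off scans and in-silico transition experiments.
#
# A transition experiment walks the growth requirement down from 100% to 0%
# of the maximal growth rate. At each grid point the product flux is
# maximized subject to mu >= f * mu_max; the product flux is then fixed at
# its step optimum and the variability of every reaction flux is determined.
# Each reaction's trajectory between the growth-only endpoint (f = 1) and
# the production-only endpoint (f = 0) is classified into one of six
# categories from its endpoint flux-range midpoints.

#' Classification rules for transition trajectories
#'
#' @param focus_threshold_biomass focus threshold on the growth-only endpoint
#'   midpoint (default 1e-6 mmol gDW^-1 h^-1).
#' @param focus_threshold_product focus threshold on the production-only
#'   endpoint midpoint (default 1e-4 mmol gDW^-1 h^-1).
#' @param relative_change_cutoff relative change below which a reaction is
#'   marked unchanged (default 0.05).
#' @return list of rules.
#' @export
classificationRules <- function(focus_threshold_biomass = 1e-6,
                                focus_threshold_product = 1e-4,
                                relative_change_cutoff = 0.05) {
  stopifnot(focus_threshold_biomass > 0, focus_threshold_product > 0,
            relative_change_cutoff > 0, relative_change_cutoff < 1)
  list(focus_threshold_biomass = focus_threshold_biomass,
       focus_threshold_product = focus_threshold_product,
       relative_change_cutoff = relative_change_cutoff)
}

.transitionCategories <- c("sign_change", "increase_from_flux",
                           "increase_from_zero", "decrease_to_flux",
                           "decrease_to_zero", "no_change", "below_focus")

#' Growth-versus-production trade-off scan
#'
#' Computes the production frontier: for each growth fraction f on a grid
#' from 1 to 0, the maximal product flux subject to mu >= f * mu_max at
#' constant light. The frontier is non-increasing and concave in f. The
#' default scenario is yield mode (no maintenance, Rubisco decoupled), the
#' regime under which the published trade-off curves were computed; pass a
#' transition-mode scenario to include the wild-type couplings.
#'
#' @param model augmented model carrying a growth objective (reaction named
#'   by the model's biomass role).
#' @param product a [ProductDefinition-class] or product id.
#' @param scenario a [Scenario-class], or NULL to use the model as-is.
#' @param n_steps number of grid points (>= 2; default 101).
#' @param roles optional role map.
#' @param product_export optional reaction id used as the production
#'   objective (defaults to the product's export reaction).
#' @return data.frame with columns growth_fraction, growth_rate_bound,
#'   max_product_flux; attribute \code{"mu_max"}.
#' @export
tradeoffScan <- function(model, product, scenario = yieldScenario(),
                         n_steps = 101, roles = NULL, product_export = NULL) {
  if (is.character(product)) product <- getProduct(product)
  if (n_steps < 2) stop("need at least both endpoints (n_steps >= 2)")
  roles <- .modelRoles(model, roles)
  bio <- roles$biomass
  if (is.null(bio) || !bio %in% model@reactions$id)
    stop("model has no biomass reaction (role 'biomass')")
  expid <- product_export %||% product@export_reaction$id
  if (!expid %in% model@reactions$id)
    stop("model is not augmented with product '", product@product_id, "'")
  ap <- if (is.null(scenario)) list(model = model, constraints = list())
        else applyScenario(model, scenario, roles)
  gsol <- solveFBA(ap$model, setNames(1, bio), "max", ap$constraints)
  if (gsol@status != "optimal") stop("growth maximization failed: ", gsol@status)
  mu_max <- gsol@objective_value
  fracs <- seq(1, 0, length.out = n_steps)
  out <- data.frame(growth_fraction = fracs,
                    growth_rate_bound = fracs * mu_max,
                    max_product_flux = NA_real_)
  for (i in seq_along(fracs)) {
    # growth enforced as a lower bound (inequality), with a whisker of slack
    # at f = 1 against numerical infeasibility
    glb <- fracs[i] * mu_max - if (fracs[i] == 1) 1e-9 else 0
    m <- setBounds(ap$model, bio, lower = glb)
    psol <- solveFBA(m, setNames(1, expid), "max", ap$constraints)
    if (psol@status != "optimal")
      stop("trade-off scan infeasible at growth fraction ", fracs[i])
    out$max_product_flux[i] <- psol@objective_value
  }
  attr(out, "mu_max") <- mu_max
  out
}

#' Classify one transition trajectory
#'
#' Applies the endpoint rules: with a and b the flux-range midpoints at 100%
#' growth and 100% product synthesis, a reaction is below focus when both
#' |a| <= the biomass threshold and |b| <= the product threshold; it is a
#' sign change when the product of the endpoint minima or of the endpoint
#' maxima is negative; unchanged when |b - a| / max(|a|, |b|) is below the
#' cutoff; otherwise an increase (from zero when |a| is below the biomass
#' threshold) or a decrease (to zero when |b| is below the product threshold).
#'
#' @param trajectory data.frame with columns growth_fraction, min, max,
#'   midpoint, containing rows for growth_fraction 1 and 0.
#' @param rules a [classificationRules()] list.
#' @return one of "sign_change", "increase_from_flux", "increase_from_zero",
#'   "decrease_to_flux", "decrease_to_zero", "no_change", "below_focus".
#' @export
classifyTrajectory <- function(trajectory, rules = classificationRules()) {
  gi <- which(trajectory$growth_fraction == 1)
  pi_ <- which(trajectory$growth_fraction == 0)
  if (length(gi) != 1L || length(pi_) != 1L)
    stop("trajectory must contain exactly one row for each endpoint")
  a <- trajectory$midpoint[gi]; b <- trajectory$midpoint[pi_]
  if (abs(a) <= rules$focus_threshold_biomass &&
      abs(b) <= rules$focus_threshold_product) return("below_focus")
  if (trajectory$min[gi] * trajectory$min[pi_] < 0 ||
      trajectory$max[gi] * trajectory$max[pi_] < 0) return("sign_change")
  if (abs(b - a) / max(abs(a), abs(b)) < rules$relative_change_cutoff)
    return("no_change")
  if (abs(b) > abs(a)) {
    if (abs(a) <= rules$focus_threshold_biomass) "increase_from_zero"
    else "increase_from_flux"
  } else {
    if (abs(b) <= rules$focus_threshold_product) "decrease_to_zero"
    else "decrease_to_flux"
  }
}

#' In-silico transition experiment
#'
#' Runs the full growth-to-production transition with per-step
#' flux-variability analysis and endpoint classification of every reaction.
#' Isoenzymes should be collapsed beforehand (see [collapseIsoenzymes()]).
#'
#' @inheritParams tradeoffScan
#' @param rules a [classificationRules()] list.
#' @param targets reactions to trace (default: all).
#' @return list of class \code{"transitionExperiment"}: \code{trajectories}
#'   (long data.frame: reaction_id, growth_fraction, min, max, midpoint),
#'   \code{categories} (named character), \code{counts} (see
#'   [categoryCounts()]), \code{frontier} (the trade-off curve),
#'   \code{mu_max}, \code{grid}.
#' @export
transitionExperiment <- function(model, product,
                                 scenario = transitionScenario(),
                                 rules = classificationRules(), n_steps = 101,
                                 targets = NULL, roles = NULL,
                                 product_export = NULL) {
  if (is.character(product)) product <- getProduct(product)
  if (n_steps < 2) stop("need at least both endpoints (n_steps >= 2)")
  roles <- .modelRoles(model, roles)
  bio <- roles$biomass
  if (is.null(bio) || !bio %in% model@reactions$id)
    stop("model has no biomass reaction (role 'biomass')")
  expid <- product_export %||% product@export_reaction$id
  if (!expid %in% model@reactions$id)
    stop("model is not augmented with product '", product@product_id, "'")
  ap <- if (is.null(scenario)) list(model = model, constraints = list())
        else applyScenario(model, scenario, roles)
  targets <- targets %||% ap$model@reactions$id
  gsol <- solveFBA(ap$model, setNames(1, bio), "max", ap$constraints)
  if (gsol@status != "optimal") stop("growth maximization failed: ", gsol@status)
  mu_max <- gsol@objective_value
  fracs <- seq(1, 0, length.out = n_steps)
  frontier <- data.frame(growth_fraction = fracs,
                         max_product_flux = NA_real_)
  traj <- vector("list", length(fracs))
  for (i in seq_along(fracs)) {
    glb <- fracs[i] * mu_max - if (fracs[i] == 1) 1e-9 else 0
    m <- setBounds(ap$model, bio, lower = glb)
    psol <- solveFBA(m, setNames(1, expid), "max", ap$constraints)
    if (psol@status != "optimal")
      stop("transition experiment infeasible at step ", i,
           " (growth fraction ", fracs[i], ")")
    p <- psol@objective_value
    frontier$max_product_flux[i] <- p
    mfix <- setBounds(m, expid, lower = p - 1e-9)
    fva <- runFVA(mfix, targets = targets, extra_constraints = ap$constraints)
    # reported fluxes are rounded to 1e-6, below the smallest classification
    # threshold, so solver-level noise cannot flip a category
    fva$min <- round(fva$min, 6)
    fva$max <- round(fva$max, 6)
    fva$midpoint <- (fva$min + fva$max) / 2
    fva$growth_fraction <- fracs[i]
    traj[[i]] <- fva
  }
  long <- do.call(rbind, traj)
  names(long)[names(long) == "id"] <- "reaction_id"
  long <- long[, c("reaction_id", "growth_fraction", "min", "max", "midpoint")]
  cats <- vapply(targets, function(r) {
    tr <- long[long$reaction_id == r, ]
    classifyTrajectory(data.frame(growth_fraction = tr$growth_fraction,
                                  min = tr$min, max = tr$max,
                                  midpoint = tr$midpoint), rules)
  }, character(1))
  structure(list(trajectories = long, categories = cats,
                 counts = categoryCounts(cats), frontier = frontier,
                 mu_max = mu_max, grid = fracs, product = product@product_id),
            class = "transitionExperiment")
}

#' Tally transition categories
#'
#' Counts classified reactions per category, excluding those below the focus
#' thresholds. Column order follows the published summary: sign change, flux
#' increase (from flux / from zero), flux decrease (to flux / to zero),
#' no change.
#'
#' @param categories named character vector of per-reaction categories.
#' @return named integer vector over the six categories.
#' @export
categoryCounts <- function(categories) {
  if (is.list(categories)) categories <- unlist(categories)
  lv <- setdiff(.transitionCategories, "below_focus")
  tab <- table(factor(categories[categories != "below_focus"], levels = lv))
  setNames(as.integer(tab), lv)
}

#' @export
print.transitionExperiment <- function(x, ...) {
  cat("Transition experiment:", x$product, "\n")
  cat("  mu_max:", format(x$mu_max, digits = 6), "  grid points:",
      length(x$grid), "\n")
  cat("  category counts (focus reactions):\n")
  print(x$counts)
  invisible(x)
}
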