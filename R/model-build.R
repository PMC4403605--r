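#' Construct a MetabolicModel
#'
#' Low-level constructor used by the generators and readers. Missing optional
#' columns are filled with defaults (bounds -1000/1000 for reversible entries
#' must be set by the caller; here plain defaults are 0/1000).
#'
#' @param metabolites data.frame with at least an \code{id} column.
#' @param reactions data.frame with at least an \code{id} column.
#' @param stoichiometry named list of named numeric vectors.
#' @param objective named numeric vector.
#' @param annotations named list.
#' @return a validated [MetabolicModel-class].
#' @export
makeModel <- function(metabolites, reactions, stoichiometry,
                      objective = numeric(0), annotations = list()) {
  met <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  rxn <- as.data.frame(reactions, stringsAsFactors = FALSE)
  n <- nrow(met)
  if (is.null(met$name)) met$name <- met$id
  if (is.null(met$compartment)) met$compartment <- rep("c", n)
  if (is.null(met$formula)) met$formula <- rep("", n)
  if (is.null(met$charge)) met$charge <- rep(NA_real_, n)
  m <- nrow(rxn)
  if (is.null(rxn$name)) rxn$name <- rxn$id
  if (is.null(rxn$lower_bound)) rxn$lower_bound <- rep(0, m)
  if (is.null(rxn$upper_bound)) rxn$upper_bound <- rep(1000, m)
  if (is.null(rxn$subsystem)) rxn$subsystem <- rep("", m)
  if (is.null(rxn$isoenzyme_group)) rxn$isoenzyme_group <- rep(NA_character_, m)
  if (is.null(rxn$is_exchange)) rxn$is_exchange <- rep(FALSE, m)
  if (is.null(rxn$unbalanced)) rxn$unbalanced <- rep(FALSE, m)
  rownames(met) <- NULL; rownames(rxn) <- NULL
  obj <- objective
  mod <- new("MetabolicModel", metabolites = met, reactions = rxn,
             stoichiometry = stoichiometry[rxn$id], objective = obj,
             annotations = annotations)
  validObject(mod)
  mod
}

#' @describeIn makeModel Reaction identifiers, in model order.
#' @param model a MetabolicModel.
#' @export
reactionIds <- function(model) model@reactions$id

#' @describeIn makeModel Metabolite identifiers, in model order.
#' @export
metaboliteIds <- function(model) model@metabolites$id

#' Reaction bounds of a model
#'
#' @param model a MetabolicModel.
#' @return data.frame with columns id, lower_bound, upper_bound.
#' @export
reactionBounds <- function(model)
  model@reactions[, c("id", "lower_bound", "upper_bound")]

#' Set flux bounds on one or more reactions
#'
#' @param model a MetabolicModel.
#' @param id character vector of reaction ids.
#' @param lower,upper numeric, recycled to \code{length(id)}; NA leaves the
#'   existing bound unchanged.
#' @return the modified model.
#' @export
setBounds <- function(model, id, lower = NA, upper = NA) {
  idx <- match(id, model@reactions$id)
  if (anyNA(idx)) stop("unknown reaction id(s): ",
                       paste(id[is.na(idx)], collapse = ", "))
  lower <- rep_len(lower, length(id)); upper <- rep_len(upper, length(id))
  take <- !is.na(lower)
  model@reactions$lower_bound[idx[take]] <- lower[take]
  take <- !is.na(upper)
  model@reactions$upper_bound[idx[take]] <- upper[take]
  if (any(model@reactions$lower_bound[idx] > model@reactions$upper_bound[idx]))
    stop("setBounds() would leave lower_bound > upper_bound")
  model
}

#' Objective coefficients of a model
#' @param model a MetabolicModel.
#' @return named numeric vector.
#' @export
objectiveCoefficients <- function(model) model@objective

#' Replace the objective of a model
#' @param model a MetabolicModel.
#' @param objective named numeric (reaction id -> weight).
#' @return the modified model.
#' @export
setObjective <- function(model, objective) {
  if (length(setdiff(names(objective), model@reactions$id)))
    stop("objective references unknown reaction(s)")
  model@objective <- objective
  model
}

#' Add a reaction to a model
#'
#' @param model a MetabolicModel.
#' @param id,name reaction identifier and display name.
#' @param stoichiometry named numeric vector (metabolite id -> coefficient);
#'   all referenced metabolites must already exist unless supplied via
#'   \code{new_metabolites}.
#' @param lower_bound,upper_bound flux bounds.
#' @param subsystem,isoenzyme_group,is_exchange,unbalanced reaction metadata.
#' @param new_metabolites optional data.frame of metabolites to add first.
#' @return the extended model.
#' @export
addReaction <- function(model, id, stoichiometry, lower_bound = 0,
                        upper_bound = 1000, name = id, subsystem = "",
                        isoenzyme_group = NA_character_, is_exchange = FALSE,
                        unbalanced = FALSE, new_metabolites = NULL) {
  if (id %in% model@reactions$id) stop("reaction already present: ", id)
  if (!is.null(new_metabolites)) {
    nm <- as.data.frame(new_metabolites, stringsAsFactors = FALSE)
    nm <- nm[!nm$id %in% model@metabolites$id, , drop = FALSE]
    if (nrow(nm)) {
      if (is.null(nm$name)) nm$name <- nm$id
      if (is.null(nm$compartment)) nm$compartment <- "c"
      if (is.null(nm$formula)) nm$formula <- ""
      if (is.null(nm$charge)) nm$charge <- NA_real_
      model@metabolites <- rbind(model@metabolites,
                                 nm[, names(model@metabolites)])
    }
  }
  missing <- setdiff(names(stoichiometry), model@metabolites$id)
  if (length(missing))
    stop("reaction ", id, " references missing species: ",
         paste(missing, collapse = ", "))
  model@reactions <- rbind(model@reactions, data.frame(
    id = id, name = name, lower_bound = lower_bound, upper_bound = upper_bound,
    subsystem = subsystem, isoenzyme_group = isoenzyme_group,
    is_exchange = is_exchange, unbalanced = unbalanced,
    stringsAsFactors = FALSE))
  model@stoichiometry[[id]] <- stoichiometry
  validObject(model)
  model
}

#' Remove reactions from a model
#' @param model a MetabolicModel.
#' @param id character vector of reaction ids to drop.
#' @return the reduced model.
#' @export
removeReactions <- function(model, id) {
  keep <- !model@reactions$id %in% id
  model@reactions <- model@reactions[keep, , drop = FALSE]
  rownames(model@reactions) <- NULL
  model@stoichiometry <- model@stoichiometry[model@reactions$id]
  model@objective <- model@objective[names(model@objective) %in% model@reactions$id]
  model
}
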