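#' Build the stoichiometric matrix S
#'
#' Rows are metabolites (model order), columns are reactions (model order);
#' entry (i, j) is the signed coefficient of metabolite i in reaction j. A
#' steady-state flux vector satisfies S v = 0.
#'
#' @param model a [MetabolicModel-class].
#' @return a sparse \code{dgCMatrix} with dimnames (metabolites, reactions).
#' @export
stoichMatrix <- function(model) {
  mets <- model@metabolites$id
  rxns <- model@reactions$id
  if (length(rxns) == 0L)
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(length(mets), 0L),
                                dimnames = list(mets, character(0))))
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (j in seq_along(rxns)) {
    st <- model@stoichiometry[[rxns[j]]]
    idx <- match(names(st), mets)
    if (anyNA(idx))
      stop("structural-integrity error: reaction ", rxns[j],
           " references unknown metabolite(s): ",
           paste(names(st)[is.na(idx)], collapse = ", "))
    ii <- c(ii, idx); jj <- c(jj, rep.int(j, length(st))); xx <- c(xx, unname(st))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(length(mets), length(rxns)),
                       dimnames = list(mets, rxns))
}

#' Check elemental balance of all reactions
#'
#' Verifies conservation of C, H, N, O, P and S for every reaction whose
#' participants all carry formulas. Exchange reactions and reactions tagged
#' \code{unbalanced} (photon uptake, biomass and similar pseudo-reactions,
#' which are unbalanced by design) are skipped. Reactions with a formula-less
#' participant are reported as \emph{uncheckable}, not as imbalanced.
#'
#' @param model a [MetabolicModel-class].
#' @param elements elements to check; default C, H, N, O, P, S.
#' @return data.frame with columns \code{reaction}, \code{element},
#'   \code{imbalance} (signed products-minus-substrates excess; NA with
#'   element "uncheckable" for reactions lacking formulas). Zero rows for a
#'   fully balanced model.
#' @export
checkElementalBalance <- function(model, elements = c("C", "H", "N", "O", "P", "S")) {
  met <- model@metabolites
  forms <- lapply(seq_len(nrow(met)), function(i) parseFormula(met$formula[i]))
  names(forms) <- met$id
  hasFormula <- vapply(forms, function(f) length(f) > 0L, logical(1))
  out <- list()
  pseudo <- model@annotations$pseudo_species %||% character(0)
  for (j in seq_len(nrow(model@reactions))) {
    r <- model@reactions[j, ]
    if (r$is_exchange || r$unbalanced) next
    st <- model@stoichiometry[[r$id]]
    st <- st[!names(st) %in% pseudo]
    if (length(st) == 0L) next
    if (!all(hasFormula[names(st)])) {
      out[[length(out) + 1L]] <- data.frame(reaction = r$id,
                                            element = "uncheckable",
                                            imbalance = NA_real_,
                                            stringsAsFactors = FALSE)
      next
    }
    tot <- setNames(numeric(length(elements)), elements)
    for (m in names(st)) {
      f <- forms[[m]]
      common <- intersect(names(f), elements)
      tot[common] <- tot[common] + st[[m]] * f[common]
    }
    bad <- which(abs(tot) > 1e-9)
    for (b in bad)
      out[[length(out) + 1L]] <- data.frame(reaction = r$id,
                                            element = elements[b],
                                            imbalance = unname(tot[b]),
                                            stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(reaction = character(0), element = character(0),
                      imbalance = numeric(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Collapse isoenzymes into representative reactions
#'
#' Reactions sharing an \code{isoenzyme_group} key are merged into a single
#' representative (the first member, in model order) carrying the summed flux
#' bounds. Group members must have identical stoichiometry. When
#' \code{auto_group} is TRUE, ungrouped reactions with identical stoichiometry
#' up to positive scaling are first assigned automatic groups (the published
#' analysis excluded isoreactions but did not publish the grouping, so a
#' structural heuristic stands in).
#'
#' Idempotent: collapsing a collapsed model is a no-op.
#'
#' @param model a [MetabolicModel-class].
#' @param auto_group logical; auto-group structurally identical reactions.
#' @return the collapsed model.
#' @export
collapseIsoenzymes <- function(model, auto_group = FALSE) {
  rxn <- model@reactions
  if (auto_group) {
    keyOf <- function(rid) {
      st <- model@stoichiometry[[rid]]
      st <- st[order(names(st))]
      sc <- abs(st[[1]])
      paste(names(st), format(st / sc, digits = 12), collapse = "|")
    }
    ungrouped <- which(is.na(rxn$isoenzyme_group))
    keys <- vapply(rxn$id[ungrouped], keyOf, character(1))
    dupGroups <- split(ungrouped, keys)
    gi <- 0L
    for (grp in dupGroups) {
      if (length(grp) > 1L) {
        gi <- gi + 1L
        rxn$isoenzyme_group[grp] <- paste0("auto", gi)
      }
    }
    model@reactions <- rxn
  }
  grouped <- !is.na(rxn$isoenzyme_group)
  if (!any(grouped)) return(model)
  drop <- character(0)
  for (g in unique(rxn$isoenzyme_group[grouped])) {
    members <- rxn$id[grouped & rxn$isoenzyme_group == g]
    if (length(members) < 2L) next
    ref <- model@stoichiometry[[members[1]]]
    ref <- ref[order(names(ref))]
    i1 <- match(members[1], rxn$id)
    lbSum <- rxn$lower_bound[i1]; ubSum <- rxn$upper_bound[i1]
    for (m in members[-1]) {
      st <- model@stoichiometry[[m]]
      st <- st[order(names(st))]
      alpha <- if (identical(names(st), names(ref))) st[[1]] / ref[[1]] else NA
      if (is.na(alpha) || alpha <= 0 || max(abs(st - alpha * ref)) > 1e-9)
        stop("isoenzyme group '", g, "' members have conflicting stoichiometry (",
             members[1], " vs ", m, ")")
      # member bounds expressed on the representative's flux scale
      im <- match(m, rxn$id)
      lbSum <- lbSum + alpha * rxn$lower_bound[im]
      ubSum <- ubSum + alpha * rxn$upper_bound[im]
    }
    rxn$lower_bound[i1] <- lbSum
    rxn$upper_bound[i1] <- ubSum
    drop <- c(drop, members[-1])
  }
  model@reactions <- rxn
  if (length(drop)) model <- removeReactions(model, drop)
  model
}
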