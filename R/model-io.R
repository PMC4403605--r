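# Model and scenario input/output.
#
# Three serializations: (i) a tab-separated tabular dialect (a reactions
# table with equation strings and a metabolites table), (ii) SBML - written
# as Level 3 Version 1 with the fbc package, read from L3+fbc or from
# Level 2 with COBRA-style kineticLaw/notes-encoded bounds, (iii) flat
# key/value scenario files. All output is UTF-8.

#' Write a model in the tabular dialect
#'
#' @param model a [MetabolicModel-class].
#' @param reactions_path,metabolites_path output file paths (TSV).
#' @return invisibly, the two paths.
#' @export
writeTabularModel <- function(model, reactions_path, metabolites_path) {
  rxn <- model@reactions
  eqs <- vapply(rxn$id, function(rid)
    formatEquation(model@stoichiometry[[rid]],
                   reversible = rxn$lower_bound[match(rid, rxn$id)] < 0),
    character(1))
  rt <- data.frame(id = rxn$id, name = rxn$name, equation = eqs,
                   lower_bound = rxn$lower_bound, upper_bound = rxn$upper_bound,
                   subsystem = rxn$subsystem,
                   isoenzyme_group = rxn$isoenzyme_group,
                   stringsAsFactors = FALSE)
  mt <- model@metabolites
  write.table(rt, reactions_path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  write.table(mt, metabolites_path, sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  invisible(c(reactions_path, metabolites_path))
}

#' Read a model from the tabular dialect
#'
#' Reaction equations use \code{"=>"} (irreversible) and \code{"<=>"}
#' (reversible); coefficients precede metabolite tokens, which are opaque
#' identifiers (compartment suffixes are part of the token). Reversible
#' equations without explicit bounds default to [-1000, 1000], irreversible
#' ones to [0, 1000].
#'
#' @param reactions_path,metabolites_path input TSV paths.
#' @return a [MetabolicModel-class].
#' @export
readTabularModel <- function(reactions_path, metabolites_path) {
  rt <- read.delim(reactions_path, stringsAsFactors = FALSE,
                   check.names = FALSE)
  mt <- read.delim(metabolites_path, stringsAsFactors = FALSE,
                   check.names = FALSE)
  if (!all(c("id", "equation") %in% names(rt)))
    stop("reactions table must have 'id' and 'equation' columns")
  if (!"id" %in% names(mt)) stop("metabolites table must have an 'id' column")
  st <- list(); lb <- numeric(nrow(rt)); ub <- numeric(nrow(rt))
  for (i in seq_len(nrow(rt))) {
    pe <- tryCatch(parseEquation(rt$equation[i]), error = function(e)
      stop("row ", i, " (", rt$id[i], "): ", conditionMessage(e)))
    unknown <- setdiff(names(pe$stoichiometry), mt$id)
    if (length(unknown))
      stop("row ", i, " (", rt$id[i], "): unknown metabolite(s): ",
           paste(unknown, collapse = ", "))
    st[[rt$id[i]]] <- pe$stoichiometry
    lb[i] <- if ("lower_bound" %in% names(rt) && !is.na(rt$lower_bound[i]))
      rt$lower_bound[i] else if (pe$reversible) -1000 else 0
    ub[i] <- if ("upper_bound" %in% names(rt) && !is.na(rt$upper_bound[i]))
      rt$upper_bound[i] else 1000
  }
  rxn <- data.frame(id = rt$id,
                    name = if ("name" %in% names(rt)) rt$name else rt$id,
                    lower_bound = lb, upper_bound = ub,
                    subsystem = if ("subsystem" %in% names(rt)) rt$subsystem
                      else rep("", nrow(rt)),
                    isoenzyme_group = if ("isoenzyme_group" %in% names(rt))
                      as.character(rt$isoenzyme_group)
                      else rep(NA_character_, nrow(rt)),
                    stringsAsFactors = FALSE)
  nsp <- vapply(st, length, integer(1))
  rxn$is_exchange <- nsp == 1L
  rxn$unbalanced <- rxn$is_exchange
  makeModel(mt, rxn, st)
}

# ---------------------------------------------------------------- scenarios

.scenarioKeys <- c("mode", "photon_influx", "maintenance_atp",
                   "oxygenase_fraction", "respiration_fraction",
                   "mehler_fraction", "ros_fraction", "rubisco_coupled",
                   "nitrogen_source", "dynamic_coupling")

#' Read a scenario configuration file
#'
#' Flat key/value text, one \code{key value} pair per line, \code{#}
#' comments. Recognized keys: \code{mode} (yield|transition),
#' \code{photon_influx}, \code{maintenance_atp}, \code{oxygenase_fraction},
#' \code{respiration_fraction}, \code{mehler_fraction}, \code{ros_fraction},
#' \code{rubisco_coupled} (true/false), \code{nitrogen_source}
#' (nitrate|ammonium), \code{dynamic_coupling} (true/false). Unknown keys are
#' rejected. An empty file yields the all-defaults yield-mode preset; setting
#' any wild-type-state key (positive maintenance, a coupling fraction,
#' \code{rubisco_coupled true}) without an explicit \code{mode} starts from
#' the transition-mode preset.
#'
#' @param path input file.
#' @return a [Scenario-class].
#' @export
readScenarioConfig <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "[ \t]+")[[1]]
    if (length(parts) != 2L)
      stop("cannot parse scenario line: '", ln, "' (expected 'key value')")
    if (!parts[1] %in% .scenarioKeys)
      stop("unknown scenario key '", parts[1], "'; valid keys: ",
           paste(.scenarioKeys, collapse = ", "))
    kv[[parts[1]]] <- parts[2]
  }
  num <- function(k) if (k %in% names(kv)) as.numeric(kv[[k]]) else NULL
  flag <- function(k) if (k %in% names(kv))
    tolower(kv[[k]]) %in% c("true", "1", "yes") else NULL
  for (k in c("photon_influx", "maintenance_atp"))
    if (!is.null(num(k)) && (is.na(num(k)) || num(k) < 0))
      stop("scenario key '", k, "' must be a non-negative number")
  mode <- kv$mode %||% NULL
  transitionish <- isTRUE((num("maintenance_atp") %||% 0) > 0) ||
    isTRUE(flag("rubisco_coupled")) ||
    any(c("oxygenase_fraction", "respiration_fraction", "mehler_fraction",
          "ros_fraction") %in% names(kv))
  base <- if (identical(mode, "transition") ||
              (is.null(mode) && transitionish)) transitionScenario()
          else yieldScenario()
  if (!is.null(num("photon_influx"))) {
    if (num("photon_influx") <= 0) stop("photon_influx must be positive")
    base@photon_influx <- num("photon_influx")
  }
  if (!is.null(num("maintenance_atp"))) base@maintenance_atp <- num("maintenance_atp")
  for (k in c("oxygenase_fraction", "respiration_fraction", "mehler_fraction",
              "ros_fraction"))
    if (!is.null(num(k))) slot(base, k) <- num(k)
  if (!is.null(flag("rubisco_coupled"))) base@rubisco_coupled <- flag("rubisco_coupled")
  if (!is.null(flag("dynamic_coupling"))) base@dynamic_coupling <- flag("dynamic_coupling")
  if ("nitrogen_source" %in% names(kv)) base@nitrogen_source <- kv$nitrogen_source
  validObject(base)
  base
}

#' Write a scenario configuration file
#' @param scenario a [Scenario-class].
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeScenarioConfig <- function(scenario, path) {
  lines <- c(
    paste("mode", if (scenario@name == "transition_mode") "transition" else "yield"),
    paste("photon_influx", format(scenario@photon_influx, digits = 12)),
    paste("maintenance_atp", format(scenario@maintenance_atp, digits = 12)),
    paste("oxygenase_fraction", format(scenario@oxygenase_fraction, digits = 12)),
    paste("respiration_fraction", format(scenario@respiration_fraction, digits = 12)),
    paste("mehler_fraction", format(scenario@mehler_fraction, digits = 12)),
    paste("ros_fraction", format(scenario@ros_fraction, digits = 12)),
    paste("rubisco_coupled", tolower(scenario@rubisco_coupled)),
    paste("nitrogen_source", scenario@nitrogen_source),
    paste("dynamic_coupling", tolower(scenario@dynamic_coupling)))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

# --------------------------------------------------------------------- SBML

.sbmlSanitize <- function(x) gsub("[^A-Za-z0-9_]", "_", x)

#' Write a model as SBML (Level 3 Version 1 + fbc)
#'
#' @param model a [MetabolicModel-class].
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeSBMLModel <- function(model, path) {
  fbcNS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"
  doc <- xml2::xml_new_root(
    "sbml", xmlns = "http://www.sbml.org/sbml/level3/version1/core",
    "xmlns:fbc" = fbcNS, level = "3", version = "1", "fbc:required" = "false")
  mdl <- xml2::xml_add_child(doc, "model", id = "cyanoflux_model",
                             "fbc:strict" = "false")
  cmps <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cp in unique(model@metabolites$compartment))
    xml2::xml_add_child(cmps, "compartment", id = .sbmlSanitize(cp),
                        constant = "true")
  sps <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(model@metabolites))) {
    m <- model@metabolites[i, ]
    sp <- xml2::xml_add_child(sps, "species", id = m$id, name = m$name,
                              compartment = .sbmlSanitize(m$compartment),
                              hasOnlySubstanceUnits = "false",
                              boundaryCondition = "false", constant = "false")
    if (nzchar(m$formula) && !is.na(m$formula))
      xml2::xml_set_attr(sp, "fbc:chemicalFormula", m$formula)
    if (!is.na(m$charge))
      xml2::xml_set_attr(sp, "fbc:charge", format(m$charge))
  }
  # distinct flux-bound parameters
  bvals <- sort(unique(c(model@reactions$lower_bound,
                         model@reactions$upper_bound)))
  pid <- setNames(paste0("fb_", seq_along(bvals)),
                  vapply(bvals, format, "", digits = 17))
  prs <- xml2::xml_add_child(mdl, "listOfParameters")
  for (i in seq_along(bvals))
    xml2::xml_add_child(prs, "parameter", id = pid[[i]],
                        value = format(bvals[i], digits = 17),
                        constant = "true")
  rxs <- xml2::xml_add_child(mdl, "listOfReactions")
  for (i in seq_len(nrow(model@reactions))) {
    r <- model@reactions[i, ]
    rx <- xml2::xml_add_child(rxs, "reaction", id = r$id, name = r$name,
                              reversible = tolower(r$lower_bound < 0),
                              fast = "false")
    xml2::xml_set_attr(rx, "fbc:lowerFluxBound",
                       pid[[format(r$lower_bound, digits = 17)]])
    xml2::xml_set_attr(rx, "fbc:upperFluxBound",
                       pid[[format(r$upper_bound, digits = 17)]])
    meta <- c(
      if (r$is_exchange) "EXCHANGE:true",
      if (r$unbalanced) "UNBALANCED:true",
      if (nzchar(r$subsystem)) paste0("SUBSYSTEM:", r$subsystem),
      if (!is.na(r$isoenzyme_group)) paste0("ISOGROUP:", r$isoenzyme_group))
    if (length(meta)) {
      nt <- xml2::xml_add_child(rx, "notes")
      bd <- xml2::xml_add_child(nt, "body",
                                xmlns = "http://www.w3.org/1999/xhtml")
      for (mm in meta) xml2::xml_add_child(bd, "p", mm)
    }
    st <- model@stoichiometry[[r$id]]
    subs <- st[st < 0]; prods <- st[st > 0]
    if (length(subs)) {
      lr <- xml2::xml_add_child(rx, "listOfReactants")
      for (mname in names(subs))
        xml2::xml_add_child(lr, "speciesReference", species = mname,
                            stoichiometry = format(-subs[[mname]], digits = 17),
                            constant = "true")
    }
    if (length(prods)) {
      lp <- xml2::xml_add_child(rx, "listOfProducts")
      for (mname in names(prods))
        xml2::xml_add_child(lp, "speciesReference", species = mname,
                            stoichiometry = format(prods[[mname]], digits = 17),
                            constant = "true")
    }
  }
  if (length(model@objective)) {
    lo <- xml2::xml_add_child(mdl, "fbc:listOfObjectives",
                              "fbc:activeObjective" = "obj")
    ob <- xml2::xml_add_child(lo, "fbc:objective", "fbc:id" = "obj",
                              "fbc:type" = "maximize")
    lf <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
    for (rid in names(model@objective))
      xml2::xml_add_child(lf, "fbc:fluxObjective", "fbc:reaction" = rid,
                          "fbc:coefficient" = format(model@objective[[rid]],
                                                     digits = 17))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

.xfind <- function(node, name)
  xml2::xml_find_all(node, paste0(".//*[local-name()='", name, "']"))

.xattr <- function(node, name) {
  # attribute lookup tolerant of namespace prefixes
  at <- xml2::xml_attrs(node)
  hit <- which(names(at) == name | grepl(paste0(":", name, "$"), names(at)))
  if (length(hit)) at[[hit[1]]] else NA_character_
}

#' Read a model from SBML
#'
#' Accepts Level 3 with the fbc package (flux bounds as parameters,
#' objectives as fluxObjective entries) or Level 2 with COBRA-style
#' kineticLaw LOWER_BOUND/UPPER_BOUND parameters; unspecified bounds default
#' to [-1000, 1000] for reversible and [0, 1000] for irreversible reactions.
#' Species marked \code{boundaryCondition="true"} are dropped from reaction
#' stoichiometries (their reactions become exchange reactions).
#'
#' @param path SBML file.
#' @return a [MetabolicModel-class].
#' @export
readSBMLModel <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("SBML parse error in '", path, "': ", conditionMessage(e)))
  level <- xml2::xml_attr(doc, "level") %||% "3"
  # parameters (flux bounds)
  pars <- .xfind(doc, "parameter")
  pmap <- setNames(as.numeric(xml2::xml_attr(pars, "value")),
                   xml2::xml_attr(pars, "id"))
  # species
  spn <- .xfind(doc, "species")
  boundary <- xml2::xml_attr(spn, "boundaryCondition") %in% c("true", "1")
  getFormula <- function(nd) {
    f <- .xattr(nd, "chemicalFormula")
    if (!is.na(f)) return(f)
    nt <- xml2::xml_text(nd)
    m <- regmatches(nt, regexec("FORMULA: *([A-Za-z0-9]*)", nt))[[1]]
    if (length(m) == 2L && nzchar(m[2])) m[2] else ""
  }
  mets <- data.frame(
    id = xml2::xml_attr(spn, "id"),
    name = ifelse(is.na(xml2::xml_attr(spn, "name")),
                  xml2::xml_attr(spn, "id"), xml2::xml_attr(spn, "name")),
    compartment = ifelse(is.na(xml2::xml_attr(spn, "compartment")), "c",
                         xml2::xml_attr(spn, "compartment")),
    formula = vapply(spn, getFormula, character(1)),
    charge = suppressWarnings(as.numeric(vapply(spn, .xattr, "", "charge"))),
    stringsAsFactors = FALSE)
  boundaryIds <- mets$id[boundary]
  # reactions
  rxn <- .xfind(doc, "reaction")
  n <- length(rxn)
  ids <- xml2::xml_attr(rxn, "id")
  st <- list()
  lb <- numeric(n); ub <- numeric(n)
  isex <- logical(n); unb <- logical(n); subsys <- character(n)
  isog <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    nd <- rxn[[i]]
    rev <- !identical(xml2::xml_attr(nd, "reversible"), "false")
    s <- numeric(0)
    for (side in c("listOfReactants", "listOfProducts")) {
      sgn <- if (side == "listOfReactants") -1 else 1
      refs <- xml2::xml_find_all(nd, paste0(
        "./*[local-name()='", side, "']/*[local-name()='speciesReference']"))
      for (rf in refs) {
        sp <- xml2::xml_attr(rf, "species")
        coef <- xml2::xml_attr(rf, "stoichiometry")
        coef <- if (is.na(coef)) 1 else as.numeric(coef)
        prev <- if (sp %in% names(s)) s[[sp]] else 0
        s[sp] <- prev + sgn * coef
      }
    }
    if (length(s) == 0L)
      stop("structural error: reaction '", ids[i], "' has no stoichiometry")
    dropped <- names(s) %in% boundaryIds
    if (any(dropped) && !all(dropped)) s <- s[!dropped]
    s <- s[s != 0]
    if (length(s) == 0L)
      stop("structural error: reaction '", ids[i],
           "' has only boundary species")
    st[[ids[i]]] <- s
    # bounds
    lbv <- ubv <- NA_real_
    lbp <- .xattr(nd, "lowerFluxBound"); ubp <- .xattr(nd, "upperFluxBound")
    if (!is.na(lbp) && lbp %in% names(pmap)) lbv <- pmap[[lbp]]
    if (!is.na(ubp) && ubp %in% names(pmap)) ubv <- pmap[[ubp]]
    if (is.na(lbv) || is.na(ubv)) {
      kl <- xml2::xml_find_all(nd, paste0(
        "./*[local-name()='kineticLaw']//*[local-name()='parameter']"))
      if (length(kl)) {
        kid <- xml2::xml_attr(kl, "id")
        kv <- as.numeric(xml2::xml_attr(kl, "value"))
        if (is.na(lbv) && "LOWER_BOUND" %in% kid)
          lbv <- kv[match("LOWER_BOUND", kid)]
        if (is.na(ubv) && "UPPER_BOUND" %in% kid)
          ubv <- kv[match("UPPER_BOUND", kid)]
      }
    }
    if (is.na(lbv)) lbv <- if (rev) -1000 else 0
    if (is.na(ubv)) ubv <- 1000
    lb[i] <- lbv; ub[i] <- ubv
    nt <- xml2::xml_text(nd)
    isex[i] <- sum(!dropped) == 1L || any(dropped) ||
      grepl("EXCHANGE:true", nt, fixed = TRUE)
    unb[i] <- grepl("UNBALANCED:true", nt, fixed = TRUE) || isex[i]
    sm <- regmatches(nt, regexec("SUBSYSTEM:([^\n<]*)", nt))[[1]]
    if (length(sm) == 2L) subsys[i] <- trimws(sm[2])
    gm <- regmatches(nt, regexec("ISOGROUP:([^\n<]*)", nt))[[1]]
    if (length(gm) == 2L) isog[i] <- trimws(gm[2])
  }
  rdf <- data.frame(id = ids,
                    name = ifelse(is.na(xml2::xml_attr(rxn, "name")), ids,
                                  xml2::xml_attr(rxn, "name")),
                    lower_bound = lb, upper_bound = ub, subsystem = subsys,
                    isoenzyme_group = isog, is_exchange = isex,
                    unbalanced = unb, stringsAsFactors = FALSE)
  # objective (fbc fluxObjective)
  fo <- .xfind(doc, "fluxObjective")
  obj <- numeric(0)
  if (length(fo)) {
    orx <- vapply(fo, .xattr, "", "reaction")
    oco <- as.numeric(vapply(fo, .xattr, "", "coefficient"))
    obj <- setNames(oco, orx)
    obj <- obj[names(obj) %in% ids]
  }
  makeModel(mets, rdf, st, objective = obj,
            annotations = list(source = path, sbml_level = level))
}
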