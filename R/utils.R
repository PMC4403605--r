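#' @importFrom methods new validObject is slot slot<- show
#' @importFrom stats setNames
#' @importFrom utils read.delim write.table head tail
NULL

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

#' Parse a molecular formula into elemental counts
#'
#' Converts a Hill-style formula string such as \code{"C2H6O"} into a named
#' numeric vector of elemental counts. An empty or \code{NA} formula returns a
#' zero-length vector, which marks the species as formula-less (pseudo-species
#' such as photons or biomass).
#'
#' @param formula character scalar, e.g. \code{"C21H26N7O17P3"}.
#' @return named numeric vector of counts, names are element symbols.
#' @examples
#' parseFormula("C2H6O")
#' @export
parseFormula <- function(formula) {
  if (length(formula) != 1L) stop("parseFormula() expects a single string")
  if (is.na(formula) || !nzchar(formula)) return(setNames(numeric(0), character(0)))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (!nzchar(paste(toks, collapse = "")) || nchar(paste(toks, collapse = "")) != nchar(formula))
    stop("cannot parse formula: ", formula)
  el <- sub("[0-9]*$", "", toks)
  nct <- sub("^[A-Z][a-z]?", "", toks)
  n <- ifelse(nzchar(nct), as.numeric(nct), 1)
  counts <- tapply(n, el, sum)
  setNames(as.numeric(counts), names(counts))
}

#' Parse a reaction equation string
#'
#' Understands the tabular dialect \code{"2 A + B => C"} (irreversible) and
#' \code{"A <=> B"} (reversible). Metabolite tokens are opaque identifiers;
#' compartment suffixes in square brackets (\code{glc[e]}) are part of the
#' token. An empty side (exchange reactions) is written as nothing or
#' \code{" "} around the arrow.
#'
#' @param equation character scalar.
#' @return list with \code{stoichiometry} (named numeric, negative =
#'   substrate) and \code{reversible} (logical).
#' @export
parseEquation <- function(equation) {
  if (grepl("<=>", equation, fixed = TRUE)) {
    rev <- TRUE
    sides <- strsplit(equation, "<=>", fixed = TRUE)[[1]]
  } else if (grepl("=>", equation, fixed = TRUE)) {
    rev <- FALSE
    sides <- strsplit(equation, "=>", fixed = TRUE)[[1]]
  } else stop("equation has no recognized arrow ('=>' or '<=>'): ", equation)
  if (length(sides) == 1L) sides <- c(sides, "")
  if (length(sides) != 2L) stop("equation has more than one arrow: ", equation)
  parseSide <- function(s, sign) {
    s <- trimws(s)
    if (!nzchar(s)) return(setNames(numeric(0), character(0)))
    terms <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
    terms <- terms[nzchar(terms)]
    out <- numeric(0)
    for (tm in terms) {
      m <- regmatches(tm, regexec("^([0-9]*\\.?[0-9]*(?:/[0-9]+)?)\\s*(.+)$", tm))[[1]]
      coefTok <- m[2]
      met <- trimws(m[3])
      coef <- if (!nzchar(coefTok)) 1
      else if (grepl("/", coefTok, fixed = TRUE)) {
        p <- as.numeric(strsplit(coefTok, "/", fixed = TRUE)[[1]]); p[1] / p[2]
      } else as.numeric(coefTok)
      if (!nzchar(met)) stop("unparseable term '", tm, "' in equation: ", equation)
      prev <- if (met %in% names(out)) out[[met]] else 0
      out[met] <- prev + sign * coef
    }
    out
  }
  lhs <- parseSide(sides[1], -1)
  rhs <- parseSide(sides[2], +1)
  st <- lhs
  for (m in names(rhs)) {
    prev <- if (m %in% names(st)) st[[m]] else 0
    st[m] <- prev + rhs[[m]]
  }
  st <- st[st != 0]
  list(stoichiometry = st, reversible = rev)
}

#' Format a stoichiometry map as an equation string
#'
#' Inverse of [parseEquation()]: renders a named coefficient vector as
#' \code{"2 A + B => C"} (or \code{"<=>"} when \code{reversible}).
#'
#' @param stoichiometry named numeric vector, negative = substrate.
#' @param reversible logical.
#' @return character scalar.
#' @export
formatEquation <- function(stoichiometry, reversible = FALSE) {
  fmtSide <- function(x) {
    if (length(x) == 0L) return("")
    paste(vapply(names(x), function(m) {
      cf <- x[[m]]
      if (isTRUE(all.equal(cf, 1))) m else paste(format(cf, digits = 12), m)
    }, character(1)), collapse = " + ")
  }
  subs <- -stoichiometry[stoichiometry < 0]
  prods <- stoichiometry[stoichiometry > 0]
  arrow <- if (reversible) "<=>" else "=>"
  trimws(paste(fmtSide(subs), arrow, fmtSide(prods)))
}
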