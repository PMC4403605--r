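# Flux-balance analysis on top of the simplex engine.
#
# The LP is  max/min  c'v  s.t.  S v = 0,  lb <= v <= ub,  plus optional
# extra linear constraints over fluxes (coupling rows, growth bounds).
# Extra constraints are lists:  list(coef = c(R1 = 1, R2 = -0.1),
# dir = "=" | "<=" | ">=", rhs = 0).  Inequalities get slack columns.

.assembleLP <- function(model, extra_constraints = list()) {
  S <- as.matrix(stoichMatrix(model))
  rxns <- model@reactions$id
  n <- length(rxns)
  lb <- model@reactions$lower_bound
  ub <- model@reactions$upper_bound
  m0 <- nrow(S)
  nc <- length(extra_constraints)
  if (nc == 0L)
    return(list(A = S, b = rep(0, m0), lb = lb, ub = ub, n = n, rxns = rxns))
  rows <- matrix(0, nc, n)
  rhs <- numeric(nc)
  slackLB <- numeric(0); slackUB <- numeric(0); slackRow <- integer(0)
  for (i in seq_len(nc)) {
    con <- extra_constraints[[i]]
    bad <- setdiff(names(con$coef), rxns)
    if (length(bad))
      stop("constraint references missing reaction(s): ",
           paste(bad, collapse = ", "))
    rows[i, match(names(con$coef), rxns)] <- unname(con$coef)
    rhs[i] <- con$rhs %||% 0
    dir <- con$dir %||% "="
    if (dir == "<=") { slackRow <- c(slackRow, i); slackLB <- c(slackLB, 0); slackUB <- c(slackUB, Inf) }
    else if (dir == ">=") { slackRow <- c(slackRow, i); slackLB <- c(slackLB, -Inf); slackUB <- c(slackUB, 0) }
    else if (dir != "=") stop("constraint dir must be '=', '<=' or '>='")
  }
  A <- rbind(cbind(S, matrix(0, m0, length(slackRow))),
             cbind(rows, matrix(0, nc, length(slackRow))))
  for (k in seq_along(slackRow)) A[m0 + slackRow[k], n + k] <- 1
  list(A = A, b = c(rep(0, m0), rhs),
       lb = c(lb, slackLB), ub = c(ub, slackUB), n = n, rxns = rxns)
}

#' Flux-balance analysis
#'
#' Maximizes (or minimizes) a linear flux objective subject to steady state
#' (S v = 0), flux bounds, and optional extra linear constraints.
#'
#' @param model a [MetabolicModel-class].
#' @param objective named numeric (reaction id -> weight); defaults to the
#'   model's stored objective.
#' @param direction "max" or "min".
#' @param extra_constraints list of \code{list(coef=, dir=, rhs=)} linear
#'   relations over fluxes.
#' @param tol solver feasibility/optimality tolerance.
#' @return a [FluxSolution-class]. Infeasible or unbounded problems are
#'   reported in \code{status}, never silently zeroed.
#' @export
solveFBA <- function(model, objective = NULL, direction = c("max", "min"),
                     extra_constraints = list(), tol = 1e-9) {
  direction <- match.arg(direction)
  obj <- objective %||% model@objective
  if (length(obj) == 0L) stop("no objective given and model has none")
  lp <- .assembleLP(model, extra_constraints)
  cc <- numeric(ncol(lp$A))
  idx <- match(names(obj), lp$rxns)
  if (anyNA(idx)) stop("objective references unknown reaction(s): ",
                       paste(names(obj)[is.na(idx)], collapse = ", "))
  cc[idx] <- unname(obj)
  res <- simplexSolve(lp$A, lp$b, cc, lp$lb, lp$ub,
                      maximize = direction == "max", tol = tol)
  if (res$status != "optimal")
    return(new("FluxSolution", fluxes = setNames(numeric(0), character(0)),
               objective_value = NA_real_, status = res$status,
               dual_objective = NA_real_))
  new("FluxSolution",
      fluxes = setNames(res$x[seq_len(lp$n)], lp$rxns),
      objective_value = res$obj, status = "optimal",
      dual_objective = res$dual_obj)
}

#' Flux-variability analysis
#'
#' For each target reaction, computes the minimum and maximum flux over the
#' steady-state polytope after fixing the listed fluxes, using two LP solves
#' per target with warm-started bases.
#'
#' @param model a [MetabolicModel-class].
#' @param fixed named numeric vector: reaction id -> value to fix (equality,
#'   implemented as a tight bound pair), or NULL.
#' @param targets character vector of reaction ids (default: all reactions).
#' @param extra_constraints as in [solveFBA()].
#' @param tol solver tolerance.
#' @return data.frame with columns \code{id}, \code{min}, \code{max},
#'   \code{midpoint} (the arithmetic mean of the endpoints).
#' @export
runFVA <- function(model, fixed = NULL, targets = NULL,
                   extra_constraints = list(), tol = 1e-9) {
  if (!is.null(fixed) && length(fixed)) {
    model <- setBounds(model, names(fixed), lower = unname(fixed),
                       upper = unname(fixed))
  }
  targets <- targets %||% model@reactions$id
  bad <- setdiff(targets, model@reactions$id)
  if (length(bad)) stop("unknown target reaction(s): ", paste(bad, collapse = ", "))
  lp <- .assembleLP(model, extra_constraints)
  warm <- NULL
  nall <- ncol(lp$A)
  res <- data.frame(id = targets, min = NA_real_, max = NA_real_,
                    midpoint = NA_real_, stringsAsFactors = FALSE)
  for (k in seq_along(targets)) {
    j <- match(targets[k], lp$rxns)
    cc <- numeric(nall); cc[j] <- 1
    for (dirmax in c(FALSE, TRUE)) {
      out <- simplexSolve(lp$A, lp$b, cc, lp$lb, lp$ub, maximize = dirmax,
                          tol = tol, warm = warm)
      if (out$status == "infeasible") {
        # identify a binding culprit for the error message
        stop("FVA infeasible after fixing fluxes",
             if (length(fixed)) paste0(" (fixed: ",
               paste(names(fixed), collapse = ", "), ")") else "")
      }
      if (out$status == "unbounded") {
        if (dirmax) res$max[k] <- Inf else res$min[k] <- -Inf
        warm <- NULL
      } else {
        if (dirmax) res$max[k] <- out$obj else res$min[k] <- out$obj
        warm <- out$warm
      }
    }
  }
  res$midpoint <- (res$min + res$max) / 2
  res
}

#' Parsimonious active-reaction count at an optimum
#'
#' With the objective fixed at its optimum, minimizes the total absolute flux
#' (each reaction split into forward and reverse parts) and counts reactions
#' with |v| above threshold. Futile cycles that are free at the optimum carry
#' zero flux in the minimal-total-flux solution.
#'
#' @param model a [MetabolicModel-class] (isoenzymes should be collapsed
#'   beforehand if the count is to exclude them).
#' @param objective named numeric objective (default: model objective).
#' @param objective_optimum optional precomputed optimum; computed by an
#'   initial FBA solve when NULL.
#' @param extra_constraints as in [solveFBA()].
#' @param threshold active-flux threshold (default 1e-9).
#' @param slack absolute slack subtracted from the optimum when fixing it.
#' @return list with \code{count}, \code{fluxes} (the flux-minimal solution),
#'   and \code{total_flux}.
#' @export
minimalActiveSet <- function(model, objective = NULL, objective_optimum = NULL,
                             extra_constraints = list(), threshold = 1e-9,
                             slack = 1e-9) {
  obj <- objective %||% model@objective
  if (is.null(objective_optimum)) {
    sol <- solveFBA(model, obj, "max", extra_constraints)
    if (sol@status != "optimal") stop("optimum computation failed: ", sol@status)
    objective_optimum <- sol@objective_value
  }
  lp <- .assembleLP(model, extra_constraints)
  n <- lp$n; nall <- ncol(lp$A)
  # objective-fixing row: c'v >= opt - slack
  objrow <- numeric(nall); objrow[match(names(obj), lp$rxns)] <- unname(obj)
  # split each structural flux v = vp - vn, vp,vn >= 0
  A2 <- cbind(lp$A, -lp$A[, seq_len(n), drop = FALSE])
  A2 <- rbind(A2, c(objrow, -objrow[seq_len(n)]))
  b2 <- c(lp$b, objective_optimum - slack)
  # slack column for the >= row
  A2 <- cbind(A2, c(rep(0, nrow(A2) - 1L), 1))
  lbp <- pmax(lp$lb[seq_len(n)], 0); ubp <- pmax(lp$ub[seq_len(n)], 0)
  lbn <- pmax(-lp$ub[seq_len(n)], 0); ubn <- pmax(-lp$lb[seq_len(n)], 0)
  lb2 <- c(lbp, lp$lb[-seq_len(n)], lbn, -Inf)
  ub2 <- c(ubp, lp$ub[-seq_len(n)], ubn, 0)
  # the parsimonious penalty approximates enzyme usage: reactions tagged as
  # penalty-exempt (passive diffusion such as the lumen proton leak) cost 0
  w <- rep(1, n)
  exempt <- model@annotations$flux_penalty_exempt %||% character(0)
  w[lp$rxns %in% exempt] <- 0
  cc <- c(w, rep(0, nall - n), w, 0)
  out <- simplexSolve(A2, b2, cc, lb2, ub2, maximize = FALSE)
  if (out$status != "optimal")
    stop("total-flux minimization failed: ", out$status)
  v <- out$x[seq_len(n)] - out$x[nall + seq_len(n)]
  total <- sum(abs(v))
  # reported fluxes rounded to 1e-6 so that slack-level activity (the 1e-9
  # objective whisker) never counts as an active reaction
  v <- setNames(round(v, 6), lp$rxns)
  list(count = sum(abs(v) > threshold), fluxes = v, total_flux = total)
}
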