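# Bounded-variable primal simplex.
#
# Solves   min / max  c'x   s.t.  A x = b,  lb <= x <= ub
# with a two-phase revised simplex: product-form basis-inverse updates with
# periodic refactorization, Dantzig pricing with a Bland's-rule fallback for
# anti-cycling, and warm starts from a previous basis (used heavily by FVA,
# where only the objective changes between solves).
#
# Written in-package: the R environment targeted by this package ships no
# general LP solver, and the flux polytopes here (a few hundred variables)
# are comfortably within reach of a careful dense implementation.

#' Solve a bounded linear program
#'
#' @param A constraint matrix (m x n), dense or sparse.
#' @param b right-hand side (length m).
#' @param cc objective coefficients (length n).
#' @param lb,ub variable bounds (may contain -Inf/Inf).
#' @param maximize logical; FALSE minimizes.
#' @param tol feasibility/optimality tolerance.
#' @param warm optional warm-start object (\code{$basis}, \code{$nstat})
#'   returned by a previous call on the same constraint data.
#' @param maxiter iteration cap.
#' @return list with \code{status} ("optimal"/"infeasible"/"unbounded"),
#'   \code{x}, \code{obj}, \code{y} (row duals), \code{dj} (reduced costs),
#'   \code{dual_obj}, and \code{warm} for reuse.
#' @keywords internal
simplexSolve <- function(A, b, cc, lb, ub, maximize = FALSE, tol = 1e-9,
                         warm = NULL, maxiter = 50000L) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(b) == m, length(cc) == n, length(lb) == n, length(ub) == n)
  if (any(lb > ub + tol)) return(list(status = "infeasible"))
  sgn <- if (maximize) -1 else 1
  cost2 <- c(sgn * cc, rep(0, m))          # phase-2 cost incl. artificials
  cost1 <- c(rep(0, n), rep(1, m))         # phase-1 cost
  LB <- c(lb, rep(0, m))
  UB <- c(ub, rep(Inf, m))

  # initial nonbasic values at the finite bound nearest zero; free vars at 0
  initVal <- function(j) {
    if (is.finite(LB[j]) && is.finite(UB[j])) {
      if (abs(LB[j]) <= abs(UB[j])) LB[j] else UB[j]
    } else if (is.finite(LB[j])) LB[j]
    else if (is.finite(UB[j])) UB[j]
    else 0
  }

  Afull <- cbind(A, diag(1, m))            # artificial signs fixed below

  x <- numeric(n + m)
  nstat <- integer(n + m)  # 0 = nonbasic at lb, 1 = at ub, 2 = free-at-zero, 3 = basic

  phase <- 1L
  if (!is.null(warm) && length(warm$basis) == m) {
    basis <- warm$basis
    nstat <- warm$nstat
    nstat[basis] <- 3L
    nonb <- setdiff(seq_len(n + m), basis)
    for (j in nonb) {
      x[j] <- switch(nstat[j] + 1L, LB[j], UB[j], 0)
      if (!is.finite(x[j])) { x[j] <- 0; nstat[j] <- 2L }
    }
    Binv <- tryCatch(solve(Afull[, basis, drop = FALSE]),
                     error = function(e) NULL)
    if (!is.null(Binv)) {
      xB <- drop(Binv %*% (b - Afull[, nonb, drop = FALSE] %*% x[nonb]))
      if (all(xB >= LB[basis] - 1e-7) && all(xB <= UB[basis] + 1e-7)) {
        x[basis] <- xB
        phase <- 2L
      }
    }
    if (phase == 1L) { x[] <- 0; nstat[] <- 0L }  # warm start unusable
  }

  if (phase == 1L) {
    for (j in seq_len(n)) {
      x[j] <- initVal(j)
      nstat[j] <- if (is.finite(LB[j]) && x[j] == LB[j]) 0L
                  else if (is.finite(UB[j]) && x[j] == UB[j]) 1L else 2L
    }
    r <- b - drop(A %*% x[seq_len(n)])
    s <- ifelse(r >= 0, 1, -1)
    Afull[, n + seq_len(m)] <- diag(s, m)
    basis <- n + seq_len(m)
    nstat[basis] <- 3L
    x[basis] <- abs(r)
    Binv <- diag(s, m)                     # inverse of diag(s)
    if (max(abs(r)) <= tol) phase <- 2L    # already feasible
  }
  if (phase == 2L) UB[n + seq_len(m)] <- 0  # artificials never re-enter

  cost <- if (phase == 1L) cost1 else cost2
  iter <- 0L; sincefactor <- 0L; bland <- FALSE
  refactor <- function() {
    Binv <<- solve(Afull[, basis, drop = FALSE])
    nonb <- setdiff(seq_len(n + m), basis)
    x[basis] <<- drop(Binv %*% (b - Afull[, nonb, drop = FALSE] %*% x[nonb]))
    sincefactor <<- 0L
  }

  repeat {
    iter <- iter + 1L
    if (iter > maxiter) stop("simplex iteration limit reached")
    if (sincefactor >= 120L) refactor()
    if (iter == 5000L) bland <- TRUE

    y <- drop(crossprod(Binv, cost[basis]))
    dj <- cost - drop(crossprod(Afull, y))
    dj[basis] <- 0

    viol <- numeric(n + m)
    atlb <- nstat == 0L; atub <- nstat == 1L; fre <- nstat == 2L
    viol[atlb] <- pmax(0, -dj[atlb])
    viol[atub] <- pmax(0, dj[atub])
    viol[fre] <- abs(dj[fre])
    cand <- which(viol > tol)
    if (length(cand) == 0L) {
      # optimal for current phase
      if (phase == 1L) {
        p1 <- sum(cost1 * x)
        if (p1 > 1e-7) return(list(status = "infeasible"))
        UB[n + seq_len(m)] <- 0           # lock artificials at zero
        phase <- 2L
        cost <- cost2
        next
      }
      obj <- sum(cost2[seq_len(n)] * x[seq_len(n)])
      nonb <- setdiff(seq_len(n + m), basis)
      dualObj <- sum(y * b) + sum(dj[nonb] * x[nonb])
      xs <- x[seq_len(n)]
      return(list(status = "optimal",
                  x = xs,
                  obj = sgn * obj,
                  y = sgn * y,
                  dj = sgn * dj[seq_len(n)],
                  dual_obj = sgn * dualObj,
                  warm = list(basis = basis, nstat = nstat)))
    }
    jin <- if (bland) min(cand) else cand[which.max(viol[cand])]
    dir <- if (nstat[jin] == 1L) -1 else if (nstat[jin] == 0L) 1
           else if (dj[jin] < 0) 1 else -1

    w <- drop(Binv %*% Afull[, jin])
    # ratio test: x_B(t) = x_B - dir * t * w
    dw <- dir * w
    tmax <- Inf; leave <- 0L; leaveAt <- NA_integer_  # 0 -> lb, 1 -> ub
    for (i in seq_len(m)) {
      bi <- basis[i]
      if (dw[i] > tol) {
        if (is.finite(LB[bi])) {
          ti <- (x[bi] - LB[bi]) / dw[i]
          if (ti < tmax - 1e-12) { tmax <- ti; leave <- i; leaveAt <- 0L }
        }
      } else if (dw[i] < -tol) {
        if (is.finite(UB[bi])) {
          ti <- (UB[bi] - x[bi]) / (-dw[i])
          if (ti < tmax - 1e-12) { tmax <- ti; leave <- i; leaveAt <- 1L }
        }
      }
    }
    span <- UB[jin] - LB[jin]
    flip <- FALSE
    if (is.finite(span) && span < tmax) { tmax <- span; flip <- TRUE }
    if (!is.finite(tmax)) {
      if (phase == 1L) stop("phase-1 unboundedness: inconsistent state")
      return(list(status = "unbounded"))
    }
    tmax <- max(tmax, 0)
    # apply step
    if (tmax > 0) x[basis] <- x[basis] - tmax * dw
    newv <- x[jin] + dir * tmax
    if (flip) {
      x[jin] <- newv
      nstat[jin] <- if (dir > 0) 1L else 0L
    } else {
      bout <- basis[leave]
      x[jin] <- newv
      x[bout] <- if (leaveAt == 0L) LB[bout] else UB[bout]
      nstat[bout] <- leaveAt
      nstat[jin] <- 3L
      basis[leave] <- jin
      # product-form update of Binv
      piv <- w[leave]
      if (abs(piv) < 1e-11) { refactor() } else {
        Binv[leave, ] <- Binv[leave, ] / piv
        oth <- setdiff(seq_len(m), leave)
        if (length(oth))
          Binv[oth, ] <- Binv[oth, ] - outer(w[oth], Binv[leave, ])
        sincefactor <- sincefactor + 1L
      }
    }
  }
}
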