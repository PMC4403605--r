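# Small models built in code for the test suite.

# linear chain:  -> A -> B -> ... -> export, uptake fixed at `uptake`
chainModel <- function(k = 3, uptake = 5) {
  mets <- data.frame(id = paste0("M", seq_len(k)), formula = "C")
  rxn <- data.frame(id = c("SRC", paste0("R", seq_len(k - 1)), "OUT"),
                    lower_bound = c(uptake, rep(0, k - 1), 0),
                    upper_bound = c(uptake, rep(1000, k - 1), 1000),
                    is_exchange = c(TRUE, rep(FALSE, k - 1), TRUE),
                    unbalanced = c(TRUE, rep(FALSE, k - 1), TRUE))
  st <- c(list(SRC = c(M1 = 1)),
          setNames(lapply(seq_len(k - 1), function(i)
            setNames(c(-1, 1), paste0("M", c(i, i + 1)))),
            paste0("R", seq_len(k - 1))),
          list(OUT = setNames(-1, paste0("M", k))))
  makeModel(mets, rxn, st, objective = c(OUT = 1))
}

# two routes from A to B with different yields: R1 1:1, R2 2:1
branchModel <- function(uptake = 10) {
  mets <- data.frame(id = c("A", "B"))
  rxn <- data.frame(id = c("SRC", "R1", "R2", "OUT"),
                    lower_bound = c(uptake, 0, 0, 0),
                    upper_bound = c(uptake, 1000, 1000, 1000),
                    is_exchange = c(TRUE, FALSE, FALSE, TRUE),
                    unbalanced = c(TRUE, FALSE, FALSE, TRUE))
  st <- list(SRC = c(A = 1), R1 = c(A = -1, B = 1), R2 = c(A = -2, B = 1),
             OUT = c(B = -1))
  makeModel(mets, rxn, st, objective = c(OUT = 1))
}

# six-reaction transition toy with hand-enumerable endpoint FVA:
#   SRC -> A (fixed 10); CONV: A -> B (cap 6); ALT: A -> C (cap 6);
#   SHUT: B <-> C; GROW: B -> (growth); PROD: C -> (product)
# growth-only: GROW = 10, CONV in [4,6], ALT in [4,6], SHUT in [-6,-4]
# production-only: PROD = 10, SHUT in [4,6]  => SHUT changes sign
transitionToy <- function() {
  mets <- data.frame(id = c("A", "B", "C"))
  rxn <- data.frame(id = c("SRC", "CONV", "ALT", "SHUT", "GROW", "PROD"),
                    lower_bound = c(10, 0, 0, -1000, 0, 0),
                    upper_bound = c(10, 6, 6, 1000, 1000, 1000),
                    is_exchange = c(TRUE, FALSE, FALSE, FALSE, TRUE, TRUE),
                    unbalanced = c(TRUE, FALSE, FALSE, FALSE, TRUE, TRUE))
  st <- list(SRC = c(A = 1), CONV = c(A = -1, B = 1), ALT = c(A = -1, C = 1),
             SHUT = c(B = -1, C = 1), GROW = c(B = -1), PROD = c(C = -1))
  makeModel(mets, rxn, st, objective = c(GROW = 1))
}

# random feasible toy network: a chain with extra random shortcut reactions
randomToyModel <- function(seed) {
  set.seed(seed)
  k <- sample(3:6, 1)
  m <- chainModel(k, uptake = round(runif(1, 1, 8), 2))
  nextra <- sample(1:3, 1)
  for (j in seq_len(nextra)) {
    from <- sample(k, 1); to <- sample(k, 1)
    if (from == to) next
    id <- paste0("X", j)
    if (id %in% reactionIds(m)) next
    m <- addReaction(m, id,
                     setNames(c(-1, 1), paste0("M", c(from, to))),
                     lower_bound = if (runif(1) < 0.3) -round(runif(1, 0, 5), 2) else 0,
                     upper_bound = round(runif(1, 0, 10), 2))
  }
  m
}

steadyStateResidual <- function(model, sol) {
  S <- as.matrix(stoichMatrix(model))
  max(abs(S %*% sol@fluxes[colnames(S)]))
}

coreCache <- local({
  cache <- list()
  function(key, builder) {
    if (is.null(cache[[key]])) cache[[key]] <<- builder()
    cache[[key]]
  }
})

# memoized per-product yield summaries on the core network
summaryCache <- local({
  cache <- list()
  function(pid) {
    if (is.null(cache[[pid]])) {
      prod <- getProduct(pid)
      host <- generateCoreNetwork(extensions = prod@requires)
      aug <- augmentWithProduct(host, prod)
      cache[[pid]] <<- stoichiometricSummary(aug, prod)
    }
    cache[[pid]]
  }
})
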