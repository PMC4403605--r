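# Linear-programming core: FBA, FVA, parsimonious active set.

test_that("FBA solves bound-limited chains and picks the better branch", {
  chain <- chainModel(3, uptake = 5)
  sol <- solveFBA(chain)
  expect_equal(sol@status, "optimal")
  expect_equal(sol@objective_value, 5)
  expect_lt(steadyStateResidual(chain, sol), 1e-9 * max(1, max(abs(sol@fluxes))))

  # brute force over the two extreme pathways: route R1 yields 1 B per A,
  # route R2 yields 0.5; with 10 A the enumerated optimum is 10
  br <- branchModel(10)
  enumerated <- max(10 / 1, 10 / 2)
  sol <- solveFBA(br)
  expect_equal(sol@objective_value, enumerated)
  expect_equal(unname(sol@fluxes["R1"]), 10)
  expect_equal(unname(sol@fluxes["R2"]), 0)
})

test_that("infeasible and unbounded problems are reported, never zeroed", {
  m <- chainModel(3, uptake = 5)
  m <- setBounds(m, "R1", 0, 1)           # chain cannot carry the fixed uptake
  expect_equal(solveFBA(m)@status, "infeasible")

  m2 <- branchModel(10)
  # an uncapped two-reaction cycle with positive objective weight
  m2 <- setBounds(m2, "R1", upper = Inf)
  m2 <- addReaction(m2, "LOOP", c(B = -1, A = 1), 0, Inf)
  expect_equal(solveFBA(m2, c(LOOP = 1))@status, "unbounded")
})

test_that("reported optima satisfy LP duality", {
  for (m in list(chainModel(4, 3), branchModel(7))) {
    sol <- solveFBA(m)
    expect_lt(abs(sol@objective_value - sol@dual_objective),
              1e-7 * max(1, abs(sol@objective_value)))
  }
})

test_that("simplex agrees with an independent solver on random LPs", {
  set.seed(7)
  for (k in 1:25) {
    m <- sample(2:5, 1); n <- m + sample(2:6, 1)
    A <- matrix(round(rnorm(m * n), 2), m, n)
    x0 <- runif(n, 0, 5); u <- x0 + runif(n, 0, 5)
    b <- drop(A %*% x0)
    cc <- rnorm(n)
    mine <- cyanoflux:::simplexSolve(A, b, cc, rep(0, n), u)
    ref <- tryCatch(pracma::linprog(cc, A = diag(n), b = u, Aeq = A, beq = b,
                                    maxiter = 200),
                    error = function(e) NULL)
    if (is.null(ref) || is.null(ref$fval)) next
    expect_equal(mine$status, "optimal")
    expect_equal(mine$obj, ref$fval, tolerance = 1e-6)
  }
})

test_that("FVA brackets the FBA flux and is exact on determined chains", {
  chain <- chainModel(4, uptake = 2.5)
  fva <- runFVA(chain)
  expect_true(all(abs(fva$min - fva$max) < 1e-9))   # fully determined
  expect_true(all(abs(fva$midpoint - 2.5) < 1e-9))

  # two parallel identical routes carrying total flux 10: each in [0, 10]
  m <- branchModel(10)
  m <- addReaction(m, "R1b", c(A = -1, B = 1))      # duplicate of R1
  fva <- runFVA(m, fixed = c(OUT = 10), targets = c("R1", "R1b"))
  expect_equal(fva$min, c(0, 0), tolerance = 1e-9)
  expect_equal(fva$max, c(10, 10), tolerance = 1e-9)
  expect_equal(fva$midpoint, c(5, 5), tolerance = 1e-9)
})

test_that("FVA contains the FBA solution on random toy models", {
  for (seed in 1:12) {
    m <- randomToyModel(seed)
    sol <- solveFBA(m)
    expect_equal(sol@status, "optimal")
    expect_lt(steadyStateResidual(m, sol),
              1e-9 * max(1, max(abs(sol@fluxes))))
    fva <- runFVA(m, fixed = setNames(sol@objective_value, "OUT"))
    v <- sol@fluxes[fva$id]
    expect_true(all(v >= fva$min - 1e-7))
    expect_true(all(v <= fva$max + 1e-7))
  }
})

test_that("FVA ranges shrink or stay equal when constraints are added", {
  for (seed in c(3, 8)) {
    m <- randomToyModel(seed)
    sol <- solveFBA(m)
    base <- runFVA(m, fixed = setNames(sol@objective_value, "OUT"))
    extra <- list(list(coef = c(R1 = 1), dir = "<=",
                       rhs = mean(c(base$min[base$id == "R1"],
                                    base$max[base$id == "R1"]))))
    tight <- runFVA(m, fixed = setNames(sol@objective_value, "OUT"),
                    extra_constraints = extra)
    expect_true(all(tight$min >= base$min - 1e-7))
    expect_true(all(tight$max <= base$max + 1e-7))
  }
})

test_that("total-flux minimization removes futile cycles at the optimum", {
  m <- branchModel(6)
  # a futile cycle A -> B -> A that could carry arbitrary flux at the optimum
  m <- addReaction(m, "CYC", c(B = -1, A = 1), 0, 1000)
  mas <- minimalActiveSet(m)
  expect_lt(abs(mas$fluxes[["CYC"]]), 1e-9)
  expect_equal(mas$count, 3L)  # SRC, R1, OUT

  # single chain: count equals chain length (all reactions carry flux)
  chain <- chainModel(5, uptake = 1)
  expect_equal(minimalActiveSet(chain)$count, 6L)
})

test_that("minimal active set is invariant to duplicating an inactive reaction", {
  m <- branchModel(6)
  base <- minimalActiveSet(m)$count
  m2 <- addReaction(m, "R2dup", c(A = -2, B = 1))   # duplicate of unused R2
  expect_equal(minimalActiveSet(m2)$count, base)
})
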