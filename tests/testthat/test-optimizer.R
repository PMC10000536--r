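ctl <- function(...) besControl(populationSize = 10, maxIterations = 5,
                                reruns = 1, seed = 7, ...)

evalU <- function(pop, hist = rep(1 / 256, 256)) {
  pop$fit <- apply(pop$pos, 1, function(x) kapurFitness(hist, repairToThresholds(x)))
  pop
}

test_that("initPopulation respects bounds, seeds and degeneracy", {
  set.seed(1)
  p <- initPopulation(besControl(populationSize = 30), 8)
  expect_equal(dim(p$pos), c(30L, 8L))
  expect_true(all(p$pos >= 0 & p$pos <= 255))
  expect_true(all(is.na(p$fit)))

  deg <- besControl(lower = 5, upper = 5)
  set.seed(2)
  expect_true(all(initPopulation(deg, 3)$pos == 5))

  set.seed(3); a <- initPopulation(besControl(), 4)
  set.seed(3); b <- initPopulation(besControl(), 4)
  expect_identical(a, b)

  expect_error(initPopulation(besControl(), 0), "k")
})

test_that("dynamicOpposite collapses to known points under forced draws", {
  expect_equal(dynamicOpposite(2, 0, 10, w = 1, r1 = 1, r2 = 1), 8)
  expect_equal(dynamicOpposite(c(2, 7), 0, 10, w = 2, r1 = 0, r2 = 0.3), c(2, 7))
  expect_equal(dynamicOpposite(5, 0, 10, w = 3, r1 = 0.7, r2 = 1), 5)
  expect_error(dynamicOpposite(2, 0, 10, w = 0), "w")
  set.seed(4)
  for (i in 1:50) {
    x <- runif(3, 0, 255)
    expect_true(all(dynamicOpposite(x, 0, 255, w = 3) >= 0 &
                    dynamicOpposite(x, 0, 255, w = 3) <= 255))
  }
})

test_that("dolInitialization keeps the N fittest of agents plus opposites", {
  c0 <- ctl()
  set.seed(5)
  pop <- evalU(initPopulation(c0, 2))
  set.seed(6)
  out <- dolInitialization(list(pos = pop$pos, fit = rep(NA_real_, 10)),
                           function(x) kapurFitness(rep(1 / 256, 256),
                                                    repairToThresholds(x)),
                           c0)
  expect_equal(nrow(out$pos), 10L)
  expect_gte(max(out$fit), max(pop$fit))       # never worse than raw random
  expect_true(all(diff(out$fit) <= 0))         # returned in rank order
})

test_that("selectPhase reproduces the hand-evaluated update", {
  # scalars: P_best = 10, P_mean = 6, P_i = 4, alpha = 2, r = 0.5 -> 12
  pop <- list(pos = matrix(c(10, 4, 4), 3, 1), fit = c(5, 1, 1))
  c0 <- besControl(populationSize = 3, alphaSelect = 2, lower = 0, upper = 255)
  cand <- selectPhase(pop, c0, r = 0.5)
  expect_equal(cand[2, 1], 10 + 2 * 0.5 * (6 - 4))
  # r = 0 -> everyone proposes P_best
  expect_true(all(selectPhase(pop, c0, r = 0) == 10))
  # agent at the mean proposes P_best for any r
  popm <- list(pos = matrix(c(10, 6, 2), 3, 1), fit = c(5, 1, 1))
  expect_equal(selectPhase(popm, c0, r = 0.77)[2, 1], 10)
})

test_that("spiralDraws normalizes and guards the zero case", {
  d <- spiralDraws(2, u = c(0.11, 0.23), v = c(0.3, 0.4))
  expect_lte(max(abs(d$l)), 1)
  expect_lte(max(abs(d$m)), 1)
  expect_equal(abs(d$l[which.max(abs(d$lr))]), 1)

  z <- spiralDraws(3, u = 0, v = 0)
  expect_equal(z$l, rep(0, 3))
  expect_equal(z$m, rep(0, 3))

  # forced theta = pi/2, r = 1: lr = 1, mr ~ 0
  dh <- spiralDraws(1, alphaSpiral = 5, searchCycles = 0.5,
                    u = 0.1, v = (1 - pi / 2) / 0.5)
  expect_equal(dh$theta, pi / 2, tolerance = 1e-12)
  expect_equal(dh$lr, 1, tolerance = 1e-12)
  expect_lt(abs(dh$mr), 1e-12)
})

test_that("searchPhase applies the spiral update with wrapped neighbours", {
  # scalars: P_i = 4, P_next = 2, P_mean = 6, m = 0.5, l = 0.25 -> 4.5
  pop <- list(pos = matrix(c(4, 2, 12), 3, 1), fit = c(1, 1, 1))
  c0 <- besControl(populationSize = 3)
  draws <- list(l = c(0.25, 0, 0), m = c(0.5, 0, 0))
  cand <- searchPhase(pop, draws, c0)
  expect_equal(cand[1, 1], 4 + 0.5 * (4 - 2) + 0.25 * (4 - 6))
  # zero draws leave positions unchanged
  z <- list(l = rep(0, 3), m = rep(0, 3))
  expect_equal(searchPhase(pop, z, c0), pop$pos)
  # identical agents are fixed points whatever the draws
  same <- list(pos = matrix(5, 3, 1), fit = rep(1, 3))
  expect_true(all(searchPhase(same, draws, c0) == 5))
  # wrap: last agent pairs with the first
  draws3 <- list(l = c(0, 0, 0), m = c(0, 0, 1))
  expect_equal(searchPhase(pop, draws3, c0)[3, 1], 12 + (12 - 4))
})

test_that("dolSearchEnhancement adopts the fittest of three, never regressing", {
  u <- rep(1 / 256, 256)
  fn <- function(x) kapurFitness(u, repairToThresholds(x))
  c0 <- ctl()
  set.seed(8)
  pop <- evalU(initPopulation(c0, 1))
  before <- max(pop$fit)
  set.seed(9)
  out <- dolSearchEnhancement(pop, matrix(runif(10, 0, 255), 10, 1), fn, c0)
  expect_gte(max(out$fit), before)
  expect_true(all(out$fit >= pop$fit))
  # candidates and opposites all worse -> unchanged (best agent at optimum)
  popOpt <- list(pos = matrix(127, 10, 1), fit = rep(fn(127), 10))
  set.seed(10)
  outOpt <- dolSearchEnhancement(popOpt, matrix(0, 10, 1), fn, c0)
  expect_equal(outOpt$pos, popOpt$pos)
})

test_that("swoopPhase reproduces the hand-evaluated dive", {
  # u = 1, P_best = 10, P_i = 4, P_mean = 6, c1 = 2, l1 = 0.5, m1 = 0 -> 6
  pop <- list(pos = matrix(c(10, 4, 4), 3, 1), fit = c(5, 1, 1))
  c0 <- besControl(populationSize = 3, c1 = 2, c2 = 2)
  draws <- list(l = c(0, 0.5, 0), m = c(0, 0, 0))
  cand <- swoopPhase(pop, draws, c0, u = 1)
  expect_equal(cand[2, 1], 10 + 0.5 * (4 - 2 * 6))
  # u = 1, zero coordinates -> P_best for all agents
  z <- list(l = rep(0, 3), m = rep(0, 3))
  expect_true(all(swoopPhase(pop, z, c0, u = 1) == 10))
  # u = 0, zero coordinates -> clipped to the lower bound
  expect_true(all(swoopPhase(pop, z, c0, u = 0) == 0))
})

test_that("repairToThresholds rounds half-up, sorts, keeps duplicates", {
  expect_equal(repairToThresholds(c(76.4, 38.2, 76.6)), c(38L, 76L, 77L))
  expect_equal(repairToThresholds(c(5.5, 5.4)), c(5L, 6L))
  expect_equal(repairToThresholds(c(3, 9, 200)), c(3L, 9L, 200L))
  expect_equal(repairToThresholds(c(80.7, 80.9)), c(81L, 81L))
})

test_that("positions stay in bounds through randomized phase sequences", {
  u <- rep(1 / 256, 256)
  fn <- function(x) kapurFitness(u, repairToThresholds(x))
  c0 <- besControl(populationSize = 8, lower = 0, upper = 255)
  set.seed(12)
  pop <- evalU(initPopulation(c0, 2))
  for (step in 1:200) {
    op <- sample(3, 1)
    cand <- switch(op,
      selectPhase(pop, c0),
      searchPhase(pop, spiralDraws(8), c0),
      swoopPhase(pop, spiralDraws(8, hyperbolic = TRUE), c0))
    expect_true(all(cand >= 0 & cand <= 255))
    pop$pos <- cand
    pop <- evalU(pop)
  }
})

test_that("runDOBES and runBES are reproducible and elitist", {
  u <- rep(1 / 256, 256)
  c0 <- besControl(populationSize = 10, maxIterations = 12, reruns = 3, seed = 42)
  a <- runDOBES(u, 1, c0)
  b <- runDOBES(u, 1, c0)
  expect_identical(bestThresholds(a), bestThresholds(b))
  expect_identical(convergence(a), convergence(b))
  expect_identical(rerunFitness(a), rerunFitness(b))
  expect_true(all(diff(convergence(a)) >= 0))
  expect_equal(bestFitness(a), tail(convergence(a), 1))

  d <- runBES(u, 1, c0)
  e <- runBES(u, 1, c0)
  expect_identical(rerunFitness(d), rerunFitness(e))
  expect_true(all(diff(convergence(d)) >= 0))

  expect_error(runDOBES(u, 0, c0), "k")
  expect_error(runDOBES(u, 300, c0), "k")
})

test_that("both optimizers solve the trivial two-spike landscape", {
  two <- rep(0, 256); two[1] <- 0.5; two[256] <- 0.5
  c0 <- besControl(populationSize = 15, maxIterations = 25, reruns = 3, seed = 5)
  expect_equal(bestFitness(runDOBES(two, 1, c0)), log(2), tolerance = 1e-9)
  expect_equal(bestFitness(runBES(two, 1, c0)), log(2), tolerance = 1e-9)
})
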