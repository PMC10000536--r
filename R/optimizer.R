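# Bald eagle search (select / search / swoop) and its dynamic-opposite
# variant, maximizing a supplied fitness over a k-dimensional box.
#
# A population is a plain list:  pos  N x k matrix,  fit  length-N vector.
# Randomness: Eq-style draws (r, rand, u) are one scalar per agent; the
# dynamic-opposite draws r1, r2 are per dimension. All randomness comes from
# R's global RNG so a single set.seed() makes a rerun bit-reproducible.

clipBox <- function(x, lower, upper) pmin(pmax(x, lower), upper)

popBest <- function(pop) {
  i <- which.max(pop$fit)
  list(pos = pop$pos[i, , drop = TRUE], fit = pop$fit[i])
}

popMean <- function(pop) colMeans(pop$pos)

evalPop <- function(pos, fitnessFn) {
  vf <- attr(fitnessFn, "matrixEval")
  if (!is.null(vf)) vf(pos) else apply(pos, 1L, fitnessFn)
}

#' Random initial population
#'
#' Positions drawn uniformly per dimension within the control's bounds;
#' fitness left unset.
#'
#' @param control a [besControl()] object.
#' @param k search dimension (number of thresholds).
#' @return list with `pos` (N x k matrix) and `fit` (NA vector).
#' @export
initPopulation <- function(control, k) {
  if (k < 1) stop("k must be >= 1")
  n <- control@populationSize
  pos <- matrix(stats::runif(n * k, control@lower, control@upper), n, k)
  list(pos = pos, fit = rep(NA_real_, n))
}

#' Dynamic-opposite point of a position
#'
#' Per dimension, the bounds-reflected opposite is
#' `x_o = lower + upper - x` and the dynamic opposite is
#' `x_do = x + w * r1 * (r2 * x_o - x)` with `r1, r2 ~ U(0, 1)` drawn
#' independently per dimension; the result is clipped to the bounds.
#'
#' @param position numeric vector within the bounds.
#' @param lower,upper box bounds.
#' @param w positive step weight.
#' @param r1,r2 optional fixed draws (recycled per dimension); when `NULL`
#'   they are drawn from the RNG.
#' @return numeric vector of the same length, inside the bounds.
#' @export
dynamicOpposite <- function(position, lower, upper, w = 3, r1 = NULL, r2 = NULL) {
  if (w <= 0) stop("w must be > 0")
  d <- length(position)
  if (is.null(r1)) r1 <- stats::runif(d)
  if (is.null(r2)) r2 <- stats::runif(d)
  xo <- lower + upper - position
  clipBox(position + w * r1 * (r2 * xo - position), lower, upper)
}

# row-wise dynamic opposites of a whole population (same per-dimension
# draw semantics as dynamicOpposite, drawn in one block)
dynamicOppositeMatrix <- function(pos, control) {
  n <- nrow(pos); d <- ncol(pos)
  r1 <- matrix(stats::runif(n * d), n, d)
  r2 <- matrix(stats::runif(n * d), n, d)
  xo <- control@lower + control@upper - pos
  clipBox(pos + control@dolWeight * r1 * (r2 * xo - pos),
          control@lower, control@upper)
}

#' Opposition-enhanced initialization
#'
#' Evaluates the 2N union of a random population and its dynamic opposites
#' and keeps the N fittest agents, so the starting population is never worse
#' than the plain random one.
#'
#' @param pop population from [initPopulation()].
#' @param fitnessFn function(position) -> fitness (maximized).
#' @param control a [besControl()] object.
#' @return evaluated population of the original size.
#' @export
dolInitialization <- function(pop, fitnessFn, control) {
  n <- nrow(pop$pos)
  opp <- dynamicOppositeMatrix(pop$pos, control)
  allPos <- rbind(pop$pos, opp)
  allFit <- evalPop(allPos, fitnessFn)
  keep <- order(allFit, decreasing = TRUE)[seq_len(n)]
  list(pos = allPos[keep, , drop = FALSE], fit = allFit[keep])
}

#' Select phase: exploration toward the best-centred mean
#'
#' Each agent proposes `P_best + alpha * r * (P_mean - P_i)` with one
#' uniform draw r per agent; candidates are clipped to the bounds.
#'
#' @param pop evaluated population.
#' @param control a [besControl()] object.
#' @param r optional fixed per-agent draws (length N or 1).
#' @return N x k candidate matrix.
#' @export
selectPhase <- function(pop, control, r = NULL) {
  n <- nrow(pop$pos)
  if (is.null(r)) r <- stats::runif(n)
  best <- popBest(pop)$pos
  ctr <- popMean(pop)
  cand <- sweep(-pop$pos, 2L, ctr, "+")          # P_mean - P_i
  cand <- cand * (control@alphaSelect * r)       # row-recycled scalar
  cand <- sweep(cand, 2L, best, "+")
  clipBox(cand, control@lower, control@upper)
}

#' Spiral coordinate draws for the search and swoop phases
#'
#' Circular mode (search): `theta_i = alpha * pi * u_i`,
#' `r_i = theta_i + R * v_i`, `lr_i = r_i sin(theta_i)`,
#' `mr_i = r_i cos(theta_i)`. Hyperbolic mode (swoop): `r_i = theta_i`,
#' `lr_i = r_i sinh(theta_i)`, `mr_i = r_i cosh(theta_i)`. Both coordinates
#' are normalized by the maximum absolute raw value (zero maximum maps to
#' all-zero coordinates).
#'
#' @param n number of agents.
#' @param alphaSpiral angle scale.
#' @param searchCycles radius increment R (circular mode only).
#' @param hyperbolic use the sinh/cosh form.
#' @param u,v optional fixed uniform draws (length n or 1).
#' @return list with `theta`, `r`, `lr`, `mr`, and normalized `l`, `m`.
#' @export
spiralDraws <- function(n, alphaSpiral = 10, searchCycles = 1.5,
                        hyperbolic = FALSE, u = NULL, v = NULL) {
  if (is.null(u)) u <- stats::runif(n)
  if (is.null(v)) v <- stats::runif(n)
  theta <- alphaSpiral * pi * rep_len(u, n)
  if (hyperbolic) {
    r <- theta
    lr <- r * sinh(theta); mr <- r * cosh(theta)
  } else {
    r <- theta + searchCycles * rep_len(v, n)
    lr <- r * sin(theta); mr <- r * cos(theta)
  }
  norm0 <- function(x) {
    mx <- max(abs(x))
    if (mx == 0) rep(0, length(x)) else x / mx
  }
  list(theta = theta, r = r, lr = lr, mr = mr,
       l = norm0(lr), m = norm0(mr))
}

#' Search phase: spiral exploitation around neighbours
#'
#' Candidate i is `P_i + m_i (P_i - P_{i+1}) + l_i (P_i - P_mean)`; the
#' neighbour index wraps, so the last agent pairs with the first. Clipped to
#' the bounds.
#'
#' @param pop evaluated population.
#' @param draws [spiralDraws()] of matching size (circular mode).
#' @param control a [besControl()] object.
#' @return N x k candidate matrix.
#' @export
searchPhase <- function(pop, draws, control) {
  n <- nrow(pop$pos)
  nxt <- pop$pos[c(seq_len(n)[-1L], 1L), , drop = FALSE]
  ctr <- popMean(pop)
  cand <- pop$pos + draws$m * (pop$pos - nxt) +
    draws$l * sweep(pop$pos, 2L, ctr, "-")
  clipBox(cand, control@lower, control@upper)
}

#' Dynamic-opposite enhancement of search candidates
#'
#' Per agent, the fitness of the current position, the search candidate and
#' the candidate's dynamic opposite are compared and the fittest of the
#' three is adopted, so the population best can only improve.
#'
#' @param pop evaluated population.
#' @param candidates matrix from [searchPhase()].
#' @param fitnessFn function(position) -> fitness.
#' @param control a [besControl()] object.
#' @return updated evaluated population.
#' @export
dolSearchEnhancement <- function(pop, candidates, fitnessFn, control) {
  opp <- dynamicOppositeMatrix(candidates, control)
  fc <- evalPop(candidates, fitnessFn)
  fo <- evalPop(opp, fitnessFn)
  takeOpp <- fo > fc & fo > pop$fit
  takeCand <- !takeOpp & fc > pop$fit
  if (any(takeOpp)) {
    pop$pos[takeOpp, ] <- opp[takeOpp, , drop = FALSE]
    pop$fit[takeOpp] <- fo[takeOpp]
  }
  if (any(takeCand)) {
    pop$pos[takeCand, ] <- candidates[takeCand, , drop = FALSE]
    pop$fit[takeCand] <- fc[takeCand]
  }
  pop
}

#' Swoop phase: dive toward the best solution
#'
#' Candidate i is `u P_best + l1_i (P_i - c1 P_mean) + m1_i (P_i - c2 P_best)`
#' with one uniform draw u per agent, clipped to the bounds. Candidates are
#' adopted by the caller only when fitter (greedy acceptance).
#'
#' @param pop evaluated population.
#' @param draws hyperbolic [spiralDraws()].
#' @param control a [besControl()] object.
#' @param u optional fixed per-agent draws.
#' @return N x k candidate matrix.
#' @export
swoopPhase <- function(pop, draws, control, u = NULL) {
  n <- nrow(pop$pos)
  if (is.null(u)) u <- stats::runif(n)
  best <- popBest(pop)$pos
  ctr <- popMean(pop)
  a <- sweep(pop$pos, 2L, control@c1 * ctr, "-")   # P_i - c1 P_mean
  b <- sweep(pop$pos, 2L, control@c2 * best, "-")  # P_i - c2 P_best
  cand <- rep_len(u, n) * matrix(best, n, length(best), byrow = TRUE) +
    draws$l * a + draws$m * b
  clipBox(cand, control@lower, control@upper)
}

# adopt candidate rows that strictly improve an agent's fitness
acceptIfBetter <- function(pop, candidates, fitnessFn) {
  candFit <- evalPop(candidates, fitnessFn)
  better <- candFit > pop$fit
  if (any(better)) {
    pop$pos[better, ] <- candidates[better, , drop = FALSE]
    pop$fit[better] <- candFit[better]
  }
  pop
}

#' Round a continuous position to a valid threshold set
#'
#' Rounds half-up to integers and sorts non-decreasing; duplicates are kept
#' (they encode empty classes).
#'
#' @param position numeric vector in \[0, 255\] per dimension.
#' @return sorted integer vector.
#' @export
repairToThresholds <- function(position) {
  as.integer(sort(roundHalfUp(clipBox(position, 0, 255))))
}

# one seeded rerun of the select/search(+DOL)/swoop loop
besEngine <- function(fitnessFn, k, control, dol, seed) {
  set.seed(seed)
  pop <- initPopulation(control, k)
  if (dol) {
    pop <- dolInitialization(pop, fitnessFn, control)
  } else {
    pop$fit <- evalPop(pop$pos, fitnessFn)
  }
  bestSoFar <- popBest(pop)
  conv <- numeric(control@maxIterations)
  for (it in seq_len(control@maxIterations)) {
    pop <- acceptIfBetter(pop, selectPhase(pop, control), fitnessFn)
    drawsC <- spiralDraws(control@populationSize, control@alphaSpiral,
                          control@searchCycles, hyperbolic = FALSE)
    candS <- searchPhase(pop, drawsC, control)
    if (dol) {
      pop <- dolSearchEnhancement(pop, candS, fitnessFn, control)
    } else {
      pop <- acceptIfBetter(pop, candS, fitnessFn)
    }
    drawsH <- spiralDraws(control@populationSize, control@alphaSpiral,
                          control@searchCycles, hyperbolic = TRUE)
    pop <- acceptIfBetter(pop, swoopPhase(pop, drawsH, control), fitnessFn)
    cur <- popBest(pop)
    if (cur$fit > bestSoFar$fit) bestSoFar <- cur
    conv[it] <- bestSoFar$fit
  }
  list(best = bestSoFar, convergence = conv)
}

runEagleSearch <- function(hist, k, control, dol) {
  assertHistogram(hist)
  if (k < 1) stop("k must be >= 1")
  if (k > 256) stop("k may not exceed 256")
  cs <- kapurCumsums(hist)
  fitnessFn <- function(pos) kapurEval(cs, repairToThresholds(pos))
  # fast path for whole-population evaluation: one clip/round pass, cheap sort
  attr(fitnessFn, "matrixEval") <- function(P) {
    q <- floor(pmin(pmax(P, 0), 255) + 0.5)
    out <- numeric(nrow(q))
    for (i in seq_along(out))
      out[i] <- kapurEval(cs, sort.int(as.integer(q[i, ]), method = "radix"))
    out
  }
  bestRun <- NULL
  rerunFit <- numeric(control@reruns)
  for (j in seq_len(control@reruns)) {
    run <- besEngine(fitnessFn, k, control, dol,
                     seed = control@seed + j - 1)
    rerunFit[j] <- run$best$fit
    if (is.null(bestRun) || run$best$fit > bestRun$best$fit) bestRun <- run
  }
  new("ThresholdFit",
      thresholds = repairToThresholds(bestRun$best$pos),
      fitness = bestRun$best$fit,
      convergence = bestRun$convergence,
      rerunFitness = rerunFit,
      algorithm = if (dol) "DOBES" else "BES",
      control = control)
}

#' Threshold search by dynamic-opposite bald eagle search
#'
#' Maximizes [kapurFitness()] over k-threshold sets. Each rerun seeds the RNG
#' with `seed + rerun - 1`, draws a random population, improves it by
#' opposition-based selection, then iterates the select, search (with
#' dynamic-opposite candidate analysis) and swoop phases with greedy
#' per-agent acceptance. Continuous positions are rounded half-up and sorted
#' before each fitness evaluation.
#'
#' @param hist 256-bin probability histogram.
#' @param k number of thresholds (>= 1).
#' @param control a [besControl()] object.
#' @return a [ThresholdFit-class] object.
#' @examples
#' h <- rep(1 / 256, 256)
#' fit <- runDOBES(h, 1, besControl(maxIterations = 20, reruns = 2, seed = 7))
#' bestThresholds(fit)
#' @export
runDOBES <- function(hist, k, control = besControl()) {
  runEagleSearch(hist, k, control, dol = TRUE)
}

#' Threshold search by the plain bald eagle search baseline
#'
#' Identical loop to [runDOBES()] with both dynamic-opposite operations
#' disabled: plain random initialization and greedy acceptance of the raw
#' search candidates. Serves as the ablation baseline.
#'
#' @inheritParams runDOBES
#' @return a [ThresholdFit-class] object.
#' @export
runBES <- function(hist, k, control = besControl()) {
  runEagleSearch(hist, k, control, dol = FALSE)
}
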