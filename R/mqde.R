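## Memory-based quantum-inspired differential evolution. Candidates are real
## vectors (flattened network parameters); the "quantum" operators are the
## method's real-vector DE variants: a superior-blended mutation with
## schedule lambda, a Levy-flight (cuckoo-search) perturbation of the base
## vector, whole-vector crossover, greedy selection, and Lehmer-mean memory
## adaptation of F and CR.

#' Exploration/exploitation schedule lambda
#'
#' lambda = ((gMax - g)/gMax)^2: early generations (lambda near 1) behave
#' like DE/rand/1, late generations (lambda near 0) pull the base vector
#' toward a superior individual.
#'
#' @param g current generation, 1 <= g <= gMax.
#' @param gMax maximum generation count.
#' @return lambda in [0, 1).
#' @export
lambdaSchedule <- function(g, gMax) {
  if (g < 1 || g > gMax) stop("g must lie in [1, gMax]", call. = FALSE)
  ((gMax - g) / gMax)^2
}

#' Levy-flight step size
#'
#' Returns g^(-ap), the heavy-tail-inspired step that perturbs the base
#' vector in later generations less and less.
#'
#' @param g generation >= 1.
#' @param ap exponent in [1, 3].
#' @return the scalar step.
#' @export
levyStep <- function(g, ap) {
  if (ap < 1 || ap > 3) stop("ap must lie in [1, 3]", call. = FALSE)
  if (g < 1) stop("g must be >= 1", call. = FALSE)
  g^(-ap)
}

#' Lehmer mean
#'
#' sum(v^2)/sum(v), the contraharmonic mean used to adapt F and CR from the
#' generation's successful values; always >= the arithmetic mean.
#'
#' @param values nonempty vector of positive values.
#' @return the Lehmer mean.
#' @export
lehmerMean <- function(values) {
  if (!length(values)) stop("no successful rates", call. = FALSE)
  sum(values^2) / sum(values)
}

.clipBounds <- function(v, lo, hi) pmin(hi, pmax(lo, v))

#' DE/superior/1 mutation
#'
#' Draws distinct indices i1, i2, i3 (all different from i), blends a random
#' individual with a randomly chosen superior (top floor(superiorFrac * NP),
#' at least 1, by fitness) individual via lambda, and adds the scaled
#' difference F * (a_i2 - a_i3). Components are clipped to the bounds.
#' Consumes RNG draws: sample of 3 indices, then 1 superior pick.
#'
#' @param pop NP x dim population matrix.
#' @param fitness length-NP fitness vector (lower is better).
#' @param i index of the target candidate.
#' @param F mutation factor.
#' @param lambda blend from \code{\link{lambdaSchedule}}.
#' @param superiorFrac fraction of the population counted as superior.
#' @param bounds c(min, max) component bounds.
#' @return list with the mutant \code{vec} and the blended \code{base}.
#' @export
mutateSuperior <- function(pop, fitness, i, F, lambda, superiorFrac,
                           bounds) {
  NP <- nrow(pop)
  if (NP < 4) stop("population too small (need >= 4)", call. = FALSE)
  others <- setdiff(seq_len(NP), i)
  idx <- others[sample.int(length(others), 3L)]
  nSup <- max(1L, floor(superiorFrac * NP))
  supSet <- order(fitness)[seq_len(nSup)]
  sup <- pop[supSet[sample.int(nSup, 1L)], ]
  base <- lambda * pop[idx[1L], ] + (1 - lambda) * sup
  vec <- base + F * (pop[idx[2L], ] - pop[idx[3L], ])
  list(vec = .clipBounds(vec, bounds[1], bounds[2]),
       base = .clipBounds(base, bounds[1], bounds[2]))
}

#' Cuckoo-search perturbation of the mutant
#'
#' Optionally replaces the base vector by the previous generation's base
#' plus a Levy step (only for candidate index > 2 in the reference control
#' flow), then mixes base and mutant with a single uniform draw r:
#' nvec = r * base + (1 - r) * vec. Consumes one RNG draw.
#'
#' @param basePrev the operative base vector (previous generation's base
#'   when the Levy branch applies, otherwise the current one).
#' @param vec the mutant vector.
#' @param g generation.
#' @param ap Levy exponent.
#' @param applyLevy whether the Levy branch applies (candidate index > 2).
#' @param bounds c(min, max).
#' @return list with the perturbed \code{base} and the new mutant
#'   \code{nvec}.
#' @export
csPerturb <- function(basePrev, vec, g, ap, applyLevy = TRUE,
                      bounds = c(-Inf, Inf)) {
  base <- if (applyLevy) basePrev + levyStep(g, ap) else basePrev
  base <- .clipBounds(base, bounds[1], bounds[2])
  r <- stats::runif(1)
  nvec <- .clipBounds(r * base + (1 - r) * vec, bounds[1], bounds[2])
  list(base = base, nvec = nvec)
}

#' Quantum crossover and greedy selection
#'
#' With one uniform draw, the trial u is the perturbed mutant when
#' rand <= CR and the base vector otherwise; the base vector and the
#' bookkeeping individual q are then replaced greedily (ties favour the
#' newer candidate). Consumes one RNG draw plus objective evaluations.
#'
#' @param nvec perturbed mutant.
#' @param base base vector.
#' @param q bookkeeping individual from the previous generation.
#' @param CR crossover rate.
#' @param objective function mapping a candidate to a finite fitness.
#' @param fNvec,fBase optional cached fitnesses.
#' @return list: \code{base}, \code{fBase}, \code{q}, \code{u}, \code{fu},
#'   \code{crossed} (whether u is the mutant), \code{success} (whether u
#'   replaced the base).
#' @export
crossoverSelect <- function(nvec, base, q, CR, objective,
                            fNvec = NULL, fBase = NULL) {
  crossed <- stats::runif(1) <= CR
  u <- if (crossed) nvec else base
  if (is.null(fBase)) fBase <- .safeFitness(objective, base)
  fu <- if (crossed) {
    if (is.null(fNvec)) .safeFitness(objective, nvec) else fNvec
  } else fBase
  if (fu <= fBase) {
    baseNew <- u; fBaseNew <- fu; qNew <- u; success <- TRUE
  } else {
    baseNew <- base; fBaseNew <- fBase; qNew <- baseNew; success <- FALSE
  }
  list(base = baseNew, fBase = fBaseNew, q = qNew, u = u, fu = fu,
       crossed = crossed, success = success)
}

#' Global optimum scheme
#'
#' Two rules: when the mutant's fitness equals the parent's, the
#' bookkeeping individual is carried over unchanged; when the perturbed
#' mutant is at least as good as the updated base vector, it replaces the
#' parent candidate.
#'
#' @param alpha,q parent candidate and its bookkeeping individual.
#' @param qPrev the previous generation's bookkeeping individual.
#' @param nvec perturbed mutant.
#' @param fVec,fAlpha,fNvec,fBaseNew the relevant fitnesses.
#' @return list with updated \code{alpha}, \code{fAlpha}, \code{q} and a
#'   flag \code{replaced}.
#' @export
globalOptimumScheme <- function(alpha, q, qPrev, nvec, fVec, fAlpha, fNvec,
                                fBaseNew) {
  if (isTRUE(fVec == fAlpha)) q <- qPrev
  replaced <- fNvec <= fBaseNew
  if (replaced) {
    alpha <- nvec
    fAlpha <- fNvec
  }
  list(alpha = alpha, fAlpha = fAlpha, q = q, replaced = replaced)
}

#' Memory update of F and CR
#'
#' uF <- (1 - val) * uF + rand * lehmerMean(S_F) (one uniform draw),
#' likewise for uCR; an empty (or zero-sum) success list leaves the value
#' unchanged. Results are clipped to (0, 1]. The memories seed the
#' per-candidate sampling of the next generation.
#'
#' @param mem list with elements F and CR (the memories uF, uCR).
#' @param SF,SCR successful F/CR values collected this generation.
#' @param val memory rate in (0, 1].
#' @return updated list with F and CR.
#' @export
updateMemory <- function(mem, SF, SCR, val) {
  clip01 <- function(x) min(1, max(1e-8, x))
  if (length(SF) && sum(SF) > 0)
    mem$F <- clip01((1 - val) * mem$F + stats::runif(1) * lehmerMean(SF))
  if (length(SCR) && sum(SCR) > 0)
    mem$CR <- clip01((1 - val) * mem$CR + stats::runif(1) * lehmerMean(SCR))
  mem
}

## per-candidate control parameters around the memories, JADE-style:
## F_i ~ Cauchy(uF, 0.1) truncated to (0, 1], CR_i ~ N(uCR, 0.1) in [0, 1]
.sampleF <- function(uF) {
  Fi <- -1
  while (Fi <= 0) Fi <- uF + 0.1 * tan(pi * (stats::runif(1) - 0.5))
  min(Fi, 1)
}
.sampleCR <- function(uCR) min(1, max(0, uCR + 0.1 * stats::rnorm(1)))

.safeFitness <- function(objective, candidate) {
  f <- objective(candidate)
  if (!is.finite(f)) {
    message("non-finite objective value; candidate rejected")
    f <- Inf
  }
  f
}

#' Configuration of the evolutionary search
#'
#' Defaults follow the reference configuration where one exists: NP defaults to 42,
#' the (I+1)H + (H+1)K parameter count of the 1-10-2 network; bounds
#' [-3, 3] keep the sigmoids out of saturation.
#'
#' @param NP population size (>= 4).
#' @param gMax generations (>= 1).
#' @param F0,CR0 initial mutation factor and crossover rate in (0, 1].
#' @param val memory rate in (0, 1].
#' @param ap Levy exponent in [1, 3].
#' @param superiorFrac fraction of the population treated as superior.
#' @param alphaMin,alphaMax component bounds.
#' @param seed RNG seed.
#' @param plainDE if TRUE run a plain DE/rand/1 with fixed F0/CR0 and no
#'   superior blend, Levy step, memory or global-optimum scheme (the QDE
#'   ablation stand-in).
#' @return a validated config list.
#' @export
mqdeConfig <- function(NP = 42L, gMax = 100L, F0 = 0.5, CR0 = 0.9,
                       val = 0.5, ap = 1.5, superiorFrac = 0.2,
                       alphaMin = -3, alphaMax = 3, seed = 0L,
                       plainDE = FALSE) {
  cfg <- list(NP = as.integer(NP), gMax = as.integer(gMax), F0 = F0,
              CR0 = CR0, val = val, ap = ap, superiorFrac = superiorFrac,
              alphaMin = alphaMin, alphaMax = alphaMax,
              seed = as.integer(seed), plainDE = isTRUE(plainDE))
  if (cfg$NP < 4L) stop("NP must be >= 4", call. = FALSE)
  if (cfg$gMax < 1L) stop("gMax must be >= 1", call. = FALSE)
  if (F0 <= 0 || F0 > 1 || CR0 <= 0 || CR0 > 1)
    stop("F0 and CR0 must lie in (0, 1]", call. = FALSE)
  if (val <= 0 || val > 1) stop("val must lie in (0, 1]", call. = FALSE)
  if (ap < 1 || ap > 3) stop("ap must lie in [1, 3]", call. = FALSE)
  if (!is.finite(alphaMin) || !is.finite(alphaMax) || alphaMin >= alphaMax)
    stop("bounds must be finite with alphaMin < alphaMax", call. = FALSE)
  cfg
}

#' Run the evolutionary search
#'
#' Initialises a uniform population inside the bounds and runs the
#' generation loop: per-candidate F/CR sampled around the memories,
#' superior-blend mutation, Levy perturbation of the base individual's
#' trial copy (candidate index > 2 only), whole-vector crossover, greedy
#' selection of the persistent base individual, the global optimum scheme
#' (candidates at least as good as the base individual enter the
#' population), and per-generation Lehmer-mean memory updates. The best
#' candidate ever evaluated is tracked elitistically, so the fitness trace
#' is non-increasing. Deterministic under the config seed.
#'
#' @param objective function: numeric vector of length \code{dim} -> fitness
#'   (lower is better); non-finite values are treated as +Inf.
#' @param dim candidate dimension (for the contour network,
#'   (I+1)H + (H+1)K).
#' @param config a \code{\link{mqdeConfig}}.
#' @return a \linkS4class{MqdeResult}.
#' @export
mqdeOptimize <- function(objective, dim, config = mqdeConfig()) {
  stopifnot(dim >= 1)
  NP <- config$NP
  bounds <- c(config$alphaMin, config$alphaMax)
  .withSeed(config$seed, {
    pop <- matrix(stats::runif(NP * dim, config$alphaMin, config$alphaMax),
                  nrow = NP)
    fpop <- apply(pop, 1L, .safeFitness, objective = objective)
    bestIdx <- which.min(fpop)
    best <- pop[bestIdx, ]; bestFit <- fpop[bestIdx]
    mem <- list(F = config$F0, CR = config$CR0)
    qPop <- pop
    ## the persistent base individual: greedy quantum selection keeps it
    ## monotone; Levy steps only perturb its trial copies
    abase <- best; fabase <- bestFit
    trace <- numeric(config$gMax)
    FTrace <- CRTrace <- numeric(config$gMax)
    for (g in seq_len(config$gMax)) {
      if (config$plainDE) {
        for (i in seq_len(NP)) {
          others <- setdiff(seq_len(NP), i)
          idx <- others[sample.int(length(others), 3L)]
          vec <- .clipBounds(pop[idx[1L], ] +
                               config$F0 * (pop[idx[2L], ] - pop[idx[3L], ]),
                             bounds[1], bounds[2])
          u <- if (stats::runif(1) <= config$CR0) vec else pop[i, ]
          fu <- .safeFitness(objective, u)
          if (fu <= fpop[i]) {
            pop[i, ] <- u
            fpop[i] <- fu
          }
          if (fpop[i] < bestFit) {
            bestFit <- fpop[i]; best <- pop[i, ]
          }
        }
        trace[g] <- bestFit
        FTrace[g] <- config$F0; CRTrace[g] <- config$CR0
        next
      }
      SF <- numeric(0); SCR <- numeric(0)
      lambda <- lambdaSchedule(g, config$gMax)
      for (i in seq_len(NP)) {
        Fi <- .sampleF(mem$F)
        CRi <- .sampleCR(mem$CR)
        mut <- mutateSuperior(pop, fpop, i, Fi, lambda,
                              config$superiorFrac, bounds)
        cs <- csPerturb(abase, mut$vec, g, config$ap,
                        applyLevy = i > 2L, bounds = bounds)
        fTrialBase <- if (i > 2L) .safeFitness(objective, cs$base)
                      else fabase
        fNvec <- .safeFitness(objective, cs$nvec)
        fVec <- .safeFitness(objective, mut$vec)
        sel <- crossoverSelect(cs$nvec, cs$base, qPop[i, ], CRi,
                               objective, fNvec = fNvec,
                               fBase = fTrialBase)
        if (sel$fBase <= fabase) {        # quantum selection on the base
          abase <- sel$base; fabase <- sel$fBase
          if (sel$success) {
            SF <- c(SF, Fi); SCR <- c(SCR, CRi)
          }
        }
        gos <- globalOptimumScheme(pop[i, ], sel$q, qPop[i, ], cs$nvec,
                                   fVec, fpop[i], fNvec, fabase)
        pop[i, ] <- gos$alpha
        fpop[i] <- gos$fAlpha
        qPop[i, ] <- gos$q
        for (cand in list(list(sel$u, sel$fu), list(mut$vec, fVec),
                          list(cs$nvec, fNvec))) {
          if (cand[[2]] < bestFit) {
            bestFit <- cand[[2]]; best <- cand[[1]]
          }
        }
        if (fpop[i] < bestFit) {
          bestFit <- fpop[i]; best <- pop[i, ]
        }
      }
      mem <- updateMemory(mem, SF, SCR, config$val)
      trace[g] <- bestFit
      FTrace[g] <- mem$F; CRTrace[g] <- mem$CR
    }
    new("MqdeResult", best = best, bestFitness = bestFit,
        fitnessTrace = trace, FTrace = FTrace, CRTrace = CRTrace)
  })
}
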