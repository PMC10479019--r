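test_that("schedule, Levy step and Lehmer mean match hand arithmetic", {
  expect_equal(lambdaSchedule(10, 10), 0)
  expect_equal(lambdaSchedule(5, 10), 0.25)
  lam <- vapply(1:10, lambdaSchedule, numeric(1), gMax = 10)
  expect_true(all(diff(lam) < 0))
  expect_error(lambdaSchedule(0, 10), "g must")

  expect_equal(levyStep(1, 2.5), 1)
  expect_equal(levyStep(2, 2), 0.25)
  expect_true(all(diff(vapply(1:20, levyStep, numeric(1), ap = 1.5)) < 0))
  expect_error(levyStep(3, 0.5), "ap")

  expect_equal(lehmerMean(0.7), 0.7)
  expect_equal(lehmerMean(c(0.2, 0.4)), 0.2 / 0.6 * 1)
  expect_equal(lehmerMean(c(0.2, 0.4)), (0.04 + 0.16) / 0.6)
  set.seed(1)
  for (i in 1:10) {
    v <- runif(5, 0.01, 1)
    expect_gte(lehmerMean(v), mean(v))
  }
  expect_error(lehmerMean(numeric(0)), "no successful")
})

test_that("superior mutation honours the lambda limits and hand arithmetic", {
  pop <- matrix(c(0, 1, 2, 3), ncol = 1)   # scalar candidates
  fit <- c(0, 1, 2, 3)                     # candidate 1 is best
  bounds <- c(-10, 10)
  ## lambda = 1: base = alpha_i1 (DE/rand/1 limit)
  set.seed(3)
  m1 <- mutateSuperior(pop, fit, 1, F = 0.5, lambda = 1,
                       superiorFrac = 0.25, bounds)
  set.seed(3)
  others <- setdiff(1:4, 1)
  idx <- others[sample.int(3, 3)]
  sample.int(1, 1)                          # superior draw consumed
  expect_equal(m1$base, pop[idx[1], ])
  expect_equal(m1$vec, pop[idx[1], ] + 0.5 * (pop[idx[2], ] - pop[idx[3], ]))
  ## lambda = 0: base = the superior individual exactly (top1 = best)
  set.seed(4)
  m0 <- mutateSuperior(pop, fit, 2, F = 0.5, lambda = 0,
                       superiorFrac = 0.25, bounds)
  expect_equal(m0$base, pop[1, ])
  expect_error(mutateSuperior(pop[1:3, , drop = FALSE], fit[1:3], 1, 0.5, 1,
                              0.25, bounds), "too small")
})

test_that("cuckoo perturbation endpoints and scalar case check out", {
  ## r is the single uniform draw; force it via the seed
  forceR <- function(target, tol = 5e-3) {
    for (s in 1:20000) {
      set.seed(s)
      if (abs(runif(1) - target) < tol) return(s)
    }
    stop("no seed found")
  }
  sLow <- forceR(0); sHigh <- forceR(1)
  set.seed(sLow)
  low <- csPerturb(1, 3, g = 2, ap = 1, applyLevy = FALSE)
  expect_equal(low$nvec, 3, tolerance = 2e-2)        # r ~ 0 -> vec
  set.seed(sHigh)
  high <- csPerturb(1, 3, g = 2, ap = 1, applyLevy = FALSE)
  expect_equal(high$nvec, 1, tolerance = 2e-2)       # r ~ 1 -> base
  ## scalar arithmetic with the Levy branch: base = 1 + 2^-1 = 1.5
  sMid <- forceR(0.5, tol = 1e-4)
  set.seed(sMid)
  mid <- csPerturb(1, 3, g = 2, ap = 1, applyLevy = TRUE)
  expect_equal(mid$base, 1.5)
  expect_equal(mid$nvec, 0.5 * 1.5 + 0.5 * 3, tolerance = 1e-3)
})

test_that("crossover and selection follow the greedy printed rules", {
  sphere <- function(a) sum(a^2)
  ## CR = 1 forces the mutant; 0.1 beats 1 on the sphere
  set.seed(1)
  sel <- crossoverSelect(nvec = 0.1, base = 1, q = 1, CR = 1, sphere)
  expect_equal(sel$u, 0.1)
  expect_true(sel$crossed)
  expect_equal(sel$base, 0.1)
  expect_true(sel$success)
  ## a worse trial leaves the base untouched
  set.seed(1)
  sel2 <- crossoverSelect(nvec = 5, base = 1, q = 1, CR = 1, sphere)
  expect_equal(sel2$base, 1)
  expect_false(sel2$success)
})

test_that("global optimum scheme applies its two update rules", {
  st <- globalOptimumScheme(alpha = 2, q = 9, qPrev = 7, nvec = 1,
                            fVec = 4, fAlpha = 4, fNvec = 1, fBaseNew = 3)
  expect_equal(st$q, 7)          # f(vec) == f(alpha): q carried over
  expect_equal(st$alpha, 1)      # f(nvec) <= f(base'): alpha replaced
  expect_true(st$replaced)
  st2 <- globalOptimumScheme(alpha = 2, q = 9, qPrev = 7, nvec = 1,
                             fVec = 5, fAlpha = 4, fNvec = 10, fBaseNew = 3)
  expect_equal(st2$q, 9)
  expect_equal(st2$alpha, 2)     # no-op branch
  expect_false(st2$replaced)
})

test_that("memory update keeps values in (0, 1] and skips empty lists", {
  mem <- list(F = 0.4, CR = 0.8)
  expect_identical(updateMemory(mem, numeric(0), numeric(0), 0.5), mem)
  set.seed(2)
  for (i in 1:50) {
    m <- updateMemory(list(F = runif(1), CR = runif(1)),
                      runif(3), runif(3), runif(1))
    expect_true(m$F > 0 && m$F <= 1 && m$CR > 0 && m$CR <= 1)
  }
  ## val = 1 with a forced rand ~ 1 recovers the Lehmer mean
  for (s in 1:5000) {
    set.seed(s)
    if (runif(1) > 0.999) { seed <- s; break }
  }
  set.seed(seed)
  m <- updateMemory(list(F = 0.9, CR = 0.9), SF = 0.5, SCR = 0.5, val = 1)
  expect_equal(m$F, 0.5, tolerance = 2e-3)
})

test_that("the candidate dimension formula matches the network layout", {
  expect_equal((1 + 1) * 10 + (10 + 1) * 2, 42)
  expect_equal(nParams(toyParams(H = 10)), 42)
  expect_error(decodeParams(rep(0, 41), 10), "does not match")
})

test_that("the search respects bounds, trace monotonicity and determinism", {
  cfg <- mqdeConfig(NP = 12L, gMax = 15L, alphaMin = -2, alphaMax = 2,
                    seed = 5)
  r1 <- mqdeOptimize(function(a) sum((a - 1)^2), 4, cfg)
  r2 <- mqdeOptimize(function(a) sum((a - 1)^2), 4, cfg)
  expect_identical(r1@best, r2@best)
  expect_identical(r1@fitnessTrace, r2@fitnessTrace)
  expect_true(all(diff(r1@fitnessTrace) <= 1e-12))
  expect_true(all(abs(r1@best) <= 2))
  ## gMax = 1: exactly one generation of traces
  r3 <- mqdeOptimize(function(a) sum(a^2), 3,
                     mqdeConfig(NP = 8L, gMax = 1L, seed = 1))
  expect_length(r3@fitnessTrace, 1)
})

test_that("non-finite objective values are rejected as +Inf, not fatal", {
  bad <- function(a) if (abs(a[1]) < 0.5) NaN else sum(a^2)
  expect_message(
    r <- mqdeOptimize(bad, 2, mqdeConfig(NP = 8L, gMax = 5L, seed = 2)),
    "non-finite")
  expect_true(is.finite(r@bestFitness))
})

test_that("plainDE mode reproduces an independent DE/rand/1 bit for bit", {
  sphere <- function(a) sum(a^2)
  for (s in c(1, 2)) {
    cfg <- mqdeConfig(NP = 10L, gMax = 20L, F0 = 0.6, CR0 = 0.9,
                      alphaMin = -4, alphaMax = 4, seed = s, plainDE = TRUE)
    r <- mqdeOptimize(sphere, 3, cfg)
    ref <- referencePlainDE(sphere, 3, 10, 20, 0.6, 0.9, -4, 4, seed = s)
    expect_identical(r@bestFitness, ref$bestFit)
    expect_identical(r@fitnessTrace, ref$trace)
  }
})
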