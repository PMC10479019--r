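## Independent reference implementations used as oracles. These deliberately
## re-derive the algorithms from their textbook definitions rather than
## calling package internals.

## classic fixed-bandwidth mean shift: iterate every point to its mode with
## Gaussian-profile weights L(u)^2 = exp(-u^2)
referenceMeanShift <- function(points, h, tol = 1e-8, maxIters = 5000) {
  modes <- points
  for (i in seq_len(nrow(points))) {
    p <- points[i, ]
    for (it in seq_len(maxIters)) {
      w <- exp(-((points[, 1] - p[1])^2 + (points[, 2] - p[2])^2) / h^2)
      pNew <- c(sum(points[, 1] * w), sum(points[, 2] * w)) / sum(w)
      if (sqrt(sum((pNew - p)^2)) < tol) break
      p <- pNew
    }
    modes[i, ] <- p
  }
  modes
}

## deduplicate converged modes
uniqueModes <- function(modes, tol) {
  out <- modes[1, , drop = FALSE]
  for (i in seq_len(nrow(modes))[-1]) {
    d <- sqrt((out[, 1] - modes[i, 1])^2 + (out[, 2] - modes[i, 2])^2)
    if (all(d > tol)) out <- rbind(out, modes[i, ])
  }
  out
}

## plain DE/rand/1 with whole-vector crossover and greedy selection, the
## documented RNG draw order of the package's plainDE mode: per candidate
## draw 3 distinct indices (sample.int over the others), one uniform for
## the crossover decision
referencePlainDE <- function(objective, dim, NP, gMax, F, CR, lo, hi,
                             seed) {
  set.seed(seed)
  pop <- matrix(runif(NP * dim, lo, hi), nrow = NP)
  fpop <- apply(pop, 1, objective)
  bestFit <- min(fpop)
  trace <- numeric(gMax)
  for (g in seq_len(gMax)) {
    for (i in seq_len(NP)) {
      others <- setdiff(seq_len(NP), i)
      idx <- others[sample.int(length(others), 3L)]
      vec <- pop[idx[1L], ] + F * (pop[idx[2L], ] - pop[idx[3L], ])
      vec <- pmin(hi, pmax(lo, vec))
      u <- if (runif(1) <= CR) vec else pop[i, ]
      fu <- objective(u)
      if (fu <= fpop[i]) {
        pop[i, ] <- u
        fpop[i] <- fu
      }
      if (fpop[i] < bestFit) bestFit <- fpop[i]
    }
    trace[g] <- bestFit
  }
  list(bestFit = bestFit, trace = trace, pop = pop)
}

## plain momentum backpropagation trainer (integer order, no
## regularization), written against the same step convention:
## v <- mom v - lr * gradScale * dE/dw ; w <- w + v. The gradient itself
## is re-derived here by explicit per-sample loops, independent of the
## package's vectorised backpropagation.
referenceBPNNGradient <- function(w, H, D, normalizer) {
  p <- decodeParams(w, H)
  n <- nrow(D)
  grad <- numeric(length(w))
  tx <- normalizer$scale[1] * D$x + normalizer$offset[1]
  ty <- normalizer$scale[2] * D$y + normalizer$offset[2]
  for (s in seq_len(n)) {
    t <- D$t[s]
    h <- 1 / (1 + exp(-(p@w1 * t + p@a)))
    u <- as.numeric(h %*% p@w2) - p@b
    O <- ifelse(u <= 0, exp(u) - 0.5, u + 0.5)
    cn <- (2 * O + 1) / (2 * O + 2)
    dcd <- (cn - c(tx[s], ty[s])) / n
    dO <- 1 / (2 * (O + 1)^2)
    du <- ifelse(u <= 0, exp(u), 1)
    delta <- dcd * dO * du                    # length K
    gw2 <- outer(h, delta)
    gb <- -delta
    dh <- as.numeric(p@w2 %*% delta)
    dz <- dh * h * (1 - h)
    grad <- grad + c(dz * t, dz, as.numeric(gw2), gb)
  }
  grad
}

referenceBPNN <- function(paramsInit, D, normalizer, lr, momentum, epochs,
                          gradScale = 24, ownGradient = TRUE) {
  H <- paramsInit@H
  w <- flattenParams(paramsInit)
  v <- numeric(length(w))
  for (ep in seq_len(epochs)) {
    g <- if (ownGradient) referenceBPNNGradient(w, H, D, normalizer)
         else modelGradient(decodeParams(w, H), D, normalizer, l2 = 0)
    v <- momentum * v - lr * (gradScale * g)
    w <- w + v
  }
  decodeParams(w, H)
}

## brute-force nearest distance from p to a closed polygon, by dense
## sampling of every segment
bruteForcePolygonDistance <- function(vertices, p, samplesPerUnit = NULL,
                                      nTotal = 1e4) {
  v <- rbind(vertices, vertices[1, , drop = FALSE])
  segs <- nrow(v) - 1
  perSeg <- max(2, ceiling(nTotal / segs))
  dmin <- Inf
  for (i in seq_len(segs)) {
    s <- seq(0, 1, length.out = perSeg)
    px <- v[i, 1] + s * (v[i + 1, 1] - v[i, 1])
    py <- v[i, 2] + s * (v[i + 1, 2] - v[i, 2])
    dmin <- min(dmin, sqrt((px - p[1])^2 + (py - p[2])^2))
  }
  dmin
}

## small deterministic network for fixture use
toyParams <- function(H = 3, seed = 1) {
  set.seed(seed)
  networkParams(w1 = runif(H, -2, 2), a = runif(H, -1, 1),
                w2 = matrix(runif(H * 2, -2, 2), H, 2),
                b = runif(2, -1, 1))
}

## handcrafted contour model that traces a genuine loop: sharp sigmoids
## switch x up at t = 0.5 and y up at 0.25 / down at 0.75
loopModel <- function(nSamples = 1000L) {
  p <- networkParams(w1 = c(30, 30, 30), a = c(-15, -7.5, -22.5),
                     w2 = matrix(c(2, 0, 0, 0, 2, -2), 3, 2),
                     b = c(1, 0))
  new("ContourModel", params = p,
      normalizer = list(scale = c(0.002, 0.003), offset = c(0.2, 0.25)),
      nSamples = as.integer(nSamples))
}

## a circle model fitted once per session through the package's own
## search + training path; reused by recovery and smoothness tests
fittedCircleModel <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    set.seed(31)
    tg <- sort(runif(60))
    D <- data.frame(t = tg, x = 100 + 50 * cos(2 * pi * tg),
                    y = 100 + 50 * sin(2 * pi * tg))
    lo <- D[D$t < 0.05, ]; lo$t <- lo$t + 1
    Dfit <- rbind(D, lo)
    nm <- coordNormalizer(cbind(D$x, D$y))
    obj <- function(a) modelError(decodeParams(a, 10), Dfit, nm, l2 = 1e-4)
    s <- mqdeOptimize(obj, 42, mqdeConfig(gMax = 100L, seed = 2))
    fit <- trainNetwork(decodeParams(s@best, 10), Dfit,
                        trainConfig(epochs = 3000L), nm)
    cache <<- new("ContourModel", params = fit$bestParams, normalizer = nm,
                  nSamples = 1000L)
    cache
  }
})

## small test phantom shared by several files (kept small for speed)
testPhantom <- function(seed = 1, fourierCoeffs = list(c(0.1, 3, 0.5)),
                        width = 200, height = 150, baseRadius = 50) {
  generatePhantom(phantomSpec(width = width, height = height,
                              fourierCoeffs = fourierCoeffs,
                              baseRadius = baseRadius, seed = seed))
}
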