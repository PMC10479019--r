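test_that("forward pass matches hand arithmetic", {
  ## zero network: hidden 0.5, u = -0, O = g(0) = 0.5
  z <- networkParams(w1 = rep(0, 3), a = rep(0, 3),
                     w2 = matrix(0, 3, 2), b = rep(0, 2))
  expect_equal(networkForward(z, c(0, 0.5, 1)),
               matrix(0.5, 3, 2), ignore_attr = TRUE)
  ## H = 1 worked example: u = 0.5 - 1 = -0.5, O = exp(-0.5) - 0.5
  p <- networkParams(1, 0, matrix(c(1, 1), 1, 2), c(1, 1))
  expect_equal(as.numeric(networkForward(p, 0)),
               rep(exp(-0.5) - 0.5, 2), tolerance = 1e-12)
  ## output activation is continuous and strictly increasing
  u <- seq(-4, 4, by = 0.01)
  g <- ifelse(u <= 0, exp(u) - 0.5, u + 0.5)
  expect_true(all(diff(g) > 0))
  expect_lt(abs((exp(-1e-9) - 0.5) - (1e-9 + 0.5)), 1e-6)
})

test_that("model error matches the one-term oracle and is non-negative", {
  p <- toyParams(H = 2, seed = 3)
  D <- data.frame(t = 0.3, x = 10, y = 20)
  nm <- list(scale = c(1, 1), offset = c(0, 0))
  O <- networkForward(p, 0.3)
  cn <- (2 * O + 1) / (2 * O + 2)
  manual <- 0.5 * ((cn[1] - 10)^2 + (cn[2] - 20)^2)
  expect_equal(modelError(p, D, nm, l2 = 0), manual, tolerance = 1e-12)
  ## perfect fit gives zero error
  targets <- cn
  D2 <- data.frame(t = 0.3, x = targets[1], y = targets[2])
  expect_equal(modelError(p, D2, nm, l2 = 0), 0)
  expect_error(modelError(p, D[0, ], nm), "empty")
})

test_that("analytic gradients match central finite differences", {
  set.seed(10)
  for (k in 1:5) {
    H <- sample(2:5, 1)
    w <- runif(2 * H + (H + 1) * 2, -1.5, 1.5)
    p <- decodeParams(w, H)
    n <- sample(4:10, 1)
    D <- data.frame(t = runif(n), x = runif(n, 0, 100),
                    y = runif(n, 0, 100))
    nm <- coordNormalizer(cbind(D$x, D$y))
    g <- modelGradient(p, D, nm, l2 = 1e-4)
    fd <- vapply(seq_along(w), function(i) {
      e <- rep(0, length(w)); e[i] <- 1e-6
      (modelError(decodeParams(w + e, H), D, nm, 1e-4) -
       modelError(decodeParams(w - e, H), D, nm, 1e-4)) / 2e-6
    }, numeric(1))
    expect_lt(max(abs(g - fd) / pmax(abs(fd), 1e-6)), 1e-5)
  }
})

test_that("Caputo scaling reduces to the ordinary gradient at nu = 1", {
  g <- c(2, -1, 0.5)
  w <- c(1, 2, 3); w0 <- c(0, 2, 5)
  expect_identical(caputoGradient(g, w, w0, nu = 1), g)
  ## nu = 0.5, |w - w0| = 1: factor 1/gamma(1.5)
  expect_equal(caputoGradient(2, 1, 0, nu = 0.5, delta = 0),
               2 / gamma(1.5), tolerance = 1e-12)
  expect_error(caputoGradient(g, w, w0, nu = 1.5), "nu")
})

test_that("training fixed points and the frozen-lr contract hold", {
  p <- toyParams(H = 4, seed = 2)
  set.seed(2)
  tgrid <- sort(runif(20))
  O <- networkForward(p, tgrid)
  cn <- (2 * O + 1) / (2 * O + 2)
  nm <- list(scale = c(1, 1), offset = c(0, 0))
  D <- data.frame(t = tgrid, x = cn[, 1], y = cn[, 2])
  ## teacher targets, student = teacher: error stays at its minimum
  fit <- trainNetwork(p, D, trainConfig(epochs = 50, l2 = 0), nm)
  e0 <- modelError(p, D, nm, l2 = 0)
  expect_lte(tail(fit$trace$trainMse, 1), e0 + 1e-12)
  ## lr = 0 freezes the parameters
  frozen <- trainNetwork(p, D, trainConfig(lr = 0, epochs = 10), nm)
  expect_identical(flattenParams(frozen$params), flattenParams(p))
})

test_that("training a jittered circle cuts the error by at least 10x", {
  set.seed(20)
  tgrid <- sort(runif(24))
  D <- data.frame(t = tgrid,
                  x = 100 + 60 * cos(2 * pi * tgrid) + rnorm(24, 0, 1),
                  y = 80 + 60 * sin(2 * pi * tgrid) + rnorm(24, 0, 1))
  nm <- coordNormalizer(cbind(D$x, D$y))
  obj <- function(a) modelError(decodeParams(a, 10), D, nm, l2 = 1e-4)
  s <- mqdeOptimize(obj, 42, mqdeConfig(gMax = 30L, seed = 1))
  p0 <- decodeParams(s@best, 10)
  e0 <- modelError(p0, D, nm, l2 = 0)
  fit <- trainNetwork(p0, D, trainConfig(), nm)
  expect_lt(tail(fit$trace$trainMse, 1), 0.1 * e0)
})

test_that("model error is invariant under hidden-unit permutation", {
  p <- toyParams(H = 5, seed = 6)
  set.seed(6)
  D <- data.frame(t = runif(8), x = runif(8, 0, 50), y = runif(8, 0, 50))
  nm <- coordNormalizer(cbind(D$x, D$y))
  perm <- c(3, 1, 5, 2, 4)
  q <- networkParams(p@w1[perm], p@a[perm], p@w2[perm, ], p@b)
  expect_equal(modelError(p, D, nm), modelError(q, D, nm),
               tolerance = 1e-12)
})

test_that("windowed error decreases on noiseless representable targets", {
  teacher <- toyParams(H = 6, seed = 8)
  set.seed(8)
  tgrid <- sort(runif(30))
  O <- networkForward(teacher, tgrid)
  cn <- (2 * O + 1) / (2 * O + 2)
  nm <- list(scale = c(1, 1), offset = c(0, 0))
  D <- data.frame(t = tgrid, x = cn[, 1], y = cn[, 2])
  set.seed(9)
  student <- networkParams(teacher@w1 + rnorm(6, 0, 0.3),
                           teacher@a + rnorm(6, 0, 0.3),
                           teacher@w2 + rnorm(12, 0, 0.3),
                           teacher@b + rnorm(2, 0, 0.3))
  fit <- trainNetwork(student, D, trainConfig(epochs = 500, l2 = 0), nm)
  win <- vapply(seq(1, 451, by = 50), function(i)
    mean(fit$trace$trainMse[i:(i + 49)]), numeric(1))
  expect_true(all(diff(win) < 1e-12))
})
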