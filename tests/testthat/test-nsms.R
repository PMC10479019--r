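test_that("channel mapping matches direct arithmetic on a 3x3 toy image", {
  img <- matrix(c(0L, 128L, 255L,
                  128L, 128L, 128L,
                  255L, 128L, 0L), 3, 3, byrow = TRUE)
  ch <- mapChannels(img)
  expect_equal(ch@Tc, (img - 0) / 255)
  expect_equal(ch@Fc, (255 - img) / 255)
  expect_true(all(abs(ch@Tc + ch@Fc - 1) < 1e-12))
  expect_true(all(ch@Ic >= 0 & ch@Ic <= 1))
  ## endpoints: brightest pixel Tc = 1, Fc = 0
  expect_equal(ch@Tc[img == 255L], c(1, 1))
  expect_equal(ch@Fc[img == 255L], c(0, 0))
})

test_that("flat regions have zero indeterminacy and constant images error", {
  img <- matrix(100L, 12, 12)
  img[1, 1] <- 200L
  ch <- mapChannels(img)
  expect_equal(ch@Ic[7, 7], 0)    # far from the lone bright pixel
  expect_error(mapChannels(matrix(5L, 4, 4)), "degenerate intensity")
})

test_that("indeterminacy filter passes constants and reproduces the stencil", {
  flat <- matrix(77L, 10, 10)
  flat[3, 3] <- 200L              # give the image a gradient for Ic
  ch <- mapChannels(flat)
  ch@Tc <- matrix(0.4, 10, 10)    # constant signal
  out <- indeterminacyFilter(ch, a = 0, b = 1, m = 5)
  expect_equal(out@TcFiltered, matrix(0.4, 10, 10), tolerance = 1e-12)

  ## single bright pixel, constant sigma: filtered value = sampled Gaussian
  ch2 <- ch
  Tc <- matrix(0, 11, 11); Tc[6, 6] <- 1
  ch2@Tc <- Tc; ch2@Ic <- matrix(0, 11, 11); ch2@Fc <- 1 - Tc
  out2 <- indeterminacyFilter(ch2, a = 0, b = 1, m = 5)
  offs <- expand.grid(du = -2:2, dv = -2:2)
  w <- exp(-(offs$du^2 + offs$dv^2) / 2)
  expect_equal(out2@TcFiltered[6, 6], max(w) / sum(w), tolerance = 1e-12)
  expect_equal(out2@TcFiltered[6, 7], exp(-0.5) / sum(w), tolerance = 1e-12)
})

test_that("wider sigma smooths a noisy field more", {
  set.seed(9)
  img <- matrix(as.integer(pmin(255, pmax(0, rnorm(900, 128, 40)))), 30, 30)
  ch <- mapChannels(img)
  v1 <- var(as.vector(indeterminacyFilter(ch, a = 0, b = 0.5)@TcFiltered))
  v2 <- var(as.vector(indeterminacyFilter(ch, a = 0, b = 2)@TcFiltered))
  expect_lt(v2, v1)
})

test_that("adaptive bandwidth follows h = Ic_avg * range(Tc') * scale", {
  ch <- new("NeutrosophicChannels", Tc = matrix(0.5, 5, 5),
            Ic = matrix(0.5, 5, 5), Fc = matrix(0.5, 5, 5),
            TcFiltered = matrix(c(0, rep(0.5, 23), 1), 5, 5))
  pts <- cbind(c(1, 2), c(1, 2))
  expect_equal(adaptiveBandwidth(pts, ch, sH = 40), 20)   # 0.5 * 1 * 40
  ## zero indeterminacy clamps to hMin
  ch@Ic <- matrix(0, 5, 5)
  expect_message(h <- adaptiveBandwidth(pts, ch, sH = 40, hMin = 2),
                 "clamped")
  expect_equal(h, 2)
})

test_that("mean shift vector obeys symmetry and the three-term oracle", {
  pts <- rbind(c(5, 5))
  expect_equal(meanShiftVector(c(5, 5), pts, 2), c(0, 0))
  sym <- rbind(c(1, 0), c(-1, 0))
  expect_equal(meanShiftVector(c(0, 0), sym, 1), c(0, 0))
  ## p = (0,0), points (1,0), (3,0), h = 1, weights exp(-d^2)
  w <- exp(-c(1, 9))
  m <- meanShiftVector(c(0, 0), rbind(c(1, 0), c(3, 0)), 1)
  expect_equal(m, c(sum(c(1, 3) * w) / sum(w), 0), tolerance = 1e-12)
  ## underflow stagnation
  far <- meanShiftVector(c(0, 0), rbind(c(1e4, 0)), 1)
  expect_equal(as.numeric(far), c(0, 0))
  expect_true(isTRUE(attr(far, "stagnant")))
})

test_that("three separated blobs yield three modes near the sample means", {
  hits <- 0
  for (s in 1:10) {
    set.seed(s)
    centers <- rbind(c(30, 30), c(110, 30), c(70, 100))
    pts <- do.call(rbind, lapply(1:3, function(k)
      cbind(rnorm(8, centers[k, 1], 2), rnorm(8, centers[k, 2], 2))))
    cl <- nsmsCluster(pts, seed = s, fixedBandwidth = 15)
    if (nrow(clusterModes(cl)) == 3) {
      means <- rbind(colMeans(pts[1:8, ]), colMeans(pts[9:16, ]),
                     colMeans(pts[17:24, ]))
      dd <- sapply(seq_len(3), function(k)
        min(sqrt((clusterModes(cl)[, 1] - means[k, 1])^2 +
                 (clusterModes(cl)[, 2] - means[k, 2])^2)))
      if (all(dd < 1.5)) hits <- hits + 1
    }
  }
  expect_gte(hits, 9)
})

test_that("uniform indeterminacy reduces NSMS to fixed-bandwidth mean shift", {
  set.seed(11)
  centers <- rbind(c(20, 20), c(80, 20), c(50, 70))
  pts <- do.call(rbind, lapply(1:3, function(k)
    cbind(rnorm(6, centers[k, 1], 2), rnorm(6, centers[k, 2], 2))))
  ## constant Ic = 0.5, range(Tc') = 1 -> h = 0.5 * sH
  ch <- new("NeutrosophicChannels", Tc = matrix(0.5, 100, 100),
            Ic = matrix(0.5, 100, 100), Fc = matrix(0.5, 100, 100),
            TcFiltered = matrix(c(0, rep(0.5, 9998), 1), 100, 100))
  h <- 0.5 * 24
  cl <- nsmsCluster(pts, ch, sH = 24, seed = 0, tol = 1e-10)
  ref <- uniqueModes(referenceMeanShift(pts, h, tol = 1e-12), tol = h / 2)
  expect_equal(nrow(clusterModes(cl)), nrow(ref))
  for (k in seq_len(nrow(ref))) {
    d <- min(sqrt((clusterModes(cl)[, 1] - ref[k, 1])^2 +
                  (clusterModes(cl)[, 2] - ref[k, 2])^2))
    expect_lt(d, 1e-6)
  }
})

test_that("every point gets exactly one label and a single blob one mode", {
  set.seed(12)
  pts <- cbind(rnorm(15, 40, 1.5), rnorm(15, 40, 1.5))
  cl <- nsmsCluster(pts, seed = 1, fixedBandwidth = 10)
  expect_equal(nrow(clusterModes(cl)), 1)
  expect_identical(sort(unique(clusterLabels(cl))), 1L)
  expect_length(clusterLabels(cl), 15)
})
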