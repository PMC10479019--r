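test_that("shuffled square corners become an ordered unit square", {
  sq <- rbind(c(1, 1), c(0, 0), c(0, 1), c(1, 0))
  curve <- buildCurve(sq)
  expect_equal(curve@totalLength, 4)
  expect_equal(nrow(curveVertices(curve)), 4)
  ## consecutive vertices are 1 apart
  expect_equal(curve@segLengths, rep(1, 4))
})

test_that("modes on a circle are angle-sorted and perimeter converges", {
  set.seed(2)
  for (k in c(12, 48, 192)) {
    theta <- sort(runif(k, 0, 2 * pi))
    pts <- cbind(10 + 5 * cos(theta), -3 + 5 * sin(theta))
    curve <- buildCurve(pts[sample(k), ])
    ## ordering traverses the circle monotonically: every wrapped angular
    ## step is a forward step smaller than a half turn
    v <- curveVertices(curve)
    ang <- atan2(v[, 2] + 3, v[, 1] - 10)
    wd <- diff(ang) %% (2 * pi)
    expect_true(all(wd > 0 & wd < pi))
    if (k == 192)
      expect_lt(abs(curve@totalLength - 2 * pi * 5) / (2 * pi * 5), 0.01)
  }
})

test_that("degenerate vertex sets are rejected", {
  expect_error(buildCurve(rbind(c(0, 0), c(1, 1))), "insufficient")
  expect_error(buildCurve(rbind(c(0, 0), c(1, 1), c(2, 2))), "degenerate")
  ## duplicates are merged first
  expect_error(buildCurve(rbind(c(0, 0), c(0, 0), c(1, 1))), "insufficient")
  tri <- buildCurve(rbind(c(0, 0), c(4, 0), c(0, 3)))
  expect_equal(abs(polygonArea(curveVertices(tri))), 6)
})

test_that("projection returns the stated foot on the unit square", {
  curve <- buildCurve(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  p <- projectPoint(curve, c(0.5, -1))
  expect_equal(p$t, 0.125)
  expect_equal(p$dist, 1)
  expect_equal(p$element$type, "segment")
  expect_equal(p$foot, c(0.5, 0), ignore_attr = TRUE)
  ## vertex hit
  v0 <- projectPoint(curve, curveVertices(curve)[1, ])
  expect_equal(v0$t, 0)
  expect_equal(v0$dist, 0)
  expect_equal(v0$element, list(type = "vertex", index = 0L))
})

test_that("projection distance matches brute force and beats every vertex", {
  set.seed(5)
  theta <- sort(runif(9, 0, 2 * pi))
  poly <- cbind(50 + 20 * cos(theta), 40 + 20 * sin(theta))
  curve <- buildCurve(poly)
  v <- curveVertices(curve)
  for (i in 1:40) {
    p <- runif(2, 0, 100)
    pr <- projectPoint(curve, p)
    bf <- bruteForcePolygonDistance(v, p, nTotal = 1e4)
    expect_lt(abs(pr$dist - bf), 1e-3)   # brute force grid resolution
    expect_gte(pr$dist - 1e-6, 0)
    expect_true(all(pr$dist <= sqrt((v[, 1] - p[1])^2 +
                                    (v[, 2] - p[2])^2) + 1e-12))
  }
})

test_that("t is invariant under joint rigid translation", {
  set.seed(6)
  poly <- cbind(c(0, 4, 5, 2, -1), c(0, -1, 3, 5, 3))
  curve <- buildCurve(poly)
  shift <- c(13.7, -8.2)
  curve2 <- buildCurve(sweep(poly, 2, shift, "+"))
  for (i in 1:20) {
    p <- runif(2, -2, 6)
    expect_equal(projectPoint(curve, p)$t,
                 projectPoint(curve2, p + shift)$t, tolerance = 1e-12)
  }
})

test_that("data sequences are sorted permutations with order-stable ties", {
  curve <- buildCurve(rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10)))
  ## on-curve points in arc order
  on <- rbind(c(2, 0), c(8, 0), c(10, 5), c(5, 10), c(0, 3))
  D <- buildDataSequence(curve, on)
  expect_true(all(diff(D$t) > 0))
  expect_true(all(D$dist < 1e-12))
  ## reversed input gives the same sorted sequence
  D2 <- buildDataSequence(curve, on[5:1, ])
  expect_equal(D2$t, D$t)
  expect_equal(D2[, c("x", "y")], D[, c("x", "y")], ignore_attr = TRUE)
  ## random cloud: permutation property
  set.seed(7)
  cloud <- cbind(runif(30, -5, 15), runif(30, -5, 15))
  D3 <- buildDataSequence(curve, cloud)
  expect_equal(nrow(D3), 30)
  expect_setequal(paste(D3$x, D3$y), paste(cloud[, 1], cloud[, 2]))
  expect_true(!is.unsorted(D3$t))
})
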