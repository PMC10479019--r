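## Neutrosophic-set mean shift: T/I/F channel mapping, indeterminacy-driven
## adaptive filtering and bandwidth, and the point-clustering loop that
## discovers the principal-curve vertices.

## symmetric (edge-including) reflection of 1-based indices into [1, n]
.reflectIndex <- function(idx, n) {
  idx[idx < 1L] <- 1L - idx[idx < 1L]
  idx[idx > n] <- 2L * n + 1L - idx[idx > n]
  idx
}

## shift a matrix by (dy, dx) with reflect padding: result[r, c] =
## m[r + dy, c + dx]
.shiftReflect <- function(m, dy, dx) {
  r <- .reflectIndex(seq_len(nrow(m)) + dy, nrow(m))
  c <- .reflectIndex(seq_len(ncol(m)) + dx, ncol(m))
  m[r, c, drop = FALSE]
}

## Sobel gradient magnitude with reflect padding
.sobelMagnitude <- function(image) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), nrow = 3, byrow = TRUE)
  gx <- matrix(0, nrow(image), ncol(image))
  gy <- matrix(0, nrow(image), ncol(image))
  for (dy in -1:1) for (dx in -1:1) {
    wx <- kx[dy + 2, dx + 2]           # horizontal derivative weight
    wy <- kx[dx + 2, dy + 2]           # transposed kernel for vertical
    if (wx != 0 || wy != 0) {
      sh <- .shiftReflect(image, dy, dx)
      if (wx != 0) gx <- gx + wx * sh
      if (wy != 0) gy <- gy + wy * sh
    }
  }
  sqrt(gx^2 + gy^2)
}

#' Map an image to its neutrosophic channels
#'
#' Computes the true/indeterminate/false memberships of every pixel:
#' Tc = (g - g_min)/(g_max - g_min), Fc = (g_max - g)/(g_max - g_min)
#' (so Tc + Fc = 1), and Ic as the min-max normalised Sobel gradient
#' magnitude (reflect padding). Bright pixels are "true", dark pixels
#' "false", and edges/noise "indeterminate".
#'
#' @param image integer matrix, gray levels 0-255, at least two distinct
#'   levels.
#' @return a \linkS4class{NeutrosophicChannels} (TcFiltered still empty).
#' @export
mapChannels <- function(image) {
  .assertImage(image)
  g <- image
  gmin <- min(g); gmax <- max(g)
  if (gmax == gmin)
    stop("degenerate intensity range: constant image", call. = FALSE)
  Tc <- (g - gmin) / (gmax - gmin)
  Fc <- (gmax - g) / (gmax - gmin)
  Gd <- .sobelMagnitude(g)
  rng <- max(Gd) - min(Gd)
  Ic <- if (rng == 0) matrix(0, nrow(g), ncol(g)) else (Gd - min(Gd)) / rng
  new("NeutrosophicChannels", Tc = Tc, Ic = Ic, Fc = Fc,
      TcFiltered = matrix(numeric(0), 0, 0))
}

#' Adaptive indeterminacy filter of the true channel
#'
#' Smooths Tc with a Gaussian kernel whose standard deviation follows the
#' local indeterminacy, sigma_I = a * Ic + b: noisy/edgy regions are
#' smoothed more aggressively. The kernel is evaluated on the m x m window
#' centred at each pixel and normalised to unit sum, with reflect padding,
#' so constant signals pass through unchanged.
#'
#' @param channels a \linkS4class{NeutrosophicChannels}.
#' @param a,b sigma_I = a * Ic + b; a >= 0, b > 0 required so sigma_I > 0.
#' @param m odd window size >= 3.
#' @return the input channels with the \code{TcFiltered} slot filled.
#' @export
indeterminacyFilter <- function(channels, a = 10, b = 0.25, m = 5L) {
  stopifnot(is(channels, "NeutrosophicChannels"))
  m <- as.integer(m)
  if (m < 3L || m %% 2L == 0L) stop("m must be odd and >= 3", call. = FALSE)
  if (a < 0 || b <= 0)
    stop("need a >= 0 and b > 0 so sigma_I is positive everywhere",
         call. = FALSE)
  sigma <- a * channels@Ic + b
  if (min(sigma) <= 0) stop("non-positive sigma_I", call. = FALSE)
  hw <- (m - 1L) %/% 2L
  num <- matrix(0, nrow(sigma), ncol(sigma))
  den <- matrix(0, nrow(sigma), ncol(sigma))
  s2 <- 2 * sigma^2
  for (du in -hw:hw) for (dv in -hw:hw) {
    w <- exp(-(du^2 + dv^2) / s2)     # 1/(2 pi sigma^2) cancels in the sum
    num <- num + w * .shiftReflect(channels@Tc, dv, du)
    den <- den + w
  }
  channels@TcFiltered <- num / den
  channels
}

#' Adaptive mean-shift bandwidth from the uncertain domain
#'
#' h = mean(Ic at the cluster's current points) * range(Tc'), scaled to
#' pixels by \code{sH} and clamped below at \code{hMin}. Ic is sampled at
#' the nearest pixel of each point.
#'
#' @param points n x 2 matrix, the current cluster's points.
#' @param channels \linkS4class{NeutrosophicChannels} with
#'   \code{TcFiltered} computed.
#' @param sH pixel scale bridging dimensionless channel units to pixels
#'   (default 40 px).
#' @param hMin lower clamp in pixels (default 2).
#' @return bandwidth h in pixels, always > 0.
#' @export
adaptiveBandwidth <- function(points, channels, sH = 40, hMin = 2) {
  .assertPoints(points)
  if (!length(channels@TcFiltered))
    stop("TcFiltered not computed; run indeterminacyFilter first",
         call. = FALSE)
  h <- nrow(channels@Ic); w <- ncol(channels@Ic)
  rows <- pmin(pmax(round(points[, 2]) + 1L, 1L), h)
  cols <- pmin(pmax(round(points[, 1]) + 1L, 1L), w)
  icAvg <- mean(channels@Ic[cbind(rows, cols)])
  raw <- icAvg * (max(channels@TcFiltered) - min(channels@TcFiltered))
  bw <- raw * sH
  if (bw <= hMin) {
    message("bandwidth ", signif(bw, 4), " clamped to hMin = ", hMin)
    bw <- hMin
  }
  bw
}

#' Mean shift vector with Gaussian profile
#'
#' m(p) = sum_i p_i L(||p - p_i||/h)^2 / sum_i L(||p - p_i||/h)^2 - p with
#' profile L(u) = exp(-u^2/2). If every weight underflows to zero the shift
#' is (0, 0) and the result carries attribute \code{stagnant = TRUE}.
#'
#' @param p length-2 numeric, the current position.
#' @param points n x 2 matrix of data points.
#' @param h bandwidth > 0.
#' @return length-2 shift vector (dx, dy).
#' @export
meanShiftVector <- function(p, points, h) {
  .assertPoints(points)
  if (h <= 0) stop("h must be > 0", call. = FALSE)
  d2 <- (points[, 1] - p[1])^2 + (points[, 2] - p[2])^2
  w <- exp(-d2 / h^2)               # L(u)^2 = exp(-u^2)
  sw <- sum(w)
  if (sw == 0) {
    out <- c(0, 0)
    attr(out, "stagnant") <- TRUE
    return(out)
  }
  c(sum(points[, 1] * w), sum(points[, 2] * w)) / sw - p
}

#' Neutrosophic-set mean shift clustering of prior points
#'
#' Repeatedly picks a random ungrouped point as seed, computes the adaptive
#' bandwidth from the current cluster in the uncertain domain, runs the
#' mean-shift iteration to a mode, re-estimates the bandwidth from the
#' points captured by the mode, and iterates until the mode is stable. All
#' ungrouped points within h of the stable mode join the cluster; the loop
#' ends when every point is labelled. Modes closer than
#' \code{mergeTolFactor * h} are merged, weighted by member count. With
#' \code{fixedBandwidth} set the procedure degenerates to classic
#' fixed-bandwidth mean shift (the MSC ablation).
#'
#' @param points n x 2 matrix (n >= 3).
#' @param channels filtered \linkS4class{NeutrosophicChannels}; may be
#'   \code{NULL} when \code{fixedBandwidth} is given.
#' @param sH,hMin see \code{\link{adaptiveBandwidth}}.
#' @param tol convergence tolerance on the shift norm, px.
#' @param maxIters cap on mean-shift iterations per mode.
#' @param mergeTolFactor modes closer than this fraction of h are merged.
#' @param seed RNG seed for the ungrouped-point picking order.
#' @param fixedBandwidth if non-NULL, use this constant bandwidth and ignore
#'   the channels.
#' @return a \linkS4class{ClusterResult}.
#' @export
nsmsCluster <- function(points, channels = NULL, sH = 40, hMin = 2,
                        tol = 1e-3, maxIters = 200L, mergeTolFactor = 0.5,
                        seed = 0L, fixedBandwidth = NULL) {
  .assertPoints(points)
  n <- nrow(points)
  if (n < 3) stop("need at least 3 points", call. = FALSE)
  bw <- function(members) {
    if (!is.null(fixedBandwidth)) fixedBandwidth
    else adaptiveBandwidth(points[members, , drop = FALSE], channels,
                           sH = sH, hMin = hMin)
  }
  labels <- integer(n)
  modes <- list(); finalH <- numeric(0); trace <- numeric(0)
  .withSeed(seed, {
    while (any(labels == 0L)) {
      ungrouped <- which(labels == 0L)
      seedIdx <- if (length(ungrouped) == 1L) ungrouped
                 else ungrouped[sample.int(length(ungrouped), 1L)]
      h <- bw(seedIdx)
      trace <- c(trace, h)
      p <- points[seedIdx, ]
      pPrev <- c(Inf, Inf)
      for (outer in seq_len(25L)) {
        for (it in seq_len(maxIters)) {
          mv <- meanShiftVector(p, points, h)
          p <- p + mv
          if (sqrt(sum(mv^2)) < tol) break
        }
        if (it == maxIters)
          message("mean shift hit maxIters without converging")
        members <- which(sqrt((points[, 1] - p[1])^2 +
                              (points[, 2] - p[2])^2) <= h)
        if (!length(members)) members <- seedIdx
        hNew <- bw(members)
        if (sqrt(sum((p - pPrev)^2)) < tol && abs(hNew - h) < tol) break
        pPrev <- p
        h <- hNew
        trace <- c(trace, h)
      }
      id <- length(modes) + 1L
      capture <- which(labels == 0L &
                       sqrt((points[, 1] - p[1])^2 +
                            (points[, 2] - p[2])^2) <= h)
      labels[unique(c(seedIdx, capture))] <- id
      modes[[id]] <- p
      finalH[id] <- h
    }
  })
  modeMat <- do.call(rbind, modes)
  ## merge modes closer than mergeTolFactor * h (member-count weighted)
  repeat {
    k <- nrow(modeMat)
    if (k < 2L) break
    merged <- FALSE
    for (i in seq_len(k - 1L)) {
      for (j in seq(i + 1L, k)) {
        d <- sqrt(sum((modeMat[i, ] - modeMat[j, ])^2))
        if (d < mergeTolFactor * max(finalH[i], finalH[j])) {
          ni <- sum(labels == i); nj <- sum(labels == j)
          modeMat[i, ] <- (ni * modeMat[i, ] + nj * modeMat[j, ]) / (ni + nj)
          finalH[i] <- max(finalH[i], finalH[j])
          labels[labels == j] <- i
          labels[labels > j] <- labels[labels > j] - 1L
          modeMat <- modeMat[-j, , drop = FALSE]
          finalH <- finalH[-j]
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  colnames(modeMat) <- c("x", "y")
  new("ClusterResult", labels = labels, modes = modeMat,
      bandwidthTrace = trace)
}
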