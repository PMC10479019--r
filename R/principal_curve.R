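#' Build the closed polygonal principal curve from cluster modes
#'
#' Orders the modes counter-clockwise by polar angle about their centroid
#' (starting at the smallest angle), merges duplicates closer than 1e-6 px,
#' and closes the polygon. Valid for star-shaped organ outlines, where the
#' angular order is the boundary order.
#'
#' @param modes m x 2 matrix of vertex candidates (>= 3 non-collinear
#'   points).
#' @return a \linkS4class{PolygonalCurve}.
#' @export
buildCurve <- function(modes) {
  .assertPoints(modes, "modes")
  ## merge near-duplicates (< 1e-6 apart)
  keep <- rep(TRUE, nrow(modes))
  for (i in seq_len(nrow(modes))) {
    if (!keep[i]) next
    for (j in seq_len(i - 1L)) {
      if (keep[j] && sqrt(sum((modes[i, ] - modes[j, ])^2)) < 1e-6) {
        keep[i] <- FALSE
        break
      }
    }
  }
  modes <- modes[keep, , drop = FALSE]
  if (nrow(modes) < 3) stop("insufficient vertices (need >= 3)", call. = FALSE)
  centroid <- colMeans(modes)
  ang <- atan2(modes[, 2] - centroid[2], modes[, 1] - centroid[1])
  ord <- order(ang)
  v <- modes[ord, , drop = FALSE]
  area <- polygonArea(v)
  if (abs(area) < 1e-9) stop("degenerate curve: collinear modes",
                             call. = FALSE)
  segs <- rbind(v[-1L, , drop = FALSE], v[1L, , drop = FALSE]) - v
  segLen <- sqrt(rowSums(segs^2))
  if (any(segLen == 0)) stop("degenerate curve: zero-length segment",
                             call. = FALSE)
  colnames(v) <- c("x", "y")
  new("PolygonalCurve", vertices = v, closed = TRUE, segLengths = segLen,
      cumLength = c(0, cumsum(segLen))[seq_along(segLen)],
      totalLength = sum(segLen))
}

#' Project a point onto the polygonal curve
#'
#' Scans every vertex and segment and returns the globally nearest location,
#' its normalised arc-length parameter t in [0, 1) measured from the first
#' vertex, and which element (vertex or segment region) the point falls in.
#' Ties are resolved toward the lower-index element, counting elements in
#' curve order v0, s0, v1, s1, ...
#'
#' @param curve a \linkS4class{PolygonalCurve}.
#' @param p length-2 numeric point.
#' @return list with \code{t}, \code{dist}, \code{element} (list with
#'   \code{type} "vertex"/"segment" and 0-based \code{index}) and the
#'   projection \code{foot} (length-2).
#' @export
projectPoint <- function(curve, p) {
  stopifnot(is(curve, "PolygonalCurve"))
  v <- curve@vertices
  k <- nrow(v)
  best <- list(dist = Inf)
  consider <- function(dist, t, type, index, foot) {
    if (dist < best$dist - 1e-12)
      best <<- list(dist = dist, t = t %% 1, element = list(type = type,
                    index = index), foot = foot)
  }
  for (i in seq_len(k)) {
    a <- v[i, ]
    bIdx <- if (i == k) 1L else i + 1L
    b <- v[bIdx, ]
    ## vertex i first (lower element index than segment i)
    dv <- sqrt(sum((p - a)^2))
    consider(dv, curve@cumLength[i] / curve@totalLength, "vertex", i - 1L, a)
    ## then the open interior of segment i
    ab <- b - a
    len2 <- sum(ab^2)
    s <- sum((p - a) * ab) / len2
    if (s > 0 && s < 1) {
      foot <- a + s * ab
      ds <- sqrt(sum((p - foot)^2))
      consider(ds, (curve@cumLength[i] + s * curve@segLengths[i]) /
                 curve@totalLength, "segment", i - 1L, foot)
    }
  }
  best
}

#' Build the ordered data sequence of projections
#'
#' Projects every point onto the curve and sorts the records by projection
#' index t, with ties broken by input order. This ordered sequence is the
#' training set of the contour network: t is the input, the point
#' coordinates are the targets.
#'
#' @param curve a \linkS4class{PolygonalCurve}.
#' @param points n x 2 matrix.
#' @return data.frame with columns t, x, y, element (e.g. "segment:2"),
#'   dist; one row per input point, sorted ascending by t.
#' @export
buildDataSequence <- function(curve, points) {
  .assertPoints(points)
  if (!nrow(points)) stop("points must be nonempty", call. = FALSE)
  proj <- lapply(seq_len(nrow(points)), function(i)
    projectPoint(curve, points[i, ]))
  df <- data.frame(
    t = vapply(proj, `[[`, numeric(1), "t"),
    x = points[, 1], y = points[, 2],
    element = vapply(proj, function(pr)
      paste0(pr$element$type, ":", pr$element$index), character(1)),
    dist = vapply(proj, `[[`, numeric(1), "dist"))
  df <- df[order(df$t, seq_len(nrow(df))), , drop = FALSE]
  rownames(df) <- NULL
  df
}
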