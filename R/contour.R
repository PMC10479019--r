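#' Evaluate the closed-form contour formula at parameter t
#'
#' The contour is the image of t under the coordinate map
#' c_j(t) = (2 O_j(t) + 1) / (2 O_j(t) + 2), where O is the network forward
#' pass, followed by the stored denormalisation to pixel coordinates. This is
#' the same code path the training loss uses, so the exported formula is
#' literally the trained model.
#'
#' @param model a \linkS4class{ContourModel}.
#' @param t numeric vector of curve parameters in [0, 1].
#' @return length(t) x 2 matrix of pixel coordinates (x, y).
#' @export
contourPoint <- function(model, t) {
  stopifnot(is(model, "ContourModel"))
  if (any(t < -1e-12 | t > 1 + 1e-12))
    stop("t must lie in [0, 1]", call. = FALSE)
  O <- networkForward(model@params, t)          # n x 2 raw outputs
  cn <- (2 * O + 1) / (2 * O + 2)               # normalised coordinates
  nm <- model@normalizer
  px <- sweep(sweep(cn, 2L, nm$offset, "-"), 2L, nm$scale, "/")
  colnames(px) <- c("x", "y")
  px
}

#' Sample the closed contour as a polyline
#'
#' Evaluates the contour formula on the uniform grid t = k/n for
#' k = 0..n-1 and appends the t = 0 point so the polyline is explicitly
#' closed (first row equals last row).
#'
#' @param model a \linkS4class{ContourModel}.
#' @param nSamples number of distinct samples; default the model's setting.
#' @return (nSamples + 1) x 2 matrix of pixel coordinates.
#' @export
extractContour <- function(model, nSamples = model@nSamples) {
  nSamples <- as.integer(nSamples)
  if (nSamples < 16L) stop("nSamples must be >= 16", call. = FALSE)
  t <- (seq_len(nSamples) - 1L) / nSamples
  pts <- contourPoint(model, t)
  poly <- rbind(pts, pts[1L, , drop = FALSE])
  if (abs(polygonArea(poly)) < 1)
    stop("collapsed contour (area below 1 px^2)", call. = FALSE)
  poly
}

#' Signed area of a closed polyline (shoelace formula)
#'
#' @param polyline n x 2 matrix; the first point need not be repeated.
#' @return signed area in square pixels (positive for counter-clockwise
#'   orientation in x-right/y-down coordinates).
#' @export
polygonArea <- function(polyline) {
  .assertPoints(polyline, "polyline")
  p <- polyline
  if (!all(p[1L, ] == p[nrow(p), ])) p <- rbind(p, p[1L, ])
  x <- p[, 1L]; y <- p[, 2L]
  n <- nrow(p)
  sum(x[-n] * y[-1L] - x[-1L] * y[-n]) / 2
}

#' Rasterize a closed polyline to a binary mask
#'
#' Even-odd (parity) polygon fill sampled at pixel centers, which sit at
#' integer coordinates (x = column, y = row, 0-based). Pixel centers lying
#' exactly on an edge count as inside. Pixels outside the image are ignored.
#'
#' @param polyline closed n x 2 polyline (first point must equal the last).
#' @param width,height image dimensions in pixels.
#' @return integer 0/1 matrix with dim = c(height, width).
#' @export
rasterizeContour <- function(polyline, width, height) {
  .assertPoints(polyline, "polyline")
  if (!all(polyline[1L, ] == polyline[nrow(polyline), ]))
    stop("open polyline: first point must equal last point", call. = FALSE)
  p <- polyline
  x1 <- p[-nrow(p), 1L]; y1 <- p[-nrow(p), 2L]
  x2 <- p[-1L, 1L];      y2 <- p[-1L, 2L]
  keep <- !(x1 == x2 & y1 == y2)
  x1 <- x1[keep]; y1 <- y1[keep]; x2 <- x2[keep]; y2 <- y2[keep]
  if (!length(x1)) stop("degenerate polyline", call. = FALSE)
  mask <- matrix(0L, nrow = height, ncol = width)
  ylo <- pmin(y1, y2); yhi <- pmax(y1, y2)
  for (row in seq_len(height)) {
    yc <- row - 1                      # pixel-center y of this scanline
    cross <- which(ylo <= yc & yc < yhi)   # half-open rule at vertices
    if (length(cross)) {
      xi <- x1[cross] + (yc - y1[cross]) *
        (x2[cross] - x1[cross]) / (y2[cross] - y1[cross])
      xi <- sort(xi)
      for (k in seq(1L, length(xi) - 1L, by = 2L)) {
        lo <- ceiling(xi[k] - 1e-9); hi <- floor(xi[k + 1L] + 1e-9)
        lo <- max(lo, 0); hi <- min(hi, width - 1)
        if (lo <= hi) mask[row, (lo:hi) + 1L] <- 1L
      }
    }
  }
  ## pixel centers exactly on an edge are inside by convention
  for (e in seq_along(x1)) {
    xs <- seq(ceiling(min(x1[e], x2[e]) - 1e-9),
              floor(max(x1[e], x2[e]) + 1e-9))
    ys <- seq(ceiling(min(y1[e], y2[e]) - 1e-9),
              floor(max(y1[e], y2[e]) + 1e-9))
    xs <- xs[xs >= 0 & xs < width]; ys <- ys[ys >= 0 & ys < height]
    if (!length(xs) || !length(ys) || length(xs) * length(ys) > 4096) next
    g <- expand.grid(x = xs, y = ys)
    d <- .pointSegmentDistance(g$x, g$y, x1[e], y1[e], x2[e], y2[e])
    on <- d < 1e-9
    if (any(on)) mask[cbind(g$y[on] + 1L, g$x[on] + 1L)] <- 1L
  }
  mask
}

.pointSegmentDistance <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx * dx + dy * dy
  s <- if (len2 == 0) rep(0, length(px)) else
    pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / len2))
  sqrt((px - (x1 + s * dx))^2 + (py - (y1 + s * dy))^2)
}

#' Render the trained contour model as an explicit formula
#'
#' Writes the closed-form parametric contour as a plain-text R expression in
#' the single variable \code{t}: sigmoid hidden units, the piecewise
#' exponential/linear output activation, the (2 O + 1)/(2 O + 2) coordinate
#' map and the denormalisation, all with the trained numbers inlined. The
#' string evaluates (via \code{eval(parse(...))}) to the same coordinates as
#' \code{\link{contourPoint}}.
#'
#' @param model a \linkS4class{ContourModel}.
#' @return character vector of length 2 (x(t) and y(t) expressions), with a
#'   \code{names} attribute c("x", "y").
#' @export
contourFormula <- function(model) {
  p <- model@params
  num <- function(v) sprintf("%.17g", v)
  hidden <- vapply(seq_len(p@H), function(i)
    sprintf("(1/(1+exp(-(%s*t+%s))))", num(p@w1[i]), num(p@a[i])),
    character(1))
  out <- character(2)
  for (j in 1:2) {
    terms <- paste(sprintf("%s*%s", hidden, vapply(p@w2[, j], num,
                                                   character(1))),
                   collapse = "+")
    u <- sprintf("((%s)-%s)", terms, num(p@b[j]))
    O <- sprintf("(ifelse(%s<=0, exp(%s)-0.5, %s+0.5))", u, u, u)
    cn <- sprintf("((2*%s+1)/(2*%s+2))", O, O)
    out[j] <- sprintf("((%s-%s)/%s)", cn, num(model@normalizer$offset[j]),
                      num(model@normalizer$scale[j]))
  }
  names(out) <- c("x", "y")
  out
}

#' Save and load a trained contour model as JSON
#'
#' Serialises the network weights, thresholds, layer sizes, coordinate
#' normalizer and sampling density; the round trip restores the model
#' exactly (coefficients are written at full double precision).
#'
#' @param model a \linkS4class{ContourModel}.
#' @param path JSON file path.
#' @return \code{saveContourModel} returns \code{path} invisibly;
#'   \code{loadContourModel} returns the restored
#'   \linkS4class{ContourModel}.
#' @export
saveContourModel <- function(model, path) {
  stopifnot(is(model, "ContourModel"))
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite is required for model serialisation", call. = FALSE)
  p <- model@params
  obj <- list(w1 = p@w1, a = p@a, w2 = as.numeric(p@w2), b = p@b,
              H = p@H, K = p@K,
              normalizer = model@normalizer, nSamples = model@nSamples)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname saveContourModel
#' @export
loadContourModel <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite is required for model serialisation", call. = FALSE)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- networkParams(obj$w1, obj$a,
                          matrix(obj$w2, nrow = obj$H, ncol = obj$K),
                          obj$b)
  new("ContourModel", params = params,
      normalizer = list(scale = as.numeric(obj$normalizer$scale),
                        offset = as.numeric(obj$normalizer$offset)),
      nSamples = as.integer(obj$nSamples))
}

#' Evaluate an exported contour formula
#'
#' @param formula character vector from \code{\link{contourFormula}}.
#' @param t numeric vector of parameters.
#' @return length(t) x 2 matrix of pixel coordinates.
#' @export
evalContourFormula <- function(formula, t) {
  env <- list2env(list(t = t), parent = baseenv())
  cbind(x = eval(parse(text = formula[["x"]]), env),
        y = eval(parse(text = formula[["y"]]), env))
}
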