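#' @import methods
NULL

## Coordinate convention used throughout the package:
## x = column, y = row, both 0-based, pixel centers at integer coordinates.
## An image is a base integer matrix with dim = c(height, width), so pixel
## (x, y) lives at image[y + 1, x + 1]. Point sets are n x 2 matrices with
## columns x, y.

#' Neutrosophic channel stack of a grayscale image
#'
#' Per-pixel true/indeterminate/false memberships of an 8-bit image, plus the
#' indeterminacy-filtered true channel. \code{Tc} is the min-max normalised
#' intensity, \code{Fc = 1 - Tc}, and \code{Ic} is the min-max normalised
#' Sobel gradient magnitude, so bright pixels score high on \code{Tc}, dark
#' pixels on \code{Fc}, and edge/noise pixels on \code{Ic}.
#'
#' @slot Tc,Ic,Fc numeric matrices in [0, 1], same shape as the image.
#' @slot TcFiltered the true channel after adaptive indeterminacy filtering;
#'   a 0 x 0 matrix until \code{\link{indeterminacyFilter}} has run.
#' @export
setClass("NeutrosophicChannels",
  representation(Tc = "matrix", Ic = "matrix", Fc = "matrix",
                 TcFiltered = "matrix"),
  validity = function(object) {
    msg <- character()
    if (!all(dim(object@Tc) == dim(object@Ic)) ||
        !all(dim(object@Tc) == dim(object@Fc)))
      msg <- c(msg, "Tc, Ic, Fc must share dimensions")
    rng <- function(m) length(m) && (min(m) < -1e-9 || max(m) > 1 + 1e-9)
    if (rng(object@Tc) || rng(object@Ic) || rng(object@Fc))
      msg <- c(msg, "channel values must lie in [0, 1]")
    if (max(abs(object@Tc + object@Fc - 1)) > 1e-9)
      msg <- c(msg, "Tc + Fc must equal 1 at every pixel")
    if (length(msg)) msg else TRUE
  })

#' Closed polygonal principal curve
#'
#' An ordered closed chain of vertices with its arc-length bookkeeping. The
#' curve parameter t in [0, 1) is normalised arc length measured from the
#' first vertex.
#'
#' @slot vertices k x 2 matrix (x, y), ordered counter-clockwise by polar
#'   angle about the vertex centroid.
#' @slot closed logical; always \code{TRUE} for organ outlines.
#' @slot segLengths,cumLength numeric; per-segment Euclidean lengths and the
#'   cumulative arc length before each segment.
#' @slot totalLength total perimeter, strictly positive.
#' @export
setClass("PolygonalCurve",
  representation(vertices = "matrix", closed = "logical",
                 segLengths = "numeric", cumLength = "numeric",
                 totalLength = "numeric"),
  validity = function(object) {
    msg <- character()
    k <- nrow(object@vertices)
    if (object@closed && k < 3) msg <- c(msg, "closed curve needs >= 3 vertices")
    if (length(object@segLengths) && any(object@segLengths <= 0))
      msg <- c(msg, "zero-length segment")
    if (length(object@totalLength) &&
        abs(object@totalLength - sum(object@segLengths)) > 1e-9)
      msg <- c(msg, "totalLength must equal the segment sum")
    if (length(msg)) msg else TRUE
  })

#' Mean-shift clustering result
#'
#' @slot labels integer cluster id per input point (1-based, references rows
#'   of \code{modes}).
#' @slot modes m x 2 matrix of converged mode locations.
#' @slot bandwidthTrace bandwidths (pixels) used while each cluster grew.
#' @export
setClass("ClusterResult",
  representation(labels = "integer", modes = "matrix",
                 bandwidthTrace = "numeric"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@modes) < 1) msg <- c(msg, "at least one mode required")
    if (length(object@labels) &&
        (min(object@labels) < 1 || max(object@labels) > nrow(object@modes)))
      msg <- c(msg, "labels must reference existing modes")
    if (length(msg)) msg else TRUE
  })

#' Parameters of the three-layer contour network
#'
#' Weights and thresholds of the 1-input, H-hidden, 2-output network whose
#' outputs parameterise the contour. These numbers double as the coefficients
#' of the exported closed-form contour formula.
#'
#' @slot w1 hidden input weights (length H).
#' @slot a hidden thresholds (length H).
#' @slot w2 H x K output weights.
#' @slot b output thresholds (length K).
#' @slot H,K integer layer sizes; K is 2 (x and y coordinate units).
#' @export
setClass("NetworkParams",
  representation(w1 = "numeric", a = "numeric", w2 = "matrix", b = "numeric",
                 H = "integer", K = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@H < 1L) msg <- c(msg, "H must be >= 1")
    if (object@K != 2L) msg <- c(msg, "K must be 2")
    if (length(object@w1) != object@H || length(object@a) != object@H)
      msg <- c(msg, "w1 and a must have length H")
    if (!all(dim(object@w2) == c(object@H, object@K)))
      msg <- c(msg, "w2 must be H x K")
    if (length(object@b) != object@K) msg <- c(msg, "b must have length K")
    if (!all(is.finite(c(object@w1, object@a, object@w2, object@b))))
      msg <- c(msg, "parameters must be finite")
    if (length(msg)) msg else TRUE
  })

#' Trained parametric contour model
#'
#' Couples trained \linkS4class{NetworkParams} with the affine coordinate
#' normalizer so that evaluating the closed-form formula at t in [0, 1]
#' yields pixel coordinates.
#'
#' @slot params trained \linkS4class{NetworkParams}.
#' @slot normalizer list with numeric \code{scale} and \code{offset} (length
#'   2 each, x then y): normalised = scale * pixel + offset.
#' @slot nSamples default sampling density of \code{\link{extractContour}}.
#' @export
setClass("ContourModel",
  representation(params = "NetworkParams", normalizer = "list",
                 nSamples = "integer"),
  validity = function(object) {
    msg <- character()
    nm <- object@normalizer
    if (!all(c("scale", "offset") %in% names(nm)) ||
        length(nm$scale) != 2L || length(nm$offset) != 2L)
      msg <- c(msg, "normalizer needs scale and offset of length 2")
    else if (any(nm$scale == 0)) msg <- c(msg, "normalizer must be invertible")
    if (object@nSamples < 16L) msg <- c(msg, "nSamples must be >= 16")
    if (length(msg)) msg else TRUE
  })

#' Synthetic ultrasound phantom
#'
#' A speckled star-shaped test image with known ground truth: the image, its
#' binary ground-truth mask, a dense polyline tracing the true boundary, and
#' jittered prior points emulating operator clicks near that boundary.
#'
#' @slot image integer matrix, gray levels 0-255.
#' @slot gtMask binary 0/1 integer matrix, the even-odd fill of gtContour.
#' @slot gtContour dense n x 2 polyline of true boundary points.
#' @slot priorPoints n x 2 matrix of jittered boundary samples.
#' @slot spec the generating \code{\link{phantomSpec}} list.
#' @export
setClass("Phantom",
  representation(image = "matrix", gtMask = "matrix", gtContour = "matrix",
                 priorPoints = "matrix", spec = "list"),
  validity = function(object) {
    msg <- character()
    if (!all(dim(object@image) == dim(object@gtMask)))
      msg <- c(msg, "image and gtMask must share dimensions")
    if (length(object@gtMask) && !all(object@gtMask %in% c(0L, 1L)))
      msg <- c(msg, "gtMask must be binary")
    if (ncol(object@gtContour) != 2L || ncol(object@priorPoints) != 2L)
      msg <- c(msg, "contour and prior points must be n x 2")
    if (length(msg)) msg else TRUE
  })

#' Result of the evolutionary weight search
#'
#' @slot best numeric vector, the best candidate found (flattened network
#'   parameters).
#' @slot bestFitness its objective value.
#' @slot fitnessTrace per-generation best fitness; non-increasing.
#' @slot FTrace,CRTrace per-generation memory values of the mutation factor
#'   and crossover rate.
#' @export
setClass("MqdeResult",
  representation(best = "numeric", bestFitness = "numeric",
                 fitnessTrace = "numeric", FTrace = "numeric",
                 CRTrace = "numeric"),
  validity = function(object) {
    if (length(object@fitnessTrace) > 1 &&
        any(diff(object@fitnessTrace) > 1e-12))
      "fitnessTrace must be non-increasing" else TRUE
  })

setMethod("show", "NeutrosophicChannels", function(object) {
  d <- dim(object@Tc)
  cat(sprintf("NeutrosophicChannels %d x %d (filtered: %s)\n",
              d[2], d[1], if (length(object@TcFiltered)) "yes" else "no"))
})

setMethod("show", "PolygonalCurve", function(object) {
  cat(sprintf("PolygonalCurve: %d vertices, %s, perimeter %.2f px\n",
              nrow(object@vertices),
              if (object@closed) "closed" else "open", object@totalLength))
})

setMethod("show", "ClusterResult", function(object) {
  cat(sprintf("ClusterResult: %d points in %d clusters\n",
              length(object@labels), nrow(object@modes)))
})

setMethod("show", "NetworkParams", function(object) {
  cat(sprintf("NetworkParams: 1-%d-%d network, %d parameters\n",
              object@H, object@K, nParams(object)))
})

setMethod("show", "ContourModel", function(object) {
  cat(sprintf("ContourModel: H = %d, %d contour samples\n",
              object@params@H, object@nSamples))
})

setMethod("show", "Phantom", function(object) {
  d <- dim(object@image)
  cat(sprintf("Phantom %d x %d px, %d prior points, area %d px\n",
              d[2], d[1], nrow(object@priorPoints), sum(object@gtMask)))
})

setMethod("show", "MqdeResult", function(object) {
  cat(sprintf("MqdeResult: %d generations, best fitness %.4g\n",
              length(object@fitnessTrace), object@bestFitness))
})

#' Accessors for the core classes
#'
#' \code{curveVertices}, \code{clusterModes}, \code{clusterLabels},
#' \code{phantomImage}, \code{phantomMask}, \code{phantomContour},
#' \code{phantomPriors} and \code{nParams} expose slots without reaching into
#' the objects.
#'
#' @param x the object.
#' @return the corresponding slot value; \code{nParams} returns the total
#'   parameter count (1+1)H + (H+1)K.
#' @name accessors
NULL

#' @rdname accessors
#' @export
curveVertices <- function(x) x@vertices

#' @rdname accessors
#' @export
clusterModes <- function(x) x@modes

#' @rdname accessors
#' @export
clusterLabels <- function(x) x@labels

#' @rdname accessors
#' @export
phantomImage <- function(x) x@image

#' @rdname accessors
#' @export
phantomMask <- function(x) x@gtMask

#' @rdname accessors
#' @export
phantomContour <- function(x) x@gtContour

#' @rdname accessors
#' @export
phantomPriors <- function(x) x@priorPoints

#' @rdname accessors
#' @export
nParams <- function(x) (1L + 1L) * x@H + (x@H + 1L) * x@K
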