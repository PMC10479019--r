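## Three-layer fractional-order backpropagation network: projection index t
## in, two coordinate outputs. Sigmoid hidden layer, shifted-ELU output
## activation, Caputo-type fractional gradient descent with momentum and L2
## regularization.

#' Construct network parameters
#'
#' @param w1 hidden input weights (length H).
#' @param a hidden thresholds (length H).
#' @param w2 H x K output weight matrix.
#' @param b output thresholds (length K = 2).
#' @return a \linkS4class{NetworkParams}.
#' @export
networkParams <- function(w1, a, w2, b) {
  w2 <- as.matrix(w2)
  new("NetworkParams", w1 = as.numeric(w1), a = as.numeric(a), w2 = w2,
      b = as.numeric(b), H = length(w1), K = ncol(w2))
}

#' Flatten network parameters to a candidate vector / decode one back
#'
#' Order: w1, a, w2 (column-major), b — a vector of length
#' (1+1)H + (H+1)K, the candidate dimension of the evolutionary search.
#'
#' @param params a \linkS4class{NetworkParams}.
#' @param alpha numeric vector of that length.
#' @param H,K layer sizes for decoding.
#' @return \code{flattenParams}: numeric vector; \code{decodeParams}: a
#'   \linkS4class{NetworkParams}.
#' @export
flattenParams <- function(params) {
  c(params@w1, params@a, as.numeric(params@w2), params@b)
}

#' @rdname flattenParams
#' @export
decodeParams <- function(alpha, H = 10L, K = 2L) {
  H <- as.integer(H); K <- as.integer(K)
  need <- 2L * H + (H + 1L) * K
  if (length(alpha) != need)
    stop("candidate length ", length(alpha), " does not match (1+1)H+(H+1)K = ",
         need, call. = FALSE)
  w1 <- alpha[seq_len(H)]
  a <- alpha[H + seq_len(H)]
  w2 <- matrix(alpha[2L * H + seq_len(H * K)], nrow = H, ncol = K)
  b <- alpha[2L * H + H * K + seq_len(K)]
  networkParams(w1, a, w2, b)
}

## shifted-ELU output activation: continuous, strictly increasing, and equal
## to the exponential branch exp(u) - 1/2 for u <= 0
.gOut <- function(u) ifelse(u <= 0, exp(u) - 0.5, u + 0.5)
.gOutPrime <- function(u) ifelse(u <= 0, exp(u), 1)
.sigmoid <- function(z) 1 / (1 + exp(-z))

#' Forward pass of the contour network
#'
#' Hidden units h_i = sigmoid(w1_i t + a_i); output pre-activations
#' u_j = sum_i h_i w2_ij - b_j; raw outputs O_j = g(u_j) with the
#' shifted-ELU g(u) = exp(u) - 1/2 for u <= 0 and u + 1/2 otherwise, so
#' O_j lies in (-1/2, Inf).
#'
#' @param params a \linkS4class{NetworkParams}.
#' @param t numeric vector of inputs in [0, 1].
#' @return length(t) x K matrix of raw outputs.
#' @export
networkForward <- function(params, t) {
  stopifnot(is(params, "NetworkParams"))
  validObject(params)
  h <- .sigmoid(outer(params@w1, t) + params@a)   # H x n
  u <- sweep(crossprod(h, params@w2), 2L, params@b, "-")  # n x K
  .gOut(u)
}

#' Min-max coordinate normalizer
#'
#' Affine per-axis map taking the data-sequence coordinates into
#' [margin, 1 - margin] (default [0.3, 0.7]), the well-conditioned middle
#' of the output coordinate map (2O+1)/(2O+2): targets near 1 would need
#' raw outputs O of 10 or more, where the map's gradient all but vanishes.
#' normalised = scale * pixel + offset.
#'
#' @param points n x 2 matrix of pixel coordinates.
#' @param margin margin inside (0, 0.5).
#' @return list with numeric \code{scale} and \code{offset}, length 2 each.
#' @export
coordNormalizer <- function(points, margin = 0.3) {
  .assertPoints(points)
  lo <- apply(points, 2L, min)
  hi <- apply(points, 2L, max)
  scale <- ifelse(hi > lo, (1 - 2 * margin) / (hi - lo), 1)
  offset <- ifelse(hi > lo, margin - scale * lo, 0.5 - lo)
  list(scale = as.numeric(scale), offset = as.numeric(offset))
}

.normalizeTargets <- function(D, normalizer) {
  cbind(normalizer$scale[1] * D$x + normalizer$offset[1],
        normalizer$scale[2] * D$y + normalizer$offset[2])
}

#' Global model error of the network on a data sequence
#'
#' E = (1/2N) sum_n sum_j (c_j(t_n) - c*_nj)^2 + (l2/2) ||theta||^2, where
#' c_j(t) = (2 O_j + 1)/(2 O_j + 2) is the coordinate map composed into the
#' loss and c* are the normalised target coordinates. This is the objective
#' the evolutionary search minimises and the quantity gradient descent
#' trains on.
#'
#' @param params a \linkS4class{NetworkParams}.
#' @param D data.frame from \code{\link{buildDataSequence}} (columns t, x,
#'   y).
#' @param normalizer from \code{\link{coordNormalizer}}.
#' @param l2 L2 regularization coefficient.
#' @return the scalar error E >= 0.
#' @export
modelError <- function(params, D, normalizer, l2 = 1e-4) {
  if (!nrow(D)) stop("empty data sequence", call. = FALSE)
  O <- networkForward(params, D$t)
  cn <- (2 * O + 1) / (2 * O + 2)
  targets <- .normalizeTargets(D, normalizer)
  n <- nrow(D)
  sum((cn - targets)^2) / (2 * n) +
    if (l2 > 0) l2 / 2 * sum(flattenParams(params)^2) else 0
}

#' Analytic gradient of the model error
#'
#' Backpropagation through the coordinate map, output activation and hidden
#' layer; returns the gradient in the flattened parameter order of
#' \code{\link{flattenParams}} (including the l2 term when l2 > 0).
#'
#' @inheritParams modelError
#' @return numeric gradient vector.
#' @export
modelGradient <- function(params, D, normalizer, l2 = 1e-4) {
  if (!nrow(D)) stop("empty data sequence", call. = FALSE)
  t <- D$t
  n <- length(t)
  h <- .sigmoid(outer(params@w1, t) + params@a)       # H x n
  u <- sweep(crossprod(h, params@w2), 2L, params@b, "-")  # n x K
  O <- .gOut(u)
  cn <- (2 * O + 1) / (2 * O + 2)
  targets <- .normalizeTargets(D, normalizer)
  ## delta at the pre-activation: dE/du
  delta <- ((cn - targets) / n) * (1 / (2 * (O + 1)^2)) * .gOutPrime(u)
  gw2 <- h %*% delta                                  # H x K
  gb <- -colSums(delta)
  dh <- params@w2 %*% t(delta)                        # H x n
  dz <- dh * h * (1 - h)
  gw1 <- as.numeric(dz %*% t)
  ga <- rowSums(dz)
  grad <- c(gw1, ga, as.numeric(gw2), gb)
  if (l2 > 0) grad <- grad + l2 * flattenParams(params)
  grad
}

#' Caputo-type fractional scaling of a gradient
#'
#' Per parameter w with value w0 at training start:
#' D^nu = grad * (|w - w0| + delta)^(1 - nu) / Gamma(2 - nu). At nu = 1
#' this reduces exactly to the ordinary gradient; the delta guard removes
#' the singularity at w = w0 for nu < 1.
#'
#' @param grads ordinary gradient vector.
#' @param w,w0 current and initial parameter vectors.
#' @param nu fractional order in (0, 1].
#' @param delta singularity guard.
#' @return fractional gradient vector.
#' @export
caputoGradient <- function(grads, w, w0, nu = 0.9, delta = 1e-8) {
  if (nu <= 0 || nu > 1) stop("nu must lie in (0, 1]", call. = FALSE)
  grads * (abs(w - w0) + delta)^(1 - nu) / gamma(2 - nu)
}

#' Training configuration
#'
#' Defaults follow the method's reference configuration: learning rate 0.4, momentum 0.9,
#' 1000 epochs, 10 hidden neurons; fractional order 0.9 and L2 coefficient
#' 1e-4 are package defaults (configurable).
#'
#' @param lr learning rate > 0.
#' @param momentum momentum coefficient in [0, 1).
#' @param epochs full-batch epochs >= 1.
#' @param nu fractional order in (0, 1]; nu = 1 is plain backpropagation.
#' @param l2 L2 regularization coefficient.
#' @param delta fractional singularity guard.
#' @param gradScale nominal batch size multiplying the mean-sample
#'   gradient: the descent step is lr * gradScale * dE/dw, the textbook
#'   sum-squared-error step at the default prior-click count (24),
#'   independent of how many clicks the operator actually supplies.
#' @return a validated config list.
#' @export
trainConfig <- function(lr = 0.4, momentum = 0.9, epochs = 1000L, nu = 0.9,
                        l2 = 1e-4, delta = 1e-8, gradScale = 24) {
  if (lr < 0) stop("lr must be >= 0", call. = FALSE)
  if (nu <= 0 || nu > 1) stop("nu must lie in (0, 1]", call. = FALSE)
  if (epochs < 1) stop("epochs must be >= 1", call. = FALSE)
  if (gradScale <= 0) stop("gradScale must be > 0", call. = FALSE)
  list(lr = lr, momentum = momentum, epochs = as.integer(epochs), nu = nu,
       l2 = l2, delta = delta, gradScale = gradScale)
}

#' Train the contour network
#'
#' Full-batch momentum descent on the fractional gradient:
#' v <- momentum v - lr (caputo(gradScale * dE/dw) + l2 w); w <- w + v.
#' The reference learning rate (0.4 with momentum 0.9 over 1000 epochs) is
#' calibrated to the textbook sum-squared-error step, which gradScale
#' reproduces at the nominal click count while keeping the step size
#' independent of the actual number of data rows; \code{modelError}
#' reports the per-sample error E. The Caputo scaling is applied to
#' the data-loss gradient with the lower terminal at the initial weights;
#' the l2 pull is added in integer order. If the error turns non-finite,
#' training stops at the last finite state with a warning.
#'
#' @param paramsInit starting \linkS4class{NetworkParams} (typically the
#'   decoded best candidate of the evolutionary search).
#' @param D data sequence (sorted by t).
#' @param config a \code{\link{trainConfig}}.
#' @param normalizer from \code{\link{coordNormalizer}}; default computed
#'   from D.
#' @return list with \code{params} (the \linkS4class{NetworkParams} after
#'   the final epoch), \code{bestParams} (the epoch with the lowest data
#'   error — momentum can overshoot late in training, so the pipeline uses
#'   this checkpoint), \code{bestEpoch}, and \code{trace} (data.frame
#'   epoch, trainMse).
#' @export
trainNetwork <- function(paramsInit, D, config = trainConfig(),
                         normalizer = coordNormalizer(cbind(D$x, D$y))) {
  stopifnot(is(paramsInit, "NetworkParams"))
  H <- paramsInit@H; K <- paramsInit@K
  w <- flattenParams(paramsInit)
  w0 <- w
  v <- numeric(length(w))
  mse <- numeric(config$epochs)
  lastFinite <- w
  bestW <- w
  bestE <- modelError(paramsInit, D, normalizer, l2 = 0)
  bestEpoch <- 0L
  for (ep in seq_len(config$epochs)) {
    p <- decodeParams(w, H, K)
    g <- config$gradScale * modelGradient(p, D, normalizer, l2 = 0)
    fg <- caputoGradient(g, w, w0, nu = config$nu, delta = config$delta)
    v <- config$momentum * v - config$lr * (fg + config$l2 * w)
    w <- w + v
    e <- modelError(decodeParams(w, H, K), D, normalizer, l2 = 0)
    if (!is.finite(e)) {
      warning("training diverged at epoch ", ep,
              "; returning last finite state")
      w <- lastFinite
      mse <- mse[seq_len(ep - 1L)]
      break
    }
    if (e < bestE) {
      bestE <- e; bestW <- w; bestEpoch <- ep
    }
    lastFinite <- w
    mse[ep] <- e
  }
  list(params = decodeParams(w, H, K),
       bestParams = decodeParams(bestW, H, K),
       bestEpoch = bestEpoch,
       trace = data.frame(epoch = seq_along(mse), trainMse = mse))
}
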