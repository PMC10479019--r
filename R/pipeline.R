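#' End-to-end pipeline configuration
#'
#' Bundles the per-stage settings and the ablation switches. A single
#' global seed fans out to fixed per-stage seeds (seed + stage index) so
#' runs are reproducible regardless of stage internals.
#'
#' @param preprocess run Z-score prior filtering and histogram
#'   equalization.
#' @param zThreshold Z-score cut-off for the prior points.
#' @param nsA,nsB,nsM indeterminacy filter settings (sigma_I = a Ic + b,
#'   window m).
#' @param sH,hMin bandwidth pixel scale and lower clamp.
#' @param mscMode ablation: classic fixed-bandwidth mean shift instead of
#'   the neutrosophic adaptive bandwidth.
#' @param mscBandwidth the fixed bandwidth used in \code{mscMode}, px.
#' @param hidden hidden-unit count of the network.
#' @param mqde a \code{\link{mqdeConfig}}; its \code{plainDE} switch is the
#'   QDE ablation.
#' @param qdeMode ablation: force plain DE/rand/1 weight search.
#' @param train a \code{\link{trainConfig}}.
#' @param bpnnMode ablation: integer-order training (nu = 1, l2 = 0).
#' @param wrapPad periodic-continuation anchor: data-sequence entries with
#'   t below this value are duplicated at t + 1 before training, so the
#'   non-periodic network is pinned across the closure of the contour
#'   (the first vertex's cluster sits at t = 0, leaving the final stretch
#'   of the parameter range without data). 0 disables.
#' @param nSamples contour sampling density.
#' @param seed global seed.
#' @return a config list.
#' @export
pipelineConfig <- function(preprocess = TRUE, zThreshold = 3,
                           nsA = 10, nsB = 0.25, nsM = 5L,
                           sH = 40, hMin = 2,
                           mscMode = FALSE, mscBandwidth = 20,
                           hidden = 10L,
                           mqde = mqdeConfig(), qdeMode = FALSE,
                           train = trainConfig(), bpnnMode = FALSE,
                           wrapPad = 0.04,
                           nSamples = 1000L, seed = 0L) {
  list(preprocess = isTRUE(preprocess), zThreshold = zThreshold,
       nsA = nsA, nsB = nsB, nsM = as.integer(nsM), sH = sH, hMin = hMin,
       mscMode = isTRUE(mscMode), mscBandwidth = mscBandwidth,
       hidden = as.integer(hidden), mqde = mqde, qdeMode = isTRUE(qdeMode),
       train = train, bpnnMode = isTRUE(bpnnMode), wrapPad = wrapPad,
       nSamples = as.integer(nSamples), seed = as.integer(seed))
}

#' Segment an image from prior boundary points
#'
#' Runs the four stages end to end: (1) prior-point Z-score filtering and
#' histogram equalization, neutrosophic channel mapping and indeterminacy
#' filtering, mean-shift vertex discovery and principal-curve projection;
#' (2) evolutionary search of the network's initial weights (objective =
#' model error on the data sequence); (3) fractional-order training; (4)
#' closed-form contour sampling and rasterisation. Deterministic under the
#' config seed.
#'
#' @param image integer matrix, gray levels 0-255.
#' @param priorPoints n x 2 matrix of operator points (>= 8 after
#'   filtering).
#' @param config a \code{\link{pipelineConfig}}.
#' @return list: \code{model} (\linkS4class{ContourModel}), \code{mask},
#'   \code{contour} (sampled polyline), \code{report} (list with per-stage
#'   details: retained priors, curve, data sequence, search and training
#'   traces, formula text, timings).
#' @export
segmentImage <- function(image, priorPoints, config = pipelineConfig()) {
  .assertImage(image)
  .assertPoints(priorPoints, "priorPoints")
  report <- list(config = config)
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()

  ## Stage 1: preprocessing
  pts <- priorPoints
  if (config$preprocess) {
    pts <- zscoreFilter(pts, config$zThreshold)
    image <- histEqualize(image)
  }
  if (nrow(pts) < 8)
    stop("stage preprocess: fewer than 8 prior points survive filtering",
         call. = FALSE)
  report$nPriorRetained <- nrow(pts)

  ## Stage 1: vertex discovery and projection. A closed curve needs at
  ## least 3 vertices; if the bandwidth swallows the whole point set into
  ## fewer clusters, halve it and retry.
  clusterSeed <- config$seed + 1L
  cl <- tryCatch({
    shrink <- 1
    repeat {
      cl <- if (config$mscMode) {
        nsmsCluster(pts, channels = NULL, seed = clusterSeed,
                    fixedBandwidth = config$mscBandwidth * shrink,
                    hMin = config$hMin)
      } else {
        ch <- indeterminacyFilter(mapChannels(image), a = config$nsA,
                                  b = config$nsB, m = config$nsM)
        nsmsCluster(pts, ch, sH = config$sH * shrink, hMin = config$hMin,
                    seed = clusterSeed)
      }
      if (nrow(clusterModes(cl)) >= 3L || shrink <= 1 / 64) break
      shrink <- shrink / 2
      message("fewer than 3 cluster modes; retrying with bandwidth scale ",
              shrink)
    }
    cl
  }, error = function(e) stop("stage nsms: ", conditionMessage(e),
                              call. = FALSE))
  report$modes <- clusterModes(cl)
  t1 <- tic()

  curve <- tryCatch(buildCurve(clusterModes(cl)),
                    error = function(e) stop("stage principal_curve: ",
                                             conditionMessage(e),
                                             call. = FALSE))
  D <- buildDataSequence(curve, pts)
  report$curve <- curve
  report$dataSequence <- D
  t2 <- tic()

  ## Stage 2: evolutionary weight search
  ## periodic continuation across the t = 0/1 seam: the network is not
  ## periodic, so without this the contour is unconstrained between the
  ## largest data t and 1
  Dfit <- D
  if (config$wrapPad > 0) {
    lo <- D[D$t < config$wrapPad, , drop = FALSE]
    if (nrow(lo)) {
      lo$t <- lo$t + 1
      Dfit <- rbind(D, lo)
    }
  }
  normalizer <- coordNormalizer(cbind(D$x, D$y))
  H <- config$hidden
  dim <- 2L * H + (H + 1L) * 2L
  trainCfg <- config$train
  if (config$bpnnMode) {
    trainCfg$nu <- 1
    trainCfg$l2 <- 0
  }
  mqdeCfg <- config$mqde
  mqdeCfg$seed <- config$seed + 2L
  if (config$qdeMode) mqdeCfg$plainDE <- TRUE
  objective <- function(alpha)
    modelError(decodeParams(alpha, H), Dfit, normalizer, l2 = trainCfg$l2)
  search <- tryCatch(mqdeOptimize(objective, dim, mqdeCfg),
                     error = function(e) stop("stage mqde: ",
                                              conditionMessage(e),
                                              call. = FALSE))
  report$searchTrace <- search@fitnessTrace
  t3 <- tic()

  ## Stage 3: fractional-order training
  fit <- tryCatch(trainNetwork(decodeParams(search@best, H), Dfit, trainCfg,
                               normalizer),
                  error = function(e) stop("stage fbnnl: ",
                                           conditionMessage(e),
                                           call. = FALSE))
  report$trainTrace <- fit$trace
  t4 <- tic()

  ## Stage 4: closed-form contour (best-error epoch of the training run)
  model <- new("ContourModel", params = fit$bestParams,
               normalizer = normalizer,
               nSamples = config$nSamples)
  contour <- tryCatch(extractContour(model),
                      error = function(e) stop("stage contour: ",
                                               conditionMessage(e),
                                               call. = FALSE))
  mask <- rasterizeContour(contour, ncol(image), nrow(image))
  report$formula <- contourFormula(model)
  report$timings <- c(nsms = t1 - t0, curve = t2 - t1, mqde = t3 - t2,
                      fbnnl = t4 - t3, contour = tic() - t4)
  list(model = model, mask = mask, contour = contour, report = report)
}

#' Ablation battery
#'
#' Runs the four standard ablation variants on identical inputs and seed:
#' AS1 classic mean shift + plain DE + integer-order training (baseline),
#' AS2 adds the neutrosophic mean shift, AS3 adds the memory-based
#' evolutionary search, AS4 the full method.
#'
#' @param image integer matrix.
#' @param priorPoints n x 2 matrix.
#' @param config base \code{\link{pipelineConfig}}.
#' @param gtMask optional ground truth; when given, metrics are attached.
#' @return list of four run results named AS1-AS4; each has the
#'   \code{\link{segmentImage}} fields plus \code{metrics} when gtMask is
#'   given.
#' @export
ablate <- function(image, priorPoints, config = pipelineConfig(),
                   gtMask = NULL) {
  switches <- list(
    AS1 = c(msc = TRUE,  qde = TRUE,  bpnn = TRUE),
    AS2 = c(msc = FALSE, qde = TRUE,  bpnn = TRUE),
    AS3 = c(msc = FALSE, qde = FALSE, bpnn = TRUE),
    AS4 = c(msc = FALSE, qde = FALSE, bpnn = FALSE))
  lapply(switches, function(sw) {
    cfg <- config
    cfg$mscMode <- unname(sw["msc"])
    cfg$qdeMode <- unname(sw["qde"])
    cfg$bpnnMode <- unname(sw["bpnn"])
    run <- segmentImage(image, priorPoints, cfg)
    if (!is.null(gtMask)) run$metrics <- computeMetrics(run$mask, gtMask)
    run
  })
}
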