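#' Specification of a synthetic ultrasound phantom
#'
#' Describes a star-shaped organ cross-section: a Fourier-perturbed circle
#' r(theta) = baseRadius * (1 + sum_k amp_k cos(harm_k theta + phase_k)),
#' filled with contrasting interior/exterior gray levels, multiplied by
#' unit-mean gamma speckle, optionally darkened inside angular shadow
#' sectors, and annotated with jittered boundary samples standing in for
#' operator clicks. Defaults emulate the resampled clinical resolution
#' (600 x 450) and a plausible manual-click density (24 points, 2 px
#' jitter).
#'
#' @param width,height image size in pixels (>= 32).
#' @param fourierCoeffs list of c(amplitude, harmonic, phase) triples;
#'   amplitude as fraction of the base radius.
#' @param baseRadius base radius in pixels.
#' @param center c(x, y) center in pixel coordinates; default image center.
#' @param insideMean,outsideMean interior/exterior gray levels (0-255, must
#'   differ).
#' @param speckleShape gamma shape of the multiplicative speckle (larger =
#'   weaker speckle); unit mean.
#' @param shadowBands list of c(angle, width, attenuation) triples: pixels
#'   whose polar angle about the center falls within width/2 of angle are
#'   multiplied by attenuation.
#' @param nPrior number of prior boundary points (>= 8).
#' @param priorJitterSd isotropic Gaussian jitter of the prior points, px.
#' @param seed RNG seed; identical specs give bit-identical phantoms.
#' @return a validated list of class \code{phantomSpec}.
#' @export
phantomSpec <- function(width = 600, height = 450,
                        fourierCoeffs = list(c(0.12, 3, 0.6),
                                             c(0.05, 5, 2.1)),
                        baseRadius = 100,
                        center = c((width - 1) / 2, (height - 1) / 2),
                        insideMean = 70, outsideMean = 160,
                        speckleShape = 8,
                        shadowBands = list(),
                        nPrior = 24, priorJitterSd = 2, seed = 0L) {
  spec <- list(width = as.integer(width), height = as.integer(height),
               fourierCoeffs = fourierCoeffs, baseRadius = baseRadius,
               center = as.numeric(center), insideMean = insideMean,
               outsideMean = outsideMean, speckleShape = speckleShape,
               shadowBands = shadowBands, nPrior = as.integer(nPrior),
               priorJitterSd = priorJitterSd, seed = as.integer(seed))
  class(spec) <- "phantomSpec"
  .validatePhantomSpec(spec)
  spec
}

.validatePhantomSpec <- function(spec) {
  if (spec$width < 32 || spec$height < 32)
    stop("width and height must be >= 32", call. = FALSE)
  ampSum <- if (length(spec$fourierCoeffs))
    sum(vapply(spec$fourierCoeffs, function(co) abs(co[1]), numeric(1)))
  else 0
  if (spec$baseRadius * (1 + ampSum) >= min(spec$width, spec$height) / 2)
    stop("contour does not fit: baseRadius*(1+sum|amplitude|) must be < ",
         "min(width, height)/2", call. = FALSE)
  if (spec$nPrior < 8) stop("nPrior must be >= 8", call. = FALSE)
  if (spec$insideMean == spec$outsideMean)
    stop("insideMean must differ from outsideMean", call. = FALSE)
  if (spec$speckleShape <= 0) stop("speckleShape must be > 0", call. = FALSE)
  invisible(spec)
}

.phantomRadius <- function(spec, theta) {
  r <- rep(1, length(theta))
  for (co in spec$fourierCoeffs)
    r <- r + co[1] * cos(co[2] * theta + co[3])
  spec$baseRadius * r
}

#' Generate a synthetic phantom
#'
#' Deterministic under the given seed: the boundary is sampled densely, the
#' ground-truth mask is its even-odd rasterisation, the image is the
#' speckled two-level fill, and the prior points are boundary samples at
#' uniform-random angles plus isotropic Gaussian jitter.
#'
#' @param spec a \code{\link{phantomSpec}}.
#' @param nContourSamples density of the stored ground-truth polyline.
#' @return a \linkS4class{Phantom}.
#' @export
generatePhantom <- function(spec, nContourSamples = 720L) {
  .validatePhantomSpec(spec)
  .withSeed(spec$seed, {
    theta <- 2 * pi * (seq_len(nContourSamples) - 1L) / nContourSamples
    r <- .phantomRadius(spec, theta)
    gtContour <- cbind(x = spec$center[1] + r * cos(theta),
                       y = spec$center[2] + r * sin(theta))
    gtContour <- rbind(gtContour, gtContour[1L, , drop = FALSE])
    gtMask <- rasterizeContour(gtContour, spec$width, spec$height)

    base <- ifelse(gtMask == 1L, spec$insideMean, spec$outsideMean)
    speckle <- matrix(stats::rgamma(length(base), shape = spec$speckleShape,
                                    rate = spec$speckleShape),
                      nrow = nrow(base))
    img <- base * speckle

    if (length(spec$shadowBands)) {
      xs <- matrix(rep(0:(spec$width - 1), each = spec$height),
                   nrow = spec$height)
      ys <- matrix(rep(0:(spec$height - 1), spec$width), nrow = spec$height)
      ang <- atan2(ys - spec$center[2], xs - spec$center[1])
      for (bd in spec$shadowBands) {
        d <- atan2(sin(ang - bd[1]), cos(ang - bd[1]))  # wrapped difference
        img[abs(d) <= bd[2] / 2] <- img[abs(d) <= bd[2] / 2] * bd[3]
      }
    }
    img <- matrix(as.integer(pmin(255, pmax(0, round(img)))),
                  nrow = spec$height)

    thetaP <- stats::runif(spec$nPrior, 0, 2 * pi)
    rP <- .phantomRadius(spec, thetaP)
    priors <- cbind(x = spec$center[1] + rP * cos(thetaP) +
                      stats::rnorm(spec$nPrior, 0, spec$priorJitterSd),
                    y = spec$center[2] + rP * sin(thetaP) +
                      stats::rnorm(spec$nPrior, 0, spec$priorJitterSd))

    new("Phantom", image = img, gtMask = gtMask, gtContour = gtContour,
        priorPoints = priors, spec = unclass(spec))
  })
}

#' Save and load phantoms as plain-text artifacts
#'
#' The image and mask are written as ASCII PGM, the ground-truth contour and
#' prior points as CSV with header x,y; \code{loadPhantom} reproduces image,
#' mask, contour and prior points exactly.
#'
#' @param phantom a \linkS4class{Phantom}.
#' @param directory target directory (created if needed).
#' @return \code{savePhantom} returns the written paths invisibly;
#'   \code{loadPhantom} returns a \linkS4class{Phantom} (with an empty spec,
#'   which is not serialised).
#' @export
savePhantom <- function(phantom, directory) {
  stopifnot(is(phantom, "Phantom"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  paths <- c(image = file.path(directory, "image.pgm"),
             mask = file.path(directory, "gt_mask.pgm"),
             contour = file.path(directory, "gt_contour.csv"),
             priors = file.path(directory, "prior_points.csv"))
  writePGM(phantom@image, paths[["image"]])
  writePGM(phantom@gtMask * 255L, paths[["mask"]])
  writePointsCSV(phantom@gtContour, paths[["contour"]])
  writePointsCSV(phantom@priorPoints, paths[["priors"]])
  invisible(paths)
}

#' @rdname savePhantom
#' @export
loadPhantom <- function(directory) {
  img <- readPGM(file.path(directory, "image.pgm"))
  mask <- readPGM(file.path(directory, "gt_mask.pgm"))
  mask <- matrix(as.integer(mask > 127L), nrow = nrow(mask))
  contour <- readPointsCSV(file.path(directory, "gt_contour.csv"))
  priors <- readPointsCSV(file.path(directory, "prior_points.csv"))
  new("Phantom", image = img, gtMask = mask, gtContour = contour,
      priorPoints = priors, spec = list())
}
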