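#' Segmentation overlap metrics
#'
#' Pixel-count contingency over the whole image: Dice
#' dsc = 2TP/(2TP + FP + FN), Jaccard omg = TP/(TP + FP + FN), accuracy
#' acc = (TP + TN)/total. When both masks are empty all three are 1 by
#' convention (logged).
#'
#' @param pred,gt binary 0/1 matrices of identical shape.
#' @return list with \code{dsc}, \code{omg}, \code{acc}.
#' @export
computeMetrics <- function(pred, gt) {
  if (!all(dim(pred) == dim(gt)))
    stop("mask shape mismatch", call. = FALSE)
  p <- pred > 0; g <- gt > 0
  tp <- sum(p & g); fp <- sum(p & !g); fn <- sum(!p & g); tn <- sum(!p & !g)
  if (tp + fp + fn == 0) {
    message("both masks empty; metrics set to 1 by convention")
    return(list(dsc = 1, omg = 1, acc = 1))
  }
  list(dsc = 2 * tp / (2 * tp + fp + fn),
       omg = tp / (tp + fp + fn),
       acc = (tp + tn) / length(p))
}

#' Salt-and-pepper corruption at a given SNR
#'
#' SNR is the fraction of pixels left uncorrupted: exactly
#' round((1 - snr) * N) distinct pixels are chosen uniformly (seeded) and
#' corrupted, half to 255 (salt) and half to 0 (pepper), with an odd
#' remainder going to salt. Exact-count corruption keeps the contract
#' deterministic and testable.
#'
#' @param image integer matrix, 0-255.
#' @param snr fraction in (0, 1]; 1 returns the image unchanged.
#' @param seed RNG seed.
#' @return corrupted image.
#' @export
saltPepper <- function(image, snr, seed = 0L) {
  .assertImage(image)
  if (snr <= 0 || snr > 1) stop("snr must lie in (0, 1]", call. = FALSE)
  nCorrupt <- round((1 - snr) * length(image))
  if (nCorrupt == 0) return(image)
  .withSeed(seed, {
    idx <- sample.int(length(image), nCorrupt)
    nSalt <- ceiling(nCorrupt / 2)
    out <- image
    out[idx[seq_len(nSalt)]] <- 255L
    if (nSalt < nCorrupt) out[idx[(nSalt + 1L):nCorrupt]] <- 0L
    out
  })
}

#' Gray-level histogram overlap between a clean and a noisy image
#'
#' 256-bin histogram intersection normalised by the clean total:
#' sum_b min(h_clean(b), h_noisy(b)) / sum_b h_clean(b). The denominator is
#' deliberately the clean histogram, so the measure is not symmetric.
#'
#' @param clean,noisy images of identical shape.
#' @return overlap in [0, 1]; 1 when the histograms coincide.
#' @export
histogramOverlap <- function(clean, noisy) {
  .assertImage(clean, "clean"); .assertImage(noisy, "noisy")
  if (!all(dim(clean) == dim(noisy)))
    stop("image shape mismatch", call. = FALSE)
  hc <- tabulate(as.integer(round(clean)) + 1L, nbins = 256L)
  hn <- tabulate(as.integer(round(noisy)) + 1L, nbins = 256L)
  sum(pmin(hc, hn)) / sum(hc)
}

#' Noise-robustness sweep over SNR levels
#'
#' Corrupts the phantom image at each SNR (SNR = 1 uses the clean image),
#' reruns the full segmentation with the same prior points and
#' configuration, and tabulates the histogram overlap and the overlap
#' metrics against the ground truth. Failures are recorded per row and the
#' sweep continues.
#'
#' @param phantom a \linkS4class{Phantom}.
#' @param snrList SNR levels in (0, 1]; default the standard robustness protocol
#'   c(1, 0.8, 0.7, 0.6).
#' @param config a \code{\link{pipelineConfig}}.
#' @return data.frame with columns snr, overlap, dsc, omg, acc, error.
#' @export
robustnessSweep <- function(phantom, snrList = c(1, 0.8, 0.7, 0.6),
                            config = pipelineConfig()) {
  stopifnot(is(phantom, "Phantom"))
  if (any(snrList <= 0 | snrList > 1))
    stop("snrList values must lie in (0, 1]", call. = FALSE)
  rows <- lapply(snrList, function(snr) {
    img <- if (snr == 1) phantom@image
           else saltPepper(phantom@image, snr, seed = config$seed)
    ov <- histogramOverlap(phantom@image, img)
    res <- tryCatch({
      run <- segmentImage(img, phantom@priorPoints, config)
      m <- computeMetrics(run$mask, phantom@gtMask)
      data.frame(snr = snr, overlap = ov, dsc = m$dsc, omg = m$omg,
                 acc = m$acc, error = NA_character_)
    }, error = function(e)
      data.frame(snr = snr, overlap = ov, dsc = NA_real_, omg = NA_real_,
                 acc = NA_real_, error = conditionMessage(e)))
    res
  })
  do.call(rbind, rows)
}
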