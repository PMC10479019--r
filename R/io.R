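## Plain-text image and point I/O. Images travel as ASCII PGM (P2) because
## the toolchain is text-only; points and contours as CSV with header x,y.

.assertImage <- function(image, what = "image") {
  if (!is.matrix(image) || !is.numeric(image))
    stop(what, " must be a numeric matrix", call. = FALSE)
  if (nrow(image) < 1 || ncol(image) < 1)
    stop(what, " must be at least 1 x 1", call. = FALSE)
  if (any(!is.finite(image)) || min(image) < 0 || max(image) > 255)
    stop(what, " values must lie in [0, 255]", call. = FALSE)
  invisible(image)
}

.assertPoints <- function(points, what = "points") {
  if (!is.matrix(points) || ncol(points) != 2L || !is.numeric(points))
    stop(what, " must be an n x 2 numeric matrix", call. = FALSE)
  if (any(!is.finite(points)))
    stop(what, " must have finite coordinates", call. = FALSE)
  invisible(points)
}

#' Read and write plain PGM (P2) grayscale images
#'
#' Minimal ASCII PGM support: 8-bit grayscale, comment lines allowed after
#' the magic number. Used for all image and mask artifacts so every file the
#' package touches is plain text.
#'
#' @param path file path.
#' @param image integer matrix with values in [0, 255]; dim = c(height,
#'   width).
#' @return \code{readPGM} returns the image matrix (storage mode integer);
#'   \code{writePGM} returns \code{path} invisibly.
#' @export
readPGM <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || trimws(lines[1]) != "P2")
    stop("not an ASCII PGM (P2) file: ", path, call. = FALSE)
  body <- lines[-1]
  body <- body[!grepl("^\\s*#", body)]
  tokens <- scan(text = paste(body, collapse = " "), what = numeric(),
                 quiet = TRUE)
  if (length(tokens) < 3) stop("truncated PGM header: ", path, call. = FALSE)
  w <- tokens[1]; h <- tokens[2]; maxval <- tokens[3]
  px <- tokens[-(1:3)]
  if (length(px) != w * h)
    stop("corrupt PGM (expected ", w * h, " pixels, got ", length(px),
         "): ", path, call. = FALSE)
  if (maxval != 255) px <- round(px / maxval * 255)
  img <- matrix(as.integer(px), nrow = h, ncol = w, byrow = TRUE)
  .assertImage(img)
  img
}

#' @rdname readPGM
#' @export
writePGM <- function(image, path) {
  .assertImage(image)
  image <- round(image)
  h <- nrow(image); w <- ncol(image)
  rows <- apply(image, 1L, paste, collapse = " ")
  writeLines(c("P2", paste(w, h), "255", rows), path)
  invisible(path)
}

#' Read and write point sets as CSV
#'
#' CSV with header \code{x,y}, one point per row, pixel coordinates
#' (x = column, y = row, 0-based).
#'
#' @param path file path.
#' @param points n x 2 numeric matrix.
#' @return \code{readPointsCSV} returns an n x 2 matrix with columns x, y.
#' @export
readPointsCSV <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character")
  if (!all(c("x", "y") %in% names(df)))
    stop("CSV must have header x,y: ", path, call. = FALSE)
  if (nrow(df) == 0) stop("no prior points in ", path, call. = FALSE)
  xs <- suppressWarnings(as.numeric(df$x))
  ys <- suppressWarnings(as.numeric(df$y))
  bad <- which(is.na(xs) | is.na(ys))
  if (length(bad))
    stop("non-numeric point at row ", bad[1], " of ", path, call. = FALSE)
  cbind(x = xs, y = ys)
}

#' @rdname readPointsCSV
#' @export
writePointsCSV <- function(points, path) {
  .assertPoints(points)
  ## %.17g so the decimal text round-trips doubles exactly
  utils::write.csv(data.frame(x = sprintf("%.17g", points[, 1]),
                              y = sprintf("%.17g", points[, 2])),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## Run expr with a locally seeded RNG, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}
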