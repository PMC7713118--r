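#' @useDynLib topimg, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm kmeans approx
#' @importFrom grDevices contourLines
#' @importFrom utils read.csv write.csv capture.output
#' @importFrom tools file_ext
NULL

#' Grayscale image container
#'
#' A grayscale image is a numeric matrix of intensities, nominally on the
#' \[0, 1\] scale (0 = black, 1 = white), interpreted as the scalar field of
#' the sublevel-set filtration. Values may leave \[0, 1\] transiently inside
#' the pipeline (e.g. after unclamped noise injection); they are quantized
#' back to 8 bits only on file write.
#'
#' @param values numeric matrix (rows x cols) of finite intensities.
#' @return An object of class `gray_image` (a numeric matrix).
#' @examples
#' img <- gray_image(matrix(runif(12), 3, 4))
#' image_diagonal(img)
#' @export
gray_image <- function(values) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("intensities must be numeric")
  if (nrow(values) < 1 || ncol(values) < 1) stop("image must be non-empty")
  if (any(!is.finite(values))) stop("intensities must be finite")
  storage.mode(values) <- "double"
  class(values) <- c("gray_image", class(matrix()))
  values
}

#' @rdname gray_image
#' @param img object to coerce / query.
#' @export
as_gray_image <- function(img) {
  if (inherits(img, "gray_image")) return(img)
  if (is.array(img) && length(dim(img)) == 3L) return(to_gray(img))
  gray_image(img)
}

#' @rdname gray_image
#' @export
image_diagonal <- function(img) {
  d <- dim(as_gray_image(img))
  sqrt(d[1]^2 + d[2]^2)
}

#' RGB image container
#'
#' An H x W x 3 integer array with channel values in \[0, 255\].
#'
#' @param pixels numeric H x W x 3 array.
#' @return An object of class `rgb_image`.
#' @export
rgb_image <- function(pixels) {
  pixels <- as.array(pixels)
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("an RGB image must be an H x W x 3 array")
  if (dim(pixels)[1] < 2 || dim(pixels)[2] < 2)
    stop("image dimensions must be at least 2 x 2")
  if (any(pixels < 0 | pixels > 255) || any(!is.finite(pixels)))
    stop("channel values must lie in [0, 255]")
  class(pixels) <- c("rgb_image", class(array(0)))
  pixels
}

#' Binary mask container
#'
#' @param values logical or 0/1 numeric matrix.
#' @return An object of class `binary_mask` (a logical matrix).
#' @export
binary_mask <- function(values) {
  values <- as.matrix(values)
  if (is.numeric(values)) {
    if (!all(values %in% c(0, 1))) stop("mask values must be 0 or 1")
    values <- values == 1
  }
  if (!is.logical(values)) stop("mask must be logical or 0/1")
  class(values) <- c("binary_mask", class(matrix()))
  values
}

#' Convert an RGB image to grayscale
#'
#' Uses the standard linear luma converter
#' `gray = (299 R + 587 G + 114 B) / 1000`, rescaled to \[0, 1\] by division
#' by 255. Already-gray inputs (R = G = B = v) map exactly to v / 255.
#'
#' @param img an `rgb_image`, an H x W x 3 array, or a numeric matrix
#'   (returned as-is after validation).
#' @return A `gray_image`.
#' @examples
#' px <- array(0, c(2, 2, 3)); px[, , 1] <- 255
#' to_gray(rgb_image(px))[1, 1] # 76.245 / 255
#' @export
to_gray <- function(img) {
  if (is.matrix(img)) return(gray_image(img))
  if (!is.array(img) || length(dim(img)) != 3L)
    stop("expected an RGB array or a numeric matrix")
  g <- (299 * img[, , 1] + 587 * img[, , 2] + 114 * img[, , 3]) / 1000
  gray_image(g / 255)
}

#' Inject tie-breaking noise
#'
#' Adds i.i.d. zero-mean normal noise with standard deviation `sigma` (on
#' the \[0, 1\] intensity scale) so that all pixel values are distinct with
#' probability 1 and every birth in the persistence diagram maps to a unique
#' pixel. Deterministic given `seed`; values are not clamped. If a duplicate
#' value survives (numerically possible), the noise is re-drawn once.
#'
#' @param img a `gray_image` or numeric matrix.
#' @param sigma noise standard deviation, >= 0. The default corresponds to a
#'   variance of 0.01.
#' @param seed integer RNG seed.
#' @return A `gray_image`.
#' @export
add_noise <- function(img, sigma = 0.1, seed = 0L) {
  img <- as_gray_image(img)
  if (length(sigma) != 1 || !is.finite(sigma) || sigma < 0)
    stop("sigma must be a single non-negative number")
  if (sigma == 0) return(img)
  out <- withr::with_seed(as.integer(seed), {
    noisy <- img + rnorm(length(img), 0, sigma)
    if (anyDuplicated(noisy)) noisy <- img + rnorm(length(img), 0, sigma)
    noisy
  })
  gray_image(matrix(out, nrow(img), ncol(img)))
}
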