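#' Topological image modification parameters
#'
#' Container for the knobs of the modification stage: the box-smoothing
#' window side `k` (odd, pixels), the border band width `l` (pixels), the
#' tie-breaking noise level `sigma` (standard deviation on the \[0, 1\]
#' intensity scale), the RNG `seed`, and the `polarity` ("dark" objects in
#' a light background, the default, or "light" which negates the image
#' first so the superlevel filtration is captured).
#'
#' @param k odd positive integer.
#' @param l positive integer, less than half the smaller image side.
#' @param sigma noise standard deviation, >= 0.
#' @param seed integer RNG seed.
#' @param polarity `"dark"` or `"light"`.
#' @return A `tim_params` list.
#' @export
tim_params <- function(k = 3L, l = 1L, sigma = 0.1, seed = 0L,
                       polarity = c("dark", "light")) {
  polarity <- match.arg(polarity)
  k <- as.integer(k); l <- as.integer(l)
  if (k < 1L || k %% 2L == 0L) stop("k must be an odd positive integer")
  if (l < 1L) stop("l must be a positive integer")
  if (sigma < 0) stop("sigma must be non-negative")
  structure(list(k = k, l = l, sigma = sigma, seed = as.integer(seed),
                 polarity = polarity),
            class = "tim_params")
}

#' Default modification parameters from the image diagonal
#'
#' The heuristics scale with the diagonal length \eqn{\Delta(I) =
#' \sqrt{H^2 + W^2}} of the image: the smoothing window is
#' \eqn{k \sim \Delta(I)/25} (rounded, bumped up by one if even, floored at
#' 3) and the border band is \eqn{l \sim \Delta(I)/100} (rounded, floored
#' at 1). Noise defaults to variance 0.01 (`sigma = 0.1`).
#'
#' @param img a [gray_image], numeric matrix or [rgb_image].
#' @param sigma,seed,polarity passed through to [tim_params()].
#' @return A `tim_params` list.
#' @examples
#' p <- default_params(gray_image(matrix(0, 480, 640))) # diagonal 800
#' c(p$k, p$l) # 33, 8
#' @export
default_params <- function(img, sigma = 0.1, seed = 0L, polarity = "dark") {
  img <- as_gray_image(img)
  delta <- image_diagonal(img)
  k <- round(delta / 25)
  if (k %% 2 == 0) k <- k + 1
  k <- max(3, k)
  l <- max(1, round(delta / 100))
  if (l >= min(dim(img)) / 2)
    stop("image too small for the default border band")
  tim_params(k = k, l = l, sigma = sigma, seed = seed, polarity = polarity)
}

#' Box smoothing restricted to the image
#'
#' Each output pixel is the arithmetic mean of the input values in the
#' k x k window centred at it and clipped to the image: near the borders
#' the divisor is the number of valid pixels, not \eqn{k^2}. Destroys
#' small-scale topological features (outlying pixels, thin hair-like
#' curves) while preserving large objects. `k = 1` is the identity.
#'
#' @param img a [gray_image] or numeric matrix.
#' @param k odd window side.
#' @return A `gray_image`.
#' @export
smooth_image <- function(img, k) {
  img <- as_gray_image(img)
  k <- as.integer(k)
  if (k < 1L || k %% 2L == 0L) stop("k must be an odd positive integer")
  if (k == 1L) return(img)
  h <- (k - 1L) %/% 2L
  sums <- box_sum(unclass(img), h)
  counts <- box_sum(matrix(1, nrow(img), ncol(img)), h)
  gray_image(sums / counts)
}

# sum over (2h+1)^2 windows clipped to the image, via an integral image
box_sum <- function(m, h) {
  H <- nrow(m); W <- ncol(m)
  S <- matrix(0, H + 1L, W + 1L)
  S[-1, -1] <- apply(apply(m, 2, cumsum), 1, cumsum) |> t()
  r1 <- pmax(seq_len(H) - h, 1L); r2 <- pmin(seq_len(H) + h, H)
  c1 <- pmax(seq_len(W) - h, 1L); c2 <- pmin(seq_len(W) + h, W)
  S[r2 + 1L, c2 + 1L, drop = FALSE] - S[r1, c2 + 1L, drop = FALSE] -
    S[r2 + 1L, c1, drop = FALSE] + S[r1, c1, drop = FALSE]
}

#' Border modification
#'
#' Sets every pixel within Chebyshev distance `l` of the image border (an
#' l-pixel frame) to the lowest value of the image minus a small offset
#' `delta`, leaving interior pixels unchanged. The frame is then strictly
#' the earliest birth of the filtration, so by the elder rule the single
#' infinitely-persisting component is the frame itself, and every object
#' that touches the frame is born through it rather than appearing as a
#' separate finite point. All remaining finite points can then be analysed
#' for significance.
#'
#' @param img a [gray_image] or numeric matrix.
#' @param l band width in pixels, `1 <= l < min(H, W) / 2`.
#' @param delta offset below the global minimum used for the band value.
#' @return A `gray_image`.
#' @export
border_modify <- function(img, l, delta = 1e-6) {
  img <- as_gray_image(img)
  l <- as.integer(l)
  H <- nrow(img); W <- ncol(img)
  if (l < 1L) stop("l must be a positive integer")
  if (l >= min(H, W) / 2) stop("border band would cover the whole image")
  out <- unclass(img)
  band_value <- min(out) - delta
  idx <- seq_len(l)
  out[c(idx, H + 1L - idx), ] <- band_value
  out[, c(idx, W + 1L - idx)] <- band_value
  gray_image(out)
}

#' Full topological image modification pipeline
#'
#' Applies, in order: polarity negation (for light objects), tie-breaking
#' noise, box smoothing, border modification. Deterministic given the seed
#' in `params`.
#'
#' @param img a [gray_image], numeric matrix or [rgb_image].
#' @param params a [tim_params] object; default derived from the image.
#' @return A `gray_image`.
#' @export
tim_modify <- function(img, params = default_params(img)) {
  img <- as_gray_image(img)
  if (params$polarity == "light") img <- gray_image(1 - unclass(img))
  img <- add_noise(img, params$sigma, params$seed)
  img <- smooth_image(img, params$k)
  border_modify(img, params$l)
}
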